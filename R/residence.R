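#' Water survival probability around a residue selection
#'
#' Continuous (strict) survival: S(t) is the average, over time origins
#' t0, of the fraction of waters inside the shell at t0 that remain inside
#' at *every* frame of t0..t0+t. A water that exits and re-enters does not
#' survive. Shell membership is the minimum oxygen-to-selection heavy-atom
#' distance being at most `cutoff`. Origins with an empty shell are
#' skipped; if no origin has a water in the shell the curve is flagged
#' undefined.
#'
#' @param window an aligned `md_trajectory`.
#' @param selection either a function of the topology returning a logical
#'   atom mask, or a list with any of `residue_name`, `residue_id`,
#'   `chain` to match residues.
#' @param cutoff shell radius, Angstrom (default 3.6).
#' @param max_lag_ps maximum lag; default half the window length.
#' @return A `survival_curve`: `lags` (ps, starting at 0), `values`
#'   (in \[0,1\], non-increasing), `n_origins`, `undefined` flag.
#' @export
survival_probability <- function(window, selection, cutoff = 3.6,
                                 max_lag_ps = NULL) {
  topo <- window$topology
  mask <- selection_mask(topo, selection)
  if (!any(mask))
    stop("selection matches no residue in the topology")
  mask <- mask & topo$element != "H"
  nf <- n_frames(window)
  dt <- window$frame_interval_ps
  if (is.null(max_lag_ps)) max_lag_ps <- floor(nf / 2) * dt
  max_lag <- min(nf - 1L, max(1L, round(max_lag_ps / dt)))
  nW <- dim(window$water_xyz)[1]
  if (nW == 0L)
    return(structure(list(lags = (0:max_lag) * dt,
                          values = rep(NA_real_, max_lag + 1L),
                          n_origins = 0L, undefined = TRUE),
                     class = "survival_curve"))
  inside <- matrix(FALSE, nW, nf)
  for (f in seq_len(nf)) {
    sel <- window$protein_xyz[mask, , f, drop = FALSE][, , 1, drop = FALSE]
    sel <- matrix(sel, ncol = 3)
    w <- matrix(window$water_xyz[, , f], ncol = 3)
    # min distance of each water to the selection
    d2min <- rep(Inf, nW)
    for (a in seq_len(nrow(sel)))
      d2min <- pmin(d2min, colSums((t(w) - sel[a, ])^2))
    inside[, f] <- d2min <= cutoff^2
  }
  # L[w, f]: length of the in-shell run starting at frame f (0 if outside)
  L <- matrix(0L, nW, nf)
  L[, nf] <- as.integer(inside[, nf])
  for (f in (nf - 1L):1L)
    L[, f] <- ifelse(inside[, f], 1L + L[, f + 1L], 0L)
  origins <- seq_len(nf - max_lag)
  S <- numeric(max_lag + 1L)
  n_used <- 0L
  for (f in origins) {
    n0 <- sum(inside[, f])
    if (n0 == 0L) next
    n_used <- n_used + 1L
    # surviving to lag t (frames) means run length >= t+1
    surv <- vapply(0:max_lag, function(t) sum(L[, f] >= t + 1L), numeric(1))
    S <- S + surv / n0
  }
  if (n_used == 0L)
    return(structure(list(lags = (0:max_lag) * dt,
                          values = rep(NA_real_, max_lag + 1L),
                          n_origins = 0L, undefined = TRUE),
                     class = "survival_curve"))
  structure(list(lags = (0:max_lag) * dt, values = S / n_used,
                 n_origins = n_used, undefined = FALSE),
            class = "survival_curve")
}

selection_mask <- function(topo, selection) {
  if (is.function(selection)) return(selection(topo))
  if (!is.list(selection))
    stop("selection must be a function or a list of residue fields")
  mask <- rep(TRUE, nrow(topo))
  if (!is.null(selection$residue_name))
    mask <- mask & topo$residue_name %in% selection$residue_name
  if (!is.null(selection$residue_id))
    mask <- mask & topo$residue_id %in% selection$residue_id
  if (!is.null(selection$chain))
    mask <- mask & topo$chain_id %in% selection$chain
  mask
}

#' @export
print.survival_curve <- function(x, ...) {
  if (x$undefined) cat("<survival_curve> undefined (no occupied origins)\n")
  else cat(sprintf("<survival_curve> %d lags to %.1f ps, %d origins, S(end)=%.3f\n",
                   length(x$lags), max(x$lags), x$n_origins,
                   x$values[length(x$values)]))
  invisible(x)
}

#' Residence time from a survival curve
#'
#' Trapezoidal integral of S(t) over its lags. Undefined curves propagate
#' NA. When S at the last lag exceeds 0.05 the value underestimates the
#' true residence time (truncated tail); a `truncated` attribute flags
#' this.
#'
#' @param curve a `survival_curve`.
#' @return residence time tau in ps (NA for undefined curves), with
#'   attribute `truncated`.
#' @export
residence_time <- function(curve) {
  if (curve$undefined || anyNA(curve$values))
    return(structure(NA_real_, truncated = NA))
  tau <- pracma::trapz(curve$lags, curve$values)
  structure(tau, truncated = curve$values[length(curve$values)] > 0.05)
}

#' Residence times averaged over trajectory windows
#'
#' Computes the survival probability and residence time in each window and
#' reports the per-window values plus their mean.
#'
#' @param windows list of aligned `md_trajectory` windows.
#' @param selection residue selection (see [survival_probability()]).
#' @param cutoff shell radius, Angstrom.
#' @param max_lag_ps maximum survival lag, ps (default half a window).
#' @return list with `tau` (mean over defined windows, ps), `window_values`
#'   (per-window taus), `se` (standard error over windows).
#' @export
residence_time_windows <- function(windows, selection, cutoff = 3.6,
                                   max_lag_ps = NULL) {
  taus <- vapply(windows, function(w) {
    as.numeric(residence_time(
      survival_probability(w, selection, cutoff, max_lag_ps)))
  }, numeric(1))
  ok <- !is.na(taus)
  list(tau = mean(taus[ok]), window_values = taus,
       se = if (sum(ok) > 1) sd(taus[ok]) / sqrt(sum(ok)) else NA_real_)
}
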