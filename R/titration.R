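#' Read a lambda-coordinate trace
#'
#' Plain-text constant-pH output: whitespace-separated columns, time (ps)
#' and lambda; comment lines starting with `#` or `@` are skipped.
#'
#' @param path file path.
#' @return data.frame with `time` and `lambda`.
#' @export
read_lambda_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, comment.char = "#",
                    col.names = c("time", "lambda"),
                    colClasses = "numeric")
  if (!nrow(tab)) stop("empty lambda trace: ", path)
  if (any(!is.finite(tab$lambda))) stop("non-finite lambda in ", path)
  tab
}

#' Deprotonation fraction from a lambda trace
#'
#' Counts protonated samples (lambda below `lambda_low`) and deprotonated
#' samples (lambda above `lambda_high`); intermediate lambdas are
#' discarded. The default convention reports the deprotonated fraction
#' `n_deprot / (n_prot + n_deprot)`, which rises with pH; the
#' complementary `"printed"` convention reports
#' `n_prot / (n_prot + n_deprot)`. The two conventions sum to one on any
#' trace with countable samples.
#'
#' @param lambda numeric vector of lambda samples (or a data.frame from
#'   [read_lambda_trace()]).
#' @param lambda_low,lambda_high state thresholds (defaults 0.2 / 0.8).
#' @param convention "deprotonated" (default) or "printed".
#' @return list with `s_deprot` (NA with `undefined = TRUE` when no sample
#'   is countable), `n_prot`, `n_deprot`, `undefined`.
#' @export
deprotonation_fraction <- function(lambda, lambda_low = 0.2,
                                   lambda_high = 0.8,
                                   convention = c("deprotonated", "printed")) {
  convention <- match.arg(convention)
  if (is.data.frame(lambda)) lambda <- lambda$lambda
  if (!length(lambda)) stop("empty lambda trace")
  n_prot <- sum(lambda < lambda_low)
  n_deprot <- sum(lambda > lambda_high)
  if (n_prot + n_deprot == 0L)
    return(list(s_deprot = NA_real_, n_prot = 0L, n_deprot = 0L,
                undefined = TRUE))
  num <- if (convention == "deprotonated") n_deprot else n_prot
  list(s_deprot = num / (n_prot + n_deprot), n_prot = as.integer(n_prot),
       n_deprot = as.integer(n_deprot), undefined = FALSE)
}

#' Fit a titration curve (Henderson-Hasselbalch / Hill)
#'
#' Least-squares fit of `S(pH) = 1 / (1 + 10^(hill_n * (pKa - pH)))` to
#' deprotonation fractions. Initialised at the pH nearest S = 0.5 with
#' hill_n = 1; hill_n bounded to \[0.2, 4\]. Degenerate data (all fractions
#' near 0 or all near 1) leave the midpoint outside the sampled range and
#' are flagged unbounded.
#'
#' @param pH numeric vector of pH values.
#' @param s_deprot deprotonation fractions at those pH values (NA points
#'   dropped).
#' @param hill_bounds lower/upper bound on hill_n.
#' @return list with `pKa`, `hill_n`, `residual_norm`, `n_points`,
#'   `unbounded` flag, `warning` (NULL or text).
#' @export
fit_pka <- function(pH, s_deprot, hill_bounds = c(0.2, 4)) {
  keep <- is.finite(pH) & is.finite(s_deprot)
  pH <- pH[keep]; s <- s_deprot[keep]
  if (length(pH) < 3L) stop("need >= 3 titration points")
  warn <- NULL
  if (min(s) > 0.5 || max(s) < 0.5)
    warn <- "titration points do not span the transition midpoint"
  if (all(s < 0.05) || all(s > 0.95))
    return(list(pKa = NA_real_, hill_n = NA_real_, residual_norm = NA_real_,
                n_points = length(pH), unbounded = TRUE,
                warning = "degenerate all-protonated/all-deprotonated data"))
  pka0 <- pH[which.min(abs(s - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ 1 / (1 + 10^(hill * (pka - pH))),
                      start = list(pka = pka0, hill = 1),
                      lower = c(pka = min(pH) - 20, hill = hill_bounds[1]),
                      upper = c(pka = max(pH) + 20, hill = hill_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("titration fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  list(pKa = unname(est["pka"]), hill_n = unname(est["hill"]),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       n_points = length(pH), unbounded = FALSE, warning = warn)
}

#' Build a titration record for one residue
#'
#' Computes per-pH deprotonation fractions from lambda traces and fits the
#' pKa.
#'
#' @param traces named list of lambda vectors (or trace data.frames), names
#'   are the pH values.
#' @param residue_id residue identifier carried through.
#' @param lambda_low,lambda_high state thresholds.
#' @param convention fraction convention (see [deprotonation_fraction()]).
#' @return list with `residue_id`, `points` (data.frame: `pH`, `s_deprot`,
#'   `n_prot`, `n_deprot`), `pKa`, `hill_n`, `fit`.
#' @export
titration_record <- function(traces, residue_id = NA_integer_,
                             lambda_low = 0.2, lambda_high = 0.8,
                             convention = "deprotonated") {
  pH <- as.numeric(names(traces))
  if (any(is.na(pH))) stop("trace names must be numeric pH values")
  pts <- do.call(rbind, lapply(seq_along(traces), function(i) {
    fr <- deprotonation_fraction(traces[[i]], lambda_low, lambda_high,
                                 convention)
    data.frame(pH = pH[i], s_deprot = fr$s_deprot, n_prot = fr$n_prot,
               n_deprot = fr$n_deprot)
  }))
  pts <- pts[order(pts$pH), ]
  rownames(pts) <- NULL
  fit <- fit_pka(pts$pH, pts$s_deprot)
  list(residue_id = residue_id, points = pts, pKa = fit$pKa,
       hill_n = fit$hill_n, fit = fit)
}

#' Group residues by fitted pKa
#'
#' Bins: `always_deprotonated` for pKa in \[2, 4), `mid` for \[4, 5),
#' `anomalous` for pKa above 7; anything else is `unclassified`.
#'
#' @param pKa numeric vector of fitted pKa values (names = residue labels).
#' @return factor of group labels, same length/names as `pKa`.
#' @export
classify_pka_groups <- function(pKa) {
  grp <- ifelse(is.na(pKa), "unclassified",
         ifelse(pKa >= 2 & pKa < 4, "always_deprotonated",
         ifelse(pKa >= 4 & pKa < 5, "mid",
         ifelse(pKa > 7, "anomalous", "unclassified"))))
  factor(setNames(grp, names(pKa)),
         levels = c("always_deprotonated", "mid", "anomalous",
                    "unclassified"))
}
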