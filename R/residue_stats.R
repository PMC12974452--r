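# Bondi-style van der Waals radii (Angstrom) for ASA
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

#' Hopp-Woods hydrophilicity scale
#'
#' Per-residue hydrophilicity values (positive = hydrophilic), the default
#' covariate for [hydration_correlation()].
#'
#' @return named numeric vector over the 20 amino-acid types.
#' @export
hopp_woods_scale <- function() {
  c(ARG = 3.0, ASP = 3.0, GLU = 3.0, LYS = 3.0, SER = 0.3, ASN = 0.2,
    GLN = 0.2, GLY = 0.0, PRO = 0.0, THR = -0.4, ALA = -0.5, HIS = -0.5,
    CYS = -1.0, MET = -1.3, VAL = -1.5, ILE = -1.8, LEU = -1.8,
    TYR = -2.3, PHE = -2.5, TRP = -3.4)
}

#' Count bound waters per residue and per residue type
#'
#' A water is bound to a residue when the residue has a heavy atom within
#' `cutoff` of the water oxygen. In `"multi"` mode (default) a water
#' counts once for every residue it contacts, so per-type totals aggregate
#' additively; `"nearest"` mode assigns each water only to its single
#' nearest residue within the cutoff.
#'
#' @param model a `structure_model` with waters partitioned.
#' @param cutoff Angstrom (default 3.6).
#' @param mode "multi" or "nearest".
#' @return list with `per_residue` (data.frame: `chain`, `residue_id`,
#'   `residue_name`, `n_waters`) covering every protein residue,
#'   `per_type` (named vector over residue types present), and
#'   `condition_label`.
#' @export
count_bound_waters <- function(model, cutoff = 3.6,
                               mode = c("multi", "nearest")) {
  mode <- match.arg(mode)
  keep <- is_protein_atom(model) & model$atoms$element != "H"
  pa <- model$atoms[keep, , drop = FALSE]
  reskey <- paste(pa$chain_id, pa$residue_id, pa$residue_name, sep = "|")
  resdf <- unique(data.frame(chain = pa$chain_id,
                             residue_id = pa$residue_id,
                             residue_name = pa$residue_name, key = reskey,
                             stringsAsFactors = FALSE))
  counts <- setNames(integer(nrow(resdf)), resdf$key)
  wpos <- water_coords(model)
  pm <- t(as.matrix(pa[, c("x", "y", "z")]))
  if (nrow(wpos)) {
    for (i in seq_len(nrow(wpos))) {
      d <- sqrt(colSums((pm - wpos[i, ])^2))
      if (mode == "multi") {
        hit <- unique(reskey[d <= cutoff])
      } else {
        j <- which.min(d)
        hit <- if (d[j] <= cutoff) reskey[j] else character(0)
      }
      counts[hit] <- counts[hit] + 1L
    }
  }
  resdf$n_waters <- as.integer(counts[resdf$key])
  resdf$key <- NULL
  rownames(resdf) <- NULL
  per_type <- tapply(resdf$n_waters, resdf$residue_name, sum)
  list(per_residue = resdf,
       per_type = setNames(as.integer(per_type), names(per_type)),
       condition_label = model$condition_label)
}

#' Total modeled waters in a model
#'
#' The number of water records, reported alongside the occupancy-weighted
#' sum (symmetry-axis waters deposited at occupancy 0.25/0.33/0.5
#' contribute fractionally to the weighted total).
#'
#' @param model a `structure_model`.
#' @return list with `count` (integer) and `weighted` (numeric).
#' @export
total_bound_waters <- function(model) {
  w <- which(is_water_oxygen(model))
  list(count = length(w), weighted = sum(model$atoms$occupancy[w]))
}

# deterministic, roughly uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Numeric ASA over the protein heavy atoms: each atom's van der Waals
#' sphere is inflated by the probe radius and sampled with a deterministic
#' golden-spiral point set; the accessible fraction (points not occluded by
#' any neighbouring inflated sphere) times the sphere area is the atom's
#' ASA, summed per residue.
#'
#' @param model a `structure_model`.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return list with `per_residue` (data.frame: `chain`, `residue_id`,
#'   `residue_name`, `asa`), `per_type` (named vector, Angstrom^2),
#'   `per_atom` (numeric vector), `probe`, `n_points`.
#' @export
accessible_surface_area <- function(model, probe = 1.4, n_points = 960) {
  keep <- is_protein_atom(model) & model$atoms$element != "H"
  pa <- model$atoms[keep, , drop = FALSE]
  if (!nrow(pa)) stop("no protein heavy atoms")
  unknown <- setdiff(unique(pa$element), names(.VDW_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- .VDW_RADII[pa$element] + probe
  pos <- as.matrix(pa[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  n <- nrow(pos)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- r[i]
    d2 <- colSums((t(pos) - pos[i, ])^2)
    nb <- which(d2 < (Ri + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * Ri, 2, pos[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- colSums((t(surf[free, , drop = FALSE]) - pos[j, ])^2)
      free[free] <- dj2 > r[j]^2
    }
    asa[i] <- mean(free) * 4 * pi * Ri^2
  }
  reskey <- paste(pa$chain_id, pa$residue_id, pa$residue_name, sep = "|")
  per_res <- tapply(asa, reskey, sum)
  parts <- do.call(rbind, strsplit(names(per_res), "|", fixed = TRUE))
  per_residue <- data.frame(chain = parts[, 1],
                            residue_id = as.integer(parts[, 2]),
                            residue_name = parts[, 3],
                            asa = as.numeric(per_res),
                            stringsAsFactors = FALSE)
  per_residue <- per_residue[order(per_residue$chain,
                                   per_residue$residue_id), ]
  rownames(per_residue) <- NULL
  per_type <- tapply(per_residue$asa, per_residue$residue_name, sum)
  list(per_residue = per_residue,
       per_type = setNames(as.numeric(per_type), names(per_type)),
       per_atom = asa, probe = probe, n_points = n_points)
}

# ordinary least-squares trend with correlation diagnostics
trend_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired points")
  if (sd(x) == 0) stop("zero-variance covariate")
  fit <- lm(y ~ x)
  r <- cor(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = r, r_squared = r^2, n_points = length(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope %.4g, intercept %.4g, r %.3f (R^2 %.3f), n=%d\n",
              x$slope, x$intercept, x$pearson_r, x$r_squared, x$n_points))
  invisible(x)
}

#' Correlate per-type water counts with a residue-type covariate
#'
#' Ordinary least squares of bound-water counts per amino-acid type on a
#' per-type covariate, typically total accessible surface area or a
#' hydrophilicity scale ([hopp_woods_scale()]).
#'
#' @param counts named numeric vector of water counts per residue type.
#' @param covariate named numeric vector; matched to `counts` by name.
#' @return A `trend_fit` (slope, intercept, pearson_r, r_squared,
#'   n_points).
#' @export
hydration_correlation <- function(counts, covariate) {
  common <- intersect(names(counts), names(covariate))
  if (length(common) < 3L)
    stop("need >= 3 residue types shared between counts and covariate")
  trend_fit(as.numeric(covariate[common]), as.numeric(counts[common]))
}

#' Desolvation trend: total bound waters versus pH
#'
#' Least-squares line of per-condition total water counts on pH. A
#' positive slope means waters are gained as pH rises (equivalently,
#' released on acidification).
#'
#' @param totals numeric vector of total water counts, one per condition.
#' @param pH numeric vector of pH values.
#' @return A `trend_fit` whose `slope` is waters per pH unit.
#' @export
desolvation_trend <- function(totals, pH) {
  if (length(totals) < 3L) stop("need >= 3 conditions")
  trend_fit(pH, totals)
}

#' Water-to-protein distance distribution
#'
#' Per-water minimum distance to any protein heavy atom, histogrammed at
#' `bin_width`; the interquartile range serves as a flatness scalar (a
#' broader, flatter distribution has a larger IQR).
#'
#' @param model a `structure_model` with waters.
#' @param bin_width histogram bin width, Angstrom.
#' @return list with `distances`, `breaks`, `counts`, `iqr`, `median`.
#' @export
water_protein_distance_distribution <- function(model, bin_width = 0.1) {
  wpos <- water_coords(model)
  if (!nrow(wpos)) {
    return(list(distances = numeric(0), breaks = numeric(0),
                counts = integer(0), iqr = NA_real_, median = NA_real_))
  }
  pm <- t(protein_coords(model))
  d <- vapply(seq_len(nrow(wpos)),
              function(i) sqrt(min(colSums((pm - wpos[i, ])^2))),
              numeric(1))
  breaks <- seq(floor(min(d) / bin_width) * bin_width,
                ceiling(max(d) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  list(distances = d, breaks = h$breaks, counts = h$counts,
       iqr = unname(diff(quantile(d, c(0.25, 0.75)))), median = median(d))
}
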