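#' Analysis configuration
#'
#' Collects every numeric cutoff used across the pipeline in one object so a
#' run can be described (and logged) by a single config. Defaults are the
#' values used throughout the package's reference analysis: waters are
#' clustered across superposed models at 1.0 Angstrom, residues are assigned
#' within 3.6 Angstrom, MD water density is accumulated on a 0.5 Angstrom
#' grid in a 5 Angstrom shell and thresholded at 6 kg/L after neighbour
#' smoothing, and lambda traces are binarised at 0.2 / 0.8.
#'
#' @param cluster_cutoff Angstrom; single-linkage cutoff for cross-condition
#'   water clustering (strictly smaller distances link).
#' @param residue_cutoff Angstrom; nearest-residue assignment and bound-water
#'   counting cutoff.
#' @param shell_cutoff Angstrom; hydration-shell extent around the protein
#'   for density grids and ion-water contacts.
#' @param grid_spacing Angstrom; voxel edge length of the density grid.
#' @param density_threshold kg/L; minimum smoothed water density for a voxel
#'   to seed a hydration site.
#' @param merge_distance Angstrom; density peaks strictly closer than this
#'   are merged into one site.
#' @param lambda_low,lambda_high lambda thresholds: samples below
#'   `lambda_low` count as protonated, above `lambda_high` as deprotonated,
#'   in between are discarded.
#' @param symmetry_tolerance Angstrom; distances within this of the minimum
#'   count as ties when detecting symmetry-axis solvent sites.
#' @param smoothing_neighbors 6 (face-adjacent) or 18 (face- or
#'   edge-adjacent) voxel neighbourhood for density smoothing.
#' @param site_position "weighted" (density-weighted mean of merged peaks)
#'   or "unweighted".
#' @param hbond_distance Angstrom; flag ion-water contacts at or below this
#'   as hydrogen-bond range.
#' @param probe_radius Angstrom; solvent probe for accessible surface area.
#' @param asa_points sphere points per atom for Shrake-Rupley ASA.
#' @param max_lag_frac fraction of the window length used as the maximum
#'   survival-probability lag.
#' @param s_deprot_convention "deprotonated" reports
#'   n_deprot/(n_prot+n_deprot); "printed" reports the complementary
#'   n_prot/(n_prot+n_deprot).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cluster_cutoff = 1.0,
                            residue_cutoff = 3.6,
                            shell_cutoff = 5.0,
                            grid_spacing = 0.5,
                            density_threshold = 6,
                            merge_distance = 1.0,
                            lambda_low = 0.2,
                            lambda_high = 0.8,
                            symmetry_tolerance = 1e-3,
                            smoothing_neighbors = 6,
                            site_position = c("weighted", "unweighted"),
                            hbond_distance = 3.5,
                            probe_radius = 1.4,
                            asa_points = 960,
                            max_lag_frac = 0.5,
                            s_deprot_convention = c("deprotonated", "printed")) {
  site_position <- match.arg(site_position)
  s_deprot_convention <- match.arg(s_deprot_convention)
  cutoffs <- c(cluster_cutoff = cluster_cutoff, residue_cutoff = residue_cutoff,
               shell_cutoff = shell_cutoff, grid_spacing = grid_spacing,
               density_threshold = density_threshold,
               merge_distance = merge_distance,
               symmetry_tolerance = symmetry_tolerance,
               hbond_distance = hbond_distance, probe_radius = probe_radius)
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("all cutoffs must be finite and > 0")
  if (!is.finite(lambda_low) || !is.finite(lambda_high) ||
      lambda_low >= lambda_high)
    stop("lambda_low must be < lambda_high")
  if (!smoothing_neighbors %in% c(6L, 18L))
    stop("smoothing_neighbors must be 6 or 18")
  if (asa_points < 8) stop("asa_points must be >= 8")
  if (max_lag_frac <= 0 || max_lag_frac > 1)
    stop("max_lag_frac must be in (0, 1]")
  structure(list(
    cluster_cutoff = cluster_cutoff, residue_cutoff = residue_cutoff,
    shell_cutoff = shell_cutoff, grid_spacing = grid_spacing,
    density_threshold = density_threshold, merge_distance = merge_distance,
    lambda_low = lambda_low, lambda_high = lambda_high,
    symmetry_tolerance = symmetry_tolerance,
    smoothing_neighbors = as.integer(smoothing_neighbors),
    site_position = site_position, hbond_distance = hbond_distance,
    probe_radius = probe_radius, asa_points = as.integer(asa_points),
    max_lag_frac = max_lag_frac,
    s_deprot_convention = s_deprot_convention
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
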