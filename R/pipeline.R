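write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_manifest <- function(out_dir, inputs, outputs, config, stages) {
  man <- list(
    config = unclass(config),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = stages,
    package_version = as.character(utils::packageVersion("hydroshell")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the full structure-ensemble analysis
#'
#' Reads labeled models, superposes all conditions on a reference (the
#' label `"pH7"`/`"pH7.0"` when present, else the middle condition),
#' assigns solvent chains, clusters waters across conditions, classifies
#' persistence, assigns nearest residues, computes nearest water-water
#' distance distributions with pairwise KS statistics, per-condition total
#' and per-type bound-water counts, the desolvation trend versus pH, and
#' (when ions are present) ion-center distances and ion-water contacts.
#' Results are written as TSV/JSON plus a manifest with input/output
#' checksums.
#'
#' @param model_paths character vector of PDB paths named by condition
#'   label (labels like `"pH7"` are parsed for the numeric pH).
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @param reference condition label to superpose on, or NULL for the
#'   default rule.
#' @param ion_elements elements to analyse when present.
#' @return invisibly, a list with all in-memory results (`models`, `wss`,
#'   `persistence`, `distances`, `totals`, `trend`, `ions`, `paths`).
#' @export
run_structure_pipeline <- function(model_paths, out_dir,
                                   config = analysis_config(),
                                   reference = NULL,
                                   ion_elements = c("FE", "MG")) {
  if (length(model_paths) < 2L)
    stop("structure pipeline needs >= 2 labeled models")
  labels <- names(model_paths)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("model_paths must be named by condition label")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  models <- mapply(function(p, lab) read_structure(p, condition_label = lab),
                   model_paths, labels, SIMPLIFY = FALSE)
  stages$read <- "ok"
  if (is.null(reference)) {
    hit <- grep("^pH7(\\.0*)?$", labels)
    reference <- if (length(hit)) labels[hit[1]]
                 else labels[ceiling(length(labels) / 2)]
  }
  ref <- mark_superposed(models[[reference]])
  models <- lapply(models, function(m) {
    if (m$condition_label == reference) return(ref)
    apply_transform(m, superpose(m, ref, min_pair_frac = 0.9))
  })
  stages$superpose <- "ok"
  models <- lapply(models, assign_solvent_chains,
                   tol = config$symmetry_tolerance)
  stages$assign_chains <- "ok"
  wss <- cluster_waters(models, cutoff = config$cluster_cutoff)
  wss <- assign_nearest_residue(wss, models[[reference]],
                                cutoff = config$residue_cutoff)
  persistence <- classify_persistence(wss)
  prefs <- residue_preferences(wss)
  stages$persistence <- "ok"
  distances <- nearest_water_distances(wss)
  stages$distances <- "ok"
  totals <- vapply(models, function(m) total_bound_waters(m)$count,
                   numeric(1))
  pH <- suppressWarnings(as.numeric(sub("^pH", "", labels)))
  trend <- if (all(is.finite(pH)) && length(pH) >= 3)
    desolvation_trend(unname(totals), pH) else NULL
  stages$trend <- if (is.null(trend)) "skipped (labels not numeric pH)"
                  else "ok"
  ions <- list()
  for (el in ion_elements) {
    present <- any(vapply(models, function(m)
      any(is_ion(m) & m$atoms$element == el), logical(1)))
    if (!present) next
    icd <- ion_center_distances(models, el)
    contacts <- lapply(seq_len(nrow(icd)), function(i) {
      m <- models[[icd$condition[i]]]
      sel <- which(is_ion(m) & m$atoms$element == el &
                     m$atoms$residue_id == icd$residue_id[i] &
                     m$atoms$chain_id == icd$chain[i])[1]
      ion_water_contacts(as.numeric(m$atoms[sel, c("x", "y", "z")]),
                         icd$condition[i], wss,
                         shell = config$shell_cutoff,
                         hbond_distance = config$hbond_distance)
    })
    ions[[el]] <- list(center_distances = icd, contacts = contacts)
  }
  stages$metals <- if (length(ions)) "ok" else "skipped (no ions)"
  # report bundle
  outs <- c(
    write_tsv(wss$sites, file.path(out_dir, "sites.tsv")),
    write_tsv(wss$members, file.path(out_dir, "members.tsv")),
    write_tsv(persistence$per_condition,
              file.path(out_dir, "per_condition_counts.tsv")),
    write_tsv(data.frame(n_conditions = names(persistence$histogram),
                         n_clusters = as.integer(persistence$histogram)),
              file.path(out_dir, "persistence_histogram.tsv")),
    write_tsv(data.frame(residue = names(prefs),
                         count = as.integer(prefs)),
              file.path(out_dir, "residue_preferences.tsv")),
    write_tsv(do.call(rbind, lapply(distances$distributions, function(d)
      data.frame(category = d$category, count = d$count,
                 median = d$median, q1 = d$q1, q3 = d$q3))),
      file.path(out_dir, "distance_distributions.tsv")),
    write_tsv(as.data.frame(distances$ks_matrix),
              file.path(out_dir, "ks_matrix.tsv")))
  cond_json <- file.path(out_dir, "condition_counts.json")
  jsonlite::write_json(
    list(totals = as.list(totals),
         trend = if (is.null(trend)) NULL else unclass(trend)),
    cond_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  outs <- c(outs, cond_json)
  if (length(ions))
    for (el in names(ions))
      outs <- c(outs, write_tsv(ions[[el]]$center_distances,
                                file.path(out_dir,
                                          paste0("ions_", el, ".tsv"))))
  run_manifest(out_dir, as.list(model_paths), as.list(outs), config, stages)
  invisible(list(models = models, wss = wss, persistence = persistence,
                 preferences = prefs, distances = distances,
                 totals = totals, trend = trend, ions = ions,
                 reference = reference, out_dir = out_dir))
}

#' Run the trajectory analysis (hydration sites + residence times)
#'
#' Samples windows, aligns each on the trajectory's first-frame protein
#' conformation, accumulates the water density grid per window, averages
#' the grids, smooths, detects hydration sites, assigns each site its
#' majority-vote residue and frame occupancy, and computes residence times
#' for a residue selection averaged over windows.
#'
#' @param traj an `md_trajectory` (see [read_trajectory_xyz()] /
#'   [read_trajectory_pdb()] / [generate_trajectory()]).
#' @param out_dir output directory.
#' @param window_frames frames per window.
#' @param interval_ns window anchor spacing, ns.
#' @param config an [analysis_config()].
#' @param selection residue selection for residence times (default all
#'   glutamates), or NULL to skip.
#' @return invisibly, list with `sites` (data.frame incl. residue and
#'   occupancy), `residence`, `grid` (averaged, smoothed), `windows_used`.
#' @export
run_trajectory_pipeline <- function(traj, out_dir, window_frames,
                                    interval_ns,
                                    config = analysis_config(),
                                    selection = list(residue_name = "GLU")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  windows <- sample_windows(traj, window_frames, interval_ns)
  reference <- traj$protein_xyz[, , 1]
  aligned <- lapply(windows, function(w) align_window(w, reference)$window)
  grids <- lapply(aligned, accumulate_density, config = config,
                  reference_protein = reference)
  grid <- grids[[1]]
  if (length(grids) > 1) {
    for (g in grids[-1]) grid$values <- grid$values + g$values
    grid$values <- grid$values / length(grids)
  }
  grid <- smooth_density(grid, config)
  sites <- detect_sites(grid, config)
  if (nrow(sites)) {
    res <- lapply(seq_len(nrow(sites)), function(i)
      assign_site_residue(as.numeric(sites[i, c("x", "y", "z")]),
                          aligned[[1]]))
    sites$residue_name <- vapply(res, `[[`, character(1), "residue_name")
    sites$residue_id <- vapply(res, `[[`, integer(1), "residue_id")
    sites$chain <- vapply(res, `[[`, character(1), "chain")
    sites$occupancy <- vapply(seq_len(nrow(sites)), function(i)
      mean(vapply(aligned, function(w)
        site_occupancy(as.numeric(sites[i, c("x", "y", "z")]), w,
                       cutoff = 1.2), numeric(1))), numeric(1))
  }
  residence <- NULL
  if (!is.null(selection)) {
    residence <- residence_time_windows(aligned, selection,
                                        cutoff = config$residue_cutoff)
  }
  outs <- write_tsv(sites, file.path(out_dir, "sites.tsv"))
  if (!is.null(residence)) {
    outs <- c(outs, write_tsv(
      data.frame(tau_ps = residence$tau, se = residence$se,
                 t(setNames(residence$window_values,
                            paste0("window_", seq_along(
                              residence$window_values))))),
      file.path(out_dir, "tau.tsv")))
  }
  run_manifest(out_dir, list(), as.list(outs), config,
               list(windows = length(windows), align = "ok",
                    density = "ok", sites = nrow(sites),
                    residence = if (is.null(residence)) "skipped" else "ok"))
  invisible(list(sites = sites, residence = residence, grid = grid,
                 windows_used = length(windows), out_dir = out_dir))
}

#' Run the titration analysis from a trace manifest
#'
#' Reads a JSON manifest mapping residue ids to per-pH lambda trace files,
#' computes deprotonation fractions, fits per-residue pKa values and
#' classifies the pKa groups.
#'
#' @param manifest_path JSON manifest (residue id -> named list of files
#'   keyed by pH), as written by [generate_lambda_traces()].
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @return invisibly, list with `records` (per-residue titration records),
#'   `table` (data.frame: residue_id, pKa, hill_n, group).
#' @export
run_titration_pipeline <- function(manifest_path, out_dir,
                                   config = analysis_config()) {
  man <- jsonlite::read_json(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- dirname(manifest_path)
  records <- lapply(names(man), function(rid) {
    files <- man[[rid]]
    traces <- lapply(files, function(f) {
      p <- if (file.exists(f[[1]])) f[[1]] else file.path(base,
                                                          basename(f[[1]]))
      read_lambda_trace(p)$lambda
    })
    titration_record(traces, residue_id = as.integer(rid),
                     lambda_low = config$lambda_low,
                     lambda_high = config$lambda_high,
                     convention = config$s_deprot_convention)
  })
  tab <- data.frame(
    residue_id = vapply(records, `[[`, integer(1), "residue_id"),
    pKa = vapply(records, `[[`, numeric(1), "pKa"),
    hill_n = vapply(records, `[[`, numeric(1), "hill_n"))
  tab$group <- as.character(classify_pka_groups(tab$pKa))
  outs <- c(write_tsv(tab, file.path(out_dir, "pka.tsv")),
            write_tsv(do.call(rbind, lapply(records, function(r)
              cbind(residue_id = r$residue_id, r$points))),
              file.path(out_dir, "titration_points.tsv")))
  run_manifest(out_dir, list(manifest_path), as.list(outs), config,
               list(residues = length(records)))
  invisible(list(records = records, table = tab, out_dir = out_dir))
}
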