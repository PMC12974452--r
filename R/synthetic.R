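# sidechain tip atom (name, element) used for each residue type on the
# toy scaffold
.SIDECHAIN_TIP <- list(
  ALA = c("CB", "C"),  ARG = c("NH1", "N"), ASN = c("OD1", "O"),
  ASP = c("OD1", "O"), CYS = c("SG", "S"),  GLN = c("OE1", "O"),
  GLU = c("OE1", "O"), GLY = c("CA2", "C"), HIS = c("ND1", "N"),
  ILE = c("CD1", "C"), LEU = c("CD1", "C"), LYS = c("NZ", "N"),
  MET = c("SD", "S"),  PHE = c("CZ", "C"),  PRO = c("CG", "C"),
  SER = c("OG", "O"),  THR = c("OG1", "O"), TRP = c("NE1", "N"),
  TYR = c("OH", "O"),  VAL = c("CG1", "C"))

#' Deterministic toy protein scaffold
#'
#' A rigid poly-residue ring with all 20 amino-acid types represented:
#' residue i sits at angle 2*pi*i/n on a circle of radius `radius`, with a
#' backbone C-alpha and a type-specific sidechain tip atom 1.5 Angstrom
#' further out; z alternates to break planarity. No randomness: the
#' scaffold is identical across calls, so condition ensembles share an
#' exact common frame.
#'
#' @param n_repeats how many times the 20-type sequence repeats.
#' @param chain_id chain identifier.
#' @param radius ring radius, Angstrom.
#' @param arc_frac fraction of the full circle the chain spans (1 = closed
#'   ring; smaller values give an open arc, used by [toy_assembly()]).
#' @return A `structure_model`.
#' @export
toy_protein_scaffold <- function(n_repeats = 2, chain_id = "A", radius = 12,
                                 arc_frac = 1) {
  types <- rep(.AA3, n_repeats)
  n <- length(types)
  theta <- 2 * pi * arc_frac * (seq_len(n) - 1) / n
  zz <- rep(c(-1.5, 1.5), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    tip <- .SIDECHAIN_TIP[[types[i]]]
    dirv <- c(cos(theta[i]), sin(theta[i]))
    data.frame(
      record = "ATOM",
      element = c("C", tip[2]),
      atom_name = c("CA", tip[1]),
      residue_name = types[i],
      residue_id = i,
      chain_id = chain_id,
      insert = "",
      x = c(radius * dirv[1], (radius + 1.5) * dirv[1]),
      y = c(radius * dirv[2], (radius + 1.5) * dirv[2]),
      z = c(zz[i], zz[i] + 0.5),
      occupancy = 1, b_factor = 20,
      stringsAsFactors = FALSE)
  })
  structure_model(do.call(rbind, rows), "scaffold")
}

#' Cyclic multi-chain toy assembly
#'
#' Replicates a single-chain scaffold n-fold by rotation about the z axis
#' (chains A, B, C, ...). A solvent atom on the axis is equidistant, at
#' identical within-chain atom indices, to every chain: the symmetry-axis
#' occupancy test case.
#'
#' @param n_chains number of chains (2-24).
#' @param ... passed to [toy_protein_scaffold()].
#' @return A `structure_model`.
#' @export
toy_assembly <- function(n_chains = 4, ...) {
  stopifnot(n_chains >= 2, n_chains <= 24)
  # each chain spans 80% of its sector so chains never overlap in space
  base <- toy_protein_scaffold(chain_id = "A",
                               arc_frac = 0.8 / n_chains, ...)
  rows <- lapply(seq_len(n_chains), function(k) {
    ang <- 2 * pi * (k - 1) / n_chains
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
    a <- base$atoms
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$chain_id <- LETTERS[k]
    a
  })
  structure_model(do.call(rbind, rows), "assembly")
}

# place n points near randomly chosen scaffold heavy atoms, at contact
# distance, pairwise separations >= min_sep among themselves and
# >= avoid_sep from the `avoid` set; errors when packing is infeasible
place_shell_sites <- function(scaffold, n, min_sep = 3.0,
                              avoid = NULL, avoid_sep = min_sep,
                              avoid2 = NULL, avoid2_sep = min_sep,
                              contact = c(2.6, 3.4),
                              max_tries = 2000L) {
  pm <- protein_coords(scaffold)
  placed <- matrix(NA_real_, 0, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- pm[sample.int(nrow(pm), 1), ]
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p <- a + u * runif(1, contact[1], contact[2])
      if (!is.null(avoid) && nrow(avoid) &&
          min(sqrt(colSums((t(avoid) - p)^2))) < avoid_sep) next
      if (!is.null(avoid2) && nrow(avoid2) &&
          min(sqrt(colSums((t(avoid2) - p)^2))) < avoid2_sep) next
      if (nrow(placed) &&
          min(sqrt(colSums((t(placed) - p)^2))) < min_sep) next
      # stay at contact range: not buried inside the scaffold
      if (min(sqrt(colSums((t(pm) - p)^2))) < contact[1] - 0.4) next
      placed <- rbind(placed, p)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("infeasible packing: cannot place ", n, " sites with ",
           "min_sep = ", min_sep, " Angstrom")
  }
  dimnames(placed) <- NULL
  placed
}

# uniform placement in the hydration-shell volume (protein distance in
# `range`), >= avoid_sep from `avoid` and >= min_sep mutually and from
# `prior`; chunked rejection sampling
place_filler_sites <- function(scaffold, n, min_sep = 1.2, avoid = NULL,
                               avoid_sep = 3.0, prior = NULL,
                               range = c(2.2, 5.0), max_rounds = 200L) {
  if (n == 0L) return(matrix(NA_real_, 0, 3))
  pm <- protein_coords(scaffold)
  lo <- apply(pm, 2, min) - range[2]
  hi <- apply(pm, 2, max) + range[2]
  accepted <- matrix(NA_real_, 0, 3)
  others <- rbind(prior, accepted)
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(accepted)
    if (need == 0L) break
    cand <- cbind(runif(4L * need + 50L, lo[1], hi[1]),
                  runif(4L * need + 50L, lo[2], hi[2]),
                  runif(4L * need + 50L, lo[3], hi[3]))
    dprot <- apply(cand, 1, function(p)
      sqrt(min(colSums((t(pm) - p)^2))))
    cand <- cand[dprot >= range[1] & dprot <= range[2], , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (!is.null(avoid) && nrow(avoid) &&
          min(colSums((t(avoid) - p)^2)) < avoid_sep^2) next
      if (nrow(others) &&
          min(colSums((t(others) - p)^2)) < min_sep^2) next
      accepted <- rbind(accepted, p)
      others <- rbind(others, p)
      if (nrow(accepted) == n) break
    }
  }
  if (nrow(accepted) < n)
    stop("infeasible packing: placed ", nrow(accepted), " of ", n,
         " filler waters at min_sep = ", min_sep, " Angstrom")
  dimnames(accepted) <- NULL
  accepted
}

# isotropic Gaussian jitter with the displacement norm truncated at
# 2.4*sigma, so members of a shared site always stay mutually linkable at
# a cutoff of 5*sigma or more (the clean-recovery regime)
truncated_jitter <- function(n, sigma) {
  if (sigma <= 0) return(matrix(0, n, 3))
  out <- matrix(rnorm(3 * n, 0, sigma), ncol = 3)
  bad <- sqrt(rowSums(out^2)) > 2.4 * sigma
  while (any(bad)) {
    out[bad, ] <- matrix(rnorm(3 * sum(bad), 0, sigma), ncol = 3)
    bad <- sqrt(rowSums(out^2)) > 2.4 * sigma
  }
  out
}

water_rows <- function(pos, start_id = 1001L) {
  if (!nrow(pos)) return(NULL)
  data.frame(record = "HETATM", element = "O", atom_name = "O",
             residue_name = "HOH",
             residue_id = start_id + seq_len(nrow(pos)) - 1L,
             chain_id = "A", insert = "",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             occupancy = 1, b_factor = 30, stringsAsFactors = FALSE)
}

#' Generate a multi-condition ensemble with planted water persistence
#'
#' Writes one PDB per condition: an identical toy scaffold plus waters.
#' Shared ("persistent") sites appear, Gaussian-jittered, in the conditions
#' designated by `persistence_map` (default: all); each condition also
#' receives `n_lone_per_condition` unique sites far from everything else.
#' With `desolvation_slope` set, extra unique filler waters bring the
#' per-condition totals onto the line
#' `total = intercept + slope * pH + N(0, total_noise_sd)`.
#' All placements respect a minimum separation of `2 * cluster_cutoff` or
#' more so that clean-recovery clustering is exact. Ground truth is
#' serialized as JSON next to the models.
#'
#' @param out_dir output directory (created if needed).
#' @param pH_labels numeric pH values, one condition each.
#' @param n_persistent_sites sites shared across conditions.
#' @param n_lone_per_condition unique sites per condition.
#' @param jitter_sigma Angstrom; isotropic Gaussian jitter of shared
#'   sites, displacement norm truncated at 2.4 sigma so shared sites stay
#'   linkable whenever `jitter_sigma < cluster_cutoff / 2` (the
#'   clean-recovery regime).
#' @param persistence_map logical matrix sites x conditions (default all
#'   TRUE).
#' @param desolvation_slope waters per pH unit, or NULL for no filler.
#' @param desolvation_intercept waters at pH 0 (default chosen so every
#'   condition needs a non-negative filler count).
#' @param total_noise_sd Gaussian noise on target totals.
#' @param min_separation Angstrom between distinct planted sites
#'   (default 3).
#' @param filler_min_sep Angstrom between filler waters (default 1.2,
#'   above the 1.0 clustering cutoff so each filler stays a singleton
#'   lone site).
#' @param scaffold a `structure_model` to decorate; default a three-repeat
#'   toy scaffold of radius 18 Angstrom, large enough to host
#'   desolvation-series water counts.
#' @param seed integer RNG seed; runs are byte-identical given the seed.
#' @return list with `paths` (named by condition label), `ground_truth`
#'   (also written to `ground_truth.json`).
#' @export
generate_condition_ensemble <- function(out_dir,
                                        pH_labels = c(3.5, 4, 5, 7, 9),
                                        n_persistent_sites = 20,
                                        n_lone_per_condition = 7,
                                        jitter_sigma = 0.2,
                                        persistence_map = NULL,
                                        desolvation_slope = NULL,
                                        desolvation_intercept = NULL,
                                        total_noise_sd = 0,
                                        min_separation = 3.0,
                                        filler_min_sep = 1.2,
                                        scaffold = NULL,
                                        seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(scaffold))
    scaffold <- toy_protein_scaffold(n_repeats = 3, radius = 18)
  n_cond <- length(pH_labels)
  labels <- paste0("pH", format(pH_labels, trim = TRUE))
  if (is.null(persistence_map))
    persistence_map <- matrix(TRUE, n_persistent_sites, n_cond)
  stopifnot(nrow(persistence_map) == n_persistent_sites,
            ncol(persistence_map) == n_cond)
  shared <- place_shell_sites(scaffold, n_persistent_sites, min_separation)
  # lone sites keep min_separation from shared sites AND from the lone
  # sites of every other condition, so they can never bridge
  avoid_all <- shared
  lone <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    lone[[ci]] <- place_shell_sites(scaffold, n_lone_per_condition,
                                    min_separation, avoid = avoid_all)
    avoid_all <- rbind(avoid_all, lone[[ci]])
  }
  base_counts <- colSums(persistence_map) + n_lone_per_condition
  n_filler <- rep(0L, n_cond)
  if (!is.null(desolvation_slope)) {
    if (is.null(desolvation_intercept))
      desolvation_intercept <-
        max(base_counts) + 5 + 5 * total_noise_sd -
          min(desolvation_slope * pH_labels)
    target <- round(desolvation_intercept + desolvation_slope * pH_labels +
                      rnorm(n_cond, 0, total_noise_sd))
    n_filler <- as.integer(target - base_counts)
    if (any(n_filler < 0))
      stop("desolvation targets below the planted base counts; raise the ",
           "intercept")
  }
  # filler waters stay clear of the planted sites (so persistence classes
  # are undisturbed) but may pack tighter among themselves, down to
  # filler_min_sep; each remains a singleton lone site as long as
  # filler_min_sep exceeds the clustering cutoff
  planted <- avoid_all   # shared + lone: keep filler min_separation away
  filler_acc <- matrix(NA_real_, 0, 3)
  filler <- lapply(seq_len(n_cond), function(ci) {
    if (n_filler[ci] == 0L) return(matrix(NA_real_, 0, 3))
    p <- place_filler_sites(scaffold, n_filler[ci],
                            min_sep = filler_min_sep,
                            avoid = planted, avoid_sep = min_separation,
                            prior = filler_acc)
    filler_acc <<- rbind(filler_acc, p)
    p
  })
  paths <- character(n_cond)
  totals <- integer(n_cond)
  for (ci in seq_len(n_cond)) {
    present <- which(persistence_map[, ci])
    wpos <- rbind(
      if (length(present))
        shared[present, , drop = FALSE] +
          truncated_jitter(length(present), jitter_sigma),
      lone[[ci]], filler[[ci]])
    atoms <- rbind(scaffold$atoms, water_rows(wpos))
    model <- structure_model(atoms, labels[ci])
    paths[ci] <- file.path(out_dir, paste0(labels[ci], ".pdb"))
    write_structure(model, paths[ci])
    totals[ci] <- nrow(wpos)
  }
  names(paths) <- labels
  gt <- list(seed = seed, pH = pH_labels, labels = labels,
             n_persistent_sites = n_persistent_sites,
             n_lone_per_condition = n_lone_per_condition,
             jitter_sigma = jitter_sigma,
             persistence_map = persistence_map,
             shared_sites = shared,
             totals = totals, n_filler = n_filler,
             desolvation_slope = desolvation_slope,
             desolvation_intercept = desolvation_intercept)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       digits = 10, auto_unbox = TRUE, pretty = TRUE)
  list(paths = paths, ground_truth = gt)
}

write_xyz_trajectory <- function(path, elements, xyz) {
  # xyz: natoms x 3 x nframes
  natoms <- dim(xyz)[1]; nf <- dim(xyz)[3]
  blocks <- vapply(seq_len(nf), function(f) {
    m <- xyz[, , f, drop = FALSE][, , 1, drop = FALSE]
    paste(c(natoms, paste("frame", f),
            sprintf("%s %.4f %.4f %.4f", elements, m[, 1, 1], m[, 2, 1],
                    m[, 3, 1])),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Generate a toy trajectory with planted hydration sites
#'
#' A static scaffold is surrounded by one water per planted site. Each
#' water alternates between a bound state (site position plus Gaussian
#' jitter) and an unbound state (parked in a far bulk reservoir outside
#' the analysis shell), with exponentially distributed bound dwell times
#' of mean `tau_ps` and a two-state chain whose stationary bound fraction
#' is the site occupancy; re-entry is allowed. Optional background waters
#' are redrawn uniformly in the box every frame at the requested bulk
#' density. The generator plants statistics (densities, occupancies,
#' lifetimes), not water physics.
#'
#' @param out_dir output directory, or NULL to skip writing files.
#' @param n_frames number of frames.
#' @param frame_interval_ps frame spacing, ps.
#' @param sites data.frame with `x`, `y`, `z`, `occupancy`, `tau_ps`; or
#'   NULL to place `n_sites` automatically near the scaffold.
#' @param n_sites,occupancy_range,tau_ps defaults used when `sites` is
#'   NULL: site count, per-site occupancy range, common mean dwell time.
#' @param near_residue optional residue-name filter: auto-placed sites
#'   attach only to atoms of these residue types (e.g. `"GLU"`).
#' @param jitter_sigma Angstrom; spatial width of a bound water.
#' @param bulk_density kg/L of background water (0 disables).
#' @param box_margin Angstrom added around the scaffold for the bulk box.
#' @param scaffold a `structure_model`; default [toy_protein_scaffold()].
#' @param seed integer RNG seed.
#' @return list with `trajectory` (an `md_trajectory`), `paths`
#'   (`topology`, `xyz`, `ground_truth` or NULL), `ground_truth`.
#' @export
generate_trajectory <- function(out_dir = NULL, n_frames = 1000,
                                frame_interval_ps = 2, sites = NULL,
                                n_sites = 12,
                                occupancy_range = c(0.6, 0.95),
                                tau_ps = 10, near_residue = NULL,
                                jitter_sigma = 0.15, bulk_density = 1,
                                box_margin = 7, scaffold = NULL,
                                seed = 1L) {
  set.seed(seed)
  if (is.null(scaffold)) scaffold <- toy_protein_scaffold()
  if (is.null(sites)) {
    sc <- scaffold
    if (!is.null(near_residue)) {
      keep <- is_protein_atom(sc) & sc$atoms$residue_name %in% near_residue
      if (!any(keep)) stop("near_residue matches no scaffold residue")
      sc <- structure_model(sc$atoms[keep, , drop = FALSE], "sel")
    }
    if (n_sites > 0L) {
      pos <- place_shell_sites(sc, n_sites, min_sep = 3.0,
                               contact = c(2.6, 3.2))
      sites <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          occupancy = runif(n_sites, occupancy_range[1],
                                            occupancy_range[2]),
                          tau_ps = rep(tau_ps, length.out = n_sites))
    } else {
      sites <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          occupancy = numeric(0), tau_ps = numeric(0))
    }
  }
  ns <- nrow(sites)
  pm <- protein_coords(scaffold)
  lo <- apply(pm, 2, min) - box_margin
  hi <- apply(pm, 2, max) + box_margin
  vol <- prod(hi - lo)
  # bulk number density per A^3 from mass density in kg/L
  n_bulk <- round(bulk_density * .A3_TO_L / .WATER_MASS_KG * vol)
  if (bulk_density * .A3_TO_L / .WATER_MASS_KG * 0.5^3 > 1)
    warning("bulk density implies > 1 water per 0.5 Angstrom voxel")
  dt <- frame_interval_ps
  nW <- ns + n_bulk
  wxyz <- array(NA_real_, c(max(nW, 1L), 3, n_frames))
  far <- hi + 15   # bulk reservoir, outside every analysis shell
  for (s in seq_len(ns)) {
    occ <- sites$occupancy[s]
    tau <- sites$tau_ps[s]
    p_off <- if (occ >= 1) 0 else 1 - exp(-dt / tau)
    p_on <- if (occ >= 1) 1 else min(1, p_off * occ / (1 - occ))
    state <- runif(1) < occ
    ctr <- as.numeric(sites[s, c("x", "y", "z")])
    for (f in seq_len(n_frames)) {
      wxyz[s, , f] <- if (state) ctr + rnorm(3, 0, jitter_sigma)
                      else far + runif(3, 0, 5)
      state <- if (state) runif(1) > p_off else runif(1) < p_on
    }
  }
  if (n_bulk > 0) {
    for (f in seq_len(n_frames))
      wxyz[ns + seq_len(n_bulk), , f] <-
        cbind(runif(n_bulk, lo[1], hi[1]), runif(n_bulk, lo[2], hi[2]),
              runif(n_bulk, lo[3], hi[3]))
  }
  if (nW == 0L) wxyz <- array(NA_real_, c(0, 3, n_frames))
  pxyz <- array(rep(as.matrix(scaffold$atoms[
    is_protein_atom(scaffold), c("x", "y", "z")]), n_frames),
    c(sum(is_protein_atom(scaffold)), 3, n_frames))
  topo <- scaffold$atoms[is_protein_atom(scaffold), , drop = FALSE]
  traj <- md_trajectory(topo, pxyz, wxyz[seq_len(nW), , , drop = FALSE],
                        frame_interval_ps)
  gt <- list(seed = seed, n_frames = n_frames,
             frame_interval_ps = frame_interval_ps,
             sites = sites, n_bulk = n_bulk, bulk_density = bulk_density,
             jitter_sigma = jitter_sigma,
             box = list(lo = lo, hi = hi))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    topo_path <- file.path(out_dir, "topology.pdb")
    first_w <- wxyz[seq_len(nW), , 1, drop = FALSE][, , 1, drop = FALSE]
    wr <- water_rows(matrix(first_w, ncol = 3))
    write_structure(structure_model(rbind(topo, wr), "trajectory"),
                    topo_path)
    xyz_path <- file.path(out_dir, "trajectory.xyz")
    elements <- c(topo$element, rep("O", nW))
    allxyz <- array(NA_real_, c(nrow(topo) + nW, 3, n_frames))
    allxyz[seq_len(nrow(topo)), , ] <- pxyz
    if (nW > 0) allxyz[nrow(topo) + seq_len(nW), , ] <-
      wxyz[seq_len(nW), , , drop = FALSE]
    write_xyz_trajectory(xyz_path, elements, allxyz)
    gt_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(gt, gt_path, digits = 10, auto_unbox = TRUE,
                         pretty = TRUE)
    paths <- list(topology = topo_path, xyz = xyz_path,
                  ground_truth = gt_path)
  }
  list(trajectory = traj, paths = paths, ground_truth = gt)
}

#' Generate constant-pH lambda traces with planted pKa values
#'
#' For each residue and pH, draws `n_samples` lambda values as a mixture:
#' with probability `intermediate_fraction` a transition-region sample
#' U(0.2, 0.8); otherwise a two-state draw with deprotonation probability
#' given by the Henderson-Hasselbalch/Hill law at the planted pKa, lambda
#' ~ N(0.95, 0.03) when deprotonated and N(0.05, 0.03) when protonated,
#' clipped to \[0, 1\]. One trace file per residue per pH plus a JSON
#' manifest and ground truth.
#'
#' @param out_dir output directory, or NULL to return traces in memory
#'   only.
#' @param residues data.frame with `residue_id`, `pKa`, `hill_n`.
#' @param pH_grid pH values (default 1 to 10.5 in steps of 0.5).
#' @param n_samples lambda samples per (residue, pH).
#' @param intermediate_fraction fraction of transition-region samples.
#' @param seed integer RNG seed.
#' @return list with `traces` (per residue: named list of lambda vectors by
#'   pH), `manifest` (residue -> files, when written), `ground_truth`.
#' @export
generate_lambda_traces <- function(out_dir = NULL,
                                   residues = data.frame(
                                     residue_id = c(104L, 131L),
                                     pKa = c(8.9, 7.9), hill_n = 1),
                                   pH_grid = seq(1, 10.5, by = 0.5),
                                   n_samples = 2000,
                                   intermediate_fraction = 0,
                                   seed = 1L) {
  set.seed(seed)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- list(); manifest <- list()
  for (r in seq_len(nrow(residues))) {
    rid <- residues$residue_id[r]
    res_traces <- list(); files <- character(0)
    for (ph in pH_grid) {
      s_true <- 1 / (1 + 10^(residues$hill_n[r] * (residues$pKa[r] - ph)))
      inter <- runif(n_samples) < intermediate_fraction
      state <- runif(n_samples) < s_true
      lam <- ifelse(state, rnorm(n_samples, 0.95, 0.03),
                    rnorm(n_samples, 0.05, 0.03))
      lam[inter] <- runif(sum(inter), 0.2, 0.8)
      lam <- pmin(pmax(lam, 0), 1)
      key <- format(ph, trim = TRUE)
      res_traces[[key]] <- lam
      if (!is.null(out_dir)) {
        fname <- sprintf("res%d_pH%s.dat", rid, key)
        write.table(data.frame(time = seq_len(n_samples) * 10,
                               lambda = round(lam, 6)),
                    file.path(out_dir, fname),
                    row.names = FALSE, col.names = FALSE)
        files[key] <- fname   # relative to the manifest directory
      }
    }
    traces[[as.character(rid)]] <- res_traces
    if (!is.null(out_dir))
      manifest[[as.character(rid)]] <- as.list(files)
  }
  gt <- list(seed = seed, residues = residues, pH_grid = pH_grid,
             n_samples = n_samples,
             intermediate_fraction = intermediate_fraction)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         digits = 10, auto_unbox = TRUE, pretty = TRUE)
  }
  list(traces = traces,
       manifest = if (is.null(out_dir)) NULL
                  else file.path(out_dir, "manifest.json"),
       ground_truth = gt)
}
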