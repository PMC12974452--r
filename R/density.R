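#' Accumulate a water mass-density grid from a trajectory window
#'
#' Voxelizes the region up to `shell_cutoff` around the protein at
#' `grid_spacing` and accumulates, per voxel, the mean number of water
#' oxygens per frame, converted to mass density in kg/L (one water of mass
#' 18.015 u in a 0.5 Angstrom voxel corresponds to about 239.3 kg/L).
#' Voxels whose centers lie farther than `shell_cutoff` from every protein
#' atom are zeroed unless `apply_mask = FALSE`.
#'
#' @param window an aligned `md_trajectory` window.
#' @param config an [analysis_config()].
#' @param apply_mask zero voxels outside the protein shell (default TRUE).
#' @param reference_protein protein coordinates defining the grid extent
#'   and shell; default the window's first frame.
#' @return A `density_grid`: `origin` (corner, Angstrom), `spacing`,
#'   `values` (3-D array, kg/L), `shell_mask` (logical array), `n_frames`.
#' @export
accumulate_density <- function(window, config = analysis_config(),
                               apply_mask = TRUE, reference_protein = NULL) {
  sp <- config$grid_spacing
  shell <- config$shell_cutoff
  if (is.null(reference_protein)) reference_protein <- window$protein_xyz[, , 1]
  lo <- apply(reference_protein, 2, min) - shell - sp
  hi <- apply(reference_protein, 2, max) + shell + sp
  dims <- pmax(as.integer(ceiling((hi - lo) / sp)), 1L)
  vals <- array(0, dims)
  nf <- n_frames(window)
  nW <- dim(window$water_xyz)[1]
  if (nW > 0) {
    w <- matrix(aperm(window$water_xyz, c(1, 3, 2)), ncol = 3) # all frames
    ijk <- floor(sweep(w, 2, lo) / sp) + 1L
    ok <- ijk[, 1] >= 1L & ijk[, 1] <= dims[1] &
          ijk[, 2] >= 1L & ijk[, 2] <= dims[2] &
          ijk[, 3] >= 1L & ijk[, 3] <= dims[3]
    ijk <- ijk[ok, , drop = FALSE]
    if (nrow(ijk)) {
      lin <- (ijk[, 3] - 1L) * dims[1] * dims[2] +
             (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
      counts <- tabulate(lin, nbins = prod(dims))
      vals[] <- counts / nf
    }
  }
  vox_vol_L <- sp^3 * .A3_TO_L
  vals <- vals * .WATER_MASS_KG / vox_vol_L
  mask <- shell_mask(dims, lo, sp, reference_protein, shell)
  if (apply_mask) vals[!mask] <- 0
  structure(list(origin = lo, spacing = sp, values = vals,
                 shell_mask = mask, n_frames = nf),
            class = "density_grid")
}

# logical array marking voxels whose centers are within `shell` of any
# protein atom; per-atom local sub-boxes keep this linear in atom count
shell_mask <- function(dims, origin, sp, protein, shell) {
  mask <- array(FALSE, dims)
  centers <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 0.5) * sp)
  for (i in seq_len(nrow(protein))) {
    p <- protein[i, ]
    rng <- lapply(1:3, function(k) {
      lo <- max(1L, floor((p[k] - shell - origin[k]) / sp))
      hi <- min(dims[k], ceiling((p[k] + shell - origin[k]) / sp) + 1L)
      if (lo > hi) integer(0) else lo:hi
    })
    if (!all(lengths(rng))) next
    dx2 <- (centers[[1]][rng[[1]]] - p[1])^2
    dy2 <- (centers[[2]][rng[[2]]] - p[2])^2
    dz2 <- (centers[[3]][rng[[3]]] - p[3])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= shell^2
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]]] | within
  }
  mask
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s voxels at %.2f A, max %.1f kg/L (%d frames)\n",
              paste(dim(x$values), collapse = "x"), x$spacing,
              max(x$values), x$n_frames))
  invisible(x)
}

#' Smooth a density grid over adjacent voxels
#'
#' Replaces each voxel by the unweighted mean of itself and its adjacent
#' voxels: the 6 face-adjacent neighbours by default, or the 18 face- or
#' edge-adjacent neighbours with `config$smoothing_neighbors = 18`.
#' Boundary voxels average over their existing neighbours only. If the grid
#' carries a shell mask that was applied, out-of-shell voxels are re-zeroed
#' after smoothing.
#'
#' @param grid a `density_grid`.
#' @param config an [analysis_config()].
#' @param remask re-apply the shell mask after smoothing (default TRUE).
#' @return The smoothed `density_grid`.
#' @export
smooth_density <- function(grid, config = analysis_config(), remask = TRUE) {
  offs <- if (config$smoothing_neighbors == 6L) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(abs(o)) %in% c(1L, 2L), , drop = FALSE]
  }
  v <- grid$values
  d <- dim(v)
  acc <- v
  cnt <- array(1, d)
  idx <- function(n, s) {  # source/target ranges for a shift by s
    if (s >= 0) list(src = seq_len(n - s), dst = seq_len(n - s) + s)
    else list(src = seq_len(n + s) - s, dst = seq_len(n + s))
  }
  for (r in seq_len(nrow(offs))) {
    s <- offs[r, ]
    ix <- idx(d[1], s[1]); iy <- idx(d[2], s[2]); iz <- idx(d[3], s[3])
    acc[ix$dst, iy$dst, iz$dst] <- acc[ix$dst, iy$dst, iz$dst] +
      v[ix$src, iy$src, iz$src]
    cnt[ix$dst, iy$dst, iz$dst] <- cnt[ix$dst, iy$dst, iz$dst] + 1
  }
  grid$values <- acc / cnt
  if (remask) grid$values[!grid$shell_mask] <- 0
  grid
}

#' Detect hydration sites from a smoothed density grid
#'
#' Local density maxima (voxels at least as dense as all 26 surrounding
#' voxels; plateaus kept) with smoothed density at or above
#' `density_threshold` are candidate peaks. Peaks strictly closer than
#' `merge_distance` are grouped by single-linkage (density-based clustering
#' with eps = `merge_distance`, minimum one member) and each group becomes
#' one site at its density-weighted mean position (unweighted via
#' `config$site_position`); the site density is the group maximum.
#'
#' @param grid a smoothed `density_grid`.
#' @param config an [analysis_config()].
#' @return data.frame with `x`, `y`, `z`, `density` (kg/L), `n_merged`,
#'   sorted by descending density. Zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_sites <- function(grid, config = analysis_config()) {
  v <- grid$values
  d <- dim(v)
  thr <- config$density_threshold
  cand <- which(v >= thr, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      density = numeric(0), n_merged = integer(0))
  if (!nrow(cand)) return(empty)
  is_max <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
    nb <- v[max(1, i - 1):min(d[1], i + 1),
            max(1, j - 1):min(d[2], j + 1),
            max(1, k - 1):min(d[3], k + 1)]
    is_max[r] <- v[i, j, k] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  pos <- sweep((cand - 0.5) * grid$spacing, 2, grid$origin, "+")
  dens <- v[cand]
  pairs <- neighbor_pairs(pos, config$merge_distance)
  g <- igraph::make_empty_graph(n = nrow(pos), directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  out <- lapply(split(seq_along(comp), comp), function(idx) {
    w <- if (config$site_position == "weighted") dens[idx] else
      rep(1, length(idx))
    ctr <- colSums(pos[idx, , drop = FALSE] * w) / sum(w)
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
               density = max(dens[idx]), n_merged = length(idx))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$density, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority-vote residue assignment for a hydration site
#'
#' In each frame of an aligned window, finds the protein residue whose
#' heavy atom is closest to the site position; returns the residue that
#' wins the most frames (ties broken by lower residue id, then chain).
#'
#' @param position length-3 site position, Angstrom.
#' @param window an aligned `md_trajectory`.
#' @return list with `residue_name`, `residue_id`, `chain`,
#'   `vote_fraction` (fraction of frames won).
#' @export
assign_site_residue <- function(position, window) {
  topo <- window$topology
  heavy <- topo$element != "H"
  reskey <- paste(topo$chain_id[heavy], topo$residue_id[heavy],
                  topo$residue_name[heavy], sep = "|")
  nf <- n_frames(window)
  votes <- character(nf)
  for (f in seq_len(nf)) {
    pm <- window$protein_xyz[heavy, , f, drop = FALSE][, , 1]
    d2 <- colSums((t(pm) - position)^2)
    votes[f] <- reskey[which.min(d2)]
  }
  tab <- table(votes)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1L) {
    parts <- do.call(rbind, strsplit(winners, "|", fixed = TRUE))
    ord <- order(as.integer(parts[, 2]), parts[, 1])
    winners <- winners[ord]
  }
  parts <- strsplit(winners[1], "|", fixed = TRUE)[[1]]
  list(residue_name = parts[3], residue_id = as.integer(parts[2]),
       chain = parts[1], vote_fraction = max(tab) / nf)
}

#' Fraction of frames with a water at a site
#'
#' @param position length-3 site position, Angstrom.
#' @param window an aligned `md_trajectory`.
#' @param cutoff Angstrom; a frame counts when any water oxygen is within
#'   `cutoff` of the position.
#' @return occupancy fraction in \[0, 1\].
#' @export
site_occupancy <- function(position, window, cutoff = 1.2) {
  nW <- dim(window$water_xyz)[1]
  if (nW == 0L) return(0)
  nf <- n_frames(window)
  hit <- logical(nf)
  for (f in seq_len(nf)) {
    w <- window$water_xyz[, , f, drop = FALSE][, , 1]
    hit[f] <- any(colSums((t(w) - position)^2) <= cutoff^2)
  }
  mean(hit)
}
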