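make_static_trajectory <- function(wpos, nf = 50, dt = 2,
                                   scaffold = toy_protein_scaffold()) {
  pm <- as.matrix(scaffold$atoms[is_protein_atom(scaffold),
                                 c("x", "y", "z")])
  px <- array(rep(pm, nf), c(nrow(pm), 3, nf))
  nW <- nrow(wpos)
  wx <- array(NA_real_, c(nW, 3, nf))
  for (f in seq_len(nf)) wx[, , f] <- wpos
  md_trajectory(scaffold$atoms[is_protein_atom(scaffold), ], px, wx, dt)
}

test_that("window sampling anchors at interval multiples", {
  g <- generate_trajectory(NULL, n_frames = 1000, frame_interval_ps = 2,
                           n_sites = 2, bulk_density = 0, seed = 1)
  # 2 ns trajectory, 50-frame (0.1 ns) windows at 0.2 ns intervals
  wins <- sample_windows(g$trajectory, 50, 0.2)
  expect_length(wins, 10L)
  expect_true(all(vapply(wins, n_frames, numeric(1)) == 50L))
  # 0.6 ns worth of frames -> 3 windows
  g2 <- generate_trajectory(NULL, n_frames = 300, frame_interval_ps = 2,
                            n_sites = 1, bulk_density = 0, seed = 2)
  expect_length(sample_windows(g2$trajectory, 50, 0.2), 3L)
  # too short
  expect_error(sample_windows(g2$trajectory, 50, 10), "too short")
  # overlap refused
  expect_error(sample_windows(g$trajectory, 200, 0.2), "overlap")
})

test_that("window alignment removes per-frame rigid motion and moves waters along", {
  g <- generate_trajectory(NULL, n_frames = 20, n_sites = 3,
                           bulk_density = 0, seed = 3)
  tr <- g$trajectory
  ref <- tr$protein_xyz[, , 1]
  # rotate every frame by a frame-dependent rigid motion
  for (f in seq_len(n_frames(tr))) {
    R <- rotz(0.1 * f)
    tr$protein_xyz[, , f] <- tr$protein_xyz[, , f] %*% R
    tr$water_xyz[, , f] <- tr$water_xyz[, , f] %*% R
    tr$protein_xyz[, , f] <- sweep(tr$protein_xyz[, , f], 2, c(1, 2, 3), "+")
    tr$water_xyz[, , f] <- sweep(tr$water_xyz[, , f], 2, c(1, 2, 3), "+")
  }
  al <- align_window(tr, ref)
  expect_lt(max(al$rmsd), 1e-6)
  # waters co-transformed back to the original frame
  expect_equal(al$window$water_xyz, g$trajectory$water_xyz,
               tolerance = 1e-6)
  # already-aligned window unchanged
  al2 <- align_window(g$trajectory, ref)
  expect_equal(al2$window$protein_xyz, g$trajectory$protein_xyz,
               tolerance = 1e-9)
  expect_error(align_window(tr, ref[1:5, ]), "coordinate matrix")
})

test_that("density accumulation reproduces analytic mass and bulk values", {
  scaf <- toy_protein_scaffold()
  pm <- as.matrix(scaf$atoms[is_protein_atom(scaf), c("x", "y", "z")])
  # empty water set -> all-zero grid
  tr0 <- make_static_trajectory(matrix(NA_real_, 0, 3))
  expect_equal(sum(accumulate_density(tr0)$values), 0)

  # one stationary water: its voxel holds 18.015 u / (0.5 A)^3
  tr1 <- make_static_trajectory(matrix(pm[1, ] + c(3, 0, 0), 1))
  g1 <- accumulate_density(tr1)
  expect_equal(max(g1$values), 239.32, tolerance = 1e-4)
  expect_equal(sum(g1$values > 0), 1L)

  # pre-masking mass conservation: total mass = one water per frame
  g1u <- accumulate_density(tr1, apply_mask = FALSE)
  water_mass_kg <- 18.015 * 1.66053906660e-27
  expect_equal(sum(g1u$values) * 0.5^3 * 1e-27 / water_mass_kg, 1,
               tolerance = 1e-9)

  # uniform bulk at 1 kg/L
  gb <- generate_trajectory(NULL, n_frames = 400, n_sites = 0,
                            bulk_density = 1, seed = 8)
  grb <- accumulate_density(gb$trajectory, apply_mask = FALSE)
  expect_equal(mean(grb$values), 1.00, tolerance = 0.02)
})

test_that("smoothing averages face-adjacent voxels and conserves interior mass", {
  scaf <- toy_protein_scaffold()
  tr <- make_static_trajectory(matrix(c(15, 0, 0), 1), nf = 2)
  gr <- accumulate_density(tr)
  gr$shell_mask[] <- TRUE
  # uniform grid unchanged
  gr$values[] <- 3.3
  expect_equal(smooth_density(gr)$values, gr$values)
  # single interior voxel v -> v/7 at itself and each face neighbour
  gr$values[] <- 0
  gr$values[10, 10, 10] <- 7
  sm <- smooth_density(gr)
  expect_equal(sm$values[10, 10, 10], 1)
  expect_equal(sm$values[9, 10, 10], 1)
  expect_equal(sm$values[10, 11, 10], 1)
  expect_equal(sm$values[9, 9, 10], 0)   # edge neighbour untouched at 6
  expect_equal(sum(sm$values), 7)        # interior mass conserved
  # all-zero stays zero
  gr$values[] <- 0
  expect_equal(sum(smooth_density(gr)$values), 0)
  # 18-neighbour option reaches edge-adjacent voxels
  gr$values[10, 10, 10] <- 19
  sm18 <- smooth_density(gr, analysis_config(smoothing_neighbors = 18))
  expect_equal(sm18$values[9, 9, 10], 1)
  expect_equal(sm18$values[9, 9, 9], 0)  # corner still excluded
})

test_that("site detection thresholds, merges sub-Angstrom peaks and recovers plants", {
  scaf <- toy_protein_scaffold()
  tr <- make_static_trajectory(matrix(c(15, 0, 0), 1), nf = 2)
  gr <- accumulate_density(tr)
  gr$shell_mask[] <- TRUE
  gr$values[] <- 0
  # all below threshold -> nothing
  gr$values[10, 10, 10] <- 5.9
  expect_equal(nrow(detect_sites(gr)), 0L)
  # two peaks 1 voxel (0.5 A) apart merge into a density-weighted site
  gr$values[] <- 0
  gr$values[10, 10, 10] <- 10
  gr$values[11, 10, 10] <- 10   # local maxima plateau, 0.5 A apart
  s <- detect_sites(gr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_merged, 2L)
  # peaks 1.5 A apart stay separate
  gr$values[] <- 0
  gr$values[10, 10, 10] <- 10
  gr$values[13, 10, 10] <- 8
  s2 <- detect_sites(gr)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$density, c(10, 8))
  # site count non-increasing in threshold and merge distance
  g <- generate_trajectory(NULL, n_frames = 600, n_sites = 5,
                           bulk_density = 1, seed = 21)
  win <- sample_windows(g$trajectory, 200, 0.4)[[1]]
  grid <- smooth_density(accumulate_density(win))
  counts_thr <- vapply(c(2, 6, 12, 20), function(th)
    nrow(detect_sites(grid, analysis_config(density_threshold = th))),
    numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_eps <- vapply(c(0.6, 1.0, 2.0, 4.0), function(eps)
    nrow(detect_sites(grid, analysis_config(merge_distance = eps))),
    numeric(1))
  expect_true(all(diff(counts_eps) <= 0))
  # plants recovered: count exact, positions within 0.5 A
  sites <- detect_sites(grid)
  expect_equal(nrow(sites), 5L)
  gt <- as.matrix(g$ground_truth$sites[, c("x", "y", "z")])
  err <- apply(as.matrix(sites[, c("x", "y", "z")]), 1, function(p)
    sqrt(min(colSums((t(gt) - p)^2))))
  expect_lt(max(err), 0.5)
})

test_that("site residue vote is modal over frames with documented tie-break", {
  # static protein: 100% vote for the closest residue
  scaf <- toy_protein_scaffold()
  site <- as.matrix(scaf$atoms[1, c("x", "y", "z")]) + c(2, 0, 0)
  tr <- make_static_trajectory(matrix(c(16, 0, 0), 1), nf = 10)
  v <- assign_site_residue(as.numeric(site), tr)
  oracle <- brute_nearest_residue(scaf, as.numeric(site))
  expect_equal(v$residue_id, oracle$residue_id)
  expect_equal(v$vote_fraction, 1)

  # 6/4 split vote: majority wins
  topo <- rbind(atom_row("C", "CA", "ALA", 1, "A", -2, 0, 0),
                atom_row("C", "CA", "GLY", 2, "A", 2, 0, 0))
  nf <- 10
  px <- array(NA_real_, c(2, 3, nf))
  for (f in seq_len(nf)) {
    # residue 2 swings closer to the origin in 4 of 10 frames
    px[, , f] <- rbind(c(-2, 0, 0), if (f <= 4) c(1, 0, 0) else c(3, 0, 0))
  }
  wx <- array(0, c(1, 3, nf))
  win <- md_trajectory(topo, px, wx, 2)
  v2 <- assign_site_residue(c(0, 0, 0), win)
  expect_equal(v2$residue_id, 1L)
  expect_equal(v2$vote_fraction, 0.6)

  # exact 5/5 tie -> lower residue id
  for (f in seq_len(nf))
    px[, , f] <- rbind(c(-2, 0, 0), if (f <= 5) c(1, 0, 0) else c(3, 0, 0))
  win2 <- md_trajectory(topo, px, wx, 2)
  expect_equal(assign_site_residue(c(0, 0, 0), win2)$residue_id, 1L)

  # occupancy fraction counts frames with a water at the site
  g <- generate_trajectory(NULL, n_frames = 400, n_sites = 1,
                           occupancy_range = c(0.7, 0.7),
                           bulk_density = 0, seed = 4)
  st <- g$ground_truth$sites
  occ <- site_occupancy(as.numeric(st[1, c("x", "y", "z")]),
                        g$trajectory, cutoff = 1.2)
  expect_equal(occ, 0.7, tolerance = 0.12)
})
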