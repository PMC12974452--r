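test_that("bound-water counting is per-residue, multi-assigning and monotone", {
  scaf <- toy_protein_scaffold()
  # no waters
  bw0 <- count_bound_waters(scaf)
  expect_true(all(bw0$per_residue$n_waters == 0L))
  # one water 3.0 A from a single glutamate sidechain
  glu <- which(scaf$atoms$residue_name == "GLU" &
                 scaf$atoms$atom_name == "OE1")[1]
  p <- as.numeric(scaf$atoms[glu, c("x", "y", "z")])
  u <- p / sqrt(sum(p^2))   # radially outward: away from everything else
  m <- with_waters(scaf, matrix(p + 3.0 * u, 1))
  bw <- count_bound_waters(m)
  expect_equal(unname(bw$per_type[["GLU"]]), 1L)
  expect_equal(sum(bw$per_type), 1L)
  row <- bw$per_residue[bw$per_residue$residue_id ==
                          scaf$atoms$residue_id[glu], ]
  expect_equal(row$n_waters, 1L)
  # per-type totals equal the sum of per-residue rows
  expect_equal(sum(bw$per_type), sum(bw$per_residue$n_waters))
  # monotone in cutoff; multi-assignment >= nearest-only
  ens <- generate_condition_ensemble(withr::local_tempdir(), seed = 13)
  m5 <- read_ensemble(ens$paths)[[1]]
  tot <- vapply(c(2.8, 3.6, 4.5, 6), function(cc)
    sum(count_bound_waters(m5, cc)$per_type), numeric(1))
  expect_true(all(diff(tot) >= 0))
  expect_gte(sum(count_bound_waters(m5, 3.6)$per_type),
             sum(count_bound_waters(m5, 3.6, mode = "nearest")$per_type))
})

test_that("water totals count records and weight occupancies", {
  scaf <- toy_protein_scaffold()
  expect_equal(total_bound_waters(scaf)$count, 0L)
  ens <- generate_condition_ensemble(withr::local_tempdir(), seed = 23,
                                     desolvation_slope = 100)
  models <- read_ensemble(ens$paths, superposed = FALSE)
  tots <- vapply(models, function(m) total_bound_waters(m)$count,
                 integer(1))
  expect_equal(unname(tots), ens$ground_truth$totals)
  # planted increasing series is strictly increasing with pH
  expect_true(all(diff(tots) > 0))
  # occupancy weighting: water at 0.5 counts half
  m <- with_waters(scaf, matrix(c(15, 0, 0), 1))
  m$atoms$occupancy[is_water_oxygen(m)] <- 0.5
  tw <- total_bound_waters(m)
  expect_equal(tw$count, 1L)
  expect_equal(tw$weighted, 0.5)
})

test_that("Shrake-Rupley ASA matches closed forms and a dense-sampling oracle", {
  iso <- structure_model(atom_row("C", "CA", "ALA", 1, "A", 0, 0, 0), "iso")
  a <- accessible_surface_area(iso)
  expect_equal(a$per_atom, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)

  # atom fully enclosed by a tight cage contributes zero
  cage_pts <- hydroshell:::sphere_points(60) * 2.0
  cage <- do.call(rbind, lapply(seq_len(60), function(i)
    atom_row("C", "CA", "GLY", i + 1, "A", cage_pts[i, 1], cage_pts[i, 2],
             cage_pts[i, 3])))
  caged <- structure_model(rbind(atom_row("C", "CA", "ALA", 1, "A", 0, 0, 0),
                                 cage), "cage")
  ac <- accessible_surface_area(caged)
  expect_equal(ac$per_residue$asa[ac$per_residue$residue_id == 1], 0)

  # two-atom pair: 960-point estimate within 2% of a 20000-point oracle
  for (sep in c(2.0, 3.0, 4.5)) {
    pair <- structure_model(rbind(
      atom_row("C", "CA", "ALA", 1, "A", 0, 0, 0),
      atom_row("O", "OG", "SER", 2, "A", sep, 0, 0)), "pair")
    est <- sum(accessible_surface_area(pair, n_points = 960)$per_atom)
    oracle <- sum(accessible_surface_area(pair, n_points = 20000)$per_atom)
    expect_equal(est, oracle, tolerance = 0.02)
  }
  # residue ASA never exceeds the isolated-sphere total
  scaf <- toy_protein_scaffold()
  asa <- accessible_surface_area(scaf)
  iso_area <- vapply(seq_len(nrow(asa$per_residue)), function(i) {
    keep <- scaf$atoms$residue_id == asa$per_residue$residue_id[i]
    r <- hydroshell:::.VDW_RADII[scaf$atoms$element[keep]] + 1.4
    sum(4 * pi * r^2)
  }, numeric(1))
  expect_true(all(asa$per_residue$asa <= iso_area + 1e-9))
  # unknown element radius errors by name
  odd <- structure_model(atom_row("XE", "XE", "ALA", 1, "A", 0, 0, 0), "xe")
  expect_error(accessible_surface_area(odd), "XE")
})

test_that("hydration correlations and the desolvation trend behave like OLS", {
  asa <- setNames(seq(20, 400, 20), hydroshell:::.AA3)
  counts <- 0.5 * asa + 3
  fit <- hydration_correlation(counts, asa)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$pearson_r^2, fit$r_squared, tolerance = 1e-12)
  # independent counts: r^2 stays small across seeds (n = 20)
  r2 <- vapply(1:10, function(s) {
    set.seed(s)
    hydration_correlation(setNames(rnorm(20), hydroshell:::.AA3),
                          asa)$r_squared
  }, numeric(1))
  expect_lt(median(r2), 0.05)
  expect_error(hydration_correlation(counts, setNames(rep(1, 20),
                                                      hydroshell:::.AA3)),
               "zero-variance")

  # exact slope-100 desolvation line
  pH <- c(3.5, 4, 5, 7, 9)
  tr <- desolvation_trend(100 * pH + 7, pH)
  expect_equal(tr$slope, 100, tolerance = 1e-12)
  expect_equal(tr$pearson_r, 1, tolerance = 1e-12)
  # shift invariance: slope and r unchanged, intercept absorbs the shift
  tr2 <- desolvation_trend(100 * pH + 7, pH + 2)
  expect_equal(tr2$slope, tr$slope, tolerance = 1e-9)
  expect_equal(tr2$pearson_r, tr$pearson_r, tolerance = 1e-12)
  expect_equal(tr2$intercept, tr$intercept - 200, tolerance = 1e-9)
  expect_error(desolvation_trend(c(1, 2), c(1, 2)), ">= 3")
})

test_that("water-protein distance distributions flag flatness via the IQR", {
  scaf <- toy_protein_scaffold()
  m1 <- with_waters(scaf, matrix(c(16.3, 0, 0), 1))
  d1 <- water_protein_distance_distribution(m1)
  expect_length(d1$distances, 1L)
  oracle <- brute_nearest_residue(scaf, c(16.3, 0, 0))
  expect_equal(d1$distances, oracle$distance)
  # tight vs broad planted spread orders the IQR
  set.seed(7)
  base <- 3.0 + abs(rnorm(100, 0, 0.1))
  broad <- 3.0 + abs(rnorm(100, 0, 0.6))
  mk <- function(depths) {
    pos <- t(vapply(depths, function(dd) c(13.5 + dd, 0, 0), numeric(3)))
    pos[, 2] <- seq(0, 5, length.out = length(depths))  # avoid stacking
    pos
  }
  mt <- with_waters(scaf, mk(base))
  mb <- with_waters(scaf, mk(broad))
  it <- water_protein_distance_distribution(mt)$iqr
  ib <- water_protein_distance_distribution(mb)$iqr
  expect_lt(it, ib)
  # distances equal the exhaustive scan on random waters
  set.seed(8)
  rnd <- cbind(runif(50, -18, 18), runif(50, -18, 18), runif(50, -4, 4))
  keep <- apply(rnd, 1, function(p)
    brute_nearest_residue(scaf, p)$distance > 1)
  mrnd <- with_waters(scaf, rnd[keep, ])
  dr <- water_protein_distance_distribution(mrnd)
  expect_equal(dr$distances,
               apply(rnd[keep, ], 1, function(p)
                 brute_nearest_residue(scaf, p)$distance),
               tolerance = 1e-12)
})
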