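test_that("cross-condition clustering recovers planted persistence exactly", {
  # single model, single water
  scaf <- toy_protein_scaffold()
  m <- mark_superposed(with_waters(scaf, matrix(c(14, 0, 0), 1), "pH7"))
  wss <- cluster_waters(list(m), 1.0)
  expect_equal(nrow(wss$sites), 1L)
  expect_equal(wss$sites$category, "lone")
  expect_equal(wss$sites$n_conditions, 1L)

  # planted 20 five-way shared + 7 lone per condition
  ens <- generate_condition_ensemble(withr::local_tempdir(), seed = 202)
  models <- read_ensemble(ens$paths)
  wss <- cluster_waters(models, 1.0)
  cp <- classify_persistence(wss)
  expect_equal(unname(cp$histogram),
               c(5L * 7L, 0L, 0L, 0L, 20L))
  expect_true(all(cp$per_condition$lone == 7L))
  expect_true(all(cp$per_condition$persistent == 20L))
  # partition: members cover every water record
  expect_equal(nrow(wss$members),
               sum(vapply(models, function(m) sum(is_water_oxygen(m)),
                          numeric(1))))
  # centroids are unweighted member means
  for (cid in wss$sites$cluster_id[1:3]) {
    mem <- wss$members[wss$members$cluster_id == cid, ]
    expect_equal(unlist(wss$sites[wss$sites$cluster_id == cid,
                                  c("x", "y", "z")]),
                 c(x = mean(mem$x), y = mean(mem$y), z = mean(mem$z)))
  }
  # memberships agree with a brute-force single-linkage oracle
  pos <- as.matrix(wss$members[, c("x", "y", "z")])
  oracle <- brute_single_linkage(pos, 1.0)
  expect_equal(length(unique(oracle)), nrow(wss$sites))
  expect_true(all(tapply(oracle, wss$members$cluster_id,
                         function(v) length(unique(v))) == 1L))

  # unsuperposed ensemble -> error
  raw <- read_ensemble(ens$paths, superposed = FALSE)
  expect_error(cluster_waters(raw, 1.0), "superposed")
})

test_that("linkage uses strict distances below the cutoff", {
  scaf <- toy_protein_scaffold()
  place <- function(d) {
    m1 <- mark_superposed(with_waters(scaf, matrix(c(14, 0, 0), 1), "pH4"))
    m2 <- mark_superposed(with_waters(scaf, matrix(c(14 + d, 0, 0), 1),
                                      "pH7"))
    nrow(cluster_waters(list(m1, m2), 1.0)$sites)
  }
  expect_equal(place(1.01), 2L)
  expect_equal(place(0.99), 1L)
  expect_equal(place(1.00), 2L)  # boundary does not link
})

test_that("clustering is order-independent and monotone in the cutoff", {
  ens <- generate_condition_ensemble(withr::local_tempdir(), seed = 31,
                                     jitter_sigma = 0.35)
  models <- read_ensemble(ens$paths)
  wss1 <- cluster_waters(models, 1.0)
  wss2 <- cluster_waters(rev(models), 1.0)
  expect_equal(wss1$sites[, c("x", "y", "z", "n_conditions", "category")],
               wss2$sites[, c("x", "y", "z", "n_conditions", "category")])

  n_clusters <- vapply(c(0.3, 0.6, 1.0, 1.8, 3.0), function(cc)
    nrow(cluster_waters(models, cc)$sites), numeric(1))
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("nearest-residue assignment matches an exhaustive scan", {
  ens <- generate_condition_ensemble(withr::local_tempdir(), seed = 5)
  models <- read_ensemble(ens$paths)
  wss <- assign_nearest_residue(cluster_waters(models, 1.0), models[[1]],
                                cutoff = 3.6)
  s <- wss$sites
  for (i in seq_len(nrow(s))) {
    oracle <- brute_nearest_residue(models[[1]],
                                    c(s$x[i], s$y[i], s$z[i]), 3.6)
    if (is.null(oracle)) {
      expect_true(is.na(s$nearest_residue_id[i]))
    } else {
      expect_equal(s$nearest_residue_id[i], oracle$residue_id)
      expect_equal(s$nearest_distance[i], oracle$distance)
    }
  }
  # beyond-cutoff centroid stays unassigned
  scaf <- toy_protein_scaffold()
  far <- mark_superposed(with_waters(scaf, matrix(c(40, 0, 0), 1), "pH7"))
  wss_far <- assign_nearest_residue(cluster_waters(list(far), 1.0), far)
  expect_true(is.na(wss_far$sites$nearest_residue_id))
})

test_that("residue preferences conserve site counts", {
  ens <- generate_condition_ensemble(withr::local_tempdir(), seed = 17)
  models <- read_ensemble(ens$paths)
  wss <- assign_nearest_residue(cluster_waters(models, 1.0), models[[1]])
  prefs <- residue_preferences(wss)
  expect_equal(sum(prefs), sum(wss$sites$category == "most_persistent"))
  # all-ASN construction: every site nearest an asparagine
  asn <- structure_model(atom_row("N", "ND2", "ASN", 1, "A", 0, 0, 0),
                         "pH7")
  m1 <- mark_superposed(with_waters(asn, matrix(c(2, 0, 0), 1), "pH4"))
  m2 <- mark_superposed(with_waters(asn, matrix(c(2.1, 0, 0), 1), "pH7"))
  wss2 <- assign_nearest_residue(cluster_waters(list(m1, m2), 1.0), m1)
  prefs2 <- residue_preferences(wss2)
  expect_equal(unname(prefs2[["ASN"]]), 1L)
  expect_equal(sum(prefs2), 1L)
})

test_that("KS statistic is exact and nearest water-water distances pool by category", {
  # two waters 2.8 apart: both nearest distances 2.8
  scaf <- toy_protein_scaffold()
  m <- mark_superposed(with_waters(scaf, rbind(c(14, 0, 0), c(14, 2.8, 0)),
                                   "pH7"))
  wss <- cluster_waters(list(m), 1.0)
  nwd <- nearest_water_distances(wss)
  expect_equal(nwd$distributions$lone$values, c(2.8, 2.8))
  expect_true(nwd$distributions$persistent$degenerate)

  # identical samples -> KS 0
  expect_equal(ks_statistic(1:10, 1:10), 0)
  # exactness against an independent counting implementation
  set.seed(99)
  tight <- rnorm(1000, 2.8, 0.15)
  disp <- rnorm(1000, 6.0, 0.8)
  expect_equal(ks_statistic(tight, disp), ks_oracle(tight, disp),
               tolerance = 1e-15)
  expect_equal(ks_statistic(tight, disp),
               unname(suppressWarnings(
                 stats::ks.test(tight, disp)$statistic)),
               tolerance = 1e-12)
  expect_gte(ks_statistic(tight, disp), 0)
  expect_lte(ks_statistic(tight, disp), 1)
})
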