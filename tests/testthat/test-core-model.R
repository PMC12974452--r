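test_that("PDB round trip preserves atoms, partitions and coordinates", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f, condition_label = "tiny")
  expect_equal(nrow(m2$atoms), 3L)
  expect_equal(sum(is_water_oxygen(m2)), 1L)
  expect_equal(sum(is_protein_atom(m2)), 2L)
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # water + iron HETATM partitioning
  fe <- structure_model(rbind(
    m$atoms,
    atom_row("FE", "FE", "FE", 201, "A", 5, 5, 5, record = "HETATM")),
    "fe")
  write_structure(fe, f)
  fe2 <- read_structure(f)
  expect_equal(sum(is_ion(fe2)), 1L)
  expect_equal(sum(is_water_oxygen(fe2)), 1L)

  # multi-chain assembly: per-chain counts survive the round trip
  asm <- toy_assembly(24, n_repeats = 1)
  write_structure(asm, f)
  asm2 <- read_structure(f)
  expect_equal(nrow(asm2$atoms), nrow(asm$atoms))
  expect_equal(table(asm2$atoms$chain_id), table(asm$atoms$chain_id))
  expect_equal(max(abs(as.matrix(asm2$atoms[, c("x", "y", "z")]) -
                         as.matrix(asm$atoms[, c("x", "y", "z")]))),
               0, tolerance = 5.1e-4)  # PDB 3-decimal precision

  expect_error(read_structure(withr::local_tempfile()), "not found")
})

test_that("solvent chain assignment handles proximity and symmetry axes", {
  asm <- toy_assembly(4, n_repeats = 1)
  # water clearly nearest one chain-A atom
  a1 <- as.numeric(asm$atoms[1, c("x", "y", "z")])
  w <- assign_solvent_chain(asm, a1 + c(1, 0, 0))
  expect_equal(w$chain_id, "A")
  expect_equal(w$occupancy, 1.0)

  # fourfold axis: same within-chain indices tie across 4 chains
  w4 <- assign_solvent_chain(asm, c(0, 0, 10))
  expect_equal(w4$chain_id, "A")
  expect_equal(w4$occupancy, 0.25)
  expect_equal(w4$multiplicity, 4L)

  w3 <- assign_solvent_chain(toy_assembly(3, n_repeats = 1), c(0, 0, 10))
  expect_equal(w3$occupancy, 0.33)

  # twofold axis verified against exhaustive distance enumeration
  asm2 <- toy_assembly(2, n_repeats = 1)
  w2 <- assign_solvent_chain(asm2, c(0, 0, 10))
  expect_equal(w2$occupancy, 0.5)
  prot <- which(is_protein_atom(asm2))
  pm <- as.matrix(asm2$atoms[prot, c("x", "y", "z")])
  d <- sqrt(colSums((t(pm) - c(0, 0, 10))^2))
  mins <- tapply(d, asm2$atoms$chain_id[prot], min)
  expect_lt(abs(mins[["A"]] - mins[["B"]]), 1e-3)
  expect_equal(w2$distance, min(d))

  # occupancy x multiplicity = 1 within 0.01
  for (n in 2:4) {
    wn <- assign_solvent_chain(toy_assembly(n, n_repeats = 1), c(0, 0, 10))
    expect_lt(abs(wn$occupancy * wn$multiplicity - 1), 0.011)
  }

  # no protein atoms -> error
  only_w <- structure_model(
    atom_row("O", "O", "HOH", 1, "A", 0, 0, 0, record = "HETATM"), "w")
  expect_error(assign_solvent_chain(only_w, c(1, 1, 1)), "no protein")
})

test_that("chain extraction keeps assigned solvent and rejects unknown chains", {
  m <- tiny_model()
  expect_equal(extract_chain(m, "A")$atoms, m$atoms)

  # 2-chain model, waters assigned 3:A and 2:B
  asm <- toy_assembly(2, n_repeats = 1)
  aA <- as.numeric(asm$atoms[1, c("x", "y", "z")])
  iB <- which(asm$atoms$chain_id == "B")[1]
  aB <- as.numeric(asm$atoms[iB, c("x", "y", "z")])
  wpos <- rbind(aA + c(3, 0, 0), aA + c(0, 3, 0), aA + c(0, 0, 3),
                aB + c(3, 0, 0), aB + c(0, 3, 0))
  m2 <- assign_solvent_chains(with_waters(asm, wpos))
  exA <- extract_chain(m2, "A")
  expect_equal(sum(is_water_oxygen(exA)), 3L)
  exB <- extract_chain(m2, "B")
  expect_equal(sum(is_water_oxygen(exB)), 2L)

  expect_error(extract_chain(m2, "Z"), "available chains: A, B")
})

test_that("superposition removes rigid motion and matches closed-form RMSD", {
  m <- toy_protein_scaffold()
  # self: rmsd 0
  expect_equal(superpose(m, m)$rmsd, 0, tolerance = 1e-12)

  # rigid motion removed
  m2 <- transform_model(m, rotz(0.8), c(5, -3, 1))
  sup <- superpose(m2, m)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)

  # noisy copy: rmsd symmetric and reproduced by applying the transform
  set.seed(42)
  m3 <- m
  m3$atoms$x <- m3$atoms$x + rnorm(nrow(m3$atoms), 0, 0.3)
  m3$atoms$y <- m3$atoms$y + rnorm(nrow(m3$atoms), 0, 0.3)
  m3$atoms$z <- m3$atoms$z + rnorm(nrow(m3$atoms), 0, 0.3)
  s_ab <- superpose(m3, m)
  s_ba <- superpose(m, m3)
  expect_equal(s_ab$rmsd, s_ba$rmsd, tolerance = 1e-9)
  fitted <- apply_transform(m3, s_ab)
  ca <- select_calpha(fitted$atoms)
  dev <- sqrt(mean(rowSums((as.matrix(fitted$atoms[ca, c("x", "y", "z")]) -
                              as.matrix(m$atoms[ca, c("x", "y", "z")]))^2)))
  expect_equal(dev, s_ab$rmsd, tolerance = 1e-12)

  # independent Kabsch oracle: bio3d::fit.xyz on the same CA pairing
  xyz_a <- as.vector(t(as.matrix(m3$atoms[ca, c("x", "y", "z")])))
  xyz_b <- as.vector(t(as.matrix(m$atoms[select_calpha(m$atoms),
                                         c("x", "y", "z")])))
  fitted_b <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_b,
                                              mobile = xyz_a))
  oracle_rmsd <- sqrt(mean(colSums(
    matrix((fitted_b - xyz_b)^2, nrow = 3))))
  expect_equal(s_ab$rmsd, oracle_rmsd, tolerance = 1e-6)

  # <3 paired atoms -> error
  small <- structure_model(m$atoms[1:2, ], "small")
  expect_error(superpose(small, small), "3 paired atoms|ambiguous|no")
})
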