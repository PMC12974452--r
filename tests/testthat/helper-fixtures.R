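# shared fixtures and independent oracles

atom_row <- function(element, atom_name, residue_name, residue_id, chain_id,
                     x, y, z, record = "ATOM", occupancy = 1, b_factor = 0) {
  data.frame(record = record, element = element, atom_name = atom_name,
             residue_name = residue_name, residue_id = as.integer(residue_id),
             chain_id = chain_id, insert = "", x = x, y = y, z = z,
             occupancy = occupancy, b_factor = b_factor,
             stringsAsFactors = FALSE)
}

# minimal three-atom model: two protein atoms, one water
tiny_model <- function() {
  structure_model(rbind(
    atom_row("C", "CA", "ALA", 1, "A", 0, 0, 0),
    atom_row("O", "OE1", "GLU", 2, "A", 3, 0, 0),
    atom_row("O", "O", "HOH", 101, "A", 0, 0, 3, record = "HETATM")),
    "tiny")
}

# model with explicit waters at given positions added to a scaffold
with_waters <- function(scaffold, wpos, label = "wtest") {
  wdf <- do.call(rbind, lapply(seq_len(nrow(wpos)), function(i)
    atom_row("O", "O", "HOH", 1000 + i, "A", wpos[i, 1], wpos[i, 2],
             wpos[i, 3], record = "HETATM")))
  structure_model(rbind(scaffold$atoms, wdf), label)
}

read_ensemble <- function(paths, superposed = TRUE) {
  models <- mapply(function(p, l) read_structure(p, condition_label = l),
                   paths, names(paths), SIMPLIFY = FALSE)
  if (superposed) models <- lapply(models, mark_superposed)
  models
}

# independent KS oracle: direct counting, no ecdf()
ks_oracle <- function(x, y) {
  z <- sort(unique(c(x, y)))
  d <- vapply(z, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1))
  max(d)
}

# exhaustive nearest protein heavy atom for a point
brute_nearest_residue <- function(model, p, cutoff = Inf) {
  keep <- is_protein_atom(model) & model$atoms$element != "H"
  a <- model$atoms[keep, , drop = FALSE]
  d <- sqrt((a$x - p[1])^2 + (a$y - p[2])^2 + (a$z - p[3])^2)
  j <- which.min(d)
  if (d[j] > cutoff) return(NULL)
  list(residue_name = a$residue_name[j], residue_id = a$residue_id[j],
       chain = a$chain_id[j], distance = d[j])
}

# brute-force single-linkage clustering: repeated merging on the full
# distance matrix, strict < cutoff
brute_single_linkage <- function(pos, cutoff) {
  n <- nrow(pos)
  comp <- seq_len(n)
  dm <- as.matrix(dist(pos))
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (dm[i, j] < cutoff && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# rigid rotation matrix about z
rotz <- function(ang) {
  matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
}

transform_model <- function(model, R, tvec) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  model$atoms$x <- xyz[, 1] + tvec[1]
  model$atoms$y <- xyz[, 2] + tvec[2]
  model$atoms$z <- xyz[, 3] + tvec[3]
  model
}
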