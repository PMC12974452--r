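# Kabsch least-squares rotation for row-vector coordinate matrices:
# returns R such that Am %*% R best matches Bm (both already centered).
kabsch_rotation <- function(Am, Bm) {
  H <- crossprod(Am, Bm)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose one model on another (rigid-body least squares)
#'
#' Pairs atoms between the two models by chain + residue id + insertion
#' code + atom name over a selection, then computes the Kabsch
#' least-squares rotation and translation. The RMSD is evaluated after the
#' fit. The returned transform applies to all atoms of the mobile model,
#' waters and ions included.
#'
#' @param mobile,reference `structure_model`s.
#' @param selection function taking the atom table and returning a logical
#'   vector; default selects C-alpha atoms.
#' @param min_pair_frac minimum fraction of selected mobile atoms that must
#'   pair with the reference; below this the pairing is considered
#'   mismatched and an error names the first unmatched atom.
#' @return A `superposition_result`: `rotation` (3x3, det +1), `translation`
#'   (length-3, Angstrom), `rmsd` (Angstrom over the fitted pairs),
#'   `n_atoms`.
#' @export
superpose <- function(mobile, reference, selection = select_calpha,
                      min_pair_frac = 0.9) {
  am <- mobile$atoms; ar <- reference$atoms
  sm <- which(selection(am)); sr <- which(selection(ar))
  key <- function(a, i) paste(a$chain_id[i], a$residue_id[i], a$insert[i],
                              a$atom_name[i], sep = "|")
  km <- key(am, sm); kr <- key(ar, sr)
  if (anyDuplicated(km) || anyDuplicated(kr))
    stop("selection is ambiguous: duplicated atom identities within a model")
  match_idx <- match(km, kr)
  unpaired <- which(is.na(match_idx))
  if (length(unpaired)) {
    frac <- 1 - length(unpaired) / length(km)
    if (frac < min_pair_frac)
      stop("atom pairing mismatch: mobile atom ", km[unpaired[1]],
           " has no counterpart in the reference (only ",
           round(100 * frac), "% of atoms pair)")
    warning(length(unpaired), " selected atom(s) without a counterpart ",
            "skipped (first: ", km[unpaired[1]], ")")
  }
  paired <- !is.na(match_idx)
  A <- as.matrix(am[sm[paired], c("x", "y", "z")])
  B <- as.matrix(ar[sr[match_idx[paired]], c("x", "y", "z")])
  if (nrow(A) < 3L) stop("need >= 3 paired atoms, have ", nrow(A))
  ca <- colMeans(A); cb <- colMeans(B)
  R <- kabsch_rotation(sweep(A, 2, ca), sweep(B, 2, cb))
  tr <- cb - as.numeric(ca %*% R)
  fitted <- sweep(A %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_atoms = nrow(A)),
            class = "superposition_result")
}

#' @rdname superpose
#' @param atoms an atom table (used as a selection predicate).
#' @export
select_calpha <- function(atoms) {
  atoms$atom_name == "CA" & atoms$residue_name %in% .AA3
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition transform to a whole model
#'
#' Transforms every atom (protein, waters, ions) into the reference frame
#' and flags the model as superposed.
#'
#' @param model a `structure_model`.
#' @param sup a `superposition_result` from [superpose()].
#' @return The transformed `structure_model`.
#' @export
apply_transform <- function(model, sup) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% sup$rotation, 2, sup$translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  mark_superposed(model)
}
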