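#' Assign a solvent atom to a protein chain
#'
#' A water (or ion) is assigned the chain of its globally nearest protein
#' atom. When several chains tie within `tol` *and* the tying atoms occupy
#' the same atom index within their respective chains, the site lies on a
#' symmetry axis: the solvent atom receives occupancy 1/multiplicity
#' (0.5 twofold, 0.33 threefold, 0.25 fourfold, stored at two decimals as
#' conventionally deposited) and the alphabetically first tying chain.
#' Ties between different atom indices are ordinary coincidences: occupancy
#' stays 1.0 and the alphabetically first chain is used.
#'
#' @param model a `structure_model` with at least one protein atom.
#' @param atom_index row index of the solvent atom in `model$atoms`, or a
#'   numeric xyz position of length 3.
#' @param tol Angstrom; distances within `tol` of the minimum count as tied.
#' @return list with `chain_id`, `occupancy`, `distance` (Angstrom to the
#'   nearest protein atom) and `multiplicity`.
#' @export
assign_solvent_chain <- function(model, atom_index, tol = 1e-3) {
  prot <- which(is_protein_atom(model))
  if (!length(prot)) stop("model has no protein atoms")
  p <- if (length(atom_index) == 3L && is.numeric(atom_index) &&
           !is.integer(atom_index)) {
    as.numeric(atom_index)
  } else {
    as.numeric(model$atoms[atom_index, c("x", "y", "z")])
  }
  pm <- as.matrix(model$atoms[prot, c("x", "y", "z")])
  d <- sqrt(colSums((t(pm) - p)^2))
  dmin <- min(d)
  tied <- which(d <= dmin + tol)
  chains <- model$atoms$chain_id[prot]
  # index of each protein atom within its own chain's atom ordering
  within_idx <- stats::ave(seq_along(prot), chains, FUN = seq_along)
  tied_chains <- chains[tied]
  uniq_chains <- sort(unique(tied_chains))
  mult <- 1L
  occ <- 1.0
  if (length(uniq_chains) > 1L) {
    # symmetry axis: every tying chain contributes the same set of
    # within-chain atom indices at the tied distance
    idx_sets <- lapply(uniq_chains, function(ch)
      sort(unique(within_idx[tied[tied_chains == ch]])))
    same <- all(vapply(idx_sets[-1], identical, logical(1), idx_sets[[1]]))
    if (same) {
      mult <- length(uniq_chains)
      occ <- switch(as.character(mult), "2" = 0.5, "3" = 0.33, "4" = 0.25,
                    round(1 / mult, 2))
    }
  }
  list(chain_id = uniq_chains[1L], occupancy = occ, distance = dmin,
       multiplicity = mult)
}

#' Assign every water and ion in a model to a chain
#'
#' Applies [assign_solvent_chain()] to each water oxygen and ion, rewriting
#' their `chain_id` and `occupancy` in place. Water hydrogens (if present)
#' follow their oxygen's assignment via shared residue identity.
#'
#' @param model a `structure_model`.
#' @param tol Angstrom tie tolerance (see [assign_solvent_chain()]).
#' @return The model with solvent chains and occupancies assigned.
#' @export
assign_solvent_chains <- function(model, tol = 1e-3) {
  solvent <- which(is_water_oxygen(model) | is_ion(model))
  for (i in solvent) {
    asg <- assign_solvent_chain(model, i, tol = tol)
    model$atoms$chain_id[i] <- asg$chain_id
    model$atoms$occupancy[i] <- asg$occupancy
  }
  model
}
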