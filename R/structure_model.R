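#' Construct a structure model
#'
#' A `structure_model` is a labeled atomic model: an atom table plus a
#' condition label (e.g. `"pH7.0"`). Atoms are partitioned into protein
#' atoms, water oxygens (residue name `HOH`, element `O`) and single-atom
#' ions; the partitions are disjoint and cover all atoms. Water hydrogens
#' (rare in deposited models) are carried but belong to no partition used
#' by downstream analyses.
#'
#' @param atoms data.frame with columns `record` ("ATOM"/"HETATM"),
#'   `element`, `atom_name`, `residue_name`, `residue_id`, `chain_id`,
#'   `insert`, `x`, `y`, `z`, `occupancy`, `b_factor`.
#' @param condition_label character scalar naming the condition.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, condition_label = "unlabeled") {
  required <- c("record", "element", "atom_name", "residue_name",
                "residue_id", "chain_id", "insert", "x", "y", "z",
                "occupancy", "b_factor")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  atoms$element <- toupper(trimws(atoms$element))
  if (any(!nzchar(atoms$element)))
    stop("atom(s) with empty element symbol")
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(pos))) stop("non-finite coordinates")
  if (any(!is.finite(atoms$occupancy)) || any(atoms$occupancy <= 0) ||
      any(atoms$occupancy > 1))
    stop("occupancy must be in (0, 1]")
  rownames(atoms) <- NULL
  m <- structure(list(condition_label = condition_label, atoms = atoms),
                 class = "structure_model")
  m
}

# partition helpers --------------------------------------------------------

#' @rdname structure_model
#' @param model a `structure_model`.
#' @export
is_water_oxygen <- function(model) {
  a <- model$atoms
  a$residue_name == "HOH" & a$element == "O"
}

#' @rdname structure_model
#' @export
is_ion <- function(model) {
  a <- model$atoms
  a$record == "HETATM" & a$residue_name != "HOH" &
    a$element %in% .ION_ELEMENTS
}

#' @rdname structure_model
#' @export
is_protein_atom <- function(model) {
  a <- model$atoms
  a$residue_name != "HOH" & !is_ion(model)
}

protein_coords <- function(model, heavy_only = TRUE) {
  keep <- is_protein_atom(model)
  if (heavy_only) keep <- keep & model$atoms$element != "H"
  as.matrix(model$atoms[keep, c("x", "y", "z")])
}

water_coords <- function(model) {
  as.matrix(model$atoms[is_water_oxygen(model), c("x", "y", "z")])
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s'> %d atoms (%d protein, %d water O, %d ion)%s\n",
              x$condition_label, nrow(x$atoms), sum(is_protein_atom(x)),
              sum(is_water_oxygen(x)), sum(is_ion(x)),
              if (isTRUE(attr(x, "superposed"))) " [common frame]" else ""))
  invisible(x)
}

#' Mark a model as being in the ensemble's common reference frame
#'
#' `superpose()` marks transformed models automatically; the reference model
#' itself must be marked explicitly before cross-condition clustering.
#'
#' @param model a `structure_model`.
#' @return The model with the common-frame flag set.
#' @export
mark_superposed <- function(model) {
  attr(model, "superposed") <- TRUE
  model
}

#' @rdname mark_superposed
#' @export
is_superposed <- function(model) isTRUE(attr(model, "superposed"))

# I/O ----------------------------------------------------------------------

#' Read an atomic model from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records via bio3d. Alternate locations are
#' collapsed to the highest-occupancy conformer per atom (first wins on
#' ties); insertion codes are preserved. Waters are recognised by residue
#' name `HOH`; single-atom HETATM species with a metal/halide element are
#' partitioned as ions.
#'
#' @param path file path.
#' @param format "pdb" or "mmcif" (default guessed from the extension).
#' @param condition_label label stored on the model (defaults to the file
#'   base name).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           condition_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model: ", path)
  element <- toupper(trimws(a$elesy))
  noel <- is.na(element) | !nzchar(element)
  if (any(noel)) # fall back to the first letter of the atom name
    element[noel] <- toupper(substr(gsub("[^A-Za-z].*", "",
                                         trimws(a$elety[noel])), 1, 1))
  atoms <- data.frame(
    record = a$type,
    element = element,
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_id = as.integer(a$resno),
    chain_id = ifelse(is.na(a$chain) | !nzchar(a$chain), " ", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  atoms <- collapse_altlocs(atoms)
  atoms$altloc <- NULL
  if (is.null(condition_label))
    condition_label <- sub("\\.[^.]*$", "", basename(path))
  structure_model(atoms, condition_label)
}

# keep the highest-occupancy altloc per atom identity; first wins on ties
collapse_altlocs <- function(atoms) {
  has_alt <- nzchar(atoms$altloc)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain_id, atoms$residue_id, atoms$insert,
               atoms$residue_name, atoms$atom_name, sep = "|")
  ord <- order(seq_len(nrow(atoms)))  # stable
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      best <- idx[which.max(atoms$occupancy[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atoms[keep, , drop = FALSE]
}

#' Write a structure model as PDB
#'
#' Coordinates are written at the PDB format's 3-decimal precision;
#' round-tripping a model through `write_structure()` / `read_structure()`
#' preserves coordinates to that precision.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = a$record,
                   resno = a$residue_id, resid = a$residue_name,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = ifelse(a$chain_id == " ", "", a$chain_id),
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   o = a$occupancy, b = a$b_factor, elesy = a$element)
  invisible(path)
}

#' Extract one chain (the asymmetric unit)
#'
#' Keeps the protein atoms of `chain_id` together with the waters and ions
#' whose `chain_id` matches, i.e. the solvent previously assigned to that
#' chain (see [assign_solvent_chains()]).
#'
#' @param model a `structure_model`.
#' @param chain_id single character chain identifier.
#' @return A `structure_model` restricted to that chain.
#' @export
extract_chain <- function(model, chain_id) {
  chains <- sort(unique(model$atoms$chain_id[is_protein_atom(model)]))
  if (!chain_id %in% chains)
    stop("chain '", chain_id, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  keep <- model$atoms$chain_id == chain_id
  out <- model
  out$atoms <- model$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}
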