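#' Construct an MD trajectory
#'
#' A minimal in-memory trajectory: a protein topology (atom table), protein
#' coordinates and water-oxygen coordinates per frame, and the frame
#' spacing in picoseconds. Atom identity is constant across frames by
#' construction (coordinates are dense arrays).
#'
#' @param topology atom table for the protein (columns as in
#'   [structure_model()]; waters excluded).
#' @param protein_xyz numeric array `n_protein x 3 x n_frames`.
#' @param water_xyz numeric array `n_waters x 3 x n_frames` (may have 0
#'   rows).
#' @param frame_interval_ps time between consecutive frames, ps.
#' @param start_time_ns time of the first frame, ns.
#' @return An `md_trajectory`.
#' @export
md_trajectory <- function(topology, protein_xyz, water_xyz,
                          frame_interval_ps, start_time_ns = 0) {
  stopifnot(length(dim(protein_xyz)) == 3L, dim(protein_xyz)[2] == 3L,
            length(dim(water_xyz)) == 3L, dim(water_xyz)[2] == 3L,
            dim(protein_xyz)[3] == dim(water_xyz)[3])
  if (dim(protein_xyz)[1] != nrow(topology))
    stop("protein_xyz rows must match topology atoms")
  if (frame_interval_ps <= 0) stop("frame_interval_ps must be > 0")
  structure(list(topology = topology, protein_xyz = protein_xyz,
                 water_xyz = water_xyz,
                 frame_interval_ps = frame_interval_ps,
                 start_time_ns = start_time_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<md_trajectory> %d frames x (%d protein + %d water) ",
                     "atoms, dt %.3g ps (%.3g ns total)\n"),
              n_frames(x), dim(x$protein_xyz)[1], dim(x$water_xyz)[1],
              x$frame_interval_ps, n_frames(x) * x$frame_interval_ps / 1000))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$protein_xyz)[3]

# readers ------------------------------------------------------------------

#' Read a trajectory from an XYZ file plus a PDB topology
#'
#' The topology PDB defines atom identity and ordering (protein atoms and
#' water oxygens, in file order); the XYZ file holds one block per frame
#' (`n` line, comment line, then `element x y z` rows) with atoms in the
#' same order.
#'
#' @param xyz_path multi-frame XYZ file.
#' @param topology_path PDB file with the same atoms (waters as `HOH`).
#' @param frame_interval_ps frame spacing, ps.
#' @return An `md_trajectory`.
#' @export
read_trajectory_xyz <- function(xyz_path, topology_path, frame_interval_ps) {
  topo <- read_structure(topology_path)
  lines <- readLines(xyz_path)
  natoms <- suppressWarnings(as.integer(lines[1]))
  if (is.na(natoms) || natoms <= 0)
    stop("malformed XYZ: first line is not an atom count")
  block <- natoms + 2L
  nf <- length(lines) %/% block
  if (nf < 1L || length(lines) %% block != 0L)
    stop("malformed XYZ: file length is not a whole number of frames")
  coord_rows <- rep(seq_len(block) > 2L, nf)
  con <- textConnection(lines[coord_rows])
  on.exit(close(con))
  tab <- read.table(con, col.names = c("el", "x", "y", "z"),
                    colClasses = c("character", rep("numeric", 3)))
  if (nrow(tab) != natoms * nf) stop("malformed XYZ coordinate rows")
  is_w <- is_water_oxygen(topo)
  keep <- is_protein_atom(topo) | is_w
  if (sum(keep) != natoms)
    stop("topology has ", sum(keep), " protein/water atoms but XYZ frames ",
         "have ", natoms)
  xyz <- array(NA_real_, c(natoms, 3, nf))
  m <- as.matrix(tab[, c("x", "y", "z")])
  for (f in seq_len(nf))
    xyz[, , f] <- m[((f - 1L) * natoms + 1L):(f * natoms), ]
  ord <- which(keep)
  wsel <- is_w[ord]
  md_trajectory(topology = topo$atoms[ord[!wsel], , drop = FALSE],
                protein_xyz = xyz[!wsel, , , drop = FALSE],
                water_xyz = xyz[wsel, , , drop = FALSE],
                frame_interval_ps = frame_interval_ps)
}

#' Read a trajectory from a multi-model PDB
#'
#' @param path multi-model (NMR-style) PDB file.
#' @param frame_interval_ps frame spacing, ps.
#' @return An `md_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_interval_ps) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  topo <- read_structure(path)   # first model defines identity
  nf <- nrow(pdb$xyz)
  natoms <- ncol(pdb$xyz) / 3L
  if (natoms != nrow(topo$atoms))
    stop("atom count mismatch between models in ", path)
  xyz <- array(NA_real_, c(natoms, 3, nf))
  for (f in seq_len(nf))
    xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  is_w <- is_water_oxygen(topo)
  is_p <- is_protein_atom(topo)
  md_trajectory(topology = topo$atoms[is_p, , drop = FALSE],
                protein_xyz = xyz[is_p, , , drop = FALSE],
                water_xyz = xyz[is_w, , , drop = FALSE],
                frame_interval_ps = frame_interval_ps)
}

# windows ------------------------------------------------------------------

#' Sample analysis windows from a trajectory
#'
#' Extracts non-overlapping windows of `window_frames` consecutive frames,
#' one ending at each multiple of `interval_ns` (e.g. a 100 ns trajectory
#' sampled with 1 ns windows at 10 ns intervals yields 10 windows ending at
#' 10, 20, ..., 100 ns). Downstream statistics are averaged over windows.
#'
#' @param traj an `md_trajectory`.
#' @param window_frames frames per window.
#' @param interval_ns spacing between window anchors, ns.
#' @return list of `md_trajectory` windows (with `start_time_ns` set).
#' @export
sample_windows <- function(traj, window_frames, interval_ns) {
  fpi <- round(interval_ns * 1000 / traj$frame_interval_ps)
  if (fpi < 1L) stop("interval shorter than one frame")
  if (window_frames > fpi)
    stop("window_frames (", window_frames, ") exceeds the frames per ",
         "interval (", fpi, "); windows would overlap")
  nf <- n_frames(traj)
  n_windows <- nf %/% fpi
  if (n_windows < 1L)
    stop("trajectory too short: ", nf, " frames, need at least ", fpi,
         " (one ", interval_ns, " ns interval)")
  lapply(seq_len(n_windows), function(k) {
    anchor <- k * fpi
    sel <- (anchor - window_frames + 1L):anchor
    md_trajectory(traj$topology,
                  traj$protein_xyz[, , sel, drop = FALSE],
                  traj$water_xyz[, , sel, drop = FALSE],
                  traj$frame_interval_ps,
                  start_time_ns = traj$start_time_ns +
                    (sel[1] - 1L) * traj$frame_interval_ps / 1000)
  })
}

#' Align every frame of a window on a reference protein conformation
#'
#' Rigid-body superposes each frame's protein atoms on the reference
#' (default: the window's first frame) by the Kabsch fit and co-transforms
#' the water coordinates.
#'
#' @param window an `md_trajectory`.
#' @param reference `n_protein x 3` coordinate matrix, or NULL for the
#'   first frame.
#' @return list with `window` (aligned) and `rmsd` (per-frame protein RMSD
#'   to the reference after the fit).
#' @export
align_window <- function(window, reference = NULL) {
  nP <- dim(window$protein_xyz)[1]
  if (is.null(reference)) reference <- window$protein_xyz[, , 1]
  reference <- as.matrix(reference)
  if (!all(dim(reference) == c(nP, 3)))
    stop("reference must be an ", nP, " x 3 coordinate matrix matching ",
         "the window's protein atoms")
  cb <- colMeans(reference)
  Bm <- sweep(reference, 2, cb)
  nf <- n_frames(window)
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    A <- window$protein_xyz[, , f]
    ca <- colMeans(A)
    R <- kabsch_rotation(sweep(A, 2, ca), Bm)
    tr <- cb - as.numeric(ca %*% R)
    Af <- sweep(A %*% R, 2, tr, "+")
    window$protein_xyz[, , f] <- Af
    rmsd[f] <- sqrt(mean(rowSums((Af - reference)^2)))
    if (dim(window$water_xyz)[1] > 0)
      window$water_xyz[, , f] <-
        sweep(window$water_xyz[, , f, drop = FALSE][, , 1] %*% R, 2, tr, "+")
  }
  list(window = window, rmsd = rmsd)
}
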