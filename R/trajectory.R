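#' Construct a trajectory object
#'
#' Shared container for time-ordered particle coordinates with a topology,
#' used for both coarse-grained simulator output and externally produced
#' all-atom trajectories. Coordinates are in nm, times in ps. The topology
#' labels every atom with chain, residue, residue type, atom name, element and
#' mass, which is what the contact, compaction and amide-vector analyses need.
#'
#' @param coords numeric array `c(n_frames, n_atoms, 3)` in nm.
#' @param topology data.frame with one row per atom and columns `atom` (name,
#'   e.g. "CA", "N", "H"), `resid` (integer residue number), `resname`
#'   (one-letter code), `chain` (integer chain id), `mass` (amu), `element`
#'   (element symbol; "H" marks non-heavy atoms).
#' @param box numeric length-3 box edge lengths (nm), or NULL for
#'   non-periodic.
#' @param time numeric frame times in ps (strictly increasing); defaults to
#'   `0:(n_frames-1)`.
#' @param bonds optional integer matrix (n_bonds x 2) of 1-based atom indices.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, topology, box = NULL, time = NULL,
                       bonds = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  stopifnot(nrow(topology) == n_atoms)
  req <- c("atom", "resid", "resname", "chain", "mass", "element")
  miss <- setdiff(req, names(topology))
  if (length(miss) > 0L) stop("topology lacks column(s): ",
                              paste(miss, collapse = ", "))
  if (is.null(time)) time <- as.numeric(seq_len(n_frames) - 1L)
  stopifnot(length(time) == n_frames)
  if (n_frames > 1L && any(diff(time) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!is.null(box)) stopifnot(length(box) == 3, all(box > 0))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(coords = coords, topology = topology,
                 box = if (is.null(box)) NULL else as.numeric(box),
                 time = as.numeric(time), bonds = bonds),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %d chains%s\n",
              n_frames(x), n_atoms(x), length(unique(x$topology$chain)),
              if (is.null(x$box)) "" else
                sprintf(", box %.2f x %.2f x %.2f nm", x$box[1], x$box[2],
                        x$box[3])))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Subset the frames of a trajectory
#'
#' @param traj a [trajectory()].
#' @param frames integer frame indices to keep.
#' @return a [trajectory()] with the selected frames.
#' @export
subset_frames <- function(traj, frames) {
  trajectory(traj$coords[frames, , , drop = FALSE], traj$topology,
             box = traj$box, time = traj$time[frames], bonds = traj$bonds)
}

heavy_atoms <- function(traj) which(traj$topology$element != "H")

#' Make chains whole across periodic boundaries
#'
#' Rebuilds each chain by walking consecutive atoms (topology order within a
#' chain) and removing box jumps larger than half the box, so that intra-chain
#' geometry (Rg, inter-residue distances) is computed on whole molecules.
#' Non-periodic trajectories are returned unchanged.
#'
#' @param traj a [trajectory()].
#' @return an unwrapped [trajectory()].
#' @export
unwrap_chains <- function(traj) {
  if (is.null(traj$box)) return(traj)
  coords <- traj$coords
  box <- traj$box
  chains <- traj$topology$chain
  for (ch in unique(chains)) {
    idx <- which(chains == ch)
    if (length(idx) < 2L) next
    for (k in 2L:length(idx)) {
      d <- coords[, idx[k], , drop = FALSE] - coords[, idx[k - 1L], , drop = FALSE]
      for (dim3 in 1:3) {
        shift <- round(d[, 1, dim3] / box[dim3]) * box[dim3]
        coords[, idx[k], dim3] <- coords[, idx[k], dim3] - shift
      }
    }
  }
  trajectory(coords, traj$topology, box = box, time = traj$time,
             bonds = traj$bonds)
}

#' Detect chains broken across the periodic box
#'
#' @param traj a [trajectory()].
#' @return TRUE if any consecutive intra-chain atom pair is farther apart than
#'   half the box in some dimension in some frame.
#' @export
has_wrapped_chains <- function(traj) {
  if (is.null(traj$box)) return(FALSE)
  chains <- traj$topology$chain
  for (ch in unique(chains)) {
    idx <- which(chains == ch)
    if (length(idx) < 2L) next
    d <- abs(traj$coords[, idx[-1L], , drop = FALSE] -
               traj$coords[, idx[-length(idx)], , drop = FALSE])
    for (dim3 in 1:3) {
      if (any(d[, , dim3] > traj$box[dim3] / 2)) return(TRUE)
    }
  }
  FALSE
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, CA-style records (coordinates converted
#' from nm to Angstrom), with a CRYST1 record carrying the box. The format is
#' plain text and readable by standard structural-biology tools (e.g. bio3d).
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, frames = seq_len(n_frames(traj))) {
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  top <- traj$topology
  resn <- ifelse(top$resname %in% names(aa3), aa3[top$resname], "UNK")
  chain_letters <- rep(c(LETTERS, letters, 0:9), length.out =
                         max(top$chain))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       traj$box[1] * 10, traj$box[2] * 10, traj$box[3] * 10),
               con)
  }
  for (f in frames) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- traj$coords[f, , ] * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(top)) %% 100000L,
      substr(top$atom, 1, 4), resn, chain_letters[top$chain],
      top$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      substr(top$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a multi-model PDB into a trajectory
#'
#' Minimal reader for the multi-model PDB files produced by
#' [write_trajectory_pdb()] and by standard MD tools: parses ATOM records,
#' groups MODEL blocks into frames, converts Angstrom to nm, and assigns
#' masses/elements from the atom records. For DCD/XTC inputs read the frames
#' with an external tool (e.g. bio3d's `read.dcd`) and build the container
#' with [trajectory()].
#'
#' @param path PDB file.
#' @param time_step_ps spacing of frame time stamps, ps.
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(path, time_step_ps = 1) {
  aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  lines <- readLines(path)
  box <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) > 0L) {
    box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33))) / 10
  }
  model_starts <- grep("^MODEL", lines)
  atom_idx <- grep("^ATOM", lines)
  if (length(model_starts) == 0L) {
    frame_of <- rep(1L, length(atom_idx))
  } else {
    frame_of <- findInterval(atom_idx, model_starts)
  }
  n_fr <- max(frame_of)
  first <- lines[atom_idx[frame_of == 1L]]
  n_at <- length(first)
  atom <- trimws(substr(first, 13, 16))
  resn3 <- trimws(substr(first, 18, 20))
  chain_ch <- substr(first, 22, 22)
  resid <- as.integer(substr(first, 23, 26))
  element <- trimws(substr(first, 77, 78))
  element[element == ""] <- substr(atom[element == ""], 1, 1)
  resname <- ifelse(resn3 %in% names(aa1), aa1[resn3], "G")
  mass <- HPS_URRY_TABLE$mass[match(resname, HPS_URRY_TABLE$aa)]
  mass[element == "H"] <- 1.008
  coords <- array(NA_real_, dim = c(n_fr, n_at, 3))
  all_atoms <- lines[atom_idx]
  x <- as.numeric(substr(all_atoms, 31, 38)) / 10
  y <- as.numeric(substr(all_atoms, 39, 46)) / 10
  z <- as.numeric(substr(all_atoms, 47, 54)) / 10
  for (f in seq_len(n_fr)) {
    sel <- which(frame_of == f)
    coords[f, , 1] <- x[sel]
    coords[f, , 2] <- y[sel]
    coords[f, , 3] <- z[sel]
  }
  topology <- data.frame(atom = atom, resid = resid, resname = resname,
                         chain = as.integer(factor(chain_ch,
                                                   levels = unique(chain_ch))),
                         mass = mass, element = element,
                         stringsAsFactors = FALSE)
  trajectory(coords, topology, box = box,
             time = (seq_len(n_fr) - 1) * time_step_ps)
}
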