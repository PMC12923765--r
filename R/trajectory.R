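#' Construct a trajectory object
#'
#' A trajectory is an ordered set of coordinate frames over a fixed topology.
#' The topology is a data frame of per-atom records (serial, name,
#' residue_name, chain_id, residue_number, element); every frame is an
#' `n_atoms x 3` matrix of coordinates in Angstroms. Residue numbers follow
#' author (PDB) numbering, 1-based, and are never renumbered.
#'
#' @param topology data frame with columns `serial`, `name`, `residue_name`,
#'   `chain_id`, `residue_number`, `element`.
#' @param frames list of `n_atoms x 3` numeric matrices (Angstroms).
#' @param frame_times optional numeric vector of frame times (ns), strictly
#'   increasing.
#' @param box optional numeric triple of orthorhombic box lengths (Angstroms).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, frame_times = NULL, box = NULL) {
  required <- c("serial", "name", "residue_name", "chain_id",
                "residue_number", "element")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols))
    stop("topology lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!is.list(frames) || !length(frames))
    stop("frames must be a non-empty list of coordinate matrices")
  n_atoms <- nrow(topology)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!is.matrix(fr) || ncol(fr) != 3L)
      stop("frame ", k, " is not an n x 3 matrix")
    if (nrow(fr) != n_atoms)
      stop("frame ", k, " has ", nrow(fr), " atoms; topology has ", n_atoms)
    if (!all(is.finite(fr)))
      stop("frame ", k, " contains non-finite coordinates")
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != length(frames))
      stop("frame_times length must equal number of frames")
    if (any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  if (!is.null(box) && (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)))
    stop("box must be a positive numeric triple")
  if (any(nchar(as.character(topology$name)) == 0))
    stop("atom names must be non-empty")
  structure(
    list(topology = topology, frames = frames,
         frame_times = frame_times, box = box),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,", nrow(x$topology), "atoms")
  if (!is.null(x$frame_times))
    cat(sprintf(", t = %.3g..%.3g ns", x$frame_times[1],
                x$frame_times[length(x$frame_times)]))
  if (!is.null(x$box))
    cat(sprintf(", box %.1f x %.1f x %.1f A", x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Number of atoms in a trajectory
#' @param traj trajectory.
#' @return integer atom count.
#' @export
n_atoms <- function(traj) nrow(traj$topology)

#' Subset a trajectory by frame index
#' @param traj trajectory.
#' @param idx integer frame indices (1-based).
#' @return trajectory restricted to those frames.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > n_frames(traj)))
    stop("frame index out of range")
  trajectory(traj$topology, traj$frames[idx],
             frame_times = if (!is.null(traj$frame_times)) traj$frame_times[idx],
             box = traj$box)
}

# element inferred from PDB v3 atom-name conventions when the element
# column is absent: leading digits stripped, two-letter elements recognised
infer_element <- function(atom_name) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(atom_name)))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA")
  # bare "CA" in a protein context is an alpha carbon, not calcium; only map
  # two-letter elements when the name is exactly that element
  out <- substr(nm, 1, 1)
  is2 <- nm %in% setdiff(known2, "CA")
  out[is2] <- two[is2]
  out
}
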