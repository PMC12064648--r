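# Trajectory container: fixed topology + ordered coordinate frames.

#' Construct a trajectory
#'
#' @param topology an `md_structure`; its atom order defines the frame
#'   layout.
#' @param frames either a list of n_atoms x 3 matrices or a 3-d array
#'   `(n_atoms, 3, n_frames)`, coordinates in angstroms.
#' @param times per-frame time stamps in nanoseconds; strictly increasing.
#'   Default: frame indices 0, 1, 2, ...
#' @return object of class `md_trajectory` with fields `topology`,
#'   `coords` (n_atoms x 3 x n_frames array) and `times`.
#' @export
md_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "md_structure"))
  na <- n_atoms(topology)
  if (is.list(frames)) {
    nf <- length(frames)
    stopifnot(nf >= 1)
    for (i in seq_len(nf)) {
      f <- frames[[i]]
      if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3) {
        stop("frame ", i, " has wrong shape: expected ", na, " x 3")
      }
    }
    coords <- array(unlist(frames, use.names = FALSE), dim = c(na, 3, nf))
    # unlist concatenates column-major per matrix, matching array layout
  } else {
    stopifnot(is.array(frames), length(dim(frames)) == 3)
    if (dim(frames)[1] != na || dim(frames)[2] != 3) {
      stop("coordinate array must be n_atoms x 3 x n_frames")
    }
    coords <- frames
    nf <- dim(frames)[3]
  }
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1)
  stopifnot(length(times) == nf)
  if (nf > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  structure(list(topology = topology, coords = coords, times = times),
            class = "md_trajectory")
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one trajectory frame
#' @param traj an `md_trajectory`
#' @param i frame number (1-based)
#' @return n_atoms x 3 matrix, angstroms.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "md_trajectory: %d frames x %d atoms, t = %.3f..%.3f ns\n",
    n_frames(x), dim(x$coords)[1], x$times[1], x$times[n_frames(x)]))
  invisible(x)
}
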