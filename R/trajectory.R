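## Trajectory container: ordered frames of coordinates (nm) over a fixed
## atom roster, with timestamps (ps).

#' Construct a trajectory
#'
#' @param topology A `psi_topology`.
#' @param xyz Numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   flat `x1,y1,z1,x2,...` order, units nm.
#' @param times Numeric vector of frame times (ps), strictly increasing.
#' @param box Optional periodic box vectors (nm); carried, not used.
#' @return Object of class `psi_trajectory`.
#' @export
psi_trajectory <- function(topology, xyz, times, box = NULL) {
  if (!inherits(topology, "psi_topology")) abort("topology must be a psi_topology")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(topology$atoms))
    abort("xyz has ", ncol(xyz), " columns; expected ",
          3L * nrow(topology$atoms), " (3 per topology atom)")
  if (nrow(xyz) != length(times))
    abort("length(times) must equal the number of frames")
  if (length(times) > 1L && any(diff(times) <= 0))
    abort("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times),
                 box = box),
            class = "psi_trajectory")
}

#' @rdname psi_trajectory
#' @param traj A `psi_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @export
print.psi_trajectory <- function(x, ...) {
  cat("psi_trajectory:", n_frames(x), "frames,",
      nrow(x$topology$atoms), "atoms, t =", x$times[1], "..",
      x$times[length(x$times)], "ps\n")
  invisible(x)
}

## one frame as an n_atoms x 3 matrix
frame_xyz <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}
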