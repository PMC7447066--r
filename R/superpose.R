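## Least-squares rigid-body superposition (Kabsch algorithm).

#' Optimal rigid superposition of one frame onto a reference
#'
#' Computes the proper rotation (det = +1) and translation minimising the
#' least-squares deviation of the fit selection, and applies the transform
#' to all atoms of the mobile frame. Fitting and measurement selections may
#' differ, which is how loop-excluded fitting is realised.
#'
#' @param mobile Numeric: flat xyz vector or `n x 3` matrix (nm).
#' @param reference Same shape as `mobile`.
#' @param fit_idx Atom indices used for the fit (default all atoms); at
#'   least 3 non-collinear atoms are required.
#' @return List with `xyz` (transformed mobile, same shape as input), `R`
#'   (3x3 rotation), `t` (translation), and `rmsd_fit` (nm, over the fit
#'   selection).
#' @export
superpose <- function(mobile, reference, fit_idx = NULL) {
  flat <- is.null(dim(mobile))
  M <- if (flat) matrix(mobile, ncol = 3L, byrow = TRUE) else as.matrix(mobile)
  Rf <- if (is.null(dim(reference))) matrix(reference, ncol = 3L, byrow = TRUE)
        else as.matrix(reference)
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(M))
  if (length(fit_idx) < 3L)
    abort("superposition needs at least 3 fit atoms")
  P <- M[fit_idx, , drop = FALSE]
  Q <- Rf[fit_idx, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  ## degenerate fit sets (coincident or collinear atoms) have rank < 2
  s_p <- svd(P0, nu = 0, nv = 0)$d
  if (length(s_p) < 2L || s_p[2] < 1e-8 * max(s_p[1], 1e-12))
    abort("degenerate fit selection (coincident or collinear atoms)")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)  # applied as x %*% t(rot)
  transform <- function(X) sweep(sweep(X, 2, pc) %*% t(rot), 2, qc, `+`)
  out <- transform(M)
  fitted <- out[fit_idx, , drop = FALSE]
  rmsd_fit <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(xyz = if (flat) as.numeric(t(out)) else out,
       R = rot, t = qc - as.numeric(pc %*% t(rot)), rmsd_fit = rmsd_fit)
}

## plain RMSD between two coordinate sets over an atom selection
rmsd_xyz <- function(a, b, idx = NULL) {
  A <- if (is.null(dim(a))) matrix(a, ncol = 3L, byrow = TRUE) else as.matrix(a)
  B <- if (is.null(dim(b))) matrix(b, ncol = 3L, byrow = TRUE) else as.matrix(b)
  if (!is.null(idx)) {
    A <- A[idx, , drop = FALSE]
    B <- B[idx, , drop = FALSE]
  }
  sqrt(mean(rowSums((A - B)^2)))
}
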