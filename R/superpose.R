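# Rigid-body ensemble superposition (Kabsch least squares).
#
# Fluctuation statistics are only meaningful after overall rotation and
# translation have been removed, so every ensemble is rigidly fitted before
# RMSF/PCC are computed.  The fit is two-pass: frames are first fitted to
# frame 1 on the fit selection, the time-average structure of that pass is
# computed, and each frame is then re-fitted to the average.  Fitting to the
# run average (rather than to a crystal reference) minimises the total
# fluctuation attributed to rigid motion.

# Optimal proper rotation R and translation mapping rows of P onto Q.
# Returns list(R, p0, q0, sv); fitted = sweep(P,2,p0) %*% R + q0.
kabsch <- function(P, Q) {
  p0 <- colMeans(P)
  q0 <- colMeans(Q)
  H <- crossprod(sweep(P, 2, p0), sweep(Q, 2, q0))
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, p0 = p0, q0 = q0, sv = s$d)
}

apply_rigid <- function(X, fit) {
  sweep(sweep(X, 2, fit$p0) %*% fit$R, 2, fit$q0, "+")
}

# Fit every frame to the target structure on fit_selection; the derived
# rigid transform is applied to all atoms of the frame.
fit_frames_to <- function(coords, target_fit, fit_idx1, check = FALSE) {
  nfr <- dim(coords)[1]
  out <- coords
  for (f in seq_len(nfr)) {
    P <- coords[f, fit_idx1, , drop = TRUE]
    fit <- kabsch(P, target_fit)
    if (check && fit$sv[2] < 1e-8 * max(fit$sv[1], 1))
      stop("fit selection is collinear/degenerate in frame ", f)
    out[f, , ] <- apply_rigid(coords[f, , , drop = TRUE], fit)
  }
  out
}

#' Superpose an ensemble by two-pass least-squares fitting
#'
#' Removes overall translation and rotation.  Pass 1 fits every frame to
#' frame 1 on `fit_selection`; pass 2 re-fits every frame to the pass-1
#' time-average structure.  The rigid transform is estimated on
#' `fit_selection` but applied to all atoms, so intra-frame geometry is
#' untouched.
#'
#' @param ensemble an `flx_ensemble`.
#' @param fit_selection 0-based atom indices to fit on; needs at least 3
#'   non-collinear atoms in every frame.  Conventionally the receptor
#'   backbone heavy atoms.
#' @param target optional atoms x 3 coordinates fixing the overall pose:
#'   pass 1 fits to `target` instead of frame 1.  The per-pair correlation
#'   components are basis-dependent, so ensembles whose statistics will be
#'   differenced (active vs inactive) should be superposed to a common
#'   target pose.
#' @return the fitted `flx_ensemble`.
#' @export
superpose_ensemble <- function(ensemble, fit_selection, target = NULL) {
  stopifnot(inherits(ensemble, "flx_ensemble"))
  fit_idx <- as.integer(fit_selection) + 1L
  if (length(fit_idx) < 3L)
    stop("fit selection needs >= 3 atoms")
  if (any(fit_idx < 1L) || any(fit_idx > dim(ensemble$coords)[2]))
    stop("fit selection out of range")
  pass1_target <- if (is.null(target))
    ensemble$coords[1, fit_idx, , drop = TRUE]
  else {
    stopifnot(nrow(target) == dim(ensemble$coords)[2])
    target[fit_idx, , drop = FALSE]
  }
  pass1 <- fit_frames_to(ensemble$coords, pass1_target, fit_idx,
                         check = TRUE)
  avg <- apply(pass1, c(2, 3), mean)
  pass2 <- fit_frames_to(pass1, avg[fit_idx, , drop = FALSE], fit_idx)
  ensemble$coords <- pass2
  ensemble
}

# RMSD between two atoms x 3 coordinate matrices (no fitting).
coord_rmsd <- function(A, B) {
  sqrt(mean(rowSums((A - B)^2)))
}
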