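# Per-atom and per-pair fluctuation statistics.
#
# RMSF_i = sqrt(<dx_i^2> + <dy_i^2> + <dz_i^2>), with deviations taken about
# the ensemble mean and averages using denominator T (the plain ensemble
# mean), not T-1.
#
# For an atom pair (i, j) the 3x3 covariance submatrix C_ij with entries
# <da_i db_j> (a, b in {x, y, z}) is normalised per component by the axis
# standard deviations to the Pearson submatrix R_ij, and the scalar pair
# statistic is PCC_ij = sqrt(sum of the 9 squared components).  A "mean"
# normalisation variant (divide the component sum by 9 before the root)
# is available; it rescales every PCC by the constant 1/sqrt(9).

#' Per-atom root mean square fluctuation
#'
#' @param ensemble a superposed `flx_ensemble` with >= 2 frames (the
#'   function does not re-fit; see [superpose_ensemble()]).
#' @param selection 0-based atom indices to evaluate.
#' @return an `flx_fluct_profile`: list with `ligand_id`, `state`,
#'   `atom_indices` and non-negative `rmsf` (Angstrom) of equal length.
#' @examples
#' co <- array(0, c(2, 1, 3)); co[2, 1, 1] <- 2
#' e <- new_ensemble(co, "toy", "inactive")
#' compute_rmsf(e, 0L)$rmsf  # 1.0
#' @export
compute_rmsf <- function(ensemble, selection) {
  stopifnot(inherits(ensemble, "flx_ensemble"))
  if (!length(selection)) stop("empty selection")
  idx <- as.integer(selection) + 1L
  co <- ensemble$coords[, idx, , drop = FALSE]
  Tn <- dim(co)[1]
  mu <- apply(co, c(2, 3), mean)
  # sum over axes of per-axis mean squared deviation, denominator T
  msd <- numeric(dim(co)[2])
  for (ax in 1:3) {
    dev <- matrix(co[, , ax], nrow = Tn)
    dev <- sweep(dev, 2, mu[, ax])
    msd <- msd + colSums(dev^2) / Tn
  }
  structure(list(ligand_id = ensemble$ligand_id, state = ensemble$state,
                 atom_indices = as.integer(selection),
                 rmsf = as.numeric(sqrt(msd))),
            class = "flx_fluct_profile")
}

#' @export
print.flx_fluct_profile <- function(x, ...) {
  cat(sprintf("<flx_fluct_profile> %s/%s: %d atoms, RMSF %.3f-%.3f A\n",
              x$ligand_id, x$state, length(x$rmsf),
              min(x$rmsf), max(x$rmsf)))
  invisible(x)
}

#' Write a fluctuation profile as TSV
#'
#' Columns: 1-based atom serial, residue number, RMSF (Angstrom).
#'
#' @param profile an `flx_fluct_profile`.
#' @param topology matching `flx_topology`.
#' @param path output file.
#' @export
write_fluct_profile <- function(profile, topology, path) {
  a <- topology$atoms
  row <- match(profile$atom_indices, a$atom_index)
  write_tsv(data.frame(serial = a$serial[row],
                       residue = a$residue_number[row],
                       rmsf = profile$rmsf), path)
}

#' Pairwise cross-correlation statistics
#'
#' For each requested pair computes the 9 Pearson correlation components
#' between the two atoms' x/y/z deviation series and the scalar PCC (root
#' of the component sum of squares).  Self-pairs `(i, i)` are allowed; their
#' PCC lies in `[sqrt(3), 3]`.  A component involving a zero-variance axis
#' is defined as 0 (never NaN) and the pair's degenerate flag is raised.
#'
#' @param ensemble a superposed `flx_ensemble` with >= 3 frames.
#' @param pairs 2-column matrix (or data.frame) of 0-based atom indices.
#' @param pcc_normalization `"sum"` (root of the 9-component sum, the
#'   default) or `"mean"` (root mean: divides the sum by 9).
#' @return an `flx_pair_map`: `pairs`, `rho` (pairs x 9 matrix, columns
#'   `xx, xy, xz, yx, ..., zz` with the first letter naming atom i's axis),
#'   `pcc`, and logical `degenerate`.
#' @export
compute_pair_correlation <- function(ensemble, pairs,
                                     pcc_normalization = c("sum", "mean")) {
  stopifnot(inherits(ensemble, "flx_ensemble"))
  pcc_normalization <- match.arg(pcc_normalization)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  storage.mode(pairs) <- "integer"
  Tn <- dim(ensemble$coords)[1]
  if (Tn < 3L) stop("pair correlation needs >= 3 frames")
  nat <- dim(ensemble$coords)[2]
  if (any(pairs < 0L) || any(pairs >= nat))
    stop("pair index out of range")

  atoms_u <- sort(unique(as.vector(pairs)))
  m <- length(atoms_u)
  # T x 3m deviation matrix, columns grouped x,y,z per atom
  X <- matrix(0, nrow = Tn, ncol = 3L * m)
  for (k in seq_len(m)) {
    blk <- ensemble$coords[, atoms_u[k] + 1L, , drop = TRUE]
    X[, (3L * k - 2L):(3L * k)] <- blk
  }
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / Tn
  v <- diag(C)
  sd <- sqrt(pmax(v, 0))
  zero_var <- sd < 1e-12
  denom <- outer(sd, sd)
  rho_full <- ifelse(denom > 0, C / ifelse(denom > 0, denom, 1), 0)
  rho_full[zero_var, ] <- 0
  rho_full[, zero_var] <- 0

  np <- nrow(pairs)
  comp_names <- c("xx", "xy", "xz", "yx", "yy", "yz", "zx", "zy", "zz")
  rho <- matrix(NA_real_, nrow = np, ncol = 9L,
                dimnames = list(NULL, comp_names))
  degenerate <- logical(np)
  pos <- match(pairs, atoms_u)
  dim(pos) <- dim(pairs)
  for (p in seq_len(np)) {
    ri <- (3L * pos[p, 1] - 2L):(3L * pos[p, 1])
    rj <- (3L * pos[p, 2] - 2L):(3L * pos[p, 2])
    blk <- rho_full[ri, rj, drop = FALSE]
    rho[p, ] <- as.vector(t(blk))      # row-major: xx xy xz yx ...
    degenerate[p] <- any(zero_var[ri]) || any(zero_var[rj])
  }
  ss <- rowSums(rho^2)
  pcc <- if (pcc_normalization == "sum") sqrt(ss) else sqrt(ss / 9)
  structure(list(ligand_id = ensemble$ligand_id, state = ensemble$state,
                 pairs = pairs, rho = rho, pcc = as.numeric(pcc),
                 degenerate = degenerate,
                 normalization = pcc_normalization),
            class = "flx_pair_map")
}

#' @export
print.flx_pair_map <- function(x, ...) {
  cat(sprintf("<flx_pair_map> %s/%s: %d pairs (%d degenerate), PCC norm '%s'\n",
              x$ligand_id, x$state, nrow(x$pairs), sum(x$degenerate),
              x$normalization))
  invisible(x)
}

#' Write a pair-correlation map as TSV
#'
#' Columns: i/j serials (1-based), the 9 correlation components, PCC and
#' the degenerate flag.
#'
#' @param map an `flx_pair_map`.
#' @param topology matching `flx_topology`.
#' @param path output file.
#' @export
write_pair_map <- function(map, topology, path) {
  a <- topology$atoms
  df <- data.frame(i_serial = a$serial[match(map$pairs[, 1], a$atom_index)],
                   j_serial = a$serial[match(map$pairs[, 2], a$atom_index)])
  df <- cbind(df, as.data.frame(map$rho))
  df$pcc <- map$pcc
  df$degenerate <- map$degenerate
  write_tsv(df, path)
}

#' State-monitoring metrics for one ensemble
#'
#' Per-frame monitors used to confirm that a run stays in its conformational
#' state: backbone RMSD to a reference structure, the C-alpha distance
#' between two named residues (for the beta2 adrenergic receptor, the
#' helix 3-helix 6 Arg131-Leu272 distance), the backbone RMSD of the NPxxY
#' motif and the heavy-atom RMSD of the connector region.  RMSD series are
#' computed after fitting each frame to the reference on the monitor
#' config's fit selection; the distance series needs no fitting.
#'
#' @param ensemble an `flx_ensemble`.
#' @param reference atoms x 3 reference coordinates (same topology).
#' @param topology matching `flx_topology`.
#' @param monitor_config list with `distance_residues` (length-2 residue
#'   numbers, C-alpha distance), optional `npxxy_residues` and
#'   `connector_residues` (residue-number vectors), and optional
#'   `fit_selection` (0-based indices; default all backbone heavy atoms).
#' @return an `flx_state_metrics`: per-frame numeric series
#'   `backbone_rmsd`, `ca_distance`, `npxxy_rmsd`, `connector_rmsd`
#'   (the latter two `NULL` when unconfigured).
#' @export
compute_state_metrics <- function(ensemble, reference, topology,
                                  monitor_config) {
  stopifnot(inherits(ensemble, "flx_ensemble"),
            inherits(topology, "flx_topology"))
  a <- topology$atoms
  backbone <- select_atoms(topology, atom_query(
    heavy = TRUE, atom_names = c("N", "CA", "C", "O")))
  fit_sel <- monitor_config$fit_selection %||% backbone
  fit_idx <- as.integer(fit_sel) + 1L

  ca_of <- function(resno) {
    hit <- a$atom_index[a$residue_number == resno & a$is_calpha]
    if (!length(hit)) stop("residue ", resno, " lacks a C-alpha atom")
    hit[1]
  }
  dres <- monitor_config$distance_residues
  if (is.null(dres) || length(dres) != 2L)
    stop("monitor_config$distance_residues must name two residues")
  ca_i <- ca_of(dres[1]) + 1L
  ca_j <- ca_of(dres[2]) + 1L

  rmsd_sel <- function(residues, heavy_only) {
    if (is.null(residues)) return(NULL)
    q <- atom_query(heavy = TRUE, residues = residues)
    idx <- select_atoms(topology, q)
    if (!heavy_only)
      idx <- intersect(idx, backbone)
    idx + 1L
  }
  bb1 <- backbone + 1L
  np1 <- rmsd_sel(monitor_config$npxxy_residues, heavy_only = FALSE)
  cn1 <- rmsd_sel(monitor_config$connector_residues, heavy_only = TRUE)

  nfr <- n_frames(ensemble)
  backbone_rmsd <- numeric(nfr)
  ca_distance <- numeric(nfr)
  npxxy_rmsd <- if (is.null(np1)) NULL else numeric(nfr)
  connector_rmsd <- if (is.null(cn1)) NULL else numeric(nfr)
  ref_fit <- reference[fit_idx, , drop = FALSE]
  for (f in seq_len(nfr)) {
    fr <- ensemble$coords[f, , , drop = TRUE]
    fit <- kabsch(fr[fit_idx, , drop = FALSE], ref_fit)
    fr_fit <- apply_rigid(fr, fit)
    backbone_rmsd[f] <- coord_rmsd(fr_fit[bb1, , drop = FALSE],
                                   reference[bb1, , drop = FALSE])
    ca_distance[f] <- sqrt(sum((fr[ca_i, ] - fr[ca_j, ])^2))
    if (!is.null(np1))
      npxxy_rmsd[f] <- coord_rmsd(fr_fit[np1, , drop = FALSE],
                                  reference[np1, , drop = FALSE])
    if (!is.null(cn1))
      connector_rmsd[f] <- coord_rmsd(fr_fit[cn1, , drop = FALSE],
                                      reference[cn1, , drop = FALSE])
  }
  structure(list(backbone_rmsd = backbone_rmsd, ca_distance = ca_distance,
                 npxxy_rmsd = npxxy_rmsd, connector_rmsd = connector_rmsd),
            class = "flx_state_metrics")
}
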