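# Coordinate ensembles: frames x atoms x 3 arrays in Angstrom for one
# ligand-state run, plus frame bookkeeping.

#' Construct a coordinate ensemble
#'
#' @param coords numeric array with dim `c(frames, atoms, 3)`, Angstrom.
#' @param ligand_id ligand identifier.
#' @param state `"active"` or `"inactive"`.
#' @param frame_interval time per saved frame in ps (default 100, the
#'   trajectory-saving interval the analysis assumes).
#' @param n_discarded number of leading equilibration frames that were
#'   dropped before `coords` was formed (bookkeeping only).
#' @return an `flx_ensemble`.
#' @export
new_ensemble <- function(coords, ligand_id, state,
                         frame_interval = 100, n_discarded = 0L) {
  state <- match.arg(state, c("active", "inactive"))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 2L) stop("ensemble needs >= 2 frames")
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  structure(list(coords = coords, ligand_id = ligand_id, state = state,
                 frame_interval = frame_interval,
                 n_discarded = as.integer(n_discarded)),
            class = "flx_ensemble")
}

#' @export
print.flx_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<flx_ensemble> %s/%s: %d frames x %d atoms (%g ps/frame, %d discarded)\n",
              x$ligand_id, x$state, d[1], d[2], x$frame_interval, x$n_discarded))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `flx_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' Default equilibration discard in frames
#'
#' Equilibration removal is frame-count based: by default the frames
#' spanning the first 20 ns of a run are dropped.
#'
#' @param frame_interval ps per saved frame.
#' @param equilibration_ps equilibration span in ps (default 20000 = 20 ns).
#' @return integer number of frames to discard.
#' @export
default_discard <- function(frame_interval, equilibration_ps = 20000) {
  as.integer(floor(equilibration_ps / frame_interval))
}

#' Load a coordinate ensemble from a multi-model PDB file
#'
#' @param path multi-model PDB file (MODEL/ENDMDL records; a single-model
#'   file is rejected because an ensemble needs at least 2 frames).
#' @param topology the `flx_topology` the frames must match.
#' @param ligand_id,state run identity (see [new_ensemble()]).
#' @param n_discard leading frames dropped as equilibration; must leave at
#'   least 2 frames.  See [default_discard()].
#' @param frame_interval ps per saved frame.
#' @return an `flx_ensemble` with frame order preserved.
#' @export
load_ensemble <- function(path, topology, ligand_id = "unknown",
                          state = "inactive", n_discard = 0L,
                          frame_interval = 100) {
  parsed <- parse_pdb(path)
  if (dim(parsed$coords)[2] != n_atoms(topology))
    stop("frame atom count (", dim(parsed$coords)[2],
         ") does not match topology (", n_atoms(topology), ")")
  total <- dim(parsed$coords)[1]
  if (n_discard < 0L || n_discard > total - 2L)
    stop("n_discard = ", n_discard, " leaves fewer than 2 of ", total,
         " frames")
  keep <- (n_discard + 1L):total
  new_ensemble(parsed$coords[keep, , , drop = FALSE], ligand_id, state,
               frame_interval = frame_interval, n_discarded = n_discard)
}

#' Write an ensemble (or a single structure) as a multi-model PDB file
#'
#' Output uses 1-based serials and the topology's author residue numbers;
#' coordinates are written with the format's 3-decimal precision, so a
#' round trip reproduces them to 1e-3 Angstrom.
#'
#' @param coords either an `flx_ensemble` or an atoms x 3 matrix.
#' @param topology matching `flx_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(coords, topology, path) {
  if (inherits(coords, "flx_ensemble")) coords <- coords$coords
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(dim(coords)[2] == n_atoms(topology))
  a <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  nfr <- dim(coords)[1]
  for (f in seq_len(nfr)) {
    if (nfr > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$atom_index + 1L,
      ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
      a$residue_name,
      ifelse(a$chain_id == "", "A", a$chain_id),
      a$residue_number,
      coords[f, , 1], coords[f, , 2], coords[f, , 3],
      1, 0, a$element)
    writeLines(lines, con)
    if (nfr > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Ensemble-average structure
#'
#' The arithmetic mean position over frames, per atom and axis: the
#' reference about which fluctuations are measured.
#'
#' @param ensemble an `flx_ensemble`.
#' @return atoms x 3 matrix.
#' @export
mean_structure <- function(ensemble) {
  stopifnot(inherits(ensemble, "flx_ensemble"))
  apply(ensemble$coords, c(2, 3), mean)
}
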