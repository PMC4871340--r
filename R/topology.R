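# Topology container and atom selections.
#
# A topology is a table of atom records plus a segment table.  Atom indices
# are 0-based internally; everything written to disk uses 1-based PDB
# serials and author residue numbers.

new_topology <- function(atoms, segments) {
  stopifnot(is.data.frame(atoms), is.data.frame(segments))
  structure(list(atoms = atoms, segments = segments), class = "flx_topology")
}

#' @export
print.flx_topology <- function(x, ...) {
  cat(sprintf("<flx_topology> %d atoms, %d residues, %d segments\n",
              nrow(x$atoms), length(unique(x$atoms$residue_number)),
              nrow(x$segments)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology an `flx_topology`.
#' @return integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

# -- PDB parsing -------------------------------------------------------------

# Parse ATOM/HETATM records of a (possibly multi-model) PDB file.
# Returns list(atoms = data.frame for the first model, coords = frames x
# atoms x 3 array).  Fixed-column parsing per the PDB format spec.
parse_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # frame id per atom line: count MODEL records seen so far (0 if none)
  model_no <- cumsum(is_model)
  frame_of <- model_no[is_atom]
  if (all(frame_of == 0)) frame_of <- rep(1L, sum(is_atom))

  al <- lines[is_atom]
  serial <- as.integer(substr(al, 7, 11))
  name <- trimws(substr(al, 13, 16))
  resn <- trimws(substr(al, 18, 20))
  chain <- trimws(substr(al, 22, 22))
  resi <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  elem <- trimws(substr(al, 77, 78))
  # derive the element from the atom name when columns 77-78 are absent
  miss <- elem == "" | is.na(elem)
  if (any(miss)) {
    guess <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1", name[miss]))
    elem[miss] <- guess
  }
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("unparseable coordinates in ", path)

  frames <- split(seq_along(al), frame_of)
  n_per <- lengths(frames)
  if (length(unique(n_per)) != 1L)
    stop("models in ", path, " differ in atom count")
  nat <- n_per[[1]]
  nfr <- length(frames)

  first <- frames[[1]]
  atoms <- data.frame(
    atom_index = seq_len(nat) - 1L,
    serial = serial[first],
    atom_name = name[first],
    element = toupper(elem[first]),
    residue_number = resi[first],
    residue_name = resn[first],
    chain_id = chain[first],
    stringsAsFactors = FALSE
  )
  coords <- array(NA_real_, dim = c(nfr, nat, 3L))
  for (f in seq_len(nfr)) {
    idx <- frames[[f]]
    coords[f, , 1] <- x[idx]
    coords[f, , 2] <- y[idx]
    coords[f, , 3] <- z[idx]
  }
  list(atoms = atoms, coords = coords)
}

# Assign segment ids from a segment table (segment_id -> c(first, last)
# residue numbers); unmapped residues get consecutive "loop:auto<n>" ids,
# one per contiguous run of unmapped residues.
assign_segments <- function(atoms, segment_config) {
  resi_order <- unique(atoms$residue_number)
  seg_of <- setNames(rep(NA_character_, length(resi_order)),
                     as.character(resi_order))
  seg_rows <- list()
  if (length(segment_config)) {
    rng <- lapply(segment_config, function(r) as.integer(unlist(r)[1:2]))
    # reject overlapping ranges and ranges that touch no existing residue
    lo <- vapply(rng, `[`, integer(1), 1L)
    hi <- vapply(rng, `[`, integer(1), 2L)
    if (any(hi < lo)) stop("segment range with last < first")
    o <- order(lo)
    if (any(lo[o][-1] <= hi[o][-length(o)]))
      stop("overlapping segment ranges in segment config")
    for (k in seq_along(rng)) {
      sid <- names(segment_config)[k]
      members <- resi_order[resi_order >= lo[k] & resi_order <= hi[k]]
      if (!length(members))
        stop("segment '", sid, "' references no existing residue")
      seg_of[as.character(members)] <- sid
      seg_rows[[sid]] <- data.frame(segment_id = sid, first_residue = lo[k],
                                    last_residue = hi[k],
                                    stringsAsFactors = FALSE)
    }
  }
  # auto loops over contiguous unmapped runs (in residue order)
  auto_n <- 0L
  in_run <- FALSE
  for (i in seq_along(resi_order)) {
    if (is.na(seg_of[i])) {
      if (!in_run) { auto_n <- auto_n + 1L; in_run <- TRUE }
      seg_of[i] <- paste0("loop:auto", auto_n)
    } else in_run <- FALSE
  }
  for (sid in unique(seg_of[grepl("^loop:auto", seg_of)])) {
    members <- resi_order[seg_of == sid]
    seg_rows[[sid]] <- data.frame(segment_id = sid,
                                  first_residue = min(members),
                                  last_residue = max(members),
                                  stringsAsFactors = FALSE)
  }
  atoms$segment_id <- unname(seg_of[as.character(atoms$residue_number)])
  list(atoms = atoms, segments = do.call(rbind, unname(seg_rows)))
}

#' Load a topology from a PDB file
#'
#' Reads the first model of a (multi-model) PDB file and builds the atom
#' table used throughout the package: 0-based `atom_index`, heavy-atom and
#' C-alpha flags, per-residue segment membership and optional
#' Ballesteros-Weinstein (BW) labels.  BW labels are annotations supplied
#' by configuration, never inferred from sequence.
#'
#' @param path PDB file.
#' @param segment_config named list (or JSON/YAML file path) mapping
#'   `segment_id` to `c(first_residue, last_residue)`; residues not covered
#'   by any segment are assigned consecutive `"loop:auto<n>"` segments.
#' @param bw_config optional named list (or config file path) mapping
#'   residue numbers (as names) to BW strings such as `"6.30"`.
#' @return an `flx_topology`.
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "fluctnet")
#' top <- load_topology(pdb, segment_config = list(H1 = c(1, 2)))
#' top$atoms$segment_id
#' @export
load_topology <- function(path, segment_config = NULL, bw_config = NULL) {
  if (is.character(segment_config) && length(segment_config) == 1L &&
      file.exists(segment_config))
    segment_config <- read_config(segment_config)
  if (is.character(bw_config) && length(bw_config) == 1L &&
      file.exists(bw_config))
    bw_config <- read_config(bw_config)

  parsed <- parse_pdb(path)
  atoms <- parsed$atoms
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serials in ", path)

  atoms$is_heavy <- atoms$element != "H"
  atoms$is_calpha <- atoms$atom_name == "CA" & atoms$element == "C"
  atoms$bw_label <- NA_character_
  if (length(bw_config)) {
    known <- as.character(atoms$residue_number)
    for (rn in names(bw_config)) {
      hit <- known == rn
      if (!any(hit))
        stop("bw_config references missing residue ", rn)
      atoms$bw_label[hit] <- as.character(bw_config[[rn]])
    }
  }
  seg <- assign_segments(atoms, segment_config)
  new_topology(seg$atoms, seg$segments)
}

# -- selections --------------------------------------------------------------

#' Build an atom selection query
#'
#' Fields are combined conjunctively (logical AND); `NULL` fields are
#' ignored.  Use [select_union()] for disjunctions.
#'
#' @param heavy if `TRUE`, keep heavy (non-hydrogen) atoms only.
#' @param calpha if `TRUE`, keep C-alpha atoms only.
#' @param residues integer vector of author residue numbers (a range is just
#'   `first:last`).
#' @param segments character vector of segment ids.
#' @param bw character vector of Ballesteros-Weinstein labels.
#' @param atom_names character vector of PDB atom names (e.g. `c("N","CA","C")`).
#' @return an `flx_query` object.
#' @export
atom_query <- function(heavy = NULL, calpha = NULL, residues = NULL,
                       segments = NULL, bw = NULL, atom_names = NULL) {
  structure(list(heavy = heavy, calpha = calpha, residues = residues,
                 segments = segments, bw = bw, atom_names = atom_names),
            class = "flx_query")
}

#' Select atoms from a topology
#'
#' @param topology an `flx_topology`.
#' @param query an [atom_query()].
#' @return sorted integer vector of 0-based atom indices.  Idempotent in the
#'   sense that the result depends only on the query, and querying a field
#'   value absent from the topology (unknown segment, residue or BW label)
#'   is an error rather than a silent empty result.
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "fluctnet")
#' top <- load_topology(pdb, segment_config = list(H1 = c(1, 2)))
#' select_atoms(top, atom_query(heavy = TRUE, calpha = TRUE))
#' @export
select_atoms <- function(topology, query) {
  stopifnot(inherits(topology, "flx_topology"), inherits(query, "flx_query"))
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(query$heavy)) keep <- keep & (a$is_heavy == query$heavy)
  if (!is.null(query$calpha)) keep <- keep & (a$is_calpha == query$calpha)
  if (!is.null(query$residues)) {
    unknown <- setdiff(query$residues, a$residue_number)
    if (length(unknown))
      stop("query references unknown residue(s): ",
           paste(unknown, collapse = ", "))
    keep <- keep & a$residue_number %in% query$residues
  }
  if (!is.null(query$segments)) {
    unknown <- setdiff(query$segments, a$segment_id)
    if (length(unknown))
      stop("query references unknown segment(s): ",
           paste(unknown, collapse = ", "))
    keep <- keep & a$segment_id %in% query$segments
  }
  if (!is.null(query$bw)) {
    unknown <- setdiff(query$bw, a$bw_label[!is.na(a$bw_label)])
    if (length(unknown))
      stop("query references unknown BW label(s): ",
           paste(unknown, collapse = ", "))
    keep <- keep & !is.na(a$bw_label) & a$bw_label %in% query$bw
  }
  if (!is.null(query$atom_names))
    keep <- keep & a$atom_name %in% query$atom_names
  sort(a$atom_index[keep])
}

#' Union of several selections
#'
#' `select_union(top, list(A, B))` equals the index-set union of
#' `select_atoms(top, A)` and `select_atoms(top, B)`.
#'
#' @param topology an `flx_topology`.
#' @param queries list of [atom_query()] objects.
#' @return sorted 0-based atom indices.
#' @export
select_union <- function(topology, queries) {
  idx <- unlist(lapply(queries, function(q) select_atoms(topology, q)))
  sort(unique(idx))
}
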