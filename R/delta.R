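# Active-minus-inactive differences per ligand, stacked across the panel.

#' Read and preprocess a ligand efficacy table
#'
#' Input TSV columns: `ligand_id`, `gprotein_emax`, `barrestin_emax` (percent
#' of the reference full response; extra columns are kept).  Preprocessing
#' clips E_max at 100% -- assay values above the reference response are
#' treated as full response.  Raw values are retained in `*_emax_raw`.
#' The packaged 14-ligand beta2 adrenergic receptor panel is available via
#' `system.file("extdata", "ligand_efficacy.tsv", package = "fluctnet")`;
#' in that table the two inverse agonists carry an assumed 0% and the
#' reference full agonist an assumed 100% in both pathways.
#'
#' @param path TSV file.
#' @return data.frame with raw and clipped efficacy columns.
#' @export
read_efficacy_table <- function(path) {
  df <- read_tsv(path)
  need <- c("ligand_id", "gprotein_emax", "barrestin_emax")
  if (!all(need %in% names(df)))
    stop("efficacy table must have columns: ", paste(need, collapse = ", "))
  if (any(df$gprotein_emax < 0) || any(df$barrestin_emax < 0))
    stop("E_max values must be >= 0")
  df$gprotein_emax_raw <- df$gprotein_emax
  df$barrestin_emax_raw <- df$barrestin_emax
  df$gprotein_emax <- pmin(df$gprotein_emax, 100)
  df$barrestin_emax <- pmin(df$barrestin_emax, 100)
  df
}

#' Per-atom RMSF difference between states
#'
#' `delta_rmsf(active, inactive)` is the active-state RMSF minus the
#' inactive-state RMSF, atom by atom; values may be negative.  The two
#' profiles must cover the identical atom set -- a mismatch is an error,
#' never a silent intersection.
#'
#' @param active,inactive `flx_fluct_profile` objects over identical
#'   `atom_indices`.
#' @return numeric vector of differences (Angstrom), named by atom index.
#' @export
delta_rmsf <- function(active, inactive) {
  stopifnot(inherits(active, "flx_fluct_profile"),
            inherits(inactive, "flx_fluct_profile"))
  if (!identical(active$atom_indices, inactive$atom_indices))
    stop("atom sets of the two profiles differ")
  setNames(active$rmsf - inactive$rmsf, active$atom_indices)
}

#' Per-pair PCC difference between states
#'
#' Pairs degenerate in either state are flagged and carry `NA`; downstream
#' screens exclude them.
#'
#' @param active,inactive `flx_pair_map` objects over identical pair lists.
#' @return list with `delta` (numeric, `NA` where excluded) and logical
#'   `excluded`.
#' @export
delta_pcc <- function(active, inactive) {
  stopifnot(inherits(active, "flx_pair_map"),
            inherits(inactive, "flx_pair_map"))
  if (!identical(unname(active$pairs), unname(inactive$pairs)))
    stop("pair lists of the two maps differ")
  if (!identical(active$normalization, inactive$normalization))
    stop("PCC normalization differs between states")
  excluded <- active$degenerate | inactive$degenerate
  delta <- active$pcc - inactive$pcc
  delta[excluded] <- NA_real_
  list(delta = delta, excluded = excluded)
}

#' Assemble per-ligand deltas into a panel
#'
#' Stacks per-ligand ΔRMSF vectors and ΔPCC vectors into ligands x atoms
#' and ligands x pairs matrices in the declared ligand order.  All ligands
#' must share the atom order and pair order; the panel records both orders
#' for reproducibility.  At least 3 ligands are required (a Pearson
#' correlation across the panel is undefined below that).
#'
#' @param ligand_ids character vector declaring the ligand order.
#' @param atom_indices shared 0-based atom order.
#' @param drmsf_list list (per ligand, in order) of ΔRMSF vectors from
#'   [delta_rmsf()].
#' @param pairs shared pair matrix (2 columns, 0-based), or `NULL` if no
#'   pair statistics are carried.
#' @param dpcc_list list of [delta_pcc()] results, or `NULL`.
#' @return an `flx_delta_panel` with `delta_rmsf` (L x A), `delta_pcc`
#'   (L x P or `NULL`) and `pair_excluded` (logical P, excluded in any
#'   ligand).
#' @export
assemble_panel <- function(ligand_ids, atom_indices, drmsf_list,
                           pairs = NULL, dpcc_list = NULL) {
  L <- length(ligand_ids)
  if (L < 3L) stop("panel needs >= 3 ligands")
  if (length(drmsf_list) != L) stop("one ΔRMSF vector per ligand required")
  A <- length(atom_indices)
  for (d in drmsf_list)
    if (length(d) != A) stop("ΔRMSF length differs from shared atom order")
  drmsf <- do.call(rbind, lapply(drmsf_list, unname))
  rownames(drmsf) <- ligand_ids
  dpcc <- NULL
  pair_excluded <- NULL
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    if (is.null(dpcc_list) || length(dpcc_list) != L)
      stop("one ΔPCC result per ligand required")
    P <- nrow(pairs)
    for (d in dpcc_list)
      if (length(d$delta) != P) stop("ΔPCC length differs from shared pair order")
    dpcc <- do.call(rbind, lapply(dpcc_list, function(d) d$delta))
    rownames(dpcc) <- ligand_ids
    pair_excluded <- Reduce(`|`, lapply(dpcc_list, function(d) d$excluded))
  }
  if (!all(is.finite(drmsf))) stop("non-finite ΔRMSF in panel")
  structure(list(ligand_ids = ligand_ids,
                 atom_indices = as.integer(atom_indices),
                 delta_rmsf = drmsf,
                 pairs = pairs, delta_pcc = dpcc,
                 pair_excluded = pair_excluded),
            class = "flx_delta_panel")
}

#' @export
print.flx_delta_panel <- function(x, ...) {
  cat(sprintf("<flx_delta_panel> %d ligands x %d atoms%s\n",
              length(x$ligand_ids), length(x$atom_indices),
              if (is.null(x$pairs)) "" else
                sprintf(" x %d pairs", nrow(x$pairs))))
  invisible(x)
}

#' Write a delta panel to disk
#'
#' Writes `<prefix>_delta_rmsf.tsv` (atom rows, one column per ligand),
#' `<prefix>_delta_pcc.tsv` (pair rows) if pairs are present, and a JSON
#' manifest `<prefix>_manifest.json` recording ligand/atom/pair orders and
#' a content hash.
#'
#' @param panel an `flx_delta_panel`.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_delta_panel <- function(panel, prefix) {
  paths <- character(0)
  df <- data.frame(atom_index = panel$atom_indices)
  df <- cbind(df, as.data.frame(t(panel$delta_rmsf)))
  p <- paste0(prefix, "_delta_rmsf.tsv"); write_tsv(df, p); paths <- c(paths, p)
  if (!is.null(panel$pairs)) {
    dfp <- data.frame(i = panel$pairs[, 1], j = panel$pairs[, 2],
                      excluded = panel$pair_excluded)
    dfp <- cbind(dfp, as.data.frame(t(panel$delta_pcc)))
    p <- paste0(prefix, "_delta_pcc.tsv"); write_tsv(dfp, p)
    paths <- c(paths, p)
  }
  manifest <- list(ligand_ids = panel$ligand_ids,
                   n_atoms = length(panel$atom_indices),
                   n_pairs = if (is.null(panel$pairs)) 0L else nrow(panel$pairs),
                   hash = object_hash(list(panel$delta_rmsf, panel$delta_pcc)))
  p <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
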