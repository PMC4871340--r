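# Efficacy-linked network extraction.
#
# Across the ligand panel, each atom's ΔRMSF vector (and each pair's ΔPCC
# vector) is correlated with the per-ligand efficacy.  "Fluctuating atoms"
# are heavy atoms passing the correlation threshold (default 0.6);
# "atom-atom couplings" are heavy-atom pairs with at least one fluctuating
# endpoint, within the distance cutoff (default 12 Angstrom) on a reference
# structure, that pass the same threshold on ΔPCC.

#' Network extraction parameters
#'
#' @param correlation_threshold Pearson threshold in (0, 1); default 0.6.
#' @param distance_cutoff reference-structure distance cutoff in Angstrom
#'   for candidate pairs; default 12.
#' @param correlation_mode `"absolute"` selects on `|r| > threshold` (the
#'   default: strong-efficacy ligands can sit at either end of the Δ scale);
#'   `"signed_positive"` selects on `r > threshold` only.
#' @param pathway `"gprotein"` or `"barrestin"`; the two networks use the
#'   same machinery and differ only in the efficacy column.
#' @return an `flx_network_params` list.
#' @export
network_params <- function(correlation_threshold = 0.6,
                           distance_cutoff = 12,
                           correlation_mode = c("absolute", "signed_positive"),
                           pathway = c("gprotein", "barrestin")) {
  correlation_mode <- match.arg(correlation_mode)
  pathway <- match.arg(pathway)
  if (!(correlation_threshold > 0 && correlation_threshold < 1) ||
      !is.finite(correlation_threshold))
    stop("correlation_threshold must lie in (0, 1)")
  if (!(distance_cutoff > 0)) stop("distance_cutoff must be > 0")
  structure(list(correlation_threshold = correlation_threshold,
                 distance_cutoff = distance_cutoff,
                 correlation_mode = correlation_mode,
                 pathway = pathway),
            class = "flx_network_params")
}

#' Pearson correlation of one panel statistic with efficacy
#'
#' Plain product-moment coefficient across the ligand panel.  Returns `NA`
#' (reported as undefined, excluded downstream) when either vector has zero
#' variance, rather than warning or producing NaN.
#'
#' @param values per-ligand statistic (length >= 3).
#' @param efficacy per-ligand efficacy, same length.
#' @return scalar r in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_across_panel <- function(values, efficacy) {
  if (length(values) != length(efficacy))
    stop("values and efficacy differ in length")
  if (length(values) < 3L) stop("Pearson across the panel needs >= 3 ligands")
  if (anyNA(values) || anyNA(efficacy)) return(NA_real_)
  vx <- values - mean(values)
  vy <- efficacy - mean(efficacy)
  sx <- sum(vx^2)
  sy <- sum(vy^2)
  if (sx <= 0 || sy <= 0) return(NA_real_)
  sum(vx * vy) / sqrt(sx * sy)
}

passes_threshold <- function(r, params) {
  if (is.na(r)) return(FALSE)
  if (params$correlation_mode == "absolute")
    abs(r) > params$correlation_threshold
  else
    r > params$correlation_threshold
}

#' Select fluctuating atoms
#'
#' Atoms whose ΔRMSF-vs-efficacy Pearson correlation passes the threshold
#' under the active correlation mode.  Undefined correlations (zero
#' variance) are skipped, never selected.
#'
#' @param panel an `flx_delta_panel` over heavy atoms.
#' @param efficacy per-ligand efficacy values in the panel's ligand order
#'   (already preprocessed/clipped).
#' @param params [network_params()].
#' @return data.frame `(atom_index, r)` ordered by atom index.
#' @export
select_fluctuating_atoms <- function(panel, efficacy, params = network_params()) {
  stopifnot(inherits(panel, "flx_delta_panel"))
  if (length(efficacy) != length(panel$ligand_ids))
    stop("efficacy length does not match panel ligand order")
  r <- apply(panel$delta_rmsf, 2, pearson_across_panel, efficacy = efficacy)
  sel <- vapply(r, passes_threshold, logical(1), params = params)
  out <- data.frame(atom_index = panel$atom_indices[sel], r = unname(r[sel]))
  out[order(out$atom_index), , drop = FALSE]
}

#' Enumerate candidate atom pairs for coupling analysis
#'
#' All unordered heavy-atom pairs (i < j) with at least one fluctuating
#' endpoint and a reference-structure Euclidean distance within the cutoff.
#' An empty fluctuating set yields an empty list (not an error).
#'
#' @param fluctuating_atoms 0-based indices (e.g. the `atom_index` column
#'   of [select_fluctuating_atoms()] output).
#' @param topology an `flx_topology` (supplies the heavy-atom set).
#' @param reference atoms x 3 coordinates the cutoff is evaluated on.  A
#'   single deterministic reference keeps the candidate list
#'   ligand-independent; the pipeline default is the panel average of the
#'   inactive-state mean structures.
#' @param params [network_params()].
#' @return integer matrix with columns `i`, `j` (0-based, i < j).
#' @export
enumerate_candidate_pairs <- function(fluctuating_atoms, topology, reference,
                                      params = network_params()) {
  heavy <- select_atoms(topology, atom_query(heavy = TRUE))
  fl <- intersect(as.integer(fluctuating_atoms), heavy)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (!length(fl)) return(empty)
  if (nrow(reference) != n_atoms(topology))
    stop("reference does not match topology atom count")
  cut2 <- params$distance_cutoff^2
  ref_h <- reference[heavy + 1L, , drop = FALSE]
  out <- vector("list", length(fl))
  for (k in seq_along(fl)) {
    f <- fl[k]
    p <- reference[f + 1L, ]
    d2 <- (ref_h[, 1] - p[1])^2 + (ref_h[, 2] - p[2])^2 + (ref_h[, 3] - p[3])^2
    partners <- heavy[d2 <= cut2 & heavy != f]
    if (length(partners))
      out[[k]] <- cbind(pmin(f, partners), pmax(f, partners))
  }
  m <- do.call(rbind, out)
  if (is.null(m) || !nrow(m)) return(empty)
  m <- unique(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("i", "j")
  storage.mode(m) <- "integer"
  m
}

#' Select atom-atom couplings
#'
#' Among the candidate pairs, keeps those whose ΔPCC-vs-efficacy Pearson
#' correlation passes the threshold.  Pairs excluded as degenerate in
#' either state of any ligand are never selected.
#'
#' @param panel an `flx_delta_panel` whose pair order contains every
#'   candidate pair (missing pair columns are an error, never skipped).
#' @param efficacy per-ligand efficacy in panel ligand order.
#' @param params [network_params()].
#' @param candidate_pairs 2-column 0-based matrix from
#'   [enumerate_candidate_pairs()]; default all panel pairs.
#' @return data.frame `(i, j, r)`.
#' @export
select_couplings <- function(panel, efficacy, params = network_params(),
                             candidate_pairs = NULL) {
  stopifnot(inherits(panel, "flx_delta_panel"))
  if (is.null(panel$pairs)) stop("panel carries no pair statistics")
  if (is.null(candidate_pairs)) candidate_pairs <- panel$pairs
  candidate_pairs <- as.matrix(candidate_pairs)
  if (!nrow(candidate_pairs))
    return(data.frame(i = integer(0), j = integer(0), r = numeric(0)))
  key_panel <- paste(panel$pairs[, 1], panel$pairs[, 2])
  key_cand <- paste(candidate_pairs[, 1], candidate_pairs[, 2])
  col <- match(key_cand, key_panel)
  if (anyNA(col))
    stop("panel lacks ΔPCC columns for ", sum(is.na(col)), " candidate pair(s)")
  keep <- logical(length(col))
  rs <- numeric(length(col))
  for (k in seq_along(col)) {
    if (panel$pair_excluded[col[k]]) next
    r <- pearson_across_panel(panel$delta_pcc[, col[k]], efficacy)
    rs[k] <- if (is.na(r)) NA_real_ else r
    keep[k] <- passes_threshold(r, params)
  }
  data.frame(i = candidate_pairs[keep, 1], j = candidate_pairs[keep, 2],
             r = rs[keep])
}

#' Assemble a fluctuating network
#'
#' Bundles the selected atoms and couplings with the parameters and the
#' reference used for the distance cutoff, re-checking the membership
#' invariant (every coupling touches a fluctuating atom and respects the
#' cutoff on the stored reference).
#'
#' @param fluctuating_atoms data.frame from [select_fluctuating_atoms()].
#' @param couplings data.frame from [select_couplings()].
#' @param params [network_params()].
#' @param reference atoms x 3 coordinates used for the cutoff.
#' @return an `flx_network`.
#' @export
build_network <- function(fluctuating_atoms, couplings, params, reference) {
  fl <- fluctuating_atoms$atom_index
  if (nrow(couplings)) {
    touches <- couplings$i %in% fl | couplings$j %in% fl
    if (!all(touches))
      stop("coupling without a fluctuating endpoint")
    d <- sqrt(rowSums((reference[couplings$i + 1L, , drop = FALSE] -
                         reference[couplings$j + 1L, , drop = FALSE])^2))
    if (any(d > params$distance_cutoff + 1e-9))
      stop("coupling beyond the distance cutoff")
    couplings$distance <- d
  } else couplings$distance <- numeric(0)
  structure(list(pathway = params$pathway,
                 fluctuating_atoms = fluctuating_atoms,
                 couplings = couplings,
                 params = params, reference = reference),
            class = "flx_network")
}

#' @export
print.flx_network <- function(x, ...) {
  cat(sprintf("<flx_network> %s: %d fluctuating atoms, %d couplings (|r| > %g, <= %g A)\n",
              x$pathway, nrow(x$fluctuating_atoms), nrow(x$couplings),
              x$params$correlation_threshold, x$params$distance_cutoff))
  invisible(x)
}

#' Reduce a network to visualization edges
#'
#' Display rules: a coupling whose two endpoints are both fluctuating atoms
#' is kept atom-to-atom (`both_fluctuating`).  A coupling with exactly one
#' fluctuating endpoint has its non-fluctuating endpoint replaced by the
#' C-alpha of that atom's residue and is kept only if the two final
#' endpoints lie in different segments (`one_fluctuating`) -- couplings
#' within one secondary-structure element are dropped from the drawing
#' (analysis output is unaffected).  Edges with identical endpoint sets and
#' class are merged; `weight` counts the merged couplings (line width).
#'
#' @param network an `flx_network`.
#' @param topology matching `flx_topology`.
#' @return data.frame `(endpoint_a, endpoint_b, color_class, weight)` with
#'   0-based endpoints, `endpoint_a < endpoint_b`.
#' @export
build_visual_edges <- function(network, topology) {
  a <- topology$atoms
  fl <- network$fluctuating_atoms$atom_index
  cp <- network$couplings
  if (!nrow(cp))
    return(data.frame(endpoint_a = integer(0), endpoint_b = integer(0),
                      color_class = character(0), weight = integer(0)))
  seg_of <- setNames(a$segment_id, a$atom_index)
  res_of <- setNames(a$residue_number, a$atom_index)
  ca_of_res <- setNames(a$atom_index[a$is_calpha],
                        a$residue_number[a$is_calpha])
  rows <- list()
  for (k in seq_len(nrow(cp))) {
    i <- cp$i[k]; j <- cp$j[k]
    fi <- i %in% fl; fj <- j %in% fl
    if (fi && fj) {
      rows[[length(rows) + 1L]] <-
        c(min(i, j), max(i, j), "both_fluctuating")
    } else {
      flu <- if (fi) i else j
      oth <- if (fi) j else i
      ca <- ca_of_res[as.character(res_of[as.character(oth)])]
      if (is.na(ca))
        stop("residue ", res_of[as.character(oth)], " lacks a C-alpha for ",
             "endpoint substitution")
      ca <- unname(ca)
      if (seg_of[as.character(flu)] == seg_of[as.character(ca)]) next
      rows[[length(rows) + 1L]] <-
        c(min(flu, ca), max(flu, ca), "one_fluctuating")
    }
  }
  if (!length(rows))
    return(data.frame(endpoint_a = integer(0), endpoint_b = integer(0),
                      color_class = character(0), weight = integer(0)))
  m <- do.call(rbind, rows)
  df <- data.frame(endpoint_a = as.integer(m[, 1]),
                   endpoint_b = as.integer(m[, 2]),
                   color_class = m[, 3], stringsAsFactors = FALSE)
  key <- paste(df$endpoint_a, df$endpoint_b, df$color_class)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  first <- df[!duplicated(key), , drop = FALSE]
  first$weight <- agg$Freq[match(paste(first$endpoint_a, first$endpoint_b,
                                       first$color_class), agg$key)]
  first <- first[order(first$endpoint_a, first$endpoint_b), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Write network tables and a VMD draw script
#'
#' Writes `<prefix>_atoms.tsv` (serial, residue, r), `<prefix>_couplings.tsv`
#' (i/j serials, r, distance), `<prefix>_edges.tsv` (visual edge list) and
#' `<prefix>_edges.tcl`, a VMD-loadable script drawing one line per visual
#' edge with width proportional to its weight.
#'
#' @param network an `flx_network`.
#' @param topology matching `flx_topology`.
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
write_network <- function(network, topology, prefix) {
  a <- topology$atoms
  fl <- network$fluctuating_atoms
  row <- match(fl$atom_index, a$atom_index)
  p1 <- paste0(prefix, "_atoms.tsv")
  write_tsv(data.frame(serial = a$serial[row], residue = a$residue_number[row],
                       r = fl$r), p1)
  cp <- network$couplings
  p2 <- paste0(prefix, "_couplings.tsv")
  write_tsv(data.frame(i_serial = a$serial[match(cp$i, a$atom_index)],
                       j_serial = a$serial[match(cp$j, a$atom_index)],
                       r = cp$r, distance = cp$distance), p2)
  edges <- build_visual_edges(network, topology)
  p3 <- paste0(prefix, "_edges.tsv")
  write_tsv(edges, p3)
  p4 <- paste0(prefix, "_edges.tcl")
  ref <- network$reference
  con <- file(p4, "w")
  writeLines("# VMD draw script: efficacy-linked fluctuating network edges", con)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      col <- if (edges$color_class[k] == "both_fluctuating") "red" else "orange"
      pa <- ref[edges$endpoint_a[k] + 1L, ]
      pb <- ref[edges$endpoint_b[k] + 1L, ]
      writeLines(sprintf(
        "draw color %s\ndraw line {%.3f %.3f %.3f} {%.3f %.3f %.3f} width %d",
        col, pa[1], pa[2], pa[3], pb[1], pb[2], pb[3], edges$weight[k]), con)
    }
  }
  close(con)
  invisible(c(p1, p2, p3, p4))
}
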