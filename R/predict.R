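# Region-mean scores that track ligand efficacy, and the banded
# classification of ligands by their measured E_max.
#
# The G-protein score pair is the mean C-alpha ΔRMSF over the lower half of
# helix 6 and the mean C-alpha ΔPCC over all helix 6 x helix 3 cross pairs.
# The beta-arrestin scores use the helix 1 residue set plus the NPxxY end of
# helix 7.  Region definitions ship as a config fixture and are always
# evaluated over *all* region cross pairs, not the network-selected subset.

#' Per-ligand mean ΔRMSF over a region
#'
#' Unweighted arithmetic mean of ΔRMSF over the region's atoms (typically
#' the region's C-alpha atoms), per ligand.
#'
#' @param panel an `flx_delta_panel`.
#' @param region_atoms 0-based atom indices; must all be present in the
#'   panel atom order and non-empty.
#' @return named numeric vector, one mean per ligand in panel order.
#' @export
region_mean_delta_rmsf <- function(panel, region_atoms) {
  stopifnot(inherits(panel, "flx_delta_panel"))
  region_atoms <- as.integer(region_atoms)
  if (!length(region_atoms)) stop("region resolves to 0 atoms")
  col <- match(region_atoms, panel$atom_indices)
  if (anyNA(col)) stop("region atom(s) missing from the panel atom order")
  m <- panel$delta_rmsf[, col, drop = FALSE]
  setNames(rowMeans(m), panel$ligand_ids)
}

#' Per-ligand mean ΔPCC between two regions
#'
#' Mean over all `|A| x |B|` cross pairs between the two regions
#' (within-region pairs are excluded by construction).  Every cross pair
#' must be present in the panel pair order -- a missing pair column is an
#' error, never silently skipped.
#'
#' @param panel an `flx_delta_panel` carrying pair statistics.
#' @param region_a,region_b disjoint 0-based atom index sets.
#' @return named numeric vector, one mean per ligand.
#' @export
region_mean_delta_pcc <- function(panel, region_a, region_b) {
  stopifnot(inherits(panel, "flx_delta_panel"))
  if (is.null(panel$pairs)) stop("panel carries no pair statistics")
  region_a <- as.integer(region_a)
  region_b <- as.integer(region_b)
  if (!length(region_a) || !length(region_b))
    stop("region resolves to 0 atoms")
  if (length(intersect(region_a, region_b)))
    stop("regions overlap; cross-region ΔPCC is undefined")
  cross <- expand.grid(a = region_a, b = region_b)
  key_panel <- paste(panel$pairs[, 1], panel$pairs[, 2])
  key_cross <- paste(pmin(cross$a, cross$b), pmax(cross$a, cross$b))
  col <- match(key_cross, key_panel)
  if (anyNA(col))
    stop("panel lacks ΔPCC columns for ", sum(is.na(col)),
         " region cross pair(s)")
  m <- panel$delta_pcc[, col, drop = FALSE]
  setNames(rowMeans(m), panel$ligand_ids)
}

#' Classify ligands into efficacy bands
#'
#' Beta-arrestin banding follows the fixed assay-scale rule: strong if E_max >= 50,
#' moderate if 10 <= E_max < 50, weak_or_none if E_max < 10.  G-protein
#' banding is anchored to a reference full agonist: strong if E_max exceeds
#' the reference ligand's value (default isoprenaline, 99.14%),
#' weak_or_none if E_max is at or below `weak_threshold` (default 20%, a
#' configurable bound -- the original banding is given only as figure
#' coloring), moderate otherwise.  E_max values are the preprocessed
#' (clipped) ones.
#'
#' @param emax numeric vector of preprocessed E_max values (percent).
#' @param pathway `"gprotein"` or `"barrestin"`.
#' @param reference_emax reference ligand E_max for the G-protein strong
#'   band (default 99.14).
#' @param weak_threshold G-protein weak/none upper bound (default 20).
#' @return factor with levels `strong`, `moderate`, `weak_or_none`.
#' @export
classify_efficacy <- function(emax, pathway = c("gprotein", "barrestin"),
                              reference_emax = 99.14, weak_threshold = 20) {
  pathway <- match.arg(pathway)
  if (anyNA(emax)) stop("E_max contains NA")
  cls <- if (pathway == "barrestin") {
    ifelse(emax >= 50, "strong", ifelse(emax >= 10, "moderate", "weak_or_none"))
  } else {
    if (is.na(reference_emax))
      stop("G-protein banding needs the reference ligand's E_max")
    ifelse(emax > reference_emax, "strong",
           ifelse(emax <= weak_threshold, "weak_or_none", "moderate"))
  }
  factor(cls, levels = c("strong", "moderate", "weak_or_none"))
}

#' Compute pathway scores and classes for a panel
#'
#' Convenience wrapper: region-mean ΔRMSF and ΔPCC plus the efficacy band
#' per ligand, as a tidy table.
#'
#' @param panel an `flx_delta_panel`.
#' @param efficacy preprocessed per-ligand E_max, panel ligand order.
#' @param pathway `"gprotein"` or `"barrestin"`.
#' @param rmsf_region 0-based atom indices of the ΔRMSF region.
#' @param pcc_region_a,pcc_region_b 0-based atom index sets of the ΔPCC
#'   cross-pair regions.
#' @param ... passed to [classify_efficacy()].
#' @return data.frame `(ligand_id, pathway, mean_delta_rmsf,
#'   mean_delta_pcc, emax, class)`.
#' @export
efficacy_scores <- function(panel, efficacy, pathway, rmsf_region,
                            pcc_region_a, pcc_region_b, ...) {
  mr <- region_mean_delta_rmsf(panel, rmsf_region)
  mp <- region_mean_delta_pcc(panel, pcc_region_a, pcc_region_b)
  data.frame(ligand_id = panel$ligand_ids,
             pathway = pathway,
             mean_delta_rmsf = unname(mr),
             mean_delta_pcc = unname(mp),
             emax = efficacy,
             class = classify_efficacy(efficacy, pathway, ...),
             stringsAsFactors = FALSE)
}

#' Resolve packaged region definitions on a topology
#'
#' Reads a region config (JSON/YAML; see
#' `system.file("extdata", "regions_b2ar.json", package = "fluctnet")`)
#' whose entries give residue-number vectors per named region
#' (`rmsf_region`, `pcc_region_a`, `pcc_region_b`), and resolves each to
#' 0-based C-alpha atom indices on `topology`.  The config may either be
#' flat (one region set shared by both pathways) or nested under
#' `gprotein` / `barrestin` keys; the result mirrors the input shape.
#'
#' @param topology an `flx_topology`.
#' @param config named list or config file path.
#' @return named list of 0-based C-alpha atom index vectors (possibly
#'   nested per pathway).
#' @export
resolve_regions <- function(topology, config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  one <- function(residues) {
    idx <- select_atoms(topology,
                        atom_query(calpha = TRUE,
                                   residues = as.integer(unlist(residues))))
    if (!length(idx)) stop("region resolves to 0 atoms on this topology")
    idx
  }
  if (all(c("gprotein", "barrestin") %in% names(config)))
    lapply(config[c("gprotein", "barrestin")], function(g) lapply(g, one))
  else
    lapply(config, one)
}
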