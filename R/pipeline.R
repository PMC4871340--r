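# End-to-end pipeline: superpose -> RMSF/PCC -> deltas -> network per
# pathway -> region-mean prediction scores.
#
# Pair statistics are expensive, so PCC is computed only for the pairs the
# analysis needs: the candidate pairs of both pathways (all heavy pairs
# within the cutoff touching a fluctuating atom) plus every prediction-
# region C-alpha cross pair (the predictors are defined over all region
# pairs, independent of the network selection).

#' Analyze a ligand panel of paired ensembles
#'
#' Runs the full fluctuating-network analysis in memory.
#'
#' @param topology an `flx_topology`.
#' @param ensembles named list (by ligand) of `list(active =, inactive =)`
#'   `flx_ensemble` objects, e.g. the `ensembles` element of a synthetic
#'   panel from [generate_panel()].
#' @param efficacy preprocessed efficacy table (see
#'   [read_efficacy_table()]) with one row per ligand of `ensembles`.
#' @param regions named list of residue-number vectors (`rmsf_region`,
#'   `pcc_region_a`, `pcc_region_b`) or a config file path; resolved to
#'   C-alpha atoms.  Used for both pathways' predictors.
#' @param params_gprotein,params_barrestin [network_params()] per pathway.
#' @param fit_query fit selection for superposition; default all backbone
#'   heavy atoms (N, CA, C, O).
#' @param pcc_normalization passed to [compute_pair_correlation()].
#' @return an `flx_analysis`: `panel` (the assembled `flx_delta_panel`
#'   over heavy atoms and analysed pairs), `reference` (panel average of
#'   inactive mean structures; the distance-cutoff coordinates),
#'   `networks` and `scores` per pathway, and `region_atoms`.
#' @export
analyze_panel <- function(topology, ensembles, efficacy, regions,
                          params_gprotein = network_params(pathway = "gprotein"),
                          params_barrestin = network_params(pathway = "barrestin"),
                          fit_query = atom_query(heavy = TRUE,
                                                 atom_names = c("N", "CA", "C", "O")),
                          pcc_normalization = "sum") {
  ids <- names(ensembles)
  if (is.null(ids) || length(ids) < 3L)
    stop("need a named list of >= 3 ligand ensembles")
  row <- match(ids, efficacy$ligand_id)
  if (anyNA(row)) stop("efficacy table missing ligand(s): ",
                       paste(ids[is.na(row)], collapse = ", "))
  efficacy <- efficacy[row, , drop = FALSE]
  heavy <- select_atoms(topology, atom_query(heavy = TRUE))
  fit_sel <- select_atoms(topology, fit_query)
  region_atoms <- resolve_regions(topology, regions)
  # a flat region config is shared by both pathways
  if (!all(c("gprotein", "barrestin") %in% names(region_atoms)))
    region_atoms <- list(gprotein = region_atoms, barrestin = region_atoms)

  # pass 1: superpose and per-atom RMSF
  fitted <- list()
  drmsf <- list()
  ref_sum <- 0
  for (lig in ids) {
    # common pose per ligand: the active run is aligned to the inactive
    # run's average so that paired correlation components share a basis
    fi <- superpose_ensemble(ensembles[[lig]]$inactive, fit_sel)
    fa <- superpose_ensemble(ensembles[[lig]]$active, fit_sel,
                             target = mean_structure(fi))
    fitted[[lig]] <- list(active = fa, inactive = fi)
    drmsf[[lig]] <- delta_rmsf(compute_rmsf(fa, heavy),
                               compute_rmsf(fi, heavy))
    ref_sum <- ref_sum + mean_structure(fi)
  }
  reference <- ref_sum / length(ids)
  panel_atoms <- assemble_panel(ids, heavy, drmsf)

  # fluctuating atoms per pathway, then the pair list to analyse
  eff_g <- efficacy$gprotein_emax
  eff_b <- efficacy$barrestin_emax
  fl_g <- select_fluctuating_atoms(panel_atoms, eff_g, params_gprotein)
  fl_b <- select_fluctuating_atoms(panel_atoms, eff_b, params_barrestin)
  cand_g <- enumerate_candidate_pairs(fl_g$atom_index, topology, reference,
                                      params_gprotein)
  cand_b <- enumerate_candidate_pairs(fl_b$atom_index, topology, reference,
                                      params_barrestin)
  region_cross <- function(ra) {
    m <- as.matrix(expand.grid(ra$pcc_region_a, ra$pcc_region_b))
    m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    matrix(as.integer(m), ncol = 2, dimnames = list(NULL, c("i", "j")))
  }
  all_pairs <- unique(rbind(cand_g, cand_b,
                            region_cross(region_atoms$gprotein),
                            region_cross(region_atoms$barrestin)))
  all_pairs <- all_pairs[order(all_pairs[, 1], all_pairs[, 2]), ,
                         drop = FALSE]

  # pass 2: pair statistics on the analysed pair list
  dpcc <- list()
  for (lig in ids) {
    pa <- compute_pair_correlation(fitted[[lig]]$active, all_pairs,
                                   pcc_normalization)
    pi <- compute_pair_correlation(fitted[[lig]]$inactive, all_pairs,
                                   pcc_normalization)
    dpcc[[lig]] <- delta_pcc(pa, pi)
  }
  panel <- assemble_panel(ids, heavy, drmsf, pairs = all_pairs,
                          dpcc_list = dpcc)

  cp_g <- select_couplings(panel, eff_g, params_gprotein, cand_g)
  cp_b <- select_couplings(panel, eff_b, params_barrestin, cand_b)
  net_g <- build_network(fl_g, cp_g, params_gprotein, reference)
  net_b <- build_network(fl_b, cp_b, params_barrestin, reference)

  sc_g <- efficacy_scores(panel, eff_g, "gprotein",
                          region_atoms$gprotein$rmsf_region,
                          region_atoms$gprotein$pcc_region_a,
                          region_atoms$gprotein$pcc_region_b)
  sc_b <- efficacy_scores(panel, eff_b, "barrestin",
                          region_atoms$barrestin$rmsf_region,
                          region_atoms$barrestin$pcc_region_a,
                          region_atoms$barrestin$pcc_region_b)

  structure(list(panel = panel, reference = reference,
                 networks = list(gprotein = net_g, barrestin = net_b),
                 scores = rbind(sc_g, sc_b),
                 region_atoms = region_atoms,
                 efficacy = efficacy),
            class = "flx_analysis")
}

#' @export
print.flx_analysis <- function(x, ...) {
  cat(sprintf(paste0("<flx_analysis> %d ligands; fluctuating atoms: ",
                     "%d (G protein), %d (beta-arrestin); couplings: %d / %d\n"),
              length(x$panel$ligand_ids),
              nrow(x$networks$gprotein$fluctuating_atoms),
              nrow(x$networks$barrestin$fluctuating_atoms),
              nrow(x$networks$gprotein$couplings),
              nrow(x$networks$barrestin$couplings)))
  invisible(x)
}

#' Write all analysis artifacts to a directory
#'
#' Emits the delta panel (TSV + manifest), per-pathway network tables,
#' visual edge lists and VMD scripts, the score table and a run manifest.
#'
#' @param analysis an `flx_analysis`.
#' @param topology matching `flx_topology`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, topology, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_delta_panel(analysis$panel, file.path(dir, "panel"))
  for (pw in names(analysis$networks))
    write_network(analysis$networks[[pw]], topology,
                  file.path(dir, paste0("network_", pw)))
  write_tsv(analysis$scores, file.path(dir, "scores.tsv"))
  write_pdb(analysis$reference, topology, file.path(dir, "reference.pdb"))
  manifest <- list(
    ligands = analysis$panel$ligand_ids,
    n_atoms = length(analysis$panel$atom_indices),
    n_pairs = nrow(analysis$panel$pairs),
    version = as.character(utils::packageVersion("fluctnet")),
    hash = object_hash(list(analysis$panel$delta_rmsf,
                            analysis$panel$delta_pcc,
                            analysis$scores)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a delta panel written by [write_delta_panel()]
#'
#' @param prefix the path prefix the panel was written under.
#' @return an `flx_delta_panel`.
#' @export
read_delta_panel <- function(prefix) {
  dr <- read_tsv(paste0(prefix, "_delta_rmsf.tsv"))
  atom_indices <- as.integer(dr$atom_index)
  ligand_ids <- setdiff(names(dr), "atom_index")
  drmsf <- t(as.matrix(dr[, ligand_ids, drop = FALSE]))
  rownames(drmsf) <- ligand_ids
  pairs <- NULL; dpcc <- NULL; excl <- NULL
  pp <- paste0(prefix, "_delta_pcc.tsv")
  if (file.exists(pp)) {
    dp <- read_tsv(pp)
    pairs <- as.matrix(dp[, c("i", "j")])
    storage.mode(pairs) <- "integer"
    excl <- as.logical(dp$excluded)
    dpcc <- t(as.matrix(dp[, ligand_ids, drop = FALSE]))
    rownames(dpcc) <- ligand_ids
  }
  structure(list(ligand_ids = ligand_ids, atom_indices = atom_indices,
                 delta_rmsf = drmsf, pairs = pairs, delta_pcc = dpcc,
                 pair_excluded = excl),
            class = "flx_delta_panel")
}

#' Run the pipeline from files
#'
#' File-based front end for [analyze_panel()]: loads topology, per-ligand
#' multi-model PDB ensembles (named `<ligand>_active.pdb` /
#' `<ligand>_inactive.pdb` in `input_dir`), the efficacy table and the
#' segment/region configs, and writes all artifacts to `output_dir`.
#' Validation failures (missing paths, malformed configs) abort before any
#' computation.
#'
#' @param input_dir directory holding `topology.pdb`, the run PDBs,
#'   `efficacy.tsv`, `segments.json` and `regions.json` (the layout
#'   written by [write_panel()]).
#' @param output_dir artifact directory.
#' @param n_discard equilibration frames to drop per run.
#' @param correlation_threshold,distance_cutoff,correlation_mode network
#'   parameters shared by both pathways.
#' @return the `flx_analysis`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir, n_discard = 0L,
                         correlation_threshold = 0.6, distance_cutoff = 12,
                         correlation_mode = "absolute") {
  need <- file.path(input_dir, c("topology.pdb", "efficacy.tsv",
                                 "segments.json", "regions.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    validate_stop("missing input file(s): ", paste(missing, collapse = ", "))
  efficacy <- read_efficacy_table(file.path(input_dir, "efficacy.tsv"))
  topology <- load_topology(file.path(input_dir, "topology.pdb"),
                            segment_config = file.path(input_dir, "segments.json"))
  runs <- list.files(input_dir, pattern = "_(active|inactive)\\.pdb$")
  ids <- unique(sub("_(active|inactive)\\.pdb$", "", runs))
  ids <- intersect(efficacy$ligand_id, ids)
  if (length(ids) < 3L) stop("found ", length(ids), " ligand runs; need >= 3")
  ensembles <- list()
  for (lig in ids) {
    ensembles[[lig]] <- list(
      active = load_ensemble(file.path(input_dir, paste0(lig, "_active.pdb")),
                             topology, lig, "active", n_discard),
      inactive = load_ensemble(file.path(input_dir, paste0(lig, "_inactive.pdb")),
                               topology, lig, "inactive", n_discard))
  }
  mk <- function(pw) network_params(correlation_threshold, distance_cutoff,
                                    correlation_mode, pw)
  analysis <- analyze_panel(topology, ensembles, efficacy,
                            file.path(input_dir, "regions.json"),
                            params_gprotein = mk("gprotein"),
                            params_barrestin = mk("barrestin"))
  write_analysis(analysis, topology, output_dir)
  invisible(analysis)
}
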