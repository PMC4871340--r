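# Synthetic coordinate ensembles with planted, efficacy-scaled collective
# modes.
#
# Each run is reference + isotropic Gaussian noise + a planted collective
# mode: a per-frame latent amplitude vector a(t) in R^3 (one independent
# component per Cartesian axis, sample-orthogonalised and exactly scaled to
# the programmed amplitude) times a fixed per-atom weight pattern supported
# on the planted atoms.  The shared latent makes the planted atoms move
# coherently (couplings); the active-state amplitude is a linear function
# of the ligand's efficacy while the inactive amplitude is constant, so the
# active-minus-inactive fluctuation difference tracks efficacy across the
# panel.
#
# The weight pattern is projected orthogonal to the rigid-body modes of the
# reference structure (net translation and net torque zero), so rigid-body
# superposition leaves the planted signal intact instead of smearing it
# over the non-planted atoms.
#
# Closed forms (used by the test oracles): with weights w_i (RMS 1 over the
# planted set), baseline sigma and mode amplitude A, a planted atom's
# per-axis variance is sigma^2 + A^2 w_i^2, so RMSF_i =
# sqrt(3 (sigma^2 + A^2 w_i^2)); for a planted pair the same-axis Pearson
# component is A^2 w_i w_j / sqrt((sigma^2 + A^2 w_i^2)(sigma^2 + A^2 w_j^2))
# and the cross-axis components vanish, so PCC = sqrt(3) |rho_xx|.  At
# sigma = 0 these are exact (the latent columns have exact zero mean, exact
# amplitude and exact mutual orthogonality in sample).

#' Build an idealized toy receptor
#'
#' A deterministic helical-bundle point cloud: `n_segments` straight
#' helix-like rods arranged on a circle, 3 heavy atoms per residue (N,
#' C-alpha, C roles), residues assigned to segments contiguously.  Used as
#' the structure for synthetic panels; no physical realism intended.
#'
#' @param n_residues total residue count (>= n_segments).
#' @param n_segments number of segments (>= 2), named `"H1"`, `"H2"`, ...
#' @return list with `topology` (an `flx_topology`) and `reference`
#'   (atoms x 3 coordinates, Angstrom).
#' @export
build_toy_receptor <- function(n_residues = 60, n_segments = 6) {
  n_residues <- as.integer(n_residues)
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L || n_residues < n_segments)
    stop("need n_residues >= n_segments >= 2")
  per <- n_residues %/% n_segments
  seg_sizes <- rep(per, n_segments)
  seg_sizes[n_segments] <- n_residues - per * (n_segments - 1L)

  bundle_radius <- 8    # segment axis distance from bundle centre (A)
  helix_radius <- 2.3   # C-alpha distance from the segment axis (A)
  rise <- 1.5           # per-residue rise along z (A)
  twist <- 100 * pi / 180

  atoms <- list()
  coords <- list()
  resno <- 0L
  seg_rows <- list()
  for (s in seq_len(n_segments)) {
    phi <- 2 * pi * (s - 1) / n_segments
    cx <- bundle_radius * cos(phi)
    cy <- bundle_radius * sin(phi)
    first <- resno + 1L
    for (k in seq_len(seg_sizes[s])) {
      resno <- resno + 1L
      th <- twist * (k - 1)
      base <- c(cx + helix_radius * cos(th), cy + helix_radius * sin(th),
                rise * (k - 1))
      # N / CA / C offsets break collinearity within the residue
      offs <- rbind(c(-0.55, -0.35, -0.45), c(0, 0, 0), c(0.55, 0.35, 0.45))
      for (an in 1:3) {
        atoms[[length(atoms) + 1L]] <- data.frame(
          atom_name = c("N", "CA", "C")[an],
          element = c("N", "C", "C")[an],
          residue_number = resno, residue_name = "GLY", chain_id = "A",
          segment_id = paste0("H", s), stringsAsFactors = FALSE)
        coords[[length(coords) + 1L]] <- base + offs[an, ]
      }
    }
    seg_rows[[s]] <- data.frame(segment_id = paste0("H", s),
                                first_residue = first, last_residue = resno,
                                stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, atoms)
  a$atom_index <- seq_len(nrow(a)) - 1L
  a$serial <- seq_len(nrow(a))
  a$is_heavy <- TRUE
  a$is_calpha <- a$atom_name == "CA"
  a$bw_label <- NA_character_
  a <- a[, c("atom_index", "serial", "atom_name", "element",
             "residue_number", "residue_name", "chain_id", "bw_label",
             "segment_id", "is_heavy", "is_calpha")]
  ref <- do.call(rbind, coords)
  list(topology = new_topology(a, do.call(rbind, seg_rows)), reference = ref)
}

# Project weights (supported on planted atoms) orthogonal to the rigid-body
# modes {1, x, y, z} evaluated on the planted support, then scale to RMS 1.
rigid_orthogonal_weights <- function(reference, planted_idx0) {
  S <- planted_idx0 + 1L
  w <- rep_len(c(1, -1), length(S))
  B <- cbind(1, reference[S, , drop = FALSE])
  # remove the projection onto the column space of B
  qrB <- qr(B)
  w <- w - qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE] %*%
    crossprod(qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE], w)
  w <- as.numeric(w)
  rms <- sqrt(mean(w^2))
  if (rms < 1e-8)
    stop("planted set too small/degenerate for a rigid-orthogonal pattern")
  w / rms
}

#' Configuration for a synthetic ligand panel
#'
#' Defaults state the panel the analysis assumes: 14 ligands with the
#' packaged efficacy table, 1300 retained frames per run (130 ns at 100
#' ps/frame), 0.3 Angstrom isotropic thermal noise, a constant
#' inactive-state mode amplitude of 1.0 Angstrom and an active-state
#' amplitude `a0 + slope * E_max/100` with `a0 = 1.0` and `slope = -0.8`
#' (negative: high-efficacy ligands quench the active-state mode, the
#' direction observed for the helix-6 region).  The planted atoms default
#' to the C-alpha atoms of the last two segments of the toy receptor (20
#' atoms at the default size); planted pairs are their cross- and
#' intra-segment pairs within `pair_margin` of the reference.
#'
#' @param n_ligands number of ligands (must match the efficacy table).
#' @param efficacy data.frame with `ligand_id` and the efficacy column(s),
#'   or `NULL` for the packaged 14-ligand table.
#' @param efficacy_column which column drives the planted amplitude.
#' @param n_residues,n_segments toy receptor size.
#' @param planted_residues residue numbers whose C-alpha atoms carry the
#'   mode; `NULL` = residues of the last two segments.
#' @param sigma_baseline isotropic thermal noise sd per axis (Angstrom).
#' @param inactive_amplitude constant inactive-state mode amplitude (A).
#' @param active_amp0,slope active amplitude `a0 + slope * E/100`, floored
#'   at 0.
#' @param n_frames retained frames per run (>= 100).
#' @param frame_interval ps per frame (bookkeeping).
#' @param pair_margin reference distance bound (A) defining the planted
#'   pair list; kept inside the 12 A analysis cutoff so every planted pair
#'   is a candidate pair.
#' @param seed master seed; per-(ligand, state) streams are derived from it
#'   by a counter scheme independent of generation order.
#' @return an `flx_synth_config`.
#' @export
synthetic_panel_config <- function(n_ligands = 14, efficacy = NULL,
                                   efficacy_column = "gprotein_emax",
                                   n_residues = 60, n_segments = 6,
                                   planted_residues = NULL,
                                   sigma_baseline = 0.3,
                                   inactive_amplitude = 1.0,
                                   active_amp0 = 1.0, slope = -0.8,
                                   n_frames = 1300, frame_interval = 100,
                                   pair_margin = 11, seed = 1) {
  if (is.null(efficacy)) {
    path <- system.file("extdata", "ligand_efficacy.tsv", package = "fluctnet")
    efficacy <- read_efficacy_table(path)
  }
  if (nrow(efficacy) != n_ligands)
    stop("efficacy table has ", nrow(efficacy), " rows, expected ", n_ligands)
  if (!efficacy_column %in% names(efficacy))
    stop("efficacy table lacks column ", efficacy_column)
  if (n_frames < 100) stop("n_frames must be >= 100")
  if (sigma_baseline < 0 || inactive_amplitude < 0 || active_amp0 < 0)
    stop("noise and amplitudes must be >= 0")

  toy <- build_toy_receptor(n_residues, n_segments)
  segs <- toy$topology$segments
  if (is.null(planted_residues)) {
    tail_segs <- segs[(nrow(segs) - 1L):nrow(segs), ]
    planted_residues <- unlist(mapply(seq, tail_segs$first_residue,
                                      tail_segs$last_residue,
                                      SIMPLIFY = FALSE))
  }
  planted <- select_atoms(toy$topology,
                          atom_query(calpha = TRUE,
                                     residues = as.integer(planted_residues)))
  if (!length(planted)) stop("planted set is empty")
  w <- rigid_orthogonal_weights(toy$reference, planted)

  # planted pairs: pairs of planted atoms within pair_margin on the reference
  pr <- t(combn(planted, 2))
  d <- sqrt(rowSums((toy$reference[pr[, 1] + 1L, , drop = FALSE] -
                       toy$reference[pr[, 2] + 1L, , drop = FALSE])^2))
  planted_pairs <- pr[d <= pair_margin, , drop = FALSE]
  colnames(planted_pairs) <- c("i", "j")

  # prediction regions on the toy receptor: the two planted segments
  seg_res <- function(row) seq(segs$first_residue[row], segs$last_residue[row])
  regions <- list(rmsf_region = seg_res(nrow(segs)),
                  pcc_region_a = seg_res(nrow(segs) - 1L),
                  pcc_region_b = seg_res(nrow(segs)))

  structure(list(n_ligands = n_ligands, efficacy = efficacy,
                 efficacy_column = efficacy_column,
                 topology = toy$topology, reference = toy$reference,
                 planted_atoms = planted, weights = w,
                 planted_pairs = planted_pairs, regions = regions,
                 sigma_baseline = sigma_baseline,
                 inactive_amplitude = inactive_amplitude,
                 active_amp0 = active_amp0, slope = slope,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 pair_margin = pair_margin, seed = as.integer(seed)),
            class = "flx_synth_config")
}

# T x 3 latent matrix: exact zero column means, exact mutual orthogonality,
# exact per-column sample sd (denominator T) equal to amp.
draw_latents <- function(Tn, amp) {
  if (amp <= 0) return(matrix(0, Tn, 3))
  L <- matrix(stats::rnorm(Tn * 3), Tn, 3)
  L <- sweep(L, 2, colMeans(L))
  Q <- qr.Q(qr(L))
  Q <- sweep(Q, 2, colMeans(Q))           # re-centre (Q cols of centred L are centred)
  nrm <- sqrt(colSums(Q^2))
  sweep(Q, 2, nrm / (amp * sqrt(Tn)), "/")
}

#' Programmed mode amplitudes for one ligand
#'
#' @param config an `flx_synth_config`.
#' @param ligand_id ligand present in the config's efficacy table.
#' @return list with `active`, `inactive` amplitudes and `emax`.
#' @export
planted_amplitudes <- function(config, ligand_id) {
  row <- match(ligand_id, config$efficacy$ligand_id)
  if (is.na(row)) stop("unknown ligand: ", ligand_id)
  e <- config$efficacy[[config$efficacy_column]][row]
  list(active = max(0, config$active_amp0 + config$slope * e / 100),
       inactive = config$inactive_amplitude, emax = e)
}

#' Generate the paired active/inactive ensembles for one ligand
#'
#' Active and inactive runs differ only in the planted-mode amplitude;
#' both get independent thermal noise.  Random streams are derived from
#' the master seed and the (ligand, state) counters, so a ligand's
#' ensembles do not depend on panel order.
#'
#' @param config an `flx_synth_config`.
#' @param ligand_id ligand present in the config's efficacy table.
#' @return list with `active` and `inactive` (`flx_ensemble`s) and
#'   `ground_truth` (planted atoms, weights, pairs, programmed amplitudes,
#'   seed).
#' @export
generate_ensemble_pair <- function(config, ligand_id) {
  stopifnot(inherits(config, "flx_synth_config"))
  amps <- planted_amplitudes(config, ligand_id)
  lig_idx <- match(ligand_id, config$efficacy$ligand_id)
  nat <- n_atoms(config$topology)
  Tn <- config$n_frames
  make_run <- function(state, amp, state_index) {
    set.seed(derive_seed(config$seed, lig_idx, state_index))
    co <- array(stats::rnorm(Tn * nat * 3, sd = config$sigma_baseline),
                dim = c(Tn, nat, 3))
    co <- sweep(co, c(2, 3), config$reference, "+")
    if (amp > 0) {
      a <- draw_latents(Tn, amp)
      pl <- config$planted_atoms + 1L
      for (ax in 1:3)
        co[, pl, ax] <- co[, pl, ax] + outer(a[, ax], config$weights)
    }
    new_ensemble(co, ligand_id, state,
                 frame_interval = config$frame_interval)
  }
  gt <- list(planted_atoms = config$planted_atoms,
             weights = config$weights,
             planted_pairs = config$planted_pairs,
             amp_active = amps$active, amp_inactive = amps$inactive,
             sigma_baseline = config$sigma_baseline,
             emax = amps$emax, seed = config$seed)
  list(active = make_run("active", amps$active, 1L),
       inactive = make_run("inactive", amps$inactive, 2L),
       ground_truth = gt)
}

#' Generate a full synthetic ligand panel
#'
#' One active/inactive ensemble pair per ligand of the efficacy table, plus
#' the ground truth needed by test oracles and a manifest recording the
#' seed and a config hash.
#'
#' @param config an `flx_synth_config`.
#' @return an `flx_synth_panel`: `topology`, `reference`, `ensembles`
#'   (named list of `list(active, inactive)`), `efficacy`, `regions`,
#'   `ground_truth`, `manifest`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "flx_synth_config"))
  ids <- config$efficacy$ligand_id
  ens <- list()
  gt_amp <- numeric(0)
  for (lig in ids) {
    pair <- generate_ensemble_pair(config, lig)
    ens[[lig]] <- pair[c("active", "inactive")]
    gt_amp[lig] <- pair$ground_truth$amp_active -
      pair$ground_truth$amp_inactive
  }
  gt <- list(planted_atoms = config$planted_atoms,
             weights = config$weights,
             planted_pairs = config$planted_pairs,
             amp_diff = gt_amp, sigma_baseline = config$sigma_baseline,
             amp_inactive = config$inactive_amplitude,
             seed = config$seed)
  cfg_fields <- config[setdiff(names(config), c("topology", "reference"))]
  manifest <- list(seed = config$seed, n_ligands = config$n_ligands,
                   n_frames = config$n_frames,
                   config_hash = object_hash(cfg_fields))
  structure(list(config = config, topology = config$topology,
                 reference = config$reference, ensembles = ens,
                 efficacy = config$efficacy, regions = config$regions,
                 ground_truth = gt, manifest = manifest),
            class = "flx_synth_panel")
}

#' @export
print.flx_synth_panel <- function(x, ...) {
  cat(sprintf("<flx_synth_panel> %d ligands x %d frames x %d atoms (seed %d)\n",
              length(x$ensembles), x$config$n_frames, n_atoms(x$topology),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic panel to a directory
#'
#' Writes `topology.pdb`, one multi-model PDB per run
#' (`<ligand>_<state>.pdb`), `efficacy.tsv`, `segments.json`,
#' `regions.json`, `ground_truth.json` and `manifest.json`, all loadable
#' by the structure-io layer without special-casing.  Multi-model PDB at
#' full frame counts is bulky; prefer in-memory panels unless files are
#' needed.
#'
#' @param panel an `flx_synth_panel`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(panel$reference, panel$topology, file.path(dir, "topology.pdb"))
  for (lig in names(panel$ensembles))
    for (state in c("active", "inactive"))
      write_pdb(panel$ensembles[[lig]][[state]], panel$topology,
                file.path(dir, paste0(lig, "_", state, ".pdb")))
  raw <- function(col) panel$efficacy[[paste0(col, "_raw")]] %||%
    panel$efficacy[[col]]
  ef <- data.frame(ligand_id = panel$efficacy$ligand_id,
                   gprotein_emax = raw("gprotein_emax"),
                   barrestin_emax = raw("barrestin_emax"))
  write_tsv(ef, file.path(dir, "efficacy.tsv"))
  segs <- panel$topology$segments
  seg_cfg <- setNames(lapply(seq_len(nrow(segs)), function(k)
    c(segs$first_residue[k], segs$last_residue[k])), segs$segment_id)
  jsonlite::write_json(seg_cfg, file.path(dir, "segments.json"),
                       auto_unbox = FALSE, digits = NA)
  jsonlite::write_json(panel$regions, file.path(dir, "regions.json"),
                       digits = NA)
  gt <- panel$ground_truth
  gt$planted_pairs <- unname(apply(gt$planted_pairs, 1, as.list))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(panel$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
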