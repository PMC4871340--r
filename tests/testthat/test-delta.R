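mk_profile <- function(rmsf, state, atoms = seq_along(rmsf) - 1L) {
  structure(list(ligand_id = "L", state = state,
                 atom_indices = as.integer(atoms), rmsf = rmsf),
            class = "flx_fluct_profile")
}

test_that("delta_rmsf is active minus inactive, strict about atom sets", {
  a <- mk_profile(c(1.2, 0.5), "active")
  i <- mk_profile(c(0.9, 0.5), "inactive")
  expect_equal(unname(delta_rmsf(a, i)), c(0.3, 0))
  expect_equal(unname(delta_rmsf(i, i)), c(0, 0))
  short <- mk_profile(0.9, "inactive", atoms = 0L)
  expect_error(delta_rmsf(a, short), "atom sets")
})

test_that("delta_pcc flags degenerate pairs and excludes them as values", {
  e <- gaussian_ensemble(toy$reference, 30, 0.4, seed = 11)
  pairs <- rbind(c(0, 5), c(1, 6))
  act <- compute_pair_correlation(e, pairs)
  co <- e$coords; co[, 2, 1] <- 0        # degenerate axis on atom 1 (pair 2)
  ina <- compute_pair_correlation(new_ensemble(co, "t", "inactive"), pairs)
  d <- delta_pcc(act, ina)
  expect_false(d$excluded[1])
  expect_true(d$excluded[2])
  expect_true(is.na(d$delta[2]))
  expect_equal(d$delta[1], act$pcc[1] - ina$pcc[1])
  # identical maps -> zeros
  d0 <- delta_pcc(act, act)
  expect_equal(d0$delta, c(0, 0))
  # pair-list mismatch
  other <- compute_pair_correlation(e, rbind(c(0, 5)))
  expect_error(delta_pcc(act, other), "pair lists")
})

test_that("assemble_panel stacks in declared order and enforces bounds", {
  d1 <- setNames(c(0.1, 0.2), 0:1)
  d2 <- setNames(c(0.3, 0.4), 0:1)
  d3 <- setNames(c(0.5, 0.6), 0:1)
  p <- assemble_panel(c("A", "B", "C"), 0:1, list(d1, d2, d3))
  expect_equal(dim(p$delta_rmsf), c(3, 2))
  expect_equal(unname(p$delta_rmsf["B", 2]), 0.4)
  expect_identical(p$ligand_ids, c("A", "B", "C"))
  expect_error(assemble_panel(c("A", "B"), 0:1, list(d1, d2)), ">= 3 ligands")
  expect_error(assemble_panel(c("A", "B", "C"), 0:1,
                              list(d1, d2, c(x = 1))), "length differs")
})

test_that("swapping state labels negates every delta exactly", {
  pair <- generate_ensemble_pair(
    synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                           n_residues = 12, n_segments = 2, n_frames = 120,
                           seed = 12),
    "L2")
  heavy <- 0:(dim(pair$active$coords)[2] - 1)
  pa <- compute_rmsf(pair$active, heavy)
  pi_ <- compute_rmsf(pair$inactive, heavy)
  expect_equal(delta_rmsf(pa, pi_), -delta_rmsf(pi_, pa))
  pairs <- rbind(c(0, 3), c(10, 20))
  ma <- compute_pair_correlation(pair$active, pairs)
  mi <- compute_pair_correlation(pair$inactive, pairs)
  expect_equal(delta_pcc(ma, mi)$delta, -delta_pcc(mi, ma)$delta)
})

test_that("same-distribution runs give panel ΔRMSF centred at 0", {
  # slope 0 makes active and inactive statistically identical; over 20
  # seeds the grand-mean ΔRMSF must sit within 3 SE of 0
  means <- vapply(1:20, function(s) {
    cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                  n_residues = 8, n_segments = 2,
                                  n_frames = 100, slope = 0, seed = s)
    pr <- generate_ensemble_pair(cfg, "L1")
    heavy <- 0:(n_atoms(cfg$topology) - 1)
    mean(delta_rmsf(compute_rmsf(pr$active, heavy),
                    compute_rmsf(pr$inactive, heavy)))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-12)
})

test_that("efficacy table preprocessing clips at 100 and keeps raw values", {
  path <- system.file("extdata", "ligand_efficacy.tsv", package = "fluctnet")
  tab <- read_efficacy_table(path)
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$gprotein_emax <= 100 & tab$gprotein_emax >= 0))
  expect_equal(tab$gprotein_emax[tab$ligand_id == "FEN"], 100)
  expect_equal(tab$gprotein_emax_raw[tab$ligand_id == "FEN"], 102.2)
  expect_equal(tab$barrestin_emax[tab$ligand_id == "DOB"], 4.803)
  # assumed endpoints: inverse agonists 0, reference full agonist 100
  expect_equal(tab$gprotein_emax[tab$ligand_id %in% c("CAU", "ICI")], c(0, 0))
  expect_equal(tab$barrestin_emax[tab$ligand_id == "BI"], 100)
  bad <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(ligand_id = "X", gprotein_emax = -1,
                       barrestin_emax = 0), bad)
  expect_error(read_efficacy_table(bad), ">= 0")
})

test_that("delta panel serialization round-trips", {
  cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                n_residues = 8, n_segments = 2,
                                n_frames = 100, seed = 14)
  heavy <- 0:(n_atoms(cfg$topology) - 1)
  pairs <- rbind(c(0L, 3L), c(2L, 7L))
  dr <- list(); dp <- list()
  for (lig in cfg$efficacy$ligand_id) {
    pr <- generate_ensemble_pair(cfg, lig)
    dr[[lig]] <- delta_rmsf(compute_rmsf(pr$active, heavy),
                            compute_rmsf(pr$inactive, heavy))
    dp[[lig]] <- delta_pcc(compute_pair_correlation(pr$active, pairs),
                           compute_pair_correlation(pr$inactive, pairs))
  }
  panel <- assemble_panel(cfg$efficacy$ligand_id, heavy, dr, pairs, dp)
  prefix <- file.path(tempdir(), "panelrt")
  write_delta_panel(panel, prefix)
  back <- read_delta_panel(prefix)
  expect_equal(back$delta_rmsf, panel$delta_rmsf, tolerance = 1e-12)
  expect_equal(back$delta_pcc, panel$delta_pcc, tolerance = 1e-12)
  expect_identical(back$pair_excluded, panel$pair_excluded)
  expect_identical(unname(back$pairs), unname(panel$pairs))
})
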