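test_that("build_toy_receptor constructs the documented point cloud", {
  r <- build_toy_receptor(10, 2)
  expect_equal(n_atoms(r$topology), 30)
  expect_equal(nrow(r$topology$segments), 2)
  expect_equal(r$topology$segments$last_residue -
                 r$topology$segments$first_residue + 1L, c(5L, 5L))
  expect_true(all(r$topology$atoms$is_heavy))
  d <- dist(r$reference)
  expect_true(all(is.finite(d)) && all(d > 0))
  # bit-identical determinism
  r2 <- build_toy_receptor(10, 2)
  expect_identical(r$reference, r2$reference)
  expect_identical(r$topology$atoms, r2$topology$atoms)
  expect_error(build_toy_receptor(3, 4), "n_residues >= n_segments")
})

test_that("config validation enforces the stated world", {
  expect_error(synthetic_panel_config(n_ligands = 3,
                                      efficacy = tiny_efficacy(),
                                      n_frames = 50), ">= 100")
  expect_error(synthetic_panel_config(n_ligands = 3,
                                      efficacy = tiny_efficacy(),
                                      sigma_baseline = -1), ">= 0")
  expect_error(synthetic_panel_config(n_ligands = 5,
                                      efficacy = tiny_efficacy(3)),
               "expected 5")
  cfg <- synthetic_panel_config(seed = 1)
  expect_equal(cfg$n_ligands, 14)       # packaged panel by default
  expect_length(cfg$planted_atoms, 20)
  expect_true(all(cfg$planted_pairs[, 1] < cfg$planted_pairs[, 2]))
})

test_that("the planted pattern is orthogonal to rigid-body modes", {
  cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                seed = 2)
  w <- cfg$weights
  S <- cfg$planted_atoms + 1L
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-12)
  expect_lt(abs(sum(w)), 1e-9)
  for (ax in 1:3)
    expect_lt(abs(sum(w * cfg$reference[S, ax])), 1e-8)
})

test_that("programmed amplitudes follow the efficacy scaling", {
  cfg <- synthetic_panel_config(seed = 3)   # a0 = 1, slope = -0.8
  expect_equal(planted_amplitudes(cfg, "CAU")$active, 1.0)   # E = 0
  expect_equal(planted_amplitudes(cfg, "BI")$active, 0.2)    # E = 100
  expect_equal(planted_amplitudes(cfg, "BI")$inactive, 1.0)
  expect_error(planted_amplitudes(cfg, "nope"), "unknown ligand")
})

test_that("noise-free runs match the closed-form RMSF and PCC exactly", {
  cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                sigma_baseline = 0, n_frames = 300, seed = 4)
  pr <- generate_ensemble_pair(cfg, "L1")   # E = 0 -> amp_active = 1
  gt <- pr$ground_truth
  prof <- compute_rmsf(pr$active, cfg$planted_atoms)
  expect_equal(prof$rmsf, sqrt(3) * gt$amp_active * abs(gt$weights),
               tolerance = 1e-9)
  m <- compute_pair_correlation(pr$active, cfg$planted_pairs)
  expect_equal(m$pcc, rep(sqrt(3), nrow(cfg$planted_pairs)),
               tolerance = 1e-6)
  # non-planted atoms are frozen -> degenerate pairs, zero RMSF
  np <- setdiff(0:(n_atoms(cfg$topology) - 1), cfg$planted_atoms)
  expect_lt(max(compute_rmsf(pr$active, np)$rmsf), 1e-12)
})

test_that("noisy runs match the latent-factor closed forms within 3 SE", {
  cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                n_frames = 1300, seed = 5)
  pr <- generate_ensemble_pair(cfg, "L1")
  gt <- pr$ground_truth
  s2 <- gt$sigma_baseline^2
  Tn <- cfg$n_frames
  amp <- gt$amp_active
  prof <- compute_rmsf(pr$active, cfg$planted_atoms)
  truth <- sqrt(3 * (s2 + amp^2 * gt$weights^2))
  # delta-method SE of the RMSF estimate: the latent contribution is
  # exactly scaled, so only the noise variance and the noise-latent cross
  # term fluctuate
  se <- sqrt(3 * (2 * s2^2 + 4 * s2 * amp^2 * gt$weights^2) / Tn) /
    (2 * truth)
  expect_true(all(abs(prof$rmsf - truth) < 3 * se + 1e-12))
  # per-pair PCC: sqrt(3) |rho| with the same-axis component closed form
  m <- compute_pair_correlation(pr$active, cfg$planted_pairs[1:20, ])
  wi <- gt$weights[match(cfg$planted_pairs[1:20, 1], cfg$planted_atoms)]
  wj <- gt$weights[match(cfg$planted_pairs[1:20, 2], cfg$planted_atoms)]
  rho <- amp^2 * wi * wj /
    sqrt((s2 + amp^2 * wi^2) * (s2 + amp^2 * wj^2))
  expect_true(all(abs(m$pcc - sqrt(3) * abs(rho)) < 0.03))
})

test_that("matched amplitudes (slope 0) centre planted ΔRMSF at 0", {
  means <- vapply(1:20, function(s) {
    cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                  n_residues = 8, n_segments = 2,
                                  n_frames = 100, slope = 0, seed = s)
    pr <- generate_ensemble_pair(cfg, "L3")
    mean(delta_rmsf(compute_rmsf(pr$active, cfg$planted_atoms),
                    compute_rmsf(pr$inactive, cfg$planted_atoms)))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-12)
})

test_that("panels are reproducible and order-independent", {
  cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                n_residues = 8, n_segments = 2,
                                n_frames = 100, seed = 77)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1$ensembles$L2$active$coords,
                   p2$ensembles$L2$active$coords)
  expect_identical(p1$manifest$config_hash, p2$manifest$config_hash)
  # a ligand's streams do not depend on panel order
  solo <- generate_ensemble_pair(cfg, "L2")
  expect_identical(solo$inactive$coords, p1$ensembles$L2$inactive$coords)
  # different seed -> different data
  cfg2 <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                 n_residues = 8, n_segments = 2,
                                 n_frames = 100, seed = 78)
  expect_false(identical(generate_panel(cfg2)$ensembles$L2$active$coords,
                         p1$ensembles$L2$active$coords))
})

test_that("written panels are loadable by the structure-io layer", {
  cfg <- synthetic_panel_config(n_ligands = 3, efficacy = tiny_efficacy(),
                                n_residues = 8, n_segments = 2,
                                n_frames = 100, seed = 9)
  panel <- generate_panel(cfg)
  dir <- file.path(tempdir(), "panel_io")
  write_panel(panel, dir)
  top <- load_topology(file.path(dir, "topology.pdb"),
                       segment_config = file.path(dir, "segments.json"))
  expect_equal(n_atoms(top), n_atoms(panel$topology))
  expect_identical(top$atoms$segment_id, panel$topology$atoms$segment_id)
  ens <- load_ensemble(file.path(dir, "L1_active.pdb"), top, "L1", "active")
  expect_equal(ens$coords, panel$ensembles$L1$active$coords,
               tolerance = 1e-3)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(gt$planted_atoms), sort(cfg$planted_atoms))
  eff <- read_efficacy_table(file.path(dir, "efficacy.tsv"))
  expect_equal(nrow(eff), 3)
})
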