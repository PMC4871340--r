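# panel with iid standard-normal delta statistics (no planted signal)
make_noise_panel <- function(n_lig, n_atoms, pairs = NULL, seed = 1) {
  set.seed(seed)
  ids <- paste0("L", seq_len(n_lig))
  dr <- lapply(seq_len(n_lig), function(k)
    setNames(rnorm(n_atoms), seq_len(n_atoms) - 1L))
  dp <- NULL
  if (!is.null(pairs))
    dp <- lapply(seq_len(n_lig), function(k)
      list(delta = rnorm(nrow(pairs)), excluded = rep(FALSE, nrow(pairs))))
  assemble_panel(ids, seq_len(n_atoms) - 1L, dr, pairs, dp)
}

eff14 <- read_efficacy_table(system.file("extdata", "ligand_efficacy.tsv",
                                         package = "fluctnet"))$gprotein_emax

test_that("pearson_across_panel matches the defining formula", {
  e <- c(0, 20, 40, 100)
  expect_equal(pearson_across_panel(e, e), 1)
  expect_equal(pearson_across_panel(-e + 7, e), -1)
  v <- c(1, 2, 3, 5)
  expect_equal(pearson_across_panel(v, e), oracle_pearson(v, e),
               tolerance = 1e-12)
  expect_true(is.na(pearson_across_panel(c(2, 2, 2, 2), e)))
  expect_true(is.na(pearson_across_panel(v, rep(1, 4))))
  expect_error(pearson_across_panel(1:3, 1:4), "length")
  expect_error(pearson_across_panel(1:2, 1:2), ">= 3")
})

test_that("fluctuating-atom selection respects mode, threshold and NA", {
  # atom 0 tracks efficacy, atom 1 anti-tracks, atom 2 constant, atom 3 noise
  ids <- paste0("L", 1:5)
  e <- c(0, 25, 50, 75, 100)
  dr <- lapply(seq_along(ids), function(k)
    setNames(c(e[k] / 100, -e[k] / 100, 1, c(0.3, -0.2, 0.9, -0.7, 0.1)[k]),
             0:3))
  panel <- assemble_panel(ids, 0:3, dr)
  sel_abs <- select_fluctuating_atoms(panel, e, network_params())
  expect_identical(sel_abs$atom_index, c(0L, 1L))
  expect_equal(sel_abs$r, c(1, -1), tolerance = 1e-12)
  sel_pos <- select_fluctuating_atoms(
    panel, e, network_params(correlation_mode = "signed_positive"))
  expect_identical(sel_pos$atom_index, 0L)
  # a threshold just under 1 excludes everything not perfectly correlated,
  # and thresholds outside (0,1) are rejected by the constructor
  near1 <- select_fluctuating_atoms(
    panel, e, network_params(correlation_threshold = 1 - 1e-9))
  expect_true(all(near1$atom_index %in% c(0L, 1L)))
  expect_error(network_params(correlation_threshold = 1.01), "\\(0, 1\\)")
  expect_error(network_params(distance_cutoff = -1), "> 0")
})

test_that("selection is monotone in the threshold", {
  panel <- make_noise_panel(14, 40, seed = 3)
  thr <- c(0.2, 0.4, 0.6, 0.8)
  sels <- lapply(thr, function(th)
    select_fluctuating_atoms(panel, eff14,
                             network_params(correlation_threshold = th)))
  for (k in seq_along(thr)[-1])
    expect_true(all(sels[[k]]$atom_index %in% sels[[k - 1]]$atom_index))
})

test_that("candidate pair enumeration follows the distance and membership rules", {
  # 5 heavy atoms on a line at x = 0, 3, 11, 13, 20
  path <- tempfile(fileext = ".pdb")
  writeLines(c(sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:5, 1:5, c(0, 3, 11, 13, 20), rep(0, 5), rep(0, 5)), "END"), path)
  top <- load_topology(path)
  ref <- parse_pdb(path)$coords[1, , ]
  p <- enumerate_candidate_pairs(0L, top, ref, network_params())
  expect_identical(unname(p), rbind(c(0L, 1L), c(0L, 2L)))  # 3 and 11 A in, 13 out
  # tiny cutoff -> empty; empty fluctuating set -> empty, not an error
  expect_equal(nrow(enumerate_candidate_pairs(
    0L, top, ref, network_params(distance_cutoff = 0.1))), 0)
  expect_equal(nrow(enumerate_candidate_pairs(
    integer(0), top, ref, network_params())), 0)
  # 1 fluctuating atom among 5 mutually-near atoms -> 4 pairs
  ref_close <- matrix(rnorm(15, sd = 1), 5, 3)
  p4 <- enumerate_candidate_pairs(2L, top, ref_close, network_params())
  expect_equal(nrow(p4), 4)
  expect_true(all(p4[, 1] == 2L | p4[, 2] == 2L))
  expect_true(all(p4[, 1] < p4[, 2]))
})

test_that("coupling selection excludes degenerate pairs and honours candidates", {
  ids <- paste0("L", 1:5)
  e <- c(0, 25, 50, 75, 100)
  pairs <- rbind(c(0L, 1L), c(0L, 2L), c(1L, 2L))
  dp <- lapply(seq_along(ids), function(k)
    list(delta = c(e[k] / 100, e[k] / 100, 0.5),
         excluded = c(FALSE, TRUE, FALSE)))
  dr <- lapply(seq_along(ids), function(k) setNames(rnorm(3), 0:2))
  set.seed(5)
  panel <- assemble_panel(ids, 0:2, dr, pairs, dp)
  cp <- select_couplings(panel, e, network_params())
  expect_identical(cp$i, 0L)             # perfect tracker kept,
  expect_identical(cp$j, 1L)             # degenerate pair dropped despite r
  expect_gt(cp$r, 0.99)
  # empty candidate list -> empty result
  empty <- select_couplings(panel, e, network_params(),
                            matrix(integer(0), ncol = 2))
  expect_equal(nrow(empty), 0)
  # candidate pair absent from the panel is an error, never skipped
  expect_error(select_couplings(panel, e, network_params(),
                                rbind(c(0L, 9L))), "lacks")
})

test_that("pure-noise pairs pass the 0.6 screen at about the null rate", {
  # 500 independent noise pairs at n = 14: the analytic two-sided tail of
  # the null Pearson distribution gives the expected selection rate
  pairs <- cbind(0L, seq_len(500))
  panel <- make_noise_panel(14, 501, pairs, seed = 6)
  cp <- select_couplings(panel, eff14, network_params())
  rate <- nrow(cp) / nrow(pairs)
  p0 <- pearson_null_tail(0.6, 14)
  expect_lt(rate, 0.03)
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / 500))
})

test_that("build_network re-checks membership and distance invariants", {
  ref <- toy$reference
  fl <- data.frame(atom_index = 0L, r = 0.9)
  ok <- data.frame(i = 0L, j = 1L, r = 0.8)
  net <- build_network(fl, ok, network_params(), ref)
  expect_equal(nrow(net$couplings), 1)
  expect_true(net$couplings$distance <= 12)
  bad_member <- data.frame(i = 5L, j = 6L, r = 0.8)
  expect_error(build_network(fl, bad_member, network_params(), ref),
               "without a fluctuating endpoint")
  far <- ref; far[2, ] <- far[1, ] + c(50, 0, 0)
  expect_error(build_network(fl, ok, network_params(), far),
               "beyond the distance cutoff")
})

test_that("visual edge reduction: keep, substitute+drop, merge", {
  top <- toy$topology     # residues 1-5 in H1, 6-10 in H2, atoms N/CA/C
  a <- top$atoms
  idx <- function(res, name) a$atom_index[a$residue_number == res &
                                            a$atom_name == name]
  fl <- c(idx(1, "CA"), idx(2, "CA"))
  params <- network_params(distance_cutoff = 100)
  ref <- toy$reference
  couplings <- data.frame(
    i = c(fl[1], fl[1], fl[1], fl[1], fl[1]),
    j = c(fl[2],                    # both fluctuating, same helix -> kept
          idx(3, "N"),              # one fluctuating, same segment -> dropped
          idx(6, "N"), idx(6, "CA"), idx(6, "C")),  # 3 couplings -> 1 edge
    r = rep(0.9, 5))
  net <- build_network(data.frame(atom_index = fl, r = c(0.9, 0.9)),
                       couplings, params, ref)
  edges <- build_visual_edges(net, top)
  expect_equal(nrow(edges), 2)
  both <- edges[edges$color_class == "both_fluctuating", ]
  expect_equal(nrow(both), 1)
  expect_equal(both$weight, 1)
  expect_setequal(c(both$endpoint_a, both$endpoint_b), fl)
  sub <- edges[edges$color_class == "one_fluctuating", ]
  expect_equal(nrow(sub), 1)
  expect_equal(sub$weight, 3)        # merged onto the residue-6 C-alpha
  expect_setequal(c(sub$endpoint_a, sub$endpoint_b), c(fl[1], idx(6, "CA")))
})

test_that("network tables and the VMD script are written", {
  fl <- data.frame(atom_index = c(0L, 3L), r = c(0.9, -0.8))
  cp <- data.frame(i = c(0L, 0L), j = c(3L, 16L), r = c(0.95, 0.7))
  net <- build_network(fl, cp, network_params(distance_cutoff = 100),
                       toy$reference)
  prefix <- file.path(tempdir(), "nettest")
  paths <- write_network(net, toy$topology, prefix)
  expect_true(all(file.exists(paths)))
  atoms <- read_tsv(paste0(prefix, "_atoms.tsv"))
  expect_equal(atoms$serial, c(1L, 4L))
  tcl <- readLines(paste0(prefix, "_edges.tcl"))
  expect_true(any(grepl("^draw line", tcl)))
})
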