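test_that("pair statistics handle identity, mismatch, gaps and ambiguity", {
  ps <- pair_stats("ACGT", "ACGT")
  expect_equal(ps$overlap_fraction, 1)
  expect_equal(ps$difference_fraction, 0)
  ps <- pair_stats("ACGT", "ACGA")
  expect_equal(ps$overlap_fraction, 1)
  expect_equal(ps$difference_fraction, 0.25)
  # disjoint coverage: overlap 0, difference undefined
  ps <- pair_stats("AC--", "--GT")
  expect_equal(ps$overlap_fraction, 0)
  expect_true(is.na(ps$difference_fraction))
  # an N or IUPAC code removes the column from both numerator and
  # comparison
  ps <- pair_stats("ANGT", "ACGT")
  expect_equal(ps$overlap_fraction, 0.75)
  expect_equal(ps$difference_fraction, 0)
  expect_equal(pair_stats("ARGT", "ATGT")$n_compared, 3)
  expect_error(pair_stats("ACG", "ACGT"), "equal")
})

test_that("species pi matches the hand-enumerated pair list", {
  aln <- species_alignment("sp", c("AAAA", "AAAT", "AATT"))
  # pairwise differences {0.25, 0.50, 0.25}; with relaxed filters
  # pi = 1/3
  out <- species_pi(aln, max_difference = 0.6)
  expect_equal(out$pi, 1 / 3)
  expect_equal(out$n_valid_pairs, 3L)
  # under the default <0.10 rule every pair is excluded: no estimate
  strict <- species_pi(aln)
  expect_true(is.na(strict$pi))
  expect_equal(strict$n_filtered_pairs, 3L)
})

test_that("identical sequences give pi 0 from one valid pair", {
  out <- species_pi(species_alignment("sp", c("ACGTACGTAC", "ACGTACGTAC")))
  expect_equal(out$pi, 0)
  expect_equal(out$n_valid_pairs, 1L)
})

test_that("filter boundaries are strict: ties at 0.60 and 0.10 are excluded", {
  # 10 sites, 1 mismatch: difference exactly 0.10
  a <- "AAAAAAAAAA"; b <- "AAAAAAAAAT"
  expect_equal(species_pi(species_alignment("sp", c(a, b)))$n_valid_pairs, 0L)
  expect_equal(species_pi(species_alignment("sp", c(a, b)),
                          max_difference = 0.100001)$n_valid_pairs, 1L)
  # 10 sites, 6 compared: overlap exactly 0.60
  c1 <- "AAAAAAAAAA"; c2 <- "AAAAAA----"
  expect_equal(species_pi(species_alignment("sp", c(c1, c2)))$n_valid_pairs,
               0L)
  expect_equal(species_pi(species_alignment("sp", c(c1, c2)),
                          min_overlap = 0.59)$n_valid_pairs, 1L)
})

test_that("species below min_sequences yield a flagged no-estimate record", {
  one <- species_pi(species_alignment("sp", c(s1 = "ACGT")))
  expect_true(is.na(one$pi))
  expect_equal(one$n_sequences, 1L)
  pair <- species_pi(species_alignment("sp", c("ACGT", "ACGT")),
                     min_sequences = 5)
  expect_true(is.na(pair$pi))
  expect_equal(pair$n_valid_pairs, 1L)  # pairs evaluated, estimate withheld
})

test_that("pi is invariant to record order and sequence IDs", {
  set.seed(21)
  seqs <- random_alignment_strings(6, 40)
  names(seqs) <- sprintf("x%d", 1:6)
  base <- species_pi(species_alignment("sp", seqs), max_difference = 0.9)
  perm <- sample(6)
  shuffled <- seqs[perm]
  names(shuffled) <- sprintf("y%d", 1:6)
  again <- species_pi(species_alignment("sp", shuffled), max_difference = 0.9)
  expect_equal(again$pi, base$pi)
  expect_equal(again$n_valid_pairs, base$n_valid_pairs)
})

test_that("pi equals the brute-force all-pairs oracle on random alignments", {
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(2:8, 1)
    seqs <- random_alignment_strings(n, sample(20:50, 1))
    got <- species_pi(species_alignment("sp", seqs))
    want <- oracle_pi(seqs)
    expect_equal(got$pi, want$pi)
    expect_equal(got$n_valid_pairs, want$n_valid)
  }
})

test_that("per-cell GD is the mean pi of contributing species", {
  expect_equal(cell_gd(c(0.1, 0.3)), 0.2)
  expect_equal(cell_gd(0.25), 0.25)
  expect_true(is.na(cell_gd(c(NA, NA))))
  tw <- toy_world()
  gd <- gd_surface(tw$presence, tw$pi_table)
  expect_equal(unname(gd["c1_1"]), mean(c(0.02, 0.10)))  # A and D
  expect_equal(unname(gd["c1_3"]), NA_real_)             # only C (no pi)
})

test_that("estimated pi tracks true theta with slope near 1", {
  w <- generate_world(world_config(
    grid_rows = 8, grid_cols = 8, n_species = 60,
    range_size_log_mean = log(5), range_size_log_sd = 0.4,
    seq_per_species_mean = 20, seq_length = 600,
    theta_low = 0.005, theta_high = 0.05, hotspot_strength = 0,
    theta_hotspot_factor = 1, seed = 91))
  pt <- species_pi_table(w$alignments)
  fit <- lm(pt$pi ~ w$truth$theta[pt$species_id])
  slope <- unname(coef(fit)[2])
  expect_gt(slope, 0.7)
  expect_lt(slope, 1.3)
})

test_that("GD surfaces are robust across min-sequence thresholds", {
  w <- generate_world(world_config(
    grid_rows = 14, grid_cols = 14, n_species = 150,
    seq_per_species_mean = 7, seq_length = 250, seed = 13))
  tab <- gd_sensitivity(w$alignments, w$presence, w$grid,
                        min_sequences_values = c(2, 2))
  expect_equal(tab$r[1], 1)  # identical settings give identical surfaces
  tab2 <- gd_sensitivity(w$alignments, w$presence, w$grid,
                         min_sequences_values = c(2, 8),
                         aggregation_factors = 2)
  r28 <- tab2$r[tab2$surface_a == "minseq2" & tab2$surface_b == "minseq8"]
  p28 <- tab2$p[tab2$surface_a == "minseq2" & tab2$surface_b == "minseq8"]
  expect_gt(r28, 0)
  expect_lt(p28, 0.05)
  # the coarse surface is compared against the block-averaged base surface
  expect_true(any(grepl("coarse2x", tab2$surface_a) |
                    grepl("coarse2x", tab2$surface_b)))
})

test_that("surfaces with too few common defined cells are an error", {
  w <- small_world(seed = 3)
  pt <- species_pi_table(w$alignments)
  gd <- gd_surface(w$presence, pt)
  cent <- grid_centroids(w$grid, rownames(w$presence))
  a <- gd; a[4:length(a)] <- NA
  b <- gd; b[1:(length(b) - 2)] <- NA
  expect_error(
    surface_correlation_matrix(list(a = a, b = b), cent),
    "fewer than 3 common")
})
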