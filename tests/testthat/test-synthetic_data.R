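test_that("identical seed and config give a bit-identical world", {
  cfg <- world_config(grid_rows = 6, grid_cols = 6, n_species = 15,
                      seq_per_species_mean = 3, seq_length = 60, seed = 5)
  a <- generate_world(cfg)
  b <- generate_world(cfg)
  expect_identical(a$presence, b$presence)
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$sst, b$sst)
  expect_identical(a$mpa_cells, b$mpa_cells)
  expect_identical(a$truth, b$truth)
  cfg2 <- world_config(grid_rows = 6, grid_cols = 6, n_species = 15,
                       seq_per_species_mean = 3, seq_length = 60, seed = 6)
  c_ <- generate_world(cfg2)
  expect_false(identical(a$presence, c_$presence))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_world(world_config(grid_rows = 4, grid_cols = 4,
                                        n_species = 4, seq_length = 30,
                                        seed = 3)))
  expect_identical(runif(1), before)
})

test_that("theta = 0 yields identical sequences", {
  w <- generate_world(world_config(grid_rows = 4, grid_cols = 4,
                                   n_species = 1, seq_per_species_mean = 2,
                                   seq_length = 100, theta_low = 0,
                                   theta_high = 0, seed = 8))
  seqs <- w$alignments[[1]]$seqs
  expect_gte(length(seqs), 2)
  expect_equal(length(unique(unname(seqs))), 1)
})

test_that("world structure is internally consistent", {
  w <- small_world(seed = 81)
  expect_setequal(w$tree$tip.label, colnames(w$presence))
  expect_setequal(names(w$alignments), colnames(w$presence))
  expect_true(all(w$mpa_cells %in% rownames(w$presence)))
  expect_equal(unname(w$truth$range_size),
               unname(colSums(w$presence)[names(w$truth$range_size)]))
  # every sequence's coordinate falls inside a cell where its species
  # is present
  side <- w$config$cell_side_km
  for (aln in w$alignments) {
    col <- round(aln$lon / side) + 1
    row <- round(aln$lat / side) + 1
    cells <- sprintf("c%d_%d", row, col)
    expect_true(all(w$presence[cbind(cells, aln$species_id)] == 1))
  }
})

test_that("with no hotspot, seed cells are uniform over ocean cells", {
  w <- generate_world(world_config(grid_rows = 5, grid_cols = 5,
                                   n_species = 500,
                                   range_size_log_mean = log(2),
                                   range_size_log_sd = 0.3,
                                   seq_per_species_mean = 2, seq_length = 10,
                                   hotspot_strength = 0, seed = 82))
  counts <- table(factor(w$truth$seed_cells, levels = w$grid$cell_id))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("hotspot species carry elevated diversity across worlds", {
  diffs <- vapply(1:20, function(s) {
    w <- generate_world(world_config(
      grid_rows = 8, grid_cols = 8, n_species = 40,
      range_size_log_mean = log(5), range_size_log_sd = 0.5,
      seq_per_species_mean = 2, seq_length = 10,
      hotspot_strength = 5, theta_hotspot_factor = 3, seed = 900 + s))
    hs <- w$truth$hotspot_species
    if (!length(hs) || length(hs) == length(w$truth$theta)) return(NA_real_)
    mean(w$truth$theta[hs]) - mean(w$truth$theta[setdiff(names(w$truth$theta), hs)])
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  expect_gte(length(diffs), 15)
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("realized pairwise difference converges to theta at 50 sequences", {
  w <- generate_world(world_config(
    grid_rows = 6, grid_cols = 6, n_species = 30,
    range_size_log_mean = log(4), range_size_log_sd = 0.4,
    seq_per_species_mean = 50, seq_length = 500,
    theta_low = 0.01, theta_high = 0.05, hotspot_strength = 0,
    theta_hotspot_factor = 1, seed = 83))
  pt <- species_pi_table(w$alignments, max_difference = 1)
  theta <- w$truth$theta[pt$species_id]
  rel_err <- abs(pt$pi - theta) / theta
  expect_lt(mean(rel_err), 0.20)
})

test_that("range targets larger than the ocean raise a named error", {
  expect_error(
    generate_world(world_config(grid_rows = 2, grid_cols = 2, n_species = 3,
                                range_size_log_mean = log(50),
                                range_size_log_sd = 0.01, seq_length = 10,
                                seed = 84)),
    "range size target of species")
})

test_that("a written world round-trips exactly", {
  w <- generate_world(world_config(grid_rows = 5, grid_cols = 5,
                                   n_species = 4, seq_per_species_mean = 3,
                                   seq_length = 80, seed = 85))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_length(list.files(file.path(dir, "fasta"), pattern = "\\.fasta$"), 4)
  expect_error(write_world(w, dir), "manifest already exists")
  expect_silent(write_world(w, dir, overwrite = TRUE))
  pres <- read.csv(file.path(dir, "presence.csv"), check.names = FALSE)
  expect_equal(ncol(pres), 4 + 1)  # cell_id + one column per species
  w2 <- read_world(dir)
  expect_identical(w2$presence, w$presence)
  expect_identical(w2$alignments, w$alignments)
  expect_identical(w2$sst, w$sst)
  expect_identical(w2$mpa_cells, w$mpa_cells)
  expect_identical(w2$truth, w$truth)
  expect_equal(w2$config, w$config)
  expect_equal(length(w2$tree$tip.label), 4)
  expect_true(ape::all.equal.phylo(w2$tree, w$tree, use.edge.length = TRUE))
  expect_equal(w2$grid, w$grid)
})
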