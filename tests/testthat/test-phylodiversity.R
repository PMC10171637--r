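toy_tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")

test_that("Faith's PD matches hand-computed spanning sums on the toy tree", {
  expect_equal(faith_pd(toy_tree, c("A", "B")), 6)   # 1 + 2 + 3
  expect_equal(faith_pd(toy_tree, "A"), 4)           # tip-to-root path
  expect_equal(faith_pd(toy_tree, c("A", "B", "C", "D")),
               sum(toy_tree$edge.length))
  expect_equal(faith_pd(toy_tree, character(0)), 0)
  # without the root path, single species contribute nothing and {A,B}
  # spans only the cherry
  expect_equal(faith_pd(toy_tree, "A", include_root = FALSE), 0)
  expect_equal(faith_pd(toy_tree, c("A", "B"), include_root = FALSE), 3)
  expect_error(faith_pd(toy_tree, c("A", "Z")), "Z")
})

test_that("PD agrees with the picante implementation on random trees", {
  set.seed(7)
  for (i in 1:20) {
    tr <- ape::rtree(sample(5:12, 1))
    taxa <- sample(tr$tip.label, sample(2:4, 1))
    samp <- matrix(as.integer(tr$tip.label %in% taxa), nrow = 1,
                   dimnames = list("cell", tr$tip.label))
    expect_equal(faith_pd(tr, taxa),
                 picante::pd(samp, tr, include.root = TRUE)$PD)
  }
})

test_that("PD is monotone under community growth and bounded by the tree", {
  set.seed(8)
  tr <- ape::rtree(15)
  inc <- biodivgrid:::tree_incidence(tr)
  total <- sum(tr$edge.length)
  for (i in 1:30) {
    comm <- sample(tr$tip.label, sample(1:10, 1))
    extra <- sample(setdiff(tr$tip.label, comm), 1)
    pd1 <- faith_pd(tr, comm, inc = inc)
    pd2 <- faith_pd(tr, c(comm, extra), inc = inc)
    expect_gte(pd2, pd1)
    expect_lte(pd2, total)
  }
})

test_that("SES-PD is reproducible under seed and degenerate when community = pool", {
  set.seed(9)
  tr <- ape::rtree(12)
  pool <- tr$tip.label
  comm <- pool[1:4]
  a <- ses_pd(tr, comm, pool, n_rand = 200, seed = 42)
  b <- ses_pd(tr, comm, pool, n_rand = 200, seed = 42)
  expect_identical(a$ses, b$ses)
  deg <- ses_pd(tr, pool, pool, n_rand = 50, seed = 1)
  expect_true(is.na(deg$ses))
  expect_equal(deg$null_sd, 0)
  expect_error(ses_pd(tr, "t1", "t1"), "at least 2")
})

test_that("per-cell PD equals the brute-force oracle and SES flags degeneracy", {
  set.seed(10)
  tr <- ape::rtree(6)
  tr$tip.label <- sprintf("sp%d", 1:6)
  presence <- matrix(rbinom(5 * 6, 1, 0.6), nrow = 5,
                     dimnames = list(sprintf("c1_%d", 1:5), tr$tip.label))
  presence[1, ] <- 1  # one cell holds the full pool
  tab <- pd_surface(tr, presence, n_rand = 300, seed = 5)
  for (i in seq_len(nrow(tab))) {
    taxa <- colnames(presence)[presence[i, ] == 1]
    if (!length(taxa)) {
      expect_true(is.na(tab$pd_obs[i]))
    } else {
      expect_equal(tab$pd_obs[i], oracle_pd(tr, taxa))
    }
  }
  expect_true(is.na(tab$ses_pd[1]))  # community = pool: undefined SES
  # identical species sets give identical pd_obs
  p2 <- rbind(presence, presence[2, , drop = FALSE])
  rownames(p2)[6] <- "c1_6"
  tab2 <- pd_surface(tr, p2, n_rand = 50, seed = 5)
  expect_equal(tab2$pd_obs[6], tab2$pd_obs[2])
})

test_that("species absent from the tree are dropped with a report", {
  set.seed(12)
  tr <- ape::rtree(5)
  tr$tip.label <- sprintf("sp%d", 1:5)
  presence <- matrix(1L, nrow = 3, ncol = 7,
                     dimnames = list(sprintf("c1_%d", 1:3),
                                     sprintf("sp%d", 1:7)))
  expect_message(tab <- pd_surface(tr, presence, n_rand = 20, seed = 1),
                 "2 presence species absent")
  expect_equal(attr(tab, "n_dropped_species"), 2)
  expect_equal(tab$n_taxa[1], 5)
})

test_that("richness and PD are positively correlated on synthetic worlds", {
  w <- generate_world(world_config(grid_rows = 20, grid_cols = 20,
                                   n_species = 120,
                                   seq_per_species_mean = 2, seq_length = 10,
                                   seed = 14))
  tab <- pd_surface(w$tree, w$presence, n_rand = 10, seed = 2)
  ok <- tab$n_taxa > 0
  ct <- cor.test(tab$n_taxa[ok], tab$pd_obs[ok], method = "spearman",
                 exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("decile classification matches a sort-based oracle", {
  mk <- function(ses) {
    data.frame(cell_id = sprintf("c1_%d", seq_along(ses)), ses_pd = ses)
  }
  # 10 distinct values: exactly one top, one bottom
  cls <- ses_deciles(mk(c(5, 3, 8, 1, 7, 2, 9, 4, 6, 0)))
  expect_equal(sum(cls == "top10", na.rm = TRUE), 1)
  expect_equal(sum(cls == "bottom10", na.rm = TRUE), 1)
  expect_equal(unname(cls[["c1_7"]]), "top10")
  expect_equal(unname(cls[["c1_10"]]), "bottom10")
  # 100 known values against an explicit sort
  set.seed(15)
  v <- rnorm(100)
  cls <- ses_deciles(mk(v))
  ord <- order(v)
  expect_setequal(names(cls)[cls == "bottom10"],
                  sprintf("c1_%d", ord[1:10]))
  expect_setequal(names(cls)[cls == "top10"],
                  sprintf("c1_%d", ord[91:100]))
  expect_error(ses_deciles(mk(rep(1, 12))), "degenerate")
  expect_error(ses_deciles(mk(rnorm(5))), "at least 10")
})
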