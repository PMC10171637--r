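# Independent oracles and small fixtures used across the suite. These are
# deliberately naive re-derivations (character-level loops, explicit path
# unions, exhaustive enumeration) that share no code with the package
# internals they check.

ALPHABET <- c("A", "C", "G", "T")

random_alignment_strings <- function(n, L,
                                     chars = c(ALPHABET, "-", "N", "R"),
                                     probs = c(rep(0.2, 4), 0.1, 0.05, 0.05)) {
  vapply(seq_len(n), function(i) {
    paste(sample(chars, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

# character-level pair statistics: only unambiguous A/C/G/T columns in
# both sequences are compared
oracle_pair <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% ALPHABET & bv %in% ALPHABET
  nc <- sum(ok)
  list(overlap = nc / length(av),
       diff = if (nc == 0) NA_real_ else sum(av[ok] != bv[ok]) / nc)
}

# all-pairs enumeration of pi under the strict >min_overlap / <max_diff
# filters
oracle_pi <- function(seqs, min_overlap = 0.60, max_diff = 0.10) {
  n <- length(seqs)
  kept <- numeric(0); n_valid <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ps <- oracle_pair(seqs[i], seqs[j])
    if (!is.na(ps$diff) && ps$overlap > min_overlap && ps$diff < max_diff) {
      kept <- c(kept, ps$diff)
      n_valid <- n_valid + 1L
    }
  }
  list(pi = if (n_valid > 0) mean(kept) else NA_real_, n_valid = n_valid)
}

# brute-force Faith's PD: union of the edges on every selected tip's
# root-to-tip path (root path therefore included)
oracle_pd <- function(tree, taxa) {
  if (!length(taxa)) return(0)
  root <- length(tree$tip.label) + 1L
  sel <- integer(0)
  for (t in taxa) {
    tip <- match(t, tree$tip.label)
    np <- ape::nodepath(tree, from = root, to = tip)
    for (k in seq_len(length(np) - 1)) {
      sel <- c(sel, which(tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]))
    }
  }
  sum(tree$edge.length[unique(sel)])
}

# row-normalized Gaussian smoothing operator for building spatially
# autocorrelated noise fields
blur_operator <- function(coords, sigma) {
  D <- as.matrix(dist(coords))
  W <- exp(-0.5 * (D / sigma)^2)
  W / rowSums(W)
}

grid_centroids <- function(grid, cells = retained_cells(grid)) {
  m <- as.matrix(grid[match(cells, grid$cell_id), c("x_km", "y_km")])
  rownames(m) <- cells
  m
}

# a tiny fully hand-checkable world: 3 cells, 4 species, explicit tree
toy_world <- function() {
  presence <- matrix(
    c(1, 0, 0, 1,
      0, 1, 0, 1,
      0, 0, 1, 0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("c1_1", "c1_2", "c1_3"), c("A", "B", "C", "D")))
  pi_table <- data.frame(species_id = c("A", "B", "C", "D"),
                         pi = c(0.02, 0.04, NA, 0.10))
  tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  list(presence = presence, pi_table = pi_table, tree = tree)
}

small_world <- function(seed = 1, rows = 10, cols = 10, n_species = 40, ...) {
  generate_world(world_config(grid_rows = rows, grid_cols = cols,
                              n_species = n_species,
                              range_size_log_mean = log(6),
                              range_size_log_sd = 0.5,
                              seq_per_species_mean = 4, seq_length = 150,
                              seed = seed, ...))
}
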