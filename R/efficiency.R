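# Shared machinery: percentage of taxonomic / genetic / phylogenetic
# diversity captured by each column of a cells x m 0/1 set-indicator
# matrix. Denominators are taken over the species of the presence matrix
# (and, for PD, those of them that are tree tips) so that covering every
# retained cell scores exactly 100 on all three dimensions.
coverage_batch <- function(setmat, presence, pi_table, inc) {
  sp <- colnames(presence)
  covered <- crossprod(presence > 0, setmat) > 0      # species x m
  pct_tax <- 100 * colSums(covered) / length(sp)
  piv <- pi_table$pi[match(sp, pi_table$species_id)]
  piv[is.na(piv)] <- 0
  tot_pi <- sum(piv)
  pct_gen <- if (tot_pi > 0) {
    100 * as.numeric(crossprod(covered, piv)) / tot_pi
  } else {
    rep(NA_real_, ncol(setmat))
  }
  tips <- intersect(sp, inc$tip_labels)
  denom_pd <- faith_pd(NULL, tips, inc = inc)
  sel <- matrix(FALSE, length(inc$tip_labels), ncol(setmat),
                dimnames = list(inc$tip_labels, NULL))
  sel[tips, ] <- covered[tips, , drop = FALSE]
  pct_phy <- if (denom_pd > 0) 100 * pd_batch(inc, sel) / denom_pd else
    rep(NA_real_, ncol(setmat))
  rbind(taxonomic = pct_tax, genetic = pct_gen, phylogenetic = pct_phy)
}

#' Diversity coverage of a protected cell set
#'
#' Scores a set of grid cells for the percentage of taxonomic, genetic and
#' phylogenetic diversity it conserves. A species counts as covered when
#' present in at least one set cell. `pct_taxonomic` is the percentage of
#' species covered; `pct_genetic` is the pi-weighted species coverage
#' (sum of pi over covered species with an estimate / sum over all species
#' with an estimate); `pct_phylogenetic` is the Faith's PD spanned by the
#' covered species as a percentage of the PD of all presence species on
#' the tree. All three are 100 for the full cell set and 0 for the empty
#' set.
#'
#' @param cell_set character vector of cell IDs (must be retained cells of
#'   `presence`; unknown IDs are an error).
#' @param presence cells x species 0/1 matrix.
#' @param pi_table per-species pi ([species_pi_table()]).
#' @param tree rooted `phylo`; @param inc optional [tree_incidence()].
#' @return list of class `coverage_report`: `pct_taxonomic`,
#'   `pct_genetic`, `pct_phylogenetic`, `n_cells`, `fraction_of_ocean`,
#'   `covered_species`.
#' @export
coverage_report <- function(cell_set, presence, pi_table, tree, inc = NULL) {
  if (is.null(inc)) inc <- tree_incidence(tree)
  cell_set <- unique(cell_set)
  unknown <- setdiff(cell_set, rownames(presence))
  if (length(unknown)) {
    stop("unknown cell IDs: ", paste(unknown, collapse = ", "))
  }
  setmat <- matrix(as.numeric(rownames(presence) %in% cell_set), ncol = 1)
  pct <- coverage_batch(setmat, presence, pi_table, inc)
  covered <- colnames(presence)[
    colSums(presence[cell_set, , drop = FALSE] > 0) > 0]
  structure(list(
    pct_taxonomic = unname(pct["taxonomic", 1]),
    pct_genetic = unname(pct["genetic", 1]),
    pct_phylogenetic = unname(pct["phylogenetic", 1]),
    n_cells = length(cell_set),
    fraction_of_ocean = length(cell_set) / nrow(presence),
    covered_species = covered
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "Coverage of %d cells (%.1f%% of ocean): taxonomic %.1f%%, genetic %.1f%%, phylogenetic %.1f%%\n",
    x$n_cells, 100 * x$fraction_of_ocean, x$pct_taxonomic, x$pct_genetic,
    x$pct_phylogenetic))
  invisible(x)
}

#' Random-subsampling biodiversity accumulation curve
#'
#' For each requested sample size, draws `n_replicates` uniform random
#' cell sets (without replacement within a set) from the retained cells
#' and records the three coverage percentages, summarized as the mean and
#' the percentile 95% band (2.5 and 97.5 percentiles). Size 0 is exactly
#' (0, 0, 0) and the full size exactly (100, 100, 100).
#'
#' @param presence cells x species 0/1 matrix.
#' @param pi_table per-species pi; @param tree rooted `phylo`.
#' @param sample_sizes integer vector of cell counts (0..nrow(presence)).
#' @param n_replicates replicates per size (default 1000).
#' @param seed optional RNG seed.
#' @return `data.frame` of class `accumulation_curve` with one row per
#'   size x dimension: `size`, `dimension`, `mean`, `lower`, `upper`;
#'   replicate draws kept in attribute `replicates` (list of 3 x reps
#'   matrices keyed by size) for [compare_to_null()].
#' @export
accumulation_curve <- function(presence, pi_table, tree, sample_sizes,
                               n_replicates = 1000, seed = NULL) {
  inc <- tree_incidence(tree)
  n <- nrow(presence)
  sample_sizes <- as.integer(sample_sizes)
  if (any(sample_sizes < 0 | sample_sizes > n)) {
    stop("sample sizes must lie in 0..", n)
  }
  reps <- with_seed(seed, {
    out <- list()
    for (s in sort(unique(sample_sizes))) {
      if (s == 0) {
        m <- matrix(0, 3, n_replicates,
                    dimnames = list(c("taxonomic", "genetic",
                                      "phylogenetic"), NULL))
      } else if (s == n) {
        m <- matrix(100, 3, n_replicates,
                    dimnames = list(c("taxonomic", "genetic",
                                      "phylogenetic"), NULL))
      } else {
        setmat <- matrix(0, n, n_replicates)
        for (r in seq_len(n_replicates)) {
          setmat[sample.int(n, s), r] <- 1
        }
        m <- coverage_batch(setmat, presence, pi_table, inc)
      }
      out[[as.character(s)]] <- m
    }
    out
  })
  rows <- list()
  for (s in names(reps)) {
    m <- reps[[s]]
    for (d in rownames(m)) {
      q <- quantile(m[d, ], c(0.025, 0.975), na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        size = as.integer(s), dimension = d, mean = mean(m[d, ]),
        lower = as.numeric(q[1]), upper = as.numeric(q[2]),
        stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  attr(curve, "replicates") <- reps
  attr(curve, "n_replicates") <- n_replicates
  attr(curve, "seed") <- seed
  class(curve) <- c("accumulation_curve", "data.frame")
  curve
}

#' Compare an observed coverage report with the random-sampling null
#'
#' Positions an observed cell set's coverage relative to the percentile
#' 95% band of random sets of the same size: `below` (observed < 2.5
#' percentile), `above` (> 97.5 percentile) or `within`. The empirical
#' two-sided p-value is twice the smaller tail fraction of replicates at
#' or beyond the observed value (capped at 1).
#'
#' @param observed a [coverage_report()].
#' @param curve an [accumulation_curve()] whose sizes include
#'   `observed$n_cells`.
#' @return `data.frame`: `dimension`, `observed`, `null_mean`, `lower`,
#'   `upper`, `verdict`, `p_value`.
#' @export
compare_to_null <- function(observed, curve) {
  stopifnot(inherits(observed, "coverage_report"),
            inherits(curve, "accumulation_curve"))
  reps <- attr(curve, "replicates")
  key <- as.character(observed$n_cells)
  if (!key %in% names(reps)) {
    stop("the curve has no replicates at size ", key,
         "; regenerate it including that size")
  }
  m <- reps[[key]]
  obs <- c(taxonomic = observed$pct_taxonomic,
           genetic = observed$pct_genetic,
           phylogenetic = observed$pct_phylogenetic)
  out <- lapply(rownames(m), function(d) {
    q <- quantile(m[d, ], c(0.025, 0.975), na.rm = TRUE)
    verdict <- if (obs[d] < q[1]) "below" else if (obs[d] > q[2]) "above"
      else "within"
    p <- 2 * min(mean(m[d, ] <= obs[d]), mean(m[d, ] >= obs[d]))
    data.frame(dimension = d, observed = as.numeric(obs[d]),
               null_mean = mean(m[d, ]), lower = as.numeric(q[1]),
               upper = as.numeric(q[2]), verdict = verdict,
               p_value = min(p, 1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
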