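# Edge-by-tip incidence of a rooted tree: inc[e, t] is TRUE when tip t
# descends from the child node of edge e. PD of any tip set then reduces
# to summing the lengths of edges with at least one selected descendant,
# which lets surfaces and randomization nulls be computed by one matrix
# product per batch.
tree_incidence <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels")
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  inc <- matrix(FALSE, nrow(tr$edge), nt,
                dimnames = list(NULL, tr$tip.label))
  for (e in seq_len(nrow(tr$edge))) inc[e, desc[[tr$edge[e, 2]]]] <- TRUE
  structure(list(incidence = inc, edge_length = tr$edge.length,
                 tip_labels = tr$tip.label),
            class = "tree_incidence")
}

# PD for each column of a tips x m logical selection matrix.
pd_batch <- function(inc, sel, include_root = TRUE) {
  counts <- inc$incidence %*% sel            # edges x m
  on_path <- counts > 0
  if (!include_root) {
    tot <- colSums(sel)
    on_path <- on_path & sweep(counts, 2, tot, "<")
  }
  as.numeric(crossprod(on_path, inc$edge_length))
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of branch lengths of the minimal subtree connecting the given taxa.
#' By default the path to the root is included (so a single species' PD is
#' its tip-to-root distance), matching the rooted include-root convention
#' of the picante implementation; set `include_root = FALSE` to count only
#' the spanning subtree of the taxa themselves.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param taxa character vector of tip labels (the community). The empty
#'   set has PD 0.
#' @param include_root include the root path (default TRUE).
#' @param inc optional precomputed [tree_incidence()] of `tree` (for
#'   repeated calls).
#' @return a single nonnegative number.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
#' faith_pd(tr, c("A", "B"))  # 1 + 2 + 3 = 6
#' faith_pd(tr, "A")          # 1 + 3 = 4
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE, inc = NULL) {
  if (is.null(inc)) inc <- tree_incidence(tree)
  if (!length(taxa)) return(0)
  unknown <- setdiff(taxa, inc$tip_labels)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  sel <- matrix(inc$tip_labels %in% taxa, ncol = 1)
  pd_batch(inc, sel, include_root)
}

#' Standardized effect size of PD under taxa-label randomization
#'
#' Draws `n_rand` null communities of the same size as `community` by
#' sampling tips uniformly without replacement from `pool` (equivalent to
#' shuffling taxa labels over the pool), and standardizes the observed PD:
#' SES = (PD_obs - mean(PD_null)) / sd(PD_null). When the null has zero
#' spread (e.g. community = pool) the SES is flagged undefined (`NA`).
#'
#' @param tree rooted `phylo`; @param community tip-label set (>= 1 taxa);
#' @param pool tip-label superset of `community` (>= 2 taxa).
#' @param n_rand number of randomizations (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @param inc optional precomputed [tree_incidence()].
#' @return list of class `ses_pd`: `pd_obs`, `null_mean`, `null_sd`,
#'   `ses`, `n_randomizations`, `seed`.
#' @export
ses_pd <- function(tree, community, pool, n_rand = 1000, seed = NULL,
                   inc = NULL) {
  if (is.null(inc)) inc <- tree_incidence(tree)
  if (length(pool) < 2) stop("pool must contain at least 2 taxa")
  if (!length(community)) stop("community must contain at least 1 taxon")
  if (!all(pool %in% inc$tip_labels)) {
    stop("pool taxa not in tree: ",
         paste(setdiff(pool, inc$tip_labels), collapse = ", "))
  }
  if (!all(community %in% pool)) stop("community must be a subset of pool")
  pd_obs <- faith_pd(tree, community, inc = inc)
  s <- length(unique(community)); np <- length(unique(pool))
  pool <- unique(pool)
  nulls <- with_seed(seed, {
    sel <- matrix(FALSE, length(inc$tip_labels), n_rand,
                  dimnames = list(inc$tip_labels, NULL))
    for (r in seq_len(n_rand)) sel[pool[sample.int(np, s)], r] <- TRUE
    pd_batch(inc, sel)
  })
  null_mean <- mean(nulls); null_sd <- sd(nulls)
  structure(list(
    pd_obs = pd_obs, null_mean = null_mean, null_sd = null_sd,
    ses = if (null_sd > 0) (pd_obs - null_mean) / null_sd else NA_real_,
    n_randomizations = n_rand, seed = seed
  ), class = "ses_pd")
}

#' Per-cell PD and SES-PD surface
#'
#' Computes Faith's PD and its standardized effect size for every retained
#' cell with at least one species on the tree. The randomization pool is
#' the full set of presence-matrix species that are tree tips; species
#' missing from the tree are dropped (their count is reported via
#' `message()`). Because the taxa-label null depends only on community
#' size, one null sample of `n_rand` draws is shared by all cells of equal
#' richness.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param presence cells x species 0/1 matrix.
#' @param n_rand randomizations per cell (default 1000).
#' @param seed optional RNG seed.
#' @return `data.frame`: `cell_id`, `n_taxa`, `pd_obs`, `null_mean`,
#'   `null_sd`, `ses_pd` (NA rows for cells with no tree species; NA
#'   `ses_pd` where the null is degenerate).
#' @export
pd_surface <- function(tree, presence, n_rand = 1000, seed = NULL) {
  inc <- tree_incidence(tree)
  pool <- intersect(colnames(presence), inc$tip_labels)
  dropped <- ncol(presence) - length(pool)
  if (dropped > 0) {
    message(dropped, " presence species absent from the tree were dropped",
            " from PD")
  }
  if (length(pool) < 2) stop("fewer than 2 presence species are tree tips")
  np <- length(pool)
  comm <- lapply(rownames(presence), function(cl) {
    pool[presence[cl, pool] > 0]
  })
  sizes <- lengths(comm)
  out <- data.frame(cell_id = rownames(presence), n_taxa = sizes,
                    pd_obs = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, ses_pd = NA_real_,
                    stringsAsFactors = FALSE)
  nonempty <- which(sizes >= 1)
  if (!length(nonempty)) return(out)
  sel <- matrix(FALSE, length(inc$tip_labels), length(nonempty),
                dimnames = list(inc$tip_labels, NULL))
  for (k in seq_along(nonempty)) sel[comm[[nonempty[k]]], k] <- TRUE
  out$pd_obs[nonempty] <- pd_batch(inc, sel)
  # one shared null per distinct community size (label-shuffle null is a
  # function of size only)
  usz <- sort(unique(sizes[nonempty]))
  nulls <- with_seed(seed, {
    lapply(usz, function(s) {
      nm <- matrix(FALSE, length(inc$tip_labels), n_rand,
                   dimnames = list(inc$tip_labels, NULL))
      for (r in seq_len(n_rand)) nm[pool[sample.int(np, s)], r] <- TRUE
      pd_batch(inc, nm)
    })
  })
  names(nulls) <- as.character(usz)
  for (i in nonempty) {
    nd <- nulls[[as.character(sizes[i])]]
    out$null_mean[i] <- mean(nd)
    out$null_sd[i] <- sd(nd)
    if (out$null_sd[i] > 0) {
      out$ses_pd[i] <- (out$pd_obs[i] - out$null_mean[i]) / out$null_sd[i]
    }
  }
  attr(out, "n_randomizations") <- n_rand
  attr(out, "seed") <- seed
  attr(out, "n_dropped_species") <- dropped
  out
}

#' Classify cells into top/bottom SES-PD deciles
#'
#' The `ceiling(0.1 n)` cells with the highest defined SES-PD are `top10`,
#' the same number with the lowest are `bottom10`, the rest `middle`
#' (nearest-rank deciles; ties broken by cell_id order so the
#' classification is reproducible). Cells with undefined SES are `NA`.
#'
#' @param pd_table output of [pd_surface()].
#' @return character vector (`top10`/`bottom10`/`middle`/NA) named by
#'   cell_id.
#' @export
ses_deciles <- function(pd_table) {
  ses <- pd_table$ses_pd
  names(ses) <- pd_table$cell_id
  def <- which(!is.na(ses))
  if (length(def) < 10) stop("need at least 10 cells with defined SES-PD")
  if (length(unique(ses[def])) == 1) {
    stop("degenerate SES-PD distribution: all defined values are equal")
  }
  n10 <- ceiling(0.1 * length(def))
  ord <- def[order(ses[def], pd_table$cell_id[def])]
  cls <- rep(NA_character_, length(ses))
  names(cls) <- pd_table$cell_id
  cls[def] <- "middle"
  cls[ord[seq_len(n10)]] <- "bottom10"
  cls[ord[seq(length(ord) - n10 + 1, length(ord))]] <- "top10"
  cls
}
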