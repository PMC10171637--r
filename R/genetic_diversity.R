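# Encode an alignment (character vector of equal-length strings) as an
# L x n integer matrix: A=1, C=2, G=3, T=4, anything else (gaps, N, IUPAC
# ambiguity codes) NA. Ambiguous columns are simply never compared.
encode_alignment <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("aligned sequences must all have equal length")
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ch <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
               nrow = L, ncol = length(seqs))
  matrix(unname(codes[ch]), nrow = L, ncol = length(seqs))
}

#' Construct a species alignment object
#'
#' Bundles one species' aligned barcode sequences with the sampling
#' coordinate of each record. Sequences may contain gaps (`-`), `N` and
#' IUPAC ambiguity letters; all must have equal (aligned) length.
#'
#' @param species_id species identifier.
#' @param seqs named character vector of aligned sequences (names are
#'   sequence IDs).
#' @param lat,lon numeric sampling coordinates, one per sequence (planar km
#'   reinterpretation in synthetic mode).
#' @return list of class `species_alignment`.
#' @export
species_alignment <- function(species_id, seqs, lat = NA_real_, lon = NA_real_) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences of ", species_id, " differ in length")
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%03d", seq_along(seqs))
  structure(list(species_id = species_id, seqs = seqs,
                 lat = rep_len(lat, length(seqs)),
                 lon = rep_len(lon, length(seqs))),
            class = "species_alignment")
}

#' Pairwise overlap and difference of two aligned sequences
#'
#' Columns where either sequence carries a gap, `N` or an ambiguity code
#' are excluded from both the overlap numerator and the comparison.
#' `overlap_fraction` is compared columns / alignment length;
#' `difference_fraction` is mismatching compared columns / compared
#' columns, and is `NA` (flagged undefined) when no column is comparable.
#'
#' @param a,b aligned sequences (equal-length strings).
#' @return list with `overlap_fraction`, `difference_fraction`,
#'   `n_compared`.
#' @examples
#' pair_stats("ACGT", "ACGA")  # overlap 1, difference 0.25
#' @export
pair_stats <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal aligned length")
  m <- encode_alignment(c(a, b))
  ok <- !is.na(m[, 1]) & !is.na(m[, 2])
  n_comp <- sum(ok)
  list(
    overlap_fraction = n_comp / nrow(m),
    difference_fraction = if (n_comp == 0) NA_real_ else
      sum(m[ok, 1] != m[ok, 2]) / n_comp,
    n_compared = n_comp
  )
}

#' Per-species nucleotide diversity under pair filters
#'
#' Evaluates every unordered pair of sequences. A pair contributes to pi
#' only when its overlap fraction is strictly greater than `min_overlap`
#' and its difference fraction strictly less than `max_difference` (the
#' ">60% overlap, <10% difference" rule; ties at the boundaries are
#' excluded). pi is the arithmetic mean of the surviving pairwise
#' p-distances — no multiple-hit correction is applied. Species with fewer
#' than `min_sequences` sequences, or with no surviving pair, yield a
#' flagged no-estimate record (`pi = NA`).
#'
#' @param aln a [species_alignment()].
#' @param min_overlap exclusive lower bound on pair overlap (default 0.60).
#' @param max_difference exclusive upper bound on pair difference
#'   (default 0.10).
#' @param min_sequences minimum number of sequences for an estimate
#'   (default 2, the minimum that yields a pair).
#' @return one-row `data.frame`: `species_id`, `pi`, `n_sequences`,
#'   `n_valid_pairs`, `n_filtered_pairs`.
#' @examples
#' aln <- species_alignment("sp1", c("AAAA", "AAAT", "AATT"))
#' # with the filters relaxed, pi is the mean of {0.25, 0.5, 0.25} = 1/3;
#' # under the default <0.10 difference filter all three pairs are excluded
#' species_pi(aln, max_difference = 0.6)$pi
#' species_pi(aln)$n_filtered_pairs
#' @export
species_pi <- function(aln, min_overlap = 0.60, max_difference = 0.10,
                       min_sequences = 2) {
  stopifnot(inherits(aln, "species_alignment"),
            min_overlap >= 0, min_overlap <= 1,
            max_difference >= 0, max_difference <= 1, min_sequences >= 1)
  n <- length(aln$seqs)
  res <- data.frame(species_id = aln$species_id, pi = NA_real_,
                    n_sequences = n, n_valid_pairs = 0L,
                    n_filtered_pairs = 0L, stringsAsFactors = FALSE)
  if (n < 2) return(res)
  m <- encode_alignment(aln$seqs)
  L <- nrow(m)
  present <- !is.na(m)
  idx <- combn(n, 2)
  diffs <- numeric(ncol(idx)); keep <- logical(ncol(idx))
  for (p in seq_len(ncol(idx))) {
    i <- idx[1, p]; j <- idx[2, p]
    ok <- present[, i] & present[, j]
    n_comp <- sum(ok)
    ov <- n_comp / L
    d <- if (n_comp == 0) NA_real_ else sum(m[ok, i] != m[ok, j]) / n_comp
    keep[p] <- !is.na(d) && ov > min_overlap && d < max_difference
    diffs[p] <- d
  }
  res$n_valid_pairs <- sum(keep)
  res$n_filtered_pairs <- ncol(idx) - sum(keep)
  if (n >= min_sequences && any(keep)) res$pi <- mean(diffs[keep])
  res
}

#' Nucleotide diversity for a set of species alignments
#'
#' @param alignments list of [species_alignment()] objects.
#' @inheritParams species_pi
#' @return `data.frame` with one row per species (see [species_pi()]).
#' @export
species_pi_table <- function(alignments, min_overlap = 0.60,
                             max_difference = 0.10, min_sequences = 2) {
  do.call(rbind, lapply(alignments, species_pi, min_overlap = min_overlap,
                        max_difference = max_difference,
                        min_sequences = min_sequences))
}

#' Per-cell genetic diversity
#'
#' GD of a cell is the arithmetic mean of species-level pi over the S
#' species present in the cell that carry a pi estimate
#' (GD = (1/S) * sum of pi); species without an estimate are dropped from
#' S, and cells with S = 0 carry `NA`.
#'
#' @param pi_values numeric vector of pi values of the species present in
#'   one cell (NAs allowed; they are dropped).
#' @return the cell's GD, or `NA` if no species contributes.
#' @examples
#' cell_gd(c(0.1, 0.3))  # 0.2
#' @export
cell_gd <- function(pi_values) {
  v <- pi_values[!is.na(pi_values)]
  if (!length(v)) NA_real_ else mean(v)
}

#' Genetic-diversity surface
#'
#' Applies [cell_gd()] to every retained cell of a presence matrix, using
#' globally estimated per-species pi (each species' pi uses all of its
#' sequences, wherever sampled; the per-cell value averages those global
#' estimates over the locally present species).
#'
#' @param presence cells x species 0/1 matrix.
#' @param pi_table output of [species_pi_table()].
#' @return named numeric vector of per-cell GD (NA where no species has an
#'   estimate).
#' @export
gd_surface <- function(presence, pi_table) {
  stopifnot(is.matrix(presence), all(c("species_id", "pi") %in% names(pi_table)))
  pi <- pi_table$pi[match(colnames(presence), pi_table$species_id)]
  gd <- apply(presence > 0, 1, function(pres) cell_gd(pi[pres]))
  names(gd) <- rownames(presence)
  gd
}

#' Sensitivity of the GD surface to analysis settings
#'
#' Recomputes the GD surface under each value of `min_sequences_values`
#' (and, optionally, under block-aggregated coarser grids) and reports the
#' spatially corrected correlation ([modified_t_test()]) between every pair
#' of surfaces on the intersection of their defined cells. For coarser
#' grids the base surface is block-averaged onto the coarse cells first.
#'
#' @param alignments list of [species_alignment()] objects.
#' @param presence cells x species 0/1 matrix on `grid`.
#' @param grid the `grid_spec` the presence matrix lives on.
#' @param min_sequences_values integer vector of thresholds to compare.
#' @param aggregation_factors optional integer vector of grid-coarsening
#'   factors (resolution sensitivity).
#' @inheritParams species_pi
#' @return `data.frame` with one row per surface pair: `surface_a`,
#'   `surface_b`, `r`, `n`, `m_eff`, `t`, `df`, `p`.
#' @export
gd_sensitivity <- function(alignments, presence, grid,
                           min_sequences_values = c(2, 5, 10),
                           aggregation_factors = integer(0),
                           min_overlap = 0.60, max_difference = 0.10) {
  if (length(min_sequences_values) + length(aggregation_factors) < 1 ||
      length(min_sequences_values) < 1) {
    stop("need at least one min_sequences threshold")
  }
  if (length(min_sequences_values) < 2 && !length(aggregation_factors)) {
    stop("need at least two settings to compare")
  }
  keep <- rownames(presence)
  cent <- as.matrix(grid[match(keep, grid$cell_id), c("x_km", "y_km")])
  rownames(cent) <- keep
  surfaces <- list(); coords <- list(); gtag <- character(0)
  base_pi <- NULL
  ms_names <- make.unique(sprintf("minseq%d", min_sequences_values),
                          sep = "_")
  for (i in seq_along(min_sequences_values)) {
    pt <- species_pi_table(alignments, min_overlap, max_difference,
                           min_sequences = min_sequences_values[i])
    if (i == 1) base_pi <- pt
    nm <- ms_names[i]
    surfaces[[nm]] <- gd_surface(presence, pt)
    coords[[nm]] <- cent
    gtag[nm] <- "base"
  }
  for (f in aggregation_factors) {
    agg <- aggregate_grid(grid, presence, f)
    nm <- sprintf("coarse%dx", f)
    tag <- nm
    surfaces[[nm]] <- gd_surface(agg$presence, base_pi)
    coords[[nm]] <- as.matrix(agg$grid[match(rownames(agg$presence),
                                             agg$grid$cell_id),
                                       c("x_km", "y_km")])
    rownames(coords[[nm]]) <- rownames(agg$presence)
    gtag[nm] <- tag
    # block-average the finest surface onto the same coarse cells
    blk <- sprintf("c%d_%d", ceiling(grid$row / f), ceiling(grid$col / f))
    names(blk) <- grid$cell_id
    base <- surfaces[[1]]
    bm <- tapply(base, blk[names(base)], mean, na.rm = TRUE)
    nm0 <- sprintf("base_on_coarse%dx", f)
    surfaces[[nm0]] <- as.numeric(bm[rownames(agg$presence)])
    names(surfaces[[nm0]]) <- rownames(agg$presence)
    coords[[nm0]] <- coords[[nm]]
    gtag[nm0] <- tag
  }
  out <- list()
  nms <- names(surfaces)
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    # surfaces on different grids are never paired (their cell IDs are
    # incommensurable); resolution comparisons pair coarse GD against the
    # block-averaged base surface on the same coarse grid
    if (gtag[nms[i]] != gtag[nms[j]]) next
    xi <- surfaces[[i]]; xj <- surfaces[[j]]
    common <- intersect(names(xi)[!is.na(xi)], names(xj)[!is.na(xj)])
    if (length(common) < 3) {
      stop("fewer than 3 common defined cells between ", nms[i], " and ",
           nms[j])
    }
    tt <- modified_t_test(xi[common], xj[common],
                          coords[[i]][common, , drop = FALSE])
    out[[length(out) + 1]] <- data.frame(
      surface_a = nms[i], surface_b = nms[j], r = tt$r, n = tt$n,
      m_eff = tt$m_eff, t = tt$t_stat, df = tt$df, p = tt$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
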