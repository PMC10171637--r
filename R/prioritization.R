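#' Min-max normalization to [0, 1]
#'
#' `(v - min) / (max - min)`. A constant input maps to all zeros with a
#' warning (degenerate range).
#'
#' @param values numeric vector (NAs preserved).
#' @return numeric vector on `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))  # 0, 0.5, 1
#' @export
minmax_normalize <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("need at least one defined value")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant input: min-max normalization returns all zeros",
            call. = FALSE)
    out <- ifelse(is.na(values), NA_real_, 0)
    return(out)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Assemble the normalized per-cell feature table
#'
#' Joins the three diversity surfaces on cells where all three are defined
#' and min-max normalizes each dimension. Cells missing any dimension are
#' excluded (their count is available as attribute `n_dropped`).
#'
#' @param sr named per-cell species richness ([richness_surface()]).
#' @param gd named per-cell genetic diversity ([gd_surface()]).
#' @param ses named per-cell SES-PD (column `ses_pd` of [pd_surface()],
#'   named by cell).
#' @return numeric matrix (cells x 3, columns `sr_norm`, `gd_norm`,
#'   `sespd_norm`) with rownames = cell_id.
#' @export
build_feature_table <- function(sr, gd, ses) {
  cells <- Reduce(intersect, list(names(sr)[!is.na(sr)],
                                  names(gd)[!is.na(gd)],
                                  names(ses)[!is.na(ses)]))
  if (!length(cells)) stop("no cell has all three dimensions defined")
  f <- cbind(sr_norm = minmax_normalize(as.numeric(sr[cells])),
             gd_norm = minmax_normalize(as.numeric(gd[cells])),
             sespd_norm = minmax_normalize(as.numeric(ses[cells])))
  rownames(f) <- cells
  n_all <- length(union(union(names(sr), names(gd)), names(ses)))
  attr(f, "n_dropped") <- n_all - length(cells)
  f
}

#' K-means clustering of cells in normalized feature space
#'
#' Best-of-`n_restarts` k-means (Hartigan-Wong), deterministic under
#' `seed`. The returned solution has the smallest within-cluster sum of
#' squares among the restarts.
#'
#' @param features numeric matrix, cells x dims, rownames = cell_id.
#' @param k number of clusters (>= 2; fewer distinct points than k is an
#'   error).
#' @param n_restarts random restarts (default 25).
#' @param max_iter maximum Lloyd/Hartigan iterations (default 300).
#' @param seed optional RNG seed.
#' @return list: `cluster` (named integer vector), `centers`, `wcss`
#'   (total within-cluster sum of squares), `size`.
#' @export
kmeans_cluster <- function(features, k, n_restarts = 25, max_iter = 300,
                           seed = NULL) {
  stopifnot(is.matrix(features), k >= 2)
  if (nrow(unique(features)) < k) {
    stop("fewer distinct points (", nrow(unique(features)),
         ") than clusters (", k, ")")
  }
  if (k == nrow(features)) {
    # every point its own cluster: the unique zero-WCSS optimum, which the
    # Hartigan-Wong implementation refuses to compute
    cl <- seq_len(k)
    names(cl) <- rownames(features)
    return(list(cluster = cl, centers = features, wcss = 0,
                size = rep(1L, k)))
  }
  km <- with_seed(seed,
    kmeans(features, centers = k, nstart = n_restarts, iter.max = max_iter))
  cl <- km$cluster
  names(cl) <- rownames(features)
  list(cluster = cl, centers = km$centers, wcss = km$tot.withinss,
       size = km$size)
}

#' Choose the number of clusters
#'
#' Runs [kmeans_cluster()] for each k in `k_range` and evaluates the mean
#' silhouette width (default) or the total within-cluster sum of squares.
#' With `method = "silhouette"` the chosen k maximizes the mean width;
#' with `method = "wss"` the full elbow table is returned and the caller
#' picks (the chosen k is then the silhouette-free heuristic of the
#' largest relative WSS drop).
#'
#' @param features cells x dims matrix (needs at least `max(k_range) + 1`
#'   rows).
#' @param k_range candidate cluster counts (default 2:10).
#' @param method `"silhouette"` (default) or `"wss"`.
#' @param seed optional RNG seed.
#' @param n_restarts passed to [kmeans_cluster()].
#' @return list: `k` (chosen), `diagnostics` (data.frame k/criterion).
#' @export
select_k <- function(features, k_range = 2:10,
                     method = c("silhouette", "wss"), seed = NULL,
                     n_restarts = 25) {
  method <- match.arg(method)
  stopifnot(is.matrix(features))
  if (nrow(features) < max(k_range) + 1) {
    stop("need at least max(k_range) + 1 = ", max(k_range) + 1, " cells")
  }
  d <- dist(features)
  crit <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    km <- kmeans_cluster(features, k_range[i], n_restarts = n_restarts,
                         seed = if (is.null(seed)) NULL else seed + i)
    crit[i] <- if (method == "silhouette") {
      mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    } else {
      km$wcss
    }
  }
  k <- if (method == "silhouette") {
    k_range[which.max(crit)]
  } else {
    drops <- -diff(crit) / crit[-length(crit)]
    k_range[which.max(drops) + 1]
  }
  list(k = k,
       diagnostics = data.frame(k = k_range, criterion = crit,
                                method = method))
}

#' Rank clusters and select the priority cell set
#'
#' Scores each cluster by the mean (over its member cells) of the weighted
#' mean of the normalized dimensions, ranks clusters by score (ties broken
#' by larger cluster size, then lower cluster index), and returns the
#' cells of the top `n_top` clusters as the conservation-priority set,
#' together with the fraction of all retained ocean cells they cover.
#'
#' @param features cells x 3 normalized matrix ([build_feature_table()]).
#' @param clustering result of [kmeans_cluster()] on `features`.
#' @param n_top number of top clusters selected (default 3, of the
#'   standard 6).
#' @param n_total_cells total number of retained ocean cells (coverage
#'   denominator); defaults to `nrow(features)`.
#' @param weights per-dimension weights (default equal).
#' @return list of class `priority_model`: `k`, `assignments`,
#'   `cluster_scores`, `ranking`, `priority_clusters`, `priority_cells`,
#'   `coverage_fraction`, `cluster_summary`.
#' @export
rank_and_select <- function(features, clustering, n_top = 3,
                            n_total_cells = nrow(features),
                            weights = c(1, 1, 1)) {
  cl <- clustering$cluster
  stopifnot(length(cl) == nrow(features), n_top >= 1)
  k <- max(cl)
  if (n_top > k) stop("n_top exceeds the number of clusters")
  w <- weights / sum(weights)
  cellscore <- as.numeric(features %*% w)
  score <- tapply(cellscore, cl, mean)
  size <- tabulate(cl, nbins = k)
  ranking <- order(-as.numeric(score[as.character(seq_len(k))]), -size,
                   seq_len(k))
  priority_clusters <- ranking[seq_len(n_top)]
  priority_cells <- names(cl)[cl %in% priority_clusters]
  summ <- data.frame(
    cluster = seq_len(k),
    size = size,
    mean_sr_norm = as.numeric(tapply(features[, 1], cl, mean)),
    mean_gd_norm = as.numeric(tapply(features[, 2], cl, mean)),
    mean_sespd_norm = as.numeric(tapply(features[, 3], cl, mean)),
    score = as.numeric(score[as.character(seq_len(k))]),
    rank = match(seq_len(k), ranking),
    is_priority = seq_len(k) %in% priority_clusters
  )
  structure(list(
    k = k, assignments = cl,
    cluster_scores = summ$score, ranking = ranking,
    priority_clusters = priority_clusters,
    priority_cells = priority_cells,
    coverage_fraction = length(priority_cells) / n_total_cells,
    cluster_summary = summ[order(summ$rank), ]
  ), class = "priority_model")
}

#' @export
print.priority_model <- function(x, ...) {
  cat("Conservation priority model: k =", x$k, "clusters, top",
      length(x$priority_clusters), "selected\n")
  cat(sprintf("%d priority cells, %.2f%% of retained ocean cells\n",
              length(x$priority_cells), 100 * x$coverage_fraction))
  print(x$cluster_summary, row.names = FALSE)
  invisible(x)
}
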