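#' Build the analysis grid
#'
#' Lays out a planar `rows x cols` grid of square cells of side
#' `cell_side_km` (default 385.9 km, i.e. the resolution used for global
#' marine mapping) and applies the ocean-fraction exclusion rule: cells in
#' which ocean covers strictly less than 50% of the area are excluded from
#' every downstream surface. A cell with exactly 50% ocean is retained.
#'
#' The grid is indexed row-major from the north-west corner; the coordinate
#' origin is the NW cell centroid, with x increasing eastwards (along
#' columns) and y increasing southwards (along rows). Cell IDs are
#' `"c<row>_<col>"`.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param cell_side_km side length of a (square) cell, in km.
#' @param ocean_fraction per-cell ocean fraction in `[0, 1]`: a single
#'   number recycled to all cells, or a vector of length `rows * cols` in
#'   row-major order.
#' @return A `data.frame` of class `grid_spec` with columns `cell_id`,
#'   `row`, `col`, `x_km`, `y_km`, `ocean_fraction`, `retained`, and
#'   attribute `cell_side_km`.
#' @examples
#' g <- build_grid(2, 3, ocean_fraction = c(1, 1, 0.4, 0.5, 1, 1))
#' sum(g$retained)  # the 0.4 cell is excluded, the 0.5 cell retained
#' @export
build_grid <- function(rows, cols, cell_side_km = 385.9, ocean_fraction = 1) {
  stopifnot(length(rows) == 1, length(cols) == 1, rows >= 1, cols >= 1,
            cell_side_km > 0)
  n <- rows * cols
  if (length(ocean_fraction) == 1) ocean_fraction <- rep(ocean_fraction, n)
  if (length(ocean_fraction) != n) {
    stop("ocean_fraction must have length 1 or rows*cols (row-major)")
  }
  if (any(ocean_fraction < 0 | ocean_fraction > 1)) {
    stop("ocean_fraction values must lie in [0, 1]")
  }
  row <- rep(seq_len(rows), each = cols)
  col <- rep(seq_len(cols), times = rows)
  g <- data.frame(
    cell_id = sprintf("c%d_%d", row, col),
    row = row, col = col,
    x_km = (col - 1) * cell_side_km,
    y_km = (row - 1) * cell_side_km,
    ocean_fraction = ocean_fraction,
    retained = ocean_fraction >= 0.5,
    stringsAsFactors = FALSE
  )
  attr(g, "cell_side_km") <- cell_side_km
  class(g) <- c("grid_spec", "data.frame")
  g
}

#' Retained (analysis) cell IDs of a grid
#' @param grid a `grid_spec` from [build_grid()].
#' @return character vector of retained cell IDs.
#' @export
retained_cells <- function(grid) grid$cell_id[grid$retained]

# Clip polygon `poly` (matrix of vertices, columns x,y, open ring) against
# the axis-aligned rectangle [x0,x1] x [y0,y1] (Sutherland-Hodgman) and
# return the clipped area (shoelace). Used for positive-area presence tests.
clip_area <- function(poly, x0, x1, y0, y1) {
  clip_edge <- function(pts, inside, intersect) {
    if (nrow(pts) == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(pts)
    for (i in seq_len(np)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1) np else i - 1, ]
      ci <- inside(cur); pi_ <- inside(prev)
      if (ci) {
        if (!pi_) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi_) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  lerp <- function(p, q, t) p + t * (q - p)
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1] >= x0,
                   function(p, q) lerp(p, q, (x0 - p[1]) / (q[1] - p[1])))
  pts <- clip_edge(pts, function(p) p[1] <= x1,
                   function(p, q) lerp(p, q, (x1 - p[1]) / (q[1] - p[1])))
  pts <- clip_edge(pts, function(p) p[2] >= y0,
                   function(p, q) lerp(p, q, (y0 - p[2]) / (q[2] - p[2])))
  pts <- clip_edge(pts, function(p) p[2] <= y1,
                   function(p, q) lerp(p, q, (y1 - p[2]) / (q[2] - p[2])))
  if (nrow(pts) < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rasterize species ranges into a presence-absence matrix
#'
#' Converts per-species ranges into an incidence matrix over the retained
#' cells of a grid. Each range is either a character vector of cell IDs
#' (passed through, intersected with retained cells) or a polygon given as
#' a two-column matrix of planar (x_km, y_km) vertices; a polygon marks a
#' cell present when it intersects the cell's square with any positive
#' area (not a centroid rule, because range maps are coarse).
#'
#' @param ranges named list (names = species IDs), each element a character
#'   vector of cell IDs or a numeric vertex matrix.
#' @param grid a `grid_spec`.
#' @return integer 0/1 matrix, retained cells x species, with `dimnames`;
#'   class `presence_matrix`.
#' @examples
#' g <- build_grid(2, 2, cell_side_km = 1)
#' rasterize_ranges(list(spA = c("c1_1", "c2_2")), g)
#' @export
rasterize_ranges <- function(ranges, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.list(ranges))
  sp <- names(ranges)
  if (is.null(sp) || anyDuplicated(sp) || any(sp == "")) {
    stop("ranges must be a named list with unique, non-empty species IDs")
  }
  keep <- grid[grid$retained, , drop = FALSE]
  side <- attr(grid, "cell_side_km")
  pm <- matrix(0L, nrow = nrow(keep), ncol = length(sp),
               dimnames = list(keep$cell_id, sp))
  for (s in sp) {
    r <- ranges[[s]]
    if (is.character(r)) {
      unknown <- setdiff(r, grid$cell_id)
      if (length(unknown)) {
        stop("unknown cell IDs in range of ", s, ": ",
             paste(unknown, collapse = ", "))
      }
      hit <- intersect(r, keep$cell_id)
    } else if (is.matrix(r) && ncol(r) == 2) {
      a <- vapply(seq_len(nrow(keep)), function(i) {
        clip_area(r,
                  keep$x_km[i] - side / 2, keep$x_km[i] + side / 2,
                  keep$y_km[i] - side / 2, keep$y_km[i] + side / 2)
      }, numeric(1))
      hit <- keep$cell_id[a > 0]
    } else {
      stop("range of ", s, " must be a cell-ID vector or an x/y vertex matrix")
    }
    if (!length(hit)) {
      warning("species ", s, " is present in no retained cell", call. = FALSE)
    }
    pm[hit, s] <- 1L
  }
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

#' Per-cell species richness
#'
#' @param presence a cells x species 0/1 matrix (e.g. from
#'   [rasterize_ranges()]).
#' @return named integer vector of per-cell richness (row sums).
#' @export
richness_surface <- function(presence) {
  stopifnot(is.matrix(presence))
  sr <- as.integer(rowSums(presence > 0))
  names(sr) <- rownames(presence)
  sr
}

#' Aggregate a grid and presence matrix to a coarser resolution
#'
#' Blocks of `factor x factor` cells are merged: a species is present in a
#' block if present in any member cell; block ocean fraction is the mean of
#' member fractions (so the <50% exclusion rule is re-applied at the coarse
#' scale); block centroid is the mean of member centroids. Used for
#' grid-resolution sensitivity analyses.
#'
#' @param grid a `grid_spec`; @param presence its presence matrix.
#' @param factor integer aggregation factor >= 2.
#' @return list with elements `grid` (coarse `grid_spec`) and `presence`.
#' @export
aggregate_grid <- function(grid, presence, factor) {
  stopifnot(inherits(grid, "grid_spec"), factor >= 2, factor == round(factor))
  rows <- max(grid$row); cols <- max(grid$col)
  crows <- ceiling(rows / factor); ccols <- ceiling(cols / factor)
  blk_row <- ceiling(grid$row / factor)
  blk_col <- ceiling(grid$col / factor)
  blk <- paste(blk_row, blk_col, sep = "_")
  of <- tapply(grid$ocean_fraction, blk, mean)
  key <- paste(rep(seq_len(crows), each = ccols), rep(seq_len(ccols), crows),
               sep = "_")
  cg <- build_grid(crows, ccols, attr(grid, "cell_side_km") * factor,
                   ocean_fraction = as.numeric(of[key]))
  blk_id <- sprintf("c%s", blk)
  keep_fine <- rownames(presence)
  blk_of_fine <- blk_id[match(keep_fine, grid$cell_id)]
  cp <- matrix(0L, nrow = sum(cg$retained), ncol = ncol(presence),
               dimnames = list(retained_cells(cg), colnames(presence)))
  for (b in rownames(cp)) {
    member <- presence[blk_of_fine == b, , drop = FALSE]
    if (nrow(member)) cp[b, ] <- as.integer(colSums(member) > 0)
  }
  class(cp) <- c("presence_matrix", class(cp))
  list(grid = cg, presence = cp)
}
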