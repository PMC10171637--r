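#' Configuration for a synthetic biodiversity world
#'
#' Collects every parameter of the synthetic-world generator with the
#' study defaults: a 20 x 20 planar grid of 385.9 km cells, 150 species
#' with lognormal range sizes grown by a spreading-dye process, a
#' pure-birth species tree, star-shaped barcode sequence sets whose
#' within-species diversity is controlled by a per-species theta, a
#' sea-surface-temperature field peaking at the diversity hotspot, and a
#' marine-protected-area cell set that under-samples the hotspot.
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param cell_side_km cell side (km), default 385.9.
#' @param ocean_fraction per-cell ocean fraction (scalar or row-major
#'   vector), default all ocean.
#' @param n_species number of species.
#' @param range_size_log_mean,range_size_log_sd lognormal parameters of
#'   target range size (cells).
#' @param hotspot_center cell ID of the diversity hotspot (default: grid
#'   center).
#' @param hotspot_strength >= 0; 0 gives spatially uniform seeding,
#'   larger values concentrate range seeds (and deplete MPA placement)
#'   around the hotspot.
#' @param hotspot_radius_cells radius (in cell sides) defining the true
#'   hotspot cell set recorded in the ground truth.
#' @param theta_hotspot_factor multiplicative theta boost for species
#'   whose range touches the hotspot (default 2).
#' @param birth_rate pure-birth (Yule) speciation rate for the species
#'   tree.
#' @param seq_per_species_mean mean sequences per species (min 2 drawn).
#' @param seq_length alignment length (sites).
#' @param theta_low,theta_high uniform bounds for per-species expected
#'   pairwise diversity theta.
#' @param sst_base,sst_amplitude,sst_noise_sd SST field: baseline (deg C),
#'   hotspot peak amplitude, white-noise SD.
#' @param mpa_fraction fraction of retained cells designated MPA.
#' @param mpa_hotspot_avoidance >= 0; larger values push MPA cells away
#'   from the hotspot.
#' @param seed RNG seed: identical config + seed gives a bit-identical
#'   world.
#' @return validated list of class `world_config`.
#' @export
world_config <- function(grid_rows = 20, grid_cols = 20,
                         cell_side_km = 385.9, ocean_fraction = 1,
                         n_species = 150,
                         range_size_log_mean = log(12),
                         range_size_log_sd = 0.6,
                         hotspot_center = NULL, hotspot_strength = 3,
                         hotspot_radius_cells = 2.5,
                         theta_hotspot_factor = 2,
                         birth_rate = 1,
                         seq_per_species_mean = 8, seq_length = 500,
                         theta_low = 0.002, theta_high = 0.02,
                         sst_base = 8, sst_amplitude = 18,
                         sst_noise_sd = 1,
                         mpa_fraction = 0.15, mpa_hotspot_avoidance = 3,
                         seed = 1) {
  cfg <- list(grid_rows = grid_rows, grid_cols = grid_cols,
              cell_side_km = cell_side_km, ocean_fraction = ocean_fraction,
              n_species = n_species,
              range_size_log_mean = range_size_log_mean,
              range_size_log_sd = range_size_log_sd,
              hotspot_center = hotspot_center,
              hotspot_strength = hotspot_strength,
              hotspot_radius_cells = hotspot_radius_cells,
              theta_hotspot_factor = theta_hotspot_factor,
              birth_rate = birth_rate,
              seq_per_species_mean = seq_per_species_mean,
              seq_length = seq_length,
              theta_low = theta_low, theta_high = theta_high,
              sst_base = sst_base, sst_amplitude = sst_amplitude,
              sst_noise_sd = sst_noise_sd,
              mpa_fraction = mpa_fraction,
              mpa_hotspot_avoidance = mpa_hotspot_avoidance,
              seed = seed)
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_species >= 1,
            seq_per_species_mean >= 2, seq_length >= 1,
            theta_low >= 0, theta_high >= theta_low, theta_high <= 0.75,
            hotspot_strength >= 0, mpa_hotspot_avoidance >= 0,
            mpa_fraction >= 0, mpa_fraction <= 1,
            all(ocean_fraction >= 0), all(ocean_fraction <= 1),
            birth_rate > 0, theta_hotspot_factor >= 1)
  class(cfg) <- "world_config"
  cfg
}

# 4-neighbour adjacency among retained cells, as a list keyed by cell_id.
grid_adjacency <- function(grid) {
  keep <- grid[grid$retained, , drop = FALSE]
  key <- function(r, c) sprintf("c%d_%d", r, c)
  ok <- keep$cell_id
  adj <- lapply(seq_len(nrow(keep)), function(i) {
    r <- keep$row[i]; c <- keep$col[i]
    intersect(c(key(r - 1, c), key(r + 1, c), key(r, c - 1), key(r, c + 1)),
              ok)
  })
  names(adj) <- ok
  adj
}

# Spreading-dye range growth from a seed cell to (at most) a target size
# through retained-ocean 4-neighbours. If the connected component is
# exhausted early the realized range is smaller than the target.
grow_range <- function(seed_cell, target, adj) {
  members <- seed_cell
  frontier <- setdiff(adj[[seed_cell]], members)
  while (length(members) < target && length(frontier)) {
    nxt <- frontier[sample.int(length(frontier), 1)]
    members <- c(members, nxt)
    frontier <- setdiff(union(frontier, adj[[nxt]]), members)
  }
  members
}

# Star-shaped sequence set: mutate a random ancestral sequence
# independently per lineage with per-site substitution probability
# theta / 2, so the expected pairwise p-distance is
# 2q(1 - q) + (2/3)q^2 ~ theta for small theta.
simulate_sequences <- function(n, L, theta) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  q <- theta / 2
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    mut <- runif(L) < q
    if (any(mut)) {
      s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%03d", seq_len(n))
  seqs
}

#' Generate a synthetic biodiversity world with known ground truth
#'
#' Builds, under one RNG seed, every input the analysis pipeline consumes:
#' a grid with the <50%-ocean exclusion applied; species ranges grown by a
#' spreading-dye process whose seed cells are biased toward a diversity
#' hotspot; a pure-birth species tree; per-species aligned sequence sets
#' with controlled expected pairwise diversity theta (boosted for hotspot
#' species); an SST surface peaking at the hotspot plus white noise; and
#' an MPA cell set whose placement avoids the hotspot. The `truth`
#' element records hotspot cells, seed cells, true theta and realized
#' range sizes for parameter-recovery tests.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world`: `config`, `grid`, `presence`,
#'   `tree`, `alignments`, `sst`, `mpa_cells`, `truth`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, {
    grid <- build_grid(config$grid_rows, config$grid_cols,
                       config$cell_side_km, config$ocean_fraction)
    keep <- grid[grid$retained, , drop = FALSE]
    n_ocean <- nrow(keep)
    if (n_ocean < 1) stop("no retained ocean cells")
    side <- config$cell_side_km
    center <- config$hotspot_center %||%
      sprintf("c%d_%d", ceiling(config$grid_rows / 2),
              ceiling(config$grid_cols / 2))
    if (!center %in% grid$cell_id) stop("unknown hotspot_center ", center)
    cx <- grid$x_km[grid$cell_id == center]
    cy <- grid$y_km[grid$cell_id == center]
    d <- sqrt((keep$x_km - cx)^2 + (keep$y_km - cy)^2)
    dmax <- max(d, side)
    hotspot_cells <- keep$cell_id[d <= config$hotspot_radius_cells * side]
    sp <- sprintf("sp%03d", seq_len(config$n_species))

    # ranges: lognormal target size, spreading dye from a hotspot-biased
    # seed cell
    adj <- grid_adjacency(grid)
    seed_w <- exp(-config$hotspot_strength * d / dmax)
    targets <- pmax(1, round(rlnorm(config$n_species,
                                    config$range_size_log_mean,
                                    config$range_size_log_sd)))
    over <- which(targets > n_ocean)
    if (length(over)) {
      stop("range size target of species ", over[1], " (", targets[over[1]],
           " cells) exceeds the ", n_ocean, " available ocean cells")
    }
    seed_cells <- keep$cell_id[sample.int(n_ocean, config$n_species,
                                          replace = TRUE, prob = seed_w)]
    ranges <- lapply(seq_len(config$n_species), function(i) {
      grow_range(seed_cells[i], targets[i], adj)
    })
    names(ranges) <- sp
    presence <- rasterize_ranges(ranges, grid)

    # pure-birth species tree, tips relabeled to species IDs
    tree <- ape::rphylo(config$n_species, birth = config$birth_rate,
                        death = 0)
    tree$tip.label <- sp
    tree$edge.length <- round(tree$edge.length, 6)

    # per-species theta, boosted multiplicatively for hotspot species
    theta <- round(runif(config$n_species, config$theta_low,
                         config$theta_high), 10)
    touches <- vapply(ranges, function(r) any(r %in% hotspot_cells),
                      logical(1))
    theta[touches] <- pmin(theta[touches] * config$theta_hotspot_factor,
                           0.75)
    names(theta) <- sp

    # star-shaped sequence sets; sampling coordinates jittered inside
    # cells of the species' range
    alignments <- lapply(seq_len(config$n_species), function(i) {
      n <- 2 + rpois(1, config$seq_per_species_mean - 2)
      seqs <- simulate_sequences(n, config$seq_length, theta[i])
      cells <- sample(ranges[[i]], n, replace = TRUE)
      ix <- match(cells, grid$cell_id)
      lat <- round(grid$y_km[ix] + runif(n, -0.45, 0.45) * side, 4)
      lon <- round(grid$x_km[ix] + runif(n, -0.45, 0.45) * side, 4)
      names(seqs) <- sprintf("%s_s%03d", sp[i], seq_len(n))
      species_alignment(sp[i], seqs, lat = lat, lon = lon)
    })
    names(alignments) <- sp

    # SST: smooth peak at the hotspot plus white noise
    sigma <- 0.35 * dmax
    sst <- round(config$sst_base +
                   config$sst_amplitude * exp(-0.5 * (d / sigma)^2) +
                   rnorm(n_ocean, 0, config$sst_noise_sd), 4)
    names(sst) <- keep$cell_id

    # MPA cells: sampling weight grows away from the hotspot
    n_mpa <- round(config$mpa_fraction * n_ocean)
    mpa_cells <- character(0)
    if (n_mpa > 0) {
      mpa_w <- exp(config$mpa_hotspot_avoidance * d / dmax)
      mpa_cells <- keep$cell_id[sample.int(n_ocean, n_mpa, prob = mpa_w)]
    }

    structure(list(
      config = config, grid = grid, presence = presence, tree = tree,
      alignments = alignments, sst = sst, mpa_cells = sort(mpa_cells),
      truth = list(hotspot_center = center, hotspot_cells = hotspot_cells,
                   seed_cells = stats::setNames(seed_cells, sp),
                   theta = theta,
                   range_size = stats::setNames(lengths(ranges), sp),
                   hotspot_species = sp[touches])
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world: %dx%d grid (%d retained cells), %d species, %d MPA cells, seed %s\n",
    x$config$grid_rows, x$config$grid_cols, nrow(x$presence),
    length(x$alignments), length(x$mpa_cells), format(x$config$seed)))
  invisible(x)
}
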