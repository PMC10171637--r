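#' Write a synthetic world to a directory of standard text formats
#'
#' Emits one aligned FASTA per species (headers
#' `seqID|speciesID|lat|lon`), the species tree as Newick, the presence
#' matrix and grid as CSV, the SST surface as CSV, the MPA cell list as
#' plain text, and a JSON manifest carrying the full config, seed and
#' ground truth. [read_world()] round-trips the result exactly.
#'
#' @param world a [generate_world()] result.
#' @param directory output directory (created if missing).
#' @param overwrite overwrite an existing manifest (default FALSE: a
#'   collision is an error).
#' @return (invisibly) the manifest list, with `$files` naming every
#'   artifact.
#' @export
write_world <- function(world, directory, overwrite = FALSE) {
  stopifnot(inherits(world, "synthetic_world"))
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE")
  }
  dir.create(file.path(directory, "fasta"), recursive = TRUE,
             showWarnings = FALSE)
  for (aln in world$alignments) {
    set <- Biostrings::DNAStringSet(aln$seqs)
    names(set) <- sprintf("%s|%s|%s|%s", names(aln$seqs), aln$species_id,
                          sprintf("%.4f", aln$lat), sprintf("%.4f", aln$lon))
    Biostrings::writeXStringSet(
      set, file.path(directory, "fasta", paste0(aln$species_id, ".fasta")))
  }
  ape::write.tree(world$tree, file.path(directory, "tree.nwk"))
  pres <- data.frame(cell_id = rownames(world$presence),
                     as.data.frame(unclass(world$presence)),
                     check.names = FALSE)
  write.csv(pres, file.path(directory, "presence.csv"), row.names = FALSE)
  write.csv(as.data.frame(world$grid), file.path(directory, "grid.csv"),
            row.names = FALSE)
  write.csv(data.frame(cell_id = names(world$sst), sst = world$sst),
            file.path(directory, "sst.csv"), row.names = FALSE)
  writeLines(world$mpa_cells, file.path(directory, "mpa_cells.txt"))
  truth <- world$truth
  # named atomic vectors serialize as bare arrays; keep the names
  truth$theta <- as.list(truth$theta)
  truth$range_size <- as.list(truth$range_size)
  truth$seed_cells <- as.list(truth$seed_cells)
  manifest <- list(
    format = "biodivgrid synthetic world v1",
    config = unclass(world$config),
    truth = truth,
    files = list(fasta_dir = "fasta", tree = "tree.nwk",
                 presence = "presence.csv", grid = "grid.csv",
                 sst = "sst.csv", mpa = "mpa_cells.txt")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

# Parse one `seqID|speciesID|lat|lon` FASTA into a species_alignment.
read_species_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad)) {
    stop("malformed FASTA header in ", path, ": ", names(set)[which(bad)[1]])
  }
  f <- function(k) vapply(parts, `[[`, character(1), k)
  seqs <- as.character(set)
  names(seqs) <- f(1)
  species <- unique(f(2))
  if (length(species) != 1) {
    stop("multiple species IDs in one alignment file: ", path)
  }
  species_alignment(species, seqs, lat = as.numeric(f(3)),
                    lon = as.numeric(f(4)))
}

#' Read a synthetic world back from disk
#'
#' Inverse of [write_world()]. The grid is reconstructed from the manifest
#' config (which stores the ocean-fraction field at full precision), so the
#' round trip `read_world(write_world(w))` reproduces `w` exactly.
#'
#' @param directory directory written by [write_world()].
#' @return a `synthetic_world`.
#' @export
read_world <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", directory)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  config <- world_config(
    grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols,
    cell_side_km = cfg$cell_side_km, ocean_fraction = cfg$ocean_fraction,
    n_species = cfg$n_species,
    range_size_log_mean = cfg$range_size_log_mean,
    range_size_log_sd = cfg$range_size_log_sd,
    hotspot_center = cfg$hotspot_center,
    hotspot_strength = cfg$hotspot_strength,
    hotspot_radius_cells = cfg$hotspot_radius_cells,
    theta_hotspot_factor = cfg$theta_hotspot_factor,
    birth_rate = cfg$birth_rate,
    seq_per_species_mean = cfg$seq_per_species_mean,
    seq_length = cfg$seq_length,
    theta_low = cfg$theta_low, theta_high = cfg$theta_high,
    sst_base = cfg$sst_base, sst_amplitude = cfg$sst_amplitude,
    sst_noise_sd = cfg$sst_noise_sd,
    mpa_fraction = cfg$mpa_fraction,
    mpa_hotspot_avoidance = cfg$mpa_hotspot_avoidance,
    seed = cfg$seed)
  grid <- build_grid(config$grid_rows, config$grid_cols,
                     config$cell_side_km, config$ocean_fraction)
  pres_df <- read.csv(file.path(directory, man$files$presence),
                      check.names = FALSE, stringsAsFactors = FALSE)
  presence <- as.matrix(pres_df[, -1, drop = FALSE])
  storage.mode(presence) <- "integer"
  rownames(presence) <- pres_df$cell_id
  class(presence) <- c("presence_matrix", class(presence))
  tree <- ape::read.tree(file.path(directory, man$files$tree))
  fasta_files <- sort(list.files(file.path(directory, man$files$fasta_dir),
                                 pattern = "\\.fasta$", full.names = TRUE))
  alignments <- lapply(fasta_files, read_species_fasta)
  names(alignments) <- vapply(alignments, `[[`, character(1), "species_id")
  sst_df <- read.csv(file.path(directory, man$files$sst),
                     stringsAsFactors = FALSE)
  sst <- sst_df$sst
  names(sst) <- sst_df$cell_id
  mpa <- readLines(file.path(directory, man$files$mpa))
  mpa <- mpa[nzchar(mpa)]
  truth <- man$truth
  truth$theta <- unlist(truth$theta)
  truth$range_size <- unlist(truth$range_size)
  storage.mode(truth$range_size) <- "integer"
  truth$seed_cells <- unlist(truth$seed_cells)
  structure(list(config = config, grid = grid, presence = presence,
                 tree = tree, alignments = alignments, sst = sst,
                 mpa_cells = mpa, truth = truth),
            class = "synthetic_world")
}
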