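# Fixtures built in code; no files on disk except through tempdir().

# minimal otu_table: counts given as a named list of sample columns
make_table <- function(cols, otu_ids, taxonomy = NULL, samples = NULL) {
  counts <- do.call(cbind, cols)
  rownames(counts) <- otu_ids
  otu_table(counts, samples = samples, taxonomy = taxonomy)
}

# random integer table with self-describing sample names
random_table <- function(n_otu = 8, sources = c("L1", "L2"), max_count = 500) {
  ids <- sprintf("OTU_%02d", seq_len(n_otu))
  cols <- list()
  for (src in sources) {
    for (f in c("S", "M", "L", "XL")) {
      for (r in 1:2) {
        cols[[sprintf("%s_%s_r%d", src, f, r)]] <-
          rpois(n_otu, lambda = runif(1, 1, max_count))
      }
    }
  }
  cols[["NC_1"]] <- rpois(n_otu, 0.2)
  make_table(cols, ids)
}

# hand-built specimen_set (bypasses draw_community) for distributional tests
manual_specimens <- function(species_id, weight, fraction, efficiency = NULL,
                             source = "L1") {
  ids <- unique(species_id)
  if (is.null(efficiency)) efficiency <- rep(1, length(ids))
  pool <- data.frame(otu_id = ids, lambda = 1,
                     mean_length_mm = 1, efficiency = efficiency,
                     stringsAsFactors = FALSE)
  structure(data.frame(species_id = species_id, body_length_mm = 1,
                       dry_weight_mg = weight, fraction = fraction,
                       is_fragment = FALSE, stringsAsFactors = FALSE),
            pool = pool, source = source,
            class = c("specimen_set", "data.frame"))
}

# a small but fully populated scenario configuration used by several suites;
# only the community size is reduced relative to the package defaults
small_config <- function(...) {
  sim_config(n_species = 120, ...)
}
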