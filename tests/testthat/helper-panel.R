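# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# A defect-free universe (every locus clean, high MAF, good designability).
clean_universe <- function(n_loci, seed, divergence = 0.15, ...) {
  generate_locus_universe(n_loci = n_loci, divergence = divergence,
                          seed = seed, ...)
}

# Full clean study: universe + population + intensities, no planted defects.
clean_study <- function(n_loci, seed, profile = noise_profile(), ...) {
  universe <- clean_universe(n_loci, seed)
  population <- generate_population(universe, seed = seed, ...)
  intensities <- generate_intensities(universe, population, profile,
                                      seed = seed)
  list(universe = universe, population = population,
       intensities = intensities)
}

# Deterministic long-format intensities for one locus: points at the given
# thetas with the given total signals (r = x + y convention).
locus_points <- function(thetas, r = 1, locus_id = "L1",
                         sample_ids = sprintf("S%03d", seq_along(thetas))) {
  r <- rep_len(r, length(thetas))
  tn <- tan(thetas * pi / 2)
  x <- r / (1 + tn)
  x[thetas >= 1] <- 0
  y <- r - x
  data.frame(sample_id = sample_ids, locus_id = locus_id, x = x, y = y,
             stringsAsFactors = FALSE)
}

# Call matrix from a named list of per-sample call vectors (loci as names).
call_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

# Minimal QC row for boundary tests on the selection stages.
qc_row <- function(locus_id, quality_score = 0.95, missing_count = 0,
                   n_samples = 96, flags = "", reproducibility = 1) {
  data.frame(locus_id = locus_id, quality_score = quality_score,
             missing_count = missing_count, n_samples = n_samples,
             missing_rate = missing_count / n_samples, flags = flags,
             reproducibility = reproducibility, stringsAsFactors = FALSE)
}

# Minimal locus-map row for selection-stage tests.
map_row <- function(locus_id, chromosome = 1, position = NULL,
                    genic_category = "exon",
                    genic_region_id = paste0("R_", locus_id),
                    copy_number = 1, designability = 0.9) {
  if (is.null(position)) position <- 1000 * seq_along(locus_id)
  data.frame(locus_id = locus_id, chromosome = chromosome,
             position = position, genic_category = genic_category,
             genic_region_id = genic_region_id, copy_number = copy_number,
             designability = designability, stringsAsFactors = FALSE)
}
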