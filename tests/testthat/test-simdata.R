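test_that("a zero-defect universe is entirely clean and validly laid out", {
  u <- generate_locus_universe(n_loci = 100, seed = 1)
  expect_equal(nrow(u$loci), 100)
  expect_true(all(u$loci$defect_class == "none"))
  expect_true(all(u$loci$designability >= 0 & u$loci$designability <= 1))
  expect_true(all(u$loci$copy_number >= 1))
  # positions strictly increasing within each chromosome
  for (chr in unique(u$loci$chromosome)) {
    pos <- u$loci$position[u$loci$chromosome == chr]
    expect_true(all(diff(pos) > 0))
  }
  # every locus belongs to exactly one genic region
  expect_false(anyNA(u$loci$genic_region_id))
})

test_that("designability scores follow the configured three-interval mixture", {
  u <- generate_locus_universe(n_loci = 10000, seed = 42)
  frac_top <- mean(u$loci$designability > 0.80)
  sd3 <- 3 * sqrt(0.71 * 0.29 / 10000)
  expect_lt(abs(frac_top - 0.71), sd3)
  frac_mid <- mean(u$loci$designability > 0.60 & u$loci$designability <= 0.80)
  expect_lt(abs(frac_mid - 0.275), 3 * sqrt(0.275 * 0.725 / 10000))
})

test_that("fixed seed gives bit-identical universe, population and intensities", {
  a <- simulate_study(n_loci = 60, seed = 9, n_duplicates = 2)
  b <- simulate_study(n_loci = 60, seed = 9, n_duplicates = 2)
  expect_identical(a$universe, b$universe)
  expect_identical(a$population, b$population)
  expect_identical(a$intensities, b$intensities)
})

test_that("invalid planted fractions are rejected with the offending name", {
  expect_error(
    generate_locus_universe(10, defect_fractions = c(weak_signal = -0.1),
                            seed = 1),
    "defect_fractions.*negative|negative.*defect_fractions")
  expect_error(
    generate_locus_universe(10, defect_fractions = c(weak_signal = 0.9,
                                                     shifted = 0.3), seed = 1),
    "exceeds 1")
  expect_error(
    generate_locus_universe(10, defect_fractions = c(bogus = 0.1), seed = 1),
    "unknown defect class")
})

test_that("planted defect fractions are realized within 3 binomial SD", {
  fr <- c(weak_signal = 0.05, shifted = 0.10, multicopy_compressed = 0.08)
  u <- generate_locus_universe(n_loci = 5000, defect_fractions = fr, seed = 3)
  for (cls in names(fr)) {
    got <- mean(u$loci$defect_class == cls)
    expect_lt(abs(got - fr[[cls]]), 3 * sqrt(fr[[cls]] * (1 - fr[[cls]]) / 5000))
  }
})

test_that("F1 truth is the Mendelian combination of homozygous parents", {
  u <- clean_universe(300, seed = 5)
  pop <- generate_population(u, n_triplets = 5, n_hybrids = 5,
                             n_duplicates = 0, seed = 5)
  g <- pop$truth$genotypes
  for (i in seq_len(nrow(pop$triplets))) {
    p1 <- g[pop$triplets$parent1[i], ]
    p2 <- g[pop$triplets$parent2[i], ]
    f1 <- g[pop$triplets$f1[i], ]
    expect_true(all(mendel_consistent(p1, p2, f1)))
    # distinct homozygous parents always give a heterozygous F1
    het <- p1 != p2
    expect_true(all(f1[het] == "AB"))
    expect_true(all(f1[!het] == p1[!het]))
  }
  # inbreds are homozygous everywhere (clean universe)
  inb <- inbred_lines(pop$samples)
  expect_false(any(g[inb, ] == "AB"))
})

test_that("similar-line series realize the configured mutation fraction", {
  u <- clean_universe(2000, seed = 11)
  spec <- list(list(name = "bc", n_copies = 1, mutation_fraction = 0.02))
  pop <- generate_population(u, similar_line_spec = spec, n_duplicates = 0,
                             enforce_maf_margin = FALSE, seed = 11)
  copy_id <- pop$samples$sample_id[!is.na(pop$samples$series)]
  expect_length(copy_id, 1)
  # the copy differs from every other line; find its base by max identity
  g <- pop$truth$genotypes
  base_ids <- setdiff(inbred_lines(pop$samples), copy_id)
  ident <- vapply(base_ids, function(s) mean(g[s, ] == g[copy_id, ]),
                  numeric(1))
  expect_lt(abs(max(ident) - 0.98), 3 * sqrt(0.02 * 0.98 / 2000))
})

test_that("radiation-series copies and duplicates are exact genotype copies", {
  u <- clean_universe(200, seed = 13)
  spec <- list(list(name = "rad", n_copies = 2, mutation_fraction = 0))
  pop <- generate_population(u, similar_line_spec = spec, n_duplicates = 2,
                             seed = 13)
  g <- pop$truth$genotypes
  rad <- pop$samples$sample_id[pop$samples$series %in% "rad"]
  expect_identical(g[rad[1], ], g[rad[2], ])
  for (i in seq_len(nrow(pop$duplicate_pairs))) {
    expect_identical(g[pop$duplicate_pairs$sample_a[i], ],
                     g[pop$duplicate_pairs$sample_b[i], ])
  }
  dup <- pop$samples[!is.na(pop$samples$duplicate_of), ]
  expect_true(all(dup$duplicate_of %in% pop$samples$sample_id))
})

test_that("empirical inbred allele frequency tracks the group frequencies", {
  u <- generate_locus_universe(n_loci = 40, divergence = 0, seed = 17)
  pop <- generate_population(u, n_inbreds_per_group = 60, n_hybrids = 0,
                             n_triplets = 0, n_duplicates = 0,
                             similar_line_spec = list(),
                             enforce_maf_margin = FALSE, seed = 17)
  g <- pop$truth$genotypes
  for (grp in u$groups[1:2]) {
    ids <- pop$samples$sample_id[pop$samples$group %in% grp]
    emp <- colMeans(g[ids, ] == "BB")
    p <- u$allele_freq[, grp]
    sd3 <- 3 * sqrt(p * (1 - p) / length(ids))
    expect_true(all(abs(emp - p) <= pmax(sd3, 1e-9)))
  }
})

test_that("population construction rejects impossible requests", {
  u <- clean_universe(50, seed = 19)
  expect_error(generate_population(u, groups = c("STPT", "NotAGroup"), seed = 1),
               "NotAGroup")
  expect_error(generate_population(u, n_inbreds_per_group = 1, n_triplets = 22,
                                   seed = 1),
               "triplets")
  expect_error(generate_population(u, n_hybrids = 2, n_triplets = 5, seed = 1),
               "n_hybrids")
})

test_that("intensity emission honors genotype geometry and the zero-noise limit", {
  u <- clean_universe(30, seed = 23)
  pop <- generate_population(u, n_inbreds_per_group = 2, n_hybrids = 4,
                             n_triplets = 2, n_duplicates = 0, seed = 23)
  exact <- noise_profile(theta_sd = 0, signal_sd = 0)
  ints <- generate_intensities(u, pop, exact, seed = 23)
  tr <- to_theta_r(ints$x, ints$y)
  geno <- pop$truth$genotypes[cbind(ints$sample_id, ints$locus_id)]
  centers <- exact$theta_centers
  expect_equal(tr$theta, unname(centers[geno]), tolerance = 1e-12)
  expect_equal(tr$r, rep(1, nrow(ints)), tolerance = 1e-12)

  noisy <- generate_intensities(u, pop, noise_profile(), seed = 23)
  expect_true(all(noisy$x >= 0 & noisy$y >= 0))
  trn <- to_theta_r(noisy$x, noisy$y)
  expect_true(all(trn$theta[geno == "AA"] < 0.2))
})

test_that("weak-signal loci emit median total signal below the caller floor", {
  u <- generate_locus_universe(n_loci = 40,
                               defect_fractions = c(weak_signal = 0.5),
                               seed = 29)
  pop <- generate_population(u, n_inbreds_per_group = 4, n_hybrids = 2,
                             n_triplets = 1, n_duplicates = 0, seed = 29)
  ints <- generate_intensities(u, pop, seed = 29)
  tr <- to_theta_r(ints$x, ints$y)
  weak <- u$loci$locus_id[u$loci$defect_class == "weak_signal"]
  cfg <- cluster_config()
  med <- tapply(tr$r, ints$locus_id, median)
  expect_true(all(med[weak] < cfg$r_floor_min))
  expect_true(all(med[setdiff(names(med), weak)] > cfg$r_floor_min))
})
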