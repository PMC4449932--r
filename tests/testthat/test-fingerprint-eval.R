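test_that("MAF counts alleles correctly and is label-swap invariant", {
  m <- call_matrix(
    s01 = c(L1 = "AA", L2 = "AA", L3 = "AA", L4 = "NC"),
    s02 = c(L1 = "AA", L2 = "AA", L3 = "AA", L4 = "NC"))
  # hand-built panel: 10 AA + 10 BB at one locus; 6 AA + 2 AB + 2 BB at another
  g1 <- c(rep("AA", 10), rep("BB", 10))
  g2 <- c(rep("AA", 6), rep("AB", 2), rep("BB", 2), rep("AA", 10))
  big <- cbind(Lhalf = g1, Lmix = g2)
  rownames(big) <- sprintf("s%02d", 1:20)
  maf <- compute_maf(big)
  expect_equal(maf$maf[maf$locus_id == "Lhalf"], 0.5)
  # 6 AA, 2 AB, 2 BB over the first ten samples plus 10 AA:
  # B alleles = 2*2 + 2 = 6 of 40 -> recompute on the intended subset
  sub <- compute_maf(big, sample_subset = sprintf("s%02d", 1:10))
  expect_equal(sub$maf[sub$locus_id == "Lmix"], (2 * 2 + 2) / 20)
  maf2 <- compute_maf(m)
  expect_equal(maf2$maf[maf2$locus_id == "L3"], 0)       # monomorphic
  expect_true(is.na(maf2$maf[maf2$locus_id == "L4"]))    # all NC
  # relabeling A <-> B leaves the MAF unchanged
  swapped <- big
  swapped[big == "AA"] <- "BB"; swapped[big == "BB"] <- "AA"
  expect_equal(compute_maf(swapped)$maf, maf$maf)
  expect_true(all(maf$maf <= 0.5, na.rm = TRUE))
})

test_that("pedigree consistency scores Mendelian triplets", {
  m <- call_matrix(
    p1 = c(L1 = "AA", L2 = "AA", L3 = "AA", L4 = "NC"),
    p2 = c(L1 = "BB", L2 = "AA", L3 = "AB", L4 = "BB"),
    f1 = c(L1 = "AB", L2 = "AB", L3 = "AB", L4 = "AB"))
  r <- pedigree_consistency(m, c(parent1 = "p1", parent2 = "p2", f1 = "f1"))
  # L1: AAxBB -> AB consistent; L2: AAxAA -> AB inconsistent;
  # L3: AAxAB -> {AA, AB} so AB consistent; L4 unscorable (NC parent)
  expect_equal(r$n_scorable, 3)
  expect_equal(r$n_consistent, 2)
  expect_equal(r$consistency, 2 / 3)
  expect_error(pedigree_consistency(m, c(parent1 = "p1", parent2 = "ghost",
                                         f1 = "f1")), "ghost")
})

test_that("error-free simulated triplets are 100 % consistent at any panel size", {
  for (n_loci in c(50, 500)) {
    study <- clean_study(n_loci, seed = 71)
    cf <- build_cluster_file(study$intensities)
    calls <- call_genotypes(study$intensities, cf)
    res <- pedigree_consistency_all(calls$calls, study$population$triplets)
    expect_true(all(res$consistency == 1))
    expect_true(all(res$n_scorable > 0))
  }
})

test_that("pairwise comparisons enumerate all unordered pairs", {
  for (n in c(2, 5, 24)) {
    m <- matrix("AA", n, 3,
                dimnames = list(sprintf("s%02d", 1:n), c("L1", "L2", "L3")))
    pw <- pairwise_differences(m)
    expect_equal(nrow(pw$pairs), n * (n - 1) / 2)
    expect_true(all(pw$pairs$differential_rate == 0))
    expect_equal(sum(pw$histogram$count), n * (n - 1) / 2)
  }
})

test_that("differential rates count mismatches over co-called loci only", {
  set.seed(73)
  n_loci <- 100
  a <- rep("AA", n_loci)
  b <- a; b[1:30] <- "BB"                       # 30 of 100 differ
  c <- a; c[1:10] <- "NC"                       # NC excluded
  m <- rbind(a = a, b = b, c = c)
  colnames(m) <- sprintf("L%03d", 1:n_loci)
  pw <- pairwise_differences(m)
  p <- pw$pairs
  rate_ab <- p$differential_rate[p$sample_a == "a" & p$sample_b == "b"]
  expect_equal(rate_ab, 0.30)
  rate_ac <- p$differential_rate[p$sample_a == "a" & p$sample_b == "c"]
  expect_equal(rate_ac, 0)
  n_ac <- p$n_cocalled[p$sample_a == "a" & p$sample_b == "c"]
  expect_equal(n_ac, 90)
  # hom vs het counts as a difference
  d <- a; d[1] <- "AB"
  m2 <- rbind(a = a, d = d)
  colnames(m2) <- colnames(m)
  pw2 <- pairwise_differences(m2)
  expect_equal(pw2$pairs$n_diff, 1)
})

test_that("genetic similarity is the complement of the differential rate", {
  m <- rbind(a = rep(c("AA", "BB"), 50), b = rep(c("AA", "BB"), 50))
  colnames(m) <- sprintf("L%03d", 1:100)
  expect_equal(genetic_similarity(m, c("a", "b")), 1)
  m["b", 1:2] <- "AB"
  expect_equal(genetic_similarity(m, c("a", "b")), 0.98)
  m2 <- rbind(a = c(L1 = "NC"), b = c(L1 = "AA"))
  expect_error(genetic_similarity(m2, c("a", "b")), "co-called")
})

test_that("backcross similar lines land near 98 % similarity after calling", {
  u <- clean_universe(2000, seed = 77)
  spec <- list(list(name = "bc", n_copies = 1, mutation_fraction = 0.02))
  pop <- generate_population(u, similar_line_spec = spec, n_duplicates = 0,
                             seed = 77)
  ints <- generate_intensities(u, pop, seed = 77)
  calls <- call_genotypes(ints, build_cluster_file(ints))
  copy_id <- pop$samples$sample_id[!is.na(pop$samples$series)]
  g <- pop$truth$genotypes
  base_ids <- setdiff(inbred_lines(pop$samples), copy_id)
  base <- base_ids[which.max(vapply(base_ids, function(s)
    mean(g[s, ] == g[copy_id, ]), numeric(1)))]
  sim <- genetic_similarity(calls$calls, c(base, copy_id))
  expect_lt(abs(sim - 0.98), 3 * sqrt(0.02 * 0.98 / 2000))
})

test_that("platform concordance scores shared non-missing entries", {
  m <- matrix("AA", 10, 10, dimnames = list(sprintf("s%02d", 1:10),
                                            sprintf("L%02d", 1:10)))
  expect_equal(platform_concordance(m, m)$concordance, 1)
  b <- m; b[1, 1] <- "BB"
  expect_equal(platform_concordance(m, b)$concordance, 0.99)
  b2 <- m; b2[1, 1] <- "NC"
  out <- platform_concordance(m, b2)
  expect_equal(out$concordance, 1)          # NC excluded from the denominator
  expect_equal(out$n_compared, 99)
  other <- matrix("AA", 2, 2, dimnames = list(c("x", "y"), c("Lx", "Ly")))
  expect_error(platform_concordance(m, other), "share no")
})

test_that("randomly corrupting 5 % of calls drops concordance by about 2/3 of 5 %", {
  set.seed(79)
  n_s <- 60; n_l <- 400
  m <- matrix(sample(c("AA", "AB", "BB"), n_s * n_l, replace = TRUE), n_s, n_l,
              dimnames = list(sprintf("s%02d", 1:n_s), sprintf("L%03d", 1:n_l)))
  b <- m
  hit <- sample(length(b), 0.05 * length(b))
  b[hit] <- sample(c("AA", "AB", "BB"), length(hit), replace = TRUE)
  conc <- platform_concordance(m, b)$concordance
  expected <- 1 - 0.05 * (2 / 3)
  expect_lt(abs(conc - expected), 3 * sqrt(expected * (1 - expected) / (n_s * n_l)))
})

test_that("genomic windows conserve counts and use the documented boundary", {
  map <- map_row(c("w1", "w2", "w3"), chromosome = c(1, 1, 2),
                 position = c(1e6, 1e6 + 1, 5e5))
  gd <- genomic_distribution(c("w1", "w2", "w3"), map)
  expect_equal(sum(gd$windows$count), 3)
  expect_equal(gd$windows$window[gd$windows$chromosome == 1], c(1, 2))
  expect_error(genomic_distribution("ghost", map), "ghost")
  expect_equal(sum(gd$category_proportions), 1)
})

test_that("default genic-category proportions are realized at scale", {
  u <- generate_locus_universe(n_loci = 10000, seed = 81)
  props <- table(factor(u$loci$genic_category,
                        levels = names(genic_category_default()))) / 10000
  want <- genic_category_default()
  for (cat in names(want)) {
    sd3 <- 3 * sqrt(want[[cat]] * (1 - want[[cat]]) / 10000)
    expect_lt(abs(props[[cat]] - want[[cat]]), sd3)
  }
})

test_that("comparative reports line up panels evaluated on one sample set", {
  study <- simulate_study(n_loci = 400, seed = 83)
  cf <- build_cluster_file(study$intensities)
  calls <- call_genotypes(study$intensities, cf)
  pop <- study$population
  qc <- score_loci(study$intensities, calls, cf, pop$samples,
                   triplets = pop$triplets,
                   duplicate_pairs = pop$duplicate_pairs)
  maf <- compute_maf(calls, sample_subset = inbred_lines(pop$samples))
  panel <- run_pipeline(study$universe$loci, qc, maf)$panel
  all_loci <- study$universe$loci$locus_id
  ev_panel <- evaluate_panel(panel, calls, qc, maf, pop$samples)
  ev_all <- evaluate_panel(all_loci, calls, qc, maf, pop$samples)
  rep <- comparative_report(ev_panel, ev_all, names = c("curated", "universe"))
  expect_equal(nrow(rep), 2)
  # a curated panel beats the universe it came from
  expect_gte(rep["curated", "average_maf"], rep["universe", "average_maf"])
  expect_gte(rep["curated", "marker_success_rate"],
             rep["universe", "marker_success_rate"])
  # a panel against itself yields identical columns
  self <- comparative_report(ev_panel, ev_panel)
  expect_equal(unname(unlist(self[1, ])), unname(unlist(self[2, ])))
  # mismatched sample sets are rejected
  ev_sub <- evaluate_panel(panel, calls$calls[1:10, ], qc, maf, pop$samples)
  expect_error(comparative_report(ev_panel, ev_sub), "different sample sets")
})
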