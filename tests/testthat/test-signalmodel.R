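test_that("theta hits its endpoints and midpoint exactly", {
  expect_equal(to_theta_r(1, 0)$theta, 0)
  expect_equal(to_theta_r(0, 1)$theta, 1)
  for (c in c(0.01, 1, 7, 1e4)) {
    expect_equal(to_theta_r(c, c)$theta, 0.5)
  }
  expect_equal(to_theta_r(3, 4)$r, 7)
  expect_equal(to_theta_r(3, 4, r_metric = "euclidean")$r, 5)
})

test_that("theta is monotone in y/x and bounded in [0, 1]", {
  set.seed(31)
  for (i in 1:50) {
    x <- runif(1, 0.1, 5)
    ys <- sort(runif(5, 0, 5))
    th <- to_theta_r(rep(x, 5), ys)$theta
    expect_true(all(diff(th) > 0))
    expect_true(all(th >= 0 & th <= 1))
  }
})

test_that("the origin point is rejected unless explicitly allowed", {
  expect_error(to_theta_r(0, 0), "undefined")
  out <- to_theta_r(c(0, 1), c(0, 1), allow_undefined = TRUE)
  expect_true(is.na(out$theta[1]))
  expect_equal(out$theta[2], 0.5)
  expect_error(to_theta_r(-1, 1), "nonnegative")
})

test_that("cluster building recovers three tight blobs", {
  set.seed(33)
  blob_means <- c(0.05, 0.50, 0.95)
  thetas <- c(rnorm(30, blob_means[1], 0.01), rnorm(30, blob_means[2], 0.01),
              rnorm(30, blob_means[3], 0.01))
  thetas <- pmin(pmax(thetas, 0), 1)
  ints <- locus_points(thetas)
  cf <- build_cluster_file(ints)
  expect_equal(nrow(cf$regions), 3)
  expect_true(all(cf$regions$occupied))
  truth_means <- c(mean(thetas[1:30]), mean(thetas[31:60]), mean(thetas[61:90]))
  expect_true(all(abs(cf$regions$theta_center - truth_means) < 0.02))
  # zero-noise limit: centers exactly at the blob thetas
  exact <- locus_points(rep(blob_means, each = 10))
  cfe <- build_cluster_file(exact)
  expect_equal(cfe$regions$theta_center, blob_means, tolerance = 1e-12)
})

test_that("a monomorphic locus keeps default unoccupied regions at 0.5/0.95", {
  ints <- locus_points(rep(0.05, 20))
  cf <- build_cluster_file(ints)
  expect_equal(cf$regions$occupied, c(TRUE, FALSE, FALSE))
  expect_equal(cf$regions$theta_center[2:3], c(0.5, 0.95))
  expect_false(cf$loci$weak)
})

test_that("call regions are pairwise disjoint and ordered AA < AB < BB", {
  study <- clean_study(40, seed = 35)
  cf <- build_cluster_file(study$intensities)
  for (id in cf$loci$locus_id[1:10]) {
    r <- cf$regions[cf$regions$locus_id == id, ]
    expect_equal(r$genotype, c("AA", "AB", "BB"))
    expect_true(all(diff(r$theta_center) > 0))
    expect_lte(r$theta_high[1], r$theta_low[2] + 1e-12)
    expect_lte(r$theta_high[2], r$theta_low[3] + 1e-12)
  }
})

test_that("a locus with every point under the floor is marked weak", {
  ints <- locus_points(rep(c(0.05, 0.5), 10), r = 0.01)
  cf <- build_cluster_file(ints)
  expect_true(cf$loci$weak)
  expect_true(all(!cf$regions$occupied))
})

test_that("calling maps points to regions with sensible confidence", {
  ints <- locus_points(rep(0.05, 10))
  cf <- build_cluster_file(ints)
  ctr <- cf$regions$theta_center[1]
  probe <- rbind(locus_points(ctr, sample_ids = "center"),
                 locus_points(0.5, r = 0.01, sample_ids = "dim"))
  out <- call_genotypes(probe, cf)
  expect_equal(unname(out$calls["center", ]), "AA")
  expect_equal(unname(out$confidence["center", ]), 1)
  expect_equal(unname(out$calls["dim", ]), "NC")
  expect_equal(unname(out$confidence["dim", ]), 0)
})

test_that("calling a locus absent from the cluster file is an explicit error", {
  ints <- locus_points(rep(0.05, 10))
  cf <- build_cluster_file(ints)
  probe <- locus_points(0.05, locus_id = "L999")
  expect_error(call_genotypes(probe, cf), "L999")
})

test_that("calls match the nearest-center brute-force oracle on clean loci", {
  study <- clean_study(50, seed = 37)
  cf <- build_cluster_file(study$intensities)
  out <- call_genotypes(study$intensities, cf)
  tr <- to_theta_r(study$intensities$x, study$intensities$y)
  ids <- cf$loci$locus_id
  agree <- 0; total <- 0
  for (li in seq_along(ids)) {
    sel <- study$intensities$locus_id == ids[li]
    reg <- cf$regions[cf$regions$locus_id == ids[li], ]
    th <- tr$theta[sel]; r <- tr$r[sel]
    # oracle: nearest occupied center, subject to the signal floor
    oracle <- vapply(seq_along(th), function(i) {
      if (is.na(th[i]) || r[i] < cf$loci$r_floor[li]) return("NC")
      reg$genotype[which.min(abs(th[i] - reg$theta_center))]
    }, character(1))
    called <- out$calls[cbind(study$intensities$sample_id[sel],
                              ids[li])]
    cmp <- called != "NC"  # interval misses are the caller's prerogative
    agree <- agree + sum(called[cmp] == oracle[cmp])
    total <- total + sum(cmp)
  }
  expect_equal(agree, total)
})

test_that("calling is deterministic and permutation-equivariant", {
  study <- clean_study(30, seed = 39)
  cf <- build_cluster_file(study$intensities)
  a <- call_genotypes(study$intensities, cf)
  b <- call_genotypes(study$intensities, cf)
  expect_identical(a, b)
  perm <- study$intensities[order(rev(seq_len(nrow(study$intensities)))), ]
  c2 <- call_genotypes(perm, cf)
  expect_identical(a$calls[rownames(a$calls), colnames(a$calls)],
                   c2$calls[rownames(a$calls), colnames(a$calls)])
})

test_that("clean loci call at >= 99 % accuracy with < 1 % missing", {
  study <- clean_study(300, seed = 41)
  cf <- build_cluster_file(study$intensities)
  out <- call_genotypes(study$intensities, cf)
  truth <- study$population$truth$genotypes
  truth <- truth[rownames(out$calls), colnames(out$calls)]
  expect_gt(mean(out$calls == truth), 0.99)
  expect_lt(mean(out$calls == "NC"), 0.01)
})

test_that("a curated cluster file never raises the missing rate over default regions", {
  study <- clean_study(200, seed = 43, profile = noise_profile(theta_sd = 0.025))
  curated <- build_cluster_file(study$intensities)
  default <- default_cluster_file(curated$loci$locus_id,
                                  r_floor = curated$loci$r_floor)
  miss_curated <- mean(call_genotypes(study$intensities, curated)$calls == "NC")
  miss_default <- mean(call_genotypes(study$intensities, default)$calls == "NC")
  expect_lte(miss_curated, miss_default)
})
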