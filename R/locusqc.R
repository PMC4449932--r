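# Per-locus genotyping quality: a composite clustering-quality score built
# from the four canonical cluster characteristics (angle, dispersion,
# overlap, intensity), defect-class detection, and duplicate reproducibility.

#' Locus-QC configuration
#'
#' @param dispersion_cap Mean within-cluster theta SD at which the dispersion
#'   subscore reaches 0 (default 0.1).
#' @param shifted_tol Max tolerated deviation of an occupied cluster center
#'   from its canonical position before the locus is flagged shifted.
#' @param high_missing_rate Missing-data rate above which (strictly) a locus
#'   is flagged high-missing (default 0.05, i.e. more than 5 %; more than 5
#'   failed samples on a 96-sample panel).
#' @param max_bad_triplets Flag pedigree failure when strictly more than this
#'   many triplets are Mendelian-inconsistent (default 3).
#' @param max_het_inbreds Flag het-inbred when strictly more than this many
#'   inbred samples are called AB (default 5).
#' @param canonical_centers Canonical AA/AB/BB theta positions.
#' @param gap_norm Adjacent-center gap treated as full separation (default
#'   0.45, the canonical AA-AB spacing).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(dispersion_cap = 0.1, shifted_tol = 0.15,
                      high_missing_rate = 0.05, max_bad_triplets = 3,
                      max_het_inbreds = 5,
                      canonical_centers = c(AA = 0.05, AB = 0.50, BB = 0.95),
                      gap_norm = 0.45) {
  stopifnot(dispersion_cap > 0, shifted_tol >= 0, max_bad_triplets >= 0,
            max_het_inbreds >= 0, gap_norm > 0)
  check_scalar_prob(high_missing_rate, "high_missing_rate")
  if (max_bad_triplets != round(max_bad_triplets) ||
      max_het_inbreds != round(max_het_inbreds)) {
    stop("count thresholds must be nonnegative integers", call. = FALSE)
  }
  structure(list(dispersion_cap = dispersion_cap, shifted_tol = shifted_tol,
                 high_missing_rate = high_missing_rate,
                 max_bad_triplets = max_bad_triplets,
                 max_het_inbreds = max_het_inbreds,
                 canonical_centers = canonical_centers[GENOTYPES],
                 gap_norm = gap_norm),
            class = "qc_config")
}

#' Mendelian consistency of an F1 call given two parent calls
#'
#' Vectorized over loci. The expected F1 set is every unordered combination of
#' one allele from each parent: AA x AA -> {AA}; AA x BB -> {AB};
#' AA x AB -> {AA, AB}; AB x AB -> {AA, AB, BB}. Returns `NA` where any of the
#' three calls is NC.
#'
#' @param p1,p2,f1 Character vectors of calls in AA/AB/BB/NC.
#' @return Logical vector: is the F1 call Mendelian-consistent?
#' @export
mendel_consistent <- function(p1, p2, f1) {
  ok <- p1 %in% GENOTYPES & p2 %in% GENOTYPES & f1 %in% GENOTYPES
  x1 <- substr(p1, 1, 1); x2 <- substr(p1, 2, 2)
  y1 <- substr(p2, 1, 1); y2 <- substr(p2, 2, 2)
  comb <- function(a, b) {
    ifelse(a <= b, paste0(a, b), paste0(b, a))
  }
  res <- f1 == comb(x1, y1) | f1 == comb(x1, y2) |
    f1 == comb(x2, y1) | f1 == comb(x2, y2)
  res[!ok] <- NA
  res
}

#' Expected F1 genotypes of a parent pair
#'
#' @param g1,g2 Single parental genotypes in AA/AB/BB.
#' @return Character vector of possible F1 genotypes (sorted, unique).
#' @export
expected_f1_genotypes <- function(g1, g2) {
  stopifnot(g1 %in% GENOTYPES, g2 %in% GENOTYPES)
  a <- c(substr(g1, 1, 1), substr(g1, 2, 2))
  b <- c(substr(g2, 1, 1), substr(g2, 2, 2))
  combos <- outer(a, b, function(p, q) {
    ifelse(p <= q, paste0(p, q), paste0(q, p))
  })
  sort(unique(as.vector(combos)))
}

# per-locus count of Mendelian-inconsistent triplets (NC-containing excluded)
count_inconsistent_triplets <- function(calls, triplets) {
  n_loci <- ncol(calls)
  out <- integer(n_loci)
  if (is.null(triplets) || nrow(triplets) == 0) return(out)
  for (t in seq_len(nrow(triplets))) {
    p1 <- calls[triplets$parent1[t], ]
    p2 <- calls[triplets$parent2[t], ]
    f1 <- calls[triplets$f1[t], ]
    cons <- mendel_consistent(p1, p2, f1)
    out <- out + as.integer(!is.na(cons) & !cons)
  }
  out
}

#' Per-locus duplicate reproducibility
#'
#' Fraction of duplicate pairs with identical non-NC calls at each locus;
#' pairs where either call is NC are excluded from the denominator. A locus
#' with no informative pair gets `NA` (undefined, not penalized).
#'
#' @param calls Samples x loci call matrix.
#' @param duplicate_pairs Data frame with columns `sample_a`, `sample_b`.
#' @return Named numeric vector (one entry per locus) in `[0, 1]` or `NA`.
#' @export
reproducibility <- function(calls, duplicate_pairs) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  if (is.null(duplicate_pairs) || nrow(duplicate_pairs) == 0) {
    stop("at least one duplicate pair is required", call. = FALSE)
  }
  n_inf <- n_agree <- numeric(ncol(calls))
  for (i in seq_len(nrow(duplicate_pairs))) {
    a <- calls[duplicate_pairs$sample_a[i], ]
    b <- calls[duplicate_pairs$sample_b[i], ]
    inf <- a != NO_CALL & b != NO_CALL
    n_inf <- n_inf + inf
    n_agree <- n_agree + (inf & a == b)
  }
  out <- ifelse(n_inf > 0, n_agree / n_inf, NA_real_)
  names(out) <- colnames(calls)
  out
}

#' Detect per-locus defect classes
#'
#' Applies the five defect rules to per-locus summary statistics, all with
#' strict ("more than") inequalities: `weak_signal` when the median total
#' signal falls below the signal floor; `high_missing` when the failed-sample
#' count exceeds `ceiling(n_samples * high_missing_rate)` (more than 5 failed
#' samples of 96 at the default 5 % rate); `pedigree_fail` when more than `max_bad_triplets`
#' parent/F1 triplets are Mendelian-inconsistent; `het_inbred` when more than
#' `max_het_inbreds` inbred samples are called heterozygous; `shifted` when
#' any occupied cluster center deviates more than `shifted_tol` in theta from
#' its canonical position.
#'
#' @param stats Data frame with columns `median_r`, `r_floor`, `missing_count`,
#'   `n_samples`, `inconsistent_triplet_count`, `het_inbred_count`,
#'   `max_center_shift`.
#' @param config A [qc_config()].
#' @return Character vector of semicolon-joined flags ("" when clean).
#' @export
detect_defects <- function(stats, config = qc_config()) {
  need <- c("median_r", "r_floor", "missing_count", "n_samples",
            "inconsistent_triplet_count", "het_inbred_count",
            "max_center_shift")
  stopifnot(all(need %in% names(stats)))
  miss_max <- ceiling(stats$n_samples * config$high_missing_rate - 1e-9)
  flag <- function(cond, name) ifelse(!is.na(cond) & cond, name, "")
  f <- cbind(
    flag(stats$median_r < stats$r_floor, "weak_signal"),
    flag(stats$missing_count > miss_max, "high_missing"),
    flag(stats$inconsistent_triplet_count > config$max_bad_triplets, "pedigree_fail"),
    flag(stats$het_inbred_count > config$max_het_inbreds, "het_inbred"),
    flag(stats$max_center_shift > config$shifted_tol, "shifted")
  )
  apply(f, 1, function(z) paste(z[z != ""], collapse = ";"))
}

#' Score every locus of a called panel
#'
#' Computes the clustering-quality composite (geometric mean of the angle-
#' separation, dispersion, overlap, and intensity subscores, each in
#' `[0, 1]`), missing statistics, het-inbred and inconsistent-triplet counts,
#' duplicate reproducibility, and defect flags for every locus.
#'
#' Subscores: angle separation is the minimum gap between adjacent occupied
#' region centers normalized by the canonical spacing; dispersion is
#' `1 - mean within-cluster theta SD / cap`; overlap is one minus the
#' fraction of points that also fall inside another occupied region's
#' untruncated interval; intensity is the fraction of points above the signal
#' floor. A locus whose every point fails the floor scores 0 and is flagged
#' `weak_signal`.
#'
#' @param intensities Long-format intensity data frame.
#' @param calls A `genotype_calls` object (or bare call matrix).
#' @param cluster_file The `cluster_file` used for calling.
#' @param sample_meta Sample metadata with `sample_id` and `role`.
#' @param triplets Optional triplet table (`parent1`, `parent2`, `f1`).
#' @param duplicate_pairs Optional duplicate-pair table.
#' @param config A [qc_config()].
#' @return Data frame, one row per locus: subscores, composite
#'   `quality_score`, counts, `reproducibility`, semicolon-joined `flags`.
#' @export
score_loci <- function(intensities, calls, cluster_file, sample_meta,
                       triplets = NULL, duplicate_pairs = NULL,
                       config = qc_config()) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  stopifnot(inherits(cluster_file, "cluster_file"))
  locus_ids <- cluster_file$loci$locus_id
  stopifnot(identical(sort(colnames(calls)), sort(locus_ids)))
  calls <- calls[, locus_ids, drop = FALSE]
  n_loci <- length(locus_ids)
  n_samples <- nrow(calls)

  cfg <- cluster_file$config
  tr <- to_theta_r(intensities$x, intensities$y,
                   r_metric = if (is.null(cfg$r_metric)) "manhattan" else cfg$r_metric,
                   allow_undefined = TRUE)
  li <- match(intensities$locus_id, locus_ids)
  floor_r <- cluster_file$loci$r_floor

  med_r <- rep(0, n_loci)
  ok <- !is.na(tr$theta)
  mr <- tapply(tr$r[ok], li[ok], stats::median)
  med_r[as.integer(names(mr))] <- mr

  n_pts <- tabulate(li, nbins = n_loci)
  above <- ok & tr$r >= floor_r[li]
  n_above <- tabulate(li[above], nbins = n_loci)
  intensity <- ifelse(n_pts > 0, n_above / n_pts, 0)

  reg <- cluster_file$regions
  ctr <- matrix(reg$theta_center, n_loci, 3, byrow = TRUE)
  hw <- matrix(reg$theta_halfwidth, n_loci, 3, byrow = TRUE)
  occ <- matrix(reg$occupied, n_loci, 3, byrow = TRUE)

  ## angle separation over occupied centers
  gap12 <- ctr[, 2] - ctr[, 1]
  gap23 <- ctr[, 3] - ctr[, 2]
  gap13 <- ctr[, 3] - ctr[, 1]
  angle <- rep(1, n_loci)
  all3 <- occ[, 1] & occ[, 2] & occ[, 3]
  angle[all3] <- pmin(gap12[all3], gap23[all3]) / config$gap_norm
  two <- !all3 & rowSums(occ) == 2
  g2 <- ifelse(occ[, 1] & occ[, 2], gap12,
               ifelse(occ[, 2] & occ[, 3], gap23, gap13))
  angle[two] <- g2[two] / config$gap_norm
  angle <- pmin(pmax(angle, 0), 1)

  ## per-point nearest-center assignment among above-floor points
  theta_a <- tr$theta[above]
  la <- li[above]
  d <- cbind(abs(theta_a - ctr[la, 1]), abs(theta_a - ctr[la, 2]),
             abs(theta_a - ctr[la, 3]))
  assign <- max.col(-d, ties.method = "first")

  ## dispersion: mean within-cluster SD over occupied clusters
  key <- (la - 1L) * 3L + assign
  cnt <- rowsum(rep(1, length(theta_a)), key)
  mu <- rowsum(theta_a, key) / cnt
  sq <- rowsum(theta_a^2, key)
  v <- (sq - cnt * mu^2) / pmax(cnt - 1, 1)
  v[cnt < 2] <- 0
  sdm <- matrix(NA_real_, n_loci, 3)
  idx <- as.integer(rownames(cnt))
  sdm[cbind((idx - 1L) %/% 3L + 1L, (idx - 1L) %% 3L + 1L)] <- sqrt(pmax(v, 0))
  use <- occ & !is.na(sdm)
  mean_sd <- rowSums(ifelse(use, sdm, 0)) / pmax(rowSums(use), 1)
  dispersion <- pmin(pmax(1 - mean_sd / config$dispersion_cap, 0), 1)

  ## overlap: points inside another occupied region's untruncated interval
  in_other <- rep(FALSE, length(theta_a))
  for (k in 1:3) {
    other <- assign != k & occ[cbind(la, rep(k, length(la)))]
    in_other <- in_other |
      (other & abs(theta_a - ctr[cbind(la, rep(k, length(la)))]) <=
         hw[cbind(la, rep(k, length(la)))])
  }
  n_overlap <- tabulate(la[in_other], nbins = n_loci)
  overlap <- ifelse(n_above > 0, 1 - n_overlap / n_above, 1)

  composite <- pmin(pmax((pmax(angle, 0) * dispersion * overlap * intensity)^(1 / 4),
                         0), 1)
  composite[n_above == 0] <- 0

  missing_count <- colSums(calls == NO_CALL)
  missing_rate <- missing_count / n_samples
  inbreds <- sample_meta$sample_id[sample_meta$role == "inbred"]
  inbreds <- intersect(inbreds, rownames(calls))
  het_inbred_count <- if (length(inbreds)) {
    colSums(calls[inbreds, , drop = FALSE] == "AB")
  } else rep(0L, n_loci)
  bad_trip <- count_inconsistent_triplets(calls, triplets)

  shift_dev <- abs(ctr - matrix(rep(config$canonical_centers, each = n_loci),
                                n_loci, 3))
  shift_dev[!occ] <- 0
  max_shift <- apply(shift_dev, 1, max)

  repro <- rep(NA_real_, n_loci)
  if (!is.null(duplicate_pairs) && nrow(duplicate_pairs) > 0) {
    repro <- unname(reproducibility(calls, duplicate_pairs))
  }

  stats_df <- data.frame(
    locus_id = locus_ids, median_r = med_r, r_floor = floor_r,
    missing_count = as.integer(missing_count), n_samples = n_samples,
    inconsistent_triplet_count = bad_trip,
    het_inbred_count = as.integer(het_inbred_count),
    max_center_shift = max_shift, stringsAsFactors = FALSE
  )
  flags <- detect_defects(stats_df, config)

  data.frame(
    locus_id = locus_ids, quality_score = composite,
    angle_separation = angle, dispersion = dispersion, overlap = overlap,
    intensity = intensity,
    missing_count = as.integer(missing_count), missing_rate = missing_rate,
    n_samples = n_samples,
    het_inbred_count = as.integer(het_inbred_count),
    inconsistent_triplet_count = bad_trip,
    reproducibility = repro, median_r = med_r, r_floor = floor_r,
    max_center_shift = max_shift, flags = flags,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
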