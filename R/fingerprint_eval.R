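# Panel evaluation statistics: MAF spectra, parent/F1 pedigree consistency,
# pairwise differential-locus distributions, genetic similarity, cross-
# platform concordance, genomic distribution, and comparative summaries.

#' Per-locus minor allele frequency
#'
#' Allele counting over called genotypes: AA contributes two A alleles, BB
#' two B, AB one of each; NC contributes nothing. MAF is the frequency of the
#' rarer allele, hence in `[0, 0.5]` and invariant under allele relabeling.
#' Polymorphism is conventionally assessed on the inbred-line subset.
#'
#' @param calls Samples x loci call matrix (or `genotype_calls`).
#' @param sample_subset Optional character vector of sample ids (e.g. the
#'   inbreds); default all samples.
#' @return Data frame `locus_id`, `n_a`, `n_b` (allele counts), `n_informative`
#'   (samples contributing), `maf` (`NA` where no sample was called).
#' @export
compute_maf <- function(calls, sample_subset = NULL) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, rownames(calls))
    if (length(missing_s)) {
      stop("samples not in matrix: ", paste(missing_s, collapse = ", "),
           call. = FALSE)
    }
    calls <- calls[sample_subset, , drop = FALSE]
    if (!nrow(calls)) stop("`sample_subset` is empty", call. = FALSE)
  }
  n_a <- colSums(calls == "AA") * 2 + colSums(calls == "AB")
  n_b <- colSums(calls == "BB") * 2 + colSums(calls == "AB")
  n_inf <- colSums(calls != NO_CALL)
  tot <- n_a + n_b
  maf <- ifelse(tot > 0, pmin(n_a, n_b) / tot, NA_real_)
  data.frame(locus_id = colnames(calls), n_a = as.integer(n_a),
             n_b = as.integer(n_b), n_informative = as.integer(n_inf),
             maf = maf, stringsAsFactors = FALSE, row.names = NULL)
}

#' Parent/F1 pedigree consistency for one triplet
#'
#' Scores every locus called (non-NC) in the hybrid and both parents: the F1
#' call is consistent when it lies in the Mendelian expectation set of the
#' two parental calls (see [mendel_consistent()]). Consistency is the
#' fraction of scorable loci that are consistent.
#'
#' @param calls Samples x loci call matrix (or `genotype_calls`).
#' @param triplet Character vector or one-row data frame naming `parent1`,
#'   `parent2`, `f1`.
#' @return List of class `triplet_result`: ids, `n_scorable`, `n_consistent`,
#'   `consistency`, and per-locus `verdicts` (logical, `NA` where unscorable).
#' @export
pedigree_consistency <- function(calls, triplet) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  if (is.data.frame(triplet)) {
    triplet <- c(parent1 = triplet$parent1[1], parent2 = triplet$parent2[1],
                 f1 = triplet$f1[1])
  }
  stopifnot(all(c("parent1", "parent2", "f1") %in% names(triplet)))
  absent <- setdiff(unname(triplet[c("parent1", "parent2", "f1")]),
                    rownames(calls))
  if (length(absent)) {
    stop("triplet sample(s) missing from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  verdict <- mendel_consistent(calls[triplet[["parent1"]], ],
                               calls[triplet[["parent2"]], ],
                               calls[triplet[["f1"]], ])
  n_scor <- sum(!is.na(verdict))
  n_cons <- sum(verdict, na.rm = TRUE)
  structure(list(parent1 = triplet[["parent1"]], parent2 = triplet[["parent2"]],
                 f1 = triplet[["f1"]], n_scorable = n_scor,
                 n_consistent = n_cons,
                 consistency = if (n_scor > 0) n_cons / n_scor else NA_real_,
                 verdicts = verdict),
            class = "triplet_result")
}

#' Pedigree consistency for a table of triplets
#'
#' @param calls Samples x loci call matrix (or `genotype_calls`).
#' @param triplets Data frame with columns `parent1`, `parent2`, `f1` (and
#'   optionally `triplet_id`).
#' @return Data frame, one row per triplet, with `n_scorable`,
#'   `n_consistent`, `consistency`.
#' @export
pedigree_consistency_all <- function(calls, triplets) {
  rows <- lapply(seq_len(nrow(triplets)), function(i) {
    r <- pedigree_consistency(calls, triplets[i, ])
    data.frame(triplet_id = if ("triplet_id" %in% names(triplets))
                 triplets$triplet_id[i] else sprintf("T%02d", i),
               parent1 = r$parent1, parent2 = r$parent2, f1 = r$f1,
               n_scorable = r$n_scorable, n_consistent = r$n_consistent,
               consistency = r$consistency, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

call_codes <- function(calls) {
  m <- matrix(match(calls, GENOTYPES, nomatch = 0L), nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  m
}

#' Pairwise differential-locus comparisons
#'
#' All `n * (n - 1) / 2` unordered sample pairs. For each pair, loci with an
#' NC in either sample are excluded; any call mismatch among the co-called
#' loci (including homozygous vs heterozygous) counts as a difference. The
#' differential rate is differing / co-called (`NA` when no locus is
#' co-called). A binned histogram of the defined rates is attached.
#'
#' @param calls Samples x loci call matrix (or `genotype_calls`).
#' @param sample_set Optional sample ids to compare (default all, >= 2).
#' @param bin_width Histogram bin width on `[0, 1]` (default 0.05).
#' @return List of class `pairwise_result`: `pairs` (data frame `sample_a`,
#'   `sample_b`, `n_cocalled`, `n_diff`, `differential_rate`) and `histogram`
#'   (`bin_low`, `bin_high`, `count`; counts sum to the defined pairs).
#' @export
pairwise_differences <- function(calls, sample_set = NULL, bin_width = 0.05) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  if (!is.null(sample_set)) {
    calls <- calls[sample_set, , drop = FALSE]
  }
  n <- nrow(calls)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  codes <- call_codes(calls)           # samples x loci, 0 = NC
  inf <- t(codes != 0L) * 1            # loci x samples
  co <- crossprod(inf)                 # co-called counts per pair
  eq <- matrix(0, n, n)
  for (g in 1:3) {
    ig <- t(codes == g) * 1
    eq <- eq + crossprod(ig)
  }
  diffm <- co - eq
  iu <- which(upper.tri(co), arr.ind = TRUE)
  nc <- co[iu]
  nd <- diffm[iu]
  rate <- ifelse(nc > 0, nd / nc, NA_real_)
  pairs <- data.frame(sample_a = rownames(calls)[iu[, 1]],
                      sample_b = rownames(calls)[iu[, 2]],
                      n_cocalled = as.integer(nc), n_diff = as.integer(nd),
                      differential_rate = rate, stringsAsFactors = FALSE)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  n_bins <- length(breaks) - 1
  defined <- rate[!is.na(rate)]
  # bins are [low, high); a rate of exactly 1 lands in the last bin
  bin <- pmin(findInterval(defined, breaks), n_bins)
  histogram <- data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1],
                          count = tabulate(bin, nbins = n_bins))
  structure(list(pairs = pairs, histogram = histogram),
            class = "pairwise_result")
}

#' Genetic similarity of a sample pair
#'
#' Defined as the complement of the pairwise differential-locus rate over
#' co-called loci.
#'
#' @param calls Samples x loci call matrix (or `genotype_calls`).
#' @param sample_pair Character vector of two sample ids.
#' @return Similarity in `[0, 1]`.
#' @export
genetic_similarity <- function(calls, sample_pair) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  stopifnot(length(sample_pair) == 2)
  a <- calls[sample_pair[1], ]
  b <- calls[sample_pair[2], ]
  co <- a != NO_CALL & b != NO_CALL
  if (!any(co)) {
    stop("pair has no co-called locus; similarity undefined", call. = FALSE)
  }
  1 - sum(a[co] != b[co]) / sum(co)
}

#' Cross-platform genotype concordance
#'
#' Fraction of shared (sample, locus) entries, called on both platforms, with
#' identical genotypes (complete-case: entries with NC on either platform are
#' excluded from the denominator).
#'
#' @param matrix_a,matrix_b Call matrices sharing samples and loci.
#' @return List: `concordance` (overall), `n_compared`, and `per_locus`
#'   (data frame `locus_id`, `n_compared`, `concordance`).
#' @export
platform_concordance <- function(matrix_a, matrix_b) {
  if (inherits(matrix_a, "genotype_calls")) matrix_a <- matrix_a$calls
  if (inherits(matrix_b, "genotype_calls")) matrix_b <- matrix_b$calls
  assert_call_matrix(matrix_a, "matrix_a")
  assert_call_matrix(matrix_b, "matrix_b")
  s <- intersect(rownames(matrix_a), rownames(matrix_b))
  l <- intersect(colnames(matrix_a), colnames(matrix_b))
  if (!length(s) || !length(l)) {
    stop("matrices share no (sample, locus) entries", call. = FALSE)
  }
  a <- matrix_a[s, l, drop = FALSE]
  b <- matrix_b[s, l, drop = FALSE]
  both <- a != NO_CALL & b != NO_CALL
  same <- both & a == b
  n_cmp <- colSums(both)
  per_locus <- data.frame(locus_id = l, n_compared = as.integer(n_cmp),
                          concordance = ifelse(n_cmp > 0,
                                               colSums(same) / n_cmp, NA_real_),
                          stringsAsFactors = FALSE)
  list(concordance = sum(same) / sum(both), n_compared = sum(both),
       per_locus = per_locus)
}

#' Genomic distribution of a panel
#'
#' Divides each chromosome into fixed-size windows (half-open on 1-based
#' positions: window k covers `[(k-1)*w + 1, k*w]`), counts panel loci per
#' window, and summarizes genic-category proportions.
#'
#' @param panel Character vector of panel locus ids.
#' @param locus_map Locus map data frame (`locus_id`, `chromosome`,
#'   `position`, `genic_category`).
#' @param window_size Window size in bp (default 1,000,000).
#' @return List: `windows` (data frame `chromosome`, `window`, `count`; counts
#'   sum to the panel size) and `category_proportions` (named, sums to 1).
#' @export
genomic_distribution <- function(panel, locus_map, window_size = 1e6) {
  unmapped <- setdiff(panel, locus_map$locus_id)
  if (length(unmapped)) {
    stop("unmapped loci: ", paste(utils::head(unmapped, 10), collapse = ", "),
         if (length(unmapped) > 10) sprintf(" (and %d more)", length(unmapped) - 10),
         call. = FALSE)
  }
  m <- locus_map[match(panel, locus_map$locus_id), , drop = FALSE]
  win <- (m$position - 1) %/% window_size + 1
  tab <- stats::aggregate(list(count = rep(1L, nrow(m))),
                          by = list(chromosome = m$chromosome, window = win),
                          FUN = sum)
  tab <- tab[order(tab$chromosome, tab$window), , drop = FALSE]
  rownames(tab) <- NULL
  cat_tab <- table(factor(m$genic_category, levels = GENIC_CATEGORIES))
  props <- as.numeric(cat_tab) / nrow(m)
  names(props) <- GENIC_CATEGORIES
  list(windows = tab, category_proportions = props)
}

#' Evaluate a panel on a called sample set
#'
#' Produces the comparative-table metrics for one panel: marker success rate
#' (fraction of panel loci passing the quality and data-quality gates),
#' average MAF over defined loci, fraction of loci with quality score
#' strictly above 0.6 and above 0.7, and the variety-distinguishing
#' efficiency (mean pairwise differential-locus rate) among inbreds and among
#' hybrids.
#'
#' @param panel Character vector of panel locus ids.
#' @param calls Samples x loci call matrix covering the panel.
#' @param qualities QC data frame from [score_loci()].
#' @param maf_table MAF table from [compute_maf()].
#' @param sample_meta Sample metadata with `sample_id` and `role`.
#' @param config A [selection_config()] (for the success-rate gates).
#' @return One-row data frame of class `panel_evaluation`.
#' @export
evaluate_panel <- function(panel, calls, qualities, maf_table, sample_meta,
                           config = selection_config()) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  q <- qualities[match(panel, qualities$locus_id), , drop = FALSE]
  maf <- maf_table$maf[match(panel, maf_table$locus_id)]
  pass <- q$quality_score >= config$quality_min & missing_ok(q, config) &
    q$flags == "" &
    (is.na(q$reproducibility) | q$reproducibility == 1)
  inb <- intersect(sample_meta$sample_id[sample_meta$role == "inbred"],
                   rownames(calls))
  hyb <- intersect(sample_meta$sample_id[sample_meta$role == "hybrid"],
                   rownames(calls))
  sub <- calls[, intersect(panel, colnames(calls)), drop = FALSE]
  mean_rate <- function(ids) {
    if (length(ids) < 2) return(NA_real_)
    pw <- pairwise_differences(sub, sample_set = ids)
    mean(pw$pairs$differential_rate, na.rm = TRUE)
  }
  out <- data.frame(
    n_loci = length(panel),
    marker_success_rate = mean(pass, na.rm = TRUE),
    average_maf = mean(maf, na.rm = TRUE),
    frac_quality_gt_0.6 = mean(q$quality_score > 0.6, na.rm = TRUE),
    frac_quality_gt_0.7 = mean(q$quality_score > 0.7, na.rm = TRUE),
    diff_rate_inbred = mean_rate(inb),
    diff_rate_hybrid = mean_rate(hyb),
    stringsAsFactors = FALSE
  )
  attr(out, "sample_ids") <- sort(rownames(calls))
  class(out) <- c("panel_evaluation", class(out))
  out
}

#' Comparative report of two panels
#'
#' Side-by-side metrics of two panels evaluated on the same sample set.
#'
#' @param panel_a_results,panel_b_results Results from [evaluate_panel()].
#' @param names Row labels (default "panel_a", "panel_b").
#' @return Two-row data frame.
#' @export
comparative_report <- function(panel_a_results, panel_b_results,
                               names = c("panel_a", "panel_b")) {
  sa <- attr(panel_a_results, "sample_ids")
  sb <- attr(panel_b_results, "sample_ids")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("panels were evaluated on different sample sets", call. = FALSE)
  }
  out <- rbind(as.data.frame(panel_a_results), as.data.frame(panel_b_results))
  rownames(out) <- names
  out
}
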