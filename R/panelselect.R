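# Staged marker selection: quality gate -> data-quality/defect gate ->
# copy-number/MAF/genic-region gate -> designability gate and evenness-
# preserving trim to the target panel size.

#' Selection configuration
#'
#' Boundary semantics follow the screening procedure's wording exactly:
#' quality "between 0.70 and 1.00" is inclusive at 0.70; missing "more than
#' 5 %" is strict (more than 5 failed samples of 96); copy number "greater
#' than or equal to 2" is inclusive; MAF "under 0.2" is strict (0.20 itself
#' kept); designability "below 0.4" is strict (0.40 itself eligible).
#'
#' @param quality_min Minimum composite quality score (default 0.70,
#'   inclusive).
#' @param missing_rate_max Maximum missing-data rate (default 0.05; applied
#'   as a count threshold `missing_count <= ceiling(n_samples * rate)`).
#' @param maf_min Minimum minor allele frequency (default 0.20, inclusive).
#' @param copy_number_max_exclusive Loci with copy number at or above this are
#'   dropped (default 2).
#' @param designability_delete_below Designability scores strictly below this
#'   are dropped (default 0.40).
#' @param designability_good Scores above this rank first during the trim
#'   (default 0.60).
#' @param target_panel_size Final panel size cap (default 3072).
#' @param window_size Window (bp) used to preserve genomic evenness while
#'   trimming (default 1,000,000).
#' @return List of class `selection_config`.
#' @export
selection_config <- function(quality_min = 0.70, missing_rate_max = 0.05,
                             maf_min = 0.20, copy_number_max_exclusive = 2,
                             designability_delete_below = 0.40,
                             designability_good = 0.60,
                             target_panel_size = 3072,
                             window_size = 1e6) {
  stopifnot(quality_min >= 0, quality_min <= 1,
            maf_min >= 0,
            copy_number_max_exclusive >= 1,
            designability_delete_below >= 0, designability_delete_below <= 1,
            target_panel_size >= 1, window_size >= 1)
  check_scalar_prob(missing_rate_max, "missing_rate_max")
  structure(list(quality_min = quality_min,
                 missing_rate_max = missing_rate_max, maf_min = maf_min,
                 copy_number_max_exclusive = copy_number_max_exclusive,
                 designability_delete_below = designability_delete_below,
                 designability_good = designability_good,
                 target_panel_size = target_panel_size,
                 window_size = window_size),
            class = "selection_config")
}

missing_ok <- function(qc, config) {
  if (all(c("missing_count", "n_samples") %in% names(qc))) {
    qc$missing_count <= ceiling(qc$n_samples * config$missing_rate_max - 1e-9)
  } else {
    qc$missing_rate <= config$missing_rate_max
  }
}

#' Stage 1: clustering-quality gate
#'
#' Keeps loci whose composite quality score lies between `quality_min` and
#' 1.00 (boundary inclusive).
#'
#' @param qualities QC data frame from [score_loci()] (needs `locus_id`,
#'   `quality_score`).
#' @param config A [selection_config()].
#' @return Character vector of surviving locus ids.
#' @export
stage1_quality <- function(qualities, config = selection_config()) {
  qualities$locus_id[qualities$quality_score >= config$quality_min]
}

#' Stage 2: data-quality gate
#'
#' Keeps loci with acceptable missing data (see [selection_config()]), no
#' defect flags, and perfect duplicate reproducibility among informative
#' pairs (loci with no informative pair are not penalized).
#'
#' @inheritParams stage1_quality
#' @return Character vector of surviving locus ids.
#' @export
stage2_dataquality <- function(qualities, config = selection_config()) {
  ok <- missing_ok(qualities, config) &
    qualities$flags == "" &
    (is.na(qualities$reproducibility) | qualities$reproducibility == 1)
  qualities$locus_id[ok]
}

#' Stage 3: population gate (copy number, MAF, genic-region uniqueness)
#'
#' Drops loci with copy number at or above the cap, loci with MAF strictly
#' under `maf_min` (or undefined MAF), then keeps exactly one locus per genic
#' region by category priority exon > promoter > utr3 > utr5 > intron, ties
#' broken by higher quality score then lower position.
#'
#' @param loci Locus map data frame (`locus_id`, `genic_category`,
#'   `genic_region_id`, `copy_number`, `position`).
#' @param maf_table Data frame `locus_id`, `maf` (NA where undefined).
#' @param qualities QC data frame (for the tie-break quality score).
#' @param config A [selection_config()].
#' @return Character vector of surviving locus ids.
#' @export
stage3_population <- function(loci, maf_table, qualities,
                              config = selection_config()) {
  maf <- maf_table$maf[match(loci$locus_id, maf_table$locus_id)]
  qs <- qualities$quality_score[match(loci$locus_id, qualities$locus_id)]
  keep <- loci$copy_number < config$copy_number_max_exclusive &
    !is.na(maf) & maf >= config$maf_min
  cand <- loci[keep, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  prio <- match(cand$genic_category, GENIC_CATEGORIES)
  qs <- qs[keep]
  ord <- order(cand$genic_region_id, prio, -qs, cand$position,
               cand$locus_id, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  best <- !duplicated(cand$genic_region_id)
  sort(cand$locus_id[best])
}

#' Stage 4: designability gate and evenness-preserving trim
#'
#' Drops loci with designability strictly below the deletion threshold. If
#' more loci survive than the target panel size, the panel is trimmed by
#' repeatedly removing the lowest-ranked locus from the currently densest
#' 1000-kbp window, where rank prefers good designability (>= 0.60), then
#' higher quality score, then higher designability. Survivors at or below the
#' target are all kept.
#'
#' @param loci Locus map rows for the candidate loci (`locus_id`,
#'   `chromosome`, `position`, `designability`).
#' @param qualities QC data frame (for the trim ranking).
#' @param config A [selection_config()].
#' @return Character vector: the final panel locus ids.
#' @export
stage4_designability <- function(loci, qualities, config = selection_config()) {
  cand <- loci[loci$designability >= config$designability_delete_below, ,
               drop = FALSE]
  if (nrow(cand) <= config$target_panel_size) return(sort(cand$locus_id))
  qs <- qualities$quality_score[match(cand$locus_id, qualities$locus_id)]
  qs[is.na(qs)] <- 0
  # rank 1 = best kept; removal pops the worst rank within the densest window
  ord <- order(-(cand$designability >= config$designability_good), -qs,
               -cand$designability, cand$locus_id, method = "radix")
  rank <- integer(nrow(cand))
  rank[ord] <- seq_len(nrow(cand))
  win <- paste(cand$chromosome,
               (cand$position - 1) %/% config$window_size + 1, sep = ":")
  alive <- rep(TRUE, nrow(cand))
  win_count <- table(win)
  n_alive <- nrow(cand)
  while (n_alive > config$target_panel_size) {
    dense <- names(win_count)[which.max(win_count)]
    in_win <- which(alive & win == dense)
    victim <- in_win[which.max(rank[in_win])]
    alive[victim] <- FALSE
    win_count[dense] <- win_count[dense] - 1L
    n_alive <- n_alive - 1L
  }
  sort(cand$locus_id[alive])
}

#' Run the staged selection pipeline
#'
#' Executes the four stages in order on a scored, evaluated locus set and
#' reports each locus's first failing criterion. Surviving sets are strictly
#' nested across stages.
#'
#' @param loci Locus map data frame covering every scored locus.
#' @param qualities QC data frame from [score_loci()].
#' @param maf_table MAF table from [compute_maf()].
#' @param config A [selection_config()].
#' @return Object of class `panel_report`: list with `table` (per-locus
#'   stagewise pass flags and `first_failure`), `stages` (surviving id sets),
#'   `panel` (final ids), and `counts` (the selection funnel).
#' @export
run_pipeline <- function(loci, qualities, maf_table,
                         config = selection_config()) {
  stopifnot(all(qualities$locus_id %in% loci$locus_id))
  ids <- qualities$locus_id
  loci <- loci[match(ids, loci$locus_id), , drop = FALSE]

  s1 <- stage1_quality(qualities, config)
  q2 <- qualities[qualities$locus_id %in% s1, , drop = FALSE]
  s2 <- stage2_dataquality(q2, config)
  s3 <- stage3_population(loci[loci$locus_id %in% s2, , drop = FALSE],
                          maf_table, qualities, config)
  s4 <- stage4_designability(loci[loci$locus_id %in% s3, , drop = FALSE],
                             qualities, config)

  maf <- maf_table$maf[match(ids, maf_table$locus_id)]
  in1 <- ids %in% s1
  in2 <- ids %in% s2
  in3 <- ids %in% s3
  in4 <- ids %in% s4
  first_failure <- rep(NA_character_, length(ids))
  fail2 <- in1 & !in2
  miss_bad <- !missing_ok(qualities, config)
  first_failure[!in1] <- "quality"
  first_failure[fail2] <- ifelse(
    miss_bad[fail2], "missing_rate",
    ifelse(qualities$flags[fail2] != "", paste0("defect:", qualities$flags[fail2]),
           "reproducibility"))
  fail3 <- in2 & !in3
  first_failure[fail3] <- ifelse(
    loci$copy_number[fail3] >= config$copy_number_max_exclusive, "copy_number",
    ifelse(is.na(maf[fail3]) | maf[fail3] < config$maf_min, "maf",
           "genic_region"))
  fail4 <- in3 & !in4
  first_failure[fail4] <- ifelse(
    loci$designability[fail4] < config$designability_delete_below,
    "designability", "panel_trim")

  tab <- data.frame(locus_id = ids, stage1 = in1, stage2 = in2, stage3 = in3,
                    stage4 = in4, first_failure = first_failure,
                    selected = in4, stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    stages = list(stage1 = sort(s1), stage2 = sort(s2), stage3 = sort(s3),
                  stage4 = sort(s4)),
    panel = sort(s4),
    counts = c(input = length(ids), stage1 = length(s1), stage2 = length(s2),
               stage3 = length(s3), panel = length(s4)),
    config = unclass(config)
  ), class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("panel_report selection funnel:\n")
  cat(sprintf("  %-7s %6d loci\n", names(x$counts), x$counts), sep = "")
  fails <- table(x$table$first_failure[!x$table$selected])
  if (length(fails)) {
    cat("first-failure breakdown:\n")
    for (nm in names(sort(fails, decreasing = TRUE))) {
      cat(sprintf("  %-24s %6d\n", nm, fails[[nm]]))
    }
  }
  invisible(x)
}
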