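# Synthetic genotyping-array panels: locus universe, sample population with
# ground-truth genotypes, and two-channel intensity emission. The generator
# reproduces the structure an array-evaluation experiment assumes: ~96-sample
# panels mixing inbreds and hybrids, parent/parent/F1 triplets, similar-line
# series, duplicate assays, 10 chromosomes, genic-region annotations, and
# per-locus clustering defect classes.

#' Default designability-score mixture
#'
#' Three-interval mixture for per-locus designability scores: mass 0.015 on
#' `[0.40, 0.60]`, 0.275 on `(0.60, 0.80]`, and 0.71 on `(0.80, 1.00]`, the
#' published score spectrum of a curated GoldenGate fingerprinting panel.
#' Scores are drawn uniformly within the sampled interval.
#'
#' @return A data frame with columns `lower`, `upper`, `mass`.
#' @export
designability_mixture_default <- function() {
  data.frame(
    lower = c(0.40, 0.60, 0.80),
    upper = c(0.60, 0.80, 1.00),
    mass  = c(0.015, 0.275, 0.71)
  )
}

#' Default genic-category proportions
#'
#' Proportions of exon / promoter / 3'UTR / 5'UTR / intron annotations
#' (0.43 / 0.21 / 0.22 / 0.09 / 0.05).
#'
#' @return Named numeric vector over the five genic categories.
#' @export
genic_category_default <- function() {
  c(exon = 0.43, promoter = 0.21, utr3 = 0.22, utr5 = 0.09, intron = 0.05)
}

default_groups <- function() {
  c("STPT", "P", "ImpReid", "Lancaster", "Waxy", "Landrace")
}

#' Generate a synthetic locus universe
#'
#' Lays `n_loci` bi-allelic markers on `n_chromosomes` chromosomes with
#' strictly increasing positions, assigns genic categories and genic-region
#' grouping keys, draws designability scores from an interval mixture, assigns
#' clustering defect classes at requested fractions, and draws per-group
#' B-allele frequencies from a Balding-Nichols model around an ancestral
#' frequency.
#'
#' Defect classes (`weak_signal`, `high_missing`, `pedigree_fail`,
#' `het_inbred`, `shifted`, `multicopy_compressed`) perturb the intensity
#' emission; `low_maf_fraction` and `low_designability_fraction` instead plant
#' loci that fail the population-level or designability selection gates while
#' clustering cleanly. All planted classes are mutually exclusive.
#'
#' @param n_loci Number of loci (>= 1).
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param defect_fractions Named numeric over the six defect classes; missing
#'   names default to 0. Fractions must be nonnegative and, together with the
#'   two `low_*` fractions, sum to at most 1.
#' @param designability_mixture Data frame `lower`/`upper`/`mass`
#'   (see [designability_mixture_default()]).
#' @param low_maf_fraction Fraction of loci with ancestral minor allele
#'   frequency drawn from `low_maf_range`.
#' @param low_designability_fraction Fraction of loci with designability drawn
#'   uniformly from `[0.05, 0.35]` (below the 0.40 design gate).
#' @param genic_category_props Named proportions over the genic categories.
#' @param groups Character vector of heterotic-group labels.
#' @param divergence Balding-Nichols divergence parameter F in `[0, 1)`
#'   controlling between-group allele-frequency spread.
#' @param maf_range Ancestral minor-allele-frequency range for ordinary loci.
#' @param low_maf_range Ancestral MAF range for planted low-MAF loci.
#' @param loci_per_region Number of consecutive same-chromosome loci sharing a
#'   genic region (default 1: one locus per region).
#' @param seed Explicit integer seed.
#' @return An object of class `locus_universe`: list with `loci` (data frame,
#'   one row per marker), `allele_freq` (loci x groups matrix of B-allele
#'   frequencies), and `groups`.
#' @export
generate_locus_universe <- function(n_loci,
                                    n_chromosomes = 10,
                                    defect_fractions = NULL,
                                    designability_mixture = designability_mixture_default(),
                                    low_maf_fraction = 0,
                                    low_designability_fraction = 0,
                                    genic_category_props = genic_category_default(),
                                    groups = default_groups(),
                                    divergence = 0.15,
                                    maf_range = c(0.25, 0.5),
                                    low_maf_range = c(0.02, 0.10),
                                    loci_per_region = 1,
                                    seed) {
  stopifnot(n_loci >= 1, n_chromosomes >= 1, length(groups) >= 1)
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  defect_classes <- setdiff(DEFECT_CLASSES, "none")
  if (is.null(defect_fractions)) {
    defect_fractions <- stats::setNames(numeric(length(defect_classes)), defect_classes)
  }
  unknown <- setdiff(names(defect_fractions), defect_classes)
  if (length(unknown)) {
    stop("unknown defect class in `defect_fractions`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(numeric(length(defect_classes)), defect_classes)
  full[names(defect_fractions)] <- defect_fractions
  check_fractions(c(full, low_maf = low_maf_fraction,
                    low_designability = low_designability_fraction),
                  "defect_fractions")
  check_scalar_prob(divergence, "divergence")
  stopifnot(is.data.frame(designability_mixture),
            all(c("lower", "upper", "mass") %in% names(designability_mixture)))
  if (abs(sum(designability_mixture$mass) - 1) > 1e-8) {
    stop("`designability_mixture` masses must sum to 1", call. = FALSE)
  }
  cat_props <- genic_category_props[GENIC_CATEGORIES]
  if (anyNA(cat_props) || abs(sum(cat_props) - 1) > 1e-8) {
    stop("`genic_category_props` must cover ",
         paste(GENIC_CATEGORIES, collapse = "/"), " and sum to 1", call. = FALSE)
  }

  with_seed(substream_seed(seed, "locus_universe"), {
    locus_id <- sprintf("L%05d", seq_len(n_loci))
    chromosome <- sort(rep_len(seq_len(n_chromosomes), n_loci))
    position <- integer(n_loci)
    for (chr in unique(chromosome)) {
      idx <- which(chromosome == chr)
      gaps <- sample.int(145001L, length(idx), replace = TRUE) + 4999L
      position[idx] <- cumsum(gaps)
    }

    # planted-class assignment: one class (or none) per locus
    classes <- c(defect_classes, "low_maf", "low_designability", "none")
    probs <- c(full, low_maf_fraction, low_designability_fraction,
               1 - sum(full) - low_maf_fraction - low_designability_fraction)
    planted <- sample(classes, n_loci, replace = TRUE, prob = probs)
    defect_class <- ifelse(planted %in% defect_classes, planted, "none")
    maf_class <- ifelse(planted == "low_maf", "low", "high")

    genic_category <- sample(GENIC_CATEGORIES, n_loci, replace = TRUE,
                             prob = cat_props)
    if (loci_per_region <= 1) {
      genic_region_id <- sprintf("GR%05d", seq_len(n_loci))
    } else {
      genic_region_id <- character(n_loci)
      for (chr in unique(chromosome)) {
        idx <- which(chromosome == chr)
        genic_region_id[idx] <- sprintf("GR%d_%04d", chr,
                                        ceiling(seq_along(idx) / loci_per_region))
      }
    }
    copy_number <- ifelse(defect_class == "multicopy_compressed", 2L, 1L)

    mix_row <- sample.int(nrow(designability_mixture), n_loci, replace = TRUE,
                          prob = designability_mixture$mass)
    designability <- stats::runif(n_loci,
                                  designability_mixture$lower[mix_row],
                                  designability_mixture$upper[mix_row])
    low_d <- planted == "low_designability"
    designability[low_d] <- stats::runif(sum(low_d), 0.05, 0.35)

    maf <- stats::runif(n_loci, maf_range[1], maf_range[2])
    maf[maf_class == "low"] <- stats::runif(sum(maf_class == "low"),
                                            low_maf_range[1], low_maf_range[2])
    # randomize which allele is minor
    p_anc <- ifelse(stats::runif(n_loci) < 0.5, maf, 1 - maf)
    allele_freq <- matrix(NA_real_, n_loci, length(groups),
                          dimnames = list(locus_id, groups))
    if (divergence <= 0) {
      allele_freq[] <- p_anc
    } else {
      f <- (1 - divergence) / divergence
      for (g in seq_along(groups)) {
        allele_freq[, g] <- stats::rbeta(n_loci, p_anc * f, (1 - p_anc) * f)
      }
      allele_freq <- pmin(pmax(allele_freq, 0.001), 0.999)
    }

    loci <- data.frame(
      locus_id = locus_id, chromosome = as.integer(chromosome),
      position = position, genic_category = genic_category,
      genic_region_id = genic_region_id, copy_number = copy_number,
      designability = designability, defect_class = defect_class,
      maf_class = maf_class, stringsAsFactors = FALSE
    )
    structure(list(loci = loci, allele_freq = allele_freq, groups = groups),
              class = "locus_universe")
  })
}

#' @export
print.locus_universe <- function(x, ...) {
  cat(sprintf("locus_universe: %d loci on %d chromosomes, %d heterotic groups\n",
              nrow(x$loci), length(unique(x$loci$chromosome)), length(x$groups)))
  tab <- table(x$loci$defect_class)
  cat("defect classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default similar-line specification
#'
#' Two similar-line series: a radiation-mutant series (copies with mutation
#' fraction 0, i.e. no differences) and a backcross-derived series (mutation
#' fraction 0.02, emulating >97 % genetic similarity).
#'
#' @return List of per-series specs (`name`, `n_copies`, `mutation_fraction`).
#' @export
similar_line_default <- function() {
  list(
    list(name = "radiation", n_copies = 2, mutation_fraction = 0),
    list(name = "backcross", n_copies = 2, mutation_fraction = 0.02)
  )
}

# draw homozygous genotypes for one locus across base inbreds, then apply
# purity off-types and similar-line mutations; returns calls for all inbreds
draw_inbred_locus <- function(p_by_sample, purity_by_sample) {
  g <- ifelse(stats::runif(length(p_by_sample)) < p_by_sample, "BB", "AA")
  imp <- purity_by_sample < 1
  if (any(imp)) {
    flip <- imp & stats::runif(length(g)) < (1 - purity_by_sample)
    g[flip] <- ifelse(g[flip] == "AA", "BB", "AA")
  }
  g
}

f1_genotype <- function(g1, g2) {
  a1 <- substr(g1, 1, 1)
  b1 <- substr(g1, 2, 2)
  a2 <- substr(g2, 1, 1)
  b2 <- substr(g2, 2, 2)
  # inbred parents are homozygous; for safety pick the first allele of each
  al <- cbind(ifelse(a1 == b1, a1, a1), ifelse(a2 == b2, a2, a2))
  apply(al, 1, function(z) paste(sort(z), collapse = ""))
}

#' Generate a sample population with ground-truth genotypes
#'
#' Draws per-group inbred genotypes from the universe's group allele
#' frequencies (homozygous; impurity introduces off-type homozygous calls at
#' rate `1 - purity`), constructs parent/parent/F1 triplets and additional
#' hybrids as Mendelian combinations of inbred parents, clones similar-line
#' series with a configured mutation fraction, and copies duplicate samples
#' exactly.
#'
#' The realised inbred minor allele frequency of every locus is kept out of
#' the narrow band `(maf_margin["low"], maf_margin["high"])` around the
#' selection gate by rejection-resampling the inbred draws at that locus
#' (planted low-MAF loci are additionally held at or below
#' `maf_margin["low"]`). Loci whose realised MAF lands at or above
#' `maf_margin["high"]` — and that carry no defect, a single copy, and an
#' acceptable designability — form `planted_good_loci`, satisfying every
#' selection criterion by construction; all other loci violate at least one.
#'
#' @param universe A `locus_universe`.
#' @param n_inbreds_per_group Base inbred lines per heterotic group.
#' @param groups Groups to sample from (must exist in the universe).
#' @param n_hybrids Total hybrids, including triplet F1s (>= `n_triplets`).
#' @param n_triplets Number of parent/parent/F1 triplets to record.
#' @param n_duplicates Number of duplicate (re-assayed) samples.
#' @param similar_line_spec List of similar-line series specs
#'   (see [similar_line_default()]).
#' @param purity Fraction of loci at which an inbred matches its nominal line
#'   (default 1: fully pure).
#' @param maf_margin Named vector `c(low=, high=)` of realised-MAF guarantees.
#' @param enforce_maf_margin Enforce the margins by rejection-resampling.
#' @param seed Explicit integer seed.
#' @return An object of class `snp_population`: list with `samples` (metadata
#'   data frame), `truth` (list: `genotypes` samples x loci matrix over
#'   AA/AB/BB, `planted_good_loci`), `triplets`, `duplicate_pairs`.
#' @export
generate_population <- function(universe,
                                n_inbreds_per_group = 8,
                                groups = universe$groups,
                                n_hybrids = 40,
                                n_triplets = 22,
                                n_duplicates = 4,
                                similar_line_spec = similar_line_default(),
                                purity = 1,
                                maf_margin = c(low = 0.18, high = 0.215),
                                enforce_maf_margin = TRUE,
                                seed) {
  stopifnot(inherits(universe, "locus_universe"))
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  missing_groups <- setdiff(groups, colnames(universe$allele_freq))
  if (length(missing_groups)) {
    stop("no allele frequencies in universe for group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  check_scalar_prob(purity, "purity")
  n_base <- n_inbreds_per_group * length(groups)
  if (2 * n_triplets > n_base) {
    stop(sprintf("cannot build %d triplets from %d base inbreds", n_triplets,
                 n_base), call. = FALSE)
  }
  if (n_hybrids < n_triplets) {
    stop("`n_hybrids` counts all hybrids and must be >= `n_triplets`",
         call. = FALSE)
  }
  loci <- universe$loci
  n_loci <- nrow(loci)

  with_seed(substream_seed(seed, "population"), {
    ## base inbreds
    inb_group <- rep(groups, each = n_inbreds_per_group)
    inb_id <- sprintf("IB%03d", seq_len(n_base))
    p_mat <- universe$allele_freq[, inb_group, drop = FALSE]  # loci x inbreds
    pur <- rep(purity, n_base)
    geno_inb <- matrix(NA_character_, n_base, n_loci,
                       dimnames = list(inb_id, loci$locus_id))
    for (l in seq_len(n_loci)) {
      geno_inb[, l] <- draw_inbred_locus(p_mat[l, ], pur)
    }

    ## similar-line series: clone a base inbred, mutate a fixed locus set
    sim_id <- character(0); sim_group <- character(0); sim_series <- character(0)
    geno_sim <- NULL
    sim_info <- list()  # per series: base index, copy ids, mutated locus sets
    if (length(similar_line_spec)) {
      base_pick <- sample.int(n_base, length(similar_line_spec))
      rows <- list()
      for (s in seq_along(similar_line_spec)) {
        sp <- similar_line_spec[[s]]
        n_mut <- round(sp$mutation_fraction * n_loci)
        ids <- sprintf("SL%s%02d", substr(sp$name, 1, 1), seq_len(sp$n_copies))
        ids <- paste0(ids, "_", s)
        mut_sets <- lapply(seq_len(sp$n_copies), function(k) {
          if (n_mut > 0) sample.int(n_loci, n_mut) else integer(0)
        })
        for (k in seq_len(sp$n_copies)) {
          g <- geno_inb[base_pick[s], ]
          ms <- mut_sets[[k]]
          g[ms] <- ifelse(g[ms] == "AA", "BB", "AA")
          rows[[length(rows) + 1]] <- g
        }
        sim_id <- c(sim_id, ids)
        sim_group <- c(sim_group, rep(inb_group[base_pick[s]], sp$n_copies))
        sim_series <- c(sim_series, rep(sp$name, sp$n_copies))
        sim_info[[s]] <- list(base = base_pick[s], ids = ids, mut_sets = mut_sets)
      }
      geno_sim <- do.call(rbind, rows)
      rownames(geno_sim) <- sim_id
    }

    all_inb_geno <- rbind(geno_inb, geno_sim)

    ## enforce realised-MAF margins on the inbred roster
    if (enforce_maf_margin) {
      for (l in seq_len(n_loci)) {
        want_low <- loci$maf_class[l] == "low"
        for (try in seq_len(200)) {
          g <- all_inb_geno[, l]
          nb <- sum(g == "BB") * 2 + sum(g == "AB")
          freq_b <- nb / (2 * length(g))
          m <- min(freq_b, 1 - freq_b)
          # keep realised MAF out of the band around the selection gate;
          # planted low-MAF loci must stay below it
          ok <- if (want_low) m <= maf_margin[["low"]] else
            (m <= maf_margin[["low"]] || m >= maf_margin[["high"]])
          if (ok) break
          # redraw this locus for base inbreds, re-derive similar copies
          newg <- draw_inbred_locus(p_mat[l, ], pur)
          all_inb_geno[seq_len(n_base), l] <- newg
          for (s in seq_along(sim_info)) {
            si <- sim_info[[s]]
            for (k in seq_along(si$ids)) {
              gg <- newg[si$base]
              if (l %in% si$mut_sets[[k]]) gg <- ifelse(gg == "AA", "BB", "AA")
              all_inb_geno[si$ids[k], l] <- gg
            }
          }
        }
      }
    }

    ## triplets and hybrids
    parent_order <- sample.int(n_base)
    trip_p1 <- inb_id[parent_order[seq_len(n_triplets) * 2 - 1]]
    trip_p2 <- inb_id[parent_order[seq_len(n_triplets) * 2]]
    f1_ids <- sprintf("F1%03d", seq_len(n_triplets))
    n_extra <- n_hybrids - n_triplets
    hy_ids <- if (n_extra > 0) sprintf("HY%03d", seq_len(n_extra)) else character(0)
    hy_p1 <- hy_p2 <- character(0)
    if (n_extra > 0) {
      hy_p1 <- inb_id[sample.int(n_base, n_extra, replace = TRUE)]
      repeat {
        hy_p2 <- inb_id[sample.int(n_base, n_extra, replace = TRUE)]
        if (all(hy_p1 != hy_p2)) break
      }
    }
    hyb_id <- c(f1_ids, hy_ids)
    hyb_p1 <- c(trip_p1, hy_p1)
    hyb_p2 <- c(trip_p2, hy_p2)
    geno_hyb <- matrix(NA_character_, length(hyb_id), n_loci,
                       dimnames = list(hyb_id, loci$locus_id))
    for (h in seq_along(hyb_id)) {
      geno_hyb[h, ] <- f1_genotype(all_inb_geno[hyb_p1[h], ],
                                   all_inb_geno[hyb_p2[h], ])
    }

    geno <- rbind(all_inb_geno, geno_hyb)
    samples <- data.frame(
      sample_id = rownames(geno),
      role = c(rep("inbred", nrow(all_inb_geno)), rep("hybrid", length(hyb_id))),
      group = c(inb_group, sim_group, rep(NA_character_, length(hyb_id))),
      parent1_id = c(rep(NA_character_, nrow(all_inb_geno)), hyb_p1),
      parent2_id = c(rep(NA_character_, nrow(all_inb_geno)), hyb_p2),
      duplicate_of = NA_character_,
      purity = c(pur, rep(purity, length(sim_id)), rep(1, length(hyb_id))),
      series = c(rep(NA_character_, n_base), sim_series,
                 rep(NA_character_, length(hyb_id))),
      stringsAsFactors = FALSE
    )

    ## duplicates: exact copies of existing samples
    dup_pairs <- data.frame(sample_a = character(0), sample_b = character(0))
    if (n_duplicates > 0) {
      src <- sample(samples$sample_id, n_duplicates)
      dup_id <- paste0(src, "_dup")
      dup_rows <- samples[match(src, samples$sample_id), ]
      dup_rows$sample_id <- dup_id
      dup_rows$duplicate_of <- src
      samples <- rbind(samples, dup_rows)
      geno <- rbind(geno, geno[src, , drop = FALSE])
      rownames(geno) <- samples$sample_id
      dup_pairs <- data.frame(sample_a = src, sample_b = dup_id,
                              stringsAsFactors = FALSE)
    }
    rownames(samples) <- NULL

    ## planted-good set: satisfies every selection gate by construction.
    ## Realised MAF is over distinct inbred lines (duplicates are the same
    ## DNA re-assayed and are excluded from allele-frequency estimation).
    distinct_inb <- samples$role == "inbred" & is.na(samples$duplicate_of)
    freq_b <- colMeans(geno[distinct_inb, , drop = FALSE] == "BB") +
      colMeans(geno[distinct_inb, , drop = FALSE] == "AB") / 2
    realised_maf <- pmin(freq_b, 1 - freq_b)
    good <- loci$locus_id[
      loci$defect_class == "none" & loci$copy_number < 2 &
        loci$designability >= 0.40 & realised_maf >= maf_margin[["high"]]
    ]

    triplets <- data.frame(triplet_id = sprintf("T%02d", seq_len(n_triplets)),
                           parent1 = trip_p1, parent2 = trip_p2, f1 = f1_ids,
                           stringsAsFactors = FALSE)
    structure(list(samples = samples,
                   truth = list(genotypes = geno, planted_good_loci = good),
                   triplets = triplets, duplicate_pairs = dup_pairs),
              class = "snp_population")
  })
}

#' @export
print.snp_population <- function(x, ...) {
  cat(sprintf("snp_population: %d samples (%d inbred, %d hybrid), %d loci\n",
              nrow(x$samples), sum(x$samples$role == "inbred"),
              sum(x$samples$role == "hybrid"), ncol(x$truth$genotypes)))
  cat(sprintf("%d triplets, %d duplicate pairs, %d planted-good loci\n",
              nrow(x$triplets), nrow(x$duplicate_pairs),
              length(x$truth$planted_good_loci)))
  invisible(x)
}

#' Distinct inbred lines of a sample table
#'
#' Returns the sample ids of inbred lines excluding duplicate re-assays —
#' the subset on which allele frequencies are conventionally estimated.
#'
#' @param samples Sample metadata data frame (`sample_id`, `role`,
#'   `duplicate_of`).
#' @return Character vector of sample ids.
#' @export
inbred_lines <- function(samples) {
  samples$sample_id[samples$role == "inbred" & is.na(samples$duplicate_of)]
}

#' Intensity noise profile
#'
#' Parameters of the two-channel intensity emission. Total signal R is drawn
#' normal around `signal_mean` (nominal scale 1.0); the normalized theta of a
#' point is its genotype's cluster center plus normal noise of SD `theta_sd`.
#' Defect classes perturb emission: `weak_scale` multiplies R on weak-signal
#' loci; `missing_fraction` of samples are pushed into the failed zone on
#' high-missing loci; `shift_offset` displaces every cluster center on shifted
#' loci; `compress_factor` shrinks the theta span toward 0.5 on compressed
#' multicopy loci; `n_het_inbreds` inbreds emit heterozygous signal on
#' het-inbred loci; `n_bad_triplets` triplets get Mendelian-inconsistent F1
#' signal on pedigree-fail loci. `f1_error_rate` corrupts triplet F1 signal at
#' random loci at the given per-locus rate (clean loci included).
#'
#' @param signal_mean,signal_sd Mean and SD of total signal R.
#' @param theta_sd SD of theta around the cluster center.
#' @param theta_centers Named centers for AA/AB/BB (defaults 0.05/0.50/0.95).
#' @param weak_scale,missing_fraction,shift_offset,compress_factor,n_het_inbreds,n_bad_triplets,f1_error_rate
#'   Defect-emission parameters (see Description).
#' @return A list of class `noise_profile`.
#' @export
noise_profile <- function(signal_mean = 1, signal_sd = 0.1, theta_sd = 0.02,
                          theta_centers = c(AA = 0.05, AB = 0.50, BB = 0.95),
                          weak_scale = 0.1, missing_fraction = 0.08,
                          shift_offset = 0.2, compress_factor = 0.8,
                          n_het_inbreds = 8, n_bad_triplets = 5,
                          f1_error_rate = 0) {
  stopifnot(signal_mean > 0, signal_sd >= 0, theta_sd >= 0,
            all(GENOTYPES %in% names(theta_centers)))
  check_scalar_prob(f1_error_rate, "f1_error_rate")
  check_scalar_prob(missing_fraction, "missing_fraction")
  structure(list(signal_mean = signal_mean, signal_sd = signal_sd,
                 theta_sd = theta_sd,
                 theta_centers = theta_centers[GENOTYPES],
                 weak_scale = weak_scale, missing_fraction = missing_fraction,
                 shift_offset = shift_offset, compress_factor = compress_factor,
                 n_het_inbreds = n_het_inbreds, n_bad_triplets = n_bad_triplets,
                 f1_error_rate = f1_error_rate),
            class = "noise_profile")
}

# genotype inconsistent with the Mendelian expectation of two parents
inconsistent_genotype <- function(p1, p2) {
  exp_set <- expected_f1_genotypes(p1, p2)
  setdiff(GENOTYPES, exp_set)[1]
}

#' Emit two-channel intensities for a population
#'
#' Converts true genotypes into (X, Y) channel signals: each point's theta is
#' its genotype's cluster center (AA near 0.05, AB near 0.50, BB near 0.95)
#' plus noise, its total signal R is drawn around the nominal mean, and the
#' channels are recovered as `x = R / (1 + tan(theta * pi/2))`, `y = R - x`.
#' Per-locus defect classes perturb the emission as configured in the
#' [noise_profile()].
#'
#' @param universe A `locus_universe`.
#' @param population A `snp_population` from [generate_population()].
#' @param profile A [noise_profile()].
#' @param seed Explicit integer seed.
#' @return Long-format data frame `sample_id`, `locus_id`, `x`, `y` with
#'   `x, y >= 0`, one row per (sample, locus).
#' @export
generate_intensities <- function(universe, population,
                                 profile = noise_profile(), seed) {
  stopifnot(inherits(universe, "locus_universe"),
            inherits(population, "snp_population"),
            inherits(profile, "noise_profile"))
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  loci <- universe$loci
  bad <- setdiff(unique(loci$defect_class), DEFECT_CLASSES)
  if (length(bad)) {
    stop("unknown defect class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  geno <- population$truth$genotypes
  if (!identical(colnames(geno), loci$locus_id)) {
    geno <- geno[, loci$locus_id, drop = FALSE]
  }
  samples <- population$samples
  n_s <- nrow(geno); n_l <- ncol(geno)

  with_seed(substream_seed(seed, "intensities"), {
    # sample-major long layout: row = (sample s, locus l), l fastest
    centers <- matrix(profile$theta_centers[geno], n_s, n_l)

    inbred_idx <- which(samples$role == "inbred")
    trips <- population$triplets
    f1_idx <- match(trips$f1, rownames(geno))
    p1_idx <- match(trips$parent1, rownames(geno))
    p2_idx <- match(trips$parent2, rownames(geno))

    for (l in seq_len(n_l)) {
      dc <- loci$defect_class[l]
      if (dc == "het_inbred") {
        k <- min(profile$n_het_inbreds, length(inbred_idx))
        pick <- sample(inbred_idx, k)
        centers[pick, l] <- profile$theta_centers[["AB"]]
      } else if (dc == "pedigree_fail" && nrow(trips) > 0) {
        k <- min(profile$n_bad_triplets, nrow(trips))
        pick <- sample.int(nrow(trips), k)
        for (t in pick) {
          g_bad <- inconsistent_genotype(geno[p1_idx[t], l], geno[p2_idx[t], l])
          centers[f1_idx[t], l] <- profile$theta_centers[[g_bad]]
        }
      }
    }
    if (profile$f1_error_rate > 0 && nrow(trips) > 0) {
      for (t in seq_len(nrow(trips))) {
        hit <- which(stats::runif(n_l) < profile$f1_error_rate)
        for (l in hit) {
          g_bad <- inconsistent_genotype(geno[p1_idx[t], l], geno[p2_idx[t], l])
          centers[f1_idx[t], l] <- profile$theta_centers[[g_bad]]
        }
      }
    }

    shifted <- loci$defect_class == "shifted"
    if (any(shifted)) {
      centers[, shifted] <- pmin(pmax(centers[, shifted] + profile$shift_offset, 0), 1)
    }
    compressed <- loci$defect_class == "multicopy_compressed"
    if (any(compressed)) {
      centers[, compressed] <- 0.5 + (centers[, compressed] - 0.5) * profile$compress_factor
    }

    theta <- centers
    if (profile$theta_sd > 0) {
      theta <- theta + stats::rnorm(n_s * n_l, 0, profile$theta_sd)
    }
    theta <- pmin(pmax(theta, 0), 1)

    r <- matrix(profile$signal_mean, n_s, n_l)
    if (profile$signal_sd > 0) {
      r <- r + stats::rnorm(n_s * n_l, 0, profile$signal_sd)
    }
    r <- pmax(r, 1e-6)
    weak <- loci$defect_class == "weak_signal"
    if (any(weak)) r[, weak] <- r[, weak] * profile$weak_scale
    hm <- which(loci$defect_class == "high_missing")
    for (l in hm) {
      n_fail <- max(ceiling(profile$missing_fraction * n_s),
                    floor(0.05 * n_s) + 1)
      pick <- sample.int(n_s, min(n_fail, n_s))
      r[pick, l] <- r[pick, l] * 0.05
    }

    tn <- tan(theta * pi / 2)
    x <- r / (1 + tn)
    x[theta >= 1] <- 0
    y <- r - x

    data.frame(
      sample_id = rep(rownames(geno), times = n_l),
      locus_id = rep(colnames(geno), each = n_s),
      x = as.vector(x), y = as.vector(y),
      stringsAsFactors = FALSE
    )
  })
}

#' Default study-scale simulation scenario
#'
#' One call that generates the full synthetic study: a locus universe with the
#' package's default planted composition (4 % weak-signal, 5 % high-missing,
#' 3 % pedigree-fail, 3 % het-inbred, 4 % shifted, 6 % compressed-multicopy
#' loci, 30 % low-MAF loci, 10 % low-designability loci, remainder clean), an
#' evaluation panel of inbreds, hybrids, triplets, similar-line series, and
#' duplicates, and the corresponding two-channel intensities.
#'
#' Every planted non-clean locus violates exactly one selection criterion;
#' planted-good loci satisfy all of them by construction, so the selection
#' pipeline's output can be checked against `population$truth$planted_good_loci`.
#'
#' @param n_loci Number of loci (default 5000).
#' @param seed Explicit integer seed.
#' @param profile A [noise_profile()].
#' @param ... Passed on to [generate_population()].
#' @return List with `universe`, `population`, `intensities`.
#' @export
simulate_study <- function(n_loci = 5000, seed, profile = noise_profile(), ...) {
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  universe <- generate_locus_universe(
    n_loci = n_loci,
    defect_fractions = c(weak_signal = 0.04, high_missing = 0.05,
                         pedigree_fail = 0.03, het_inbred = 0.03,
                         shifted = 0.04, multicopy_compressed = 0.06),
    low_maf_fraction = 0.30,
    low_designability_fraction = 0.10,
    seed = seed
  )
  population <- generate_population(universe, seed = seed, ...)
  intensities <- generate_intensities(universe, population, profile, seed = seed)
  list(universe = universe, population = population, intensities = intensities)
}
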