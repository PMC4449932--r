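# Normalized polar transform of two-channel intensities, per-locus cluster
# file construction, and genotype calling against a cluster file.

#' Transform two-channel signals to normalized polar coordinates
#'
#' theta is the normalized angular deviation from the pure-A axis,
#' `theta = (2/pi) * atan(y/x)`: 0 for a pure A signal (y = 0), 1.0 for a pure
#' B signal (x = 0), 0.5 for equal signals. R is the total signal; by the
#' array platform's convention this is the Manhattan magnitude `x + y`
#' (Euclidean available via `r_metric`).
#'
#' @param x,y Nonnegative channel signals (vectorized).
#' @param r_metric `"manhattan"` (default, `r = x + y`) or `"euclidean"`.
#' @param allow_undefined If `TRUE`, points with `x = y = 0` yield `NA` theta
#'   instead of an error (the caller records them as no-calls).
#' @return List with numeric vectors `theta` (in `[0, 1]`, or `NA` where
#'   undefined) and `r` (`>= 0`).
#' @export
to_theta_r <- function(x, y, r_metric = c("manhattan", "euclidean"),
                       allow_undefined = FALSE) {
  r_metric <- match.arg(r_metric)
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    stop("channel signals must be nonnegative", call. = FALSE)
  }
  undef <- x == 0 & y == 0
  if (any(undef) && !allow_undefined) {
    stop("undefined point: x = y = 0 has no theta (record as NC)",
         call. = FALSE)
  }
  theta <- (2 / pi) * atan2(y, x)
  theta[undef] <- NA_real_
  r <- if (r_metric == "manhattan") x + y else sqrt(x^2 + y^2)
  list(theta = theta, r = r)
}

#' Cluster-file construction configuration
#'
#' @param r_floor_frac Relative signal floor: fraction of the locus median R.
#' @param r_floor_min Absolute signal floor on the nominal total-signal scale
#'   (1.0 = clean signal); the effective floor is the max of both.
#' @param min_halfwidth Minimum theta halfwidth of a call region.
#' @param sd_mult Halfwidth = `max(sd_mult * cluster SD, min_halfwidth)`.
#' @param min_points Minimum member points for a cluster to count as occupied
#'   (and for its center to shift to the observed mean).
#' @param canonical_centers Default AA/AB/BB centers for unoccupied regions.
#' @param seeds Initial centers for the one-dimensional clustering.
#' @param max_iter Maximum Lloyd iterations.
#' @param r_metric Passed to [to_theta_r()].
#' @return List of class `cluster_config`.
#' @export
cluster_config <- function(r_floor_frac = 0.2, r_floor_min = 0.3,
                           min_halfwidth = 0.05, sd_mult = 3, min_points = 3,
                           canonical_centers = c(AA = 0.05, AB = 0.50, BB = 0.95),
                           seeds = c(0, 0.5, 1), max_iter = 50,
                           r_metric = "manhattan") {
  stopifnot(r_floor_frac >= 0, r_floor_min >= 0, min_halfwidth > 0,
            sd_mult > 0, min_points >= 1, length(seeds) == 3,
            all(GENOTYPES %in% names(canonical_centers)))
  structure(list(r_floor_frac = r_floor_frac, r_floor_min = r_floor_min,
                 min_halfwidth = min_halfwidth, sd_mult = sd_mult,
                 min_points = min_points,
                 canonical_centers = canonical_centers[GENOTYPES],
                 seeds = sort(seeds), max_iter = max_iter,
                 r_metric = r_metric),
            class = "cluster_config")
}

# Lloyd iterations on theta, vectorized across loci. `locus` is an integer
# index, `centers0` a 3-vector of seeds. Returns assignment (1..3) per point
# and an n_loci x 3 center matrix. Empty clusters keep their seed center.
seeded_theta_clusters <- function(theta, locus, n_loci, centers0, max_iter) {
  centers <- matrix(rep(centers0, each = n_loci), n_loci, 3)
  assign <- integer(length(theta))
  for (iter in seq_len(max_iter)) {
    dm <- cbind(abs(theta - centers[locus, 1]),
                abs(theta - centers[locus, 2]),
                abs(theta - centers[locus, 3]))
    new_assign <- max.col(-dm, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    key <- (locus - 1L) * 3L + assign
    sums <- rowsum(theta, key)
    cnts <- rowsum(rep(1, length(theta)), key)
    idx <- as.integer(rownames(sums))
    li <- (idx - 1L) %/% 3L + 1L
    ki <- (idx - 1L) %% 3L + 1L
    centers[cbind(li, ki)] <- sums / cnts
  }
  list(assign = assign, centers = centers)
}

#' Build a per-locus cluster file from a labeled panel
#'
#' For each locus: points below the signal floor are excluded; remaining
#' thetas are clustered into at most three groups by one-dimensional Lloyd
#' iterations seeded at theta 0, 0.5, and 1.0 (the canonical AA/AB/BB
#' positions); a genotype's region center shifts to the observed cluster mean
#' when at least `min_points` points support it, and otherwise stays at its
#' canonical default (flagged unoccupied); region halfwidths are
#' `max(sd_mult * SD, min_halfwidth)` and the call intervals are truncated at
#' the midpoints between adjacent centers so the three regions never overlap.
#' A locus whose every point falls below the floor is recorded as weak with
#' all three regions unoccupied.
#'
#' @param intensities Long-format data frame `sample_id`, `locus_id`, `x`, `y`.
#' @param sample_meta Optional sample metadata (recorded in provenance).
#' @param config A [cluster_config()].
#' @param provenance Optional note (e.g. panel name and seed) stored verbatim.
#' @return Object of class `cluster_file`: list with `regions` (data frame,
#'   three rows per locus: `locus_id`, `genotype`, `theta_center`,
#'   `theta_halfwidth`, `theta_low`, `theta_high`, `occupied`), `loci`
#'   (per-locus `r_floor`, `weak`, `n_points`), and `provenance`.
#' @export
build_cluster_file <- function(intensities, sample_meta = NULL,
                               config = cluster_config(), provenance = NULL) {
  stopifnot(all(c("sample_id", "locus_id", "x", "y") %in% names(intensities)))
  tr <- to_theta_r(intensities$x, intensities$y, r_metric = config$r_metric,
                   allow_undefined = TRUE)
  locus_ids <- sort(unique(intensities$locus_id))
  locus <- match(intensities$locus_id, locus_ids)
  n_loci <- length(locus_ids)

  ok <- !is.na(tr$theta)
  med_r <- rep(0, n_loci)
  mr <- tapply(tr$r[ok], locus[ok], stats::median)
  med_r[as.integer(names(mr))] <- mr
  r_floor <- pmax(config$r_floor_frac * med_r, config$r_floor_min)

  keep <- ok & tr$r >= r_floor[locus]
  theta <- tr$theta[keep]
  kl <- locus[keep]

  cl <- seeded_theta_clusters(theta, kl, n_loci, config$seeds, config$max_iter)

  key <- (kl - 1L) * 3L + cl$assign
  cnt <- rowsum(rep(1L, length(theta)), key)
  mean_t <- rowsum(theta, key) / cnt
  sq <- rowsum(theta^2, key)
  var_t <- (sq - cnt * mean_t^2) / pmax(cnt - 1, 1)
  var_t[cnt < 2] <- 0

  counts <- matrix(0L, n_loci, 3)
  means <- matrix(NA_real_, n_loci, 3)
  sds <- matrix(0, n_loci, 3)
  idx <- as.integer(rownames(cnt))
  li <- (idx - 1L) %/% 3L + 1L
  ki <- (idx - 1L) %% 3L + 1L
  counts[cbind(li, ki)] <- cnt
  means[cbind(li, ki)] <- mean_t
  sds[cbind(li, ki)] <- sqrt(pmax(var_t, 0))

  occupied <- counts >= config$min_points
  centers <- matrix(rep(config$canonical_centers, each = n_loci), n_loci, 3)
  centers[occupied] <- means[occupied]
  # keep the AA < AB < BB ordering even on degenerate geometry
  centers <- t(apply(centers, 1, sort))
  halfw <- matrix(config$min_halfwidth, n_loci, 3)
  halfw[occupied] <- pmax(config$sd_mult * sds[occupied], config$min_halfwidth)

  mid12 <- (centers[, 1] + centers[, 2]) / 2
  mid23 <- (centers[, 2] + centers[, 3]) / 2
  low <- cbind(centers[, 1] - halfw[, 1],
               pmax(centers[, 2] - halfw[, 2], mid12),
               pmax(centers[, 3] - halfw[, 3], mid23))
  high <- cbind(pmin(centers[, 1] + halfw[, 1], mid12),
                pmin(centers[, 2] + halfw[, 2], mid23),
                centers[, 3] + halfw[, 3])

  regions <- data.frame(
    locus_id = rep(locus_ids, each = 3),
    genotype = rep(GENOTYPES, n_loci),
    theta_center = as.vector(t(centers)),
    theta_halfwidth = as.vector(t(halfw)),
    theta_low = as.vector(t(low)),
    theta_high = as.vector(t(high)),
    occupied = as.vector(t(occupied)),
    stringsAsFactors = FALSE
  )
  n_points <- tabulate(kl, nbins = n_loci)
  loci <- data.frame(locus_id = locus_ids, r_floor = r_floor,
                     weak = n_points == 0L, n_points = n_points,
                     stringsAsFactors = FALSE)
  structure(list(regions = regions, loci = loci,
                 provenance = if (is.null(provenance)) list() else provenance,
                 config = unclass(config)),
            class = "cluster_file")
}

#' @export
print.cluster_file <- function(x, ...) {
  cat(sprintf("cluster_file: %d loci (%d weak), %d occupied regions\n",
              nrow(x$loci), sum(x$loci$weak), sum(x$regions$occupied)))
  invisible(x)
}

#' Default (uncurated) cluster file
#'
#' Builds a cluster file whose every region sits at the canonical AA/AB/BB
#' centers with the minimum halfwidth — the analog of fully automatic calling
#' without panel-derived curation. Useful as a baseline to quantify how much
#' a curated cluster file lowers the missing rate.
#'
#' @param locus_ids Character vector of loci.
#' @param r_floor Signal floor applied to every locus.
#' @param config A [cluster_config()].
#' @return A `cluster_file`.
#' @export
default_cluster_file <- function(locus_ids, r_floor = NULL,
                                 config = cluster_config()) {
  n <- length(locus_ids)
  if (is.null(r_floor)) r_floor <- config$r_floor_min
  centers <- config$canonical_centers
  hw <- rep(config$min_halfwidth, 3)
  mid12 <- (centers[1] + centers[2]) / 2
  mid23 <- (centers[2] + centers[3]) / 2
  low <- c(centers[1] - hw[1], max(centers[2] - hw[2], mid12),
           max(centers[3] - hw[3], mid23))
  high <- c(min(centers[1] + hw[1], mid12), min(centers[2] + hw[2], mid23),
            centers[3] + hw[3])
  regions <- data.frame(
    locus_id = rep(sort(locus_ids), each = 3), genotype = rep(GENOTYPES, n),
    theta_center = rep(unname(centers), n), theta_halfwidth = rep(hw, n),
    theta_low = rep(low, n), theta_high = rep(high, n),
    occupied = TRUE, stringsAsFactors = FALSE
  )
  loci <- data.frame(locus_id = sort(locus_ids), r_floor = r_floor,
                     weak = FALSE, n_points = NA_integer_,
                     stringsAsFactors = FALSE)
  structure(list(regions = regions, loci = loci,
                 provenance = list(note = "default canonical regions"),
                 config = unclass(config)),
            class = "cluster_file")
}

#' Call genotypes against a cluster file
#'
#' Each point is assigned to the unique call region whose theta interval
#' contains it and whose signal floor it exceeds; points below the floor or
#' outside all regions are no-calls (NC). Where truncated intervals share a
#' boundary the point goes to the nearer center; an exact midpoint resolves
#' to the lower-theta region. The call confidence is
#' `1 - min(|theta - center| / halfwidth, 1)`.
#'
#' @param intensities Long-format data frame `sample_id`, `locus_id`, `x`, `y`.
#' @param cluster_file A `cluster_file` covering every locus in `intensities`.
#' @return List of class `genotype_calls`: `calls` (samples x loci character
#'   matrix over AA/AB/BB/NC) and `confidence` (same shape, 0 for NC).
#' @export
call_genotypes <- function(intensities, cluster_file) {
  stopifnot(inherits(cluster_file, "cluster_file"),
            all(c("sample_id", "locus_id", "x", "y") %in% names(intensities)))
  locus_ids <- cluster_file$loci$locus_id
  missing_loci <- setdiff(unique(intensities$locus_id), locus_ids)
  if (length(missing_loci)) {
    stop("loci missing from cluster file: ",
         paste(utils::head(missing_loci, 10), collapse = ", "),
         if (length(missing_loci) > 10) sprintf(" (and %d more)", length(missing_loci) - 10),
         call. = FALSE)
  }
  cfg <- cluster_file$config
  tr <- to_theta_r(intensities$x, intensities$y,
                   r_metric = if (is.null(cfg$r_metric)) "manhattan" else cfg$r_metric,
                   allow_undefined = TRUE)
  li <- match(intensities$locus_id, locus_ids)
  reg <- cluster_file$regions
  n_loci <- length(locus_ids)
  # regions are emitted three per locus in AA/AB/BB order
  ctr <- matrix(reg$theta_center, n_loci, 3, byrow = TRUE)
  lo <- matrix(reg$theta_low, n_loci, 3, byrow = TRUE)
  hi <- matrix(reg$theta_high, n_loci, 3, byrow = TRUE)
  hw <- matrix(reg$theta_halfwidth, n_loci, 3, byrow = TRUE)
  floor_r <- cluster_file$loci$r_floor

  above <- !is.na(tr$theta) & tr$r >= floor_r[li]
  theta <- ifelse(is.na(tr$theta), -1, tr$theta)  # sentinel outside all regions
  d <- cbind(abs(theta - ctr[li, 1]), abs(theta - ctr[li, 2]),
             abs(theta - ctr[li, 3]))
  inside <- cbind(theta >= lo[li, 1] & theta <= hi[li, 1],
                  theta >= lo[li, 2] & theta <= hi[li, 2],
                  theta >= lo[li, 3] & theta <= hi[li, 3])
  d[!inside] <- Inf
  pick <- max.col(-d, ties.method = "first")
  best <- d[cbind(seq_along(pick), pick)]
  callable <- above & is.finite(best)
  call <- rep(NO_CALL, length(theta))
  call[callable] <- GENOTYPES[pick[callable]]
  conf <- numeric(length(theta))
  hwp <- hw[cbind(li, pick)]
  conf[callable] <- 1 - pmin(best[callable] / hwp[callable], 1)

  sample_ids <- unique(intensities$sample_id)
  si <- match(intensities$sample_id, sample_ids)
  calls <- matrix(NO_CALL, length(sample_ids), n_loci,
                  dimnames = list(sample_ids, locus_ids))
  confm <- matrix(0, length(sample_ids), n_loci,
                  dimnames = list(sample_ids, locus_ids))
  calls[cbind(si, li)] <- call
  confm[cbind(si, li)] <- conf
  structure(list(calls = calls, confidence = confm), class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  nc <- mean(x$calls == NO_CALL)
  cat(sprintf("genotype_calls: %d samples x %d loci, missing rate %.2f%%\n",
              nrow(x$calls), ncol(x$calls), 100 * nc))
  invisible(x)
}
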