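#' @keywords internal
"_PACKAGE"

GENOTYPES <- c("AA", "AB", "BB")
NO_CALL <- "NC"
GENIC_CATEGORIES <- c("exon", "promoter", "utr3", "utr5", "intron")
DEFECT_CLASSES <- c("none", "weak_signal", "high_missing", "pedigree_fail",
                    "het_inbred", "shifted", "multicopy_compressed")

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one explicit user seed. Each
#' module draws from a named substream so that, e.g., regenerating the
#' intensities does not perturb the locus universe. The substream seed is a
#' deterministic 31-bit hash of the parent seed and the stream name.
#'
#' @param seed Integer parent seed.
#' @param name Character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_prob <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1 ||
      (!allow_zero && x == 0)) {
    stop(sprintf("`%s` must be a single probability in [0, 1], got %s",
                 name, deparse(x)), call. = FALSE)
  }
  invisible(x)
}

check_fractions <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric with no NA", name), call. = FALSE)
  }
  if (any(x < 0)) {
    bad <- names(x)[x < 0]
    if (is.null(bad) || !length(bad)) bad <- which(x < 0)
    stop(sprintf("`%s` has negative entries: %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (sum(x) > 1 + 1e-12) {
    stop(sprintf("`%s` entries sum to %.4f, which exceeds 1", name, sum(x)),
         call. = FALSE)
  }
  invisible(x)
}

is_call_matrix <- function(m) {
  is.matrix(m) && is.character(m) && !is.null(rownames(m)) && !is.null(colnames(m))
}

assert_call_matrix <- function(m, name = "matrix") {
  if (!is_call_matrix(m)) {
    stop(sprintf("`%s` must be a character matrix with sample rownames and locus colnames",
                 name), call. = FALSE)
  }
  bad <- !(m %in% c(GENOTYPES, NO_CALL))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("`%s` contains invalid call '%s' at sample '%s', locus '%s'",
                 name, m[idx[1], idx[2]], rownames(m)[idx[1]],
                 colnames(m)[idx[2]]), call. = FALSE)
  }
  invisible(m)
}
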