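# File formats: tab-delimited tables (UTF-8, mandatory header, NC as the
# single missing-genotype token), cluster-file JSON, panel lists, a minimal
# VCF 4.2 export, and the YAML scenario configuration.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

read_tsv <- function(path, required, what = "table") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' lacks column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read / write a genotype matrix
#'
#' Tab-delimited, UTF-8, header row mandatory: first column `sample_id`, one
#' column per locus, cells in AA/AB/BB/NC. Duplicate sample or locus ids and
#' malformed cells are rejected with their coordinates.
#'
#' @param path File path.
#' @return Samples x loci character matrix.
#' @export
read_genotype_matrix <- function(path) {
  df <- read_tsv(path, "sample_id", "genotype matrix")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  loci <- setdiff(names(df), "sample_id")
  if (anyDuplicated(loci)) {
    stop("duplicate locus id(s): ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, loci, drop = FALSE])
  rownames(m) <- df$sample_id
  bad <- !(m %in% c(GENOTYPES, NO_CALL))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed call '%s' at row '%s', column '%s'",
                 m[idx[1], idx[2]], rownames(m)[idx[1]], loci[idx[2]]),
         call. = FALSE)
  }
  m
}

#' @rdname read_genotype_matrix
#' @param calls Samples x loci call matrix (or `genotype_calls`).
#' @export
write_genotype_matrix <- function(calls, path) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  df <- data.frame(sample_id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write a locus map
#'
#' Columns: `locus_id`, `chromosome`, `position`, `genic_category`,
#' `genic_region_id`, `copy_number`, `designability`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_locus_map <- function(path) {
  read_tsv(path, c("locus_id", "chromosome", "position", "genic_category",
                   "genic_region_id", "copy_number", "designability"),
           "locus map")
}

#' @rdname read_locus_map
#' @param loci Locus map data frame (e.g. `universe$loci`).
#' @export
write_locus_map <- function(loci, path) {
  write_tsv(loci, path)
}

#' Read / write sample metadata
#'
#' Columns: `sample_id`, `role`, `group`, `parent1_id`, `parent2_id`,
#' `duplicate_of`, `purity`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  read_tsv(path, c("sample_id", "role"), "sample metadata")
}

#' @rdname read_sample_metadata
#' @param samples Sample metadata data frame.
#' @export
write_sample_metadata <- function(samples, path) {
  write_tsv(samples, path)
}

#' Read / write a long-format intensity table
#'
#' Columns: `sample_id`, `locus_id`, `x`, `y`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_intensities <- function(path) {
  df <- read_tsv(path, c("sample_id", "locus_id", "x", "y"), "intensity")
  if (any(df$x < 0) || any(df$y < 0)) {
    stop("negative channel signal in ", path, call. = FALSE)
  }
  df
}

#' @rdname read_intensities
#' @param intensities Long-format intensity data frame.
#' @export
write_intensities <- function(intensities, path) {
  write_tsv(intensities, path)
}

CLUSTER_FILE_SCHEMA_VERSION <- "1.0"

#' Read / write a cluster file (JSON)
#'
#' Versioned JSON serialization of a [build_cluster_file()] result.
#'
#' @param cluster_file A `cluster_file`.
#' @param path File path.
#' @export
write_cluster_file <- function(cluster_file, path) {
  stopifnot(inherits(cluster_file, "cluster_file"))
  obj <- list(schema_version = CLUSTER_FILE_SCHEMA_VERSION,
              provenance = cluster_file$provenance,
              config = cluster_file$config,
              loci = cluster_file$loci,
              regions = cluster_file$regions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_cluster_file
#' @return `read_cluster_file()` returns the `cluster_file`.
#' @export
read_cluster_file <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version)) {
    stop("not a cluster file: missing schema_version", call. = FALSE)
  }
  structure(list(regions = as.data.frame(obj$regions),
                 loci = as.data.frame(obj$loci),
                 provenance = obj$provenance,
                 config = obj$config),
            class = "cluster_file")
}

#' Read / write a panel locus list (one id per line)
#'
#' @param panel Character vector of locus ids.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel, path)
  invisible(path)
}

#' @rdname write_panel
#' @return `read_panel()` returns the character vector of ids.
#' @export
read_panel <- function(path) {
  readLines(path)
}

#' Export panel genotypes as minimal VCF 4.2
#'
#' CHROM/POS from the locus map, placeholder alleles REF=A ALT=B, genotypes
#' 0/0, 0/1, 1/1, ./. for AA/AB/BB/NC, records sorted by chromosome then
#' position.
#'
#' @param panel Character vector of panel locus ids.
#' @param locus_map Locus map covering the panel.
#' @param calls Samples x loci call matrix covering the panel.
#' @param path Output path.
#' @export
write_panel_vcf <- function(panel, locus_map, calls, path) {
  if (inherits(calls, "genotype_calls")) calls <- calls$calls
  assert_call_matrix(calls, "calls")
  unmapped <- setdiff(panel, locus_map$locus_id)
  if (length(unmapped)) {
    stop("unmapped loci: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(panel, colnames(calls))
  if (length(absent)) {
    stop("loci absent from call matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  m <- locus_map[match(panel, locus_map$locus_id), , drop = FALSE]
  ord <- order(m$chromosome, m$position)
  m <- m[ord, , drop = FALSE]
  gt_map <- c(AA = "0/0", AB = "0/1", BB = "1/1", NC = "./.")
  gts <- matrix(gt_map[calls[, m$locus_id, drop = FALSE]],
                nrow(calls), nrow(m))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t")
  )
  body <- paste(m$chromosome, m$position, m$locus_id, "A", "B", ".", ".", ".",
                "GT", apply(gts, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

SCENARIO_KEYS <- c("seed", "output_dir", "log_level", "simdata", "signalmodel",
                   "locusqc", "panelselect", "fingerprint_eval")

#' Read / write a scenario configuration (YAML)
#'
#' Nested configuration with a global `seed`, `output_dir`, optional
#' `log_level`, and per-module sections (`simdata`, `signalmodel`, `locusqc`,
#' `panelselect`, `fingerprint_eval`). Unknown top-level keys are rejected;
#' the configuration round-trips through serialization unchanged.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), SCENARIO_KEYS)
  if (length(unknown)) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("scenario must set `seed`", call. = FALSE)
  cfg
}

#' @rdname read_scenario_config
#' @param config Named list of scenario settings.
#' @export
write_scenario_config <- function(config, path) {
  unknown <- setdiff(names(config), SCENARIO_KEYS)
  if (length(unknown)) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}
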