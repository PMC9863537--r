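# Tab-separated IO with column validation. All pipeline tables are plain
# TSV with a header row; unknown columns are preserved.

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_checked <- function(path, required, numeric_cols = character(0)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(tab))) {
    v <- tab[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad)) {
        stop(sprintf("malformed numeric value in column '%s', row %d: '%s'",
                     col, bad[1], v[bad[1]]), call. = FALSE)
      }
      tab[[col]] <- num
    }
  }
  tab
}

#' Read a long-format intensity table
#'
#' Expects columns `sample`, `probe`, `chrom`, `pos`, `lrr`, `baf` and
#' validates that positions are positive and BAF lies in \[0, 1\].
#'
#' @param path TSV path.
#' @param manifest Optional region manifest; when supplied the result is
#'   returned as an [as_intensity_set()] object, otherwise as the raw
#'   validated data frame.
#' @return Data frame or `intensity_set`.
#' @export
read_intensities <- function(path, manifest = NULL) {
  tab <- read_tsv_checked(path,
                          required = c("sample", "probe", "chrom", "pos",
                                       "lrr", "baf"),
                          numeric_cols = c("pos", "lrr", "baf"))
  tab$chrom <- as.character(tab$chrom)
  if (nrow(tab)) {
    bad <- which(!is.na(tab$pos) & tab$pos <= 0)
    if (length(bad)) stop("non-positive position at row ", bad[1],
                          call. = FALSE)
    bad <- which(!is.na(tab$baf) & (tab$baf < 0 | tab$baf > 1))
    if (length(bad)) {
      stop(sprintf("BAF out of [0, 1] at row %d (value %g)",
                   bad[1], tab$baf[bad[1]]), call. = FALSE)
    }
    dup <- duplicated(tab[c("sample", "probe")])
    if (any(dup)) stop("duplicate (sample, probe) row at row ",
                       which(dup)[1], call. = FALSE)
  }
  if (is.null(manifest)) tab else as_intensity_set(tab, manifest)
}

#' Read an instrument-weights table
#'
#' Expects columns `variant`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta` and optionally `maf`, `r2`.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_weights <- function(path) {
  tab <- read_tsv_checked(path,
                          required = c("variant", "chrom", "pos",
                                       "effect_allele", "other_allele",
                                       "beta"),
                          numeric_cols = c("pos", "beta", "maf", "r2"))
  if (nrow(tab)) {
    if (anyDuplicated(tab$variant)) {
      stop("duplicate variant id: ",
           tab$variant[duplicated(tab$variant)][1], call. = FALSE)
    }
    same <- which(tab$effect_allele == tab$other_allele)
    if (length(same)) stop("effect and other allele identical at row ",
                           same[1], call. = FALSE)
    if (any(!is.finite(tab$beta))) stop("non-finite beta", call. = FALSE)
  }
  tab
}

#' Read a phenotype table
#'
#' Expects at least `sample`, `sex`, `age`; all other columns (APOE,
#' diagnosis, follow-up, biomarkers, PCs, ...) are preserved as-is.
#'
#' @param path TSV path.
#' @return Validated data frame with a logical `male` column added.
#' @export
read_phenotypes <- function(path) {
  tab <- read_tsv_checked(path, required = c("sample", "sex", "age"),
                          numeric_cols = c("age", "apoe", "time", "pc1",
                                           "pc2"))
  if (nrow(tab)) {
    bad <- which(!tab$sex %in% c("male", "female"))
    if (length(bad)) stop("unknown sex at row ", bad[1], call. = FALSE)
    if (!"male" %in% names(tab)) tab$male <- tab$sex == "male"
    if (is.character(tab$male)) tab$male <- tab$male == "TRUE"
  } else if (!"male" %in% names(tab)) {
    tab$male <- logical(0)
  }
  tab
}

#' Read a probe-region manifest
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `region`, 1-based
#' inclusive coordinates.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_probe_manifest <- function(path) {
  tab <- read_tsv_checked(path, required = c("chrom", "start", "end",
                                             "region"),
                          numeric_cols = c("start", "end"))
  tab$chrom <- as.character(tab$chrom)
  if (nrow(tab) && any(tab$end < tab$start)) {
    stop("manifest interval with end < start", call. = FALSE)
  }
  tab
}
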