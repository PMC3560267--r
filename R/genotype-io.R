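#' Read a case-control genotype table
#'
#' Reads an MDR-style flat file (tab-delimited, header row, one subject per
#' row, genotype columns coded 0/1/2 followed by a binary class column) or a
#' CSV with the same schema.  Genotype codes are validated on load: every
#' non-class cell must be 0 (homozygous reference), 1 (heterozygous) or
#' 2 (homozygous variant), and the class column must be 0/1 with both
#' classes present (1 = case/affected).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by extension; `.csv` means comma), `"mdr-flat"`
#'   (tab-delimited) or `"csv"`.
#' @param class_column Name of the phenotype column. Default `"Class"`.
#' @param missing How to handle missing genotype cells: `"fail"` (default)
#'   stops with the offending cells listed; `"drop-subject"` removes the
#'   affected rows and reports how many were dropped.
#' @param na Tokens treated as missing, in addition to empty cells.
#' @param recode Optional named vector mapping non-standard genotype codes to
#'   0/1/2, e.g. `c(AA = 0, Aa = 1, aa = 2)`.
#' @param quiet Suppress the load summary message.
#' @return A tibble with one row per subject: genotype columns (integer
#'   0/1/2) and the class column (integer 0/1). Row order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("SNP1\tSNP2\tClass", "0\t1\t1", "2\t0\t0"), tf)
#' read_genotype_table(tf, quiet = TRUE)
#' @export
read_genotype_table <- function(path,
                                dialect = c("auto", "mdr-flat", "csv"),
                                class_column = "Class",
                                missing = c("fail", "drop-subject"),
                                na = c("", "NA", "?"),
                                recode = NULL,
                                quiet = FALSE) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "mdr-flat"
  }
  df <- if (dialect == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = na, progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = na, progress = FALSE)
  }
  if (!class_column %in% names(df)) {
    abort(sprintf("class column '%s' not found in %s", class_column, path))
  }
  snp_cols <- setdiff(names(df), class_column)
  if (!length(snp_cols)) abort("no genotype columns found")

  geno <- as.matrix(df[snp_cols])
  if (!is.null(recode)) {
    hit <- geno %in% names(recode)
    geno[hit] <- as.character(recode[geno[hit]])
  }

  miss_idx <- which(is.na(geno), arr.ind = TRUE)
  if (nrow(miss_idx)) {
    cells <- apply(head(miss_idx, 10), 1, function(rc) {
      sprintf("row %d, column '%s'", rc[1], snp_cols[rc[2]])
    })
    if (missing == "fail") {
      abort(paste0("missing genotype value(s) at: ",
                   paste(cells, collapse = "; "),
                   if (nrow(miss_idx) > 10) sprintf(" (and %d more)", nrow(miss_idx) - 10)))
    }
    drop_rows <- unique(miss_idx[, 1])
    df <- df[-drop_rows, , drop = FALSE]
    geno <- geno[-drop_rows, , drop = FALSE]
    if (!quiet) inform(sprintf("dropped %d subject(s) with missing genotypes",
                               length(drop_rows)))
  }

  suppressWarnings(num <- matrix(as.numeric(geno), nrow = nrow(geno)))
  bad <- which(is.na(num) | !(num %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(geno))
    abort(sprintf(
      "unparseable genotype code '%s' at row %d, column '%s' (expected 0/1/2)",
      geno[bad[1]], rc[1], snp_cols[rc[2]]))
  }

  suppressWarnings(pheno <- as.numeric(df[[class_column]]))
  if (anyNA(pheno) || !all(pheno %in% c(0, 1))) {
    abort(sprintf("class column '%s' must contain only 0/1", class_column))
  }
  if (length(unique(pheno)) < 2L) {
    abort("phenotype must contain both cases (1) and controls (0)")
  }

  out <- tibble::as_tibble(as.data.frame(num))
  names(out) <- snp_cols
  out[] <- lapply(out, as.integer)
  out[[class_column]] <- as.integer(pheno)
  if (!quiet) {
    inform(sprintf(
      "loaded %d subjects x %d SNPs (%d cases / %d controls, case fraction %.3f)",
      nrow(out), length(snp_cols), sum(pheno == 1), sum(pheno == 0),
      mean(pheno == 1)))
  }
  out
}

#' Write a genotype table to an MDR-style flat file
#'
#' @param data Tibble as returned by [read_genotype_table()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @param dialect `"mdr-flat"` (tab) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(data, path, dialect = c("mdr-flat", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    readr::write_tsv(data, path, progress = FALSE)
  }
  invisible(path)
}

#' Write interaction results to a TSV file
#'
#' Serialises the per-pair statistics table produced by
#' [amdr_interactions()]: locus labels, the calibrated pOR/pRR/pChi with
#' their 95% resampling confidence intervals, permutation p-values and
#' FDR-adjusted p-values.  Values round-trip through
#' [read_interaction_results()] at full double precision.
#'
#' @param results An `amdr_interactions` tibble (non-empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  if (!nrow(results)) abort("empty result set; refusing to write an empty file")
  flat <- results
  # ";" separators: a comma would collide with readr's grouping mark
  flat$loci <- vapply(results$loci, paste, character(1), collapse = ";")
  flat$high_risk_cells <- vapply(results$high_risk_cells, paste, character(1),
                                 collapse = ";")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Read back an interaction results TSV
#'
#' @param path Path written by [write_interaction_results()].
#' @return A tibble with the same columns; `loci` and `high_risk_cells`
#'   are restored as list-columns of integers.
#' @export
read_interaction_results <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  df$loci <- lapply(strsplit(as.character(df$loci), ";"), as.integer)
  df$high_risk_cells <- lapply(
    strsplit(ifelse(is.na(df$high_risk_cells), "", as.character(df$high_risk_cells)), ";"),
    as.integer)
  df
}

#' Write per-subject risk scores to a TSV file
#'
#' @param profile An `amdr_profile` object from [amdr_risk_profile()], or a
#'   tibble with columns `subject_id`, `score`, `phenotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_scores <- function(profile, path) {
  scores <- if (inherits(profile, "amdr_profile")) profile$scores else profile
  stopifnot(all(c("subject_id", "score", "phenotype") %in% names(scores)))
  readr::write_tsv(scores[c("subject_id", "score", "phenotype")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read back a risk-score TSV
#'
#' @param path Path written by [write_risk_scores()].
#' @return A tibble `subject_id`, `score`, `phenotype`.
#' @export
read_risk_scores <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    score = readr::col_double(),
    phenotype = readr::col_integer()), progress = FALSE)
}
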