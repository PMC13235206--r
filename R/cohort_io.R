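# Canonical data model, TSV readers/writers and the merged analytical table.
# All tables are plain data.frames keyed by `patient_id`; missing values are NA
# throughout and are serialized as empty fields (never 0 -- no imputation).

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Truncate a sample-level barcode to the 12-character patient barcode
#'
#' TCGA-style sample codes (`TCGA-AB-1234-01A`) are cut to the patient-level
#' prefix (`TCGA-AB-1234`) so that per-sample sources can be merged with
#' patient-level sources.
#'
#' @param sample_code Character vector of barcodes, each at least 12 characters.
#' @return Character vector of 12-character patient barcodes.
#' @examples
#' truncate_barcode("TCGA-AB-1234-01A")
#' @export
truncate_barcode <- function(sample_code) {
  if (!is.character(sample_code)) {
    stop("`sample_code` must be a character vector", call. = FALSE)
  }
  bad <- !is.na(sample_code) & nchar(sample_code) < 12L
  if (any(bad)) {
    stop(
      "identifier error: barcode(s) shorter than 12 characters: ",
      paste(utils::head(sample_code[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  substr(sample_code, 1L, 12L)
}

# Required epitope columns in the internal schema.
.epitope_fields <- c(
  "patient_id", "gene_symbol", "peptide", "hla_allele",
  "ic50_nm", "wt_ic50_nm", "vaf", "variant_id"
)

#' Default column mapping for pVACseq-style aggregate epitope tables
#'
#' Maps internal field names to the headers found in pVACseq "all_epitopes"
#' output. Pass (a modified copy of) this to [read_epitope_table()] when
#' reading upstream output directly.
#'
#' @return Named character vector: internal field -> source column name.
#' @export
pvacseq_column_map <- function() {
  c(
    patient_id  = "Sample Name",
    gene_symbol = "Gene Name",
    peptide     = "MT Epitope Seq",
    hla_allele  = "HLA Allele",
    ic50_nm     = "Median MT IC50 Score",
    wt_ic50_nm  = "Median WT IC50 Score",
    vaf         = "Tumor DNA VAF",
    variant_id  = "Mutation"
  )
}

#' Read and validate a predicted-epitope table
#'
#' Reads a TSV with one row per predicted peptide x HLA restriction, applies
#' the column map, truncates sample barcodes to patient level, validates the
#' record invariants (peptide of 8-11 amino-acid letters, IC50 > 0, VAF in
#' \[0,1\]) and deduplicates on (patient, peptide, allele, variant), keeping
#' the first occurrence with a warning.
#'
#' @param path Path to a tab-separated file with a header row, or a data.frame
#'   already in memory (same validation applied).
#' @param column_map Named character vector mapping internal field names to the
#'   file's column names; defaults to the identity schema.
#' @return A data.frame of validated epitope records with attribute
#'   `"rejected"` holding a data.frame of rejected row numbers and reasons.
#' @export
read_epitope_table <- function(path, column_map = NULL) {
  raw <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  if (is.null(column_map)) {
    column_map <- stats::setNames(.epitope_fields, .epitope_fields)
  }
  missing_cols <- setdiff(.epitope_fields, names(column_map))
  if (length(missing_cols)) {
    stop("column_map lacks required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- stats::setNames(raw[, unname(column_map), drop = FALSE], names(column_map))
  df$ic50_nm <- suppressWarnings(as.numeric(df$ic50_nm))
  df$wt_ic50_nm <- suppressWarnings(as.numeric(df$wt_ic50_nm))
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  df$hla_allele <- gsub("[[:space:]]+", "", as.character(df$hla_allele))
  df$peptide <- toupper(as.character(df$peptide))

  reasons <- character(nrow(df))
  flag <- function(bad, msg) {
    bad <- !is.na(bad) & bad
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], msg, sep = "; "), msg)
  }
  flag(is.na(df$patient_id) | nchar(df$patient_id) < 12L, "patient_id shorter than 12 characters")
  flag(is.na(df$ic50_nm) | df$ic50_nm <= 0, "ic50 missing or non-positive")
  flag(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1, "vaf out of [0,1]")
  flag(!nchar(df$peptide) %in% 8:11, "peptide length outside 8-11")
  flag(grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), df$peptide),
       "peptide contains non-amino-acid characters")

  rejected <- data.frame(row = which(nzchar(reasons)),
                         reason = reasons[nzchar(reasons)],
                         stringsAsFactors = FALSE)
  keep <- df[!nzchar(reasons), , drop = FALSE]
  keep$patient_id <- truncate_barcode(as.character(keep$patient_id))

  key <- paste(keep$patient_id, keep$peptide, keep$hla_allele, keep$variant_id,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate (patient, peptide, allele, variant) row(s); ",
            "keeping first occurrence", call. = FALSE)
    keep <- keep[!dup, , drop = FALSE]
  }
  rownames(keep) <- NULL
  attr(keep, "rejected") <- rejected
  keep
}

#' Read an expression matrix TSV (genes x patients)
#'
#' First column holds gene symbols; remaining headers are patient barcodes
#' (truncated to 12 characters). Values must be non-negative.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene symbols as rownames, patient barcodes as
#'   colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(genes)) stop("duplicate gene symbols", call. = FALSE)
  colnames(mat) <- truncate_barcode(colnames(mat))
  if (anyDuplicated(colnames(mat))) stop("duplicate patient ids", call. = FALSE)
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression values", call. = FALSE)
  rownames(mat) <- genes
  mat
}

#' Write a table as TSV with empty-field missing values
#'
#' Numerics are serialized at full precision (17 significant digits) so that a
#' write/read round trip is bit-identical.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_cohort_tsv()]
#'
#' @param path TSV path.
#' @return data.frame with empty fields as NA and numeric columns restored.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df
}

#' Merge per-patient sources into the analytical cohort table
#'
#' Full outer join of any number of per-patient data.frames on `patient_id`.
#' Unmatched fields become NA; a duplicated patient within any single source
#' is an error naming the source and the id.
#'
#' @param ... Named data.frames, each with a `patient_id` column and at most
#'   one row per patient.
#' @return Merged data.frame, one row per patient, ordered by `patient_id`.
#' @export
merge_cohort <- function(...) {
  sources <- list(...)
  sources <- sources[!vapply(sources, is.null, logical(1))]
  if (!length(sources)) stop("no sources to merge", call. = FALSE)
  nms <- names(sources)
  if (is.null(nms)) nms <- paste0("source", seq_along(sources))
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    if (!"patient_id" %in% names(src)) {
      stop("source '", nms[i], "' lacks a patient_id column", call. = FALSE)
    }
    dups <- unique(src$patient_id[duplicated(src$patient_id)])
    if (length(dups)) {
      stop("duplicate patient_id in source '", nms[i], "': ",
           paste(utils::head(dups, 5L), collapse = ", "), call. = FALSE)
    }
  }
  merged <- Reduce(function(a, b) merge(a, b, by = "patient_id", all = TRUE),
                   sources)
  merged <- merged[order(merged$patient_id), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Restrict a cohort to the survival-complete subset
#'
#' Keeps rows with positive overall-survival time and non-missing Clonality
#' Score, TIDE dysfunction and HPV status, returning the subset together with
#' an exclusion-accounting report (one count per reason; a row may carry
#' several reasons).
#'
#' @param cohort Merged cohort data.frame with columns `os_days`,
#'   `clonality_score`, `tide_dysfunction`, `hpv_positive`.
#' @return The retained subset with attribute `"exclusions"`: a named list
#'   with per-reason counts and `n_excluded`.
#' @export
survival_subset <- function(cohort) {
  no_time <- is.na(cohort$os_days) | cohort$os_days <= 0
  no_clon <- is.na(cohort$clonality_score)
  no_tide <- is.na(cohort$tide_dysfunction)
  no_hpv  <- is.na(cohort$hpv_positive)
  drop <- no_time | no_clon | no_tide | no_hpv
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(
    no_survival_time = sum(no_time),
    missing_clonality = sum(no_clon),
    missing_tide = sum(no_tide),
    missing_hpv = sum(no_hpv),
    n_excluded = sum(drop)
  )
  out
}
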