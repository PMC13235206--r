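# Per-patient neoantigen summarisation: binder classification, binder-weighted
# VAF, the Clonality Score and its sensitivity variants, delta-IC50,
# public/private labeling, gene-level summaries and TMB.

BINDER_IC50_NM <- 500
STRONG_BINDER_IC50_NM <- 50

#' Flag binder and strong-binder peptides
#'
#' A predicted peptide is a binder if IC50 <= 500 nM and a strong binder if
#' IC50 <= 50 nM; both thresholds are inclusive.
#'
#' @param records Epitope data.frame with an `ic50_nm` column.
#' @return `records` with logical columns `binder` and `strong_binder` added.
#' @export
classify_binders <- function(records) {
  records$binder <- !is.na(records$ic50_nm) & records$ic50_nm <= BINDER_IC50_NM
  records$strong_binder <- !is.na(records$ic50_nm) &
    records$ic50_nm <= STRONG_BINDER_IC50_NM
  records
}

#' Binder-weighted VAF for one patient
#'
#' Sum of source-variant VAFs over all binder peptides (IC50 <= 500 nM). A
#' variant yielding k binder peptides contributes k times its VAF, so the
#' metric weights mutations by both VAF and peptide yield.
#'
#' @param records Epitope data.frame for a single patient.
#' @return Non-negative scalar; 0 for empty input.
#' @export
binder_weighted_vaf <- function(records) {
  if (!nrow(records)) return(0)
  records <- classify_binders(records)
  sum(records$vaf[records$binder])
}

#' Clonality Score
#'
#' Binder-weighted VAF divided by the binder count plus one. The pseudocount
#' keeps the score defined (zero) for tumours without predicted binders.
#'
#' @param bwv Binder-weighted VAF (>= 0).
#' @param neo_n_500 Number of binder peptides (>= 0).
#' @return `bwv / (neo_n_500 + 1)`.
#' @export
clonality_score <- function(bwv, neo_n_500) {
  stopifnot(all(bwv >= 0, na.rm = TRUE), all(neo_n_500 >= 0, na.rm = TRUE))
  bwv / (neo_n_500 + 1)
}

#' Alternative clonality metrics for sensitivity analysis
#'
#' @param records Epitope data.frame for a single patient.
#' @param log_eps Offset added inside the log for the log-transformed score.
#' @return Named list: `raw_bwv`, `mean_vaf_per_binder` (NA with no binders),
#'   `bwv_over_total`, `log_clonality`.
#' @export
clonality_variants <- function(records, log_eps = 1e-6) {
  records <- classify_binders(records)
  bwv <- sum(records$vaf[records$binder])
  n500 <- sum(records$binder)
  n_total <- nrow(records)
  list(
    raw_bwv = bwv,
    mean_vaf_per_binder = if (n500 > 0) bwv / n500 else NA_real_,
    bwv_over_total = bwv / (n_total + 1),
    log_clonality = log(clonality_score(bwv, n500) + log_eps)
  )
}

#' Mean change in predicted binding affinity versus wild type
#'
#' Convention: mean of log10(mutant IC50 / wild-type IC50) over peptides with
#' a wild-type affinity (scale-free; negative values mean the mutant binds
#' more strongly). Set `convention = "difference"` for the raw nanomolar
#' difference mutant - wild type.
#'
#' @param records Epitope data.frame with `ic50_nm` and `wt_ic50_nm`.
#' @param convention `"log10_ratio"` (default) or `"difference"`.
#' @return Scalar mean; NA if no record has a wild-type affinity.
#' @export
mean_delta_ic50 <- function(records, convention = c("log10_ratio", "difference")) {
  convention <- match.arg(convention)
  ok <- !is.na(records$wt_ic50_nm) & !is.na(records$ic50_nm)
  if (!any(ok)) return(NA_real_)
  mut <- records$ic50_nm[ok]
  wt <- records$wt_ic50_nm[ok]
  if (convention == "log10_ratio") mean(log10(mut / wt)) else mean(mut - wt)
}

#' Label peptides public or private across the cohort
#'
#' A peptide sequence is public when it is predicted identically in at least
#' two distinct patients; peptides unique to one patient are private. The
#' criterion is sequence identity only (a peptide seen twice in one patient on
#' two alleles stays private). Set `allele_matched = TRUE` to additionally
#' require a shared HLA restriction, in which case the unit of sharing is the
#' (peptide, allele) pair.
#'
#' @param records Cohort-wide epitope data.frame.
#' @param allele_matched Require a shared allele for publicness.
#' @return List with `public_peptides` (character vector), `per_patient`
#'   (data.frame: patient_id, n_public, n_private, n_distinct) and cohort
#'   totals `n_public_total`, `n_private_total`.
#' @export
label_public_private <- function(records, allele_matched = FALSE) {
  unit <- if (allele_matched) {
    paste(records$peptide, records$hla_allele, sep = "|")
  } else {
    records$peptide
  }
  pp <- unique(data.frame(unit = unit, patient_id = records$patient_id,
                          peptide = records$peptide, stringsAsFactors = FALSE))
  n_pat <- table(pp$unit)
  public_units <- names(n_pat)[n_pat >= 2L]
  pp$public <- pp$unit %in% public_units
  agg <- stats::aggregate(cbind(n_public = pp$public, n_distinct = rep(1L, nrow(pp))),
                          by = list(patient_id = pp$patient_id), FUN = sum)
  agg$n_private <- agg$n_distinct - agg$n_public
  universe <- unique(pp$peptide[pp$public])
  list(
    public_peptides = universe,
    per_patient = agg[, c("patient_id", "n_public", "n_private", "n_distinct")],
    n_public_total = length(unique(pp$unit[pp$public])),
    n_private_total = length(unique(pp$unit[!pp$public]))
  )
}

#' Dominant neoantigen-producing gene for one patient
#'
#' The gene generating the most binder peptides; ties broken lexicographically
#' with a warning.
#'
#' @param records Epitope data.frame for a single patient.
#' @return Gene symbol, or NA if the patient has no binders.
#' @export
dominant_gene <- function(records) {
  records <- classify_binders(records)
  b <- records[records$binder, , drop = FALSE]
  if (!nrow(b)) return(NA_character_)
  counts <- sort(table(b$gene_symbol), decreasing = TRUE)
  top <- names(counts)[counts == counts[1L]]
  if (length(top) > 1L) {
    warning("dominant gene tie among {", paste(sort(top), collapse = ", "),
            "}; keeping lexicographically first", call. = FALSE)
  }
  sort(top)[1L]
}

#' Tumour mutational burden
#'
#' @param n_nonsynonymous Count of non-synonymous coding mutations.
#' @param covered_mb Megabases of coding sequence covered (> 0).
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(n_nonsynonymous, covered_mb) {
  if (any(covered_mb <= 0)) stop("covered_mb must be positive", call. = FALSE)
  n_nonsynonymous / covered_mb
}

#' Summarise neoantigen features for every patient
#'
#' Computes, per patient: total/binder/strong-binder counts, counts by peptide
#' length, binder-weighted VAF, Clonality Score and its variants, best binder
#' IC50, mean delta-IC50, and public/private counts (cohort-wide labeling).
#'
#' @param records Cohort-wide epitope data.frame (see [read_epitope_table()]).
#' @param log_eps Offset for the log-transformed clonality variant.
#' @param delta_convention Passed to [mean_delta_ic50()].
#' @return data.frame with one row per patient.
#' @export
summarize_neoantigens <- function(records, log_eps = 1e-6,
                                  delta_convention = "log10_ratio") {
  records <- classify_binders(records)
  pub <- label_public_private(records)
  by_patient <- split(records, records$patient_id)
  rows <- lapply(by_patient, function(r) {
    id <- r$patient_id[1L]
    bwv <- sum(r$vaf[r$binder])
    n500 <- sum(r$binder)
    n50 <- sum(r$strong_binder)
    lens <- table(factor(nchar(r$peptide), levels = 8:11))
    variants <- clonality_variants(r, log_eps = log_eps)
    data.frame(
      patient_id = id,
      neo_n_total = nrow(r),
      neo_n_500 = n500,
      neo_n_50 = n50,
      neo_frac_strong = if (n500 > 0) n50 / n500 else NA_real_,
      len_8 = as.integer(lens[["8"]]), len_9 = as.integer(lens[["9"]]),
      len_10 = as.integer(lens[["10"]]), len_11 = as.integer(lens[["11"]]),
      binder_weighted_vaf = bwv,
      clonality_score = clonality_score(bwv, n500),
      raw_bwv = variants$raw_bwv,
      mean_vaf_per_binder = variants$mean_vaf_per_binder,
      bwv_over_total = variants$bwv_over_total,
      log_clonality = variants$log_clonality,
      best_ic50 = if (n500 > 0) min(r$ic50_nm[r$binder]) else NA_real_,
      mean_delta_ic50 = mean_delta_ic50(r, delta_convention),
      dominant_gene = suppressWarnings(dominant_gene(r)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- merge(out, pub$per_patient, by = "patient_id", all.x = TRUE)
  out$n_public <- ifelse(is.na(out$n_public), 0L, out$n_public)
  out$n_private <- ifelse(is.na(out$n_private), 0L, out$n_private)
  out$n_distinct <- ifelse(is.na(out$n_distinct), 0L, out$n_distinct)
  out[order(out$patient_id), , drop = FALSE]
}

#' Gene-level neoantigen summary across the cohort
#'
#' For every gene with at least one predicted neoantigen: the number of
#' tumours harbouring one, the median per-tumour binder count from that gene,
#' the median fraction of those binders that are strong, the number of
#' patients in which the gene is the dominant neoantigen source, and medians
#' of TIDE dysfunction/exclusion and PD-L1 among harbouring patients (when a
#' cohort table with those columns is supplied).
#'
#' @param records Cohort-wide epitope data.frame.
#' @param cohort Optional cohort data.frame with `patient_id`,
#'   `tide_dysfunction`, `tide_exclusion`, `pdl1` columns.
#' @return data.frame with one row per gene, sorted by patient count.
#' @export
gene_level_summary <- function(records, cohort = NULL) {
  records <- classify_binders(records)
  b <- records[records$binder, , drop = FALSE]
  if (!nrow(b)) return(data.frame())
  per_pg <- stats::aggregate(
    cbind(n_binders = rep(1L, nrow(b)), n_strong = as.integer(b$strong_binder)),
    by = list(gene_symbol = b$gene_symbol, patient_id = b$patient_id), FUN = sum)
  per_pg$frac_strong <- per_pg$n_strong / per_pg$n_binders

  dom <- vapply(split(records, records$patient_id),
                function(r) suppressWarnings(dominant_gene(r)), character(1))
  dom_tab <- table(dom[!is.na(dom)])

  ctx <- function(gene, col) {
    if (is.null(cohort) || !col %in% names(cohort)) return(NA_real_)
    ids <- unique(per_pg$patient_id[per_pg$gene_symbol == gene])
    stats::median(cohort[[col]][cohort$patient_id %in% ids], na.rm = TRUE)
  }
  genes <- unique(per_pg$gene_symbol)
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- per_pg[per_pg$gene_symbol == g, , drop = FALSE]
    data.frame(
      gene_symbol = g,
      n_patients_with_neo = nrow(sub),
      median_neo_n_500 = stats::median(sub$n_binders),
      median_frac_strong = stats::median(sub$frac_strong),
      n_patients_dominant = if (g %in% names(dom_tab)) as.integer(dom_tab[[g]]) else 0L,
      median_tide_dysfunction = ctx(g, "tide_dysfunction"),
      median_tide_exclusion = ctx(g, "tide_exclusion"),
      median_pdl1 = ctx(g, "pdl1"),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(-out$n_patients_with_neo, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
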