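# Public-neoepitope population coverage: set-cover curves, HLA allele-group
# ("supertype") stratification, coverage efficiency and combination
# strategies for off-the-shelf vaccine design.

#' Public peptide universe
#'
#' Distinct peptide sequences predicted in at least two different patients.
#'
#' @param records Cohort-wide epitope data.frame.
#' @return Character vector of public peptide sequences.
#' @export
public_universe <- function(records) {
  label_public_private(records)$public_peptides
}

.patient_public_sets <- function(records, universe = NULL) {
  if (is.null(universe)) universe <- public_universe(records)
  pp <- unique(records[records$peptide %in% universe,
                       c("patient_id", "peptide")])
  split(pp$peptide, pp$patient_id)
}

#' Set-cover curve over the public peptide universe
#'
#' Patients are ranked by descending public-peptide count (ties by patient
#' id); the curve gives the cumulative fraction of the public universe covered
#' by the union of the first k patients' public sets. `greedy = TRUE` instead
#' re-ranks at each step by marginal gain (classical greedy set cover).
#'
#' @param public_sets Named list: patient -> character vector of public
#'   peptides (see output of internal helper, or pass `records` instead).
#' @param records Optional epitope data.frame from which to derive the sets.
#' @param greedy Rank by marginal set-cover gain instead of public count.
#' @return data.frame: `rank`, `patient_id`, `n_public`,
#'   `cumulative_fraction`; attribute `universe_size`.
#' @export
set_cover_curve <- function(public_sets = NULL, records = NULL,
                            greedy = FALSE) {
  if (is.null(public_sets)) {
    stopifnot(!is.null(records))
    public_sets <- .patient_public_sets(records)
  }
  universe <- unique(unlist(public_sets, use.names = FALSE))
  if (!length(universe)) stop("empty public universe", call. = FALSE)
  counts <- vapply(public_sets, length, integer(1))
  if (greedy) {
    order_ids <- character(0)
    covered <- character(0)
    remaining <- public_sets
    while (length(remaining)) {
      gain <- vapply(remaining, function(s) length(setdiff(s, covered)),
                     integer(1))
      pick <- names(remaining)[order(-gain, names(remaining))][1L]
      order_ids <- c(order_ids, pick)
      covered <- union(covered, remaining[[pick]])
      remaining[[pick]] <- NULL
    }
  } else {
    order_ids <- names(public_sets)[order(-counts, names(public_sets))]
  }
  seen <- new.env(hash = TRUE, size = length(universe))
  cum <- numeric(length(order_ids))
  total <- 0L
  for (i in seq_along(order_ids)) {
    for (pep in public_sets[[order_ids[i]]]) {
      if (is.null(seen[[pep]])) { seen[[pep]] <- TRUE; total <- total + 1L }
    }
    cum[i] <- total / length(universe)
  }
  out <- data.frame(rank = seq_along(order_ids), patient_id = order_ids,
                    n_public = counts[order_ids],
                    cumulative_fraction = cum, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "universe_size") <- length(universe)
  out
}

#' Map an HLA allele to its allele-group "supertype"
#'
#' Gene letter plus the two-digit first allele field, e.g. `HLA-C*07:02`
#' becomes `C07`. Unparseable strings fall into `"Other"`. A named lookup
#' table can override individual alleles.
#'
#' @param hla_allele Character vector of allele strings.
#' @param lookup Optional named character vector: allele -> supertype.
#' @return Character vector of supertype labels.
#' @export
assign_supertype <- function(hla_allele, lookup = NULL) {
  out <- rep("Other", length(hla_allele))
  if (!is.null(lookup)) {
    hit <- hla_allele %in% names(lookup)
    out[hit] <- unname(lookup[hla_allele[hit]])
  }
  m <- regmatches(hla_allele,
                  regexec("^HLA-([A-C])\\*([0-9]{2,3}):", hla_allele))
  parsed <- vapply(m, function(g) {
    if (length(g) == 3L) paste0(g[2L], substr(g[3L], 1L, 2L)) else NA_character_
  }, character(1))
  use <- !is.na(parsed)
  if (!is.null(lookup)) use <- use & !(hla_allele %in% names(lookup))
  out[use] <- parsed[use]
  out
}

#' Top-ranked HLA allele and supertype per patient
#'
#' The allele restricting the most binder peptides (ties lexicographic with a
#' warning), its supertype, and the patient's public peptide count.
#'
#' @param records Cohort-wide epitope data.frame.
#' @return data.frame: `patient_id`, `top_allele`, `supertype`,
#'   `n_public_peptides` (patients without binders are omitted).
#' @export
patient_top_allele <- function(records) {
  records <- classify_binders(records)
  pub <- label_public_private(records)$per_patient
  b <- records[records$binder, , drop = FALSE]
  rows <- lapply(split(b, b$patient_id), function(r) {
    counts <- sort(table(r$hla_allele), decreasing = TRUE)
    top <- names(counts)[counts == counts[1L]]
    if (length(top) > 1L) {
      warning("top-allele tie for ", r$patient_id[1L],
              "; keeping lexicographically first", call. = FALSE)
    }
    data.frame(patient_id = r$patient_id[1L], top_allele = sort(top)[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$supertype <- assign_supertype(out$top_allele)
  out <- merge(out, pub[, c("patient_id", "n_public")], by = "patient_id",
               all.x = TRUE)
  out$n_public[is.na(out$n_public)] <- 0L
  names(out)[names(out) == "n_public"] <- "n_public_peptides"
  rownames(out) <- NULL
  out
}

#' Per-supertype coverage efficiency
#'
#' For each supertype, the fraction of the global public universe covered by
#' the union of the public sets of its top `top_k` patients (fewer when the
#' group is smaller), patients ranked by public count.
#'
#' @param records Cohort-wide epitope data.frame.
#' @param assignments Output of [patient_top_allele()] (computed if NULL).
#' @param top_k Patients taken per supertype (default 10).
#' @return data.frame: `supertype`, `n_patients`, `n_used`, `fraction`.
#' @export
coverage_efficiency <- function(records, assignments = NULL, top_k = 10L) {
  if (is.null(assignments)) assignments <- patient_top_allele(records)
  universe <- public_universe(records)
  if (!length(universe)) stop("empty public universe", call. = FALSE)
  sets <- .patient_public_sets(records, universe)
  rows <- lapply(split(assignments, assignments$supertype), function(gr) {
    gr <- gr[order(-gr$n_public_peptides, gr$patient_id), , drop = FALSE]
    use <- utils::head(gr$patient_id, top_k)
    covered <- unique(unlist(sets[intersect(use, names(sets))],
                             use.names = FALSE))
    data.frame(supertype = gr$supertype[1L], n_patients = nrow(gr),
               n_used = length(use),
               fraction = length(covered) / length(universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage of a multi-supertype combination strategy
#'
#' Pools, over the listed supertypes, each group's top
#' `min(patients_per, group size)` patients by public count, deduplicates the
#' pool and reports its size and the fraction of the global public universe
#' covered by the union of its public sets.
#'
#' @param records Cohort-wide epitope data.frame.
#' @param strategy Character vector of supertype labels (may include
#'   `"Other"`).
#' @param patients_per Patients drawn per supertype.
#' @param assignments Output of [patient_top_allele()] (computed if NULL).
#' @return List: `strategy`, `patients_per`, `total_patients`,
#'   `coverage_fraction`.
#' @export
strategy_coverage <- function(records, strategy, patients_per = 10L,
                              assignments = NULL) {
  if (is.null(assignments)) assignments <- patient_top_allele(records)
  unknown <- setdiff(strategy, assignments$supertype)
  if (length(unknown)) {
    stop("unknown supertype(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  universe <- public_universe(records)
  if (!length(universe)) stop("empty public universe", call. = FALSE)
  sets <- .patient_public_sets(records, universe)
  pool <- character(0)
  for (st in strategy) {
    gr <- assignments[assignments$supertype == st, , drop = FALSE]
    gr <- gr[order(-gr$n_public_peptides, gr$patient_id), , drop = FALSE]
    pool <- union(pool, utils::head(gr$patient_id, patients_per))
  }
  covered <- unique(unlist(sets[intersect(pool, names(sets))],
                           use.names = FALSE))
  list(strategy = strategy, patients_per = patients_per,
       total_patients = length(pool),
       coverage_fraction = length(covered) / length(universe))
}

#' Correlate public peptide burden with immune markers
#'
#' Spearman correlations of the per-patient public peptide count with PD-L1
#' expression and cytolytic activity, overall and (optionally) within each
#' supertype group.
#'
#' @param cohort Cohort data.frame with `n_public`, `pdl1`, `cyt` and (for
#'   stratified mode) `supertype` columns.
#' @param by_supertype Also compute within-supertype correlations (groups
#'   with fewer than `min_n` complete pairs are skipped).
#' @param min_n Minimum pairs for a stratum (default 5).
#' @return data.frame: `stratum`, `marker`, `n`, `rho`, `p_value`.
#' @export
public_burden_correlations <- function(cohort, by_supertype = FALSE,
                                       min_n = 5L) {
  one <- function(df, stratum) {
    do.call(rbind, lapply(c("pdl1", "cyt"), function(marker) {
      ok <- stats::complete.cases(df$n_public, df[[marker]])
      if (sum(ok) < max(3L, min_n)) return(NULL)
      res <- spearman(df$n_public, df[[marker]])
      data.frame(stratum = stratum, marker = marker, n = res$n,
                 rho = res$rho, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one(cohort, "overall")
  if (by_supertype) {
    for (st in sort(unique(stats::na.omit(cohort$supertype)))) {
      out <- rbind(out, one(cohort[cohort$supertype %in% st, , drop = FALSE],
                            st))
    }
  }
  rownames(out) <- NULL
  out
}
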