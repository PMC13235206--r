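# End-to-end orchestration: summarize -> score -> correlate -> phenotype ->
# coverage -> survival, with TSV/JSON outputs and a run manifest. Outputs are
# pure functions of the inputs and the seed, so reruns are byte-identical.

#' Default correlation battery: clonality versus the immune readouts
#'
#' The plain Spearman family pairs the Clonality Score with the mutational
#' burden metrics and the eight immune readouts; the partial rows control the
#' exhaustion/CYT correlations for the Pan-Immune proxy.
#'
#' @return data.frame with columns `x`, `y`, `covariate` understood by
#'   [correlation_battery()].
#' @export
default_battery_spec <- function() {
  ys <- c("neo_n_500", "tmb",
          "score_exhaustion", "score_core_exhaustion", "pan_immune",
          "score_immunosuppressive", "score_cyt", "tide_dysfunction",
          "tide_exclusion", "score_antigen_presentation",
          "score_mhc_class_i", "score_ifng")
  plain <- data.frame(x = "clonality_score", y = ys,
                      covariate = NA_character_, stringsAsFactors = FALSE)
  partial <- data.frame(
    x = "clonality_score",
    y = c("score_exhaustion", "score_cyt", "tide_dysfunction"),
    covariate = "pan_immune", stringsAsFactors = FALSE)
  rbind(plain, partial)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Sequences the analysis stages on in-memory input tables: per-patient
#' neoantigen summarisation, signature scoring, cohort merge, the correlation
#' battery, four-phenotype classification with clustering validation, public
#' peptide coverage, and the survival model suite. When `out_dir` is given,
#' every stage's table is written as TSV/JSON together with a run manifest.
#'
#' @param epitopes Cohort-wide epitope data.frame ([read_epitope_table()]
#'   schema).
#' @param expression Expression matrix, genes x patients.
#' @param clinical Clinical data.frame (`patient_id`, `age_years`, `stage`,
#'   `advanced_stage`, `hpv_positive`, `os_days`, `os_event`).
#' @param scores External score data.frame (`patient_id`,
#'   `tide_dysfunction`, `tide_exclusion`, `pan_immune`, `purity`, `tmb`,
#'   cell fractions).
#' @param battery_spec Correlation battery (default
#'   [default_battery_spec()]).
#' @param out_dir Optional output directory (created if needed).
#' @param seed Integer seed for the clustering stage.
#' @return List: `cohort` (merged analytical table), `neo_summary`,
#'   `correlations`, `phenotype_counts`, `clustering`, `coverage`,
#'   `survival`, `manifest`.
#' @export
run_pipeline <- function(epitopes, expression, clinical, scores,
                         battery_spec = default_battery_spec(),
                         out_dir = NULL, seed = 1L) {
  stages <- character(0)

  neo <- .stage("summarize", summarize_neoantigens(epitopes))
  stages <- c(stages, "summarize")

  sigs <- .stage("score", {
    if (is.null(expression) || !nrow(expression)) {
      stop("expression matrix missing or empty")
    }
    s <- score_signatures(expression)
    s$pdl1 <- if ("CD274" %in% rownames(expression)) {
      as.numeric(expression["CD274", s$patient_id])
    } else NA_real_
    s
  })
  stages <- c(stages, "score")

  cohort <- .stage("merge", merge_cohort(neo = neo, signatures = sigs,
                                         scores = scores,
                                         clinical = clinical))
  stages <- c(stages, "merge")

  correlations <- .stage("correlate",
                         correlation_battery(cohort, battery_spec))
  stages <- c(stages, "correlate")

  phen <- .stage("phenotype", {
    lab <- classify_phenotypes(cohort$pan_immune, cohort$clonality_score)
    cohort$phenotype <- as.character(lab)
    feats <- data.frame(clonality = cohort$clonality_score,
                        tide = cohort$tide_dysfunction)
    ref <- classify_phenotypes(cohort$tide_dysfunction,
                               cohort$clonality_score)
    km <- kmeans_validate(feats, reference = ref, seed = seed)
    gm <- gmm_validate(feats, reference = ref, seed = seed)
    list(labels = lab, counts = table(lab), clustering = rbind(km, gm),
         cohort = cohort)
  })
  cohort <- phen$cohort
  stages <- c(stages, "phenotype")

  coverage <- .stage("coverage", {
    assignments <- suppressWarnings(patient_top_allele(epitopes))
    curve <- set_cover_curve(records = epitopes)
    eff <- coverage_efficiency(epitopes, assignments)
    top_any <- utils::head(eff$supertype, 3L)
    strategies <- list(
      top3_any = strategy_coverage(epitopes, top_any, 10L, assignments),
      top3_any_20 = strategy_coverage(epitopes, top_any, 20L, assignments)
    )
    ab <- eff$supertype[grepl("^[AB]", eff$supertype)]
    if (length(ab) >= 2L) {
      strategies$top_ab <- strategy_coverage(
        epitopes, utils::head(ab, 3L), 10L, assignments)
    }
    cohort2 <- merge(cohort, assignments[, c("patient_id", "supertype")],
                     by = "patient_id", all.x = TRUE)
    cohort2$cyt <- cohort2$score_cyt
    burden <- public_burden_correlations(cohort2, by_supertype = FALSE)
    list(assignments = assignments, curve = curve, efficiency = eff,
         strategies = strategies, burden_correlations = burden)
  })
  stages <- c(stages, "coverage")

  surv <- .stage("survival", {
    sub <- survival_subset(cohort)
    sdf <- data.frame(
      time = sub$os_days, event = sub$os_event,
      neo_n_500 = sub$neo_n_500, clonality = sub$clonality_score,
      tide_dysfunction = sub$tide_dysfunction,
      tide_exclusion = sub$tide_exclusion, pdl1 = sub$pdl1,
      age = sub$age_years, advanced_stage = sub$advanced_stage,
      hpv_positive = sub$hpv_positive, phenotype = sub$phenotype)
    main <- cox_fit(sdf, c("neo_n_500", "clonality", "tide_dysfunction",
                           "tide_exclusion", "pdl1", "age",
                           "advanced_stage"),
                    model_name = "main_effects")
    interaction <- cox_fit(sdf, c("neo_n_500", "clonality",
                                  "tide_dysfunction", "tide_exclusion",
                                  "pdl1", "age", "advanced_stage"),
                           interactions = list(c("clonality",
                                                 "tide_dysfunction")),
                           model_name = "interaction")
    strat <- stratified_cox(sdf, "tide_dysfunction",
                            c("clonality", "age", "advanced_stage"))
    categorical <- categorical_phenotype_cox(
      sdf, covariates = c("age", "advanced_stage", "hpv_positive"))
    ok <- !is.na(sdf$phenotype)
    km <- km_estimate(sdf$time[ok], sdf$event[ok], sdf$phenotype[ok])
    lr <- logrank(sdf$time[ok], sdf$event[ok], sdf$phenotype[ok],
                  pairwise = TRUE)
    list(subset_exclusions = attr(sub, "exclusions"), n = nrow(sdf),
         main = main, interaction = interaction, stratified = strat,
         categorical = categorical, km = km, logrank = lr)
  })
  stages <- c(stages, "survival")

  manifest <- list(
    package = "neoclonal",
    version = as.character(utils::packageVersion("neoclonal")),
    seed = seed, stages = stages,
    n_patients = nrow(cohort),
    n_epitope_rows = nrow(epitopes)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"))
    write_cohort_tsv(neo, file.path(out_dir, "neo_summary.tsv"))
    write_cohort_tsv(correlations, file.path(out_dir, "correlations.tsv"))
    write_cohort_tsv(phen$clustering[, c("method", "k", "silhouette", "ari",
                                         "bic", "aic")],
                     file.path(out_dir, "clustering.tsv"))
    write_cohort_tsv(coverage$curve, file.path(out_dir, "coverage_curve.tsv"))
    write_cohort_tsv(coverage$efficiency,
                     file.path(out_dir, "coverage_efficiency.tsv"))
    surv_tab <- do.call(rbind, lapply(
      list(surv$main, surv$interaction, surv$stratified$hot,
           surv$stratified$cold, surv$categorical),
      function(m) cbind(model = m$model_name, m$terms,
                        n = m$n, events = m$n_events)))
    write_cohort_tsv(surv_tab, file.path(out_dir, "survival_models.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort = cohort, neo_summary = neo, correlations = correlations,
       phenotype_counts = phen$counts, clustering = phen$clustering,
       coverage = coverage, survival = surv, manifest = manifest)
}
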