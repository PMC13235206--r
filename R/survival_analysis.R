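# Kaplan-Meier estimation, (pairwise) log-rank testing with multiplicity
# control, and the Cox model suite: main effects, clonality x immune-context
# interaction, immune-context-stratified and categorical phenotype models.
# All fits use the Efron approximation for tied event times; continuous
# covariates are z-standardised on the model's complete-case subset so hazard
# ratios are per one standard deviation.

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with right censoring and Greenwood variance
#' (wraps `survival::survfit`), plus per-group median survival.
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicator.
#' @param group Optional grouping factor (single group if NULL).
#' @return List: `curves` (data.frame: group, time, n_risk, n_event, surv,
#'   std_err), `median_survival` (named vector).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0, na.rm = TRUE)) stop("non-positive survival times",
                                         call. = FALSE)
  if (is.null(group)) group <- rep("all", length(time))
  df <- data.frame(time = time, event = as.integer(event), group = group)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(df$group), length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       std_err = sm$std.err, stringsAsFactors = FALSE)
  med <- summary(fit)$table
  med_surv <- if (is.null(dim(med))) stats::setNames(med[["median"]], "all")
  else stats::setNames(med[, "median"], sub("^group=", "", rownames(med)))
  list(curves = curves, median_survival = med_surv)
}

#' Log-rank test, with pairwise mode and multiplicity control
#'
#' Standard log-rank chi-squared across all groups (wraps
#' `survival::survdiff`). With `pairwise = TRUE`, all k(k-1)/2 two-group
#' tests are run and both BH (FDR) and Bonferroni adjusted p-values reported.
#'
#' @param time,event As in [km_estimate()].
#' @param group Grouping factor with >= 2 levels present.
#' @param pairwise Run all pairwise two-group tests as well.
#' @return List: `chisq`, `df`, `p_value`; if pairwise, also `pairwise`
#'   (data.frame: group1, group2, chisq, p_value, q_value, p_bonferroni).
#' @export
logrank <- function(time, event, group, pairwise = FALSE) {
  df <- data.frame(time = time, event = as.integer(event),
                   group = factor(group))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$group <- droplevels(df$group)
  if (nlevels(df$group) < 2L) stop("need >= 2 non-empty groups", call. = FALSE)
  sd_all <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(df$group)
  out <- list(chisq = unname(sd_all$chisq), df = k - 1L,
              p_value = stats::pchisq(sd_all$chisq, df = k - 1L,
                                      lower.tail = FALSE))
  if (pairwise) {
    pairs <- utils::combn(levels(df$group), 2L)
    rows <- apply(pairs, 2L, function(pr) {
      sub <- df[df$group %in% pr, , drop = FALSE]
      sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
      p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
      data.frame(group1 = pr[1L], group2 = pr[2L],
                 chisq = unname(sd$chisq), p_value = p,
                 stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, rows)
    pw$q_value <- stats::p.adjust(pw$p_value, method = "BH")
    pw$p_bonferroni <- stats::p.adjust(pw$p_value, method = "bonferroni")
    out$pairwise <- pw
  }
  out
}

#' Z-standardise continuous covariates on a fit subset
#'
#' (x - mean) / sd per continuous column, computed on the rows used by the
#' model; logical and two-valued 0/1 columns pass through unchanged. The
#' means and SDs are recorded so hazard ratios can be interpreted per SD.
#'
#' @param covariates data.frame of covariates.
#' @return List: `data` (transformed data.frame), `record` (data.frame of
#'   mean/sd per standardised column).
#' @export
zstandardize <- function(covariates) {
  covariates <- as.data.frame(covariates)
  rec <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.logical(v) || all(v %in% c(0, 1, NA))) next
    if (!is.numeric(v)) next
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero variance in covariate ", nm,
                                 call. = FALSE)
    m <- mean(v, na.rm = TRUE)
    covariates[[nm]] <- (v - m) / s
    rec[[nm]] <- data.frame(term = nm, mean = m, sd = s,
                            stringsAsFactors = FALSE)
  }
  list(data = covariates, record = do.call(rbind, rec))
}

.cox_result <- function(fit, model_name, extra = list()) {
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  res <- data.frame(
    term = rownames(co),
    hazard_ratio = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p_value = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  c(list(model_name = model_name, n = sm$n, n_events = sm$nevent,
         terms = res), extra)
}

#' Cox proportional hazards fit with optional interaction terms
#'
#' Complete-case partial-likelihood fit (Efron ties) of overall survival on
#' the supplied covariates, all continuous covariates z-standardised on the
#' fit subset beforehand. Interaction terms are formed as products of the
#' standardised main effects (main effects stay per-SD interpretable).
#'
#' @param data data.frame with `time` and `event` columns plus covariates.
#' @param terms Character vector of covariate column names.
#' @param interactions Optional list of 2-element character vectors naming
#'   term pairs whose product enters the model.
#' @param model_name Label carried in the result.
#' @return List: `model_name`, `n`, `n_events`, `terms` (data.frame with
#'   hazard_ratio, ci_low, ci_high, p_value), `standardization`, `fit`.
#' @export
cox_fit <- function(data, terms, interactions = NULL,
                    model_name = "cox") {
  need <- c("time", "event", terms)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) stop("missing column(s): ",
                                 paste(missing_cols, collapse = ", "),
                                 call. = FALSE)
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
             drop = FALSE]
  if (sum(df$event) < 1L) stop("no events in complete cases", call. = FALSE)
  zs <- zstandardize(df[, terms, drop = FALSE])
  df[, terms] <- zs$data
  for (ia in interactions) {
    stopifnot(length(ia) == 2L, all(ia %in% terms))
    df[[paste(ia, collapse = "_x_")]] <- df[[ia[1L]]] * df[[ia[2L]]]
  }
  all_terms <- c(terms, vapply(interactions, paste, character(1),
                               collapse = "_x_"))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", all_terms), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)))) {
    stop("Cox fit failed or design is singular", call. = FALSE)
  }
  res <- .cox_result(fit, model_name,
                     extra = list(standardization = zs$record, fit = fit))
  res$terms$term <- gsub("`", "", res$terms$term)
  res
}

#' Immune-context-stratified Cox fits
#'
#' Splits the cohort into "hot" (stratifier >= its median on the analysis
#' subset) and "cold" (< median) strata and fits an independent Cox model of
#' the given terms in each.
#'
#' @param data data.frame with `time`, `event`, the stratifier and covariates.
#' @param stratifier Column name used for the median split (e.g. TIDE
#'   dysfunction).
#' @param terms Covariate column names for the per-stratum models.
#' @return List: `hot`, `cold` (each a [cox_fit()] result),
#'   `median_stratifier`, `n_hot`, `n_cold`.
#' @export
stratified_cox <- function(data, stratifier, terms) {
  need <- c("time", "event", stratifier, terms)
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  med <- stats::median(df[[stratifier]])
  hot <- df[df[[stratifier]] >= med, , drop = FALSE]
  cold <- df[df[[stratifier]] < med, , drop = FALSE]
  if (!nrow(hot) || !nrow(cold)) stop("empty stratum", call. = FALSE)
  list(
    hot = cox_fit(hot, terms, model_name = "hot"),
    cold = cox_fit(cold, terms, model_name = "cold"),
    median_stratifier = med, n_hot = nrow(hot), n_cold = nrow(cold)
  )
}

#' Cox model with the four-phenotype label as a categorical predictor
#'
#' Dummy-codes the phenotype with Hot/LowClonality as the reference category
#' and adjusts for the supplied covariates (continuous ones z-standardised).
#'
#' @param data data.frame with `time`, `event`, `phenotype` (factor with the
#'   package's four levels) and covariate columns.
#' @param covariates Covariate column names (default age and advanced stage
#'   and HPV status where present).
#' @return [cox_fit()]-style result list.
#' @export
categorical_phenotype_cox <- function(data,
                                      covariates = intersect(
                                        c("age_years", "advanced_stage",
                                          "hpv_positive"), names(data))) {
  stopifnot("phenotype" %in% names(data))
  need <- c("time", "event", "phenotype", covariates)
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
             drop = FALSE]
  df$phenotype <- factor(as.character(df$phenotype),
                         levels = PHENOTYPE_LEVELS)
  df$phenotype <- droplevels(df$phenotype)
  if (!PHENOTYPE_LEVELS[1L] %in% levels(df$phenotype)) {
    stop("reference level ", PHENOTYPE_LEVELS[1L], " absent", call. = FALSE)
  }
  if (nlevels(df$phenotype) < 2L) stop("fewer than 2 phenotype levels",
                                       call. = FALSE)
  if (length(covariates)) {
    zs <- zstandardize(df[, covariates, drop = FALSE])
    df[, covariates] <- zs$data
  } else zs <- list(record = NULL)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ phenotype",
    if (length(covariates))
      paste("+", paste(sprintf("`%s`", covariates), collapse = " + "))
    else ""))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  res <- .cox_result(fit, "categorical_phenotype",
                     extra = list(standardization = zs$record, fit = fit))
  res$terms$term <- gsub("`|^phenotype", "", res$terms$term)
  res
}
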