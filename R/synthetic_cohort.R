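# Synthetic cohort generator. Produces epitope, expression, clinical and
# external-score tables with planted, recoverable structure: a latent
# clonality/infiltration pair with a target rank correlation, clonal and
# subclonal VAF mixtures under tumour purity, log-normal IC50 with ~50%
# binders, a shared (Zipf-weighted) public peptide pool, immune gene panels
# loading on the infiltration latent, and survival times with a clonality x
# immune-context interaction hazard.

.variant_gene_pool <- function() {
  c("TP53", "CDKN2A", "TTN", "CACNA1G", "CACNA1C", "EIF4G1", "PCDH15",
    "CASP8", "ZFP36L2", "LPHN3", "FAT1", "NOTCH1", "PIK3CA", "NSD1",
    "KMT2D", "CSMD3", "SYNE1", "MUC16", "USH2A", "FLG",
    sprintf("GENE%03d", seq_len(100)))
}

.hla_frequency_table <- function() {
  # Allele sampling weights; HLA-C alleles are up-weighted so that top-allele
  # and allele-group ("supertype") analyses see the C-dominated structure
  # typical of this setting.
  data.frame(
    allele = c("HLA-C*07:01", "HLA-C*07:02", "HLA-C*03:04", "HLA-C*12:03",
               "HLA-C*16:01", "HLA-C*15:02", "HLA-A*02:01", "HLA-A*01:01",
               "HLA-A*03:01", "HLA-B*44:02", "HLA-B*07:02", "HLA-B*58:01",
               "HLA-B*27:05"),
    gene = c(rep("C", 6L), rep("A", 3L), rep("B", 4L)),
    weight = c(20, 18, 12, 9, 8, 4, 6, 4, 3, 4, 3, 2, 1),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study regime: a 527-patient head-and-neck-like
#' cohort, target Spearman correlation of -0.5 between the latent clonality
#' and immune-infiltration axes, a clonal/subclonal VAF mixture under Beta
#' tumour purity, ~50% of predicted peptides binding (IC50 lognormal around
#' 500 nM), and survival hazard with a protective clonality effect confined
#' to immune-hot tumours (interaction hazard ratio 0.85 per SD x SD).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; every random draw funnels through it.
#' @param rho_clonality_immune Target Spearman correlation of the latent
#'   clonality and infiltration factors, in (-1, 1).
#' @param purity_beta Two shape parameters of the Beta purity distribution.
#' @param n_variants_mean,n_variants_size Negative-binomial mean and size for
#'   per-patient variant counts; the mean is modulated by
#'   `exp(n_variants_loading * C)` so mutation burden rises with latent
#'   clonality.
#' @param n_variants_loading Loading of latent clonality on log variant count.
#' @param clonal_link Intercept and slope mapping latent clonality to the
#'   per-variant clonal probability through a logistic link.
#' @param clonal_vaf_shape,subclonal_vaf_shape Beta shapes of the VAF
#'   multiplier: clonal VAFs concentrate near purity/2, subclonal VAFs are
#'   scaled below it.
#' @param peptides_per_variant Poisson mean peptide yield per variant.
#' @param ic50_meanlog,ic50_sdlog Log-normal IC50 parameters (nanomolar).
#' @param wt_ic50_sdlog10 SD of the log10 mutant/wild-type affinity ratio.
#' @param wt_missing_rate Fraction of peptides without wild-type affinity.
#' @param public_pool_size,public_rate,zipf_exponent Size of the shared
#'   ("public") peptide pool, the probability a peptide is drawn from it, and
#'   the Zipf weighting exponent over the pool.
#' @param expr_loading_immune Loading of the infiltration latent on immune
#'   panel genes (log scale).
#' @param expr_loading_apm_clonality Additional (negative) loading of the
#'   clonality latent on antigen-presentation genes.
#' @param expr_noise_sd Per-gene log-normal noise SD.
#' @param tide_noise_sd,panimmune_noise_sd Noise SDs of the TIDE dysfunction
#'   and Pan-Immune links to the infiltration latent.
#' @param covered_mb Megabases of covered coding sequence for TMB.
#' @param hazard Named vector of log-hazard coefficients: `age` (per SD),
#'   `clonality` (main effect per SD) and `interaction` (clonality x TIDE
#'   dysfunction, both standardised).
#' @param baseline_rate,censor_rate Exponential baseline hazard and censoring
#'   rates (per day).
#' @param missing Named vector of missingness rates applied last: `hpv`,
#'   `os`, `tide`, `purity`.
#' @param hpv_prevalence HPV-positive fraction.
#' @param advanced_stage_prob Probability of stage III-IV.
#' @return A `neo_synth_config` list.
#' @export
neo_synth_config <- function(
    n_patients = 527L,
    seed = 20260101L,
    rho_clonality_immune = -0.5,
    purity_beta = c(300, 100),
    n_variants_mean = 105,
    n_variants_size = 2,
    n_variants_loading = 0.25,
    clonal_link = c(intercept = 0.3, slope = 1.2),
    clonal_vaf_shape = c(60, 4),
    subclonal_vaf_shape = c(3, 15),
    peptides_per_variant = 3,
    ic50_meanlog = log(500),
    ic50_sdlog = 1.4,
    wt_ic50_sdlog10 = 0.25,
    wt_missing_rate = 0.1,
    public_pool_size = 400L,
    public_rate = 0.08,
    zipf_exponent = 1.2,
    expr_loading_immune = 0.8,
    expr_loading_apm_clonality = -0.15,
    expr_noise_sd = 0.4,
    tide_noise_sd = 0.35,
    panimmune_noise_sd = 0.15,
    covered_mb = 38,
    hazard = c(age = log(1.3), clonality = log(0.88), interaction = log(0.85)),
    baseline_rate = 1 / 1500,
    censor_rate = 1 / 1600,
    missing = c(hpv = 0.013, os = 0.085, tide = 0.011, purity = 0.07),
    hpv_prevalence = 0.14,
    advanced_stage_prob = 0.6) {
  if (abs(rho_clonality_immune) >= 1) {
    stop("|rho_clonality_immune| must be < 1", call. = FALSE)
  }
  stopifnot(n_patients >= 0, public_rate >= 0, public_rate <= 1,
            ic50_sdlog > 0, all(missing >= 0 & missing <= 1))
  structure(as.list(environment()), class = "neo_synth_config")
}

.rand_peptides <- function(n, lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- sample(8:11, n, replace = TRUE, prob = c(0.2, 0.4, 0.25, 0.15))
  }
  out <- character(n)
  for (L in unique(lengths)) {
    idx <- which(lengths == L)
    m <- matrix(sample(AA_ALPHABET, length(idx) * L, replace = TRUE),
                nrow = length(idx), ncol = L)
    out[idx] <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  out
}

#' Simulate survival data with a planted clonality x immune interaction
#'
#' Draws independent standard-normal clonality, TIDE-dysfunction and age
#' z-scores and exponential event times under the log-hazard
#' `b_age * age + b_main * clonality + b_int * clonality * tide`, with
#' independent exponential censoring. Used both inside [generate_cohort()]
#' (with the cohort's actual scores) and directly for calibration and
#' recovery simulations.
#'
#' @param n Number of subjects.
#' @param b_age,b_main,b_int Log-hazard coefficients.
#' @param baseline_rate,censor_rate Exponential rates per day.
#' @param covariates Optional data.frame with `clonality_z`, `tide_z`,
#'   `age_z` to use instead of fresh draws.
#' @return data.frame: `time`, `event`, `clonality_z`, `tide_z`, `age_z`,
#'   `hot` (TIDE >= median).
#' @export
simulate_interaction_survival <- function(n, b_age = log(1.3),
                                          b_main = log(0.88),
                                          b_int = log(0.85),
                                          baseline_rate = 1 / 1500,
                                          censor_rate = 1 / 1600,
                                          covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- data.frame(clonality_z = stats::rnorm(n),
                             tide_z = stats::rnorm(n),
                             age_z = stats::rnorm(n))
  }
  lp <- b_age * covariates$age_z + b_main * covariates$clonality_z +
    b_int * covariates$clonality_z * covariates$tide_z
  t_event <- stats::rexp(n, rate = baseline_rate * exp(lp))
  t_cens <- stats::rexp(n, rate = censor_rate)
  data.frame(
    time = ceiling(pmin(t_event, t_cens)),
    event = t_event <= t_cens,
    covariates,
    hot = covariates$tide_z >= stats::median(covariates$tide_z)
  )
}

#' Generate a full synthetic cohort
#'
#' Produces the four pipeline input tables (epitopes, expression, clinical,
#' external scores) plus the ground truth used by recovery tests. The latent
#' clonality/infiltration pair (C, I) comes from a Gaussian copula hitting
#' the target Spearman correlation via the conversion
#' rho_P = 2 sin(pi rho_S / 6); per-variant clonal status, VAFs, peptide
#' yields, IC50s, HLA restrictions and shared peptides, immune-loaded
#' expression, TIDE/Pan-Immune links, CIBERSORT-like fractions and the
#' interaction survival hazard all follow the configuration.
#'
#' @param config A [neo_synth_config()] list.
#' @return List: `epitopes`, `expression` (matrix genes x patients),
#'   `clinical`, `scores`, `truth` (latents, clonal flags, planted
#'   coefficients), `config`.
#' @export
generate_cohort <- function(config = neo_synth_config()) {
  stopifnot(inherits(config, "neo_synth_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  empty <- function(cols) stats::setNames(
    as.data.frame(lapply(cols, function(.) character(0))), cols)
  if (n == 0L) {
    return(list(
      epitopes = empty(.epitope_fields),
      expression = matrix(numeric(0), nrow = 0, ncol = 0),
      clinical = empty(c("patient_id", "age_years", "stage",
                         "advanced_stage", "hpv_positive", "os_days",
                         "os_event")),
      scores = empty(c("patient_id", "tide_dysfunction", "tide_exclusion",
                       "pan_immune", "purity", "tmb")),
      truth = list(), config = config))
  }
  ids <- sprintf("TCGA-SY-%04d", seq_len(n))

  # Latent clonality (C) and infiltration (I): Gaussian copula.
  rho_p <- 2 * sin(pi * config$rho_clonality_immune / 6)
  C <- stats::rnorm(n)
  I <- rho_p * C + sqrt(1 - rho_p^2) * stats::rnorm(n)

  purity <- stats::rbeta(n, config$purity_beta[1L], config$purity_beta[2L])
  n_var <- stats::rnbinom(n, size = config$n_variants_size,
                          mu = config$n_variants_mean *
                            exp(config$n_variants_loading * C))

  # --- variants ---
  V <- sum(n_var)
  pat_of_var <- rep(seq_len(n), n_var)
  p_clonal <- stats::plogis(config$clonal_link[["intercept"]] +
                              config$clonal_link[["slope"]] * C[pat_of_var])
  clonal <- stats::rbinom(V, 1L, p_clonal) == 1L
  mult <- numeric(V)
  mult[clonal] <- stats::rbeta(sum(clonal), config$clonal_vaf_shape[1L],
                               config$clonal_vaf_shape[2L])
  mult[!clonal] <- stats::rbeta(sum(!clonal), config$subclonal_vaf_shape[1L],
                                config$subclonal_vaf_shape[2L])
  vaf <- pmin(1, purity[pat_of_var] / 2 * mult)
  gene_pool <- .variant_gene_pool()
  gene_w <- 1 / seq_along(gene_pool)^0.9
  var_gene <- sample(gene_pool, V, replace = TRUE, prob = gene_w)
  var_id <- paste0(ids[pat_of_var], "_v",
                   unlist(lapply(n_var, seq_len), use.names = FALSE))

  # --- peptides ---
  k_pep <- stats::rpois(V, config$peptides_per_variant)
  P <- sum(k_pep)
  var_of_pep <- rep(seq_len(V), k_pep)
  pat_of_pep <- pat_of_var[var_of_pep]
  ic50 <- stats::rlnorm(P, config$ic50_meanlog, config$ic50_sdlog)
  wt_ic50 <- ic50 * 10^stats::rnorm(P, 0, config$wt_ic50_sdlog10)
  wt_ic50[stats::runif(P) < config$wt_missing_rate] <- NA_real_

  pool <- .rand_peptides(config$public_pool_size,
                         lengths = rep(9L, config$public_pool_size))
  pool_w <- 1 / seq_along(pool)^config$zipf_exponent
  from_pool <- stats::runif(P) < config$public_rate
  peptide <- character(P)
  peptide[from_pool] <- sample(pool, sum(from_pool), replace = TRUE,
                               prob = pool_w)
  peptide[!from_pool] <- .rand_peptides(sum(!from_pool))

  # --- HLA restriction: 6 alleles per patient, C-weighted per peptide ---
  freq <- .hla_frequency_table()
  pat_alleles <- t(vapply(seq_len(n), function(i) {
    vapply(c("A", "B", "C"), function(g) {
      rows <- freq[freq$gene == g, ]
      sample(rows$allele, 2L, replace = TRUE, prob = rows$weight)
    }, character(2))
  }, character(6)))
  gene_weight <- c(1, 1, 1, 1, 3, 3)  # A,A,B,B,C,C: HLA-C dominates
  allele_slot <- sample.int(6L, P, replace = TRUE, prob = gene_weight)
  hla <- pat_alleles[cbind(pat_of_pep, allele_slot)]

  epitopes <- data.frame(
    patient_id = ids[pat_of_pep],
    gene_symbol = var_gene[var_of_pep],
    peptide = peptide,
    hla_allele = hla,
    ic50_nm = ic50,
    wt_ic50_nm = wt_ic50,
    vaf = vaf[var_of_pep],
    variant_id = var_id[var_of_pep],
    stringsAsFactors = FALSE
  )
  # enforce record uniqueness on (patient, peptide, allele, variant)
  epitopes <- epitopes[!duplicated(epitopes[, c("patient_id", "peptide",
                                                "hla_allele", "variant_id")]),
                       , drop = FALSE]
  rownames(epitopes) <- NULL

  # --- expression: immune panels load on I, APM additionally on C ---
  panels <- builtin_panels()
  panel_genes <- unique(unlist(lapply(panels, `[[`, "genes")))
  apm_genes <- panels$antigen_presentation$genes
  bg_genes <- sprintf("NPC%03d", seq_len(40L))
  genes <- c(panel_genes, "CD274", bg_genes)
  baseline <- stats::runif(length(genes), 0.5, 2.5)
  load_i <- ifelse(genes %in% c(panel_genes, "CD274"),
                   config$expr_loading_immune, 0)
  load_c <- ifelse(genes %in% apm_genes, config$expr_loading_apm_clonality, 0)
  noise <- matrix(stats::rnorm(length(genes) * n, 0, config$expr_noise_sd),
                  nrow = length(genes))
  log_expr <- baseline + outer(load_i, I) + outer(load_c, C) + noise
  expression <- exp(log_expr)
  dimnames(expression) <- list(genes, ids)

  # --- external scores ---
  tide_dysfunction <- 0.8 * I + stats::rnorm(n, 0, config$tide_noise_sd)
  tide_exclusion <- -0.5 * I + stats::rnorm(n, 0, 0.6)
  pan_immune <- 0.9 * I + stats::rnorm(n, 0, config$panimmune_noise_sd)
  cd8_fraction <- stats::plogis(-2.2 + 0.6 * I + stats::rnorm(n, 0, 0.25)) * 0.5
  lymphocyte_fraction <-
    stats::plogis(-1.3 + 0.6 * I + stats::rnorm(n, 0, 0.25)) * 0.6
  treg_fraction <- stats::plogis(-3.5 + 0.3 * I + stats::rnorm(n, 0, 0.3)) * 0.3
  m1_fraction <- stats::plogis(-2.5 + 0.2 * I + stats::rnorm(n, 0, 0.3)) * 0.4
  m2_fraction <- stats::plogis(-1.4 - 0.1 * I + stats::rnorm(n, 0, 0.3)) * 0.5
  tmb <- compute_tmb(n_var, config$covered_mb)

  scores <- data.frame(
    patient_id = ids, tide_dysfunction = tide_dysfunction,
    tide_exclusion = tide_exclusion, pan_immune = pan_immune,
    purity = purity, tmb = tmb, cd8_fraction = cd8_fraction,
    lymphocyte_fraction = lymphocyte_fraction, treg_fraction = treg_fraction,
    m1_fraction = m1_fraction, m2_fraction = m2_fraction,
    stringsAsFactors = FALSE
  )

  # --- clinical & survival (hazard uses the cohort's own clonality score) ---
  age <- round(pmin(pmax(stats::rnorm(n, 61, 10), 25), 90))
  stage_lv <- c("I", "II", "III", "IVA", "IVB", "IVC")
  stage <- sample(stage_lv, n, replace = TRUE,
                  prob = c(0.05, 0.2, 0.23, 0.46, 0.03, 0.03))
  adv_target <- config$advanced_stage_prob
  # resample to hit the configured advanced fraction approximately
  advanced <- stage %in% c("III", "IVA", "IVB", "IVC")
  if (abs(mean(advanced) - adv_target) > 0.15) {
    advanced <- stats::runif(n) < adv_target
    stage <- ifelse(advanced, sample(c("III", "IVA", "IVB", "IVC"), n, TRUE,
                                     prob = c(0.3, 0.6, 0.05, 0.05)),
                    sample(c("I", "II"), n, TRUE, prob = c(0.2, 0.8)))
  }
  hpv <- stats::runif(n) < config$hpv_prevalence

  binder <- epitopes$ic50_nm <= BINDER_IC50_NM
  bwv <- rowsum(epitopes$vaf * binder, epitopes$patient_id)[, 1L]
  n500 <- rowsum(as.numeric(binder), epitopes$patient_id)[, 1L]
  cs <- stats::setNames(rep(0, n), ids)
  cs[names(bwv)] <- bwv / (n500 + 1)
  cs_z <- as.numeric(scale(cs))
  tide_z <- as.numeric(scale(tide_dysfunction))
  age_z <- as.numeric(scale(age))
  surv <- simulate_interaction_survival(
    n, b_age = config$hazard[["age"]], b_main = config$hazard[["clonality"]],
    b_int = config$hazard[["interaction"]],
    baseline_rate = config$baseline_rate, censor_rate = config$censor_rate,
    covariates = data.frame(clonality_z = cs_z, tide_z = tide_z,
                            age_z = age_z))

  clinical <- data.frame(
    patient_id = ids, age_years = age, stage = stage,
    advanced_stage = stage %in% c("III", "IVA", "IVB", "IVC"),
    hpv_positive = hpv, os_days = surv$time, os_event = surv$event,
    stringsAsFactors = FALSE
  )

  # --- missingness, applied last ---
  miss <- config$missing
  drop <- function(p) stats::runif(n) < p
  clinical$hpv_positive[drop(miss[["hpv"]])] <- NA
  os_na <- drop(miss[["os"]])
  clinical$os_days[os_na] <- NA_real_
  clinical$os_event[os_na] <- NA
  tide_na <- drop(miss[["tide"]])
  scores$tide_dysfunction[tide_na] <- NA_real_
  scores$purity[drop(miss[["purity"]])] <- NA_real_

  truth <- list(
    patient_id = ids, latent_clonality = C, latent_infiltration = I,
    purity = purity, n_variants = n_var, clonal_variant = clonal,
    planted_rho = config$rho_clonality_immune,
    hazard = config$hazard,
    generator_clonality_score = unname(cs),
    n_missing = list(hpv = sum(is.na(clinical$hpv_positive)),
                     os = sum(os_na), tide = sum(tide_na))
  )
  list(epitopes = epitopes, expression = expression, clinical = clinical,
       scores = scores, truth = truth, config = config)
}

#' Check that the pipeline recovers the generator's planted parameters
#'
#' Runs four checks against the ground truth: (a) the Spearman correlation
#' between the pipeline Clonality Score and the Pan-Immune proxy falls in a
#' band around the planted value (or is consistent with null when the planted
#' correlation is 0); (b) the two anti-diagonal phenotypes (Hot/Low,
#' Cold/High) each outnumber both diagonal phenotypes; (c) the Cox
#' clonality x TIDE interaction confidence interval covers the planted
#' coefficient (or 0 under a null hazard); (d) the clonality-exhaustion
#' correlation attenuates towards zero once the Pan-Immune proxy is
#' controlled for.
#'
#' @param sim Output of [generate_cohort()].
#' @param cohort Analysis table holding at least `clonality_score`,
#'   `pan_immune`, `tide_dysfunction`, `score_exhaustion`, `phenotype`,
#'   `os_days`, `os_event`, `age_years` columns (e.g. from [run_pipeline()]).
#' @param band Half-width of the acceptance band around the planted
#'   correlation (default 0.08).
#' @return data.frame: `check`, `value`, `target`, `pass`.
#' @export
recovery_report <- function(sim, cohort, band = 0.08) {
  rho_target <- sim$truth$planted_rho
  res_rho <- spearman(cohort$clonality_score, cohort$pan_immune)
  null_rho <- rho_target == 0
  pass_a <- if (null_rho) abs(res_rho$rho) < 0.1 else
    abs(res_rho$rho - rho_target) <= band

  counts <- table(cohort$phenotype)
  anti <- counts[c("Hot/LowClonality", "Cold/HighClonality")]
  diag <- counts[c("Hot/HighClonality", "Cold/LowClonality")]
  pass_b <- if (null_rho) TRUE else all(outer(anti, diag, `>`))

  sdf <- data.frame(time = cohort$os_days, event = cohort$os_event,
                    clonality = cohort$clonality_score,
                    tide = cohort$tide_dysfunction,
                    age = cohort$age_years)
  fit <- cox_fit(sdf[stats::complete.cases(sdf), ],
                 terms = c("clonality", "tide", "age"),
                 interactions = list(c("clonality", "tide")),
                 model_name = "interaction")
  ia <- fit$terms[fit$terms$term == "clonality_x_tide", ]
  target_hr <- exp(sim$truth$hazard[["interaction"]])
  pass_c <- ia$ci_low <= target_hr && target_hr <= ia$ci_high

  raw <- spearman(cohort$clonality_score, cohort$score_exhaustion)
  partial <- partial_spearman(cohort$clonality_score,
                              cohort$score_exhaustion, cohort$pan_immune)
  pass_d <- if (null_rho) TRUE else abs(partial$rho) < abs(raw$rho)

  data.frame(
    check = c("clonality_panimmune_rho", "antidiagonal_dominance",
              "interaction_ci_covers", "partial_attenuation"),
    value = c(res_rho$rho, min(anti) - max(diag), ia$hazard_ratio,
              abs(raw$rho) - abs(partial$rho)),
    target = c(rho_target, NA, target_hr, NA),
    pass = c(pass_a, pass_b, pass_c, pass_d),
    stringsAsFactors = FALSE
  )
}
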