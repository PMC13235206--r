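# Four-phenotype immune classification, tertile sensitivity analysis,
# unsupervised-clustering validation (k-means, GMM) and concordance metrics.

#' @importFrom mclust Mclust mclustBIC nMclustParams
NULL

PHENOTYPE_LEVELS <- c("Hot/LowClonality", "Hot/HighClonality",
                      "Cold/LowClonality", "Cold/HighClonality")

#' Classify tumours into four immune phenotypes by median dichotomization
#'
#' "Hot" means immune score >= its median, "high clonality" means clonality
#' score >= its median; both medians are computed on the complete-case subset
#' being classified (values exactly at the median fall on the hot/high side).
#'
#' @param immune Numeric immune-activity score (e.g. Pan-Immune Score).
#' @param clonality Numeric clonality score, same length.
#' @return Factor of phenotype labels (NA where either input is NA) with
#'   attributes `median_immune` and `median_clonality`.
#' @export
classify_phenotypes <- function(immune, clonality) {
  stopifnot(length(immune) == length(clonality))
  ok <- stats::complete.cases(immune, clonality)
  if (!any(ok)) stop("no complete cases to classify", call. = FALSE)
  m_i <- stats::median(immune[ok])
  m_c <- stats::median(clonality[ok])
  hot <- immune >= m_i
  high <- clonality >= m_c
  lab <- rep(NA_character_, length(immune))
  lab[ok & hot & !high] <- "Hot/LowClonality"
  lab[ok & hot & high]  <- "Hot/HighClonality"
  lab[ok & !hot & !high] <- "Cold/LowClonality"
  lab[ok & !hot & high]  <- "Cold/HighClonality"
  out <- factor(lab, levels = PHENOTYPE_LEVELS)
  attr(out, "median_immune") <- m_i
  attr(out, "median_clonality") <- m_c
  out
}

#' Tertile stratification with per-tertile summaries
#'
#' Splits `values` into three groups at the empirical tertiles (boundary
#' values assigned to the lower tertile) and summarises the mean of each
#' requested column within each tertile.
#'
#' @param values Numeric vector defining the stratification.
#' @param summarise Optional named list / data.frame of columns to average per
#'   tertile.
#' @return List: `tertile` (integer 1-3, NA for missing values), `cutpoints`,
#'   `summary` (data.frame of per-tertile means, NULL if nothing to
#'   summarise).
#' @export
tertile_stratify <- function(values, summarise = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("fewer than 3 complete values", call. = FALSE)
  cuts <- stats::quantile(values[ok], probs = c(1, 2) / 3, type = 7)
  if (cuts[1L] == cuts[2L]) {
    warning("too few distinct values for 3 groups; grouping is degenerate",
            call. = FALSE)
  }
  tert <- rep(NA_integer_, length(values))
  tert[ok] <- 1L + (values[ok] > cuts[1L]) + (values[ok] > cuts[2L])
  summary_df <- NULL
  if (!is.null(summarise)) {
    sdf <- as.data.frame(summarise)
    summary_df <- do.call(rbind, lapply(1:3, function(t) {
      rows <- which(tert == t)
      cbind(data.frame(tertile = t, n = length(rows)),
            as.data.frame(lapply(sdf, function(col) mean(col[rows], na.rm = TRUE))))
    }))
  }
  list(tertile = tert, cutpoints = unname(cuts), summary = summary_df)
}

#' Adjusted Rand Index between two partitions
#'
#' Pair-counting formula: (sum_ij C(n_ij,2) - E) / (max - E) with
#' E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2).
#'
#' @param a,b Label vectors of equal length >= 2 (any atomic type).
#' @return ARI in (-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  stopifnot(n >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Cohen's kappa and percent concordance for two raters
#'
#' kappa = (p_o - p_e) / (1 - p_e). If both raters are constant and equal
#' (p_e = 1), kappa is NA with 100% concordance.
#'
#' @param a,b Label vectors of equal length.
#' @return List: `kappa`, `concordance` (percent agreement, 0-100).
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  lev <- union(unique(a), unique(b))
  ta <- factor(a, levels = lev); tb <- factor(b, levels = lev)
  tab <- table(ta, tb)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa, concordance = 100 * p_o)
}

.zscore_matrix <- function(features) {
  m <- as.matrix(as.data.frame(features))
  scale(m)
}

#' Validate the median-split phenotypes with k-means clustering
#'
#' k-means (25 restarts, fixed seed) over a z-standardised feature matrix for
#' each k, with average silhouette width on Euclidean distance and the
#' Adjusted Rand Index against a reference labeling (typically the four
#' median-split phenotypes on the same feature pair).
#'
#' @param features Two-column (or wider) numeric matrix / data.frame;
#'   complete cases only are used.
#' @param reference Optional label vector (same length as rows of `features`)
#'   for the ARI comparison.
#' @param k_range Candidate cluster numbers (default 2:5).
#' @param seed Integer seed for reproducible restarts.
#' @param nstart Number of random restarts (default 25).
#' @return data.frame with one row per k: `method`, `k`, `silhouette`, `ari`,
#'   plus an `assignments` list-column.
#' @export
kmeans_validate <- function(features, reference = NULL, k_range = 2:5,
                            seed = 1L, nstart = 25L) {
  z <- .zscore_matrix(features)
  ok <- stats::complete.cases(z)
  z <- z[ok, , drop = FALSE]
  if (!is.null(reference)) reference <- reference[ok]
  if (nrow(unique(z)) < max(k_range)) {
    warning("fewer distinct points than max k; clustering may be degenerate",
            call. = FALSE)
  }
  d <- stats::dist(z)
  rows <- lapply(k_range, function(k) {
    if (k > nrow(z)) stop("k exceeds number of complete rows", call. = FALSE)
    set.seed(seed)
    km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
    sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    ari <- if (is.null(reference)) NA_real_ else
      adjusted_rand_index(km$cluster, as.character(reference))
    data.frame(method = "kmeans", k = k, silhouette = sil, ari = ari,
               bic = NA_real_, aic = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "complete_cases") <- which(ok)
  out
}

#' Validate the median-split phenotypes with Gaussian mixture models
#'
#' Full-covariance GMMs per k with BIC (model selection, argmin) and AIC
#' reported, average silhouette width, and ARI against a reference labeling.
#'
#' @inheritParams kmeans_validate
#' @return data.frame with one row per k: `method`, `k`, `silhouette`, `ari`,
#'   `bic`, `aic`; attribute `best_k_bic` / `best_k_aic`.
#' @export
gmm_validate <- function(features, reference = NULL, k_range = 2:5,
                         seed = 1L) {
  z <- .zscore_matrix(features)
  ok <- stats::complete.cases(z)
  z <- z[ok, , drop = FALSE]
  if (!is.null(reference)) reference <- reference[ok]
  d <- stats::dist(z)
  rows <- lapply(k_range, function(k) {
    set.seed(seed)
    fit <- Mclust(z, G = k, modelNames = "VVV", verbose = FALSE)
    if (is.null(fit)) {
      return(data.frame(method = "gmm", k = k, silhouette = NA_real_,
                        ari = NA_real_, bic = NA_real_, aic = NA_real_,
                        stringsAsFactors = FALSE))
    }
    npar <- nMclustParams("VVV", d = ncol(z), G = k)
    bic <- -2 * fit$loglik + npar * log(nrow(z))
    aic <- -2 * fit$loglik + 2 * npar
    cl <- fit$classification
    sil <- if (length(unique(cl)) > 1L) {
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    } else NA_real_
    ari <- if (is.null(reference)) NA_real_ else
      adjusted_rand_index(cl, as.character(reference))
    data.frame(method = "gmm", k = k, silhouette = sil, ari = ari,
               bic = bic, aic = aic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_k_bic") <- out$k[which.min(out$bic)]
  attr(out, "best_k_aic") <- out$k[which.min(out$aic)]
  attr(out, "complete_cases") <- which(ok)
  out
}

#' Concordance of alternative hot/cold classifications with a primary score
#'
#' Median-splits the primary score and each alternative score into hot
#' (>= median) / cold, then reports percent concordance and Cohen's kappa of
#' each alternative against the primary classification (pairwise complete
#' cases).
#'
#' @param primary_score Numeric vector (e.g. TIDE dysfunction).
#' @param alternative_scores Named list / data.frame of numeric vectors.
#' @return data.frame: `score`, `n`, `concordance`, `kappa`.
#' @export
hotcold_concordance <- function(primary_score, alternative_scores) {
  alts <- as.data.frame(alternative_scores)
  rows <- lapply(names(alts), function(nm) {
    alt <- alts[[nm]]
    ok <- stats::complete.cases(primary_score, alt)
    p_hot <- primary_score[ok] >= stats::median(primary_score[ok])
    a_hot <- alt[ok] >= stats::median(alt[ok])
    ck <- cohens_kappa(p_hot, a_hot)
    data.frame(score = nm, n = sum(ok), concordance = ck$concordance,
               kappa = ck$kappa, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
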