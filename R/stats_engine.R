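# Correlation and group-comparison battery: Spearman with BH FDR, partial
# Spearman via rank residualization, Fisher z strata comparison, Kruskal-
# Wallis with Dunn post-hoc, Mann-Whitney, chi-squared, and OLS regression.
# All tests two-sided.

.complete_pairs <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from a t statistic on n - 2 degrees of
#' freedom. Incomplete pairs are dropped (pairwise deletion).
#'
#' @param x,y Paired numeric vectors (may contain NA).
#' @return List: `rho`, `p_value`, `n`, `var_x`, `var_y`, `covariates`.
#' @export
spearman <- function(x, y) {
  cp <- .complete_pairs(x, y)
  if (cp$n < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  rx <- rank(cp$x); ry <- rank(cp$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance after ranking", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  p <- .t_pvalue(rho, df = cp$n - 2L)
  list(rho = rho, p_value = p, n = cp$n,
       var_x = deparse(substitute(x)), var_y = deparse(substitute(y)),
       covariates = character(0))
}

.t_pvalue <- function(r, df) {
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = df)
}

#' Partial Spearman correlation via rank residualization
#'
#' Rank-transforms both variables and the covariate, regresses each ranked
#' variable on the ranked covariate (with intercept), and correlates the
#' residuals. Two-sided p from a t statistic on n - 3 degrees of freedom. A
#' covariate with zero rank variance degrades to plain Spearman with a
#' warning; a covariate identical (in rank) to either variable is a
#' collinearity error.
#'
#' @param x,y,z Paired numeric vectors; `z` is the covariate.
#' @return List as in [spearman()] with `covariates = "z"`.
#' @export
partial_spearman <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("fewer than 4 complete triples", call. = FALSE)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rz) == 0) {
    warning("covariate has zero rank variance; returning plain Spearman",
            call. = FALSE)
    out <- spearman(x, y)
    out$covariates <- "z(degenerate)"
    return(out)
  }
  if (isTRUE(all.equal(stats::cor(rx, rz), 1)) ||
      isTRUE(all.equal(stats::cor(ry, rz), 1))) {
    stop("covariate is rank-collinear with a variable", call. = FALSE)
  }
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  rho <- stats::cor(ex, ey)
  list(rho = rho, p_value = .t_pvalue(rho, df = n - 3L), n = n,
       var_x = NA_character_, var_y = NA_character_, covariates = "z")
}

#' Least-squares residualization on a covariate
#'
#' Residuals of `x` regressed on `covariate` with intercept, on the raw or
#' rank scale. A constant covariate yields centered `x` with a warning.
#'
#' @param x Numeric vector.
#' @param covariate Numeric vector, same length.
#' @param on_ranks Residualize rank-transformed values instead of raw.
#' @return Residual vector (NA where either input is NA).
#' @export
residualize_on <- function(x, covariate, on_ranks = FALSE) {
  stopifnot(length(x) == length(covariate))
  ok <- stats::complete.cases(x, covariate)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  xv <- x[ok]; cv <- covariate[ok]
  if (on_ranks) { xv <- rank(xv); cv <- rank(cv) }
  out <- rep(NA_real_, length(x))
  if (stats::sd(cv) == 0) {
    warning("constant covariate; returning centered values", call. = FALSE)
    out[ok] <- xv - mean(xv)
  } else {
    out[ok] <- stats::lm.fit(cbind(1, cv), xv)$residuals
  }
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust`) with input validation.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of monotone q-values capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Compare two correlation coefficients with Fisher's z-transformation
#'
#' z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3)); two-sided p
#' from the standard normal.
#'
#' @param rho1,rho2 Correlations with |rho| < 1.
#' @param n1,n2 Stratum sample sizes (>= 4).
#' @return List: `z`, `p_value`.
#' @export
fisher_z_compare <- function(rho1, n1, rho2, n2) {
  stopifnot(n1 >= 4L, n2 >= 4L)
  if (abs(rho1) >= 1 || abs(rho2) >= 1) {
    stop("|rho| must be < 1 for the z-transformation", call. = FALSE)
  }
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Kruskal-Wallis test over a list of groups
#'
#' Tie-corrected H with chi-squared p on k - 1 degrees of freedom (wraps
#' `stats::kruskal.test`).
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List: `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) > 0L))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    stop("all observations identical", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on mean-rank differences with the pooled tie
#' correction, BH-adjusted across the k(k-1)/2 pairs.
#'
#' @param groups Named or unnamed list of numeric vectors.
#' @return data.frame: `group1`, `group2`, `z`, `p_value`, `q_value`.
#' @export
dunn_posthoc <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2L, all(lengths(groups) > 0L))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) stop("all observations identical", call. = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  mean_ranks <- tapply(r, idx, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  res <- vapply(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1L, col]; j <- pairs[2L, col]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
    z <- if (se == 0) 0 else (mean_ranks[[i]] - mean_ranks[[j]]) / se
    c(z, 2 * stats::pnorm(-abs(z)))
  }, numeric(2))
  out <- data.frame(
    group1 = names(groups)[pairs[1L, ]],
    group2 = names(groups)[pairs[2L, ]],
    z = res[1L, ], p_value = res[2L, ], stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' U statistic of the first group; exact two-sided p when the combined sample
#' is small and tie-free, otherwise the normal approximation with tie and
#' continuity correction (wraps `stats::wilcox.test`).
#'
#' @param a,b Non-empty numeric vectors.
#' @return List: `U`, `p_value`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; df = (r - 1)(c - 1). Errors on zero marginals.
#'
#' @param table Matrix of counts.
#' @return List: `statistic`, `p_value`, `df`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Ordinary least-squares fit with named predictors
#'
#' Complete-case least squares with intercept; coefficient standard errors,
#' t-based two-sided p-values and R-squared (wraps `stats::lm`).
#'
#' @param response Numeric vector.
#' @param predictors Named list or data.frame of numeric predictors.
#' @return List: `coefficients`, `standard_errors`, `p_values` (all named,
#'   including `(Intercept)`), `r_squared`, `n`.
#' @export
ols_fit <- function(response, predictors) {
  df <- as.data.frame(predictors)
  stopifnot(!is.null(names(df)), all(nzchar(names(df))))
  df$.response <- response
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= ncol(df)) stop("too few complete cases for the design", call. = FALSE)
  fit <- stats::lm(.response ~ ., data = df)
  if (fit$rank < ncol(df)) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  list(
    coefficients = stats::coef(fit),
    standard_errors = sm$coefficients[, "Std. Error"],
    p_values = sm$coefficients[, "Pr(>|t|)"],
    r_squared = sm$r.squared,
    n = n
  )
}

#' Run a declared family of (partial) Spearman correlations with shared FDR
#'
#' Each request is a pair of cohort column names with an optional covariate
#' column; plain requests use [spearman()], covariate requests
#' [partial_spearman()]. BH adjustment is applied across the whole family.
#'
#' @param cohort Cohort data.frame.
#' @param spec data.frame (or list of lists) with columns/fields `x`, `y` and
#'   optional `covariate` (NA or "" for none).
#' @return data.frame: `var_x`, `var_y`, `covariate`, `n`, `rho`, `p_value`,
#'   `q_value`.
#' @export
correlation_battery <- function(cohort, spec) {
  if (!is.data.frame(spec)) {
    spec <- do.call(rbind, lapply(spec, function(s) {
      data.frame(x = s$x, y = s$y,
                 covariate = if (is.null(s$covariate)) NA_character_ else s$covariate,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!"covariate" %in% names(spec)) spec$covariate <- NA_character_
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    xn <- spec$x[i]; yn <- spec$y[i]; zn <- spec$covariate[i]
    for (v in c(xn, yn, if (!is.na(zn) && nzchar(zn)) zn)) {
      if (!v %in% names(cohort)) stop("unknown column: ", v, call. = FALSE)
    }
    res <- if (is.na(zn) || !nzchar(zn)) {
      spearman(cohort[[xn]], cohort[[yn]])
    } else {
      partial_spearman(cohort[[xn]], cohort[[yn]], cohort[[zn]])
    }
    data.frame(var_x = xn, var_y = yn,
               covariate = if (is.na(zn)) "" else zn,
               n = res$n, rho = res$rho, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}
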