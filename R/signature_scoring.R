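# Geometric-mean composite expression scores for configurable gene panels.

#' Built-in immune signature panels
#'
#' The eight composite panels used throughout the analysis, with the default
#' pseudocount of 0.01 (TPM scale) applied uniformly:
#' \itemize{
#'   \item `exhaustion` - 17 canonical T-cell exhaustion-associated genes:
#'     six core checkpoint/exhaustion markers, eight exhaustion-associated
#'     transcription factors, and three co-inhibitory receptors.
#'   \item `core_exhaustion` - the six primary checkpoint/exhaustion markers.
#'   \item `antigen_presentation` - 17 MHC class I/II presentation-pathway
#'     genes (heavy chains, B2M, TAP, tapasin, ER chaperones,
#'     immunoproteasome, class II components).
#'   \item `mhc_class_i` - the six classical class I genes only.
#'   \item `immunosuppressive` - 14 curated immunosuppressive genes.
#'   \item `ifng` - ten interferon-gamma pathway genes.
#'   \item `estimate_style` - a 13-gene composite immune-infiltration score.
#'   \item `cyt` - cytolytic activity, GZMA and PRF1.
#' }
#'
#' @param pseudocount Positive offset added to expression before the log.
#' @return Named list of panels, each a list with `name`, `genes`,
#'   `pseudocount`.
#' @export
builtin_panels <- function(pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  panel <- function(name, genes) list(name = name, genes = genes,
                                      pseudocount = pseudocount)
  list(
    exhaustion = panel("exhaustion", c(
      "PDCD1", "LAG3", "HAVCR2", "CTLA4", "TIGIT", "ENTPD1",
      "TOX", "TCF7", "TBX21", "EOMES", "PRDM1", "BATF", "IRF4", "NR4A1",
      "CD244", "CD160", "BTLA")),
    core_exhaustion = panel("core_exhaustion", c(
      "PDCD1", "LAG3", "HAVCR2", "CTLA4", "TIGIT", "TOX")),
    antigen_presentation = panel("antigen_presentation", c(
      "HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2", "TAPBP",
      "CALR", "PDIA3", "CANX", "PSMB8", "PSMB9", "PSMB10",
      "HLA-DRA", "HLA-DRB1", "CD74", "CIITA")),
    mhc_class_i = panel("mhc_class_i", c(
      "HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2")),
    immunosuppressive = panel("immunosuppressive", c(
      "NT5E", "TNFRSF12A", "TGFB1", "TGFB2", "TGFBR1", "TGFBR2",
      "IL1A", "IL1B", "IDO1", "IDO2", "FOXP3", "IL10", "IL10RA", "VEGFA")),
    ifng = panel("ifng", c(
      "IFNG", "STAT1", "IRF1", "JAK1", "JAK2",
      "CXCL9", "CXCL10", "CXCL11", "IFNGR1", "IFNGR2")),
    estimate_style = panel("estimate_style", c(
      "CD8A", "CD3D", "CD3E", "GZMB", "GNLY", "NKG7", "IL2RB",
      "PDCD1", "CTLA4", "IFNG", "STAT1", "CXCL9", "CXCL10")),
    cyt = panel("cyt", c("GZMA", "PRF1"))
  )
}

#' Geometric-mean signature score
#'
#' Per patient, exp(mean over found panel genes of ln(value + pseudocount)).
#' Panel genes missing from the matrix are dropped and reported; when the
#' fraction found falls below `min_coverage` the score is NA.
#'
#' @param expr Numeric expression matrix, genes x patients (non-negative,
#'   TPM-like).
#' @param panel A panel list (`name`, `genes`, `pseudocount`) as produced by
#'   [builtin_panels()], or a character vector of gene symbols.
#' @param min_coverage Minimum fraction of panel genes that must be present
#'   for a non-NA score (default 0.8).
#' @return Numeric vector of per-patient scores (named by patient), with
#'   attributes `panel_name`, `n_genes_found`, `missing_genes`.
#' @export
geometric_mean_score <- function(expr, panel, min_coverage = 0.8) {
  if (is.character(panel)) panel <- list(name = "custom", genes = panel,
                                         pseudocount = 0.01)
  found <- intersect(panel$genes, rownames(expr))
  if (!length(found)) {
    stop("no genes of panel '", panel$name, "' found in expression matrix",
         call. = FALSE)
  }
  sub <- expr[found, , drop = FALSE]
  score <- exp(colMeans(log(sub + panel$pseudocount)))
  if (length(found) / length(panel$genes) < min_coverage) {
    score[] <- NA_real_
    warning("panel '", panel$name, "': only ", length(found), "/",
            length(panel$genes), " genes found (< min_coverage); score set NA",
            call. = FALSE)
  }
  attr(score, "panel_name") <- panel$name
  attr(score, "n_genes_found") <- length(found)
  attr(score, "missing_genes") <- setdiff(panel$genes, found)
  score
}

#' Cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression with a small offset:
#' sqrt((GZMA + offset) (PRF1 + offset)).
#'
#' @param expr Expression matrix, genes x patients.
#' @param offset Stabilising offset (default 0.01).
#' @return Per-patient score vector.
#' @export
cyt_score <- function(expr, offset = 0.01) {
  for (g in c("GZMA", "PRF1")) {
    if (!g %in% rownames(expr)) stop("gene ", g, " missing from expression matrix",
                                     call. = FALSE)
  }
  sqrt((expr["GZMA", ] + offset) * (expr["PRF1", ] + offset))
}

#' Score all panels and return a per-patient table
#'
#' @param expr Expression matrix, genes x patients.
#' @param panels List of panels (default [builtin_panels()]).
#' @param min_coverage Passed to [geometric_mean_score()].
#' @return data.frame: `patient_id` plus one `score_<panel>` column per panel.
#' @export
score_signatures <- function(expr, panels = builtin_panels(),
                             min_coverage = 0.8) {
  out <- data.frame(patient_id = colnames(expr), stringsAsFactors = FALSE)
  for (p in panels) {
    out[[paste0("score_", p$name)]] <-
      as.numeric(geometric_mean_score(expr, p, min_coverage))
  }
  out
}
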