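# Shared fixture builders: small epitope tables constructed in code.

make_epitopes <- function(patient_id, vaf, ic50, peptide = NULL,
                          gene = "TP53", allele = "HLA-A*02:01",
                          wt_ic50 = NA_real_, variant_id = NULL) {
  n <- max(length(patient_id), length(vaf), length(ic50), length(gene),
           length(peptide), length(allele), length(wt_ic50),
           length(variant_id))
  if (is.null(peptide)) {
    peptide <- vapply(seq_len(n), function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9,
                   replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(variant_id)) variant_id <- paste0("v", seq_len(n))
  data.frame(
    patient_id = rep_len(patient_id, n),
    gene_symbol = rep_len(gene, n),
    peptide = rep_len(peptide, n),
    hla_allele = rep_len(allele, n),
    ic50_nm = rep_len(ic50, n),
    wt_ic50_nm = rep_len(wt_ic50, n),
    vaf = rep_len(vaf, n),
    variant_id = rep_len(variant_id, n),
    stringsAsFactors = FALSE
  )
}

# Random toy patient for oracle-equivalence checks.
random_toy_patient <- function(id, max_peptides = 50L) {
  k <- sample.int(max_peptides, 1L)
  make_epitopes(
    patient_id = id,
    vaf = round(runif(k), 3),
    ic50 = round(exp(rnorm(k, log(400), 1.5)), 2),
    variant_id = paste0(id, "_v", sample.int(max(1L, k %/% 2L), k,
                                             replace = TRUE))
  )
}
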