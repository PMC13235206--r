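test_that("binder thresholds are inclusive at 500 and 50 nM", {
  rec <- classify_binders(make_epitopes("P1", vaf = 0.1,
                                        ic50 = c(500, 50, 500.01)))
  expect_equal(rec$binder, c(TRUE, TRUE, FALSE))
  expect_equal(rec$strong_binder, c(FALSE, TRUE, FALSE))
})

test_that("binder-weighted VAF sums VAFs over binder peptides only", {
  expect_equal(binder_weighted_vaf(make_epitopes("P1", vaf = numeric(0),
                                                 ic50 = numeric(0))), 0)
  rec <- make_epitopes("P1", vaf = c(0.5, 0.4, 0.2), ic50 = c(100, 600, 30))
  expect_equal(binder_weighted_vaf(rec), 0.7)
  # one variant yielding three binder peptides contributes three times
  rec3 <- make_epitopes("P1", vaf = 0.5, ic50 = c(10, 20, 30),
                        peptide = c("ACDEFGHIK", "CDEFGHIKA", "DEFGHIKAC"),
                        variant_id = "v1")
  expect_equal(binder_weighted_vaf(rec3), 1.5)
})

test_that("clonality score divides by binder count plus one", {
  expect_equal(clonality_score(0, 0), 0)
  expect_equal(clonality_score(0.7, 2), 0.7 / 3)
  expect_equal(clonality_score(1.5, 3), 0.375)
})

test_that("clonality variants follow their definitions", {
  rec <- make_epitopes("P1", vaf = c(0.5, 0.2, 0.1, 0.3),
                       ic50 = c(100, 30, 900, 700))
  v <- clonality_variants(rec, log_eps = 1e-6)
  expect_equal(v$raw_bwv, 0.7)
  expect_equal(v$mean_vaf_per_binder, 0.35)
  expect_equal(v$bwv_over_total, 0.7 / 5)
  expect_equal(v$log_clonality, log(0.7 / 3 + 1e-6))

  none <- make_epitopes("P1", vaf = 0.5, ic50 = 1000)
  v0 <- clonality_variants(none)
  expect_true(is.na(v0$mean_vaf_per_binder))
  expect_equal(v0$raw_bwv, 0)
  expect_equal(v0$log_clonality, log(1e-6))
})

test_that("log-transformed clonality preserves the score's ranking", {
  set.seed(11)
  bwv <- runif(40, 0, 5)
  n500 <- rpois(40, 10)
  cs <- clonality_score(bwv, n500)
  expect_equal(cor(cs, log(cs + 1e-6), method = "spearman"), 1)
})

test_that("mean delta IC50 uses the log-ratio convention on wild-type pairs", {
  same <- make_epitopes("P1", vaf = 0.1, ic50 = c(100, 30),
                        wt_ic50 = c(100, 30))
  expect_equal(mean_delta_ic50(same), 0)
  one <- make_epitopes("P1", vaf = 0.1, ic50 = 50, wt_ic50 = 100)
  expect_equal(mean_delta_ic50(one), log10(0.5), tolerance = 1e-12)
  expect_equal(mean_delta_ic50(one, convention = "difference"), -50)
  expect_true(is.na(mean_delta_ic50(make_epitopes("P1", vaf = 0.1,
                                                  ic50 = 10))))
})

test_that("public/private labeling requires two distinct patients", {
  rec <- rbind(
    make_epitopes("TCGA-AA-0001", vaf = 0.1, ic50 = 10,
                  peptide = c("AAAAAAAAA", "CCCCCCCCC")),
    make_epitopes("TCGA-AA-0002", vaf = 0.1, ic50 = 10,
                  peptide = "AAAAAAAAA"),
    make_epitopes("TCGA-AA-0003", vaf = 0.1, ic50 = 10,
                  peptide = "DDDDDDDDD"))
  lab <- label_public_private(rec)
  expect_identical(lab$public_peptides, "AAAAAAAAA")
  pp <- lab$per_patient
  expect_equal(pp$n_public[pp$patient_id == "TCGA-AA-0001"], 1L)
  expect_equal(pp$n_private[pp$patient_id == "TCGA-AA-0001"], 1L)
  expect_equal(pp$n_public[pp$patient_id == "TCGA-AA-0002"], 1L)
  expect_equal(pp$n_private[pp$patient_id == "TCGA-AA-0003"], 1L)

  # same peptide on two alleles of one patient stays private
  solo <- rbind(
    make_epitopes("P1", vaf = 0.1, ic50 = 10, peptide = "EEEEEEEEE",
                  allele = "HLA-A*02:01", variant_id = "v1"),
    make_epitopes("P1", vaf = 0.1, ic50 = 10, peptide = "EEEEEEEEE",
                  allele = "HLA-B*07:02", variant_id = "v1"))
  expect_length(label_public_private(solo)$public_peptides, 0L)
})

test_that("dominant gene is the binder-count argmax with lexicographic ties", {
  rec <- make_epitopes("P1", vaf = 0.1, ic50 = 10,
                       gene = c(rep("TP53", 5), rep("TTN", 3)))
  expect_identical(dominant_gene(rec), "TP53")
  tie <- make_epitopes("P1", vaf = 0.1, ic50 = 10,
                       gene = c("B", "B", "A", "A"))
  expect_warning(g <- dominant_gene(tie), "tie")
  expect_identical(g, "A")
  none <- make_epitopes("P1", vaf = 0.1, ic50 = 1000)
  expect_true(is.na(dominant_gene(none)))
})

test_that("TMB is mutations per covered megabase", {
  expect_equal(compute_tmb(110, 40), 2.75)
  expect_equal(compute_tmb(0, 38), 0)
  expect_error(compute_tmb(10, 0), "positive")
})

test_that("gene-level summary takes medians over harbouring patients", {
  rec <- rbind(
    make_epitopes("P1", vaf = 0.1, ic50 = 10, gene = "G",
                  peptide = c("AAAAAAAAA", "CCCCCCCCC")),
    make_epitopes("P2", vaf = 0.1, ic50 = 10, gene = "G",
                  peptide = c("DDDDDDDDD", "EEEEEEEEE", "FFFFFFFFF",
                              "HHHHHHHHH")),
    make_epitopes("P3", vaf = 0.1, ic50 = 10, gene = "X",
                  peptide = "IIIIIIIII"))
  cohort <- data.frame(patient_id = c("P1", "P2", "P3"),
                       tide_dysfunction = c(1, 3, 100),
                       tide_exclusion = c(0, 2, -5), pdl1 = c(10, 30, 0))
  gs <- gene_level_summary(rec, cohort)
  g <- gs[gs$gene_symbol == "G", ]
  expect_equal(g$n_patients_with_neo, 2L)
  expect_equal(g$median_neo_n_500, 3)           # median of {2, 4}
  expect_equal(g$median_tide_dysfunction, 2)    # harbouring patients only
  expect_false("ABSENT" %in% gs$gene_symbol)
})

test_that("per-patient summary satisfies count and partition invariants", {
  set.seed(21)
  recs <- do.call(rbind, lapply(sprintf("TCGA-TT-%04d", 1:30),
                                random_toy_patient))
  smry <- summarize_neoantigens(recs)
  expect_true(all(smry$neo_n_50 <= smry$neo_n_500))
  expect_true(all(smry$neo_n_500 <= smry$neo_n_total))
  expect_equal(smry$len_8 + smry$len_9 + smry$len_10 + smry$len_11,
               smry$neo_n_total)
  expect_equal(smry$n_public + smry$n_private, smry$n_distinct)
  expect_equal(smry$clonality_score,
               smry$binder_weighted_vaf / (smry$neo_n_500 + 1))
})

test_that("scaling every VAF by c scales the score by exactly c", {
  set.seed(31)
  rec <- random_toy_patient("TCGA-SC-0001")
  for (c_mult in c(0.25, 0.5, 0.9)) {
    scaled <- rec
    scaled$vaf <- scaled$vaf * c_mult
    expect_equal(binder_weighted_vaf(scaled),
                 c_mult * binder_weighted_vaf(rec), tolerance = 1e-12)
  }
})

test_that("adding a non-binder leaves the binder-weighted VAF unchanged", {
  set.seed(41)
  rec <- random_toy_patient("TCGA-NB-0001")
  extra <- make_epitopes("TCGA-NB-0001", vaf = 0.9, ic50 = 501)
  v1 <- clonality_variants(rec)
  v2 <- clonality_variants(rbind(rec, extra))
  expect_equal(v2$raw_bwv, v1$raw_bwv)
  expect_lte(v2$bwv_over_total, v1$bwv_over_total)
})
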