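make_public_fixture <- function() {
  rbind(
    make_epitopes("P1", vaf = 0.1, ic50 = 10, peptide = "AAAAAAAAA"),
    make_epitopes("P2", vaf = 0.1, ic50 = 10,
                  peptide = c("AAAAAAAAA", "CCCCCCCCC")),
    make_epitopes("P3", vaf = 0.1, ic50 = 10,
                  peptide = c("CCCCCCCCC", "DDDDDDDDD")),
    make_epitopes("P4", vaf = 0.1, ic50 = 10, peptide = "DDDDDDDDD"))
}

test_that("public universe is the set of peptides shared by >= 2 patients", {
  rec <- rbind(
    make_epitopes("P1", vaf = 0.1, ic50 = 10,
                  peptide = c("AAAAAAAAA", "CCCCCCCCC")),
    make_epitopes("P2", vaf = 0.1, ic50 = 10,
                  peptide = c("CCCCCCCCC", "DDDDDDDDD")),
    make_epitopes("P3", vaf = 0.1, ic50 = 10, peptide = "DDDDDDDDD"))
  expect_setequal(public_universe(rec), c("CCCCCCCCC", "DDDDDDDDD"))
  # no sharing -> empty
  lone <- make_epitopes(c("P1", "P2"), vaf = 0.1, ic50 = 10,
                        peptide = c("EEEEEEEEE", "FFFFFFFFF"))
  expect_length(public_universe(lone), 0L)
  # invariant to patient order
  expect_setequal(public_universe(rec[nrow(rec):1, ]), public_universe(rec))
})

test_that("set-cover curve follows count ranking with id tie-breaks", {
  rec <- make_public_fixture()
  curve <- set_cover_curve(records = rec)
  expect_equal(curve$patient_id, c("P2", "P3", "P1", "P4"))
  expect_equal(curve$cumulative_fraction, c(2 / 3, 1, 1, 1))
  expect_true(all(diff(curve$cumulative_fraction) >= 0))
  expect_equal(curve$cumulative_fraction[nrow(curve)], 1)
  expect_equal(attr(curve, "universe_size"), 3L)

  # all patients sharing one peptide saturates after the first
  one <- make_epitopes(c("P1", "P2", "P3"), vaf = 0.1, ic50 = 10,
                       peptide = "AAAAAAAAA")
  expect_equal(set_cover_curve(records = one)$cumulative_fraction,
               c(1, 1, 1))
  expect_error(set_cover_curve(records = lone <- make_epitopes(
    "P1", vaf = 0.1, ic50 = 10)), "empty public universe")
})

test_that("greedy mode orders patients by marginal gain", {
  rec <- make_public_fixture()
  g <- set_cover_curve(records = rec, greedy = TRUE)
  expect_equal(g$cumulative_fraction[2], 1)  # P2 then P3 covers everything
  expect_true(all(diff(g$cumulative_fraction) >= 0))
})

test_that("supertype assignment reads gene letter plus first field", {
  expect_equal(assign_supertype(c("HLA-C*07:02", "HLA-A*02:01",
                                  "HLA-B*44:02")),
               c("C07", "A02", "B44"))
  expect_equal(assign_supertype("garbage"), "Other")
  expect_equal(assign_supertype("C0702"), "Other")
  # lookup override wins
  expect_equal(assign_supertype("HLA-A*02:01",
                                lookup = c("HLA-A*02:01" = "A2-super")),
               "A2-super")
})

test_that("top allele is the binder-count argmax per patient", {
  rec <- rbind(
    make_epitopes("P1", vaf = 0.1, ic50 = 10, allele = "HLA-C*07:02",
                  peptide = sprintf("AAAAAAAA%s", c("A", "C", "D"))),
    make_epitopes("P1", vaf = 0.1, ic50 = 10, allele = "HLA-A*02:01",
                  peptide = "CCCCCCCCC"),
    make_epitopes("P2", vaf = 0.1, ic50 = 2000, allele = "HLA-B*44:02"))
  top <- patient_top_allele(rec)
  expect_equal(top$top_allele[top$patient_id == "P1"], "HLA-C*07:02")
  expect_equal(top$supertype[top$patient_id == "P1"], "C07")
  expect_false("P2" %in% top$patient_id)  # no binders -> no assignment

  tie <- make_epitopes("P3", vaf = 0.1, ic50 = 10,
                       allele = c("HLA-B*07:02", "HLA-A*01:01"),
                       peptide = c("DDDDDDDDD", "EEEEEEEEE"))
  expect_warning(t2 <- patient_top_allele(tie), "tie")
  expect_equal(t2$top_allele, "HLA-A*01:01")
})

test_that("coverage efficiency and strategies match exhaustive unions", {
  rec <- rbind(
    make_epitopes("P1", vaf = 0.1, ic50 = 10, allele = "HLA-C*07:02",
                  peptide = c("AAAAAAAAA", "CCCCCCCCC")),
    make_epitopes("P2", vaf = 0.1, ic50 = 10, allele = "HLA-C*07:01",
                  peptide = "AAAAAAAAA"),
    make_epitopes("P3", vaf = 0.1, ic50 = 10, allele = "HLA-A*02:01",
                  peptide = c("CCCCCCCCC", "DDDDDDDDD")),
    make_epitopes("P4", vaf = 0.1, ic50 = 10, allele = "HLA-A*02:01",
                  peptide = "DDDDDDDDD"))
  # universe = {A..., C..., D...}; C07 = {P1,P2}; A02 = {P3,P4}
  eff <- coverage_efficiency(rec, top_k = 1L)
  expect_equal(eff$fraction[eff$supertype == "C07"], 2 / 3)  # P1 covers A,C
  expect_equal(eff$fraction[eff$supertype == "A02"], 2 / 3)  # P3 covers C,D
  expect_true(all(eff$fraction <= 1))

  s <- strategy_coverage(rec, c("C07", "A02"), patients_per = 1L)
  expect_equal(s$total_patients, 2L)
  expect_equal(s$coverage_fraction, 1)  # P1 u P3 covers everything
  # group smaller than patients_per reports actual size
  s2 <- strategy_coverage(rec, "C07", patients_per = 10L)
  expect_equal(s2$total_patients, 2L)
  expect_error(strategy_coverage(rec, "Z99"), "unknown supertype")
})

test_that("coverage is invariant to duplicated peptide rows within a patient", {
  rec <- make_public_fixture()
  dup <- rbind(rec, make_epitopes("P2", vaf = 0.2, ic50 = 20,
                                  peptide = "AAAAAAAAA",
                                  variant_id = "vdup"))
  expect_equal(set_cover_curve(records = dup)$cumulative_fraction,
               set_cover_curve(records = rec)$cumulative_fraction)
})

test_that("nested strategies give nested coverage on random fixtures", {
  set.seed(23)
  sts <- c("C07", "C03", "A02", "B44", "Other")
  for (rep in 1:100) {
    n_pat <- sample(6:12, 1)
    peps <- sprintf("%s%08d", "A", 1:8)  # small shared pool forces publicity
    rec <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      k <- sample(1:4, 1)
      make_epitopes(sprintf("P%02d", i), vaf = 0.1, ic50 = 10,
                    peptide = sample(peps, k),
                    allele = sample(c("HLA-C*07:02", "HLA-C*03:04",
                                      "HLA-A*02:01", "HLA-B*44:02"), 1))
    }))
    if (length(public_universe(rec)) == 0) next
    assigned <- suppressWarnings(patient_top_allele(rec))
    present <- intersect(sts, assigned$supertype)
    if (length(present) < 2) next
    small <- present[1]
    cov_small <- strategy_coverage(rec, small, 2L, assigned)
    cov_big <- strategy_coverage(rec, present, 2L, assigned)
    expect_gte(cov_big$coverage_fraction, cov_small$coverage_fraction)
  }
})

test_that("summed per-patient public counts cover the universe at least twice", {
  set.seed(24)
  sim <- generate_cohort(neo_synth_config(n_patients = 60, seed = 77))
  lab <- label_public_private(sim$epitopes)
  expect_gte(sum(lab$per_patient$n_public), 2 * length(lab$public_peptides))
})
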