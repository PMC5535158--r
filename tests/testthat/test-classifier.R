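fx <- ecoli_ta_fixture()

test_that("the curated fixture reproduces every published class label", {
  res <- ta_classify(fx$operons, ratios = fx$ratios, tir = fx$tir,
                     synthesis = fx$synthesis)
  df <- as.data.frame(res)
  expect_identical(stats::setNames(df$class, df$operon_id),
                   fx$expected_class[df$operon_id])
  counts <- table(df$class)
  expect_identical(as.integer(counts[c("1", "2", "3", "4")]),
                   c(6L, 1L, 2L, 1L))
  # RnlAB: the only confident synthesis-rate ratio below one
  flags <- vapply(res$assignments, function(a)
    paste(a$anomaly_flags, collapse = ";"), "")
  expect_identical(names(flags)[flags == "synthesis_ratio_below_one"],
                   "RnlAB")
})

test_that("single-promoter systems with near-equal mRNA land in class 1", {
  a <- classify_operon(fx$operons$RelBE, fx$ratios$RelBE,
                       consensus = consensus_by_variant(fx$tir, "RelBE"))
  expect_identical(a$assigned_class, "1")
  expect_identical(a$mechanism, "translational")
})

test_that("a >2-fold median without promoter evidence gives class 3", {
  a <- classify_operon(fx$operons$`DinJ-YafQ`, fx$ratios$`DinJ-YafQ`,
                       consensus = consensus_by_variant(fx$tir, "DinJ-YafQ"))
  expect_identical(a$assigned_class, "3")
  expect_identical(a$mechanism, "transcript_truncation")
})

test_that("the borderline band is resolved by the TIR consensus", {
  # YafNO: 2.08 in band, toxin-higher consensus -> class 3
  y <- classify_operon(fx$operons$YafNO, fx$ratios$YafNO,
                       consensus = consensus_by_variant(fx$tir, "YafNO"))
  expect_identical(y$assigned_class, "3")
  # FicAT: 1.99 in band, antitoxin-higher consensus -> class 1
  f <- classify_operon(fx$operons$FicAT, fx$ratios$FicAT,
                       consensus = consensus_by_variant(fx$tir, "FicAT"))
  expect_identical(f$assigned_class, "1")
  # borderline without any consensus stays unclassified
  u <- classify_operon(fx$operons$FicAT, fx$ratios$FicAT)
  expect_identical(u$assigned_class, "unclassified")
})

test_that("a proximal second external promoter gives class 2", {
  h <- classify_operon(fx$operons$HicAB, fx$ratios$HicAB,
                       consensus = consensus_by_variant(fx$tir, "HicAB"))
  expect_identical(h$assigned_class, "2")
  # a distal second external promoter does not
  far <- ta_operon("far", fx$operons$HicAB$genes,
                   promoters = data.frame(promoter_id = c("P1", "P2"),
                                          tss = c(0L, 2L)))
  a <- classify_operon(far, fx$ratios$HicAB)
  expect_identical(a$assigned_class, "1")
})

test_that("an internal promoter dominates and contradictions are recorded", {
  r <- classify_operon(fx$operons$RnlAB, fx$ratios$RnlAB,
                       synthesis = fx$synthesis$RnlAB)
  expect_identical(r$assigned_class, "4")
  expect_identical(r$anomaly_flags, "synthesis_ratio_below_one")
  # internal + proximal second external: class 4 wins, contradiction logged
  g <- fx$operons$RnlAB$genes
  first_cds <- min(g$start)
  both <- ta_operon("both", g, promoters = data.frame(
    promoter_id = c("P1", "P2", "Pint"),
    tss = c(0L, first_cds - 5L,
            gene_by_role(fx$operons$RnlAB, "antitoxin")$start - 280L)))
  a <- classify_operon(both, fx$ratios$RnlAB)
  expect_identical(a$assigned_class, "4")
  expect_true(any(grepl("contradiction", a$evidence)))
})

test_that("changepoint evidence substitutes for promoter annotation", {
  # up-step between the first CDS start and the antitoxin start -> class 4
  op <- ta_operon("cp4", rbind(ta_gene("T", "toxin", 60L, 360L),
                               ta_gene("A", "antitoxin", 357L, 600L)),
                  promoters = data.frame(promoter_id = "P1", tss = 0L))
  set.seed(21)
  prof <- ta_profile("cp4", c(rpois(200, 40), rpois(400, 160)))
  cp <- detect_changepoint(prof, operon = op)
  a <- classify_operon(op, ratio_summary("cp4", 1.0, 0.1, n_datasets = 13),
                       changepoint = cp)
  expect_identical(a$assigned_class, "4")
  # down-step inside the toxin CDS -> class 3
  op3 <- ta_operon("cp3", rbind(ta_gene("A", "antitoxin", 60L, 300L),
                                ta_gene("T", "toxin", 297L, 600L)),
                   promoters = data.frame(promoter_id = "P1", tss = 0L))
  prof3 <- ta_profile("cp3", c(rpois(350, 160), rpois(250, 40)))
  cp3 <- detect_changepoint(prof3, operon = op3)
  a3 <- classify_operon(op3, ratio_summary("cp3", 1.4, 0.1, n_datasets = 13),
                        changepoint = cp3)
  expect_identical(a3$assigned_class, "3")
})

test_that("operons failing the coverage filter stay unclassified", {
  r <- ratio_summary("x", 1.5, 0.2, n_datasets = 13, included = FALSE)
  a <- classify_operon(fx$operons$RelBE, r)
  expect_identical(a$assigned_class, "unclassified")
  expect_identical(a$mechanism, "unknown")
})

test_that("classification is deterministic and monotone in the median ratio", {
  op <- fx$operons$RelBE
  cons <- consensus_by_variant(fx$tir, "RelBE")   # antitoxin_higher
  a1 <- classify_operon(op, fx$ratios$RelBE, consensus = cons)
  a2 <- classify_operon(op, fx$ratios$RelBE, consensus = cons)
  expect_identical(a1, a2)
  # increasing the median never moves class 3 back to class 1
  meds <- seq(0.5, 4, by = 0.05)
  classes <- vapply(meds, function(m)
    classify_operon(op, ratio_summary("RelBE", m, 0.1, n_datasets = 13),
                    consensus = cons)$assigned_class, "")
  seen3 <- FALSE
  for (cl in classes) {
    if (cl == "3") seen3 <- TRUE
    if (seen3) expect_identical(cl, "3")
  }
  expect_setequal(unique(classes), c("1", "3"))
})

test_that("print and summary methods render the evidence trail", {
  res <- ta_classify(fx$operons, ratios = fx$ratios, tir = fx$tir,
                     synthesis = fx$synthesis)
  expect_output(print(res), "TA operon classification")
  expect_output(print(res$assignments$RnlAB), "internal_promoter")
  s <- summary(res)
  expect_identical(as.integer(s$class_counts[c("1", "2", "3", "4")]),
                   c(6L, 1L, 2L, 1L))
})
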