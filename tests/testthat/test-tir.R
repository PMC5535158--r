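test_that("TIR calls derive the sign and reject ties", {
  cl <- tir_call("relBE", "barrick", "P1", 1200, 300)
  expect_identical(cl$sign, "antitoxin_higher")
  expect_identical(tir_call("x", "barrick", "P1", 10, 40)$sign, "toxin_higher")
  expect_error(tir_call("x", "barrick", "P1", 5, 5), "tied")
  expect_error(tir_call("x", "barrick", "P1", NA, 5), "non-numeric")
})

test_that("the TSV reader rejects non-numeric and tied rows with warnings", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "tir.tsv")
  writeLines(c("operon_id\tmethod\tvariant\ttir_antitoxin\ttir_toxin",
               "relBE\tbarrick\tP1\t1200\t300",
               "relBE\tutr_designer\tP1\tNaN?\t300",
               "relBE\trbs_calculator\tP1\t500\t500",
               "mazEF\tbarrick\tP1\t100\t900"), p)
  expect_warning(expect_warning(calls <- read_tir_table(p), "non-numeric"),
                 "tied")
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$sign, c("antitoxin_higher", "toxin_higher"))
})

test_that("2-of-3 consensus follows the majority of available signs", {
  expect_identical(tir_consensus(random_consensus_df(c("+", "+", "+")))$verdict,
                   "antitoxin_higher")
  # one dissenting thermodynamic calculator does not flip the verdict
  expect_identical(tir_consensus(random_consensus_df(c("-", "+", "+")))$verdict,
                   "antitoxin_higher")
  expect_identical(tir_consensus(random_consensus_df(c("-", "-", "+")))$verdict,
                   "toxin_higher")
  single <- random_consensus_df("+")
  expect_identical(tir_consensus(single)$verdict, "insufficient")
  expect_identical(tir_consensus(NULL)$verdict, "insufficient")
})

test_that("consensus equals brute-force majority over all 8 sign patterns", {
  for (a in c("+", "-")) for (b in c("+", "-")) for (c_ in c("+", "-")) {
    signs <- c(a, b, c_)
    v <- tir_consensus(random_consensus_df(signs))$verdict
    expected <- if (sum(signs == "+") >= 2) "antitoxin_higher"
                else "toxin_higher"
    expect_identical(v, expected)
    # permutation invariance
    v2 <- tir_consensus(random_consensus_df(signs[c(3, 1, 2)]))$verdict
    expect_identical(v2, v)
    # flipping every sign flips the verdict
    flipped <- ifelse(signs == "+", "-", "+")
    vf <- tir_consensus(random_consensus_df(flipped))$verdict
    expect_identical(vf, setdiff(c("antitoxin_higher", "toxin_higher"), v))
  }
})

test_that("the HicAB promoter variants flip the consensus verdict", {
  fx <- ecoli_ta_fixture()
  cv <- consensus_by_variant(fx$tir, "HicAB")
  expect_identical(cv$P1$verdict, "toxin_higher")
  expect_identical(cv$P2$verdict, "antitoxin_higher")
})

test_that("the fixture carries 3 sign calls per system plus the HicAB retest", {
  fx <- ecoli_ta_fixture()
  expect_identical(nrow(fx$tir), 33L)   # 10 systems x 3 + HicAB P2 x 3
  expect_identical(length(unique(fx$tir$operon_id)), 10L)
})

test_that("the surrogate scorer favors SD complementarity at good spacing", {
  cfg <- tir_scorer_config()
  # -11..+1 window: AGGAGG ending 5 nt before the start codon vs all-C
  sd_seq <- paste0("AGGAGG", "AAAAA", "AT")   # 11 upstream + A,T of ATG
  cc_seq <- paste0(strrep("C", 11), "AT")
  expect_gt(builtin_window_score(paste0(sd_seq, "G"), 11, cfg),
            builtin_window_score(paste0(cc_seq, "G"), 11, cfg))
  # determinism
  expect_identical(builtin_window_score(paste0(sd_seq, "G"), 11, cfg),
                   builtin_window_score(paste0(sd_seq, "G"), 11, cfg))
  expect_error(builtin_window_score("ATG", 0, cfg), "off the sequence")
})

test_that("the scorer equals a brute-force evaluation under random configs", {
  set.seed(88)
  for (rep in 1:100) {
    cfg <- list(
      sd_consensus = "AGGAGG",
      asd_weight = runif(1, 0.1, 2),
      spacing_penalty = runif(1, 0, 1),
      optimal_spacing = sample(3:8, 1),
      position_weights = setNames(lapply(-11:1, function(i)
        as.list(setNames(round(runif(4, -0.5, 0.5), 3),
                         c("A", "C", "G", "T")))),
        as.character(-11:1)))
    seqn <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
    pos <- sample(11:(30 - 2), 1)
    got <- builtin_window_score(seqn, pos, cfg)
    win <- strsplit(substr(seqn, pos - 11 + 1, pos + 1 + 1), "")[[1]]
    expect_equal(got, oracle_window_score(win, -11:1, cfg), tolerance = 1e-12)
  }
})

test_that("builtin calls rank a strong antitoxin RBS above a weak toxin RBS", {
  set.seed(4)
  bases <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  # plant a perfect SD in front of the antitoxin start (100), all-C before
  # the toxin start (400)
  bases[90:95] <- strsplit("AGGAGG", "")[[1]]   # rel -11..-6 before pos 100
  bases[(400 - 11 + 1):(400 + 0)] <- "C"
  op <- ta_operon("syn", rbind(ta_gene("A", "antitoxin", 100L, 403L),
                               ta_gene("T", "toxin", 400L, 700L)),
                  sequence = paste(bases, collapse = ""))
  cl <- builtin_tir_call(op)
  expect_identical(cl$method, "builtin")
  expect_identical(cl$sign, "antitoxin_higher")
})
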