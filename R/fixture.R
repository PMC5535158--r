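#' Curated ten-system E. coli K-12 TA fixture
#'
#' A bundled evidence set for the ten type II toxin-antitoxin systems of
#' E. coli K-12 MG1655 that have sufficient public RNA-seq coverage:
#' operon organization (gene order, approximate CDS lengths, promoter
#' structure), published median antitoxin/toxin coverage ratios with their
#' standard deviations (n = 13 datasets), the sign calls of three TIR
#' calculators per system (including both promoter variants of HicAB), and
#' sign-level protein synthesis-rate records. Gene coordinates are
#' synthetic-but-typical reconstructions in a local operon frame (60 nt
#' leader); only promoter structure, ratio summaries and TIR signs drive the
#' classifier, so class labels do not depend on the reconstructed lengths.
#' Synthesis-rate magnitudes are synthetic except the RelBE antitoxin/toxin
#' ratio of 7.5; read counts encode which systems fall under the 128-read
#' low-confidence rule (FicAT, HicAB).
#'
#' @return List with components \code{operons} (named list of
#'   \code{"ta_operon"}), \code{ratios} (named list of
#'   \code{"ratio_summary"}), \code{tir} (TIR call \code{data.frame}),
#'   \code{synthesis} (named list of \code{"synthesis_rates"}),
#'   \code{ratio_category} (printed mRNA-ratio category per system, with
#'   footnote markers: \code{*} borderline, \code{**} truncated functional
#'   mRNA), and \code{expected_class} (named character vector of the
#'   published class labels, for validation).
#' @examples
#' fx <- ecoli_ta_fixture()
#' res <- ta_classify(fx$operons, ratios = fx$ratios, tir = fx$tir,
#'                    synthesis = fx$synthesis)
#' summary(res)
#' @export
ecoli_ta_fixture <- function() {
  leader <- 60L
  mk <- function(id, g1, r1, L1, g2, r2, L2, overlap = 3L, gap = NA_integer_) {
    s1 <- leader; e1 <- s1 + L1
    s2 <- if (is.na(gap)) e1 - overlap else e1 + gap
    e2 <- s2 + L2
    ta_operon(id, rbind(ta_gene(g1, r1, s1, e1), ta_gene(g2, r2, s2, e2)),
              promoters = data.frame(promoter_id = "P1", tss = 10L,
                                     stringsAsFactors = FALSE))
  }
  operons <- list(
    FicAT       = mk("FicAT", "ficA", "antitoxin", 219L, "ficT", "toxin", 537L),
    `YefM-YoeB` = mk("YefM-YoeB", "yefM", "antitoxin", 252L, "yoeB", "toxin", 255L),
    MazEF       = mk("MazEF", "mazE", "antitoxin", 249L, "mazF", "toxin", 336L),
    `PrlF-YhaV` = mk("PrlF-YhaV", "prlF", "antitoxin", 336L, "yhaV", "toxin", 465L),
    MqsAR       = mk("MqsAR", "mqsR", "toxin", 297L, "mqsA", "antitoxin", 396L),
    RelBE       = mk("RelBE", "relB", "antitoxin", 240L, "relE", "toxin", 288L),
    HicAB       = mk("HicAB", "hicA", "toxin", 177L, "hicB", "antitoxin", 417L,
                     gap = 30L),
    `DinJ-YafQ` = mk("DinJ-YafQ", "dinJ", "antitoxin", 261L, "yafQ", "toxin", 279L),
    YafNO       = mk("YafNO", "yafN", "antitoxin", 294L, "yafO", "toxin", 399L),
    RnlAB       = mk("RnlAB", "rnlA", "toxin", 1071L, "rnlB", "antitoxin", 372L)
  )
  # HicAB: a second external promoter just upstream of the toxin RBS
  hic_first <- min(operons$HicAB$genes$start)
  operons$HicAB <- ta_operon("HicAB", operons$HicAB$genes,
    promoters = data.frame(promoter_id = c("P1", "P2"),
                           tss = c(0L, hic_first - 10L),
                           stringsAsFactors = FALSE))
  # RnlAB: internal promoter ~280 nt upstream of the antitoxin, inside rnlA
  rnl_a_start <- gene_by_role(operons$RnlAB, "antitoxin")$start
  operons$RnlAB <- ta_operon("RnlAB", operons$RnlAB$genes,
    promoters = data.frame(promoter_id = c("P1", "Pint"),
                           tss = c(10L, rnl_a_start - 280L),
                           stringsAsFactors = FALSE))

  med <- c(FicAT = 1.99, `YefM-YoeB` = 1.89, MazEF = 1.42,
           `PrlF-YhaV` = 1.11, MqsAR = 0.69, RelBE = 0.95, HicAB = 0.93,
           `DinJ-YafQ` = 2.89, YafNO = 2.08, RnlAB = 1.01)
  sdv <- c(FicAT = 0.53, `YefM-YoeB` = 0.42, MazEF = 0.25,
           `PrlF-YhaV` = 0.27, MqsAR = 0.16, RelBE = 0.10, HicAB = 0.20,
           `DinJ-YafQ` = 0.35, YafNO = 0.39, RnlAB = 0.25)
  ratios <- lapply(stats::setNames(names(med), names(med)), function(id)
    ratio_summary(id, median_ratio = med[[id]], sd_ratio = sdv[[id]],
                  n_datasets = 13L, included = TRUE))

  signs <- rbind(
    c("FicAT", "P1", "+", "+", "+"),
    c("MazEF", "P1", "+", "+", "+"),
    c("MqsAR", "P1", "-", "+", "+"),
    c("PrlF-YhaV", "P1", "+", "+", "+"),
    c("RelBE", "P1", "+", "+", "+"),
    c("YefM-YoeB", "P1", "+", "+", "+"),
    c("HicAB", "P1", "-", "-", "+"),
    c("HicAB", "P2", "+", "-", "+"),
    c("DinJ-YafQ", "P1", "+", "-", "-"),
    c("YafNO", "P1", "+", "-", "-"),
    c("RnlAB", "P1", "+", "+", "-"))
  methods <- c("rbs_calculator", "utr_designer", "barrick")
  tir <- do.call(rbind, lapply(seq_len(nrow(signs)), function(i) {
    do.call(rbind, lapply(1:3, function(j) {
      plus <- signs[i, 2L + j] == "+"
      tir_call(signs[i, 1L], methods[j], signs[i, 2L],
               if (plus) 1500 else 400, if (plus) 500 else 1600)
    }))
  }))

  syn <- list(
    FicAT       = synthesis_rates("FicAT", 1.8, 0.9, 90, 60),      # LC
    `YefM-YoeB` = synthesis_rates("YefM-YoeB", 10.5, 3.1, 1500, 700),
    MazEF       = synthesis_rates("MazEF", 22.0, 6.4, 2600, 1100),
    `PrlF-YhaV` = synthesis_rates("PrlF-YhaV", 7.2, 2.3, 900, 500),
    MqsAR       = synthesis_rates("MqsAR", 4.1, 1.6, 620, 380),
    RelBE       = synthesis_rates("RelBE", 15.0, 2.0, 2100, 430),  # 7.5x
    HicAB       = synthesis_rates("HicAB", 0.7, 0.4, 50, 40),      # LC
    `DinJ-YafQ` = synthesis_rates("DinJ-YafQ", 12.8, 4.0, 1700, 820),
    YafNO       = synthesis_rates("YafNO", 3.3, 1.2, 480, 260),
    RnlAB       = synthesis_rates("RnlAB", 1.4, 3.9, 300, 900))    # A < T

  ratio_category <- c(FicAT = "<2 *", `YefM-YoeB` = "<2 *", MazEF = "<2",
                      `PrlF-YhaV` = "<2", MqsAR = "<2", RelBE = "<2",
                      HicAB = "<2", `DinJ-YafQ` = ">2", YafNO = ">2",
                      RnlAB = "<2 **")
  expected_class <- c(FicAT = "1", `YefM-YoeB` = "1", MazEF = "1",
                      `PrlF-YhaV` = "1", MqsAR = "1", RelBE = "1",
                      HicAB = "2", `DinJ-YafQ` = "3", YafNO = "3",
                      RnlAB = "4")
  list(operons = operons, ratios = ratios, tir = tir, synthesis = syn,
       ratio_category = ratio_category, expected_class = expected_class)
}
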