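#' Simulation configuration for synthetic TA operon data
#'
#' Defines the study conditions the generator emulates: 13 replicate RNA-seq
#' count tables (one condition in triplicate plus five conditions in
#' duplicate), negative-binomial count noise, Poisson base-coverage
#' profiles, class-specific transcript architectures, and TIR sign structure
#' consistent with each class.
#'
#' @param n_operons_per_class Operons simulated per class (default 50).
#' @param true_ratio_by_class Expected full-operon antitoxin/toxin coverage
#'   ratio per class (defaults: class 1 = 1.3, class 2 = 1.0, class 3 = 2.9,
#'   class 4 = 1.0).
#' @param depth_mean Expected reads per base for the toxin-level coverage
#'   (default 50).
#' @param nb_dispersion Negative-binomial dispersion of gene counts (default
#'   0.1; variance = mu + dispersion * mu^2).
#' @param toxin_length_range,antitoxin_length_range CDS length ranges in nt
#'   (defaults 250-350 and 200-300, typical of type II systems).
#' @param replicate_design Data frame with columns \code{condition} and
#'   \code{n_replicates}; the default is one condition x 3 replicates plus
#'   five conditions x 2 replicates (13 datasets).
#' @param step_fold Fold change of the class 3 (down) and class 4 (up)
#'   coverage steps in the base profiles (default 4).
#' @param leader Leader length upstream of the first CDS (default 60 nt).
#' @param total_mapped Nominal library size per dataset (default 2e6;
#'   jittered per dataset).
#' @param seed Integer seed; every draw is derived from it.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_operons_per_class = 50L,
                       true_ratio_by_class = c(`1` = 1.3, `2` = 1.0,
                                               `3` = 2.9, `4` = 1.0),
                       depth_mean = 50, nb_dispersion = 0.1,
                       toxin_length_range = c(250L, 350L),
                       antitoxin_length_range = c(200L, 300L),
                       replicate_design = data.frame(
                         condition = c("expA", paste0("cond", 1:5)),
                         n_replicates = c(3L, rep(2L, 5L))),
                       step_fold = 4, leader = 60L, total_mapped = 2e6,
                       seed = 20170701L) {
  stopifnot(n_operons_per_class >= 1L, nb_dispersion > 0, depth_mean > 0,
            step_fold > 1, all(replicate_design$n_replicates >= 1L))
  structure(list(n_operons_per_class = as.integer(n_operons_per_class),
                 true_ratio_by_class = true_ratio_by_class,
                 depth_mean = depth_mean, nb_dispersion = nb_dispersion,
                 toxin_length_range = as.integer(toxin_length_range),
                 antitoxin_length_range = as.integer(antitoxin_length_range),
                 replicate_design = replicate_design,
                 step_fold = step_fold, leader = as.integer(leader),
                 total_mapped = total_mapped, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate fully labelled synthetic TA operon data
#'
#' Emulates the four transcript architectures: class 1 operons produce a
#' single transcript (flat coverage, gene-level ratio ~1.3 from
#' translational-regulation-era expression); class 2 operons are HicAB-like
#' (toxin first, a >= 25 nt intergenic gap, two external promoters with the
#' second TSS 30 nt upstream of the first CDS); class 3 operons carry a
#' truncated transcript (coverage step-down inside the toxin CDS, gene-level
#' ratio ~2.9); class 4 operons carry an internal promoter (coverage step-up
#' upstream of the antitoxin inside the toxin CDS). Gene counts per dataset
#' are negative binomial around depth x length x ratio-factor x a per-library
#' scale factor; base profiles are Poisson. TIR signs are drawn so classes
#' 1/2 reach an antitoxin-higher 2-of-3 consensus, class 3 a toxin-higher
#' consensus, and class 4 a mixed-but-resolvable pattern. Synthesis rates
#' are antitoxin-higher except class 4.
#'
#' @param config A \code{"sim_config"}.
#' @return List with \code{operons} (named list), \code{tables} (list of 13
#'   \code{"ta_count_table"}), \code{profiles} (named list of
#'   \code{"ta_profile"}), \code{tir} (TIR call \code{data.frame}),
#'   \code{synthesis} (named list), and \code{truths} (\code{data.frame}
#'   with \code{operon_id}, \code{true_class}, \code{true_ratio},
#'   \code{breakpoint_pos}, \code{internal_promoter_pos}).
#' @export
simulate_ta <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per <- config$n_operons_per_class
  classes <- rep(1:4, each = n_per)
  ids <- sprintf("sim_c%d_%03d", classes, sequence(rep(n_per, 4L)))
  lead <- config$leader

  operons <- list(); truths <- vector("list", length(ids))
  prof_means <- list()   # per-base expected coverage (depth units of 1)
  for (k in seq_along(ids)) {
    cls <- classes[k]
    Lt <- sample(config$toxin_length_range[1L]:config$toxin_length_range[2L], 1L)
    La <- sample(config$antitoxin_length_range[1L]:config$antitoxin_length_range[2L], 1L)
    gA <- paste0(ids[k], "_A"); gT <- paste0(ids[k], "_T")
    bp <- NA_integer_; ip <- NA_integer_
    if (cls == 2L) {           # toxin first, non-overlapping
      s1 <- lead; e1 <- s1 + Lt; s2 <- e1 + 30L; e2 <- s2 + La
      genes <- rbind(ta_gene(gT, "toxin", s1, e1),
                     ta_gene(gA, "antitoxin", s2, e2))
      prom <- data.frame(promoter_id = c("P1", "P2"),
                         tss = c(0L, lead - 30L), stringsAsFactors = FALSE)
    } else if (cls == 4L) {    # toxin first, overlapping, internal promoter
      s1 <- lead; e1 <- s1 + Lt; s2 <- e1 - 3L; e2 <- s2 + La
      genes <- rbind(ta_gene(gT, "toxin", s1, e1),
                     ta_gene(gA, "antitoxin", s2, e2))
      ip <- max(s1 + 50L, s2 - 280L)
      prom <- data.frame(promoter_id = c("P1", "Pint"), tss = c(0L, ip),
                         stringsAsFactors = FALSE)
    } else {                   # classes 1 and 3: antitoxin first, overlapping
      s1 <- lead; e1 <- s1 + La; s2 <- e1 - 3L; e2 <- s2 + Lt
      genes <- rbind(ta_gene(gA, "antitoxin", s1, e1),
                     ta_gene(gT, "toxin", s2, e2))
      if (cls == 3L) bp <- s2 + 50L
      prom <- data.frame(promoter_id = "P1", tss = 0L,
                         stringsAsFactors = FALSE)
    }
    op <- ta_operon(ids[k], genes, prom)
    operons[[ids[k]]] <- op
    span <- operon_span(op)
    mu <- rep(1, span)                       # relative coverage, toxin = 1
    if (cls == 3L) mu[(bp + 1L):span] <- 1 / config$step_fold
    if (cls == 4L) mu[(ip + 1L):span] <- config$step_fold
    prof_means[[ids[k]]] <- mu
    truths[[k]] <- data.frame(
      operon_id = ids[k], true_class = cls,
      true_ratio = unname(config$true_ratio_by_class[[as.character(cls)]]),
      breakpoint_pos = bp, internal_promoter_pos = ip,
      stringsAsFactors = FALSE)
  }
  truths <- do.call(rbind, truths)

  # 13 replicate count tables covering every simulated gene
  des <- config$replicate_design
  tables <- list()
  for (ci in seq_len(nrow(des))) {
    for (ri in seq_len(des$n_replicates[ci])) {
      lib <- stats::runif(1L, 0.8, 1.2)
      counts <- numeric(0L)
      for (k in seq_along(ids)) {
        op <- operons[[ids[k]]]
        R <- truths$true_ratio[k]
        for (role in c("antitoxin", "toxin")) {
          g <- gene_by_role(op, role)
          f <- if (role == "antitoxin") R else 1
          mu <- config$depth_mean * g$length * f * lib
          counts[g$gene_id] <- stats::rnbinom(1L, mu = mu,
                                              size = 1 / config$nb_dispersion)
        }
      }
      dsid <- sprintf("%s_r%d", des$condition[ci], ri)
      tables[[dsid]] <- ta_count_table(dsid, des$condition[ci],
                                       paste0("r", ri), counts,
                                       max(config$total_mapped * lib,
                                           max(counts)))
    }
  }

  profiles <- lapply(stats::setNames(ids, ids), function(id)
    ta_profile(id, stats::rpois(length(prof_means[[id]]),
                                config$depth_mean * prof_means[[id]])))

  # TIR sign structure by class
  methods <- c("rbs_calculator", "utr_designer", "barrick")
  tir <- do.call(rbind, lapply(seq_along(ids), function(k) {
    cls <- classes[k]
    n_agree <- sample(2:3, 1L)
    major <- if (cls == 3L) "toxin_higher" else "antitoxin_higher"
    sgn <- rep(major, 3L)
    if (n_agree == 2L)
      sgn[sample(3L, 1L)] <- setdiff(c("antitoxin_higher", "toxin_higher"),
                                     major)
    do.call(rbind, lapply(1:3, function(j) {
      hi <- stats::runif(1L, 1000, 3000); lo <- stats::runif(1L, 100, 600)
      if (sgn[j] == "antitoxin_higher") tir_call(ids[k], methods[j], "P1", hi, lo)
      else tir_call(ids[k], methods[j], "P1", lo, hi)
    }))
  }))

  synthesis <- lapply(stats::setNames(seq_along(ids), ids), function(k) {
    cls <- classes[k]
    rt <- stats::runif(1L, 1, 5)
    ra <- if (cls == 4L) rt * stats::runif(1L, 0.2, 0.8)
          else rt * stats::runif(1L, 1.5, 6)
    synthesis_rates(ids[k], ra, rt, round(stats::runif(1L, 300, 3000)),
                    round(stats::runif(1L, 300, 3000)))
  })

  list(operons = operons, tables = tables, profiles = profiles, tir = tir,
       synthesis = synthesis, truths = truths)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Serializes a [simulate_ta()] result as GFF3 + operon/promoter tables
#' (annotation), one TSV per count table, one bedGraph per operon profile, a
#' TIR TSV, a synthesis-rate TSV and a truth TSV. The files round-trip
#' through the package's readers.
#'
#' @param sim A [simulate_ta()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
  # GFF3: each operon on its own pseudo-contig, plus strand, operon frame
  gff <- file.path(dir, "annotation.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (op in sim$operons) {
    for (i in seq_len(nrow(op$genes)))
      writeLines(sprintf("%s\ttaclass_sim\tCDS\t%d\t%d\t.\t+\t0\tID=%s",
                         op$operon_id, op$genes$start[i] + 1L,
                         op$genes$end[i], op$genes$gene_id[i]), con)
  }
  close(con)
  op_tab <- do.call(rbind, lapply(sim$operons, function(op)
    data.frame(operon_id = op$operon_id, gene_id = op$genes$gene_id,
               role = op$genes$role, stringsAsFactors = FALSE)))
  utils::write.table(op_tab, file.path(dir, "operons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pr_tab <- do.call(rbind, lapply(sim$operons, function(op)
    if (nrow(op$promoters))
      data.frame(operon_id = op$operon_id,
                 promoter_id = op$promoters$promoter_id,
                 tss = op$promoters$tss, stringsAsFactors = FALSE)
    else NULL))
  utils::write.table(pr_tab, file.path(dir, "promoters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tb in sim$tables)
    write_count_table(tb, file.path(dir, "counts",
                                    paste0(tb$dataset_id, ".tsv")))
  for (pr in sim$profiles)
    write_bedgraph_profile(pr, file.path(dir, "profiles",
                                         paste0(pr$operon_id, ".bedgraph")))
  tir_out <- sim$tir[c("operon_id", "method", "transcript_variant",
                       "tir_antitoxin", "tir_toxin")]
  names(tir_out)[3L] <- "variant"
  utils::write.table(tir_out, file.path(dir, "tir.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  syn_tab <- do.call(rbind, lapply(sim$synthesis, function(s)
    data.frame(operon_id = s$operon_id, rate_antitoxin = s$rate_antitoxin,
               rate_toxin = s$rate_toxin, reads_antitoxin = s$reads_antitoxin,
               reads_toxin = s$reads_toxin, stringsAsFactors = FALSE)))
  utils::write.table(syn_tab, file.path(dir, "synthesis.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truths, file.path(dir, "truths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
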