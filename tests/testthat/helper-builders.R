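# Small builders shared across test files. Everything is constructed in
# code; no stored binary fixtures.

# relBE-like operon: antitoxin [100, 340), toxin [337, 622), one external
# promoter at 10.
toy_operon <- function(id = "relBE", promoters = data.frame(
                         promoter_id = "P1", tss = 10L)) {
  ta_operon(id,
            rbind(ta_gene("relB", "antitoxin", 100L, 340L),
                  ta_gene("relE", "toxin", 337L, 622L)),
            promoters = promoters)
}

# one count table with the two toy genes
toy_table <- function(dataset_id = "d1", condition_id = "c1",
                      replicate_id = "r1", n_a = 200, n_t = 200,
                      total = 1e6) {
  ta_count_table(dataset_id, condition_id, replicate_id,
                 c(relB = n_a, relE = n_t), total)
}

# list of tables with given per-dataset (n_a, n_t) pairs
toy_tables <- function(n_a, n_t, total = 1e6) {
  lapply(seq_along(n_a), function(i)
    toy_table(paste0("d", i), paste0("c", i), "r1", n_a[i], n_t[i], total))
}

# write a two-gene GFF3 (1-based inclusive coords) + operon table
write_toy_gff <- function(dir, strand = "+", chrom = "chr",
                          g1 = c("relB", 101L, 340L),
                          g2 = c("relE", 338L, 622L)) {
  gff <- file.path(dir, paste0("toy_", strand, ".gff3"))
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tCDS\t%s\t%s\t.\t%s\t0\tID=%s",
                       chrom, g1[2], g1[3], strand, g1[1]),
               sprintf("%s\ttest\tCDS\t%s\t%s\t.\t%s\t0\tID=%s",
                       chrom, g2[2], g2[3], strand, g2[1])), gff)
  tab <- file.path(dir, "operons.tsv")
  writeLines(c("operon_id\tgene_id\trole",
               "relBE\trelB\tantitoxin",
               "relBE\trelE\ttoxin"), tab)
  list(gff = gff, tab = tab)
}

# brute-force reference for the two-direction replicate log-error
oracle_log_error <- function(cA, cT) {
  r <- numeric(0); m <- numeric(0)
  for (i in seq_along(cA)) {
    r <- c(r, log(cA[i]) - log(cT[i]))
    m <- c(m, log(cA[i]) + log(cT[i]))
  }
  sample_sd <- function(x) {
    mu <- sum(x) / length(x)
    sqrt(sum((x - mu)^2) / (length(x) - 1))
  }
  c(ratio = sample_sd(r) / sqrt(length(r)),
    magnitude = sample_sd(m) / sqrt(length(m)))
}

# brute-force single-changepoint position on ln(1+x): minimise SSE over all
# admissible splits with explicit loops
oracle_changepoint_pos <- function(x, min_segment = 50L) {
  y <- log1p(x); n <- length(y)
  best_sse <- Inf; best_b <- NA_integer_
  for (b in min_segment:(n - min_segment)) {
    l <- y[1:b]; r <- y[(b + 1):n]
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (sse < best_sse) { best_sse <- sse; best_b <- b }
  }
  best_b
}

# brute-force surrogate window score from the stated log-linear formula
oracle_window_score <- function(win_chars, rel, config) {
  s <- 0
  for (i in seq_along(win_chars)) {
    w <- config$position_weights[[as.character(rel[i])]]
    if (!is.null(w) && !is.null(w[[win_chars[i]]])) s <- s + w[[win_chars[i]]]
  }
  sd <- strsplit(config$sd_consensus, "")[[1]]
  up <- win_chars[rel < 0]
  best <- 0
  if (length(up) >= length(sd)) {
    for (off in 0:(length(up) - length(sd))) {
      matches <- 0
      for (j in seq_along(sd))
        if (up[off + j] == sd[j]) matches <- matches + 1
      spacing <- length(up) - (off + length(sd))
      cand <- matches - config$spacing_penalty *
        abs(spacing - config$optimal_spacing)
      if (cand > best) best <- cand
    }
  }
  s + config$asd_weight * best
}

random_consensus_df <- function(signs, id = "op", variant = "P1") {
  do.call(rbind, lapply(seq_along(signs), function(j)
    tir_call(id, c("rbs_calculator", "utr_designer", "barrick")[j], variant,
             if (signs[j] == "+") 2 else 1, if (signs[j] == "+") 1 else 2)))
}
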