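#' Construct a protein synthesis-rate record (Ribo-Seq)
#'
#' Synthesis rates are advisory: they validate a classification but never
#' define it. A gene with fewer than 128 mapped Ribo-Seq reads is flagged low
#' confidence and the record is then ignored by the anomaly check.
#'
#' @param operon_id Operon identifier.
#' @param rate_antitoxin,rate_toxin Protein synthesis rates (arbitrary
#'   units).
#' @param reads_antitoxin,reads_toxin Mapped Ribo-Seq reads underlying each
#'   rate.
#' @param relative_error Assumed relative error of the rates (default 0.30).
#' @return An object of class \code{"synthesis_rates"}; \code{low_confidence}
#'   is \code{TRUE} iff either gene has fewer than 128 mapped reads.
#' @export
synthesis_rates <- function(operon_id, rate_antitoxin, rate_toxin,
                            reads_antitoxin, reads_toxin,
                            relative_error = 0.30) {
  structure(list(operon_id = as.character(operon_id),
                 rate_antitoxin = as.numeric(rate_antitoxin),
                 rate_toxin = as.numeric(rate_toxin),
                 reads_antitoxin = as.numeric(reads_antitoxin),
                 reads_toxin = as.numeric(reads_toxin),
                 low_confidence = reads_antitoxin < 128 || reads_toxin < 128,
                 relative_error = relative_error),
            class = "synthesis_rates")
}

#' Read synthesis-rate records from TSV
#'
#' Columns: \code{operon_id}, \code{rate_antitoxin}, \code{rate_toxin},
#' \code{reads_antitoxin}, \code{reads_toxin}.
#'
#' @param path Path to the TSV.
#' @param relative_error Assumed relative error (default 0.30).
#' @return Named list of \code{"synthesis_rates"}.
#' @export
read_synthesis_table <- function(path, relative_error = 0.30) {
  if (!file.exists(path)) stop("synthesis-rate table not found: ", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("operon_id", "rate_antitoxin", "rate_toxin", "reads_antitoxin",
            "reads_toxin")
  if (!all(need %in% names(tb)))
    stop("synthesis table needs columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tb)), function(i)
    synthesis_rates(tb$operon_id[i], tb$rate_antitoxin[i], tb$rate_toxin[i],
                    tb$reads_antitoxin[i], tb$reads_toxin[i], relative_error))
  stats::setNames(out, tb$operon_id)
}

class_mechanism <- c(`1` = "translational",
                     `2` = "transcriptional_and_translational",
                     `3` = "transcript_truncation",
                     `4` = "internal_promoter",
                     unclassified = "unknown")

#' Classify one TA operon into regulatory class 1-4
#'
#' Applies the rule-based decision procedure combining promoter
#' organization, the median antitoxin/toxin mRNA ratio, base-coverage
#' changepoint evidence and the TIR consensus:
#' \enumerate{
#'   \item An annotated internal promoter, or a significant coverage step-up
#'     strictly upstream of the antitoxin CDS but at or after the first CDS
#'     start, gives class 4 (internal promoter producing excess antitoxin
#'     mRNA).
#'   \item Otherwise, two or more external promoters with a second TSS
#'     within \code{proximal_window} nt of the first CDS start give class 2
#'     (a second, slightly shorter transcript with a weakened toxin RBS).
#'   \item Otherwise antitoxin-excess evidence gives class 3 (truncated
#'     toxin mRNA): a median ratio above \code{2 + borderline_delta}; or a
#'     median inside the borderline band around 2 together with a
#'     toxin-higher TIR consensus; or a significant coverage step-down
#'     inside the toxin CDS.
#'   \item Otherwise class 1 (single transcript, translational regulation);
#'     a median inside the borderline band additionally requires an
#'     antitoxin-higher TIR consensus, else the operon stays unclassified.
#' }
#' Operons failing the coverage filter are unclassified. Synthesis rates are
#' advisory only: a confident rate ratio below one raises the
#' \code{synthesis_ratio_below_one} anomaly flag (the RnlAB situation) but
#' never changes the class.
#'
#' @param operon A \code{"ta_operon"}.
#' @param ratio A \code{"ratio_summary"}.
#' @param changepoint A \code{"changepoint_call"} or \code{NULL}.
#' @param consensus A \code{"consensus_call"}, or a named list of them by
#'   transcript variant (the alphabetically first variant is used for the
#'   borderline tie-break), or \code{NULL}.
#' @param synthesis A \code{"synthesis_rates"} or \code{NULL}.
#' @param borderline_delta Half-width of the borderline band around the
#'   two-fold cutoff (default 0.25).
#' @param proximal_window Distance (nt) within which a second external TSS
#'   counts as near the first CDS start (default 50).
#' @param ratio_cutoff The fold cutoff separating "about equal" from
#'   "antitoxin excess" (default 2).
#' @return An object of class \code{"ta_class"} with fields
#'   \code{assigned_class} (\code{"1"}..\code{"4"} or
#'   \code{"unclassified"}), \code{mechanism}, \code{evidence} (ordered
#'   character vector of the facts consumed) and \code{anomaly_flags}.
#' @export
classify_operon <- function(operon, ratio, changepoint = NULL,
                            consensus = NULL, synthesis = NULL,
                            borderline_delta = 0.25, proximal_window = 50L,
                            ratio_cutoff = 2) {
  ev <- character(); flags <- character()
  verdict <- NA_character_
  if (!is.null(consensus)) {
    if (inherits(consensus, "consensus_call")) consensus <- list(consensus)
    consensus <- consensus[order(names(consensus))]
    verdict <- consensus[[1L]]$verdict
    ev <- c(ev, paste0("tir_consensus=", verdict,
                       if (!is.null(names(consensus)) &&
                           nzchar(names(consensus)[1L]))
                         paste0(" (variant ", names(consensus)[1L], ")")
                       else ""))
  }
  band_lo <- ratio_cutoff - borderline_delta
  band_hi <- ratio_cutoff + borderline_delta

  finish <- function(cls) {
    structure(list(operon_id = operon$operon_id, assigned_class = cls,
                   mechanism = unname(class_mechanism[cls]),
                   evidence = ev, anomaly_flags = flags),
              class = "ta_class")
  }

  if (!isTRUE(ratio$included)) {
    ev <- c(ev, "excluded_by_coverage_filter")
    return(finish("unclassified"))
  }
  med <- ratio$median_ratio
  ev <- c(ev, sprintf("median_ratio=%.3g (n=%d)", med, ratio$n_datasets))

  # advisory synthesis-rate anomaly (never a class criterion)
  if (!is.null(synthesis) && !synthesis$low_confidence &&
      synthesis$rate_antitoxin / synthesis$rate_toxin < 1) {
    flags <- c(flags, "synthesis_ratio_below_one")
    ev <- c(ev, sprintf("synthesis_ratio=%.3g (confident, below one)",
                        synthesis$rate_antitoxin / synthesis$rate_toxin))
  }

  a_start <- gene_by_role(operon, "antitoxin")$start
  first_cds <- min(operon$genes$start)

  # (1) internal promoter -> class 4
  internal <- operon$promoters$placement == "internal"
  up_internal_step <- !is.null(changepoint) && changepoint$significant &&
    changepoint$direction == "up" && changepoint$position >= first_cds &&
    changepoint$position < a_start
  if (any(internal) || up_internal_step) {
    if (any(internal))
      ev <- c(ev, paste0("internal_promoter=",
                         paste(operon$promoters$promoter_id[internal],
                               collapse = ",")))
    if (up_internal_step)
      ev <- c(ev, sprintf("coverage_step_up_at=%d (upstream of antitoxin)",
                          changepoint$position))
    ext <- operon$promoters[operon$promoters$placement == "external", ,
                            drop = FALSE]
    if (any(internal) && nrow(ext) >= 2L &&
        any(first_cds - ext$tss[-which.min(ext$tss)] <= proximal_window &
            ext$tss[-which.min(ext$tss)] <= first_cds))
      ev <- c(ev, "contradiction: proximal second external promoter also present; internal promoter takes precedence")
    return(finish("4"))
  }

  # (2) second external promoter near the first CDS start -> class 2
  ext <- operon$promoters[operon$promoters$placement == "external", ,
                          drop = FALSE]
  if (nrow(ext) >= 2L) {
    others <- ext[-which.min(ext$tss), , drop = FALSE]
    prox <- others$tss <= first_cds & (first_cds - others$tss) <= proximal_window
    if (any(prox)) {
      ev <- c(ev, sprintf("second_external_promoter=%s (%d nt upstream of first CDS)",
                          others$promoter_id[which(prox)[1L]],
                          first_cds - others$tss[which(prox)[1L]]))
      return(finish("2"))
    }
  }

  # (3) antitoxin excess -> class 3
  in_band <- med >= band_lo && med <= band_hi
  down_in_toxin <- !is.null(changepoint) && changepoint$significant &&
    changepoint$direction == "down" &&
    identical(changepoint$region, "toxin_cds")
  if (med > band_hi) {
    ev <- c(ev, sprintf("median_ratio_above_band (> %.3g)", band_hi))
    return(finish("3"))
  }
  if (in_band && identical(verdict, "toxin_higher")) {
    ev <- c(ev, "borderline_ratio_with_toxin_higher_consensus")
    return(finish("3"))
  }
  if (down_in_toxin) {
    ev <- c(ev, sprintf("coverage_step_down_at=%d (toxin CDS)",
                        changepoint$position))
    return(finish("3"))
  }

  # (4) class 1, with TIR tie-break inside the borderline band
  if (in_band) {
    if (identical(verdict, "antitoxin_higher")) {
      ev <- c(ev, "borderline_ratio_resolved_by_antitoxin_higher_consensus")
      return(finish("1"))
    }
    ev <- c(ev, "borderline_ratio_without_supporting_consensus")
    return(finish("unclassified"))
  }
  ev <- c(ev, "single_transcript_ratio_below_band")
  finish("1")
}

#' @export
print.ta_class <- function(x, ...) {
  cat(sprintf("Operon '%s': class %s (%s)%s\n", x$operon_id,
              x$assigned_class, x$mechanism,
              if (length(x$anomaly_flags))
                paste0("  [", paste(x$anomaly_flags, collapse = ", "), "]")
              else ""))
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Classify a set of TA operons from assembled evidence
#'
#' The main entry point: takes the operon models plus whichever evidence
#' channels are available (replicate count tables or precomputed ratio
#' summaries; base-coverage profiles; TIR calls; synthesis rates), runs each
#' channel's summarization, and applies [classify_operon()] to every operon.
#'
#' @param operons Named list of \code{"ta_operon"} objects.
#' @param tables Optional list of \code{"ta_count_table"} (used to compute
#'   ratio summaries and replicate errors).
#' @param ratios Optional named list of precomputed \code{"ratio_summary"}
#'   objects (overrides \code{tables} for the ratio channel).
#' @param profiles Optional named list of \code{"ta_profile"} objects, by
#'   operon id.
#' @param tir Optional \code{data.frame} of TIR calls (see [read_tir_table()]).
#' @param synthesis Optional named list of \code{"synthesis_rates"}.
#' @param borderline_delta,proximal_window,ratio_cutoff Classifier
#'   thresholds, see [classify_operon()].
#' @param changepoint_args List of arguments for [detect_changepoint()]
#'   (\code{min_segment}, \code{min_fold}, \code{bic_threshold}).
#' @param sd_denom Standard-deviation denominator for the ratio and error
#'   summaries.
#' @return An object of class \code{"ta_classification"}: a list with
#'   \code{assignments} (list of \code{"ta_class"}), \code{ratios},
#'   \code{changepoints}, \code{consensus}, \code{errors} and the thresholds
#'   used. Has \code{print}, \code{summary} and \code{as.data.frame}
#'   methods.
#' @export
ta_classify <- function(operons, tables = NULL, ratios = NULL,
                        profiles = NULL, tir = NULL, synthesis = NULL,
                        borderline_delta = 0.25, proximal_window = 50L,
                        ratio_cutoff = 2, changepoint_args = list(),
                        sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  if (is.null(names(operons)))
    names(operons) <- vapply(operons, `[[`, "", "operon_id")
  if (is.null(ratios)) {
    if (is.null(tables))
      stop("need either count tables or precomputed ratio summaries")
    ratios <- lapply(operons, function(op)
      summarize_ratios(tables, op, sd_denom = sd_denom))
  }
  errors <- if (!is.null(tables))
    lapply(operons, function(op) replicate_errors(tables, op, sd_denom))
  else NULL
  cps <- lapply(operons, function(op) {
    pr <- profiles[[op$operon_id]]
    if (is.null(pr)) return(NULL)
    do.call(detect_changepoint, c(list(profile = pr, operon = op),
                                  changepoint_args))
  })
  cons <- lapply(operons, function(op) {
    if (is.null(tir)) return(NULL)
    cv <- consensus_by_variant(tir, op$operon_id)
    if (length(cv)) cv else NULL
  })
  assignments <- lapply(operons, function(op) {
    id <- op$operon_id
    classify_operon(op, ratios[[id]], cps[[id]], cons[[id]],
                    synthesis[[id]], borderline_delta, proximal_window,
                    ratio_cutoff)
  })
  structure(list(assignments = assignments, ratios = ratios,
                 changepoints = cps, consensus = cons, errors = errors,
                 thresholds = list(borderline_delta = borderline_delta,
                                   proximal_window = proximal_window,
                                   ratio_cutoff = ratio_cutoff)),
            class = "ta_classification")
}

#' @export
as.data.frame.ta_classification <- function(x, ...) {
  do.call(rbind, lapply(x$assignments, function(a) {
    r <- x$ratios[[a$operon_id]]
    cv <- x$consensus[[a$operon_id]]
    verdict <- if (is.null(cv)) NA_character_
               else cv[[order(names(cv))[1L]]]$verdict
    data.frame(operon_id = a$operon_id, class = a$assigned_class,
               mechanism = a$mechanism,
               median_ratio = if (is.null(r)) NA_real_ else r$median_ratio,
               sd_ratio = if (is.null(r)) NA_real_ else r$sd_ratio,
               ratio_category = if (is.null(r) || is.na(r$median_ratio))
                 NA_character_
               else if (r$median_ratio > x$thresholds$ratio_cutoff) ">2"
               else "<2",
               tir_consensus = verdict,
               anomalies = paste(a$anomaly_flags, collapse = ";"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.ta_classification <- function(x, ...) {
  df <- as.data.frame(x)
  cat("TA operon classification (", nrow(df), " operons)\n", sep = "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ta_classification <- function(object, ...) {
  df <- as.data.frame(object)
  tab <- table(factor(df$class, levels = c("1", "2", "3", "4",
                                           "unclassified")))
  cat("Class counts:\n"); print(tab)
  n_anom <- sum(nzchar(df$anomalies))
  if (n_anom) cat(n_anom, "operon(s) carry anomaly flags\n")
  invisible(list(class_counts = tab, table = df))
}
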