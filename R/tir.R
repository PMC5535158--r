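#' Construct a translation-initiation-rate call
#'
#' A TIR call records, for one operon and transcript variant, the predicted
#' initiation rates of antitoxin and toxin from one calculation method. Only
#' the sign (which gene's TIR is higher) is ever compared across methods;
#' rate units are arbitrary and method-specific. Ties are rejected: a method
#' that cannot rank the two genes contributes no vote.
#'
#' @param operon_id Operon identifier.
#' @param method One of \code{"rbs_calculator"}, \code{"utr_designer"},
#'   \code{"barrick"}, \code{"builtin"}.
#' @param transcript_variant Transcript variant label (e.g. \code{"P1"},
#'   \code{"P2"} for operons with two promoters).
#' @param tir_antitoxin,tir_toxin Predicted rates (arbitrary units).
#' @return One-row \code{data.frame} with a derived \code{sign} column
#'   (\code{"antitoxin_higher"} or \code{"toxin_higher"}).
#' @export
tir_call <- function(operon_id, method, transcript_variant,
                     tir_antitoxin, tir_toxin) {
  method <- match.arg(method,
                      c("rbs_calculator", "utr_designer", "barrick", "builtin"))
  ta <- as.numeric(tir_antitoxin); tt <- as.numeric(tir_toxin)
  if (is.na(ta) || is.na(tt)) stop("non-numeric TIR value")
  if (ta == tt) stop("tied TIR values carry no sign and are rejected")
  data.frame(operon_id = as.character(operon_id), method = method,
             transcript_variant = as.character(transcript_variant),
             tir_antitoxin = ta, tir_toxin = tt,
             sign = if (ta > tt) "antitoxin_higher" else "toxin_higher",
             stringsAsFactors = FALSE)
}

#' Read TIR calculator outputs from TSV
#'
#' Expects columns \code{operon_id}, \code{method}, \code{variant},
#' \code{tir_antitoxin}, \code{tir_toxin}. Rows with non-numeric or tied TIR
#' values are dropped with a warning.
#'
#' @param path Path to the TSV.
#' @return \code{data.frame} of TIR calls (see [tir_call()]).
#' @export
read_tir_table <- function(path) {
  if (!file.exists(path)) stop("TIR table not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("operon_id", "method", "variant", "tir_antitoxin", "tir_toxin")
  if (!all(need %in% names(raw)))
    stop("TIR table needs columns ", paste(need, collapse = ", "))
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ta <- suppressWarnings(as.numeric(raw$tir_antitoxin[i]))
    tt <- suppressWarnings(as.numeric(raw$tir_toxin[i]))
    if (is.na(ta) || is.na(tt)) {
      warning("row ", i, ": non-numeric TIR value; row rejected")
      next
    }
    if (ta == tt) {
      warning("row ", i, ": tied TIR values; row rejected")
      next
    }
    out[[i]] <- tir_call(raw$operon_id[i], raw$method[i], raw$variant[i],
                         ta, tt)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

#' Two-of-three consensus over TIR sign calls
#'
#' The verdict is the majority sign among the available method calls for one
#' operon and transcript variant. With fewer than two calls the verdict is
#' \code{"insufficient"}: a single calculator is never trusted alone.
#'
#' @param calls \code{data.frame} of TIR calls for a single operon and
#'   transcript variant (see [tir_call()]); an exact majority tie (possible
#'   only with an even number of methods) is also \code{"insufficient"}.
#' @return An object of class \code{"consensus_call"} with fields
#'   \code{operon_id}, \code{transcript_variant}, \code{n_methods},
#'   \code{verdict}.
#' @export
tir_consensus <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(structure(list(operon_id = NA_character_,
                          transcript_variant = NA_character_,
                          n_methods = 0L, verdict = "insufficient"),
                     class = "consensus_call"))
  }
  if (length(unique(calls$operon_id)) > 1L ||
      length(unique(calls$transcript_variant)) > 1L)
    stop("consensus is computed per operon and transcript variant")
  n <- nrow(calls)
  up <- sum(calls$sign == "antitoxin_higher")
  verdict <- if (n < 2L || up * 2L == n) "insufficient"
             else if (up * 2L > n) "antitoxin_higher" else "toxin_higher"
  structure(list(operon_id = calls$operon_id[1L],
                 transcript_variant = calls$transcript_variant[1L],
                 n_methods = n, verdict = verdict),
            class = "consensus_call")
}

#' @export
print.consensus_call <- function(x, ...) {
  cat(sprintf("TIR consensus for '%s' (%s, %d method%s): %s\n",
              x$operon_id, x$transcript_variant, x$n_methods,
              if (x$n_methods == 1L) "" else "s", x$verdict))
  invisible(x)
}

#' Consensus calls for every variant of one operon
#'
#' @param calls \code{data.frame} of TIR calls.
#' @param operon_id Operon to select.
#' @return Named list of \code{"consensus_call"}, one per transcript
#'   variant, sorted by variant label.
#' @export
consensus_by_variant <- function(calls, operon_id) {
  sel <- calls[calls$operon_id == operon_id, , drop = FALSE]
  vars <- sort(unique(sel$transcript_variant))
  lapply(stats::setNames(vars, vars), function(v)
    tir_consensus(sel[sel$transcript_variant == v, , drop = FALSE]))
}

## -- built-in surrogate window scorer ---------------------------------------

#' Default configuration for the surrogate RBS window scorer
#'
#' Loads the position-weight coefficients and anti-Shine-Dalgarno parameters
#' shipped with the package. These coefficients are a synthetic surrogate:
#' they encode the qualitative preferences of empirical E. coli RBS models
#' (purine-rich upstream, SD complementarity with an optimal spacer) but are
#' not a reimplementation of any published calculator. Replace the file (or
#' pass your own) to use calibrated coefficients.
#'
#' @param path Optional path to a YAML config; defaults to the packaged
#'   surrogate file.
#' @return List with \code{window} (relative interval), \code{position_weights}
#'   (per-position base weights), \code{sd_consensus}, \code{asd_weight},
#'   \code{spacing_penalty}, \code{optimal_spacing}.
#' @export
tir_scorer_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tir_surrogate_config.yaml",
                        package = "taclass")
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$position_weights), nzchar(cfg$sd_consensus))
  cfg
}

#' Surrogate log-linear RBS window score
#'
#' Scores the sequence window around a start codon (default -11..+1, i.e. 11
#' bases of 5' context plus the first two bases of the start codon) as the
#' sum of per-position base coefficients plus an anti-Shine-Dalgarno
#' complementarity term: the best-scoring placement of the SD consensus
#' (default \code{AGGAGG}) within the upstream context, rewarded per matching
#' base and penalized by the deviation of its spacer (bases between SD end
#' and the start codon) from the optimal spacing. The score is an arbitrary
#' log-rate: only comparisons between windows are meaningful.
#'
#' @param sequence Nucleotide string (operon-frame orientation).
#' @param start_codon_pos 0-based position of the first base of the start
#'   codon within \code{sequence}.
#' @param config Scorer configuration (see [tir_scorer_config()]).
#' @param window Integer vector \code{c(from, to)} relative to the start
#'   codon, inclusive (default \code{c(-11, 1)}).
#' @return Numeric score (arbitrary rate units, log scale).
#' @export
builtin_window_score <- function(sequence, start_codon_pos,
                                 config = tir_scorer_config(),
                                 window = c(-11L, 1L)) {
  sequence <- toupper(as.character(sequence))
  from <- start_codon_pos + window[1L]      # 0-based
  to <- start_codon_pos + window[2L]        # inclusive
  if (from < 0L || to >= nchar(sequence))
    stop("scoring window [", from, ", ", to, "] off the sequence")
  win <- strsplit(substr(sequence, from + 1L, to + 1L), "")[[1L]]
  rel <- seq.int(window[1L], window[2L])
  pw <- config$position_weights
  score <- 0
  for (i in seq_along(win)) {
    key <- as.character(rel[i])
    if (!is.null(pw[[key]]) && !is.null(pw[[key]][[win[i]]]))
      score <- score + pw[[key]][[win[i]]]
  }
  # anti-SD complementarity over the upstream context (rel < 0)
  sd <- strsplit(toupper(config$sd_consensus), "")[[1L]]
  k <- length(sd)
  up <- win[rel < 0L]
  best <- 0
  if (length(up) >= k) {
    for (off in 0:(length(up) - k)) {
      matches <- sum(up[off + seq_len(k)] == sd)
      spacing <- length(up) - (off + k)     # bases between SD end and codon
      cand <- matches - config$spacing_penalty *
        abs(spacing - config$optimal_spacing)
      if (cand > best) best <- cand
    }
  }
  score + config$asd_weight * best
}

#' Built-in TIR calls for both genes of an operon
#'
#' Applies the surrogate window scorer to the RBS windows of the antitoxin
#' and toxin start codons and returns a TIR call (method \code{"builtin"}).
#' Requires the operon to carry its locus sequence.
#'
#' @param operon A \code{"ta_operon"} with \code{sequence} set.
#' @param transcript_variant Variant label for the call (default
#'   \code{"P1"}).
#' @param config Scorer configuration.
#' @return One-row TIR call \code{data.frame}, or \code{NULL} with a warning
#'   when the two scores tie.
#' @export
builtin_tir_call <- function(operon, transcript_variant = "P1",
                             config = tir_scorer_config()) {
  if (is.null(operon$sequence))
    stop("operon '", operon$operon_id, "' carries no sequence")
  sc <- vapply(c("antitoxin", "toxin"), function(role) {
    g <- gene_by_role(operon, role)
    builtin_window_score(operon$sequence, g$start, config)
  }, numeric(1L))
  if (sc[["antitoxin"]] == sc[["toxin"]]) {
    warning("operon '", operon$operon_id, "': tied builtin scores; no call")
    return(NULL)
  }
  tir_call(operon$operon_id, "builtin", transcript_variant,
           sc[["antitoxin"]], sc[["toxin"]])
}
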