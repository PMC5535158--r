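#' Construct a base-resolution coverage profile for an operon
#'
#' @param operon_id Operon identifier.
#' @param values Non-negative per-base coverage vector in operon frame; its
#'   length must equal the operon span when the profile is paired with an
#'   operon.
#' @return An object of class \code{"ta_profile"}.
#' @export
ta_profile <- function(operon_id, values) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("coverage values must be >= 0")
  structure(list(operon_id = as.character(operon_id), values = values),
            class = "ta_profile")
}

#' Detect a single coverage changepoint in an operon profile
#'
#' Fits piecewise-constant means to ln(1 + coverage) (a variance-stabilizing
#' transform for overdispersed counts), exhaustively searching all
#' breakpoints that leave both segments at least \code{min_segment} bases
#' long. The best two-segment fit is reported only when it beats the
#' one-segment fit by at least \code{bic_threshold} BIC units (Gaussian SSE
#' approximation; the two-segment model is charged two extra parameters: the
#' second mean and the breakpoint) and the raw-coverage fold change across
#' the breakpoint reaches \code{min_fold}. A step up in an operon's interior
#' is evidence of an internal promoter; a step down inside the toxin CDS is
#' evidence of a truncated transcript (early terminator or targeted
#' degradation).
#'
#' @param profile A \code{"ta_profile"} or bare numeric coverage vector.
#' @param operon Optional \code{"ta_operon"} used to annotate the breakpoint
#'   region.
#' @param min_segment Minimum segment length in nt (default 50).
#' @param min_fold Minimum fold change, larger of fold and 1/fold (default
#'   2).
#' @param bic_threshold Minimum BIC improvement of the two-segment model
#'   (default 10).
#' @return A \code{"changepoint_call"} with fields \code{position} (0-based
#'   operon-frame coordinate of the first base after the breakpoint),
#'   \code{direction} (\code{"up"}/\code{"down"}), \code{fold} (downstream
#'   mean over upstream mean, raw coverage), \code{delta_bic},
#'   \code{significant} (always \code{TRUE} on a returned call) and
#'   \code{region}; or \code{NULL} when no significant changepoint is found
#'   (including for an all-zero profile).
#' @export
detect_changepoint <- function(profile, operon = NULL, min_segment = 50L,
                               min_fold = 2.0, bic_threshold = 10.0) {
  x <- if (inherits(profile, "ta_profile")) profile$values
       else as.numeric(profile)
  n <- length(x)
  if (n < 2L * min_segment) stop("profile shorter than 2 * min_segment")
  if (all(x == 0)) return(NULL)
  y <- log1p(x)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  sse_tot <- cs2[n] - cs[n]^2 / n
  b <- seq.int(min_segment, n - min_segment)   # left segment = 1..b
  sl <- cs[b]; sl2 <- cs2[b]
  sr <- cs[n] - sl; sr2 <- cs2[n] - sl2
  sse2 <- (sl2 - sl^2 / b) + (sr2 - sr^2 / (n - b))
  best <- which.min(sse2)
  bb <- b[best]
  # Gaussian BIC, shared variance; 2-segment model pays for the extra mean
  # and the breakpoint location
  eps <- 1e-12
  bic1 <- n * log(max(sse_tot, eps) / n) + 2 * log(n)
  bic2 <- n * log(max(sse2[best], eps) / n) + 4 * log(n)
  delta_bic <- bic1 - bic2
  mu_l <- mean(x[seq_len(bb)]); mu_r <- mean(x[(bb + 1L):n])
  if (mu_l == 0 || mu_r == 0) {
    fold <- if (mu_r > mu_l) Inf else 0
  } else fold <- mu_r / mu_l
  if (delta_bic < bic_threshold || max(fold, 1 / fold) < min_fold)
    return(NULL)
  pos <- bb  # 0-based index of the first downstream base
  region <- if (!is.null(operon)) classify_region(operon, pos) else NA_character_
  structure(list(position = pos,
                 direction = if (fold > 1) "up" else "down",
                 fold = fold, delta_bic = delta_bic, significant = TRUE,
                 region = region),
            class = "changepoint_call")
}

#' @export
print.changepoint_call <- function(x, ...) {
  cat(sprintf(
    "Coverage changepoint at %d nt (%s, fold %.3g, delta BIC %.1f%s)\n",
    x$position, x$direction, x$fold, x$delta_bic,
    if (is.na(x$region)) "" else paste0(", region ", x$region)))
  invisible(x)
}

#' Read a per-base coverage profile from a bedGraph file
#'
#' The bedGraph's chromosome column must carry the operon id and its
#' intervals must be expressed in operon-frame coordinates (0-based
#' half-open, as bedGraph always is). Bases not covered by any interval get
#' coverage 0.
#'
#' @param path Path to the bedGraph file.
#' @param operon A \code{"ta_operon"}; the profile is expanded to the operon
#'   span.
#' @return A \code{"ta_profile"}.
#' @export
read_bedgraph_profile <- function(path, operon) {
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == operon$operon_id]
  span <- operon_span(operon)
  vals <- numeric(span)
  if (length(gr)) {
    s <- BiocGenerics::start(gr)      # 1-based after import
    e <- BiocGenerics::end(gr)
    sc <- gr$score
    for (i in seq_along(gr)) {
      lo <- max(1L, s[i]); hi <- min(span, e[i])
      if (lo <= hi) vals[lo:hi] <- sc[i]
    }
  }
  ta_profile(operon$operon_id, vals)
}

#' @rdname read_bedgraph_profile
#' @param profile A \code{"ta_profile"} to serialize (run-length encoded).
#' @export
write_bedgraph_profile <- function(profile, path) {
  r <- rle(profile$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(profile$operon_id, starts, ends,
                   format(r$values, scientific = FALSE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}
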