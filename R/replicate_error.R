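#' Two-direction replicate log-error decomposition
#'
#' Given replicate antitoxin/toxin coverages (cA, cT), decomposes replicate
#' uncertainty into two orthogonal log-space directions: the log-ratio
#' ln(cA/cT) = ln cA - ln cT, and the log-magnitude ln(cA*cT) = ln cA +
#' ln cT. Each standard error is sd over replicates divided by sqrt(m).
#' Because ln(cA/cT) is approximately (cA/cT) - 1 for ratios near 1, the
#' log-ratio error also approximates the error of the ratio itself. The
#' log-ratio error is exactly zero when every replicate has the same A/T
#' ratio, even if the overall magnitude varies between replicates.
#'
#' @param cA,cT Numeric vectors of antitoxin and toxin coverage (e.g. RPKM),
#'   one entry per replicate, in matching order.
#' @param operon_id,condition_id Identifiers carried into the result.
#' @param sd_denom \code{"sample"} (m-1, default) or \code{"population"} (m)
#'   denominator.
#' @return An object of class \code{"error_estimate"} with fields
#'   \code{n_replicates}, \code{se_log_ratio}, \code{se_log_magnitude}
#'   (natural-log units) and \code{se_log10_ratio}, \code{se_log10_magnitude}
#'   (the same, scaled by 1/ln(10) for plotting in log10 space). With fewer
#'   than two usable replicates the SEs are \code{NA} and \code{defined} is
#'   \code{FALSE}. Replicates with a zero coverage are dropped with a
#'   warning.
#' @export
log_error_decomposition <- function(cA, cT, operon_id = NA_character_,
                                    condition_id = NA_character_,
                                    sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  if (length(cA) != length(cT)) stop("cA and cT must have equal length")
  bad <- cA <= 0 | cT <= 0
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with zero coverage dropped")
    cA <- cA[!bad]; cT <- cT[!bad]
  }
  m <- length(cA)
  if (m < 2L) {
    return(structure(list(operon_id = operon_id, condition_id = condition_id,
                          n_replicates = m, se_log_ratio = NA_real_,
                          se_log_magnitude = NA_real_,
                          se_log10_ratio = NA_real_,
                          se_log10_magnitude = NA_real_, defined = FALSE),
                     class = "error_estimate"))
  }
  sdfun <- function(x) {
    s <- stats::sd(x)
    if (sd_denom == "population") s * sqrt((m - 1) / m) else s
  }
  se_r <- sdfun(log(cA) - log(cT)) / sqrt(m)
  se_m <- sdfun(log(cA) + log(cT)) / sqrt(m)
  structure(list(operon_id = operon_id, condition_id = condition_id,
                 n_replicates = m, se_log_ratio = se_r,
                 se_log_magnitude = se_m,
                 se_log10_ratio = se_r / log(10),
                 se_log10_magnitude = se_m / log(10), defined = TRUE),
            class = "error_estimate")
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf(
    "Replicate log-error (%s, %s, m = %d): SE[ln A/T] = %.4g, SE[ln A*T] = %.4g\n",
    x$operon_id, x$condition_id, x$n_replicates,
    x$se_log_ratio, x$se_log_magnitude))
  invisible(x)
}

#' Replicate error estimates for one operon across count tables
#'
#' Groups count tables by condition, computes a per-condition error estimate
#' from the replicate coverages, and a pooled estimate whose variance is the
#' mean of the per-condition variances (the pooling rule is a package
#' choice; the per-condition estimates are always available alongside).
#'
#' @param tables List of \code{"ta_count_table"} objects.
#' @param operon A \code{"ta_operon"}.
#' @param sd_denom Passed to [log_error_decomposition()].
#' @return List with \code{per_condition} (list of \code{"error_estimate"},
#'   one per condition) and \code{pooled} (an \code{"error_estimate"} with
#'   condition id \code{"pooled"}).
#' @export
replicate_errors <- function(tables, operon,
                             sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  a <- gene_by_role(operon, "antitoxin"); t <- gene_by_role(operon, "toxin")
  conds <- vapply(tables, `[[`, "", "condition_id")
  per_cond <- lapply(stats::setNames(unique(conds), unique(conds)),
                     function(cc) {
    tbs <- tables[conds == cc]
    cA <- vapply(tbs, function(tb)
      rpkm(tb$counts[[a$gene_id]], a$length, tb$total_mapped), numeric(1L))
    cT <- vapply(tbs, function(tb)
      rpkm(tb$counts[[t$gene_id]], t$length, tb$total_mapped), numeric(1L))
    log_error_decomposition(cA, cT, operon$operon_id, cc, sd_denom)
  })
  ok <- vapply(per_cond, `[[`, logical(1L), "defined")
  pooled <- if (any(ok)) {
    vr <- mean(vapply(per_cond[ok], function(e) e$se_log_ratio^2, numeric(1L)))
    vm <- mean(vapply(per_cond[ok], function(e) e$se_log_magnitude^2,
                      numeric(1L)))
    structure(list(operon_id = operon$operon_id, condition_id = "pooled",
                   n_replicates = sum(vapply(per_cond[ok], `[[`, integer(1L),
                                             "n_replicates")),
                   se_log_ratio = sqrt(vr), se_log_magnitude = sqrt(vm),
                   se_log10_ratio = sqrt(vr) / log(10),
                   se_log10_magnitude = sqrt(vm) / log(10), defined = TRUE),
              class = "error_estimate")
  } else {
    log_error_decomposition(numeric(), numeric(), operon$operon_id, "pooled",
                            sd_denom)
  }
  list(per_condition = per_cond, pooled = pooled)
}

#' Tabulate error estimates for export
#'
#' @param estimates List of \code{"error_estimate"} objects.
#' @return \code{data.frame} with one row per estimate, columns
#'   \code{operon_id}, \code{condition_id}, \code{n}, \code{se_log10_ratio},
#'   \code{se_log10_magnitude} (suitable for drawing rotated error bars on a
#'   log-log coverage scatter).
#' @export
error_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(operon_id = e$operon_id, condition_id = e$condition_id,
               n = e$n_replicates, se_log10_ratio = e$se_log10_ratio,
               se_log10_magnitude = e$se_log10_magnitude,
               stringsAsFactors = FALSE)))
}
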