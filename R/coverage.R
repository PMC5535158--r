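#' Construct a per-gene count table for one RNA-seq dataset
#'
#' Counts are fractional: reads mapping to more than one genomic region
#' contribute 0.5 each, so every count is a multiple of 0.5.
#'
#' @param dataset_id,condition_id,replicate_id Identifiers for the dataset,
#'   its experimental condition and the biological replicate.
#' @param counts Named numeric vector, gene_id -> mapped reads.
#' @param total_mapped Total mapped reads in the library (T in the RPKM
#'   formula).
#' @return An object of class \code{"ta_count_table"}.
#' @export
ta_count_table <- function(dataset_id, condition_id, replicate_id, counts,
                           total_mapped) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector (gene_id -> reads)")
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(abs(counts * 2 - round(counts * 2)) > 1e-8))
    stop("counts must be multiples of 0.5 (half-weight multi-mapped reads)")
  total_mapped <- as.numeric(total_mapped)
  if (total_mapped < max(counts))
    stop("total_mapped must be at least the largest single-gene count")
  structure(list(dataset_id = as.character(dataset_id),
                 condition_id = as.character(condition_id),
                 replicate_id = as.character(replicate_id),
                 counts = counts, total_mapped = total_mapped),
            class = "ta_count_table")
}

#' @export
print.ta_count_table <- function(x, ...) {
  cat("Count table ", x$dataset_id, " (condition ", x$condition_id,
      ", replicate ", x$replicate_id, "): ", length(x$counts),
      " genes, T = ", format(x$total_mapped, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Read a count table from TSV
#'
#' The format is a TSV with columns \code{gene_id}, \code{count}, preceded by
#' four comment header lines \code{#dataset_id}, \code{#condition_id},
#' \code{#replicate_id}, \code{#total_mapped}, each \code{#key<TAB>value}.
#'
#' @param path Path to the TSV file.
#' @return A \code{"ta_count_table"}.
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "\t")
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("dataset_id", "condition_id", "replicate_id", "total_mapped")
  if (!all(need %in% names(meta)))
    stop("count table ", path, " missing header line(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE)
  ta_count_table(meta[["dataset_id"]], meta[["condition_id"]],
                 meta[["replicate_id"]],
                 stats::setNames(as.numeric(body$count), body$gene_id),
                 as.numeric(meta[["total_mapped"]]))
}

#' @rdname read_count_table
#' @param table A \code{"ta_count_table"} to serialize.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#dataset_id\t", table$dataset_id),
               paste0("#condition_id\t", table$condition_id),
               paste0("#replicate_id\t", table$replicate_id),
               paste0("#total_mapped\t",
                      format(table$total_mapped, scientific = FALSE)),
               "gene_id\tcount",
               paste(names(table$counts),
                     format(table$counts, scientific = FALSE, trim = TRUE),
                     sep = "\t")), con)
  invisible(path)
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = 1e9 * n / (L * T), with n the (possibly fractional) reads mapped to
#' the CDS, L the CDS length in bases and T the library's total mapped reads.
#'
#' @param n Mapped reads for the CDS (multi-mapped reads counted as 0.5).
#' @param L CDS length (nt), > 0.
#' @param T_total Total mapped reads in the dataset, > 0.
#' @return RPKM value(s).
#' @examples
#' rpkm(100, 1000, 1e6)  # 100
#' @export
rpkm <- function(n, L, T_total) {
  if (any(L <= 0)) stop("L must be > 0")
  if (any(T_total <= 0)) stop("T must be > 0")
  if (any(n < 0)) stop("n must be >= 0")
  1e9 * n / (L * T_total)
}

#' Antitoxin-to-toxin coverage ratio for one dataset
#'
#' The ratio of antitoxin RPKM to toxin RPKM. The library size cancels, so
#' the ratio equals (n_A / L_A) / (n_T / L_T).
#'
#' @param table A \code{"ta_count_table"}.
#' @param operon A \code{"ta_operon"}.
#' @return The dimensionless A/T ratio, or \code{NA} (with a warning) when
#'   the toxin has zero mapped reads, in which case the dataset is excluded
#'   for this operon.
#' @export
at_ratio <- function(table, operon) {
  a <- gene_by_role(operon, "antitoxin"); t <- gene_by_role(operon, "toxin")
  for (g in c(a$gene_id, t$gene_id))
    if (!g %in% names(table$counts))
      stop("gene '", g, "' absent from count table ", table$dataset_id)
  n_t <- table$counts[[t$gene_id]]
  if (n_t == 0) {
    warning("operon '", operon$operon_id, "': zero toxin reads in dataset ",
            table$dataset_id, "; ratio undefined, dataset excluded")
    return(NA_real_)
  }
  n_a <- table$counts[[a$gene_id]]
  rpkm(n_a, a$length, table$total_mapped) /
    rpkm(n_t, t$length, table$total_mapped)
}

#' Low-coverage inclusion filter
#'
#' An operon is excluded when either the toxin or the antitoxin averages
#' fewer than one read per base (n/L < 1) in strictly more than half of the
#' datasets.
#'
#' @param tables List of \code{"ta_count_table"} objects.
#' @param operon A \code{"ta_operon"}.
#' @return \code{TRUE} if the operon passes the filter.
#' @export
coverage_filter <- function(tables, operon) {
  half <- length(tables) / 2
  for (role in c("toxin", "antitoxin")) {
    g <- gene_by_role(operon, role)
    below <- vapply(tables, function(tb) {
      n <- tb$counts[[g$gene_id]]
      if (is.null(n)) TRUE else (n / g$length) < 1
    }, logical(1L))
    if (sum(below) > half) return(FALSE)
  }
  TRUE
}

#' Summarize antitoxin/toxin ratios across datasets
#'
#' Computes the per-dataset A/T RPKM ratios, their median (the operon's A/T
#' ratio) and standard deviation, and applies the low-coverage inclusion
#' filter.
#'
#' @param tables List of \code{"ta_count_table"} objects (typically 13: one
#'   condition in triplicate plus five conditions in duplicate).
#' @param operon A \code{"ta_operon"}.
#' @param sd_denom \code{"sample"} (n-1, default) or \code{"population"} (n)
#'   denominator for the standard deviation.
#' @return An object of class \code{"ratio_summary"} with fields
#'   \code{operon_id}, \code{per_dataset_ratio} (named by dataset),
#'   \code{median_ratio}, \code{sd_ratio}, \code{n_datasets}, and
#'   \code{included}.
#' @export
summarize_ratios <- function(tables, operon,
                             sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  ratios <- vapply(tables, at_ratio, numeric(1L), operon = operon)
  names(ratios) <- vapply(tables, `[[`, "", "dataset_id")
  usable <- ratios[!is.na(ratios)]
  if (!length(usable)) {
    return(structure(list(operon_id = operon$operon_id,
                          per_dataset_ratio = usable,
                          median_ratio = NA_real_, sd_ratio = NA_real_,
                          n_datasets = 0L, included = FALSE),
                     class = "ratio_summary"))
  }
  m <- length(usable)
  sdv <- if (m < 2L) 0 else stats::sd(usable)
  if (sd_denom == "population") sdv <- sdv * sqrt((m - 1) / m)
  structure(list(operon_id = operon$operon_id, per_dataset_ratio = usable,
                 median_ratio = stats::median(usable), sd_ratio = sdv,
                 n_datasets = m,
                 included = coverage_filter(tables, operon)),
            class = "ratio_summary")
}

#' Assemble a ratio summary from precomputed values
#'
#' Used when the per-dataset ratios (or just their median/SD, as printed in a
#' publication table) are already known.
#'
#' @param operon_id Operon identifier.
#' @param median_ratio,sd_ratio Median and standard deviation of the A/T
#'   ratios.
#' @param per_dataset_ratio Optional named vector of per-dataset ratios; when
#'   given, \code{median_ratio}/\code{sd_ratio} are recomputed from it.
#' @param n_datasets Number of datasets behind the summary.
#' @param included Did the operon pass the coverage filter?
#' @export
ratio_summary <- function(operon_id, median_ratio = NA_real_,
                          sd_ratio = NA_real_, per_dataset_ratio = numeric(),
                          n_datasets = length(per_dataset_ratio),
                          included = TRUE) {
  if (length(per_dataset_ratio)) {
    median_ratio <- stats::median(per_dataset_ratio)
    sd_ratio <- if (length(per_dataset_ratio) > 1L)
      stats::sd(per_dataset_ratio) else 0
  }
  structure(list(operon_id = as.character(operon_id),
                 per_dataset_ratio = per_dataset_ratio,
                 median_ratio = as.numeric(median_ratio),
                 sd_ratio = as.numeric(sd_ratio),
                 n_datasets = as.integer(n_datasets),
                 included = isTRUE(included)),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("A/T ratio summary for '%s': median %.3g (SD %.3g, n = %d)%s\n",
              x$operon_id, x$median_ratio, x$sd_ratio, x$n_datasets,
              if (x$included) "" else "  [excluded by coverage filter]"))
  invisible(x)
}
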