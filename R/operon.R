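#' Construct a gene model for one TA operon member
#'
#' A gene is described in the operon's internal frame: 0-based, half-open
#' coordinates with transcription running left to right. Coordinates are
#' plus-strand-normalized by [read_operon_annotation()]; constructors assume
#' the frame has already been normalized.
#'
#' @param gene_id Gene identifier (e.g. \code{"relB"}).
#' @param role One of \code{"toxin"} or \code{"antitoxin"}.
#' @param start 0-based inclusive start of the CDS in operon frame (nt).
#' @param end 0-based exclusive end of the CDS in operon frame (nt).
#' @return A one-row \code{data.frame} with columns \code{gene_id},
#'   \code{role}, \code{start}, \code{end}, \code{length}.
#' @details The CDS length is \code{end - start} and must be at least 30 nt;
#'   divisibility by 3 is not required because annotations may omit stop
#'   codons.
#' @export
ta_gene <- function(gene_id, role, start, end) {
  role <- match.arg(role, c("toxin", "antitoxin"))
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("gene '", gene_id, "': end must be > start")
  len <- end - start
  if (len < 30L) stop("gene '", gene_id, "': CDS length ", len, " < 30 nt")
  data.frame(gene_id = as.character(gene_id), role = role,
             start = start, end = end, length = len,
             stringsAsFactors = FALSE)
}

#' Construct a TA operon model
#'
#' An operon holds exactly one toxin and one antitoxin gene in transcription
#' order, an optional set of promoters, and optionally the locus nucleotide
#' sequence in transcription orientation.
#'
#' @param operon_id Operon identifier.
#' @param genes \code{data.frame} of gene rows from [ta_gene()], rbind-ed in
#'   transcription order.
#' @param promoters Optional \code{data.frame} with columns
#'   \code{promoter_id} and \code{tss} (0-based operon-frame coordinate).
#'   Placement (\code{"external"} or \code{"internal"}) is derived: a TSS
#'   strictly inside the span from the first CDS start to the last CDS end is
#'   internal.
#' @param sequence Optional nucleotide string covering the operon locus in
#'   transcription orientation (position 0 of the string is operon-frame 0).
#' @param offset Genomic coordinate of operon-frame position 0 (bookkeeping
#'   only; all arithmetic is done in operon frame).
#' @return An object of class \code{"ta_operon"}.
#' @export
ta_operon <- function(operon_id, genes, promoters = NULL, sequence = NULL,
                      offset = 0L) {
  if (!is.data.frame(genes) || nrow(genes) < 2L)
    stop("operon '", operon_id, "': needs at least two genes")
  if (sum(genes$role == "toxin") != 1L || sum(genes$role == "antitoxin") != 1L)
    stop("operon '", operon_id, "': must have exactly one toxin and one antitoxin")
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  # non-nested: no gene fully contained in another
  for (i in seq_len(nrow(genes) - 1L)) {
    if (genes$end[i + 1L] <= genes$end[i])
      stop("operon '", operon_id, "': nested genes are not allowed")
  }
  cds_lo <- min(genes$start); cds_hi <- max(genes$end)
  if (!is.null(promoters)) {
    if (!all(c("promoter_id", "tss") %in% names(promoters)))
      stop("promoters need columns promoter_id, tss")
    promoters$tss <- as.integer(promoters$tss)
    if (any(promoters$tss >= cds_hi))
      stop("operon '", operon_id, "': promoter tss must lie before the last gene end")
    promoters$placement <- ifelse(promoters$tss > cds_lo & promoters$tss < cds_hi,
                                  "internal", "external")
    rownames(promoters) <- NULL
  } else {
    promoters <- data.frame(promoter_id = character(), tss = integer(),
                            placement = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) < cds_hi)
      stop("operon '", operon_id, "': sequence shorter than the CDS span")
  }
  structure(list(operon_id = as.character(operon_id), genes = genes,
                 promoters = promoters, sequence = sequence,
                 offset = as.integer(offset)),
            class = "ta_operon")
}

#' @export
print.ta_operon <- function(x, ...) {
  cat("TA operon '", x$operon_id, "' (span ", operon_span(x), " nt)\n", sep = "")
  for (i in seq_len(nrow(x$genes)))
    cat(sprintf("  %-12s %-9s [%d, %d)  %d nt\n", x$genes$gene_id[i],
                x$genes$role[i], x$genes$start[i], x$genes$end[i],
                x$genes$length[i]))
  if (nrow(x$promoters))
    for (i in seq_len(nrow(x$promoters)))
      cat(sprintf("  promoter %-8s tss %-6d %s\n", x$promoters$promoter_id[i],
                  x$promoters$tss[i], x$promoters$placement[i]))
  invisible(x)
}

#' Operon span in nucleotides
#'
#' The operon frame runs from 0 (which may include a leader upstream of the
#' first CDS) to the last gene end.
#'
#' @param operon A \code{"ta_operon"}.
#' @return Integer span (nt).
#' @export
operon_span <- function(operon) max(operon$genes$end)

gene_by_role <- function(operon, role) {
  operon$genes[operon$genes$role == role, , drop = FALSE]
}

#' Ribosome-binding-site window upstream of a gene's start codon
#'
#' Returns the interval \code{[start - upstream, start)} in operon frame,
#' clipped at 0. The upstream extent defaults to 20 nt, a typical span for
#' the Shine-Dalgarno region plus spacer; it is configurable because the RBS
#' extent is not sharply defined.
#'
#' @param operon A \code{"ta_operon"}.
#' @param gene A gene row (from the operon's \code{genes}) or a
#'   \code{gene_id} string.
#' @param upstream Window length in nt (default 20).
#' @return Integer vector \code{c(start, end)}, 0-based half-open; an empty
#'   window has \code{start == end}.
#' @export
rbs_window <- function(operon, gene, upstream = 20L) {
  if (is.character(gene)) {
    gene <- operon$genes[operon$genes$gene_id == gene, , drop = FALSE]
    if (nrow(gene) != 1L) stop("gene not found in operon")
  }
  if (!gene$gene_id[1L] %in% operon$genes$gene_id)
    stop("gene does not belong to operon '", operon$operon_id, "'")
  s <- gene$start[1L]
  c(max(0L, s - as.integer(upstream)), s)
}

#' Does the downstream gene's RBS overlap the upstream gene's CDS?
#'
#' In most E. coli type II TA systems the ribosome-binding site of the
#' downstream gene is embedded in the upstream gene's coding region; HicAB,
#' with its >25 nt intergenic gap, is the known exception.
#'
#' @inheritParams rbs_window
#' @return \code{TRUE} iff the downstream gene's RBS window intersects the
#'   upstream gene's CDS interval.
#' @export
rbs_overlaps_upstream_gene <- function(operon, upstream = 20L) {
  if (nrow(operon$genes) != 2L) stop("operon must have exactly two genes")
  up <- operon$genes[1L, ]; down <- operon$genes[2L, ]
  w <- rbs_window(operon, down, upstream)
  w[1L] < up$end && w[2L] > up$start
}

## -- annotation I/O ---------------------------------------------------------

#' Read TA operons from GFF3 plus an operon definition table
#'
#' CDS features are read from the GFF3, grouped into operons by an explicit
#' curated table (columns \code{operon_id}, \code{gene_id}, \code{role}), and
#' plus-strand-normalized so transcription runs left to right in the internal
#' frame (minus-strand operons are coordinate-flipped and the sequence, when
#' given, reverse-complemented).
#'
#' @param gff3_path Path to a GFF3 file with CDS features. The gene
#'   identifier is taken from the first of the \code{ID}, \code{gene},
#'   \code{Name} or \code{locus_tag} attributes that matches.
#' @param operon_table Path to a TSV (or a \code{data.frame}) with columns
#'   \code{operon_id}, \code{gene_id}, \code{role}.
#' @param promoter_table Optional TSV/\code{data.frame} with columns
#'   \code{operon_id}, \code{promoter_id}, \code{tss} (0-based genomic
#'   coordinate of the transcription start site).
#' @param fasta_path Optional FASTA with the genomic sequence; the operon
#'   locus is extracted and reverse-complemented for minus-strand operons.
#' @return List of \code{"ta_operon"} objects, named by operon id.
#' @export
read_operon_annotation <- function(gff3_path, operon_table,
                                   promoter_table = NULL, fasta_path = NULL) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  if (is.data.frame(operon_table)) tab <- operon_table
  else tab <- utils::read.delim(operon_table, stringsAsFactors = FALSE)
  need <- c("operon_id", "gene_id", "role")
  if (!all(need %in% names(tab)))
    stop("operon table needs columns ", paste(need, collapse = ", "))
  if (any(is.na(tab$role) | !tab$role %in% c("toxin", "antitoxin")))
    stop("missing or invalid role for gene(s): ",
         paste(tab$gene_id[is.na(tab$role) |
                             !tab$role %in% c("toxin", "antitoxin")],
               collapse = ", "))
  prom <- NULL
  if (!is.null(promoter_table)) {
    prom <- if (is.data.frame(promoter_table)) promoter_table
            else utils::read.delim(promoter_table, stringsAsFactors = FALSE)
  }
  seqs <- if (!is.null(fasta_path)) Biostrings::readDNAStringSet(fasta_path)
          else NULL

  # candidate identifier attributes, first match wins per feature
  ids <- rep(NA_character_, length(gff))
  for (attr in c("ID", "gene", "Name", "locus_tag")) {
    if (!is.null(S4Vectors::mcols(gff)[[attr]])) {
      v <- as.character(S4Vectors::mcols(gff)[[attr]])
      ids[is.na(ids) & !is.na(v)] <- v[is.na(ids) & !is.na(v)]
    }
  }

  lapply(stats::setNames(unique(tab$operon_id), unique(tab$operon_id)),
         function(op_id) {
    rows <- tab[tab$operon_id == op_id, , drop = FALSE]
    hit <- match(rows$gene_id, ids)
    if (anyNA(hit))
      stop("operon '", op_id, "': no CDS found in GFF3 for gene(s): ",
           paste(rows$gene_id[is.na(hit)], collapse = ", "))
    feats <- gff[hit]
    strands <- as.character(BiocGenerics::strand(feats))
    if (length(unique(strands)) != 1L)
      stop("operon '", op_id, "': genes on mixed strands")
    minus <- strands[1L] == "-"
    # genomic 0-based half-open
    g_start <- BiocGenerics::start(feats) - 1L
    g_end <- BiocGenerics::end(feats)
    p_rows <- if (!is.null(prom)) prom[prom$operon_id == op_id, , drop = FALSE]
              else NULL
    lo <- min(g_start); hi <- max(g_end)
    if (!is.null(p_rows) && nrow(p_rows)) {
      if (minus) hi <- max(hi, max(p_rows$tss) + 1L)
      else lo <- min(lo, min(p_rows$tss))
    }
    if (minus) {
      start <- hi - g_end; end <- hi - g_start
      tss <- if (!is.null(p_rows) && nrow(p_rows)) hi - 1L - p_rows$tss else NULL
      offset <- hi  # genomic coordinate mapping: frame i <-> genome hi-1-i
    } else {
      start <- g_start - lo; end <- g_end - lo
      tss <- if (!is.null(p_rows) && nrow(p_rows)) p_rows$tss - lo else NULL
      offset <- lo
    }
    genes <- do.call(rbind, lapply(order(start), function(i)
      ta_gene(rows$gene_id[i], rows$role[i], start[i], end[i])))
    promoters <- if (!is.null(tss))
      data.frame(promoter_id = p_rows$promoter_id, tss = tss,
                 stringsAsFactors = FALSE) else NULL
    sq <- NULL
    if (!is.null(seqs)) {
      chrom <- as.character(GenomicRanges::seqnames(feats))[1L]
      hitseq <- seqs[[match(chrom, sub("\\s.*$", "", names(seqs)))]]
      sq <- Biostrings::subseq(hitseq, lo + 1L, hi)
      if (minus) sq <- Biostrings::reverseComplement(sq)
      sq <- as.character(sq)
    }
    ta_operon(op_id, genes, promoters, sq, offset = offset)
  })
}

#' Classify an operon-frame position into a structural region
#'
#' @param operon A \code{"ta_operon"}.
#' @param position 0-based operon-frame coordinate, \code{0 <= position <
#'   operon_span(operon)}.
#' @return One of \code{"leader"} (upstream of the first CDS),
#'   \code{"toxin_cds"}, \code{"antitoxin_cds"}, or \code{"intergenic"}.
#' @export
classify_region <- function(operon, position) {
  position <- as.integer(position)
  if (position < 0L || position >= operon_span(operon))
    stop("position outside operon span")
  g <- operon$genes
  if (position < min(g$start)) return("leader")
  inside <- g$start <= position & position < g$end
  if (any(inside)) {
    return(if (g$role[which(inside)[1L]] == "toxin") "toxin_cds"
           else "antitoxin_cds")
  }
  "intergenic"
}
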