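# Assembly summary statistics, alignment hit-table filtering, and ORF
# prediction on transcript contigs. Internal coordinates are 0-based
# half-open; GFF3 output is 1-based inclusive.

#' Assembly summary statistics
#'
#' Computes contig count, mean/median length, interquartile range, N50 and
#' total length for a set of assembled contigs. N50 is the contig length L
#' such that contigs of length >= L together cover at least half of the
#' total assembly length (lengths sorted descending, cumulative sum).
#' Median and IQR use the linear-interpolation quantile convention.
#'
#' @param contigs a \code{Biostrings::DNAStringSet}, or a numeric vector of
#'   contig lengths in bp.
#' @return a one-row data.frame with columns \code{n_contigs},
#'   \code{mean_length}, \code{median_length}, \code{iqr}, \code{n50},
#'   \code{total_length}.
#' @examples
#' assembly_stats(c(2, 3, 4, 5, 6))  # n50 = 5
#' @export
assembly_stats <- function(contigs) {
  lens <- if (is.numeric(contigs)) as.numeric(contigs) else
    as.numeric(Biostrings::width(contigs))
  if (length(lens) == 0L) stop("assembly_stats: no contigs supplied")
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1L]]
  data.frame(
    n_contigs = length(lens),
    mean_length = mean(lens),
    median_length = stats::median(lens),
    iqr = stats::IQR(lens),
    n50 = n50,
    total_length = total
  )
}

#' Read a tabular alignment hit table
#'
#' Reads a tab-separated BLAST outfmt-6-like table with columns
#' query_id, subject_id, pct_identity, aln_length, query_length,
#' subject_length, evalue, matches, mismatches.
#'
#' @param path file path.
#' @return data.frame of hit records.
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "query_length", "subject_length", "evalue", "matches",
            "mismatches")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < length(cols)) {
    stop("read_hits: expected at least ", length(cols), " columns, got ",
         ncol(df))
  }
  df <- df[, seq_along(cols)]
  names(df) <- cols
  df
}

#' Filter alignment hits by significance
#'
#' Keeps hits with percent identity greater than 80, alignment length at
#' least half the length of either the query or the subject sequence, and
#' e-value below 1e-5. These are the thresholds used to call a transcript
#' hit against a model-rodent gene set significant.
#'
#' @param hits data.frame as returned by \code{read_hits}.
#' @param min_identity identity threshold (exclusive), default 80.
#' @param min_len_frac alignment-length fraction (inclusive), default 0.5.
#' @param max_evalue e-value threshold (exclusive), default 1e-5.
#' @return the subset of rows passing all three rules.
#' @export
filter_significant_hits <- function(hits, min_identity = 80,
                                    min_len_frac = 0.5, max_evalue = 1e-5) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$pct_identity > min_identity &
    (hits$aln_length >= min_len_frac * hits$query_length |
       hits$aln_length >= min_len_frac * hits$subject_length) &
    hits$evalue < max_evalue
  hits[keep, , drop = FALSE]
}

#' Reduce significant hits to one-to-one gene candidates
#'
#' A (query, subject) pair is a gene candidate when, within the
#' significance-filtered table, the query matches exactly one distinct
#' subject and that subject matches exactly one distinct query. Duplicate
#' (query, subject) rows are collapsed before counting.
#'
#' @param hits significance-filtered hit table.
#' @return data.frame with columns \code{query_id}, \code{subject_id}.
#' @export
select_gene_candidates <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- unique(hits[, c("query_id", "subject_id")])
  q_deg <- table(pairs$query_id)
  s_deg <- table(pairs$subject_id)
  keep <- q_deg[pairs$query_id] == 1L & s_deg[pairs$subject_id] == 1L
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per query
#'
#' Selects, for each query, the hit maximizing score = matches - mismatches.
#' Ties are broken by higher percent identity, then by lexicographically
#' smallest subject id.
#'
#' @param hits data.frame of hit records.
#' @return data.frame with one row per query.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  score <- hits$matches - hits$mismatches
  ord <- order(hits$query_id, -score, -hits$pct_identity, hits$subject_id,
               method = "radix")
  sorted <- hits[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Scan one reading frame of one strand for the first-ATG ORF: first ATG in
# the frame, extended to the first in-frame stop after it (excluded) or to
# the sequence end (truncated ORF, trimmed to a codon multiple).
# Returns NULL or a list with 0-based half-open coords on the + strand.
.scan_frame <- function(seq, strand, frame, min_len) {
  n <- nchar(seq)
  if (n < frame + 3L) return(NULL)
  s <- if (strand == "-") revcomp(seq) else seq
  # codon starts in this frame (1-based on the working strand)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  atg <- which(codons == "ATG")
  if (length(atg) == 0L) return(NULL)
  first <- atg[1L]
  stops <- which(codons %in% STOP_CODONS)
  stop_after <- stops[stops > first]
  last <- if (length(stop_after) > 0L) stop_after[1L] - 1L else length(codons)
  len <- 3L * (last - first + 1L)
  if (len <= min_len) return(NULL)
  w_start <- starts[first] - 1L          # 0-based on working strand
  w_end <- w_start + len                 # half-open
  if (strand == "-") {
    list(start = n - w_end, end = n - w_start, length_nt = len)
  } else {
    list(start = w_start, end = w_end, length_nt = len)
  }
}

#' Predict an open reading frame on a contig
#'
#' Reading the contig in the given strand and frame, takes the first ATG and
#' extends to the first in-frame stop codon (excluded) or to the end of the
#' sequence (a truncated ORF, trimmed 3' to a codon multiple). The ORF is
#' reported only when longer than \code{min_len} nucleotides. When strand
#' and frame are omitted, all six frames are scanned and the longest
#' qualifying ORF returned (ties: + strand first, then smallest start).
#'
#' @param contig_id contig identifier used in the annotation.
#' @param seq the contig sequence (character, ACGTN).
#' @param strand "+" or "-", or NULL to scan both.
#' @param frame 0, 1 or 2 (offset of the reading frame), or NULL to scan all.
#' @param min_len minimum ORF length in nt, exclusive; default 150.
#' @return a one-row data.frame with columns \code{contig_id}, \code{start}
#'   (0-based), \code{end} (exclusive), \code{strand}, \code{frame},
#'   \code{length_nt}, or NULL when no qualifying ORF exists.
#' @export
predict_orf <- function(contig_id, seq, strand = NULL, frame = NULL,
                        min_len = 150L) {
  seq <- toupper(seq)
  strands <- if (is.null(strand)) c("+", "-") else strand
  frames <- if (is.null(frame)) 0:2 else frame
  stopifnot(all(strands %in% c("+", "-")), all(frames %in% 0:2))
  best <- NULL
  for (st in strands) {
    for (fr in frames) {
      cand <- .scan_frame(seq, st, fr, min_len)
      if (is.null(cand)) next
      cand$strand <- st
      cand$frame <- fr
      better <- is.null(best) ||
        cand$length_nt > best$length_nt ||
        (cand$length_nt == best$length_nt && best$strand == "-" && st == "+") ||
        (cand$length_nt == best$length_nt && st == best$strand &&
           cand$start < best$start)
      if (better) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  data.frame(contig_id = contig_id, start = best$start, end = best$end,
             strand = best$strand, frame = best$frame,
             length_nt = best$length_nt, stringsAsFactors = FALSE)
}

#' Predict ORFs for a set of contigs
#'
#' @param contigs named character vector or \code{DNAStringSet} of contig
#'   sequences.
#' @param hints optional data.frame with columns \code{contig_id},
#'   \code{strand}, \code{frame} giving the alignment-derived reading frame
#'   per contig; contigs without a hint are scanned over all six frames.
#' @param min_len minimum ORF length in nt (exclusive).
#' @return data.frame of ORF annotations (possibly zero rows).
#' @export
predict_orfs <- function(contigs, hints = NULL, min_len = 150L) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  }
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    id <- names(contigs)[i]
    strand <- frame <- NULL
    if (!is.null(hints)) {
      h <- hints[hints$contig_id == id, , drop = FALSE]
      if (nrow(h) == 1L) {
        strand <- h$strand
        frame <- h$frame
      }
    }
    out[[i]] <- predict_orf(id, contigs[[i]], strand, frame, min_len)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), length_nt = integer(0)))
  }
  do.call(rbind, out)
}

#' Extract the coding sequence of an ORF from its contig
#'
#' @param orf one-row ORF annotation.
#' @param seq the contig sequence.
#' @return character string, reverse-complemented for minus-strand ORFs.
#' @export
orf_sequence <- function(orf, seq) {
  s <- substr(toupper(seq), orf$start + 1L, orf$end)
  if (orf$strand == "-") revcomp(s) else s
}

#' Write ORF annotations to GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to 1-based inclusive. Features are typed CDS; the phase column is 0 (ORFs
#' start on a codon boundary, measured from the 3' end for minus-strand
#' features); the reading-frame offset is kept in a \code{frame} attribute.
#'
#' @param orfs data.frame of ORF annotations.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gff <- function(orfs, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = orfs$contig_id,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand
  )
  S4Vectors::mcols(gr)$source <- "pnpscan"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- paste0(orfs$contig_id, ".orf")
  S4Vectors::mcols(gr)$frame <- orfs$frame
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read ORF annotations from GFF3
#'
#' Inverts \code{write_gff}: 1-based inclusive GFF coordinates become
#' 0-based half-open internal coordinates.
#'
#' @param path GFF3 file path.
#' @return data.frame of ORF annotations.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  frame <- S4Vectors::mcols(gr)$frame
  if (is.null(frame)) frame <- rep(NA_integer_, length(gr))
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame = as.integer(frame),
    length_nt = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
}
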