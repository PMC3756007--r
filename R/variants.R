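# Post-call SNP filtering and codon-aware synonymous/nonsynonymous
# classification. SNP positions are 0-based internally (converted at the
# VCF boundary by read_vcf/write_vcf).

REJECT_REASONS <- c("indel", "low_quality", "low_occurrence", "high_coverage")

#' Filter variant records with pooled-sample thresholds
#'
#' Applies the conservative post-call filters used for pooled transcriptome
#' SNP libraries: indels removed, phred quality >= \code{qmin}, alternate
#' allele observed at least \code{min_occurrence} times, and read depth at
#' most \code{max_coverage} (a cap that screens out collapsed paralogs).
#' All thresholds are inclusive. Multiallelic records must be split before
#' filtering (\code{read_vcf} does this); each alternate allele is judged
#' independently.
#'
#' A record failing several rules is logged once, under the first failing
#' rule in the order indel, low_quality, low_occurrence, high_coverage, so
#' kept + rejected counts always sum to the input count.
#'
#' @param snps data.frame with columns \code{contig_id}, \code{pos}
#'   (0-based), \code{ref}, \code{alt}, \code{qual}, \code{depth},
#'   \code{occurrence}.
#' @param qmin minimum phred quality (inclusive), default 20.
#' @param min_occurrence minimum alternate-allele observations (inclusive),
#'   default 2.
#' @param max_coverage maximum read depth (inclusive), default 200.
#' @return list with \code{kept} (data.frame of passing SnpCalls),
#'   \code{rejected} (data.frame with an extra \code{reason} column) and
#'   \code{log} (per-reason rejection counts).
#' @export
filter_snps <- function(snps, qmin = 20, min_occurrence = 2,
                        max_coverage = 200) {
  required <- c("contig_id", "pos", "ref", "alt", "qual", "depth",
                "occurrence")
  missing <- setdiff(required, names(snps))
  if (length(missing) > 0L) {
    stop("filter_snps: missing columns: ", paste(missing, collapse = ", "))
  }
  is_snv <- nchar(snps$ref) == 1L & nchar(snps$alt) == 1L &
    toupper(snps$ref) %in% BASES & toupper(snps$alt) %in% BASES
  reason <- rep(NA_character_, nrow(snps))
  reason[!is_snv] <- "indel"
  need <- is.na(reason) & snps$qual < qmin
  reason[need] <- "low_quality"
  need <- is.na(reason) & snps$occurrence < min_occurrence
  reason[need] <- "low_occurrence"
  need <- is.na(reason) & snps$depth > max_coverage
  reason[need] <- "high_coverage"
  kept <- snps[is.na(reason), , drop = FALSE]
  rejected <- snps[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  log <- table(factor(rejected$reason, levels = REJECT_REASONS))
  list(kept = kept, rejected = rejected,
       log = stats::setNames(as.integer(log), REJECT_REASONS))
}

#' Locate a SNP within an ORF
#'
#' Maps a contig-coordinate SNP into codon coordinates of an ORF. Positions
#' outside the ORF return NULL. For minus-strand ORFs the position is mapped
#' through the reverse complement and both alleles are complemented. A SNP
#' whose reference allele disagrees with the contig base is flagged
#' \code{ref_mismatch} and excluded from classification.
#'
#' @param snp one-row data.frame (or list) with \code{contig_id}, \code{pos}
#'   (0-based), \code{ref}, \code{alt}.
#' @param orf one-row ORF annotation for the same contig.
#' @param contig_seq the contig sequence.
#' @return list with \code{codon_index} (0-based), \code{codon_pos} (0..2),
#'   \code{ref_codon}, \code{alt_codon}, \code{status} ("ok" or
#'   "ref_mismatch"), or NULL when the SNP lies outside the ORF.
#' @export
locate_in_orf <- function(snp, orf, contig_seq) {
  if (snp$contig_id != orf$contig_id) return(NULL)
  pos <- snp$pos
  if (pos < orf$start || pos >= orf$end) return(NULL)
  contig_seq <- toupper(contig_seq)
  base_at <- substr(contig_seq, pos + 1L, pos + 1L)
  ref <- toupper(snp$ref)
  alt <- toupper(snp$alt)
  if (base_at != ref) {
    return(list(status = "ref_mismatch", codon_index = NA_integer_,
                codon_pos = NA_integer_, ref_codon = NA_character_,
                alt_codon = NA_character_))
  }
  if (orf$strand == "-") {
    off <- orf$end - 1L - pos       # offset within the coding strand
    ref <- complement_base(ref)
    alt <- complement_base(alt)
  } else {
    off <- pos - orf$start
  }
  cds <- orf_sequence(orf, contig_seq)
  codon_index <- off %/% 3L
  codon_pos <- off %% 3L
  ref_codon <- substr(cds, codon_index * 3L + 1L, codon_index * 3L + 3L)
  alt_codon <- substitute_base(ref_codon, codon_pos + 1L, alt)
  list(status = "ok", codon_index = codon_index, codon_pos = codon_pos,
       ref_codon = ref_codon, alt_codon = alt_codon)
}

#' Classify a located SNP as synonymous or nonsynonymous
#'
#' Compares standard-genetic-code translations of the reference and
#' alternate codons. Changes to or from a stop codon are classed
#' nonsynonymous. Codons containing N cannot be classified.
#'
#' @param ref_codon,alt_codon 3-letter codons differing at one position.
#' @return "synonymous", "nonsynonymous", or NA when a codon contains a
#'   base outside ACGT.
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  if (grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", alt_codon)) {
    return(NA_character_)
  }
  if (translate_codon(ref_codon) == translate_codon(alt_codon)) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
}

#' Classify filtered SNPs within predicted ORFs
#'
#' For each SNP, finds the ORF on its contig (if any), localizes it to a
#' codon and labels it synonymous or nonsynonymous. SNPs outside any ORF are
#' reported separately (they remain in the genome-wide SNP table but carry
#' no coding effect); reference mismatches and ambiguous codons are
#' excluded with a reason.
#'
#' @param snps data.frame of filtered SnpCalls.
#' @param orfs data.frame of ORF annotations (one per contig).
#' @param contigs named character vector or \code{DNAStringSet} of contig
#'   sequences.
#' @return list with \code{classified} (data.frame: SNP fields plus
#'   \code{orf_id}, \code{codon_index}, \code{codon_pos}, \code{ref_codon},
#'   \code{alt_codon}, \code{effect}) and \code{unclassified} (data.frame
#'   with a \code{reason} column: no_orf, outside_orf, ref_mismatch,
#'   ambiguous_codon).
#' @export
classify_snps <- function(snps, orfs, contigs) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  }
  n <- nrow(snps)
  effect <- orf_id <- ref_codon <- alt_codon <- rep(NA_character_, n)
  codon_index <- codon_pos <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    snp <- snps[i, ]
    hit <- orfs[orfs$contig_id == snp$contig_id, , drop = FALSE]
    if (nrow(hit) == 0L) {
      reason[i] <- "no_orf"
      next
    }
    orf <- hit[1L, ]
    loc <- locate_in_orf(snp, orf, contigs[[snp$contig_id]])
    if (is.null(loc)) {
      reason[i] <- "outside_orf"
      next
    }
    if (loc$status == "ref_mismatch") {
      reason[i] <- "ref_mismatch"
      next
    }
    eff <- classify_codon_change(loc$ref_codon, loc$alt_codon)
    if (is.na(eff)) {
      reason[i] <- "ambiguous_codon"
      next
    }
    effect[i] <- eff
    orf_id[i] <- paste0(orf$contig_id, ".orf")
    codon_index[i] <- loc$codon_index
    codon_pos[i] <- loc$codon_pos
    ref_codon[i] <- loc$ref_codon
    alt_codon[i] <- loc$alt_codon
  }
  ok <- is.na(reason)
  classified <- cbind(snps[ok, , drop = FALSE],
                      data.frame(orf_id = orf_id[ok],
                                 codon_index = codon_index[ok],
                                 codon_pos = codon_pos[ok],
                                 ref_codon = ref_codon[ok],
                                 alt_codon = alt_codon[ok],
                                 effect = effect[ok],
                                 stringsAsFactors = FALSE))
  unclassified <- snps[!ok, , drop = FALSE]
  unclassified$reason <- reason[!ok]
  rownames(classified) <- rownames(unclassified) <- NULL
  list(classified = classified, unclassified = unclassified)
}
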