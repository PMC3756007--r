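# Per-gene pN/pS between population pairs: Nei-Gojobori (1986) expected
# site counts, pathway-averaged difference counts, inclusion filters and
# candidate categories. Proportions are used directly (no multiple-hit
# correction): within-species distances here are far from saturation.

#' Nei-Gojobori expected synonymous and nonsynonymous site counts
#'
#' For each codon, each of the three positions contributes
#' f = (number of the 3 possible single-base changes that are synonymous)/3
#' synonymous sites and 1 - f nonsynonymous sites. Changes that create a
#' stop codon count as nonsynonymous. N_sites + S_sites equals the sequence
#' length in nucleotides.
#'
#' @param seq in-frame coding sequence with no internal stop codon.
#' @return named numeric vector \code{c(N_sites =, S_sites =)}.
#' @export
ng86_site_counts <- function(seq) {
  codons <- split_codons(toupper(seq))
  if (any(codons %in% STOP_CODONS)) {
    stop("ng86_site_counts: sequence contains an in-frame stop codon")
  }
  s_sites <- sum(syn_sites_per_codon()[codons])
  c(N_sites = 3 * length(codons) - s_sites, S_sites = s_sites)
}

# All orderings of k differing positions, as a list of integer vectors.
.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Pathway-averaged (nonsyn, syn) difference counts for one codon pair.
# Paths through stop codons are excluded; if every path is blocked, all
# steps are counted nonsynonymous (a stop-bounded change is never silent).
.codon_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(nd = 0, sd = 0, n = 0))
  totals <- c(nd = 0, sd = 0)
  n_valid <- 0L
  for (path in .permutations(pos)) {
    cur <- a
    nd <- sd <- 0
    valid <- TRUE
    for (p in path) {
      nxt <- substitute_base(cur, p, substr(b, p, p))
      if (nxt %in% STOP_CODONS) {
        valid <- FALSE
        break
      }
      if (translate_codon(cur) == translate_codon(nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (valid) {
      totals <- totals + c(nd = nd, sd = sd)
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(nd = k, sd = 0, n = k))
  c(totals / n_valid, n = k)
}

#' Pathway-averaged difference counts between two aligned coding sequences
#'
#' Codons differing at one position are classified directly; codons with k
#' differences are averaged over all k! orderings of single-step mutational
#' paths, excluding paths that pass through a stop codon (when every path
#' is blocked, all k steps count as nonsynonymous). Nd + Sd equals the
#' pathway-averaged total number of differences.
#'
#' @param seq_a,seq_b equal-length in-frame coding sequences.
#' @return named numeric vector \code{c(Nd =, Sd =, n_diffs =)} where
#'   \code{n_diffs} is the number of differing nucleotide sites.
#' @export
count_differences <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("count_differences: sequences differ in length")
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  nd <- sd <- nd_tot <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    d <- .codon_pair_diffs(ca[i], cb[i])
    nd <- nd + d[["nd"]]
    sd <- sd + d[["sd"]]
    nd_tot <- nd_tot + d[["n"]]
  }
  c(Nd = nd, Sd = sd, n_diffs = nd_tot)
}

#' Match population ORF sets into alignable pairs
#'
#' Populations assembled against a common reference share contig/gene
#' identifiers, so orthologous ORFs are paired by id. Pairs whose ORFs
#' differ in length cannot be compared without gapped alignment and are
#' reported as skipped.
#'
#' @param orfs_a,orfs_b named character vectors of in-frame ORF sequences,
#'   keyed by gene id.
#' @return list with \code{pairs} (data.frame: gene_id, seq_a, seq_b) and
#'   \code{skipped} (data.frame: gene_id, reason).
#' @export
match_orf_pairs <- function(orfs_a, orfs_b) {
  shared <- intersect(names(orfs_a), names(orfs_b))
  a <- unname(unlist(orfs_a[shared]))
  b <- unname(unlist(orfs_b[shared]))
  if (length(shared) == 0L) a <- b <- character(0)
  equal <- nchar(a) == nchar(b)
  list(
    pairs = data.frame(gene_id = shared[equal], seq_a = a[equal],
                       seq_b = b[equal], stringsAsFactors = FALSE),
    skipped = data.frame(gene_id = shared[!equal],
                         reason = rep("unequal_length", sum(!equal)),
                         stringsAsFactors = FALSE)
  )
}

#' Score one ORF pair: pN/pS and candidate category
#'
#' Computes NG86 site counts on the first sequence, pathway-averaged
#' difference counts, pN = Nd/N_sites, pS = Sd/S_sites and their ratio,
#' then assigns a category: \code{strong} when the ratio exceeds 1,
#' \code{moderate} when it lies in (0.5, 1], \code{below} otherwise.
#' Genes with fewer than \code{min_snps} differences, ORFs not longer than
#' \code{min_len} nt, or no synonymous differences (undefined ratio) are
#' \code{filtered} with a reason.
#'
#' @param gene_id gene identifier.
#' @param seq_a,seq_b equal-length in-frame coding sequences.
#' @param min_snps minimum number of differing sites (inclusive), default 3.
#' @param min_len minimum ORF length in nt (exclusive), default 150.
#' @return one-row data.frame with columns gene_id, n_diffs, Nd, Sd,
#'   N_sites, S_sites, pn, ps, ratio, category, reason.
#' @export
score_pair <- function(gene_id, seq_a, seq_b, min_snps = 3, min_len = 150) {
  sites <- ng86_site_counts(seq_a)
  d <- count_differences(seq_a, seq_b)
  pn <- d[["Nd"]] / sites[["N_sites"]]
  ps <- d[["Sd"]] / sites[["S_sites"]]
  category <- "below"
  reason <- NA_character_
  ratio <- NA_real_
  if (nchar(seq_a) <= min_len) {
    category <- "filtered"
    reason <- "min_len"
  } else if (d[["n_diffs"]] < min_snps) {
    category <- "filtered"
    reason <- "min_snps"
  } else if (d[["Sd"]] == 0) {
    category <- "filtered"
    reason <- "zero_synonymous"
  } else {
    ratio <- pn / ps
    category <- if (ratio > 1) "strong" else if (ratio > 0.5) "moderate"
      else "below"
  }
  data.frame(gene_id = gene_id, n_diffs = d[["n_diffs"]], Nd = d[["Nd"]],
             Sd = d[["Sd"]], N_sites = sites[["N_sites"]],
             S_sites = sites[["S_sites"]], pn = pn, ps = ps, ratio = ratio,
             category = category, reason = reason, stringsAsFactors = FALSE)
}

#' Scan all population pairs for pN/pS outliers
#'
#' Runs \code{score_pair} over every shared gene of every unordered pair of
#' populations.
#'
#' @param orf_sets named list (one element per population) of named
#'   character vectors of ORF sequences.
#' @param min_snps,min_len inclusion filters passed to \code{score_pair}.
#' @return data.frame with one row per (gene, population pair): columns
#'   pop_a, pop_b plus the \code{score_pair} columns.
#' @export
scan_populations <- function(orf_sets, min_snps = 3, min_len = 150) {
  if (length(orf_sets) < 2L) {
    stop("scan_populations: need at least two populations")
  }
  pops <- names(orf_sets)
  out <- list()
  for (i in seq_len(length(pops) - 1L)) {
    for (j in seq.int(i + 1L, length(pops))) {
      m <- match_orf_pairs(orf_sets[[i]], orf_sets[[j]])
      for (k in seq_len(nrow(m$pairs))) {
        row <- score_pair(m$pairs$gene_id[k], m$pairs$seq_a[k],
                          m$pairs$seq_b[k], min_snps, min_len)
        out[[length(out) + 1L]] <- cbind(
          data.frame(pop_a = pops[i], pop_b = pops[j],
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  if (length(out) == 0L) {
    empty <- score_pair("x", strrep("ATG", 60), strrep("ATG", 60))[0, ]
    return(cbind(data.frame(pop_a = character(0), pop_b = character(0)),
                 empty))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a selection scan by candidate category
#'
#' @param scores data.frame from \code{scan_populations}.
#' @return data.frame of counts and proportions per category, echoing the
#'   0.5 / 1.0 pN/pS breakdown used to rank candidates.
#' @export
summarize_scan <- function(scores) {
  lev <- c("strong", "moderate", "below", "filtered")
  counts <- table(factor(scores$category, levels = lev))
  data.frame(category = lev, n = as.integer(counts),
             proportion = as.numeric(counts) / max(1L, nrow(scores)),
             stringsAsFactors = FALSE)
}
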