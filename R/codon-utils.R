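# Codon-level helpers shared by the variant classifier, the NG86 estimator
# and the sequence simulator. All work on upper-case ACGT strings and the
# standard genetic code (Biostrings::GENETIC_CODE).

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a single codon under the standard genetic code
#'
#' @param codon character vector of 3-letter codons (ACGT only).
#' @return character vector of one-letter amino acids, `"*"` for stop.
#' @keywords internal
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Split a coding sequence into codons
#' @param seq a single in-frame DNA string (length a multiple of 3).
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Is a single-base change a transition?
#' @keywords internal
is_transition <- function(ref, alt) {
  purines <- c("A", "G")
  (ref %in% purines) == (alt %in% purines)
}

#' Substitute one base within a codon
#' @keywords internal
substitute_base <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

#' Enumerate all nine single-base changes of a codon
#'
#' Returns one row per (position, alternative base) with the mutated codon
#' and its effect relative to the input codon. Changes that create a stop
#' codon are classed nonsynonymous and flagged `to_stop`.
#'
#' @param codon one sense codon.
#' @return data.frame with columns `pos` (1..3), `ref` base, `alt` base,
#'   `alt_codon`, `effect` ("synonymous"/"nonsynonymous"), `to_stop` logical,
#'   `transition` logical.
#' @keywords internal
enumerate_codon_changes <- function(codon) {
  aa <- translate_codon(codon)
  rows <- vector("list", 9L)
  i <- 0L
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (alt in setdiff(BASES, ref)) {
      i <- i + 1L
      alt_codon <- substitute_base(codon, pos, alt)
      alt_aa <- translate_codon(alt_codon)
      rows[[i]] <- data.frame(
        pos = pos, ref = ref, alt = alt, alt_codon = alt_codon,
        effect = if (identical(alt_aa, aa)) "synonymous" else "nonsynonymous",
        to_stop = alt_aa == "*",
        transition = is_transition(ref, alt),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Reverse-complement a DNA string
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Complement single bases
#' @keywords internal
complement_base <- function(base) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[base])
}

#' Check that a string is a valid in-frame ORF
#'
#' An ORF here starts with ATG, has codon-multiple length and no internal
#' in-frame stop codon (a terminal stop is not part of the ORF).
#' @keywords internal
is_valid_orf <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L || n == 0L) return(FALSE)
  if (substr(seq, 1L, 3L) != "ATG") return(FALSE)
  !any(split_codons(seq) %in% STOP_CODONS)
}

.pnpscan_cache <- new.env(parent = emptyenv())

# Precomputed table of all single-base changes of all 64 codons, with a
# codon -> row-index list for fast per-gene assembly. Built once per session.
codon_change_table <- function() {
  if (is.null(.pnpscan_cache$changes)) {
    all_codons <- names(Biostrings::GENETIC_CODE)
    tbl <- do.call(rbind, lapply(all_codons, function(cdn) {
      ch <- enumerate_codon_changes(cdn)
      ch$codon <- cdn
      ch
    }))
    rownames(tbl) <- NULL
    .pnpscan_cache$changes <- tbl
    .pnpscan_cache$change_idx <- split(seq_len(nrow(tbl)), tbl$codon)
  }
  list(tbl = .pnpscan_cache$changes, idx = .pnpscan_cache$change_idx)
}

# Per-codon synonymous site counts (number of synonymous single-base
# changes / 3), for the NG86 estimator.
syn_sites_per_codon <- function() {
  if (is.null(.pnpscan_cache$syn_sites)) {
    cc <- codon_change_table()
    syn <- tapply(cc$tbl$effect == "synonymous", cc$tbl$codon, sum) / 3
    .pnpscan_cache$syn_sites <- syn
  }
  .pnpscan_cache$syn_sites
}

# All single-base changes for an in-frame sequence: one row per
# (0-based nt site, alternative base), with effect relative to the codon
# context of `seq`.
gene_change_table <- function(seq) {
  codons <- split_codons(seq)
  cc <- codon_change_table()
  ids <- unlist(cc$idx[codons], use.names = FALSE)
  tbl <- cc$tbl[ids, , drop = FALSE]
  tbl$site <- rep((seq_along(codons) - 1L) * 3L, each = 9L) + tbl$pos - 1L
  tbl$codon_index <- rep(seq_along(codons) - 1L, each = 9L)
  rownames(tbl) <- NULL
  tbl
}

# Stable 32-bit FNV-1a hash of a string, reduced to a positive R integer.
# Used to derive independent per-gene RNG streams from one master seed.
stable_hash <- function(x) {
  mulmod <- function(a, b, m) {
    # exact (a * b) %% m for a < 2^31, b < 2^25 using 15-bit limbs
    lo <- a %% 2^15
    hi <- a %/% 2^15
    ((((hi * b) %% m) * 2^15) %% m + lo * b) %% m
  }
  bytes <- utf8ToInt(x)
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- mulmod(h, 16777619, 2^31)
  }
  as.integer(h %% (.Machine$integer.max - 1) + 1)
}

derive_seed <- function(seed, key) {
  stable_hash(paste(seed, key, sep = "::"))
}
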