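# Independent oracles used across the suite. They deliberately share no code
# with the package: the genetic code is hard-coded in the canonical
# T/C/A/G-order string, probabilities come from choose(), and counting is
# done by explicit enumeration.

# standard genetic code, codons ordered TTT, TTC, TTA, TTG, TCT, ... (NCBI
# table 1, base order T, C, A, G)
.oracle_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(0)
  for (x in b) for (y in b) for (z in b) {
    codons <- c(codons, paste0(x, y, z))
  }
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

oracle_translate <- function(codon) unname(.oracle_code[codon])

oracle_sense_codons <- names(.oracle_code)[.oracle_code != "*"]

# brute-force N50: largest observed length L such that contigs >= L cover
# at least half the total (checked over every candidate length)
oracle_n50 <- function(lens) {
  total <- sum(lens)
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(lens[lens >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# enumeration oracle for NG86 site counts of one codon
oracle_codon_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (alt in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
  }
  c(N_sites = 3 - syn / 3, S_sites = syn / 3)
}

# brute-force pathway averaging between two codons (k <= 3 differences):
# enumerate all orderings, drop paths through stops, average syn/nonsyn
# step counts; all-nonsynonymous if every path is blocked.
oracle_pathway <- function(a, b) {
  stops <- c("TAA", "TAG", "TGA")
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(Nd = 0, Sd = 0))
  perms <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) perms[[length(perms) + 1]] <<- prefix
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), pos)
  tot <- c(Nd = 0, Sd = 0)
  nv <- 0
  for (perm in perms) {
    cur <- a
    nd <- sd <- 0
    ok <- TRUE
    for (p in perm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% stops) { ok <- FALSE; break }
      if (oracle_translate(cur) == oracle_translate(nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(Nd = nd, Sd = sd); nv <- nv + 1 }
  }
  if (nv == 0) return(c(Nd = k, Sd = 0))
  tot / nv
}

# full-enumeration oracle for the two-tailed Fisher exact p of a 2x2 table:
# hypergeometric probabilities from choose(), point-probability method.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m + n2 == 0 || k == 0 || k == m + n2) return(1)
  xs <- max(0, k - n2):min(k, m)
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(m + n2, k)
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# explicit-summation oracle for the upper hypergeometric tail P(X >= k)
oracle_hyper_tail <- function(k, K, n, Nt) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(Nt - K, n - xs)) / choose(Nt, n)
}

# a random stop-free ATG-initiated ORF, for property tests
random_orf <- function(n_codons, seed) {
  set.seed(seed)
  paste0("ATG", paste(sample(oracle_sense_codons, n_codons - 1,
                             replace = TRUE), collapse = ""))
}
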