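# McDonald-Kreitman 2x2 tables, neutrality index, and a self-contained
# two-tailed Fisher's exact test (point-probability method, computed in
# log-space).

#' Build a McDonald-Kreitman count table for one gene
#'
#' Counts within-species polymorphisms and between-species fixed
#' differences by effect class. Polymorphism and divergence strata must be
#' non-overlapping: a site present in both is counted once, as a
#' polymorphism, and logged.
#'
#' @param poly classified within-species SNPs for the gene (data.frame with
#'   \code{pos} and \code{effect} columns).
#' @param div classified fixed interspecies differences for the gene (same
#'   columns).
#' @return list with \code{counts} = named integer vector (Pn, Ps, Dn, Ds)
#'   and \code{overlap} = positions removed from the divergence stratum.
#' @export
build_mk_table <- function(poly, div) {
  overlap <- intersect(poly$pos, div$pos)
  if (length(overlap) > 0L) {
    div <- div[!div$pos %in% overlap, , drop = FALSE]
  }
  counts <- c(
    Pn = sum(poly$effect == "nonsynonymous"),
    Ps = sum(poly$effect == "synonymous"),
    Dn = sum(div$effect == "nonsynonymous"),
    Ds = sum(div$effect == "synonymous")
  )
  list(counts = counts, overlap = overlap)
}

#' Neutrality index
#'
#' NI = (Pn/Ps) / (Dn/Ds), the ratio of the polymorphism class ratio to the
#' divergence class ratio. NI > 1 indicates an excess of amino-acid
#' polymorphism relative to divergence (consistent with segregating slightly
#' deleterious or balanced variants); NI < 1 suggests adaptive fixation.
#' Undefined (NA with a \code{reason} attribute) when Ps, Dn or Ds is 0.
#'
#' @param Pn,Ps nonsynonymous / synonymous polymorphism counts.
#' @param Dn,Ds nonsynonymous / synonymous fixed-difference counts.
#' @return NI as a single number, or NA with attribute \code{reason}.
#' @examples
#' neutrality_index(6, 1, 13, 28)   # 12.923
#' @export
neutrality_index <- function(Pn, Ps, Dn, Ds) {
  stopifnot(Pn >= 0, Ps >= 0, Dn >= 0, Ds >= 0)
  if (Ps == 0 || Dn == 0 || Ds == 0) {
    bad <- c("Ps", "Dn", "Ds")[c(Ps, Dn, Ds) == 0]
    return(structure(NA_real_,
                     reason = paste0("zero_", paste(bad, collapse = "_"))))
  }
  (Pn / Ps) / (Dn / Ds)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-tailed p-value by the point-probability method:
#' the sum, over all tables with the observed margins, of the probabilities
#' not exceeding the probability of the observed table (a relative tolerance
#' of 1e-7 guards against floating-point exclusion of ties). Probabilities
#' are computed in log-space via \code{lchoose}. A table with an all-zero
#' margin has p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return the two-tailed p-value.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2/choose(10, 5)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  m <- a + b        # row 1 total
  n2 <- c + d       # row 2 total
  k <- a + c        # column 1 total
  if (m + n2 == 0 || k == 0 || k == m + n2) return(1)
  # support of the hypergeometric for cell a given the margins
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  obs <- logp[x == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' McDonald-Kreitman test for one gene
#'
#' Assembles the 2x2 table of nonsynonymous/synonymous polymorphism and
#' divergence counts, the class ratios, the neutrality index and the
#' two-tailed Fisher's exact p-value.
#'
#' @param Pn,Ps,Dn,Ds the four MK counts.
#' @param gene_id optional label.
#' @return one-row data.frame with columns gene_id, Pn, Ps, poly_ratio, Dn,
#'   Ds, div_ratio, NI, p_value, defined.
#' @examples
#' mk_test(4, 1, 15, 32)  # NI = 8.53
#' @export
mk_test <- function(Pn, Ps, Dn, Ds, gene_id = NA_character_) {
  ni <- neutrality_index(Pn, Ps, Dn, Ds)
  data.frame(
    gene_id = gene_id, Pn = Pn, Ps = Ps,
    poly_ratio = if (Ps > 0) Pn / Ps else NA_real_,
    Dn = Dn, Ds = Ds,
    div_ratio = if (Ds > 0) Dn / Ds else NA_real_,
    NI = as.numeric(ni),
    p_value = fisher_exact_2x2(Pn, Ps, Dn, Ds),
    defined = !is.na(ni),
    stringsAsFactors = FALSE
  )
}

#' McDonald-Kreitman tests over a table of genes
#'
#' @param counts data.frame with columns gene_id, Pn, Ps, Dn, Ds.
#' @return data.frame with one \code{mk_test} row per gene.
#' @export
mk_test_batch <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    mk_test(counts$Pn[i], counts$Ps[i], counts$Dn[i], counts$Ds[i],
            gene_id = counts$gene_id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
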