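# GO-term overrepresentation between sequence sets: one-tailed Fisher's
# exact (hypergeometric upper tail), Benjamini-Hochberg FDR, and reduction
# of significant terms to their most-specific members.

#' Read a GO annotation table
#'
#' Tab-separated, two columns: sequence id and a comma-separated list of
#' GO:NNNNNNN term ids.
#'
#' @param path file path.
#' @return named list mapping seq_id to a character vector of term ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("seq_id", "terms"))
  stats::setNames(strsplit(df$terms, ",", fixed = TRUE), df$seq_id)
}

#' One-tailed GO-term overrepresentation test
#'
#' For every term annotating at least one sequence in the test set, tests
#' overrepresentation of the term in the test set against the combined
#' (test + reference) background with the upper-tail hypergeometric
#' probability — the one-tailed Fisher's exact test on the 2x2 table
#' (k, n-k; K-k, (Nt-n)-(K-k)). A sequence annotated with a term more than
#' once counts once. P-values are adjusted by Benjamini-Hochberg.
#'
#' @param test_ids,ref_ids disjoint character vectors of sequence ids.
#' @param annotations named list mapping seq_id to term ids.
#' @param alpha FDR threshold, default 0.05.
#' @return data.frame with columns term, k, n, K, Nt, p_raw, p_adjusted,
#'   significant; one row per term, ordered by p_raw.
#' @export
overrepresentation_test <- function(test_ids, ref_ids, annotations,
                                    alpha = 0.05) {
  if (length(test_ids) == 0L) {
    stop("overrepresentation_test: empty test set")
  }
  if (length(intersect(test_ids, ref_ids)) > 0L) {
    stop("overrepresentation_test: test and reference sets overlap")
  }
  term_sets <- lapply(annotations, unique)
  n <- length(test_ids)
  Nt <- n + length(ref_ids)
  test_terms <- unlist(term_sets[intersect(test_ids, names(term_sets))],
                       use.names = FALSE)
  all_terms <- unlist(term_sets[intersect(c(test_ids, ref_ids),
                                          names(term_sets))],
                      use.names = FALSE)
  k_tab <- table(test_terms)
  K_tab <- table(all_terms)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  # upper tail: P(X >= k) for X ~ Hypergeom(K successes, Nt - K, draws n)
  p_raw <- stats::phyper(k - 1, K, Nt - K, n, lower.tail = FALSE)
  p_adj <- bh_fdr(p_raw)
  out <- data.frame(term = terms, k = k, n = n, K = K, Nt = Nt,
                    p_raw = p_raw, p_adjusted = p_adj,
                    significant = p_adj <= alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving wrapper around \code{stats::p.adjust(method = "BH")}.
#'
#' @param p vector of raw p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

# Transitive ancestors of a term under a child -> parents table; errors on
# cycles.
.ancestors <- function(term, parents, seen = character(0)) {
  direct <- parents$parent[parents$child == term]
  out <- character(0)
  for (p in direct) {
    if (p %in% seen) stop("reduce_to_most_specific: cycle at term ", p)
    out <- union(out, c(p, .ancestors(p, parents, c(seen, term))))
  }
  out
}

#' Reduce significant terms to their most-specific members
#'
#' Removes every term that is a (transitive) ancestor of another term in the
#' set, so only the most-specific significant annotations remain.
#'
#' @param terms character vector of significant term ids.
#' @param parents data.frame with columns \code{child}, \code{parent}
#'   (acyclic); NULL means no known relations.
#' @return the subset of \code{terms} that are not ancestors of other
#'   members.
#' @export
reduce_to_most_specific <- function(terms, parents = NULL) {
  if (is.null(parents) || nrow(parents) == 0L || length(terms) == 0L) {
    return(terms)
  }
  anc <- unique(unlist(lapply(terms, .ancestors, parents = parents)))
  setdiff(terms, anc)
}

#' Pairwise tissue overrepresentation comparison
#'
#' For each tissue, tests its sequence set against each other tissue
#' separately and reports the terms significant in every comparison (the
#' commonly-overrepresented set), optionally reduced to most-specific terms.
#'
#' @param tissue_sets named list of sequence-id vectors, one per tissue.
#' @param annotations named list mapping seq_id to term ids.
#' @param alpha FDR threshold.
#' @param parents optional child/parent table for most-specific reduction.
#' @return named list, one element per tissue, each with \code{per_comparison}
#'   (list of result data.frames keyed by the other tissue) and
#'   \code{common} (character vector of terms significant in all
#'   comparisons, most-specific if \code{parents} given).
#' @export
pairwise_tissue_comparison <- function(tissue_sets, annotations,
                                       alpha = 0.05, parents = NULL) {
  if (length(tissue_sets) < 2L) {
    stop("pairwise_tissue_comparison: need at least two tissues")
  }
  tissues <- names(tissue_sets)
  out <- list()
  for (t in tissues) {
    per <- list()
    sig_sets <- list()
    for (o in setdiff(tissues, t)) {
      res <- overrepresentation_test(tissue_sets[[t]], tissue_sets[[o]],
                                     annotations, alpha)
      per[[o]] <- res
      sig_sets[[o]] <- res$term[res$significant]
    }
    common <- Reduce(intersect, sig_sets)
    out[[t]] <- list(per_comparison = per,
                     common = reduce_to_most_specific(common, parents))
  }
  out
}
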