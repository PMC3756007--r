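---
title: "Methods: selection scans on pooled population transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans on pooled population transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpscan)
```

## The problem

Pooled transcriptome sequencing of several reproductively isolated
populations yields, per population, a set of assembled transcript contigs
and a table of variant calls against a common reference assembly. With no
per-individual genotypes, the signal available for detecting selection is
the *composition* of sequence differences: within coding regions, the
balance of nonsynonymous to synonymous changes, compared between
populations and against an outgroup species. `pnpscan` implements that scan
end to end:

1. predict open reading frames (ORFs) on frame-annotated contigs;
2. filter pooled variant calls with conservative post-call thresholds;
3. classify each retained SNP as synonymous or nonsynonymous in its codon;
4. compute per-gene pN/pS between population pairs and flag outliers;
5. contrast within-species polymorphism with between-species divergence in
   McDonald-Kreitman (MK) tables, with a neutrality index and an exact test;
6. test GO-term overrepresentation of candidate sets with FDR control.

A synthetic-data generator with fully recorded ground truth stands in for
the sequencing data, so every stage is testable without external resources.

## ORF prediction

Given a contig and a reading frame (in practice derived from a protein
alignment; all six frames are scanned when no hint exists), the ORF is the
first in-frame ATG extended to the first in-frame stop codon (excluded) or
to the contig end — a *truncated* ORF, trimmed 3′ to a codon multiple.
Only ORFs strictly longer than 150 nt (at least 51 codons) are annotated.
The length rule is read strictly (`> 150`), and truncated ORFs are accepted:
assembled transcripts frequently lack complete 3′ ends, and requiring a stop
codon would discard them wholesale. Internally all coordinates are 0-based
half-open; GFF3 output is 1-based inclusive with phase 0 (ORFs start on a
codon boundary; for minus-strand features the phase convention is measured
from the 3′ end, which for complete codons is also 0).

Alignment hit tables are reduced in two steps before any gene-level claim:
hits are significant when identity exceeds 80%, the alignment covers at
least half of the query *or* subject, and the e-value is below 1e-5; and a
(query, subject) pair is a *gene candidate* only when each side matches
exactly one partner among the significant hits (duplicate rows are collapsed
first, so a repeated identical hit cannot veto itself). Best hits maximize
`matches − mismatches`, with ties broken by identity and then lexicographic
subject id — a deterministic, reproducible order.

## SNP filtering and classification

Pooled variant calls are kept when they are single-nucleotide, biallelic
(multiallelic records are split and judged per allele), with phred quality
≥ 20, alternate-allele occurrence ≥ 2, and coverage ≤ 200. All three
thresholds are inclusive, exactly as stated; the coverage cap screens out
collapsed paralogs, and the occurrence floor suppresses singleton sequencing
errors in pooled data. "Occurrence" is read as the alternate-allele
observation count (VCF INFO/AC), the standard pooled-data usage; depth comes
from INFO/DP. A record failing several rules is logged once under the first
failing rule (indel, then quality, then occurrence, then coverage), so the
rejection log always sums with the kept set to the input count.

A retained SNP inside an ORF is mapped to its codon; for minus-strand ORFs
the position is reflected through the reverse complement and both alleles
complemented. The effect label compares standard-genetic-code translations
of the reference and alternate codons. Changes to or from a stop codon are
labelled nonsynonymous: this keeps the site-count bookkeeping total (every
one of the 9 single-base changes of a codon is either synonymous or
nonsynonymous) and matches common practice for the Nei–Gojobori estimator.
SNPs whose reference allele disagrees with the contig, or whose codon
contains an N, are excluded with a reason rather than guessed.

## The pN/pS scan

For each gene shared by a pair of populations (matched by reference contig
id — the populations are assembled against a common reference, so identifier
matching is exact and no clustering heuristic is needed), the scan computes
the Nei–Gojobori (1986) proportion estimator:

* **Expected sites.** Each codon position contributes `f` synonymous sites,
  where `f` is the fraction of its 3 possible single-base changes that are
  synonymous, and `1 − f` nonsynonymous sites. `N + S` always equals the
  sequence length in nucleotides.
* **Observed differences.** Codons differing at one position are classified
  directly. Codons differing at `k > 1` positions are averaged over all `k!`
  single-step mutational pathways, excluding pathways that pass through a
  stop codon; if every pathway is blocked, all `k` steps count as
  nonsynonymous (a stop-bounded change is never silent). All admissible
  pathways are weighted equally, the classic convention.
* **The statistic.** `pN = Nd/N`, `pS = Sd/S`, and the reported ratio is
  `pN/pS`. No multiple-hit correction is applied: within-species and
  between-population distances here are far below saturation, where the
  proportion estimator and maximum-likelihood codon models agree closely.
  This is a deliberate substitution for a full GY94-style ML estimator,
  whose machinery (codon frequency estimation, transition/transversion
  estimation) adds nothing at these distances; the estimator is validated
  by exhaustive per-codon oracles and by parameter recovery on simulated
  genes rather than by matching any published per-gene table.

Genes enter the scan only with at least 3 differences, an ORF longer than
150 nt and no in-frame stops. Genes with `Sd = 0` are excluded as undefined
rather than assigned an infinite ratio — a zero synonymous count at these
sample sizes is sampling noise, and an infinite ratio would fabricate
"strong" candidates. Categories follow the conventional screening bands:
`strong` when the ratio exceeds 1.0, `moderate` in (0.5, 1.0], `below`
otherwise.

## McDonald-Kreitman tests and the neutrality index

Per gene, polymorphisms within the focal species and fixed differences
against the outgroup are counted by effect class into a 2×2 table
(Pn, Ps, Dn, Ds). The strata must be non-overlapping: a site appearing in
both is counted once, as a polymorphism, and logged. The neutrality index is

NI = (Pn/Ps) / (Dn/Ds),

undefined when Ps, Dn or Ds is zero (reported with the zero cell named
rather than coerced to 0 or infinity). NI > 1 indicates an excess of
amino-acid polymorphism relative to divergence.

Significance uses a self-contained two-tailed Fisher's exact test: the sum
of hypergeometric probabilities, over all tables with the observed margins,
that do not exceed the observed table's probability. This point-probability
convention is the one used by common MK implementations. Probabilities are
computed in log-space (`lchoose`) and compared with a relative tolerance of
1e-7 so floating-point noise cannot exclude exact ties. Degenerate margins
(an empty row or column) give p = 1 by convention. The implementation is
checked against full enumeration for every table with margins up to 12 and
against `stats::fisher.test` on random tables.

## GO overrepresentation

For a test set against a reference set (disjoint; the combined set is the
background), each term present in the test set is scored with the one-tailed
(upper) hypergeometric probability of its 2×2 table; a sequence annotated
with a term more than once counts once. Raw p-values are adjusted with
Benjamini-Hochberg (the FDR procedure is a convention choice; BH is the
standard in annotation tools) and called significant at adjusted p ≤ 0.05.
Significant term sets can be reduced to their most-specific members by
removing any term that is a transitive ancestor of another significant term
under a child→parent table (cycles are an error). Pairwise tissue
comparisons run each tissue against every other tissue separately and
report the intersection of its significant sets.

## The synthetic-data generator

The generator emulates the statistical structure the scan assumes: a set of
ancestral ORFs; two descendant populations separated by fixed differences;
within-population polymorphism; an outgroup carrying independent divergence;
and variant records with quality/coverage/occurrence noise. It does **not**
simulate reads, assembly error, expression levels, mapping artifacts, or a
real GO graph (only a small flat parent chain) — so green tests demonstrate
the correctness of the statistical pipeline on clean, correctly assembled
input, not robustness to assembly or mapping failure.

Key design points:

* **Planted omega is the estimator's expectation by construction.** Each
  fixed difference first draws its class, nonsynonymous with probability
  `omega·N/(omega·N + S)` computed from the ancestor's own NG86 site counts,
  then draws a concrete change of that class (transition bias `kappa`) among
  changes that create no in-frame stop; a change that would create a stop in
  the current codon context is resampled. This makes the planted `omega`
  exactly the quantity the NG86 estimator estimates, so parameter-recovery
  tests measure estimator noise, not a generator/estimator convention gap.
* **Truth labels are translation-verified at planting time.** Every planted
  variant records its class from the before/after translation of the full
  affected codon in the carrying sequence; an independent re-translation in
  the tests, and agreement with the package's classifier, form a
  cross-implementation oracle.
* **The start codon is never mutated** (a broken ATG would silently change
  the ORF downstream), and polymorphisms are planted in distinct codons per
  population so each truth label corresponds to exactly the single-base
  substitution the classifier sees.
* **Contigs embed ORFs in ATG-free untranslated flanks**, so the first ATG
  of a contig, in any frame, is the planted start and ORF prediction can be
  validated exactly.
* **Noise records** are appended so that the configured fractions of *all*
  records are indels, low-quality (Q < 20), high-coverage (> 200), or
  occurrence-1 records; the manifest records every count, making filter
  bookkeeping exactly checkable.
* **Determinism.** One master seed; each gene draws from its own stream
  derived by a stable FNV-1a hash of (seed, gene id). Identical
  configuration and seed give byte-identical bundles.

Default parameters, chosen once as a realistic operating point: ORF lengths
51–200 codons (the minimum is forced by the >150 nt rule); `omega = 0.2`
(genome-wide purifying selection; scans plant contrasting values
explicitly); 4 expected fixed differences per gene (enough that a typical
gene clears the 3-difference filter); 2 polymorphisms per gene per
population, which pooled over two populations approximates the low
per-contig SNP counts typical of pooled 454 transcriptomes (mean ≈ 4,
median ≈ 2); outgroup expectations Dn = 5, Ds = 10 (synonymous excess, as
expected under purifying selection against a congeneric outgroup);
`kappa = 2`, a typical mammalian transition bias; passing records drawn with
Q ∈ [20, 60], depth ∈ [4, 200], occurrence ∈ [2, 10] — the filter thresholds
bound these ranges, with the depth floor near the median coverage of a
low-coverage pooled assembly.

## Validation strategy and problem sizes

The suite validates each statistical primitive against an oracle that shares
no code with the implementation (a hard-coded genetic code string,
`choose()`-based enumeration, brute-force path enumeration), then validates
the composed pipeline against the generator's truth tables. The headline
checks, with the problem sizes the package uses for them:

* NG86 site counts: all 64 codons against enumeration; difference counts:
  1,000 random codon pairs against the path oracle.
* Classifier: all 549 single-base changes of the 61 sense codons.
* Fisher's exact test: every 2×2 table with margins ≤ 12 against full
  enumeration (tolerance 1e-9), plus `stats::fisher.test` cross-checks.
* Parameter recovery: 500 genes of 300 codons with 30 fixed differences per
  planted omega in {0.5, 1, 2}; the median estimated ratio must fall within
  15% of the planted value, with category calls separating the regimes.
  Recovery runs at `kappa = 1`, the estimator's own operating point, since
  the NG86 proportion estimator makes no transition-bias correction; the
  class-first planting scheme keeps the class mix independent of kappa, and
  a kappa = 2 stress gives the same recovery.
* Null calibration: 2,000 neutral MK replicates (rejection rate ≤ 0.05 at
  alpha = 0.05; Fisher is conservative) and a 1,000-term null enrichment
  (FDR-significant proportion ≤ 0.05).
* Printed-table reproduction: the neutrality indices of the nine internally
  consistent candidate-gene MK count tables, at 2-decimal rounding, plus a
  divergence ratio. Two further published rows are arithmetically
  inconsistent with NI = (Pn/Ps)/(Dn/Ds) as printed; the implementation
  follows the stated formula and does not attempt to reverse-engineer them.

## Known limitations

* The pN/pS estimator applies no multiple-hit correction and is therefore
  only appropriate at small distances; it will underestimate divergence on
  saturated alignments.
* ORF pairs are matched by identifier and must be equal-length; genes with
  indels between populations are reported and skipped, not gap-aligned.
* The MK machinery is the unpolarized classic form: no outgroup
  polarization, no estimate of the adaptive fraction.
* The enrichment module consumes a flat child→parent term table; it does
  not parse a full ontology.
* Whether the "at least three SNPs" inclusion rule counts pooled
  within-population SNPs or per-pair fixed differences is ambiguous in the
  underlying protocol; the scan counts differences per population pair,
  since that is the unit on which the statistic is computed.

```{r example}
cfg <- sim_config(n_genes = 20, omega = c(rep(0.2, 16), rep(2.5, 4)),
                  target_subs_per_gene = 8, seed = 7)
bundle <- file.path(tempdir(), "bundle")
out <- file.path(tempdir(), "out")
emit_pipeline_inputs(cfg, bundle)
res <- run_pipeline(bundle, out)
summarize_scan(res$scores)
subset(res$scores, category == "strong",
       select = c(gene_id, n_diffs, Nd, Sd, ratio))
```
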