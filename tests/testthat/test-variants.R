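snp <- function(contig = "g1", pos = 4L, ref = "A", alt = "G", qual = 30,
                depth = 50L, occ = 3L) {
  data.frame(contig_id = contig, pos = pos, ref = ref, alt = alt,
             qual = qual, depth = depth, occurrence = occ,
             stringsAsFactors = FALSE)
}

test_that("SNP filter thresholds are inclusive exactly as stated", {
  # Q = 20, occurrence = 2, depth = 200: all boundaries pass
  f <- filter_snps(snp(qual = 20, occ = 2L, depth = 200L))
  expect_equal(nrow(f$kept), 1)

  expect_equal(filter_snps(snp(qual = 19.9))$rejected$reason, "low_quality")
  expect_equal(filter_snps(snp(occ = 1L))$rejected$reason, "low_occurrence")
  expect_equal(filter_snps(snp(depth = 201L))$rejected$reason,
               "high_coverage")
  expect_equal(filter_snps(snp(ref = "AT", alt = "A"))$rejected$reason,
               "indel")
  expect_equal(filter_snps(snp(ref = "A", alt = "AT"))$rejected$reason,
               "indel")
})

test_that("filtering is order-independent, idempotent, and conserves counts", {
  set.seed(5)
  n <- 200
  snps <- data.frame(
    contig_id = "g1", pos = seq_len(n),
    ref = sample(c("A", "C", "G", "T", "AT"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    qual = runif(n, 0, 60), depth = sample(1:400, n, replace = TRUE),
    occurrence = sample(0:5, n, replace = TRUE), stringsAsFactors = FALSE)
  snps <- snps[snps$ref != snps$alt, ]
  f <- filter_snps(snps)
  expect_equal(nrow(f$kept) + nrow(f$rejected), nrow(snps))
  expect_equal(nrow(f$kept) + sum(f$log), nrow(snps))
  # idempotent
  f2 <- filter_snps(f$kept)
  expect_equal(f2$kept, f$kept)
  # order-independent
  perm <- sample(nrow(snps))
  f3 <- filter_snps(snps[perm, ])
  expect_equal(nrow(f3$kept), nrow(f$kept))
  expect_setequal(paste(f3$kept$contig_id, f3$kept$pos),
                  paste(f$kept$contig_id, f$kept$pos))
})

test_that("SNPs are located in codon coordinates, with strand mapping", {
  contig <- paste0("ATG", "GAA", "TTT", strrep("GGA", 48), "TAA")
  orf <- data.frame(contig_id = "g1", start = 0L, end = 153L, strand = "+",
                    frame = 0L, length_nt = 153L, stringsAsFactors = FALSE)
  loc <- locate_in_orf(snp(pos = 4L, ref = "A", alt = "T"), orf, contig)
  expect_equal(loc$codon_index, 1)
  expect_equal(loc$codon_pos, 1)
  expect_equal(loc$ref_codon, "GAA")
  expect_equal(loc$alt_codon, "GTA")

  # position at the exclusive end is outside
  expect_null(locate_in_orf(snp(pos = 153L, ref = "T", alt = "C"), orf,
                            contig))
  # reference mismatch is flagged
  loc <- locate_in_orf(snp(pos = 4L, ref = "C", alt = "T"), orf, contig)
  expect_equal(loc$status, "ref_mismatch")

  # minus strand: alleles complemented, position mapped through revcomp
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  # the 156 nt contig maps the ORF interval [0, 153) to [3, 156) on rc
  orf_m <- data.frame(contig_id = "g1", start = 3L, end = 156L,
                      strand = "-", frame = 0L, length_nt = 153L,
                      stringsAsFactors = FALSE)
  # contig pos 4 (A in GAA) sits at rc position 156 - 1 - 4 = 151
  loc <- locate_in_orf(snp(pos = 151L, ref = "T", alt = "A"), orf_m, rc)
  expect_equal(loc$codon_index, 1)
  expect_equal(loc$codon_pos, 1)
  expect_equal(loc$ref_codon, "GAA")
  expect_equal(loc$alt_codon, "GTA")
})

test_that("codon changes are classified by translation", {
  expect_equal(classify_codon_change("GAA", "GAG"), "synonymous")
  expect_equal(classify_codon_change("GAA", "GTA"), "nonsynonymous")
  expect_equal(classify_codon_change("TAC", "TAA"), "nonsynonymous")
  expect_true(is.na(classify_codon_change("GAN", "GTN")))
})

test_that("classification splits SNPs into classified and unclassified with reasons", {
  contig <- paste0("CC", "ATG", "GAA", strrep("GGA", 49), "TAA", "GG")
  contigs <- c(g1 = contig, g2 = "ACGTACGTACGT")
  orfs <- data.frame(contig_id = "g1", start = 2L, end = 158L, strand = "+",
                     frame = 2L, length_nt = 156L, stringsAsFactors = FALSE)
  snps <- rbind(
    snp("g1", 7L, "A", "G"),    # GAA -> GAG, synonymous
    snp("g1", 6L, "A", "T"),    # GAA -> GTA, nonsynonymous
    snp("g1", 0L, "C", "T"),    # upstream of the ORF
    snp("g1", 7L, "T", "G"),    # reference mismatch
    snp("g2", 3L, "T", "C"))    # contig without ORF
  cl <- classify_snps(snps, orfs, contigs)
  expect_equal(nrow(cl$classified), 2)
  expect_equal(cl$classified$effect, c("synonymous", "nonsynonymous"))
  expect_equal(cl$classified$codon_index, c(1L, 1L))
  expect_setequal(cl$unclassified$reason,
                  c("outside_orf", "ref_mismatch", "no_orf"))
  expect_equal(nrow(cl$classified) + nrow(cl$unclassified), nrow(snps))
})
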