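test_that("assembly statistics match hand-computed and degenerate cases", {
  one <- assembly_stats(500)
  expect_equal(one$n50, 500)
  expect_equal(one$median_length, 500)
  expect_equal(one$total_length, 500)

  st <- assembly_stats(c(2, 3, 4, 5, 6))
  expect_equal(st$total_length, 20)
  expect_equal(st$n50, 5)  # cumulative 6, 11 >= 10 at length 5

  flat <- assembly_stats(c(10, 10, 10, 10))
  expect_equal(flat$n50, 10)
  expect_equal(flat$mean_length, 10)
  expect_equal(flat$iqr, 0)
})

test_that("N50 equals the brute-force oracle on random length sets", {
  set.seed(101)
  for (rep in 1:50) {
    lens <- sample(50:5000, sample(3:200, 1), replace = TRUE)
    expect_equal(assembly_stats(lens)$n50, oracle_n50(lens))
  }
})

hit <- function(q = "q1", s = "s1", id = 90, aln = 60, qlen = 100,
                slen = 200, e = 1e-10, m = 55, mm = 5) {
  data.frame(query_id = q, subject_id = s, pct_identity = id,
             aln_length = aln, query_length = qlen, subject_length = slen,
             evalue = e, matches = m, mismatches = mm,
             stringsAsFactors = FALSE)
}

test_that("hit significance filter applies the three rules with the stated strictness", {
  expect_equal(nrow(filter_significant_hits(hit())), 1)  # 60 >= 50% of query
  # identity exactly 80 fails (strict)
  expect_equal(nrow(filter_significant_hits(hit(id = 80))), 0)
  # alignment shorter than half of both fails
  expect_equal(nrow(filter_significant_hits(hit(id = 95, aln = 40,
                                                slen = 100))), 0)
  # e-value exactly 1e-5 fails (strict)
  expect_equal(nrow(filter_significant_hits(hit(e = 1e-5))), 0)
  # half of the subject qualifies even when the query does not
  expect_equal(nrow(filter_significant_hits(hit(aln = 55, qlen = 200,
                                                slen = 110))), 1)
  expect_equal(nrow(filter_significant_hits(hit()[0, ])), 0)
})

test_that("one-to-one gene candidates require unique matching on both sides", {
  h <- rbind(hit("q1", "s1"), hit("q2", "s1"))
  expect_equal(nrow(select_gene_candidates(h)), 0)  # s1 matched twice

  h <- rbind(hit("q1", "s1"), hit("q2", "s2"))
  expect_equal(nrow(select_gene_candidates(h)), 2)

  # duplicate rows collapse before counting
  h <- rbind(hit("q1", "s1"), hit("q1", "s1"))
  cand <- select_gene_candidates(h)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$query_id, "q1")

  # filtering then selecting is idempotent
  f <- filter_significant_hits(h)
  expect_identical(select_gene_candidates(f),
                   select_gene_candidates(filter_significant_hits(f)))
})

test_that("best hit maximizes match - mismatch with identity and subject-id tie-breaks", {
  h <- rbind(hit("q1", "sA", m = 95, mm = 5),    # score 90
             hit("q1", "sB", m = 90, mm = 10))   # score 80
  expect_equal(best_hit(h)$subject_id, "sA")

  h <- rbind(hit("q1", "sA", id = 90, m = 50, mm = 10),
             hit("q1", "sB", id = 95, m = 50, mm = 10))
  expect_equal(best_hit(h)$subject_id, "sB")  # equal score, higher identity

  h <- rbind(hit("q1", "chr2", id = 90, m = 50, mm = 10),
             hit("q1", "chr10", id = 90, m = 50, mm = 10))
  expect_equal(best_hit(h)$subject_id, "chr10")  # lexicographic

  h <- rbind(hit("q1", "sA", m = 95, mm = 5), hit("q2", "sB", m = 10, mm = 0))
  expect_equal(nrow(best_hit(h)), 2)
})

test_that("ORF prediction follows the first-ATG, >150 nt rule", {
  body50 <- strrep("GGA", 50)
  orf <- predict_orf("c1", paste0("ATG", body50, "TAA"))
  expect_equal(orf$start, 0)
  expect_equal(orf$end, 153)
  expect_equal(orf$length_nt, 153)
  expect_equal(orf$strand, "+")

  # 48 codons + ATG = 147 nt: not greater than 150
  expect_null(predict_orf("c1", paste0("ATG", strrep("GGA", 48), "TAA")))

  # no ATG in the requested frame
  expect_null(predict_orf("c1", paste0("CCC", strrep("GGA", 60)),
                          strand = "+", frame = 0))

  # truncated ORF: no stop reached, trimmed to codon multiple
  orf <- predict_orf("c1", paste0("ATG", body50, "GG"))
  expect_equal(orf$length_nt, 153)

  # minus strand: ORF found on the reverse complement, coordinates mapped
  fwd <- paste0("ATG", body50, "TAA")
  contig <- paste0("CC", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd))), "AGCT")
  orf <- predict_orf("c1", contig)
  expect_equal(orf$strand, "-")
  expect_equal(orf$end - orf$start, 153)
  expect_equal(orf_sequence(orf, contig), substr(fwd, 1, 153))
})

test_that("predicted ORFs always satisfy the ORF invariants", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  n_found <- 0
  for (rep in 1:200) {
    contig <- paste(sample(bases, sample(100:600, 1), replace = TRUE),
                    collapse = "")
    orf <- predict_orf("x", contig)
    if (is.null(orf)) next
    n_found <- n_found + 1
    expect_gt(orf$length_nt, 150)
    expect_equal(orf$length_nt %% 3, 0)
    expect_equal(orf$end - orf$start, orf$length_nt)
    cds <- orf_sequence(orf, contig)
    expect_equal(substr(cds, 1, 3), "ATG")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  expect_gt(n_found, 10)  # the property must actually be exercised
})

test_that("GFF3 output is 1-based inclusive and round-trips", {
  orfs <- data.frame(
    contig_id = c("c1", "c2"), start = c(0L, 7L), end = c(153L, 307L),
    strand = c("+", "-"), frame = c(0L, 1L), length_nt = c(153L, 300L),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff(orfs, path)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  f1 <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(f1[4]), 1)    # start 0 -> 1
  expect_equal(as.integer(f1[5]), 153)
  expect_equal(f1[3], "CDS")
  expect_equal(f1[8], "0")              # complete CDS: phase 0
  back <- read_gff(path)
  expect_equal(back[order(back$contig_id), names(orfs)],
               orfs[order(orfs$contig_id), ], ignore_attr = TRUE)
})
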