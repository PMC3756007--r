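test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(orf_length_codons = c(100, 60)), "max < min")
  expect_error(sim_config(orf_length_codons = c(40, 60)), "51")
  expect_error(sim_config(omega = 0), "omega")
  expect_error(sim_config(noise = c(indel = 1.2)), "noise")
})

test_that("ancestral gene sets satisfy the ORF invariants deterministically", {
  expect_length(make_gene_set(sim_config(n_genes = 0)), 0)
  cfg <- sim_config(n_genes = 100, orf_length_codons = c(51, 100), seed = 1)
  genes <- make_gene_set(cfg)
  expect_length(genes, 100)
  for (g in genes) {
    expect_equal(substr(g, 1, 3), "ATG")
    expect_equal(nchar(g) %% 3, 0)
    expect_true(nchar(g) >= 153 && nchar(g) <= 300)
    codons <- substring(g, seq(1, nchar(g), 3), seq(3, nchar(g), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  expect_identical(genes, make_gene_set(cfg))
})

test_that("population pairs carry exactly the planted fixed differences", {
  anc <- random_orf(80, 3)
  id0 <- mutate_population_pair(anc, omega = 1, n_subs = 0, seed = 5)
  expect_identical(id0$seq_a, anc)
  expect_identical(id0$seq_b, anc)
  expect_equal(nrow(id0$truth), 0)

  mp <- mutate_population_pair(anc, omega = 0.5, n_subs = 12, seed = 5)
  diff_sites <- which(strsplit(mp$seq_a, "")[[1]] !=
                        strsplit(mp$seq_b, "")[[1]])
  expect_equal(sort(mp$truth$pos + 1), diff_sites)
  expect_equal(nrow(mp$truth), 12)
  expect_error(mutate_population_pair(anc, omega = -1, n_subs = 2),
               "omega")
  expect_error(mutate_population_pair("ATGTAA", 1, 1), "valid ORF")
})

test_that("every planted variant class is reproduced by independent translation", {
  # generator labels at planting time; the oracle re-translates the affected
  # codon in the carrying sequence before and after the change
  for (seed in 1:5) {
    anc <- random_orf(70, seed + 40)
    mp <- mutate_population_pair(anc, omega = 1, n_subs = 15, seed = seed)
    og <- make_outgroup(anc, 5, 5, seed = seed)
    seqs <- list(A = mp$seq_a, B = mp$seq_b, outgroup = og$seq)
    truth <- rbind(mp$truth, og$truth)
    for (i in seq_len(nrow(truth))) {
      v <- truth[i, ]
      carrier <- seqs[[v$population]]
      ci <- v$pos %/% 3
      after <- substr(carrier, ci * 3 + 1, ci * 3 + 3)
      before <- after
      substr(before, v$pos %% 3 + 1, v$pos %% 3 + 1) <- v$ref
      want <- if (oracle_translate(before) == oracle_translate(after))
        "synonymous" else "nonsynonymous"
      expect_equal(v$class, want)
    }
  }
})

test_that("planted class mix matches the NG86-weighted expectation at omega = 1", {
  # with omega = 1 and kappa = 1 the generator draws each change's class
  # with probability N/(N+S) from its own site counts; check the realized
  # nonsynonymous fraction against that binomial expectation
  set.seed(60)
  n_per_gene <- 25
  n_genes <- 40
  total <- n_nonsyn <- 0
  exp_p <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    anc <- random_orf(120, 60 + i)
    sites <- ng86_site_counts(anc)
    exp_p[i] <- sites[["N_sites"]] / sum(sites)
    mp <- mutate_population_pair(anc, omega = 1, n_subs = n_per_gene,
                                 kappa = 1, seed = 600 + i)
    n_nonsyn <- n_nonsyn + sum(mp$truth$class == "nonsynonymous")
    total <- total + nrow(mp$truth)
  }
  p <- mean(exp_p)
  se <- sqrt(p * (1 - p) / total)
  expect_lt(abs(n_nonsyn / total - p), 3 * se)
})

test_that("outgroup divergence realizes the configured expectations", {
  anc <- random_orf(100, 9)
  same <- make_outgroup(anc, 0, 0, seed = 2)
  expect_identical(same$seq, anc)
  expect_equal(nrow(same$truth), 0)

  # Poisson means (5, 5) over 200 genes: realized means within 3 SE
  dn <- ds <- numeric(200)
  for (i in 1:200) {
    anc_i <- random_orf(80, 900 + i)
    og <- make_outgroup(anc_i, 5, 5, seed = 900 + i)
    dn[i] <- sum(og$truth$class == "nonsynonymous")
    ds[i] <- sum(og$truth$class == "synonymous")
  }
  se <- sqrt(5 / 200)
  expect_lt(abs(mean(dn) - 5), 3 * se)
  expect_lt(abs(mean(ds) - 5), 3 * se)
})

test_that("bundles are byte-identical for identical config and seed", {
  cfg <- sim_config(n_genes = 8, noise = c(indel = 0.1, low_qual = 0.1),
                    seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_pipeline_inputs(cfg, d1)
  emit_pipeline_inputs(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("bundle truth tables agree with the emitted files (composition)", {
  cfg <- sim_config(n_genes = 10, noise = c(indel = 0.2, low_occ = 0.1),
                    seed = 17)
  d <- withr::local_tempdir()
  b <- emit_pipeline_inputs(cfg, d)

  # FASTA round-trips and contains every gene
  pa <- read_fasta(file.path(d, "popA.fasta"))
  pb <- read_fasta(file.path(d, "popB.fasta"))
  expect_setequal(names(pa), sprintf("gene%04d", 1:10))

  # fixed differences in the truth table equal the sequence differences
  truth <- read_tsv(file.path(d, "truth_variants.tsv"))
  genes <- read_tsv(file.path(d, "truth_genes.tsv"))
  for (g in genes$gene_id) {
    fixed <- truth[truth$gene_id == g &
                     truth$stratum == "fixed_between_pops", ]
    diffs <- which(strsplit(pa[[g]], "")[[1]] != strsplit(pb[[g]], "")[[1]])
    expect_setequal(fixed$contig_pos, diffs)
    expect_equal(nrow(fixed), genes$n_fixed[genes$gene_id == g])
  }

  # VCF record counts equal the manifest bookkeeping
  for (p in c("A", "B")) {
    vt <- read_tsv(file.path(d, paste0("vcf_truth_pop", p, ".tsv")))
    vcf <- read_vcf(file.path(d, paste0("pop", p, ".vcf")))
    expect_equal(nrow(vcf), nrow(vt))
    expect_equal(sum(vt$expected == "pass"),
                 b$manifest$clean_records[[p]])
    expect_equal(sum(vt$expected == "indel"),
                 b$manifest$noise_records[[p]]$indel)
  }

  # ORF GFF matches the gene table
  orfs <- read_gff(file.path(d, "orfs.gff3"))
  expect_equal(nrow(orfs), 10)
  m <- merge(orfs, genes, by.x = "contig_id", by.y = "gene_id")
  expect_equal(m$start, m$orf_start)
  expect_equal(m$end, m$orf_end)
})

test_that("noise-free bundles pass the downstream filter in full", {
  cfg <- sim_config(n_genes = 6, seed = 3)
  d <- withr::local_tempdir()
  emit_pipeline_inputs(cfg, d)
  for (p in c("A", "B")) {
    snps <- read_vcf(file.path(d, paste0("pop", p, ".vcf")))
    f <- filter_snps(snps)
    expect_equal(nrow(f$rejected), 0)
    expect_equal(nrow(f$kept), nrow(snps))
  }
})
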