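# Synthetic population-pair transcriptomes with planted structure: ancestral
# ORFs, fixed differences between two isolated populations, within-population
# polymorphisms, outgroup divergence, GO annotations, and variant records
# carrying controlled fractions of filter-failing noise. Every planted change
# is recorded in a truth table labelled by before/after codon translation, so
# the downstream classifier can be validated against an independent labelling.

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
VARIANT_STRATA <- c("polymorphism_popA", "polymorphism_popB",
                    "fixed_between_pops", "fixed_between_species")

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generator. The
#' defaults describe a pooled-transcriptome study of two reproducibly
#' isolated populations: mostly purifying selection (omega 0.2), a handful
#' of fixed differences and roughly two segregating polymorphisms per gene
#' per population, moderate outgroup divergence with a synonymous excess,
#' and a 2:1 transition bias.
#'
#' @param n_genes number of genes to simulate.
#' @param orf_length_codons integer (min, max) ORF length in codons; the
#'   minimum must be at least 51 so every gene passes the >150 nt ORF rule.
#' @param omega nonsynonymous/synonymous rate ratio used to weight planted
#'   changes (single value, or one per gene).
#' @param target_subs_per_gene expected fixed differences between the two
#'   populations per gene (Poisson mean).
#' @param poly_rate expected within-population polymorphisms per gene per
#'   population (Poisson mean).
#' @param outgroup_dn,outgroup_ds expected nonsynonymous / synonymous fixed
#'   differences against the outgroup per gene (Poisson means).
#' @param kappa transition/transversion rate ratio; the probability that a
#'   planted change is a transition is kappa/(kappa + 2) when rates are
#'   otherwise equal.
#' @param noise named fractions of injected variant records that must fail
#'   the post-call filters: \code{indel}, \code{low_qual} (Q < 20),
#'   \code{high_cov} (depth > 200), \code{low_occ} (occurrence 1).
#' @param qual_range,cov_range,occ_range ranges for the phred quality, read
#'   depth and alternate-allele occurrence of passing records.
#' @param utr_length_range range (nt) of the untranslated flanks added
#'   around each ORF when contigs are emitted.
#' @param n_go_terms,go_terms_per_gene GO-annotation pool size and per-gene
#'   term count range.
#' @param seed master seed; per-gene streams are derived by stable hashing
#'   of (seed, gene id), so outputs are byte-identical for equal configs.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 100,
                       orf_length_codons = c(51, 200),
                       omega = 0.2,
                       target_subs_per_gene = 4,
                       poly_rate = 2,
                       outgroup_dn = 5,
                       outgroup_ds = 10,
                       kappa = 2,
                       noise = c(indel = 0, low_qual = 0, high_cov = 0,
                                 low_occ = 0),
                       qual_range = c(20, 60),
                       cov_range = c(4, 200),
                       occ_range = c(2, 10),
                       utr_length_range = c(10, 60),
                       n_go_terms = 50,
                       go_terms_per_gene = c(1, 4),
                       seed = 1) {
  stopifnot(n_genes >= 0, length(orf_length_codons) == 2)
  if (orf_length_codons[2] < orf_length_codons[1]) {
    stop("sim_config: impossible ORF length range (max < min)")
  }
  if (orf_length_codons[1] < 51) {
    stop("sim_config: minimum ORF length must be >= 51 codons (> 150 nt)")
  }
  if (any(omega <= 0)) stop("sim_config: omega must be positive")
  if (!(length(omega) %in% c(1L, n_genes))) {
    stop("sim_config: omega must have length 1 or n_genes")
  }
  stopifnot(target_subs_per_gene >= 0, poly_rate >= 0, outgroup_dn >= 0,
            outgroup_ds >= 0, kappa > 0)
  full_noise <- c(indel = 0, low_qual = 0, high_cov = 0, low_occ = 0)
  full_noise[names(noise)] <- noise
  if (any(full_noise < 0 | full_noise > 1)) {
    stop("sim_config: noise fractions must lie in [0, 1]")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    orf_length_codons = as.integer(orf_length_codons),
    omega = omega, target_subs_per_gene = target_subs_per_gene,
    poly_rate = poly_rate, outgroup_dn = outgroup_dn,
    outgroup_ds = outgroup_ds, kappa = kappa, noise = full_noise,
    qual_range = qual_range, cov_range = cov_range, occ_range = occ_range,
    utr_length_range = as.integer(utr_length_range),
    n_go_terms = as.integer(n_go_terms),
    go_terms_per_gene = as.integer(go_terms_per_gene),
    seed = as.integer(seed)
  ), class = "sim_config")
}

.gene_ids <- function(n) sprintf("gene%04d", seq_len(n))

#' Generate a set of ancestral ORF sequences
#'
#' Each gene starts with ATG followed by uniformly sampled sense codons
#' (so there is never an internal in-frame stop), with a codon count drawn
#' uniformly from the configured range. Each gene uses its own RNG stream
#' derived from the master seed, so the set is reproducible gene by gene.
#'
#' @param config a \code{sim_config}.
#' @return named character vector of ORF sequences.
#' @export
make_gene_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- .gene_ids(config$n_genes)
  out <- stats::setNames(character(config$n_genes), ids)
  for (i in seq_len(config$n_genes)) {
    set.seed(derive_seed(config$seed, paste0(ids[i], ":ancestor")))
    n_codons <- sample(config$orf_length_codons[1]:config$orf_length_codons[2],
                       1L)
    body <- sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)
    out[ids[i]] <- paste0("ATG", paste(body, collapse = ""))
  }
  out
}

# Draw and apply `n` single-base changes to `seq`, one per site, using the
# ancestral change table for weights: w = kappa^transition * omega^nonsyn.
# Changes creating an in-frame stop (in the current codon context) are
# resampled; when `class_filter` is given, only changes whose in-context
# effect matches are accepted. Returns list(seq=, truth=data.frame).
.plant_changes <- function(seq, n, omega, kappa, class_filter = NULL,
                           used_sites = integer(0), allow_stop = FALSE,
                           protect_start = TRUE) {
  truth <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(list(seq = seq, truth = truth, used_sites = used_sites))
  tbl <- gene_change_table(seq)
  if (protect_start) tbl <- tbl[tbl$codon_index > 0L, , drop = FALSE]
  if (!allow_stop) tbl <- tbl[!tbl$to_stop, , drop = FALSE]
  if (!is.null(class_filter)) tbl <- tbl[tbl$effect == class_filter, ,
                                         drop = FALSE]
  w <- ifelse(tbl$transition, kappa, 1) * ifelse(
    tbl$effect == "nonsynonymous", omega, 1)
  avail <- !(tbl$site %in% used_sites)
  placed <- 0L
  attempts <- 0L
  rows <- list()
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n + 200L) {
      stop("plant_changes: could not place ", n, " changes")
    }
    if (!any(avail)) stop("plant_changes: ran out of candidate sites")
    j <- sample(which(avail), 1L, prob = w[avail])
    site <- tbl$site[j]
    ci <- tbl$codon_index[j]
    cur_codon <- substr(seq, ci * 3L + 1L, ci * 3L + 3L)
    new_codon <- substitute_base(cur_codon, tbl$pos[j], tbl$alt[j])
    if (cur_codon == new_codon) {           # context already carries alt
      avail[j] <- FALSE
      next
    }
    if (!allow_stop && new_codon %in% STOP_CODONS) {
      avail[j] <- FALSE
      next
    }
    eff <- if (translate_codon(cur_codon) == translate_codon(new_codon))
      "synonymous" else "nonsynonymous"
    if (!is.null(class_filter) && eff != class_filter) {
      avail[j] <- FALSE
      next
    }
    ref_base <- substr(cur_codon, tbl$pos[j], tbl$pos[j])
    seq <- substitute_base(seq, site + 1L, tbl$alt[j])
    rows[[length(rows) + 1L]] <- data.frame(
      pos = site, ref = ref_base, alt = tbl$alt[j], class = eff,
      stringsAsFactors = FALSE)
    used_sites <- c(used_sites, site)
    avail[tbl$site == site] <- FALSE
    placed <- placed + 1L
  }
  truth <- do.call(rbind, rows)
  list(seq = seq, truth = truth, used_sites = used_sites)
}

#' Plant fixed differences between two isolated populations
#'
#' Starting from one ancestral ORF, places \code{n_subs} substitutions, each
#' at a distinct site and assigned to one of the two descendant populations
#' at random, so the populations carry \code{n_subs} fixed differences.
#' Each substitution first draws its class with probability
#' omega * N_sites / (omega * N_sites + S_sites) of being nonsynonymous
#' (Nei-Gojobori site counts of the ancestor, so the planted omega is, by
#' construction, the expectation of the pN/pS estimator), then draws a
#' change of that class with transition bias kappa among all single-base
#' changes that do not create an in-frame stop codon; changes that would
#' create a stop in the current codon context are resampled. The start
#' codon is never mutated. Every change is recorded with its class obtained
#' by translating the affected codon before and after the change.
#'
#' @param ancestor ancestral ORF sequence (ATG-initiated, stop-free).
#' @param omega nonsynonymous/synonymous rate ratio (> 0).
#' @param n_subs number of fixed differences to plant.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed for this gene's stream.
#' @return list with \code{seq_a}, \code{seq_b} and \code{truth} (data.frame:
#'   pos (0-based within the ORF), ref, alt, class, stratum, population).
#' @export
mutate_population_pair <- function(ancestor, omega, n_subs, kappa = 2,
                                   seed = 1) {
  if (omega <= 0) stop("mutate_population_pair: omega must be positive")
  if (!is_valid_orf(ancestor)) {
    stop("mutate_population_pair: ancestor is not a valid ORF")
  }
  set.seed(seed)
  empty <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), class = character(0),
                      stratum = character(0), population = character(0),
                      stringsAsFactors = FALSE)
  if (n_subs == 0) {
    return(list(seq_a = ancestor, seq_b = ancestor, truth = empty))
  }
  # Candidate changes are enumerated once on the ancestor; each placement is
  # re-checked in the codon context of the receiving population (a change
  # that would create a stop there is resampled) and its class recorded from
  # the actual before/after codons.
  tbl <- gene_change_table(ancestor)
  tbl <- tbl[tbl$codon_index > 0L & !tbl$to_stop, , drop = FALSE]
  w <- ifelse(tbl$transition, kappa, 1)
  sites <- ng86_site_counts(ancestor)
  p_nonsyn <- omega * sites[["N_sites"]] /
    (omega * sites[["N_sites"]] + sites[["S_sites"]])
  avail <- rep(TRUE, nrow(tbl))
  seqs <- list(A = ancestor, B = ancestor)
  placed <- 0L
  attempts <- 0L
  rows <- list()
  while (placed < n_subs) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_subs + 200L) {
      stop("mutate_population_pair: could not place ", n_subs, " changes")
    }
    if (!any(avail)) {
      stop("mutate_population_pair: ran out of candidate sites")
    }
    cls <- if (stats::runif(1L) < p_nonsyn) "nonsynonymous" else "synonymous"
    in_class <- avail & tbl$effect == cls
    if (!any(in_class)) next
    j <- if (sum(in_class) == 1L) which(in_class) else
      sample(which(in_class), 1L, prob = w[in_class])
    pop <- sample(c("A", "B"), 1L)
    site <- tbl$site[j]
    ci <- tbl$codon_index[j]
    cur_codon <- substr(seqs[[pop]], ci * 3L + 1L, ci * 3L + 3L)
    new_codon <- substitute_base(cur_codon, tbl$pos[j], tbl$alt[j])
    if (cur_codon == new_codon || new_codon %in% STOP_CODONS) {
      avail[j] <- FALSE
      next
    }
    eff <- if (translate_codon(cur_codon) == translate_codon(new_codon))
      "synonymous" else "nonsynonymous"
    ref_base <- substr(cur_codon, tbl$pos[j], tbl$pos[j])
    seqs[[pop]] <- substitute_base(seqs[[pop]], site + 1L, tbl$alt[j])
    placed <- placed + 1L
    rows[[placed]] <- data.frame(
      pos = site, ref = ref_base, alt = tbl$alt[j], class = eff,
      stratum = "fixed_between_pops", population = pop,
      stringsAsFactors = FALSE)
    avail[tbl$site == site] <- FALSE
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(seq_a = seqs$A, seq_b = seqs$B, truth = truth)
}

#' Generate an outgroup ortholog with planted divergence
#'
#' Draws nonsynonymous and synonymous fixed-difference counts independently
#' from Poisson distributions at the configured expectations and plants them
#' on the ancestor, each at a distinct site, with transition bias kappa.
#' Classes are enforced in codon context: a change is only accepted if its
#' in-context effect matches the intended class and it creates no stop.
#'
#' @param ancestor ancestral ORF sequence.
#' @param outgroup_dn,outgroup_ds expected nonsynonymous / synonymous fixed
#'   differences (Poisson means).
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @return list with \code{seq} (the ortholog) and \code{truth} (data.frame
#'   as in \code{mutate_population_pair}, stratum
#'   \code{fixed_between_species}).
#' @export
make_outgroup <- function(ancestor, outgroup_dn, outgroup_ds, kappa = 2,
                          seed = 1) {
  if (!is_valid_orf(ancestor)) {
    stop("make_outgroup: ancestor is not a valid ORF")
  }
  stopifnot(outgroup_dn >= 0, outgroup_ds >= 0)
  set.seed(seed)
  n_dn <- stats::rpois(1L, outgroup_dn)
  n_ds <- stats::rpois(1L, outgroup_ds)
  res_n <- .plant_changes(ancestor, n_dn, omega = 1, kappa = kappa,
                          class_filter = "nonsynonymous")
  res_s <- .plant_changes(res_n$seq, n_ds, omega = 1, kappa = kappa,
                          class_filter = "synonymous",
                          used_sites = res_n$used_sites)
  truth <- rbind(res_n$truth, res_s$truth)
  if (nrow(truth) > 0L) {
    truth$stratum <- "fixed_between_species"
    truth$population <- "outgroup"
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), class = character(0),
                        stratum = character(0), population = character(0),
                        stringsAsFactors = FALSE)
  }
  list(seq = res_s$seq, truth = truth)
}

# A random UTR of the given length containing no ATG substring (so the
# first ATG of the contig, in any frame, is the planted start codon).
.make_utr <- function(len) {
  if (len == 0L) return("")
  repeat {
    utr <- paste(sample(BASES, len, replace = TRUE), collapse = "")
    if (!grepl("ATG", utr, fixed = TRUE)) return(utr)
  }
}

# Plant within-population polymorphisms on a population ORF. Polymorphisms
# are variant records, not edits: the contig keeps `seq`, so each change is
# drawn against the pristine population sequence and polymorphic codons are
# kept distinct (no context interaction between records). Stops are allowed
# (segregating nonsense variants are nonsynonymous on both sides of the
# oracle).
.plant_polymorphisms <- function(seq, n, kappa) {
  rows <- list()
  used <- integer(0)
  for (k in seq_len(n)) {
    res <- .plant_changes(seq, 1L, omega = 1, kappa = kappa,
                          used_sites = used, allow_stop = TRUE)
    codon0 <- (res$truth$pos %/% 3L) * 3L
    used <- c(used, codon0, codon0 + 1L, codon0 + 2L)
    rows[[k]] <- res$truth
  }
  if (length(rows) == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates ancestral genes, plants fixed differences between populations
#' A and B, within-population polymorphisms and outgroup divergence, then
#' writes everything the pipeline consumes: per-population contig FASTA
#' (ORFs embedded in ATG-free untranslated flanks), per-population VCFs of
#' polymorphism records plus the configured fractions of filter-failing
#' noise records (indels, low quality, excess coverage, single occurrence),
#' the ORF annotation GFF3, a codon-aligned outgroup FASTA, a GO annotation
#' table with a flat parent table, truth tables for every planted variant
#' and every VCF record, and a JSON manifest recording the configuration and
#' all bookkeeping counts. Identical config and seed give byte-identical
#' bundles.
#'
#' @param config a \code{sim_config}.
#' @param out_dir output directory (created; must be writable).
#' @return invisibly, a list with the bundle directory, the truth tables and
#'   the manifest.
#' @export
emit_pipeline_inputs <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("emit_pipeline_inputs: cannot create output directory ", out_dir)
  }
  if (sum(config$noise) >= 1) {
    stop("emit_pipeline_inputs: noise fractions must sum to < 1")
  }
  ancestors <- make_gene_set(config)
  ids <- names(ancestors)
  omega <- rep(config$omega, length.out = config$n_genes)
  go_pool <- sprintf("GO:%07d", seq_len(config$n_go_terms))

  contigs <- list(A = character(0), B = character(0))
  outgroup_seqs <- character(0)
  orf_rows <- list()
  truth_rows <- list()
  vcf_rows <- list(A = list(), B = list())
  gene_rows <- list()
  go_rows <- list()

  for (i in seq_along(ids)) {
    id <- ids[i]
    ancestor <- ancestors[[id]]

    set.seed(derive_seed(config$seed, paste0(id, ":nsubs")))
    n_subs <- stats::rpois(1L, config$target_subs_per_gene)
    pair <- mutate_population_pair(ancestor, omega[i], n_subs, config$kappa,
                                   seed = derive_seed(config$seed,
                                                      paste0(id, ":pair")))
    og <- make_outgroup(ancestor, config$outgroup_dn, config$outgroup_ds,
                        config$kappa,
                        seed = derive_seed(config$seed,
                                           paste0(id, ":outgroup")))

    set.seed(derive_seed(config$seed, paste0(id, ":emit")))
    utr5 <- .make_utr(sample(config$utr_length_range[1]:
                               config$utr_length_range[2], 1L))
    utr3 <- .make_utr(sample(config$utr_length_range[1]:
                               config$utr_length_range[2], 1L))
    stop_codon <- sample(STOP_CODONS, 1L)
    orf_start <- nchar(utr5)
    orf_len <- nchar(ancestor)
    contigs$A[id] <- paste0(utr5, pair$seq_a, stop_codon, utr3)
    contigs$B[id] <- paste0(utr5, pair$seq_b, stop_codon, utr3)
    outgroup_seqs[id] <- og$seq
    orf_rows[[id]] <- data.frame(
      contig_id = id, start = orf_start, end = orf_start + orf_len,
      strand = "+", frame = orf_start %% 3L, length_nt = orf_len,
      stringsAsFactors = FALSE)

    # planted polymorphisms become VCF records against the population contig
    pop_seqs <- list(A = pair$seq_a, B = pair$seq_b)
    n_poly <- c(A = stats::rpois(1L, config$poly_rate),
                B = stats::rpois(1L, config$poly_rate))
    poly <- list()
    for (p in c("A", "B")) {
      tr <- .plant_polymorphisms(pop_seqs[[p]], n_poly[[p]], config$kappa)
      if (nrow(tr) > 0L) {
        tr$stratum <- paste0("polymorphism_pop", p)
        tr$population <- p
        qual <- round(stats::runif(nrow(tr), config$qual_range[1],
                                   config$qual_range[2]), 1)
        depth <- sample(config$cov_range[1]:config$cov_range[2], nrow(tr),
                        replace = TRUE)
        occ <- sample(config$occ_range[1]:config$occ_range[2], nrow(tr),
                      replace = TRUE)
        vcf_rows[[p]][[id]] <- data.frame(
          contig_id = id, pos = orf_start + tr$pos, ref = tr$ref,
          alt = tr$alt, qual = qual, depth = depth, occurrence = occ,
          expected = "pass", stringsAsFactors = FALSE)
      }
      poly[[p]] <- tr
    }

    gene_truth <- rbind(pair$truth, og$truth, poly$A, poly$B)
    if (nrow(gene_truth) > 0L) {
      gene_truth <- cbind(gene_id = id, gene_truth,
                          contig_pos = orf_start + gene_truth$pos)
      truth_rows[[id]] <- gene_truth
    }
    gene_rows[[id]] <- data.frame(
      gene_id = id, omega = omega[i], orf_start = orf_start,
      orf_end = orf_start + orf_len, orf_codons = orf_len %/% 3L,
      n_fixed = nrow(pair$truth),
      n_poly_a = nrow(poly$A), n_poly_b = nrow(poly$B),
      outgroup_dn = sum(og$truth$class == "nonsynonymous"),
      outgroup_ds = sum(og$truth$class == "synonymous"),
      stringsAsFactors = FALSE)

    n_terms <- sample(config$go_terms_per_gene[1]:config$go_terms_per_gene[2],
                      1L)
    go_rows[[id]] <- data.frame(
      seq_id = id,
      terms = paste(sort(sample(go_pool, n_terms)), collapse = ","),
      stringsAsFactors = FALSE)
  }

  # filter-failing noise records, appended per population
  noise_counts <- list()
  for (p in c("A", "B")) {
    clean <- do.call(rbind, vcf_rows[[p]])
    n_clean <- if (is.null(clean)) 0L else nrow(clean)
    total <- n_clean / (1 - sum(config$noise))
    n_noise <- stats::setNames(as.integer(round(config$noise * total)),
                               names(config$noise))
    set.seed(derive_seed(config$seed, paste0("noise:pop", p)))
    noise <- .make_noise_records(n_noise, contigs[[p]],
                                 do.call(rbind, orf_rows), clean, config)
    all_rec <- rbind(clean, noise)
    if (!is.null(all_rec) && nrow(all_rec) > 0L) {
      all_rec <- all_rec[order(all_rec$contig_id, all_rec$pos), ,
                         drop = FALSE]
      rownames(all_rec) <- NULL
    }
    vcf_rows[[p]] <- all_rec
    noise_counts[[p]] <- as.list(n_noise)
  }

  # write the bundle
  write_fasta(contigs$A, file.path(out_dir, "popA.fasta"))
  write_fasta(contigs$B, file.path(out_dir, "popB.fasta"))
  write_fasta(outgroup_seqs, file.path(out_dir, "outgroup.fasta"))
  orfs <- do.call(rbind, orf_rows)
  rownames(orfs) <- NULL
  write_gff(orfs, file.path(out_dir, "orfs.gff3"))
  for (p in c("A", "B")) {
    rec <- vcf_rows[[p]]
    if (is.null(rec)) {
      rec <- data.frame(contig_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        qual = numeric(0), depth = integer(0),
                        occurrence = integer(0), expected = character(0))
    }
    write_vcf(rec[, setdiff(names(rec), "expected")],
              file.path(out_dir, paste0("pop", p, ".vcf")),
              contig_lengths = nchar(contigs[[p]]))
    out <- cbind(population = p, rec)
    out$pos <- out$pos + 1L  # 1-based in the external truth table
    write_tsv(out, file.path(out_dir,
                             paste0("vcf_truth_pop", p, ".tsv")))
  }
  go_tab <- do.call(rbind, go_rows)
  utils::write.table(go_tab, file.path(out_dir, "go_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  n_chain <- min(10L, config$n_go_terms)
  parents <- data.frame(child = go_pool[seq_len(n_chain)][-1],
                        parent = go_pool[seq_len(n_chain - 1L)],
                        stringsAsFactors = FALSE)
  write_tsv(parents, file.path(out_dir, "go_parents.tsv"))
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth)) {
    truth <- data.frame(gene_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        class = character(0), stratum = character(0),
                        population = character(0), contig_pos = integer(0))
  }
  rownames(truth) <- NULL
  truth_out <- truth
  truth_out$contig_pos <- truth_out$contig_pos + 1L
  write_tsv(truth_out, file.path(out_dir, "truth_variants.tsv"))
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  write_tsv(genes, file.path(out_dir, "truth_genes.tsv"))

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    n_genes = config$n_genes,
    clean_records = list(
      A = sum(vcf_rows$A$expected == "pass"),
      B = sum(vcf_rows$B$expected == "pass")),
    noise_records = noise_counts,
    files = c("popA.fasta", "popB.fasta", "outgroup.fasta", "orfs.gff3",
              "popA.vcf", "popB.vcf", "vcf_truth_popA.tsv",
              "vcf_truth_popB.tsv", "go_annotations.tsv", "go_parents.tsv",
              "truth_variants.tsv", "truth_genes.tsv", "manifest.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir, truth = truth, genes = genes,
                 vcf_truth = vcf_rows, manifest = manifest))
}

# Build filter-failing variant records: indels, low quality (Q < 20),
# excess coverage (depth > 200) and single-occurrence records, at random
# ORF-interior positions not already carrying a planted polymorphism.
.make_noise_records <- function(n_noise, contigs, orfs, clean, config) {
  rows <- list()
  taken <- if (is.null(clean)) character(0) else
    paste(clean$contig_id, clean$pos)
  for (type in names(n_noise)) {
    for (k in seq_len(n_noise[[type]])) {
      repeat {
        gid <- sample(names(contigs), 1L)
        orf <- orfs[orfs$contig_id == gid, ]
        pos <- sample(orf$start:(orf$end - 2L), 1L)  # leave room for 2-mers
        if (!(paste(gid, pos) %in% taken)) break
      }
      taken <- c(taken, paste(gid, pos))
      seq <- contigs[[gid]]
      ref1 <- substr(seq, pos + 1L, pos + 1L)
      qual <- round(stats::runif(1L, config$qual_range[1],
                                 config$qual_range[2]), 1)
      depth <- sample(config$cov_range[1]:config$cov_range[2], 1L)
      occ <- sample(config$occ_range[1]:config$occ_range[2], 1L)
      ref <- ref1
      alt <- sample(setdiff(BASES, ref1), 1L)
      if (type == "indel") {
        ref <- substr(seq, pos + 1L, pos + 2L)
        alt <- ref1
      } else if (type == "low_qual") {
        qual <- round(stats::runif(1L, 0, 19.9), 1)
      } else if (type == "high_cov") {
        depth <- sample(201:400, 1L)
      } else if (type == "low_occ") {
        occ <- 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = gid, pos = pos, ref = ref, alt = alt, qual = qual,
        depth = depth, occurrence = occ, expected = type,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}
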