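# Shared fixtures and oracles, all built in code at test time.

# A tiny hand-checkable corpus: two species, three genes each.
tiny_collections <- function() {
  mk <- function(sp, i, seq) cds_record(sprintf("%s_g%d", sp, i), seq, sp)
  list(
    species_collection("spA", list(
      mk("spA", 1, "ATGGCTGCCGCTAAATAA"),
      mk("spA", 2, "ATGAAAAAGAAATAA"),
      mk("spA", 3, "ATGGCTGCAGCGGCCTAA")), domain = "Bacteria",
      phylum = "Proteobacteria"),
    species_collection("spB", list(
      mk("spB", 1, "ATGAGAAGGCGTTAA"),
      mk("spB", 2, "ATGCGCCGGCGATAA"),
      mk("spB", 3, "ATGAGAAGAAGATAA")), domain = "Archaea",
      phylum = "Euryarchaeota")
  )
}

# Write a corpus to temp files; returns the file paths.
write_tiny_corpus_files <- function(dir = withr::local_tempdir(
                                      .local_envir = parent.frame())) {
  cols <- tiny_collections()
  recs <- unlist(lapply(cols, `[[`, "records"), recursive = FALSE)
  fasta <- file.path(dir, "tiny.fasta")
  lines <- unlist(lapply(recs, function(r) c(paste0(">", r$seq_id),
                                             r$sequence)))
  writeLines(lines, fasta)
  seq_meta <- file.path(dir, "seq_meta.tsv")
  write.table(data.frame(seq_id = vapply(recs, `[[`, "", "seq_id"),
                         species_id = vapply(recs, `[[`, "", "species_id")),
              seq_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  sp_meta <- file.path(dir, "sp_meta.tsv")
  write.table(data.frame(species_id = c("spA", "spB"),
                         domain = c("Bacteria", "Archaea"),
                         phylum = c("Proteobacteria", "Euryarchaeota")),
              sp_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, seq_meta = seq_meta, sp_meta = sp_meta, dir = dir)
}

# Per-sequence domain labels of a list of collections, named by seq_id.
domains_per_sequence <- function(collections) {
  unlist(lapply(collections, function(s)
    stats::setNames(rep(s$domain, length(s$records)),
                    vapply(s$records, `[[`, "", "seq_id"))))
}

# Monte-Carlo oracle for the pair Z statistic: simulates the statistic's
# null model (codons drawn iid from the corpus within-family frequencies
# at every occurrence slot, gene boundaries preserved), estimates each
# cell's mean and sd over replicates, and forms z = (obs - mean)/sd.
# Fully independent of the analytic variance formula.
mc_pair_z_oracle <- function(seqs, aa, n_rep = 1e5, seed = 1,
                             code = genetic_code()) {
  fam <- code$families[[aa]]
  occ <- lapply(seqs, function(s) {
    cods <- codonbias:::frame0_codons(s)
    cods[code$codon_to_aa[cods] %in% aa]
  })
  allv <- match(unlist(occ), fam)
  f <- tabulate(allv, length(fam)) / length(allv)
  occ <- occ[lengths(occ) > 1]
  n_occ <- lengths(occ)
  k <- length(fam)
  N <- sum(n_occ)
  gid <- rep(seq_along(occ), n_occ)
  mask <- gid[-N] == gid[-1]
  set.seed(seed)
  sum1 <- sum2 <- numeric(k * k)
  for (r in seq_len(n_rep)) {
    p <- sample.int(k, N, replace = TRUE, prob = f)
    idx <- (p[-N][mask] - 1L) * k + p[-1][mask]
    cnt <- tabulate(idx, k * k)
    sum1 <- sum1 + cnt
    sum2 <- sum2 + cnt * cnt
  }
  mu <- sum1 / n_rep
  sd <- sqrt(pmax(sum2 / n_rep - mu^2, 0))
  vi <- match(unlist(occ), fam)
  h <- vi[-N][mask]
  t <- vi[-1][mask]
  obs <- tabulate((h - 1L) * k + t, k * k)
  z <- ifelse(sd > 0, (obs - mu) / sd, 0)
  matrix(z, k, k, byrow = TRUE, dimnames = list(fam, fam))
}

# Shuffle each gene's same-amino-acid codon order (composition fixed).
shuffle_within_genes <- function(seqs, code = genetic_code()) {
  vapply(seqs, function(s) {
    cods <- codonbias:::frame0_codons(s)
    aa <- code$codon_to_aa[cods]
    for (a in unique(aa[!is.na(aa) & aa != "STOP"])) {
      idx <- which(aa == a)
      if (length(idx) > 1L) cods[idx] <- cods[sample(idx)]
    }
    paste(cods, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Criterion-5 style corpus: one species with planted, distinct optimal
# and nonoptimal codons in every multi-codon family except arginine.
planted_optimality_spec <- function(n_genes = 500, seed = 77,
                                    sample_seed = 55) {
  code <- genetic_code()
  fams <- setdiff(names(code$families)[
    vapply(code$families, length, 1L) >= 2L], "Arg")
  set.seed(sample_seed)
  opt <- vapply(fams, function(a) sample(code$families[[a]], 1L), "")
  non <- vapply(fams, function(a)
    sample(setdiff(code$families[[a]], opt[[a]]), 1L), "")
  species_spec("planted", domain = "Eukarya", gc_target = 0.45,
               optimal_set = opt, nonoptimal_set = non,
               n_genes = n_genes, expression_spread = 1.5, seed = seed)
}
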