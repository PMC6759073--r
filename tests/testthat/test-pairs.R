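test_that("successive pairs follow transcript order within amino acids", {
  # Ala occurrences GCT, GCC, GCT with an intervening Lys codon
  sp <- successive_pairs("GCTAAAGCCGCT")
  expect_equal(sp$Ala["GCT", "GCC"], 1L)
  expect_equal(sp$Ala["GCC", "GCT"], 1L)
  expect_equal(sum(sp$Ala), 2L)
  expect_null(sp$Lys)           # single occurrence: no pair
  # adjacent mode requires contiguity: only GCC-GCT touch
  adj <- successive_pairs("GCTAAAGCCGCT", mode = "adjacent")
  expect_equal(sum(adj$Ala), 1L)
  expect_equal(adj$Ala["GCC", "GCT"], 1L)
  expect_null(successive_pairs("GCTAAAGCC", mode = "adjacent")$Ala)
})

test_that("pairs never span sequence boundaries", {
  pc <- corpus_pair_counts(c("ATGGCTAAA", "GCCAAATAA"))
  expect_equal(sum(pc$Ala), 0L)
  expect_equal(sum(pc$Lys), 0L)
})

test_that("pair totals conserve occurrences minus one per gene", {
  spec <- species_spec("cons", n_genes = 10, seed = 4, stickiness = 0.3)
  g <- generate_species(spec)
  seqs <- vapply(g$collection$records, `[[`, "", "sequence")
  pc <- corpus_pair_counts(seqs)
  code <- genetic_code()
  for (aa in c("Ala", "Leu", "Lys", "Ser")) {
    per_gene <- vapply(seqs, function(s) {
      cods <- codonbias:::frame0_codons(s)
      n <- sum(code$codon_to_aa[cods] == aa, na.rm = TRUE)
      max(0L, n - 1L)
    }, 0L)
    expect_equal(sum(pc[[aa]]), sum(per_gene))
  }
})

test_that("expected pair counts are frequency products", {
  obs <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
                dimnames = list(c("GCT", "GCA"), c("GCT", "GCA")))
  exp <- expected_pairs(obs, c(2 / 3, 1 / 3))
  expect_equal(exp[1, 1], 2 * (2 / 3)^2)  # 8/9
  expect_equal(sum(exp), sum(obs))
  uni <- expected_pairs(matrix(1L, 4, 4), rep(0.25, 4))
  expect_true(all(uni == 1))
})

test_that("binomial z matches the closed form and handles degeneracy", {
  obs <- matrix(c(8L, 0L, 4L, 4L), 2, 2)
  exp <- matrix(c(4, 4, 4, 4), 2, 2)
  zz <- pair_zscores(obs, exp)
  expect_equal(zz$z[1, 1], 4 / sqrt(16 * 0.25 * 0.75))  # 4/sqrt(3)
  expect_equal(zz$z[2, 2], 0)
  # obs = exp everywhere -> z = 0
  zz0 <- pair_zscores(matrix(4L, 2, 2), matrix(4, 2, 2))
  expect_true(all(zz0$z == 0))
  # p = 1 cell: sd = 0, defined as 0 and flagged
  zz1 <- pair_zscores(matrix(c(0L, 0L, 0L, 4L), 2, 2),
                      matrix(c(0, 0, 0, 4), 2, 2))
  expect_true(all(zz1$z == 0))
  expect_true(all(zz1$degenerate))
})

test_that("analytic z agrees with the Monte-Carlo null oracle", {
  spec <- species_spec("mc", gc_target = 0.5, n_genes = 25, seed = 11,
                       stickiness = 0.3, gene_length_range = c(450, 750))
  g <- generate_species(spec)
  seqs <- vapply(g$collection$records, `[[`, "", "sequence")
  ac <- codon_autocorrelation(seqs)
  zm <- mc_pair_z_oracle(seqs, "Ala", n_rep = 2e4, seed = 2)
  expect_lt(max(abs(ac$Ala$z - zm)), 0.15)
})

test_that("shading partitions pairs at +3 and 0", {
  tab <- list(amino_acid = "Lys",
              z = matrix(c(5, 1.2, -0.4, 0), 2, 2,
                         dimnames = list(c("AAA", "AAG"),
                                         c("AAA", "AAG"))))
  sh <- shade_pairs(tab)$shade
  expect_equal(sh[1, 1], "strong")   # z = 5
  expect_equal(sh[2, 1], "slight")   # z = 1.2
  expect_equal(sh[1, 2], "none")     # z = -0.4
  expect_equal(sh[2, 2], "none")     # z = 0 is closed ("<= 0 SD")
  # exact boundary z = 3 is slight, not strong
  tab$z[1, 1] <- 3
  expect_equal(shade_pairs(tab)$shade[1, 1], "slight")
})

test_that("pair table export is long, complete and annotatable", {
  ac <- codon_autocorrelation(c("GCTGCCGCTGCAGCT", "AAAAAGAAA"))
  df <- pair_table_df(shade_pairs(ac))
  expect_true(all(c("amino_acid", "codon1", "codon2", "observed",
                    "expected", "z", "shade") %in% names(df)))
  expect_equal(sum(df$observed), 6)
  trna <- data.frame(codon = c("GCT", "GCC"),
                     trna = c("tRNA-Ala-AGC", "tRNA-Ala-AGC"))
  df2 <- pair_table_df(ac, trna = trna)
  expect_equal(df2$trna1[df2$codon1 == "GCT"][1], "tRNA-Ala-AGC")
  expect_true(is.na(df2$trna1[df2$codon1 == "GCA"][1]))
})

test_that("RSCPU is exactly 1 under independence and 0 for unseen pairs", {
  # Lys: freqs AAA 0.6, AAG 0.4; pair counts proportional to products
  pair_counts <- list(Lys = matrix(c(18L, 12L, 12L, 8L), 2, 2, byrow = TRUE,
                                   dimnames = list(c("AAA", "AAG"),
                                                   c("AAA", "AAG"))))
  cc <- codon_counts(c(AAA = 60, AAG = 40))
  tab <- rscpu(pair_counts, cc)
  expect_equal(tab$pairs$rscpu, rep(1, 4))
  # unseen pair with both codons used
  pair_counts$Lys["AAA", "AAG"] <- 0L
  tab2 <- rscpu(pair_counts, cc)
  expect_equal(tab2$pairs$rscpu[tab2$pairs$codon1 == "AAG" &
                                  tab2$pairs$codon2 == "AAA"][1] > 0, TRUE)
  expect_equal(tab2$pairs$rscpu[tab2$pairs$codon1 == "AAA" &
                                  tab2$pairs$codon2 == "AAG"], 0)
  # scale invariance: doubling all counts changes nothing
  tab3 <- rscpu(lapply(pair_counts, `*`, 2L),
                codon_counts(cc$counts * 2L))
  expect_equal(tab3$pairs$rscpu, tab2$pairs$rscpu)
})

test_that("RSCPU is undefined (NA) when a codon is never used", {
  pair_counts <- list(Lys = matrix(c(4L, 0L, 0L, 0L), 2, 2, byrow = TRUE,
                                   dimnames = list(c("AAA", "AAG"),
                                                   c("AAA", "AAG"))))
  tab <- rscpu(pair_counts, codon_counts(c(AAA = 10)))
  p <- tab$pairs
  expect_true(is.na(p$rscpu[p$codon1 == "AAG" & p$codon2 == "AAG"]))
  expect_false(is.na(p$rscpu[p$codon1 == "AAA" & p$codon2 == "AAA"]))
})

test_that("within-gene shuffling drives mean z to 0 and RSCPU to 1", {
  spec <- species_spec("null", gc_target = 0.5, n_genes = 60, seed = 21,
                       stickiness = 0)
  g <- generate_species(spec)
  seqs <- vapply(g$collection$records, `[[`, "", "sequence")
  set.seed(9)
  zbar <- rbar <- numeric(5)
  for (r in 1:5) {
    sh <- shuffle_within_genes(seqs)
    ac <- codon_autocorrelation(sh)
    zbar[r] <- mean(unlist(lapply(ac, function(x)
      x$z[x$n_pairs > 0 & !x$degenerate])))
    tab <- corpus_rscpu(sh)
    rbar[r] <- mean(tab$pairs$rscpu, na.rm = TRUE)
  }
  expect_lt(abs(mean(zbar)), 0.2)
  expect_lt(abs(mean(rbar) - 1), 0.1)
})

test_that("species cluster by planted stickiness in RSCPU space", {
  specs <- c(
    lapply(1:4, function(i) species_spec(paste0("loose", i), n_genes = 40,
                                         seed = 300 + i, stickiness = 0)),
    lapply(1:4, function(i) species_spec(paste0("sticky", i), n_genes = 40,
                                         seed = 400 + i, stickiness = 0.8)))
  corp <- generate_corpus(specs)
  tabs <- lapply(corp$collections, function(s) corpus_rscpu(list(s)))
  names(tabs) <- vapply(specs, `[[`, "", "species_id")
  dend <- cluster_rscpu(tabs)
  top <- stats::cutree(dend$hclust, k = 2)
  expect_true(all(top[1:4] == top[1]))
  expect_true(all(top[5:8] == top[5]))
  expect_false(top[1] == top[5])
  # identical tables merge at height 0
  dup <- cluster_rscpu(list(a = tabs[[1]], b = tabs[[1]], c = tabs[[5]]))
  expect_equal(min(dup$hclust$height), 0)
  # missing pairs are imputed at the neutral value 1 for distances
  expect_true(all(dend$matrix[dend$missing] == 1))
})
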