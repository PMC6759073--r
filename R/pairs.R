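# Codon autocorrelation: successive same-amino-acid codon pairs, binomial
# Z statistics, shading categories, and the RSCPU ratio.

# Amino acids eligible for pair statistics (synonymous family size >= 2).
pair_amino_acids <- function(code) {
  names(code$families)[vapply(code$families, length, 1L) >= 2L]
}

#' Successive same-amino-acid codon pairs of one sequence
#'
#' For each amino acid, takes its codon occurrences in transcript order and
#' counts every ordered pair of successive occurrences (other codons may
#' intervene; `mode = "adjacent"` restricts to immediately adjacent codons).
#' Pairs never span sequence boundaries; stop codons, ambiguous codons and
#' the single-codon families (Met, Trp) are excluded.
#'
#' @param record A [cds_record()] or plain character sequence.
#' @param code A [genetic_code()] object.
#' @param mode `"successive"` (default) or `"adjacent"`.
#' @return Named list of integer matrices, one per amino acid observed at
#'   least twice: `observed[c1, c2]` pair counts over the family's codons.
#' @examples
#' successive_pairs("GCTAAAGCCGCT")$Ala  # Ala run GCT,GCC,GCT
#' @export
successive_pairs <- function(record, code = genetic_code(),
                             mode = c("successive", "adjacent")) {
  mode <- match.arg(mode)
  if (is.character(record)) record <- cds_record("<anonymous>", record)
  triples <- pair_triples(record$sequence, code, mode)
  aas <- intersect(pair_amino_acids(code), unique(triples$aa))
  out <- lapply(aas, function(a) {
    fam <- code$families[[a]]
    sel <- triples$aa == a
    table_pairs(triples$h[sel], triples$t[sel], fam)
  })
  names(out) <- aas
  out
}

# (aa, head, tail) triples of successive same-aa codon pairs of one
# sequence, plus the per-amino-acid count of overlapping slot pairs
# (consecutive pair slots sharing their middle occurrence).
pair_triples <- function(sequence, code, mode = "successive") {
  codons <- frame0_codons(sequence)
  aa <- code$codon_to_aa[codons]
  keep <- !is.na(aa) & aa %in% pair_amino_acids(code)
  codons <- codons[keep]
  aa <- unname(aa[keep])
  empty <- list(aa = character(0), h = character(0), t = character(0),
                ov_aa = character(0), ov_n = integer(0))
  if (length(codons) < 2L) return(empty)
  if (mode == "adjacent") {
    same <- aa[-length(aa)] == aa[-1]
    # positions must also be truly adjacent in the original frame
    pos <- which(keep)
    adj <- diff(pos) == 1L
    sel <- same & adj
    both <- sel[-length(sel)] & sel[-1]
    ov <- table(aa[-c(length(aa) - 1L, length(aa))][both])
    list(aa = aa[-length(aa)][sel], h = codons[-length(codons)][sel],
         t = codons[-1][sel],
         ov_aa = names(ov), ov_n = as.integer(ov))
  } else {
    o <- order(aa)  # stable: transcript order preserved within amino acid
    aa_o <- aa[o]; cod_o <- codons[o]
    same <- aa_o[-length(aa_o)] == aa_o[-1]
    n_occ <- table(aa)
    ov <- pmax(0L, as.integer(n_occ) - 2L)
    keep_ov <- ov > 0L
    list(aa = aa_o[-length(aa_o)][same], h = cod_o[-length(cod_o)][same],
         t = cod_o[-1][same],
         ov_aa = names(n_occ)[keep_ov], ov_n = ov[keep_ov])
  }
}

table_pairs <- function(h, t, fam) {
  m <- table(factor(h, levels = fam), factor(t, levels = fam))
  m <- matrix(as.integer(m), length(fam), length(fam),
              dimnames = list(fam, fam))
  m
}

#' Pooled pair counts over a corpus
#'
#' Counts successive same-amino-acid codon pairs per sequence (pairs never
#' cross gene boundaries) and pools them over the corpus.
#'
#' @param sequences Character vector of CDS sequences, or a list of
#'   [species_collection()]s.
#' @param code A [genetic_code()] object.
#' @param mode See [successive_pairs()].
#' @return Named list of pooled pair-count matrices, one per amino acid
#'   with family size >= 2 (all such amino acids present, possibly all-zero).
#' @export
corpus_pair_counts <- function(sequences, code = genetic_code(),
                               mode = c("successive", "adjacent")) {
  mode <- match.arg(mode)
  if (is.list(sequences) && inherits(sequences[[1]], "species_collection"))
    sequences <- corpus_sequences(sequences)
  trip <- lapply(sequences, pair_triples, code = code, mode = mode)
  aa <- unlist(lapply(trip, `[[`, "aa"), use.names = FALSE)
  h <- unlist(lapply(trip, `[[`, "h"), use.names = FALSE)
  t <- unlist(lapply(trip, `[[`, "t"), use.names = FALSE)
  ov_aa <- unlist(lapply(trip, `[[`, "ov_aa"), use.names = FALSE)
  ov_n <- unlist(lapply(trip, `[[`, "ov_n"), use.names = FALSE)
  out <- lapply(pair_amino_acids(code), function(a) {
    sel <- aa == a
    table_pairs(h[sel], t[sel], code$families[[a]])
  })
  names(out) <- pair_amino_acids(code)
  overlap <- vapply(pair_amino_acids(code), function(a)
    sum(ov_n[ov_aa == a]), 0)
  attr(out, "overlap") <- overlap
  out
}

#' Expected pair counts under codon-usage independence
#'
#' The null model: successive codon choices for an amino acid are
#' independent draws from the amino acid's within-family codon frequencies,
#' so `expected(c1, c2) = n_pairs * f(c1) * f(c2)`.
#'
#' @param observed Integer pair-count matrix for one amino acid.
#' @param freqs Within-family codon frequencies (sum 1) in matching order.
#' @return Numeric matrix of expected counts (same total as observed).
#' @export
expected_pairs <- function(observed, freqs) {
  stopifnot(nrow(observed) == length(freqs))
  n_pairs <- sum(observed)
  n_pairs * outer(freqs, freqs)
}

#' Z-transform observed vs expected pair counts
#'
#' Each cell is treated as a binomial count with `n = n_pairs` trials and
#' success probability `p = expected / n_pairs`, so
#' `z = (observed - expected) / sqrt(n p (1 - p))`. Cells with zero
#' standard deviation (p = 0 or 1) are defined as z = 0 and flagged.
#'
#' When an amino acid occurs three or more times in a gene, successive
#' pair slots share the middle occurrence, so cell counts are not sums of
#' independent pairs. With `overlap` set to the number of such overlapping
#' slot pairs the variance is corrected in closed form under the same
#' independent-draw null: diagonal cells gain
#' `2 * overlap * (p^{3/2} - p^2)` and off-diagonal cells lose
#' `2 * overlap * p^2` (using that the expected frequency of a diagonal
#' pair is the squared codon frequency). [codon_autocorrelation()] passes
#' the overlap it counts; the default 0 is the plain binomial.
#'
#' @param observed Integer pair-count matrix.
#' @param expected Matching expected-count matrix (independence products).
#' @param overlap Number of overlapping (middle-sharing) slot pairs in the
#'   corpus for this amino acid; default 0.
#' @return List: `z` (numeric matrix), `degenerate` (logical matrix, cells
#'   where the sd was zero).
#' @export
pair_zscores <- function(observed, expected, overlap = 0) {
  stopifnot(all(dim(observed) == dim(expected)))
  n_pairs <- sum(observed)
  if (n_pairs == 0L) {
    z <- observed * 0
    return(list(z = z, degenerate = z == 0))
  }
  p <- expected / n_pairs
  diag_cell <- row(p) == col(p)
  v <- n_pairs * p * (1 - p) +
    2 * overlap * ifelse(diag_cell, p^1.5 - p^2, -p^2)
  sd <- sqrt(pmax(v, 0))
  degenerate <- sd == 0
  z <- ifelse(degenerate, 0, (observed - expected) / sd)
  dimnames(z) <- dimnames(observed)
  list(z = z, degenerate = degenerate)
}

#' Full codon-autocorrelation tables for a corpus
#'
#' Pools successive same-amino-acid codon pairs over the corpus, computes
#' expected counts from the corpus within-family codon frequencies, and
#' Z-transforms each cell under the binomial model of [pair_zscores()].
#'
#' @param sequences Character vector of CDS sequences or list of
#'   [species_collection()]s.
#' @param code A [genetic_code()] object.
#' @param mode See [successive_pairs()].
#' @return An object of class `pair_table_set`: a named list of per-amino
#'   acid tables, each with `amino_acid`, `observed`, `expected`, `z`,
#'   `degenerate`, `n_pairs`, `freqs`.
#' @export
codon_autocorrelation <- function(sequences, code = genetic_code(),
                                  mode = c("successive", "adjacent")) {
  mode <- match.arg(mode)
  if (is.list(sequences) && inherits(sequences[[1]], "species_collection"))
    sequences <- corpus_sequences(sequences)
  obs <- corpus_pair_counts(sequences, code, mode)
  overlap <- attr(obs, "overlap")
  counts <- codon_counts(colSums(codon_count_matrix(sequences)))
  out <- lapply(names(obs), function(a) {
    fam <- code$families[[a]]
    fam_counts <- counts$counts[fam]
    f <- if (sum(fam_counts) > 0) fam_counts / sum(fam_counts)
         else stats::setNames(rep(0, length(fam)), fam)
    exp <- expected_pairs(obs[[a]], f)
    zz <- pair_zscores(obs[[a]], exp, overlap = overlap[[a]])
    list(amino_acid = a, observed = obs[[a]], expected = exp,
         z = zz$z, degenerate = zz$degenerate,
         n_pairs = sum(obs[[a]]), overlap = overlap[[a]], freqs = f)
  })
  names(out) <- names(obs)
  structure(out, class = "pair_table_set", mode = mode)
}

#' @export
print.pair_table_set <- function(x, ...) {
  cat("pair_table_set:", length(x), "amino acids,",
      sum(vapply(x, `[[`, 0L, "n_pairs")), "pairs\n")
  invisible(x)
}

#' Shade codon pairs by their Z score
#'
#' The three-way shading used in covariation tables: `"strong"` for
#' z > +3 SD (strongly favored pair), `"slight"` for 0 < z <= 3 SD, and
#' `"none"` for z <= 0 SD.
#'
#' @param tables A `pair_table_set` (or a single table from one).
#' @return The input with a `shade` character matrix added to each table.
#' @export
shade_pairs <- function(tables) {
  shade1 <- function(tab) {
    s <- ifelse(tab$z > 3, "strong", ifelse(tab$z > 0, "slight", "none"))
    dimnames(s) <- dimnames(tab$z)
    tab$shade <- s
    tab
  }
  if (!is.null(tables$z)) return(shade1(tables))
  out <- lapply(tables, shade1)
  attributes(out) <- attributes(tables)
  out
}

#' Flatten pair tables to a long data frame
#'
#' @param tables A `pair_table_set` (shaded or not).
#' @param trna Optional data frame `codon`, `trna` merged onto both codons
#'   of each pair as pass-through annotation.
#' @return Data frame: `amino_acid`, `codon1`, `codon2`, `observed`,
#'   `expected`, `z`, `shade` (if present), `trna1`/`trna2` (if given).
#' @export
pair_table_df <- function(tables, trna = NULL) {
  rows <- lapply(tables, function(tab) {
    fam <- rownames(tab$observed)
    g <- expand.grid(codon1 = fam, codon2 = fam, stringsAsFactors = FALSE)
    df <- data.frame(amino_acid = tab$amino_acid, g,
                     observed = as.vector(tab$observed),
                     expected = as.vector(tab$expected),
                     z = as.vector(tab$z))
    if (!is.null(tab$shade)) df$shade <- as.vector(tab$shade)
    df
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(trna)) {
    stopifnot(all(c("codon", "trna") %in% names(trna)))
    df$trna1 <- trna$trna[match(df$codon1, trna$codon)]
    df$trna2 <- trna$trna[match(df$codon2, trna$codon)]
  }
  df
}

#' Relative synonymous codon pair usage (RSCPU)
#'
#' The genome-size-independent pair-usage ratio: the observed frequency of
#' a same-amino-acid codon pair divided by its expected frequency, where
#' the expected frequency is the product of the two codons' individual
#' observed frequencies,
#' `RSCPU(c1, c2) = f_obs_pair(c1, c2) / (f_obs(c1) * f_obs(c2))`.
#' A value of 1 means the pair is used exactly as often as the two codons'
#' individual usage predicts; above 1 the pair is favored, below 1 avoided.
#'
#' @param pair_counts Named list of pair-count matrices
#'   ([corpus_pair_counts()]).
#' @param codon_counts A [codon_counts()] object from the same corpus.
#' @param code A [genetic_code()] object.
#' @param scope `"family"` (default): pair frequencies are taken within
#'   each amino acid (pair count / the amino acid's total pairs) and codon
#'   frequencies within the synonymous family. `"global"`: both are taken
#'   over all pairs / all counted codons.
#' @return An object of class `rscpu_table`: data frame `pairs` with
#'   `amino_acid`, `codon1`, `codon2`, `observed`, `f_obs_pair`,
#'   `f_exp_pair`, `rscpu` (`NA` where the expected frequency is zero),
#'   plus `n_pairs` and `scope`.
#' @export
rscpu <- function(pair_counts, codon_counts, code = genetic_code(),
                  scope = c("family", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(codon_counts, "codon_counts"))
  n_total_pairs <- sum(vapply(pair_counts, sum, 0))
  if (n_total_pairs == 0L) stop("empty corpus: no codon pairs")
  total_codons <- sum(codon_counts$counts[canonical_codons(code)])
  rows <- lapply(names(pair_counts), function(a) {
    obs <- pair_counts[[a]]
    fam <- rownames(obs)
    n_aa <- sum(obs)
    fam_counts <- codon_counts$counts[fam]
    f_cod <- if (scope == "family") {
      if (sum(fam_counts) > 0) fam_counts / sum(fam_counts) else fam_counts * 0
    } else {
      fam_counts / total_codons
    }
    denom_pairs <- if (scope == "family") n_aa else n_total_pairs
    f_pair <- if (denom_pairs > 0) obs / denom_pairs else obs * 0
    f_exp <- outer(f_cod, f_cod)
    val <- ifelse(f_exp > 0, f_pair / f_exp, NA_real_)
    g <- expand.grid(codon1 = fam, codon2 = fam, stringsAsFactors = FALSE)
    data.frame(amino_acid = a, g, observed = as.vector(obs),
               f_obs_pair = as.vector(f_pair),
               f_exp_pair = as.vector(f_exp),
               rscpu = as.vector(val))
  })
  structure(
    list(pairs = do.call(rbind, c(rows, make.row.names = FALSE)),
         n_pairs = n_total_pairs, scope = scope),
    class = "rscpu_table"
  )
}

#' @export
print.rscpu_table <- function(x, ...) {
  cat("rscpu_table:", nrow(x$pairs), "codon pairs,", x$n_pairs,
      "observed pair occurrences (scope:", x$scope, ")\n")
  invisible(x)
}

#' RSCPU table of a corpus in one call
#'
#' @param sequences Character vector of CDS sequences or list of
#'   [species_collection()]s.
#' @inheritParams rscpu
#' @param mode See [successive_pairs()].
#' @return An `rscpu_table`.
#' @export
corpus_rscpu <- function(sequences, code = genetic_code(),
                         scope = c("family", "global"),
                         mode = c("successive", "adjacent")) {
  if (is.list(sequences) && inherits(sequences[[1]], "species_collection"))
    sequences <- corpus_sequences(sequences)
  pc <- corpus_pair_counts(sequences, code, match.arg(mode))
  cc <- codon_counts(colSums(codon_count_matrix(sequences)))
  rscpu(pc, cc, code, match.arg(scope))
}

# Named RSCPU vector keyed "aa|codon1|codon2".
rscpu_profile <- function(table) {
  stopifnot(inherits(table, "rscpu_table"))
  p <- table$pairs
  stats::setNames(p$rscpu, paste(p$amino_acid, p$codon1, p$codon2, sep = "|"))
}

#' Hierarchical clustering of species by RSCPU patterns
#'
#' Builds a species-by-codon-pair RSCPU matrix (undefined entries imputed
#' at the neutral value 1 for the distance computation only) and clusters
#' species; the domain label rides along as an annotation channel.
#'
#' @param tables Named list, species_id to `rscpu_table`.
#' @param metric,linkage As in [cluster_profiles()].
#' @param domains Optional named character vector, species_id to domain.
#' @return An object of class `rscpu_dendrogram`: `hclust`, `matrix`
#'   (imputed values used for clustering), `missing` (logical matrix of
#'   imputed cells), `annotations`.
#' @export
cluster_rscpu <- function(tables, metric = "euclidean", linkage = "ward.D2",
                          domains = NULL) {
  if (length(tables) < 2L) stop("need at least 2 species to cluster")
  vecs <- lapply(tables, rscpu_profile)
  keys <- Reduce(union, lapply(vecs, names))
  m <- t(vapply(vecs, function(v) v[keys], numeric(length(keys))))
  colnames(m) <- keys
  rownames(m) <- names(tables)
  missing <- is.na(m)
  m[missing] <- 1
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  structure(
    list(hclust = hc, matrix = m, missing = missing,
         annotations = data.frame(
           species_id = rownames(m),
           domain = if (is.null(domains)) NA_character_
                    else unname(domains[rownames(m)])),
         metric = metric, linkage = linkage),
    class = "rscpu_dendrogram"
  )
}

#' @export
print.rscpu_dendrogram <- function(x, ...) {
  cat("rscpu_dendrogram:", nrow(x$matrix), "species,", ncol(x$matrix),
      "codon pairs\n")
  invisible(x)
}
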