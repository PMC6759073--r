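# Expression-stratified codon usage: abundance binning, loess trends,
# optimal/nonoptimal codon calls, preference switches, and the overlap
# between autocorrelated codon pairs and codon optimality.

#' Read a protein-abundance table
#'
#' @param path TSV with header columns `gene_id`, `abundance`.
#' @return Data frame with `gene_id`, `abundance` (> 0) and
#'   `log_abundance`; rows with missing or non-positive abundance are
#'   dropped with a message.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "abundance") %in% names(df)))
  bad <- is.na(df$abundance) | df$abundance <= 0
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing/non-positive abundance dropped")
    df <- df[!bad, ]
  }
  df$log_abundance <- log(df$abundance)
  df[, c("gene_id", "abundance", "log_abundance")]
}

#' Bin genes by abundance and pool codon counts per bin
#'
#' Genes present in both the collection and the abundance table are ranked
#' by abundance (ties broken by `gene_id`) and split into `n_bins`
#' equal-size quantile bins (bin 1 = lowest expression); codon counts are
#' pooled within each bin.
#'
#' @param collection A [species_collection()] (gene ids are the `seq_id`s).
#' @param abundance Data frame from [read_abundance()] (or with columns
#'   `gene_id`, `abundance`).
#' @param n_bins Number of bins (>= 2); default 5 (quintiles).
#' @param code A [genetic_code()] object.
#' @return An object of class `abundance_strata`: `bins` (list of
#'   [codon_counts()]), `rscu` (matrix, `n_bins` rows by 59 canonical codon
#'   columns), `assignment` (data frame `gene_id`, `abundance`, `bin`),
#'   `n_unmatched` (genes in the collection without abundance).
#' @export
stratify_by_abundance <- function(collection, abundance, n_bins = 5L,
                                  code = genetic_code()) {
  stopifnot(n_bins >= 2L)
  seqs <- corpus_sequences(list(collection))
  ab <- abundance[abundance$gene_id %in% names(seqs), ]
  if (nrow(ab) == 0L) stop("no overlap between abundance table and corpus")
  n_unmatched <- sum(!names(seqs) %in% ab$gene_id)
  ab <- ab[order(ab$abundance, ab$gene_id), ]
  bin <- ceiling(seq_len(nrow(ab)) * n_bins / nrow(ab))
  if (min(table(bin)) < 1L) stop("empty abundance bin")
  cm <- codon_count_matrix(seqs[ab$gene_id])
  bins <- lapply(seq_len(n_bins), function(b)
    codon_counts(colSums(cm[bin == b, , drop = FALSE])))
  rscu <- t(vapply(bins, function(cc) rscu_vector(cc, code)$values,
                   numeric(length(canonical_codons(code)))))
  rownames(rscu) <- paste0("bin", seq_len(n_bins))
  structure(
    list(bins = bins, rscu = rscu,
         assignment = data.frame(gene_id = ab$gene_id,
                                 abundance = ab$abundance, bin = bin),
         n_unmatched = n_unmatched, n_bins = n_bins),
    class = "abundance_strata"
  )
}

#' @export
print.abundance_strata <- function(x, ...) {
  cat("abundance_strata:", x$n_bins, "bins,", nrow(x$assignment),
      "genes (", x$n_unmatched, "without abundance )\n")
  invisible(x)
}

#' Local-polynomial trend of RSCU versus expression
#'
#' Fits, for each codon, a loess curve (degree <= 2) of per-gene RSCU
#' against log abundance. Descriptive: optimality calls use binned RSCU,
#' not the smoothed curves.
#'
#' @param rscu_per_gene Numeric matrix, rows = genes, canonical codon
#'   columns (from [rscu_matrix()]).
#' @param log_abundance Numeric vector aligned with the rows.
#' @param span Loess span; default 0.75.
#' @param degree Local polynomial degree; default 2.
#' @param min_support Minimum genes with non-imputed RSCU required per
#'   codon; codons under this are skipped with a warning. Default 10.
#' @param grid_n Evaluation-grid size over the abundance range.
#' @return An object of class `expression_trend`: `grid` (log-abundance
#'   evaluation points), `fitted_grid` (matrix codons x grid, clamped at
#'   0), `fitted` (at the observed abundances), `skipped` (codons).
#' @export
fit_trend <- function(rscu_per_gene, log_abundance, span = 0.75,
                      degree = 2L, min_support = 10L, grid_n = 50L) {
  stopifnot(nrow(rscu_per_gene) == length(log_abundance))
  codons <- colnames(rscu_per_gene)
  grid <- seq(min(log_abundance), max(log_abundance), length.out = grid_n)
  fitted_grid <- matrix(NA_real_, length(codons), grid_n,
                        dimnames = list(codons, NULL))
  fitted <- matrix(NA_real_, nrow(rscu_per_gene), length(codons),
                   dimnames = list(rownames(rscu_per_gene), codons))
  skipped <- character(0)
  for (cod in codons) {
    y <- rscu_per_gene[, cod]
    ok <- is.finite(y)
    if (sum(ok) < min_support) {
      skipped <- c(skipped, cod)
      next
    }
    fit <- stats::loess(y[ok] ~ log_abundance[ok], span = span,
                        degree = degree)
    fitted[ok, cod] <- pmax(0, stats::predict(fit))
    fitted_grid[cod, ] <- pmax(0, stats::predict(fit, newdata = grid))
  }
  if (length(skipped)) {
    warning("insufficient support, skipped: ",
            paste(skipped, collapse = ", "))
  }
  structure(
    list(grid = grid, fitted_grid = fitted_grid, fitted = fitted,
         span = span, degree = degree, skipped = skipped),
    class = "expression_trend"
  )
}

#' Call optimal and nonoptimal codons from expression strata
#'
#' A codon is `"optimal"` if it is clearly over-represented in highly
#' expressed genes (`RSCU_high >= 1 + delta`) and more used there than in
#' lowly expressed genes; `"nonoptimal"` if clearly under-represented in
#' highly expressed genes (`RSCU_high <= 1 - delta`) and less used there
#' than in lowly expressed genes; `"intermediate"` otherwise. Families
#' imputed in either stratum are intermediate and flagged.
#'
#' @param strata An `abundance_strata` (or a 2+-row RSCU matrix).
#' @param high,low Row indices of the high- and low-expression strata;
#'   defaults: top and bottom bin.
#' @param delta Half-width of the neutral band around RSCU 1; default 0.1.
#' @param code A [genetic_code()] object.
#' @return An object of class `optimality_calls`: data frame `calls` with
#'   `codon`, `amino_acid`, `class`, `rscu_high`, `rscu_low`, `imputed`;
#'   plus `delta` and `intermediate_only` (families with no optimal codon).
#' @export
call_optimality <- function(strata, high = NULL, low = NULL, delta = 0.1,
                            code = genetic_code()) {
  rscu <- if (inherits(strata, "abundance_strata")) strata$rscu else strata
  stopifnot(nrow(rscu) >= 2L)
  if (is.null(high)) high <- nrow(rscu)
  if (is.null(low)) low <- 1L
  codons <- canonical_codons(code)
  hi <- rscu[high, codons]
  lo <- rscu[low, codons]
  imputed_hi <- if (inherits(strata, "abundance_strata")) {
    fam_tot <- tapply(strata$bins[[high]]$counts[codons], names(codons), sum)
    names(codons) %in% names(fam_tot)[fam_tot == 0]
  } else rep(FALSE, length(codons))
  imputed_lo <- if (inherits(strata, "abundance_strata")) {
    fam_tot <- tapply(strata$bins[[low]]$counts[codons], names(codons), sum)
    names(codons) %in% names(fam_tot)[fam_tot == 0]
  } else rep(FALSE, length(codons))
  imputed <- imputed_hi | imputed_lo
  cls <- ifelse(hi >= 1 + delta & hi > lo, "optimal",
         ifelse(hi <= 1 - delta & hi < lo, "nonoptimal", "intermediate"))
  cls[imputed] <- "intermediate"
  calls <- data.frame(codon = codons, amino_acid = names(codons),
                      class = cls, rscu_high = hi, rscu_low = lo,
                      imputed = imputed, row.names = NULL)
  by_fam <- tapply(calls$class == "optimal", calls$amino_acid, any)
  structure(
    list(calls = calls, delta = delta, high = high, low = low,
         intermediate_only = names(by_fam)[!by_fam]),
    class = "optimality_calls"
  )
}

#' @export
print.optimality_calls <- function(x, ...) {
  cat("optimality_calls:",
      sum(x$calls$class == "optimal"), "optimal,",
      sum(x$calls$class == "nonoptimal"), "nonoptimal,",
      sum(x$calls$class == "intermediate"), "intermediate codons\n")
  invisible(x)
}

#' Detect codon-preference switches between expression strata
#'
#' An amino acid "switches" when its most-used codon in lowly expressed
#' genes differs from the most-used codon in highly expressed genes.
#' Argmaxes are taken on within-family counts (equivalently RSCU) with
#' alphabetical tie-break; ties are flagged.
#'
#' @param strata An `abundance_strata`.
#' @param high,low Stratum indices as in [call_optimality()].
#' @param code A [genetic_code()] object.
#' @return Data frame: `amino_acid`, `codon_low`, `codon_high`, `switch`
#'   (logical, `NA` when the family is absent from either stratum), `tie`.
#' @export
detect_switch <- function(strata, high = NULL, low = NULL,
                          code = genetic_code()) {
  stopifnot(inherits(strata, "abundance_strata"))
  if (is.null(high)) high <- strata$n_bins
  if (is.null(low)) low <- 1L
  cod <- canonical_codons(code)
  fams <- unique(names(cod))
  argmax <- function(counts, fam) {
    v <- counts[fam]
    if (sum(v) == 0) return(list(codon = NA_character_, tie = NA))
    top <- fam[v == max(v)]
    list(codon = sort(top)[1], tie = length(top) > 1L)
  }
  rows <- lapply(fams, function(a) {
    fam <- code$families[[a]]
    lo <- argmax(strata$bins[[low]]$counts, fam)
    hi <- argmax(strata$bins[[high]]$counts, fam)
    data.frame(amino_acid = a, codon_low = lo$codon, codon_high = hi$codon,
               switch = if (is.na(lo$codon) || is.na(hi$codon)) NA
                        else lo$codon != hi$codon,
               tie = isTRUE(lo$tie) || isTRUE(hi$tie))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Overlap between autocorrelated codon pairs and codon optimality
#'
#' Among codon pairs whose autocorrelation Z score reaches `sd_min`, the
#' fraction formed by two codons of the same optimality class
#' (optimal-optimal or nonoptimal-nonoptimal). Pairs touching an
#' intermediate codon cannot be assigned either way; by default they are
#' excluded from numerator and denominator and listed separately
#' (`accounting = "include"` keeps them in the denominator instead).
#'
#' @param tables A `pair_table_set` from [codon_autocorrelation()] on the
#'   same corpus as the optimality calls.
#' @param calls An `optimality_calls`.
#' @param sd_min Z threshold; pairs with `z >= sd_min` qualify. Default 3.
#' @param accounting `"exclude"` (default) or `"include"` for
#'   intermediate-touching pairs in the denominator.
#' @return An object of class `covariation_overlap`: `fraction` (`NA` when
#'   no pair qualifies), `n_within`, `n_cross`, `n_intermediate`, and
#'   `pairs` (data frame of qualifying pairs with both codon classes).
#' @export
covariation_overlap <- function(tables, calls, sd_min = 3,
                                accounting = c("exclude", "include")) {
  accounting <- match.arg(accounting)
  stopifnot(inherits(calls, "optimality_calls"))
  cls <- stats::setNames(calls$calls$class, calls$calls$codon)
  df <- pair_table_df(tables)
  df <- df[df$z >= sd_min, , drop = FALSE]
  if (nrow(df)) {
    df$class1 <- unname(cls[df$codon1])
    df$class2 <- unname(cls[df$codon2])
    df$category <- ifelse(
      df$class1 == "intermediate" | df$class2 == "intermediate",
      "intermediate",
      ifelse(df$class1 == df$class2, "within", "cross"))
  } else {
    df$class1 <- df$class2 <- df$category <- character(0)
  }
  n_within <- sum(df$category == "within")
  n_cross <- sum(df$category == "cross")
  n_intermediate <- sum(df$category == "intermediate")
  denom <- n_within + n_cross +
    if (accounting == "include") n_intermediate else 0L
  structure(
    list(fraction = if (denom > 0) n_within / denom else NA_real_,
         n_within = n_within, n_cross = n_cross,
         n_intermediate = n_intermediate,
         sd_min = sd_min, accounting = accounting, pairs = df),
    class = "covariation_overlap"
  )
}

#' @export
print.covariation_overlap <- function(x, ...) {
  cat(sprintf(
    "covariation_overlap: %d/%d within-class pairs at z >= %g (%s); %d intermediate-touching excluded\n",
    x$n_within, x$n_within + x$n_cross, x$sd_min,
    ifelse(is.na(x$fraction), "NA", sprintf("%.2f", x$fraction)),
    x$n_intermediate))
  invisible(x)
}
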