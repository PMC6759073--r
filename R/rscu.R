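# Relative synonymous codon usage: per-sequence and per-species vectors,
# species profiles and hierarchical clustering of profiles.

#' RSCU vector of a codon-count table
#'
#' For a codon `c` of amino acid `a` with synonymous-family size `k` and
#' total family count `n_a`, `RSCU(c) = count(c) / (n_a / k)`: the ratio of
#' the observed codon count to the count expected under equal use of the
#' synonymous codons. Values are reported for the 59 codons of the canonical
#' ordering (Met, Trp and stop codons excluded). Families with `n_a = 0`
#' carry no information and are imputed at the neutral value 1 and flagged.
#'
#' @param counts A [codon_counts()] object (sequence-level or pooled).
#' @param code A [genetic_code()] object.
#' @param source_id Identifier recorded on the vector.
#' @return An object of class `rscu_vector`: `values` (named numeric, 59
#'   canonical codons), `imputed` (codons of absent families), `source_id`.
#' @examples
#' cc <- count_codons("GCTGCCGCAGCG")   # one of each Ala codon
#' rscu_vector(cc)$values[c("GCT", "GCC", "GCA", "GCG")]  # all 1
#' @export
rscu_vector <- function(counts, code = genetic_code(),
                        source_id = NA_character_) {
  stopifnot(inherits(counts, "codon_counts"))
  codons <- canonical_codons(code)
  aa <- names(codons)
  cnt <- counts$counts[codons]
  fam_n <- tapply(cnt, aa, sum)[aa]          # family total per entry
  fam_k <- tapply(codons, aa, length)[aa]    # family size per entry
  vals <- as.numeric(ifelse(fam_n > 0, cnt * fam_k / fam_n, 1))
  names(vals) <- codons
  structure(
    list(values = vals,
         imputed = codons[fam_n == 0],
         source_id = source_id),
    class = "rscu_vector"
  )
}

#' @export
print.rscu_vector <- function(x, ...) {
  cat("rscu_vector (59 codons)")
  if (length(x$imputed)) {
    cat(";", length(unique(names(canonical_codons())[
      canonical_codons() %in% x$imputed])), "imputed codons")
  }
  cat("\n")
  invisible(x)
}

#' RSCU matrix for many sequences
#'
#' Vectorised per-sequence RSCU over a corpus. Absent families are imputed
#' at 1 per sequence, as in [rscu_vector()].
#'
#' @param count_matrix Integer matrix from [codon_count_matrix()] (rows =
#'   sequences, 64 codon columns) or any matrix with codon column names.
#' @param code A [genetic_code()] object.
#' @return A list: `values` (numeric matrix, rows = sequences, 59 canonical
#'   codon columns), `imputed_families` (integer, per row: number of amino
#'   acid families with zero counts).
#' @export
rscu_matrix <- function(count_matrix, code = genetic_code()) {
  codons <- canonical_codons(code)
  aa <- names(codons)
  m <- count_matrix[, codons, drop = FALSE]
  fams <- unique(aa)
  out <- matrix(1, nrow(m), length(codons),
                dimnames = list(rownames(m), codons))
  imputed <- integer(nrow(m))
  for (f in fams) {
    idx <- which(aa == f)
    n_a <- rowSums(m[, idx, drop = FALSE])
    k <- length(idx)
    pos <- n_a > 0
    out[pos, idx] <- m[pos, idx, drop = FALSE] * k / n_a[pos]
    imputed <- imputed + !pos
  }
  list(values = out, imputed_families = imputed)
}

#' Pooled species profile
#'
#' Pools codon counts over all of a species' sequences and computes the
#' species RSCU vector and GC content on the pool (count-weighted "average
#' RSCU"; see the vignette for the contrast with the unweighted mean of
#' per-gene vectors).
#'
#' @param collection A [species_collection()], non-empty.
#' @param code A [genetic_code()] object.
#' @param mode `"pooled"` (default) or `"mean"` (unweighted mean of
#'   per-gene RSCU vectors, imputed entries at 1).
#' @return A list of class `species_profile`: `species_id`, `domain`,
#'   `phylum`, `gc`, `rscu` (an `rscu_vector`, or the mean vector), `n_genes`.
#' @export
species_profile <- function(collection, code = genetic_code(),
                            mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "species_collection"),
            length(collection$records) > 0L)
  seqs <- vapply(collection$records, `[[`, "", "sequence")
  cm <- codon_count_matrix(seqs)
  rscu <- if (mode == "pooled") {
    rscu_vector(codon_counts(colSums(cm)), code,
                source_id = collection$species_id)
  } else {
    rm <- rscu_matrix(cm, code)
    structure(list(values = colMeans(rm$values), imputed = character(0),
                   source_id = collection$species_id),
              class = "rscu_vector")
  }
  structure(
    list(species_id = collection$species_id,
         domain = collection$domain,
         phylum = collection$phylum,
         gc = gc_content(seqs),
         rscu = rscu,
         n_genes = length(collection$records)),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("species_profile '%s' (%s): %d genes, GC %.3f\n",
              x$species_id, x$domain, x$n_genes, x$gc))
  invisible(x)
}

#' Extract one amino acid's RSCU entries
#'
#' Returns the synonymous family of one amino acid from an RSCU vector, in
#' canonical (alphabetical) codon order — e.g. the six arginine codons used
#' for arginine-only ordination.
#'
#' @param vector An `rscu_vector`, or a named numeric RSCU vector/matrix
#'   with canonical codon names.
#' @param aa Amino acid, three-letter code, family size >= 2.
#' @param code A [genetic_code()] object.
#' @return Numeric vector (or matrix columns) of the family's RSCU values.
#' @export
subset_amino_acid <- function(vector, aa, code = genetic_code()) {
  fam <- code$families[[aa]]
  if (is.null(fam)) stop("unknown amino acid: ", aa)
  if (length(fam) < 2L) stop("degenerate family: ", aa)
  if (inherits(vector, "rscu_vector")) return(vector$values[fam])
  if (is.matrix(vector)) return(vector[, fam, drop = FALSE])
  vector[fam]
}

#' Species RSCU profile matrix
#'
#' @param profiles List of `species_profile`s.
#' @return Numeric matrix, rows = species, 59 canonical codon columns.
#' @export
profile_matrix <- function(profiles) {
  m <- t(vapply(profiles, function(p) p$rscu$values,
                numeric(length(canonical_codons()))))
  rownames(m) <- vapply(profiles, `[[`, "", "species_id")
  m
}

#' Hierarchical clustering of species RSCU profiles
#'
#' Clusters species by their (pooled) RSCU vectors; GC content and domain
#' are attached as per-leaf annotation channels for heatmap export.
#'
#' @param profiles List of `species_profile`s (>= 2).
#' @param metric Distance metric for [stats::dist()]; default
#'   `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"ward.D2"`.
#' @return An object of class `profile_dendrogram`: the `hclust` tree plus
#'   `annotations` (data frame with `species_id`, `domain`, `gc`).
#' @export
cluster_profiles <- function(profiles, metric = "euclidean",
                             linkage = "ward.D2") {
  if (length(profiles) < 2L) stop("need at least 2 profiles to cluster")
  m <- profile_matrix(profiles)
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  structure(
    list(hclust = hc,
         matrix = m,
         annotations = data.frame(
           species_id = rownames(m),
           domain = vapply(profiles, `[[`, "", "domain"),
           gc = vapply(profiles, `[[`, 0, "gc")),
         metric = metric, linkage = linkage),
    class = "profile_dendrogram"
  )
}

#' @export
print.profile_dendrogram <- function(x, ...) {
  cat("profile_dendrogram:", nrow(x$matrix), "leaves (", x$metric, "/",
      x$linkage, ")\n")
  invisible(x)
}

#' Write a dendrogram in Newick format
#' @param dendro A `profile_dendrogram` (or `hclust`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  hc <- if (inherits(dendro, "profile_dendrogram")) dendro$hclust else dendro
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write an RSCU matrix as TSV
#' @param values Numeric matrix with canonical codon columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rscu_tsv <- function(values, path) {
  df <- data.frame(id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
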