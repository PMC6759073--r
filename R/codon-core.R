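# CDS validation, codon counting and GC content.

#' Create a CDS record
#'
#' A lightweight container for one coding sequence.
#'
#' @param seq_id Sequence identifier (unique within a corpus).
#' @param sequence Nucleotide string; upper-cased on construction.
#' @param species_id Species identifier (may be `NA`).
#' @return A list of class `cds_record` with `seq_id`, `species_id`,
#'   `sequence` and `length_nt`.
#' @export
cds_record <- function(seq_id, sequence, species_id = NA_character_) {
  sequence <- toupper(as.character(sequence))
  structure(
    list(seq_id = as.character(seq_id),
         species_id = as.character(species_id),
         sequence = sequence,
         length_nt = nchar(sequence)),
    class = "cds_record"
  )
}

# Frame-0 codons of a sequence string (tail shorter than 3 nt dropped).
frame0_codons <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  if (n == 0L) return(character(0))
  starts <- 3L * seq_len(n) - 2L
  substring(sequence, starts, starts + 2L)
}

#' Validate a coding sequence
#'
#' Checks reading-frame integrity: length a multiple of three, in-frame stop
#' codons before the final codon, and codons containing ambiguity characters.
#' Validation never throws; the verdict is decided by the policy.
#'
#' @param record A [cds_record()] (or a plain character sequence).
#' @param policy List with logical `reject_not_triplet` (default `TRUE`) and
#'   `reject_internal_stop` (default `FALSE`: internal stops warn but the
#'   sequence is retained).
#' @param code A [genetic_code()] object.
#' @return A list of class `cds_validation` with flags
#'   `is_multiple_of_three`, `has_internal_stop`, `ambiguous_codon_count`
#'   and `verdict` (`"pass"`, `"warn"` or `"reject"`).
#' @examples
#' validate_cds(cds_record("g1", "ATGGCTTAA"))$verdict  # "pass"
#' @export
validate_cds <- function(record, policy = list(), code = genetic_code()) {
  if (is.character(record)) record <- cds_record("<anonymous>", record)
  pol <- utils::modifyList(
    list(reject_not_triplet = TRUE, reject_internal_stop = FALSE), policy)
  codons <- frame0_codons(record$sequence)
  ok <- grepl("^[ACGT]{3}$", codons)
  internal <- if (length(codons) > 1L) {
    any(codons[-length(codons)] %in% code$stop_codons)
  } else FALSE
  triplet <- record$length_nt %% 3L == 0L
  verdict <- "pass"
  if (internal || any(!ok)) verdict <- "warn"
  if ((!triplet && pol$reject_not_triplet) ||
      (internal && pol$reject_internal_stop)) verdict <- "reject"
  structure(
    list(seq_id = record$seq_id,
         is_multiple_of_three = triplet,
         has_internal_stop = internal,
         ambiguous_codon_count = sum(!ok),
         verdict = verdict),
    class = "cds_validation"
  )
}

#' Count frame-0 codons of one sequence
#'
#' Codons are read left to right from position 1; codons containing any
#' non-ACGT character are skipped and tallied separately. Stop codons are
#' counted (they are excluded later, at the RSCU stage).
#'
#' @param record A [cds_record()] or plain character sequence.
#' @param code A [genetic_code()] object.
#' @return A list of class `codon_counts`: `counts` (named integer, all 64
#'   codons), `n_codons_counted`, `n_codons_skipped`.
#' @examples
#' count_codons("ATGGCT")$counts[c("ATG", "GCT")]
#' @export
count_codons <- function(record, code = genetic_code()) {
  if (is.character(record)) record <- cds_record("<anonymous>", record)
  codons <- frame0_codons(record$sequence)
  ok <- grepl("^[ACGT]{3}$", codons)
  counts <- table(factor(codons[ok], levels = all_codons()))
  codon_counts(stats::setNames(as.integer(counts), names(counts)),
               n_skipped = sum(!ok))
}

#' Construct a codon-counts object
#'
#' @param counts Named non-negative integer vector over (a subset of) the 64
#'   codons; missing codons are filled with zero.
#' @param n_skipped Number of codons skipped for ambiguity.
#' @return A `codon_counts` object.
#' @export
codon_counts <- function(counts, n_skipped = 0L) {
  full <- stats::setNames(integer(64), all_codons())
  if (length(counts)) {
    stopifnot(!is.null(names(counts)), all(names(counts) %in% names(full)))
    full[names(counts)] <- as.integer(counts)
  }
  stopifnot(all(full >= 0L))
  structure(
    list(counts = full,
         n_codons_counted = sum(full),
         n_codons_skipped = as.integer(n_skipped)),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts:", x$n_codons_counted, "codons counted,",
      x$n_codons_skipped, "skipped\n")
  invisible(x)
}

#' Add codon-counts objects
#' @param ... `codon_counts` objects to pool.
#' @return The pooled `codon_counts`.
#' @export
pool_codon_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "codon_counts"))
    xs <- xs[[1]]
  counts <- Reduce(`+`, lapply(xs, `[[`, "counts"))
  codon_counts(counts, n_skipped = sum(vapply(xs, `[[`, 0L, "n_codons_skipped")))
}

#' Frame-0 codon count matrix for many sequences
#'
#' Vectorised counterpart of [count_codons()] for whole corpora, built on
#' [Biostrings::trinucleotideFrequency()] with `step = 3` (frame 0; codons
#' containing ambiguity characters are not counted).
#'
#' @param sequences Character vector (or `DNAStringSet`) of CDS sequences.
#' @return Integer matrix, one row per sequence, 64 codon columns in
#'   alphabetical order.
#' @export
codon_count_matrix <- function(sequences) {
  dss <- if (inherits(sequences, "DNAStringSet")) sequences
         else Biostrings::DNAStringSet(sequences)
  m <- Biostrings::trinucleotideFrequency(dss, step = 3)
  m <- m[, all_codons(), drop = FALSE]
  rownames(m) <- names(dss)
  m
}

#' Pooled GC content of a set of sequences
#'
#' @param records List of [cds_record()]s, or a character vector of
#'   sequences. Ambiguity characters are excluded from numerator and
#'   denominator.
#' @return Fraction of G+C among unambiguous bases, pooled over all records.
#' @examples
#' gc_content(c("ATGC"))  # 0.5
#' @export
gc_content <- function(records) {
  seqs <- if (is.character(records)) records
          else vapply(records, `[[`, "", "sequence")
  seqs <- toupper(seqs)
  gc <- sum(nchar(gsub("[^GC]", "", seqs)))
  acgt <- sum(nchar(gsub("[^ACGT]", "", seqs)))
  if (acgt == 0L) stop("undefined GC content: no unambiguous bases")
  gc / acgt
}
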