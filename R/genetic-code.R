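# Genetic-code tables and the canonical codon ordering used by every
# downstream statistic.

#' Build a genetic code table
#'
#' Constructs a genetic-code object mapping the 64 DNA codons to amino acids
#' (three-letter codes) or `"STOP"`, together with the synonymous families
#' (the ordered list of codons encoding each amino acid). The default is the
#' standard code (NCBI translation table 1), built from
#' [Biostrings::getGeneticCode()].
#'
#' @param code_id Identifier of the code, passed to
#'   [Biostrings::getGeneticCode()] (`"1"`/`"Standard"` for the standard
#'   code).
#' @return An object of class `genetic_code` with elements
#'   \describe{
#'     \item{code_id}{the identifier,}
#'     \item{codon_to_aa}{named character vector, 64 codons to amino acid or
#'       `"STOP"`,}
#'     \item{families}{named list, amino acid to alphabetically ordered codon
#'       vector,}
#'     \item{stop_codons}{the stop codons.}
#'   }
#' @examples
#' gc <- genetic_code()
#' gc$families$Arg
#' @export
genetic_code <- function(code_id = "standard") {
  biostrings_id <- if (identical(code_id, "standard")) "1" else code_id
  one <- Biostrings::getGeneticCode(biostrings_id)
  aa3 <- Biostrings::AMINO_ACID_CODE  # one-letter -> three-letter
  codon_to_aa <- ifelse(one == "*", "STOP", unname(aa3[one]))
  names(codon_to_aa) <- names(one)
  stopifnot(length(codon_to_aa) == 64L, !anyNA(codon_to_aa))
  aas <- sort(unique(codon_to_aa[codon_to_aa != "STOP"]))
  families <- lapply(aas, function(a) sort(names(codon_to_aa)[codon_to_aa == a]))
  names(families) <- aas
  structure(
    list(
      code_id = code_id,
      codon_to_aa = codon_to_aa,
      families = families,
      stop_codons = sort(names(codon_to_aa)[codon_to_aa == "STOP"])
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code '", x$code_id, "': ", length(x$families),
      " amino acids, ", length(x$stop_codons), " stop codons\n", sep = "")
  invisible(x)
}

#' All 64 codons in alphabetical order
#' @return Character vector of the 64 DNA codons.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Canonical 59-codon ordering
#'
#' The fixed codon ordering used for RSCU vectors and all downstream feature
#' matrices: amino acids alphabetically by three-letter code, codons
#' alphabetically within each amino acid; Met, Trp and stop codons excluded.
#'
#' @param code A [genetic_code()] object.
#' @return Character vector of 59 codons, named by amino acid.
#' @export
canonical_codons <- function(code = genetic_code()) {
  keep <- names(code$families)[vapply(code$families, length, 1L) >= 2L]
  out <- unlist(code$families[keep], use.names = FALSE)
  names(out) <- rep(keep, vapply(code$families[keep], length, 1L))
  out
}

#' Translate a single codon
#'
#' @param codon A 3-mer over `{A,C,G,T}` (upper case).
#' @param code A [genetic_code()] object.
#' @return The amino acid (three-letter code) or `"STOP"`.
#' @examples
#' translate_codon("ATG")  # "Met"
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  aa <- code$codon_to_aa[codon]
  if (anyNA(aa)) {
    stop("untranslatable codon(s): ",
         paste(codon[is.na(aa)], collapse = ", "))
  }
  unname(aa)
}
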