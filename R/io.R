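# Corpus input: FASTA + metadata TSVs, species-level filtering and
# train/test partitioning.

#' Create a species collection
#'
#' @param species_id Species identifier.
#' @param records List of [cds_record()]s, all sharing `species_id`.
#' @param domain Domain-of-life label (`"Archaea"`, `"Bacteria"`,
#'   `"Eukarya"`) or `NA`. Labels always come from metadata, never from
#'   inference.
#' @param phylum Phylum label or `NA`.
#' @return A list of class `species_collection`.
#' @export
species_collection <- function(species_id, records,
                               domain = NA_character_,
                               phylum = NA_character_) {
  structure(
    list(species_id = as.character(species_id),
         domain = as.character(domain),
         phylum = as.character(phylum),
         records = records),
    class = "species_collection"
  )
}

#' @export
print.species_collection <- function(x, ...) {
  cat("species_collection '", x$species_id, "' (", x$domain, "): ",
      length(x$records), " CDS records\n", sep = "")
  invisible(x)
}

#' Read a CDS corpus from FASTA plus metadata tables
#'
#' Sequences are grouped into species collections using a sequence-level
#' metadata table (`seq_id`, `species_id`) and a species-level table
#' (`species_id`, `domain`, `phylum`). Sequences without metadata are
#' dropped with a message; duplicate `seq_id`s are an error.
#'
#' @param fasta_path Multi-record FASTA of coding sequences (wrapped or
#'   unwrapped).
#' @param seq_metadata_path TSV with header columns `seq_id`, `species_id`.
#' @param species_metadata_path TSV with header columns `species_id`,
#'   `domain`, `phylum`.
#' @return List of [species_collection()] objects, in order of first
#'   appearance of each species in the metadata.
#' @export
read_corpus <- function(fasta_path, seq_metadata_path,
                        species_metadata_path = NULL) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids)) {
    stop("duplicate seq_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seq_meta <- utils::read.delim(seq_metadata_path, stringsAsFactors = FALSE)
  stopifnot(all(c("seq_id", "species_id") %in% names(seq_meta)))
  if (anyDuplicated(seq_meta$seq_id)) stop("duplicate seq_id in metadata")
  sp_meta <- if (!is.null(species_metadata_path)) {
    m <- utils::read.delim(species_metadata_path, stringsAsFactors = FALSE)
    stopifnot(all(c("species_id", "domain", "phylum") %in% names(m)))
    m
  } else {
    data.frame(species_id = unique(seq_meta$species_id),
               domain = NA_character_, phylum = NA_character_)
  }
  known <- ids %in% seq_meta$seq_id
  if (any(!known)) {
    message(sum(!known), " sequence(s) absent from metadata; dropped")
  }
  if (!any(known)) return(list())
  seqs <- stats::setNames(as.character(dss)[known], ids[known])
  sp_of <- stats::setNames(seq_meta$species_id, seq_meta$seq_id)[names(seqs)]
  out <- lapply(unique(seq_meta$species_id[seq_meta$seq_id %in% names(seqs)]),
                function(sp) {
    sid <- names(seqs)[sp_of == sp]
    recs <- lapply(sid, function(i) cds_record(i, seqs[[i]], species_id = sp))
    row <- sp_meta[match(sp, sp_meta$species_id), ]
    species_collection(sp, recs,
                       domain = if (nrow(row)) row$domain else NA,
                       phylum = if (nrow(row)) row$phylum else NA)
  })
  out
}

#' Drop sparsely represented species
#'
#' Keeps species with strictly more than `min_genes` CDS records, so that
#' species represented by only a few (possibly biased) sequences do not
#' distort pooled statistics.
#'
#' @param collections List of [species_collection()]s.
#' @param min_genes Threshold; a species is kept iff it has `> min_genes`
#'   records (strict inequality). Default 1000.
#' @return The filtered list, original order preserved.
#' @export
filter_species <- function(collections, min_genes = 1000L) {
  stopifnot(min_genes >= 0L)
  keep <- vapply(collections, function(x) length(x$records), 1L) > min_genes
  collections[keep]
}

#' Split a corpus into training and test sequences
#'
#' Uniform random split at the sequence level by default (each CDS assigned
#' independently of its species); `level = "species"` assigns whole species
#' to one side, for leakage-controlled evaluation.
#'
#' @param collections List of [species_collection()]s.
#' @param train_fraction Fraction of sequences (or species) assigned to
#'   training; default 0.10.
#' @param seed Integer seed; the partition is reproducible.
#' @param level `"sequence"` (default) or `"species"`.
#' @return A list of class `corpus_partition` with `train` and `test`
#'   (seq_id vectors), `seed`, `train_fraction`. The training-set size is
#'   `round(N * train_fraction)`.
#' @export
split_train_test <- function(collections, train_fraction = 0.10, seed,
                             level = c("sequence", "species")) {
  level <- match.arg(level)
  stopifnot(train_fraction > 0, train_fraction < 1)
  ids_by_sp <- lapply(collections, function(x)
    vapply(x$records, `[[`, "", "seq_id"))
  all_ids <- unlist(ids_by_sp, use.names = FALSE)
  set.seed(as.integer(seed))
  if (level == "sequence") {
    n_train <- round(length(all_ids) * train_fraction)
    train <- sort(sample(all_ids, n_train))
  } else {
    sp <- vapply(collections, `[[`, "", "species_id")
    n_train <- round(length(sp) * train_fraction)
    train_sp <- sample(sp, n_train)
    train <- sort(unlist(ids_by_sp[sp %in% train_sp], use.names = FALSE))
  }
  structure(
    list(train = train,
         test = sort(setdiff(all_ids, train)),
         seed = as.integer(seed),
         train_fraction = train_fraction,
         level = level),
    class = "corpus_partition"
  )
}

#' @export
print.corpus_partition <- function(x, ...) {
  cat("corpus_partition:", length(x$train), "train /", length(x$test),
      "test (fraction", x$train_fraction, ", level", x$level, ")\n")
  invisible(x)
}

# All records of a list of collections, flattened.
corpus_records <- function(collections) {
  unlist(lapply(collections, `[[`, "records"), recursive = FALSE)
}

# seq_id -> sequence character vector for a list of collections.
corpus_sequences <- function(collections) {
  recs <- corpus_records(collections)
  stats::setNames(vapply(recs, `[[`, "", "sequence"),
                  vapply(recs, `[[`, "", "seq_id"))
}
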