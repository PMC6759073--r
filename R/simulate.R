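# Seeded simulator of multi-species CDS corpora with the statistical
# structure the analysis stack assumes: a GC gradient shared across
# domains, domain-specific arginine codon signatures, expression-coupled
# codon optimality, and tunable same-amino-acid codon-pair stickiness.

#' Reference amino-acid composition
#'
#' A single fixed composition (approximate averages over well-annotated
#' proteomes) used for every simulated species, so that codon-level effects
#' are isolated from amino-acid-level ones.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
aa_composition <- function() {
  x <- c(Ala = 8.3, Arg = 5.5, Asn = 4.1, Asp = 5.5, Cys = 1.4,
         Gln = 3.9, Glu = 6.8, Gly = 7.1, His = 2.3, Ile = 6.0,
         Leu = 9.7, Lys = 5.8, Met = 2.4, Phe = 3.9, Pro = 4.7,
         Ser = 6.6, Thr = 5.4, Trp = 1.1, Tyr = 2.9, Val = 6.9)
  x / sum(x)
}

# G+C count of each of the 64 codons.
codon_gc_counts <- function() {
  cods <- all_codons()
  stats::setNames(nchar(gsub("[^GC]", "", cods)), cods)
}

# GC response weight per codon: third (synonymous) position counts double,
# since mutational GC pressure acts most freely there. Within every
# synonymous family this makes GC-ended codons respond strictly more than
# AT-ended ones.
codon_gc_response <- function() {
  cods <- all_codons()
  first2 <- nchar(gsub("[^GC]", "", substring(cods, 1, 2)))
  third <- as.integer(substring(cods, 3, 3) %in% c("G", "C"))
  stats::setNames(first2 + 2 * third, cods)
}

#' Specification of one simulated species
#'
#' @param species_id Identifier.
#' @param domain Domain label carried into the metadata.
#' @param gc_target Target genomic GC fraction; codon choice within each
#'   family is weighted as if bases were drawn independently with
#'   `P(G or C) = gc_target`.
#' @param arginine_profile Named relative weights over the six arginine
#'   codons (canonical order `AGA, AGG, CGA, CGC, CGG, CGT`); arginine
#'   usage follows this profile regardless of expression.
#' @param optimal_set Named character vector, amino acid to its designated
#'   optimal codon; these codons take over as expression rises. Families
#'   absent from the set (always including Arg here) keep their baseline
#'   usage at all expression levels.
#' @param nonoptimal_set Named character vector, amino acid to the codon
#'   preferred at low expression; these codons take over as expression
#'   falls, so codon preferences reverse along the expression gradient
#'   (when `NULL`, low-expression genes simply use the baseline).
#' @param stickiness Probability, at each repeated occurrence of an amino
#'   acid within a gene, of reusing the codon chosen at the previous
#'   occurrence (plants autocorrelation). In `[0, 1]`.
#' @param n_genes Genes to simulate.
#' @param gene_length_range Range of gene lengths in nt (multiples of 3
#'   are enforced); default 300--1500 nt.
#' @param expression_spread Standard deviation of log abundance (natural
#'   log); default 1.5.
#' @param coupling Total weight of the expression-coupled point masses:
#'   codon probabilities are
#'   `(1 - coupling) * baseline + coupling * (e * optimal + (1 - e) * nonoptimal)`
#'   with `e` the min-max scaled log abundance, so the interpolation is
#'   linear in log abundance and preferences reverse between the extremes.
#'   Default 0.9. Without a `nonoptimal_set` the low-expression term is
#'   replaced by baseline usage.
#' @param nonoptimal_boost Baseline weight multiplier of the
#'   low-expression preferred codon; default 1 (no extra boost — the
#'   coupling itself plants the low-expression preference).
#' @param domain_bias Named character vector (amino acid to codon) of
#'   mildly favored codons shared by the species' domain, and
#'   `domain_bias_boost` their weight multiplier (default 1.25).
#' @param domain_bias_boost See `domain_bias`.
#' @param seed Integer seed; regeneration is byte-identical.
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(species_id, domain = NA_character_,
                         gc_target = 0.5,
                         arginine_profile = NULL,
                         optimal_set = NULL,
                         nonoptimal_set = NULL,
                         stickiness = 0,
                         n_genes = 100L,
                         gene_length_range = c(300L, 1500L),
                         expression_spread = 1.5,
                         coupling = 0.9,
                         nonoptimal_boost = 1,
                         domain_bias = character(0),
                         domain_bias_boost = 1.25,
                         seed = 1L) {
  code <- genetic_code()
  fam_arg <- code$families$Arg
  if (is.null(arginine_profile)) {
    arginine_profile <- stats::setNames(rep(1, 6), fam_arg)
  }
  stopifnot(setequal(names(arginine_profile), fam_arg),
            all(arginine_profile >= 0), sum(arginine_profile) > 0,
            stickiness >= 0, stickiness <= 1,
            gc_target > 0, gc_target < 1)
  structure(
    list(species_id = as.character(species_id), domain = domain,
         gc_target = gc_target,
         arginine_profile = arginine_profile[fam_arg],
         optimal_set = optimal_set, nonoptimal_set = nonoptimal_set,
         stickiness = stickiness, n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         expression_spread = expression_spread, coupling = coupling,
         nonoptimal_boost = nonoptimal_boost,
         domain_bias = domain_bias,
         domain_bias_boost = domain_bias_boost,
         seed = as.integer(seed)),
    class = "species_spec"
  )
}

# Domain arginine signatures (canonical order AGA, AGG, CGA, CGC, CGG, CGT):
# Archaea AGA/AGG-heavy, Bacteria CGC/CGT-heavy, Eukarya intermediate.
domain_arginine_profiles <- function() {
  list(
    Archaea = c(AGA = 0.48, AGG = 0.34, CGA = 0.04, CGC = 0.04,
                CGG = 0.04, CGT = 0.06),
    Bacteria = c(AGA = 0.04, AGG = 0.02, CGA = 0.06, CGC = 0.40,
                 CGG = 0.08, CGT = 0.40),
    Eukarya = c(AGA = 0.24, AGG = 0.22, CGA = 0.11, CGC = 0.16,
                CGG = 0.19, CGT = 0.08)
  )
}

#' Default three-domain species specifications
#'
#' Builds `n_species_per_domain` specs per domain with (a) GC targets
#' jittered over a range shared by all domains (so GC cannot separate
#' them), (b) the domain arginine signatures of
#' [domain_arginine_profiles()] with mild per-species jitter, and (c) a
#' mild domain-consistent codon bias in the other families.
#'
#' @param n_species_per_domain Species per domain (>= 1).
#' @param seed Integer seed.
#' @param n_genes Genes per species; default 100.
#' @param gc_range Shared GC range; default `c(0.30, 0.70)`.
#' @param stickiness Codon-pair stickiness for every species; default 0.
#' @param profile_jitter Log-normal sd of the per-species multiplicative
#'   jitter on the arginine profile; default 0.10.
#' @param ... Further arguments passed to [species_spec()].
#' @return List of `species_spec`s (3 x `n_species_per_domain`).
#' @export
default_domain_specs <- function(n_species_per_domain, seed = 1L,
                                 n_genes = 100L, gc_range = c(0.30, 0.70),
                                 stickiness = 0, profile_jitter = 0.10,
                                 ...) {
  stopifnot(n_species_per_domain >= 1L)
  code <- genetic_code()
  profiles <- domain_arginine_profiles()
  domains <- names(profiles)
  fams <- setdiff(names(code$families)[
    vapply(code$families, length, 1L) >= 2L], "Arg")
  set.seed(as.integer(seed))
  specs <- list()
  for (d in seq_along(domains)) {
    dom <- domains[d]
    # fixed mild per-domain preference in non-arginine families
    bias <- vapply(seq_along(fams), function(i) {
      fam <- code$families[[fams[i]]]
      fam[((i + d) %% length(fam)) + 1L]
    }, "")
    names(bias) <- fams
    for (i in seq_len(n_species_per_domain)) {
      gc <- stats::runif(1, gc_range[1], gc_range[2])
      prof <- profiles[[dom]] * exp(stats::rnorm(6, 0, profile_jitter))
      prof <- prof / sum(prof)
      # optimal/nonoptimal codons are drawn from the species' own
      # GC-calibrated baseline usage (computed without the expression
      # coupling), so the expression-optimality point masses do not pull
      # the corpus off its GC target
      base_spec <- species_spec(
        species_id = "calibration", domain = dom, gc_target = gc,
        arginine_profile = prof, optimal_set = NULL,
        nonoptimal_set = NULL, domain_bias = bias, ...)
      bw0 <- suppressWarnings(baseline_family_weights(base_spec, code))
      opt <- vapply(fams, function(a)
        sample(code$families[[a]], 1L, prob = bw0[[a]]), "")
      nonopt <- vapply(fams, function(a)
        sample(code$families[[a]], 1L, prob = bw0[[a]]), "")
      specs[[length(specs) + 1L]] <- species_spec(
        species_id = sprintf("%s_%02d", tolower(dom), i),
        domain = dom, gc_target = gc, arginine_profile = prof,
        optimal_set = opt, nonoptimal_set = nonopt,
        stickiness = stickiness, n_genes = n_genes,
        domain_bias = bias,
        seed = sample.int(.Machine$integer.max, 1L), ...)
    }
  }
  specs
}

# Preference (non-GC) within-family codon weights for one species:
# arginine profile, mild domain bias, low-expression preferred codon.
preference_weights <- function(spec, code = genetic_code()) {
  fams <- names(code$families)[vapply(code$families, length, 1L) >= 2L]
  out <- lapply(fams, function(a) {
    fam <- code$families[[a]]
    w <- stats::setNames(rep(1, length(fam)), fam)
    if (a == "Arg") {
      # the planted profile, with only a weak third-position GC preference
      # (the domain signature itself resists GC pressure)
      g <- spec$gc_target
      third_gc <- substring(fam, 3, 3) %in% c("G", "C")
      w <- spec$arginine_profile[fam] * (g / (1 - g))^(0.5 * third_gc)
    } else {
      if (a %in% names(spec$domain_bias)) {
        w[spec$domain_bias[[a]]] <- w[spec$domain_bias[[a]]] *
          spec$domain_bias_boost
      }
      if (a %in% names(spec$nonoptimal_set)) {
        w[spec$nonoptimal_set[[a]]] <- w[spec$nonoptimal_set[[a]]] *
          spec$nonoptimal_boost
      }
    }
    w / sum(w)
  })
  names(out) <- fams
  out
}

# Baseline within-family codon weights: preference weights times a
# GC factor exp(beta * nGC), with beta calibrated so the corpus-average
# expected GC matches gc_target (best effort at the attainable boundary).
baseline_family_weights <- function(spec, code = genetic_code()) {
  pref <- preference_weights(spec, code)
  gcn <- codon_gc_counts()
  gcr <- codon_gc_response()
  comp <- aa_composition()
  # Arginine keeps its planted profile: the domain-specific arginine
  # signature resists GC pressure (that robustness is what makes it a
  # usable domain marker), so its GC response is zero.
  damp <- function(a) if (a == "Arg") 0 else 1
  # corpus-average codon distribution: scaled log abundance averages 0.5
  expected_gc <- function(beta) {
    per_aa <- vapply(names(comp), function(a) {
      fam <- code$families[[a]]
      if (length(fam) == 1L) return(unname(gcn[fam]))
      w <- pref[[a]] * exp(damp(a) * beta * gcr[fam])
      p <- coupled_family_prob(spec, a, w / sum(w), fam, 0.5)
      sum(p * gcn[fam])
    }, 0)
    sum(comp * per_aa) / 3
  }
  lo <- expected_gc(-8); hi <- expected_gc(8)
  warn_miss <- function(bound) {
    if (abs(spec$gc_target - bound) > 0.02) {
      warning("gc_target ", round(spec$gc_target, 3),
              " outside the attainable range [", round(lo, 3), ", ",
              round(hi, 3), "]; best effort")
    }
  }
  beta <- if (spec$gc_target <= lo) {
    warn_miss(lo)
    -8
  } else if (spec$gc_target >= hi) {
    warn_miss(hi)
    8
  } else {
    stats::uniroot(function(b) expected_gc(b) - spec$gc_target,
                   c(-8, 8), tol = 1e-6)$root
  }
  out <- lapply(names(pref), function(a) {
    fam <- code$families[[a]]
    w <- pref[[a]] * exp(damp(a) * beta * gcr[fam])
    w / sum(w)
  })
  names(out) <- names(pref)
  out
}

#' Generate one species' CDS set
#'
#' For each gene: a length and a log-normal abundance are drawn; amino
#' acids are drawn from [aa_composition()]; each codon is drawn from its
#' family distribution, which interpolates linearly (in scaled log
#' abundance) between the species baseline and a point mass on the
#' family's optimal codon; with probability `stickiness` a repeated
#' occurrence of an amino acid reuses the previous codon. An ATG start and
#' TAA stop are added.
#'
#' @param spec A [species_spec()].
#' @param code A [genetic_code()] object.
#' @return A list: `collection` (a [species_collection()]), `abundance`
#'   (data frame `gene_id`, `abundance`), `ground_truth` (list with
#'   `optimal_set`, `low_argmax`, `high_argmax`, `switch` per amino acid,
#'   and `stickiness`).
#' @export
generate_species <- function(spec, code = genetic_code()) {
  set.seed(spec$seed)
  comp <- aa_composition()
  base_w <- baseline_family_weights(spec, code)
  single <- names(code$families)[vapply(code$families, length, 1L) == 1L]
  single_codon <- vapply(code$families[single], `[`, "", 1L)
  n <- spec$n_genes
  len_codons <- sample(
    seq(spec$gene_length_range[1] %/% 3L, spec$gene_length_range[2] %/% 3L),
    n, replace = TRUE)
  abundance <- exp(stats::rnorm(n, mean = log(100),
                                sd = spec$expression_spread))
  la <- log(abundance)
  e <- if (diff(range(la)) > 0) (la - min(la)) / diff(range(la))
       else rep(0.5, n)
  seqs <- character(n)
  for (gi in seq_len(n)) {
    aas <- sample(names(comp), len_codons[gi], replace = TRUE, prob = comp)
    codons <- character(length(aas))
    for (a in unique(aas)) {
      idx <- which(aas == a)
      if (a %in% single) {
        codons[idx] <- single_codon[[a]]
        next
      }
      fam <- code$families[[a]]
      p <- coupled_family_prob(spec, a, base_w[[a]], fam, e[gi])
      fresh <- sample(fam, length(idx), replace = TRUE, prob = p)
      if (spec$stickiness > 0 && length(idx) > 1L) {
        keep <- stats::runif(length(idx)) < spec$stickiness
        keep[1L] <- FALSE
        anchor <- cummax(ifelse(keep, 0L, seq_along(idx)))
        fresh <- fresh[anchor]
      }
      codons[idx] <- fresh
    }
    seqs[gi] <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  }
  ids <- sprintf("%s_g%04d", spec$species_id, seq_len(n))
  records <- lapply(seq_len(n), function(i)
    cds_record(ids[i], seqs[i], species_id = spec$species_id))
  gt <- species_ground_truth(spec, base_w, code)
  list(
    collection = species_collection(spec$species_id, records,
                                    domain = spec$domain),
    abundance = data.frame(gene_id = ids, abundance = abundance),
    ground_truth = gt
  )
}

# Family codon probabilities for one gene at scaled log abundance e:
# linear interpolation between the low-expression preferred codon and the
# optimal codon, around the species baseline.
coupled_family_prob <- function(spec, a, base, fam, e) {
  if (is.null(spec$optimal_set) || !a %in% names(spec$optimal_set)) {
    return(base)
  }
  oh_opt <- stats::setNames(as.numeric(fam == spec$optimal_set[[a]]), fam)
  if (!is.null(spec$nonoptimal_set) && a %in% names(spec$nonoptimal_set)) {
    oh_non <- stats::setNames(as.numeric(fam == spec$nonoptimal_set[[a]]),
                              fam)
    (1 - spec$coupling) * base +
      spec$coupling * (e * oh_opt + (1 - e) * oh_non)
  } else {
    m <- spec$coupling * e
    (1 - m) * base + m * oh_opt
  }
}

# Planted truth: low- and high-expression argmax codons and switch flag
# per multi-codon family, derived analytically from the generator weights.
species_ground_truth <- function(spec, base_w, code) {
  fams <- names(base_w)
  low <- vapply(fams, function(a) {
    p <- coupled_family_prob(spec, a, base_w[[a]], code$families[[a]], 0)
    names(base_w[[a]])[which.max(p)]
  }, "")
  high <- vapply(fams, function(a) {
    p <- coupled_family_prob(spec, a, base_w[[a]], code$families[[a]], 1)
    names(base_w[[a]])[which.max(p)]
  }, "")
  list(optimal_set = as.list(spec$optimal_set),
       low_argmax = as.list(low),
       high_argmax = as.list(high),
       switch = as.list(low != high),
       stickiness = spec$stickiness,
       gc_target = spec$gc_target)
}

#' Generate a full corpus and (optionally) write it to disk
#'
#' Runs [generate_species()] for every spec and assembles the corpus. When
#' `dir` is given, writes exactly the inputs the reading and optimality
#' stages consume: `corpus.fasta`, `seq_metadata.tsv` (`seq_id`,
#' `species_id`), `species_metadata.tsv` (`species_id`, `domain`,
#' `phylum`), `abundance.tsv` (`gene_id`, `abundance`) and a ground-truth
#' manifest `ground_truth.json`.
#'
#' @param specs List of [species_spec()]s (non-empty). Per-species seeds
#'   live in the specs, so regeneration is byte-identical.
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param code A [genetic_code()] object.
#' @return A list of class `synthetic_corpus`: `collections`, `abundance`
#'   (pooled data frame), `ground_truth` (named by species), `paths`
#'   (when written).
#' @export
generate_corpus <- function(specs, dir = NULL, code = genetic_code()) {
  stopifnot(length(specs) >= 1L)
  parts <- lapply(specs, generate_species, code = code)
  collections <- lapply(parts, `[[`, "collection")
  abundance <- do.call(rbind, lapply(parts, `[[`, "abundance"))
  gt <- lapply(parts, `[[`, "ground_truth")
  names(gt) <- vapply(specs, `[[`, "", "species_id")
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "corpus.fasta"),
      seq_metadata = file.path(dir, "seq_metadata.tsv"),
      species_metadata = file.path(dir, "species_metadata.tsv"),
      abundance = file.path(dir, "abundance.tsv"),
      ground_truth = file.path(dir, "ground_truth.json"))
    recs <- corpus_records(collections)
    write_fasta(stats::setNames(vapply(recs, `[[`, "", "sequence"),
                                vapply(recs, `[[`, "", "seq_id")),
                paths$fasta)
    utils::write.table(
      data.frame(seq_id = vapply(recs, `[[`, "", "seq_id"),
                 species_id = vapply(recs, `[[`, "", "species_id")),
      paths$seq_metadata, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(
        species_id = vapply(collections, `[[`, "", "species_id"),
        domain = vapply(collections, `[[`, "", "domain"),
        phylum = "unknown"),
      paths$species_metadata, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(abundance, paths$abundance, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  structure(
    list(collections = collections, abundance = abundance,
         ground_truth = gt, paths = paths),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("synthetic_corpus:", length(x$collections), "species,",
      sum(vapply(x$collections, function(s) length(s$records), 1L)),
      "CDS records\n")
  invisible(x)
}

# Plain 60-column-wrapped FASTA writer (byte-stable output).
write_fasta <- function(named_seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(named_seqs)) {
    writeLines(paste0(">", names(named_seqs)[i]), con)
    s <- named_seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
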