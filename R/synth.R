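## Synthetic community generator. Emulates the structure of a cellulose-rich
## alkaline niche: ~6 dominant genera spanning >= 3 phyla, log-normal
## abundances, genomes carrying or lacking the cellulolytic pathway genes
## and the two cellodextrin transporter families, one 16S rRNA locus per
## genome, and sheared contigs straddling the 300 / 1000 bp thresholds.

#' Construct a genome specification
#'
#' @param genus genus name (must exist in the taxonomy used downstream).
#' @param length genome length in bp.
#' @param gc GC fraction in (0, 1).
#' @param role truth role: `"helper"`, `"beneficiary"` or
#'   `"non_participant"`.
#' @param cassette character vector of role features (see
#'   [role_features()]) carried by the genome.
#' @param transition optional 4x4 order-1 nucleotide transition matrix
#'   (rows A,C,G,T summing to 1); defaults to the i.i.d. matrix implied by
#'   `gc`.
#' @param cassette_identity amino-acid identity of planted cassette genes
#'   to their genus reference proteins.
#' @param n_copies number of planted copies of each cassette gene.
#' @param s16_template_id genus whose packaged 16S template seeds the
#'   genome's 16S locus (defaults to `genus`).
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(genus, length = 50000L, gc = 0.5, role = "non_participant",
                        cassette = character(0), transition = NULL,
                        cassette_identity = 0.90, n_copies = 2L,
                        s16_template_id = genus) {
  stopifnot(gc > 0, gc < 1, length > 0)
  role <- match.arg(role, c("helper", "beneficiary", "non_participant"))
  if (!all(cassette %in% role_features()))
    stop("unknown cassette feature(s): ",
         paste(setdiff(cassette, role_features()), collapse = ", "))
  if (role == "helper" && !("endoglucanase" %in% cassette))
    stop("helper cassette must include endoglucanase")
  if (role == "beneficiary" && "endoglucanase" %in% cassette)
    stop("beneficiary cassette must not include endoglucanase")
  if (is.null(transition)) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    transition <- matrix(rep(p, each = 4), 4, 4,
                         dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  }
  if (any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0))
    stop("transition matrix must be row-stochastic")
  structure(list(genus = genus, length = as.integer(length), gc = gc,
                 role = role, cassette = cassette, transition = transition,
                 cassette_identity = cassette_identity,
                 n_copies = as.integer(n_copies),
                 s16_template_id = s16_template_id),
            class = "genome_spec")
}

#' Genus-specific nucleotide transition matrix
#'
#' An order-1 transition matrix whose stationary composition approximates
#' the target GC while carrying a reproducible genus-specific dinucleotide
#' bias — the oligonucleotide "genomic signature" that composition-based
#' binning exploits. The bias pattern is a fixed function of the genus
#' name.
#'
#' @param genus genus name (seeds the bias pattern).
#' @param gc target GC fraction.
#' @param strength relative magnitude of the dinucleotide bias.
#' @return 4x4 row-stochastic matrix (rows/cols A, C, G, T).
#' @export
genus_transition <- function(genus, gc = 0.5, strength = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  B <- with_seed(derive_seed(0L, paste0("signature:", genus)),
                 matrix(runif(16, -1, 1), 4, 4))
  m <- sweep(1 + strength * B, 2, p, "*")
  m <- m / rowSums(m)
  dimnames(m) <- list(names(p), names(p))
  m
}

#' Default genome specifications of the emulated community
#'
#' Six dominant genera with the gene cassettes reported for the niche: two
#' helpers carrying endoglucanase (one with PTS transporters, one with no
#' recognized transporter), four beneficiaries carrying only downstream
#' assimilation genes (one of them transporter-less). GC contents are
#' spaced ~0.07 apart so composition-based binning is exercisable.
#'
#' @param length genome length in bp applied to every spec.
#' @return named list of `genome_spec` objects.
#' @export
default_genome_specs <- function(length = 50000L) {
  mk <- function(genus, gc, role, cassette)
    genome_spec(genus, length = length, gc = gc, role = role,
                cassette = cassette,
                transition = genus_transition(genus, gc))
  list(
    Clostridium = mk("Clostridium", 0.30, "helper",
      c("endoglucanase", "beta_glucosidase", "six_phospho_beta_glucosidase",
        "pts_cel")),
    Cloacibacterium = mk("Cloacibacterium", 0.37, "beneficiary",
      c("beta_glucosidase", "six_phospho_beta_glucosidase")),
    Paludibacter = mk("Paludibacter", 0.44, "helper",
      c("endoglucanase", "beta_glucosidase", "cellobiose_phosphorylase")),
    Exiguobacterium = mk("Exiguobacterium", 0.51, "beneficiary",
      c("beta_glucosidase", "six_phospho_beta_glucosidase", "pts_cel")),
    Tolumonas = mk("Tolumonas", 0.58, "beneficiary",
      c("beta_glucosidase", "six_phospho_beta_glucosidase", "pts_cel")),
    Acetivibrio = mk("Acetivibrio", 0.65, "beneficiary",
      c("beta_glucosidase", "six_phospho_beta_glucosidase", "abc_ceb")))
}

## Sample an order-1 Markov chain. The common i.i.d. case (all rows equal)
## is vectorized; general chains fall back to a per-base loop.
markov_dna <- function(n, transition) {
  bases <- c("A", "C", "G", "T")
  if (all(abs(sweep(transition, 2, transition[1, ])) < 1e-12)) {
    return(paste(sample(bases, n, replace = TRUE, prob = transition[1, ]),
                 collapse = ""))
  }
  cum <- t(apply(transition, 1, cumsum))
  out <- integer(n)
  out[1] <- sample(1:4, 1, prob = colSums(transition) / 4)
  u <- runif(n)
  for (i in 2:n) out[i] <- findInterval(u[i], cum[out[i - 1], ]) + 1L
  paste(bases[out], collapse = "")
}

#' Simulate a truth-labeled genome
#'
#' Draws a backbone from the genus nucleotide transition matrix, plants one
#' 16S rRNA locus copied from the packaged genus template (per-base
#' substitution at `s16_divergence`, conserved primer sites protected), and
#' inserts every cassette gene as a coding region (`ATG ... stop`) whose
#' translation is a diverged copy of the genus reference protein,
#' reverse-translated with GC-biased synonymous codons. Features never
#' overlap each other or the 16S locus; minus-strand features are stored on
#' forward coordinates with a strand flag. Deterministic per (spec, seed).
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @param s16_divergence per-base substitution rate applied to the 16S
#'   template copy.
#' @param ref packaged reference data (default [reference_data()]).
#' @return object of class `synthetic_genome`: list with `id`, `sequence`,
#'   `features` (data.frame: `feature`, `start`, `end` 0-based half-open,
#'   `strand`), `genus`, `role`.
#' @export
simulate_genome <- function(spec, seed, s16_divergence = 0.01,
                            ref = reference_data()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(derive_seed(seed, paste0("genome:", spec$genus)), {
    tmpl <- ref$s16_templates[[spec$s16_template_id]]
    if (is.null(tmpl)) stop("no 16S template for ", spec$s16_template_id)
    protect <- c(seq(ref$s16_amp_start,
                     ref$s16_amp_start + 30L),
                 seq(ref$s16_amp_start + ref$s16_amp_len - 32L,
                     ref$s16_amp_start + ref$s16_amp_len - 1L))
    s16 <- mutate_dna(tmpl, s16_divergence, protect = protect)

    gene_feats <- cassette_gene_features(spec$cassette)
    refdb <- ref$refdb[ref$refdb$genus == spec$genus, ]
    inserts <- list(list(feature = "rrna_16S", seq = s16))
    for (f in rep(gene_feats, each = spec$n_copies)) {
      prot <- refdb$protein[refdb$feature == f]
      if (!length(prot)) prot <- mutate_protein(ref$feature_proteins[[f]], 0.80)
      gene_aa <- mutate_protein(prot[1], spec$cassette_identity)
      nt <- reverse_translate(gene_aa, gc = spec$gc)
      strand <- sample(c("+", "-"), 1)
      inserts[[length(inserts) + 1L]] <-
        list(feature = f, seq = if (strand == "-") revcomp(nt) else nt,
             strand = strand)
    }
    for (f in MARKER_GENES) {
      prot <- refdb$protein[refdb$feature == f]
      gene_aa <- mutate_protein(prot[1], spec$cassette_identity)
      nt <- reverse_translate(gene_aa, gc = spec$gc)
      strand <- sample(c("+", "-"), 1)
      inserts[[length(inserts) + 1L]] <-
        list(feature = f, seq = if (strand == "-") revcomp(nt) else nt,
             strand = strand)
    }

    lens <- vapply(inserts, function(x) nchar(x$seq), integer(1))
    slack <- spec$length - sum(lens)
    if (slack < length(lens) + 1L)
      stop("genome length ", spec$length,
           " too short to host cassette and 16S locus (need > ", sum(lens), ")")
    ## random non-overlapping layout: distribute slack into gaps
    gaps <- c(stats::rmultinom(1, slack, rep(1, length(lens) + 1L)))
    ord <- sample(seq_along(inserts))
    backbone <- markov_dna(spec$length, spec$transition)
    feats <- data.frame(feature = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
    pos <- 1L + gaps[1]
    for (k in seq_along(ord)) {
      ins <- inserts[[ord[k]]]
      L <- nchar(ins$seq)
      substr(backbone, pos, pos + L - 1L) <- ins$seq
      feats[nrow(feats) + 1L, ] <- list(ins$feature, pos - 1L, pos - 1L + L,
                                        ins$strand %||% "+")
      pos <- pos + L + gaps[k + 1L]
    }
    feats <- feats[order(feats$start), ]
    rownames(feats) <- NULL
    structure(list(id = spec$genus, sequence = backbone, features = feats,
                   genus = spec$genus, role = spec$role),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome", x$id, "-", nchar(x$sequence), "bp,",
      nrow(x$features), "features, role:", x$role, "\n")
  invisible(x)
}

#' Simulate per-sample community abundance profiles
#'
#' Per-sample abundances are drawn i.i.d. log-normal and normalized to sum
#' to one.
#'
#' @param genomes list of `synthetic_genome` objects (or anything with
#'   `$id`).
#' @param lognormal_params list with `meanlog` and `sdlog`.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return list of `community_profile` objects (`sample_id`, named
#'   `abundance` vector summing to 1).
#' @export
simulate_community <- function(genomes, lognormal_params = list(meanlog = 0, sdlog = 1),
                               n_samples = 2L, seed = 0L) {
  if (!length(genomes)) stop("need at least one genome")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  sdlog <- lognormal_params$sdlog
  if (is.null(sdlog) || sdlog < 0) stop("sdlog must be non-negative")
  ids <- vapply(genomes, function(g) g$id, character(1))
  with_seed(derive_seed(seed, "community"), {
    lapply(seq_len(n_samples), function(s) {
      x <- if (sdlog == 0) rep(exp(lognormal_params$meanlog %||% 0), length(ids))
      else rlnorm(length(ids), lognormal_params$meanlog %||% 0, sdlog)
      structure(list(sample_id = paste0("sample", s),
                     abundance = setNames(x / sum(x), ids)),
                class = "community_profile")
    })
  })
}

#' Shear genomes into truth-labeled contigs
#'
#' Contigs are substrings sampled from the genomes, either proportional to
#' a community profile (`n_contigs`) or a fixed number per genome
#' (`n_per_genome`). Lengths come from a two-component mixture straddling
#' the 300 and 1000 bp analysis thresholds.
#'
#' @param genomes list of `synthetic_genome` objects.
#' @param profile `community_profile` governing genome sampling weights
#'   (ignored when `n_per_genome` is given).
#' @param n_contigs total number of contigs.
#' @param length_distribution list with `min`, `max` and `frac_long`: a
#'   fraction `frac_long` of contigs is uniform on `[1000, max]`, the rest
#'   uniform on `[min, 1000)`.
#' @param seed integer seed.
#' @param n_per_genome optional fixed per-genome contig count.
#' @return object of class `contig_set`: list with `contigs` (data.frame
#'   `id`, `sequence`, `genome`, `start`, `end`) and `truth` (data.frame
#'   `contig`, `genus`, `role`).
#' @export
shear_contigs <- function(genomes, profile = NULL, n_contigs = 0L,
                          length_distribution = list(min = 400L, max = 4000L,
                                                     frac_long = 0.5),
                          seed = 0L, n_per_genome = NULL) {
  ld <- length_distribution
  if ((ld$min %||% 400L) < 300L) stop("length distribution support must be >= 300 bp")
  ids <- vapply(genomes, function(g) g$id, character(1))
  names(genomes) <- ids
  with_seed(derive_seed(seed, "shear"), {
    src <- if (!is.null(n_per_genome)) rep(ids, each = n_per_genome)
    else if (n_contigs > 0L) {
      if (is.null(profile)) stop("profile required when sampling by abundance")
      sample(ids, n_contigs, replace = TRUE, prob = profile$abundance[ids])
    } else character(0)
    n <- length(src)
    if (!n) {
      return(structure(list(
        contigs = data.frame(id = character(0), sequence = character(0),
                             genome = character(0), start = integer(0),
                             end = integer(0)),
        truth = data.frame(contig = character(0), genus = character(0),
                           role = character(0))), class = "contig_set"))
    }
    long <- runif(n) < (ld$frac_long %||% 0.5)
    len <- ifelse(long,
                  floor(runif(n, 1000, (ld$max %||% 4000L) + 1)),
                  floor(runif(n, ld$min %||% 400L, 1000)))
    glen <- vapply(src, function(id) nchar(genomes[[id]]$sequence), integer(1))
    if (any(len > glen))
      stop("requested contig length exceeds genome length")
    start <- floor(runif(n, 1, glen - len + 1))  # 1-based
    seqs <- vapply(seq_len(n), function(i)
      substr(genomes[[src[i]]]$sequence, start[i], start[i] + len[i] - 1L),
      character(1))
    contigs <- data.frame(
      id = sprintf("contig_%05d", seq_len(n)), sequence = seqs,
      genome = src, start = as.integer(start - 1L),
      end = as.integer(start - 1L + len))
    truth <- data.frame(
      contig = contigs$id, genus = vapply(src, function(id) genomes[[id]]$genus,
                                          character(1)),
      role = vapply(src, function(id) genomes[[id]]$role, character(1)))
    rownames(truth) <- NULL
    structure(list(contigs = contigs, truth = truth), class = "contig_set")
  })
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set:", nrow(x$contigs), "contigs from",
      length(unique(x$contigs$genome)), "genomes\n")
  invisible(x)
}
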