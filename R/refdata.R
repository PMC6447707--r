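## Packaged synthetic reference sets.
##
## All reference material (toy reference proteins per functional feature and
## per GH/CBM family, position-specific scoring profiles with calibrated
## thresholds, 16S rRNA gene templates and labeled training sequences) is
## generated deterministically from a fixed internal seed, so the package is
## fully self-contained. The sequences are synthetic stand-ins for the
## curated databases a production analysis would use (CAZy/dbCAN seeds,
## transporter references, RDP training sets); they reproduce the
## *structure* of those resources, not their content.

REFDATA_SEED <- 20190328L  # fixed; reference sets are constants, not dials

.cellucoop_cache <- new.env(parent = emptyenv())

#' The 13 glycoside hydrolase families containing cellulases
#'
#' The fixed set of GH families in which cellulases (notably
#' endoglucanases) have been found: GH5-GH9, GH12, GH44, GH45, GH48, GH51,
#' GH61, GH74 and GH124.
#'
#' @return character vector of 13 family labels.
#' @examples
#' length(cellulase_families())
#' @export
cellulase_families <- function() {
  c("GH5", "GH6", "GH7", "GH8", "GH9", "GH12", "GH44", "GH45", "GH48",
    "GH51", "GH61", "GH74", "GH124")
}

## Extra (non-cellulase) GH families used by downstream enzymes, CBM types
## of the representative domain architectures, and universal single-copy
## marker genes.
EXTRA_GH_FAMILIES <- c("GH1", "GH3", "GH94")
CBM_FAMILIES <- c("CBM6", "CBM_X2", "CBM36", "CBM11", "CBM17_18", "CBM30")
MARKER_GENES <- sprintf("marker%02d", 1:10)

## Functional marker labels: EC activities + the two characterized
## cellodextrin transporter families.
EC_ENDOGLUCANASE <- "EC:3.2.1.4"
EC_BETA_GLUCOSIDASE <- "EC:3.2.1.21"
EC_6P_BETA_GLUCOSIDASE <- "EC:3.2.1.86"
LBL_CELLOBIOSE_PHOSPHORYLASE <- "cellobiose_phosphorylase"
PTS_LABELS <- c("PTS_CelA", "PTS_CelB", "PTS_CelC")
ABC_LABELS <- c("ABC_CebE", "ABC_CebF", "ABC_CebG", "ABC_MsiK")

#' The closed set of role-defining gene features
#'
#' @return character vector of the six feature labels used by the role
#'   classifier: endoglucanase, the three downstream assimilation
#'   activities, and the two cellodextrin transporter families.
#' @export
role_features <- function() {
  c("endoglucanase", "beta_glucosidase", "six_phospho_beta_glucosidase",
    "cellobiose_phosphorylase", "pts_cel", "abc_ceb")
}

## The two sequencing primers bracketing the amplified 16S region
## (degenerate IUPAC bases; forward includes the linker pad).
#' Amplification primers for the 16S v3-v4 region
#'
#' @return named character vector with `fwd` and `rev` primer sequences
#'   (IUPAC degenerate bases allowed).
#' @export
amplicon_primers <- function() {
  c(fwd = "TATGGTAATTGTGTGCCAGCMGCCGCGGTAA",
    rev = "AGTCAGTCAGCCGGACTACHVGGGTWTCTAAT")
}

## Resolve IUPAC degenerate bases to one concrete realization (first listed).
iupac_realize <- function(x) {
  map <- c(A = "A", C = "C", G = "G", T = "T", M = "A", R = "A", W = "A",
           S = "C", Y = "C", K = "G", V = "A", H = "A", D = "A", B = "C",
           N = "A")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(map[ch], collapse = "")
}

## --- construction ----------------------------------------------------------

build_refdata <- function() {
  with_seed(REFDATA_SEED, {
    tree <- default_taxonomy()
    genera <- tax_genera(tree)

    ## Domain seed proteins. GH catalytic domains 200-260 aa, CBMs 60-90 aa,
    ## marker genes and transporter subunits 140-170 aa.
    dom_seeds <- list()
    for (f in c(cellulase_families(), EXTRA_GH_FAMILIES))
      dom_seeds[[f]] <- random_protein(sample(200:260, 1))
    for (f in CBM_FAMILIES)
      dom_seeds[[f]] <- random_protein(sample(60:90, 1))
    for (f in MARKER_GENES)
      dom_seeds[[f]] <- random_protein(sample(140:170, 1))

    ## Functional marker seed regions (N-terminal accessory regions unique
    ## to each activity/transporter subunit).
    marker_labels <- c(EC_ENDOGLUCANASE, EC_BETA_GLUCOSIDASE,
                       EC_6P_BETA_GLUCOSIDASE, LBL_CELLOBIOSE_PHOSPHORYLASE,
                       PTS_LABELS, ABC_LABELS)
    mark_seeds <- list()
    for (f in marker_labels)
      mark_seeds[[f]] <- random_protein(sample(110:140, 1))

    lnk <- "GGSGGSGGS"
    ## Full-length reference protein per feature gene. The endoglucanase is
    ## the classic modular cellulase: catalytic GH9 domain + CBM30.
    feature_proteins <- list(
      endoglucanase = paste0(mark_seeds[[EC_ENDOGLUCANASE]], lnk,
                             dom_seeds[["GH9"]], lnk, dom_seeds[["CBM30"]]),
      beta_glucosidase = paste0(mark_seeds[[EC_BETA_GLUCOSIDASE]], lnk,
                                dom_seeds[["GH3"]]),
      six_phospho_beta_glucosidase =
        paste0(mark_seeds[[EC_6P_BETA_GLUCOSIDASE]], lnk, dom_seeds[["GH1"]]),
      cellobiose_phosphorylase =
        paste0(mark_seeds[[LBL_CELLOBIOSE_PHOSPHORYLASE]], lnk,
               dom_seeds[["GH94"]]))
    for (f in PTS_LABELS) feature_proteins[[f]] <- mark_seeds[[f]]
    for (f in ABC_LABELS) feature_proteins[[f]] <- mark_seeds[[f]]
    for (f in MARKER_GENES) feature_proteins[[f]] <- dom_seeds[[f]]

    ## Position-specific scoring profiles: domains + functional markers.
    profiles <- list()
    for (f in names(dom_seeds))
      profiles[[f]] <- build_profile(dom_seeds[[f]], n_copies = 8,
                                     identity = 0.85, n_null = 60)
    for (f in marker_labels)
      profiles[[f]] <- build_profile(mark_seeds[[f]], n_copies = 8,
                                     identity = 0.85, n_null = 60)

    ## Per-genus reference protein database (best-hit genus assignment).
    ## Each genus carries a diverged copy (~80% identity to the seed) of
    ## every feature protein of its gene cassette plus all marker genes.
    specs <- default_genome_specs()
    refdb <- data.frame(id = character(0), genus = character(0),
                        feature = character(0), protein = character(0))
    for (g in genera) {
      sp <- specs[[g]]
      feats <- if (is.null(sp)) MARKER_GENES else
        unique(c(cassette_gene_features(sp$cassette), MARKER_GENES))
      for (f in feats) {
        refdb[nrow(refdb) + 1L, ] <- list(
          id = paste0(g, "|", f), genus = g, feature = f,
          protein = mutate_protein(feature_proteins[[f]], 0.80))
      }
    }

    ## 16S templates: a 1500 nt global scaffold; each genus diverges ~10%
    ## outside the conserved primer-binding sites. The amplified region
    ## spans 420 nt between (and including) the primer sites.
    primers <- amplicon_primers()
    fwd_site <- iupac_realize(primers["fwd"])
    rev_site_rc <- revcomp(iupac_realize(primers["rev"]))
    scaffold <- random_dna(1500, gc = 0.53)
    amp_start <- 401L
    amp_len <- 420L
    substr(scaffold, amp_start, amp_start + nchar(fwd_site) - 1L) <- fwd_site
    substr(scaffold, amp_start + amp_len - nchar(rev_site_rc),
           amp_start + amp_len - 1L) <- rev_site_rc
    protect <- c(seq(amp_start, amp_start + nchar(fwd_site) - 1L),
                 seq(amp_start + amp_len - nchar(rev_site_rc),
                     amp_start + amp_len - 1L))
    templates <- setNames(vapply(genera, function(g)
      mutate_dna(scaffold, 0.10, protect = protect), character(1)), genera)

    ## Labeled 16S training set: 8 sequences per genus at ~99% identity to
    ## the genus template (>=97% pairwise intra-genus identity).
    ref16s <- do.call(rbind, lapply(genera, function(g) {
      data.frame(id = sprintf("%s_16S_%02d", g, 1:8), genus = g,
                 seq = vapply(1:8, function(i)
                   mutate_dna(templates[[g]], 0.01, protect = protect),
                   character(1)))
    }))

    attr(refdb, "wordsets") <- lapply(refdb$protein, protein_words)

    list(tree = tree, dom_seeds = dom_seeds, mark_seeds = mark_seeds,
         feature_proteins = feature_proteins, profiles = profiles,
         refdb = refdb, s16_scaffold = scaffold, s16_templates = templates,
         s16_amp_start = amp_start, s16_amp_len = amp_len, ref16s = ref16s)
  })
}

#' Packaged synthetic reference data
#'
#' Memoised accessor for the deterministic synthetic reference sets: the
#' default taxonomy, domain and functional-marker seed proteins, scoring
#' profiles with shuffle-calibrated thresholds, the per-genus reference
#' protein database, and 16S templates with a labeled training set.
#'
#' @return a list; see the package vignette for component descriptions.
#' @export
reference_data <- function() {
  if (is.null(.cellucoop_cache$refdata))
    .cellucoop_cache$refdata <- build_refdata()
  .cellucoop_cache$refdata
}

## Gene-level features implied by a cassette: transporter families expand
## to their subunits.
cassette_gene_features <- function(cassette) {
  out <- character(0)
  for (f in cassette) {
    out <- c(out, switch(f,
      pts_cel = PTS_LABELS,
      abc_ceb = ABC_LABELS,
      f))
  }
  out
}

## Map a gene-level feature label to its RoleFeature (or NA for markers).
feature_to_role_feature <- function(f) {
  if (f %in% PTS_LABELS) return("pts_cel")
  if (f %in% ABC_LABELS) return("abc_ceb")
  if (f %in% role_features()) return(f)
  NA_character_
}
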