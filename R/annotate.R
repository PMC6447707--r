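## Gene prediction (six-frame ORF calling), Smith-Waterman best-hit genus
## assignment with identity statistics, and functional labeling from
## domain/marker profile hits.

GENETIC_STOP <- "*"

## Fast codon-table translation of one frame (plain character, no S4
## dispatch); fuzzy/ambiguous codons become X.
translate_frame <- function(seq, off, n_cod) {
  code <- Biostrings::GENETIC_CODE
  starts <- off + 1L + 3L * (seq_len(n_cod) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp_chr <- function(x) {
  ch <- strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]
  paste(base::rev(ch), collapse = "")
}

#' Predict genes on a contig by six-frame ORF calling
#'
#' Finds all maximal ATG-to-stop open reading frames in the six frames with
#' a translated length of at least `min_protein_length`; overlapping ORFs
#' on the same strand are resolved to the longest. Coordinates are 0-based
#' half-open on the forward strand and include the stop codon.
#'
#' @param contig data.frame row or list with `id` and `sequence`, or a
#'   plain DNA string.
#' @param min_protein_length minimum protein length in amino acids.
#' @return data.frame with columns `id`, `contig`, `start`, `end`,
#'   `strand`, `frame`, `nucleotide`, `protein`.
#' @export
find_orfs <- function(contig, min_protein_length = 100L) {
  if (is.character(contig)) contig <- list(id = "contig", sequence = contig)
  seq <- toupper(contig$sequence)
  if (!is_dna(seq)) stop("contig contains non-ACGTN characters")
  L <- nchar(seq)
  orfs <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    for (off in 0:2) {
      n_cod <- (L - off) %/% 3L
      if (n_cod < min_protein_length + 1L) next
      aa <- translate_frame(s, off, n_cod)
      ## maximal ATG-to-stop: within each inter-stop segment take the
      ## first M
      stops <- c(gregexpr("\\*", aa, fixed = FALSE)[[1]])
      stops <- stops[stops > 0]
      seg_start <- c(1L, stops + 1L)
      seg_end <- c(stops, nchar(aa))
      for (k in seq_along(seg_start)) {
        if (seg_end[k] < seg_start[k]) next
        if (k > length(stops)) next  # trailing segment has no stop codon
        seg <- substr(aa, seg_start[k], seg_end[k] - 1L)  # protein body
        m_rel <- regexpr("M", seg, fixed = TRUE)
        if (m_rel < 0) next
        p_start <- seg_start[k] + m_rel - 1L  # codon index of ATG
        prot <- substr(aa, p_start, seg_end[k] - 1L)
        if (nchar(prot) < min_protein_length) next
        ## codon coordinates on strand s (1-based)
        nt_start <- off + 3L * (p_start - 1L) + 1L
        nt_end <- off + 3L * seg_end[k]  # includes stop codon
        if (strand == "+") {
          g_start <- nt_start - 1L; g_end <- nt_end
        } else {
          g_start <- L - nt_end; g_end <- L - nt_start + 1L
        }
        orfs[[length(orfs) + 1L]] <- data.frame(
          contig = contig$id, start = g_start, end = g_end, strand = strand,
          frame = off + 1L,
          nucleotide = substr(s, nt_start, nt_end), protein = prot)
      }
    }
  }
  if (!length(orfs))
    return(data.frame(id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      nucleotide = character(0), protein = character(0)))
  g <- do.call(rbind, orfs)
  ## resolve same-strand overlaps to the longest ORF
  keep <- rep(TRUE, nrow(g))
  g <- g[order(-(g$end - g$start)), ]
  for (i in seq_len(nrow(g))) {
    if (!keep[i]) next
    if (i < nrow(g)) for (j in (i + 1L):nrow(g)) {
      if (!keep[j]) next
      if (g$strand[j] == g$strand[i] &&
          g$start[j] < g$end[i] && g$end[j] > g$start[i]) keep[j] <- FALSE
    }
  }
  g <- g[keep, ]
  g <- g[order(g$start), ]
  g$id <- sprintf("%s_gene%02d", g$contig, seq_len(nrow(g)))
  rownames(g) <- NULL
  g[, c("id", "contig", "start", "end", "strand", "frame", "nucleotide",
        "protein")]
}

#' Smith-Waterman local protein alignment
#'
#' BLOSUM62-scored local alignment; percent identity is matches over
#' alignment columns (gap columns included).
#'
#' @param query,subject protein strings.
#' @param substitution_matrix scoring matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return list with `score` and `identity` (percent).
#' @export
align_proteins <- function(query, subject, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (!nchar(query) || !nchar(subject)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln, type = "PID1"))
}

## Shared-word prefilter (seeding heuristic): candidate references sharing
## at least `min_shared` k-length peptide words with the query. Reference
## word sets may be precomputed and attached as attribute "wordsets".
kmer_candidates <- function(protein, ref_proteins, k = 5L, min_shared = 2L,
                            wordsets = NULL) {
  if (nchar(protein) < k) return(integer(0))
  qw <- protein_words(protein, k)
  if (is.null(wordsets))
    wordsets <- lapply(ref_proteins, protein_words, k = k)
  shared <- vapply(wordsets, function(rw) sum(qw %in% rw), numeric(1))
  which(shared >= min_shared)
}

#' Assign a gene to a genus by best reference hit
#'
#' Candidate reference proteins are selected by a shared-peptide-word
#' prefilter, then aligned by Smith-Waterman; the best hit by score wins
#' (ties broken by higher identity, then lexicographic reference id). A
#' gene whose best normalized score (score per query residue) falls below
#' `min_score_per_length`, or which shares no seed words with any
#' reference, is `"unassigned"`.
#'
#' @param protein query protein string.
#' @param reference_db data.frame with columns `id`, `genus`, `protein`
#'   (default the packaged reference database).
#' @param min_score_per_length significance threshold on score / query
#'   length.
#' @param prefilter use the shared-word prefilter (disable to force
#'   exhaustive alignment).
#' @return data.frame row (`ref_id`, `genus`, `score`, `identity`) or
#'   `NULL` when unassigned.
#' @export
assign_genus <- function(protein, reference_db = reference_data()$refdb,
                         min_score_per_length = 1.0, prefilter = TRUE) {
  if (!nrow(reference_db)) stop("empty reference database")
  cand <- if (prefilter)
    kmer_candidates(protein, reference_db$protein,
                    wordsets = attr(reference_db, "wordsets"))
  else seq_len(nrow(reference_db))
  if (!length(cand)) return(NULL)
  sub <- reference_db[cand, ]
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sub$protein), Biostrings::AAString(protein),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  sc <- Biostrings::score(alns)
  idn <- Biostrings::pid(alns, type = "PID1")
  ord <- order(-sc, -idn, sub$id)
  best <- ord[1]
  if (sc[best] / nchar(protein) < min_score_per_length) return(NULL)
  data.frame(ref_id = sub$id[best], genus = sub$genus[best],
             score = sc[best], identity = idn[best])
}

#' Per-genus identity statistics over best hits
#'
#' @param hits data.frame with columns `genus` and `identity`.
#' @return data.frame (`genus`, `n`, `mean_identity`, `sd_identity`,
#'   `single_hit`) sorted by descending `n`; the SD of a single-hit genus
#'   is reported as 0 with `single_hit = TRUE`.
#' @export
genus_identity_stats <- function(hits) {
  if (!nrow(hits)) stop("no hits")
  out <- do.call(rbind, lapply(split(hits, hits$genus), function(h) {
    data.frame(genus = h$genus[1], n = nrow(h),
               mean_identity = mean(h$identity),
               sd_identity = if (nrow(h) > 1L) sd(h$identity) else 0,
               single_hit = nrow(h) == 1L)
  }))
  out <- out[order(-out$n, out$genus), ]
  rownames(out) <- NULL
  out
}

#' Attach functional labels to a gene
#'
#' EC and transporter labels are attached when the corresponding marker
#' profile hit passed its threshold; the endoglucanase label additionally
#' requires a GH domain from the 13 cellulase families.
#'
#' @param gene_id gene identifier.
#' @param genus assigned genus or `"unassigned"`.
#' @param domain_hits data.frame from [scan_domains()] (GH/CBM families).
#' @param marker_hits data.frame from [scan_domains()] over the functional
#'   marker profiles (family column holds marker labels).
#' @return one-row data.frame (`gene`, `genus`, `gh_families`,
#'   `cbm_families`, `architecture`, `ec_labels`, `transporters`);
#'   multi-valued fields are `;`-separated.
#' @export
assign_function_labels <- function(gene_id, genus, domain_hits, marker_hits) {
  fams <- unique(domain_hits$family)
  gh <- fams[grepl("^GH", fams)]
  cbm <- fams[grepl("^CBM", fams)]
  marks <- unique(marker_hits$family)
  ec <- character(0)
  if (EC_ENDOGLUCANASE %in% marks && any(gh %in% cellulase_families()))
    ec <- c(ec, EC_ENDOGLUCANASE)
  if (EC_BETA_GLUCOSIDASE %in% marks) ec <- c(ec, EC_BETA_GLUCOSIDASE)
  if (EC_6P_BETA_GLUCOSIDASE %in% marks) ec <- c(ec, EC_6P_BETA_GLUCOSIDASE)
  if (LBL_CELLOBIOSE_PHOSPHORYLASE %in% marks)
    ec <- c(ec, LBL_CELLOBIOSE_PHOSPHORYLASE)
  trans <- marks[marks %in% c(PTS_LABELS, ABC_LABELS)]
  dom_sorted <- domain_hits[order(domain_hits$start), , drop = FALSE]
  data.frame(gene = gene_id, genus = genus,
             gh_families = paste(gh, collapse = ";"),
             cbm_families = paste(cbm, collapse = ";"),
             architecture = architecture_string(dom_sorted),
             ec_labels = paste(ec, collapse = ";"),
             transporters = paste(sort(trans), collapse = ";"))
}

#' Annotate a contig set end-to-end
#'
#' Convenience wrapper: ORF calling on every contig, genus assignment
#' against the packaged reference database, and domain/marker scanning
#' with functional labeling.
#'
#' @param contig_set a `contig_set` (or data.frame with `id`, `sequence`).
#' @param ref packaged reference data.
#' @param min_protein_length minimum protein length for ORF calling.
#' @param min_score_per_length genus-assignment significance threshold.
#' @return list with `genes` (ORF table), `annotations` (one row per gene)
#'   and `hits` (best-hit records for identity statistics).
#' @export
annotate_contigs <- function(contig_set, ref = reference_data(),
                             min_protein_length = 100L,
                             min_score_per_length = 1.0) {
  contigs <- if (inherits(contig_set, "contig_set")) contig_set$contigs
             else contig_set
  genes <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i)
    find_orfs(contigs[i, ], min_protein_length = min_protein_length)))
  if (is.null(genes) || !nrow(genes))
    return(list(genes = data.frame(), annotations = data.frame(),
                hits = data.frame()))
  dom_profiles <- ref$profiles[c(cellulase_families(), EXTRA_GH_FAMILIES,
                                 CBM_FAMILIES, MARKER_GENES)]
  mark_profiles <- ref$profiles[c(EC_ENDOGLUCANASE, EC_BETA_GLUCOSIDASE,
                                  EC_6P_BETA_GLUCOSIDASE,
                                  LBL_CELLOBIOSE_PHOSPHORYLASE,
                                  PTS_LABELS, ABC_LABELS)]
  ann <- list(); hits <- list()
  for (i in seq_len(nrow(genes))) {
    p <- genes$protein[i]
    hit <- assign_genus(p, ref$refdb,
                        min_score_per_length = min_score_per_length)
    genus <- if (is.null(hit)) "unassigned" else hit$genus
    if (!is.null(hit)) {
      hit$gene <- genes$id[i]
      hits[[length(hits) + 1L]] <- hit
    }
    dh <- scan_domains(p, dom_profiles)
    mh <- scan_domains(p, mark_profiles)
    a <- assign_function_labels(genes$id[i], genus, dh, mh)
    a$contig <- genes$contig[i]
    ## marker-gene tag (universal single-copy set) for bin overlay
    mg <- intersect(unique(dh$family), MARKER_GENES)
    a$marker_gene <- paste(mg, collapse = ";")
    ann[[length(ann) + 1L]] <- a
  }
  list(genes = genes,
       annotations = do.call(rbind, ann),
       hits = if (length(hits)) do.call(rbind, hits) else data.frame())
}
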