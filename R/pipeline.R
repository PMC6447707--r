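## End-to-end orchestration: simulate -> classify-16S -> annotate -> bin ->
## roles -> report, with a manifest sufficient to reproduce the run.

#' Default pipeline configuration
#'
#' Stage parameters default to the analysis values: merge overlap 50 bp,
#' filter length 300 bp / expected error 0.5 / mean Q > 30, confidence
#' threshold 0.5, 100 bootstrap replicates, binning contig minimum 1000 bp,
#' k-mer length 5, intermediate dimensions 50, perplexity 30.0, theta 0.5,
#' seed 0.
#'
#' @param seed master seed.
#' @return named list of stage parameters and enable flags.
#' @export
default_pipeline_config <- function(seed = 0L) {
  list(
    seed = seed,
    genome_length = 50000L,
    n_samples = 2L,
    lognormal = list(meanlog = 0, sdlog = 1.0),
    n_pairs = 150L,
    read_length = 250L,
    error_rate = 0.005,
    min_overlap = 50L,
    min_length = 300L,
    max_expected_error = 0.5,
    min_q = 30,
    threshold = 0.5,
    n_bootstrap = 100L,
    contigs_per_genome = 150L,
    contig_lengths = list(min = 400L, max = 4000L, frac_long = 0.5),
    bin_min_length = 1000L,
    kmer = 5L,
    intermediate_dims = 50L,
    perplexity = 30.0,
    theta = 0.5,
    ph = 7.0,
    stages = c(simulate = TRUE, classify = TRUE, annotate = TRUE,
               bin = TRUE, roles = TRUE, protprops = TRUE))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of DNA or protein sequences.
#' @param path output file.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, classify-16S, annotate,
#' bin, roles, protprops), writes every output table under `outdir`, and
#' records a manifest of parameters and seed sufficient to reproduce the
#' run. Reruns with the same configuration are byte-identical.
#'
#' @param config list from [default_pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = tempfile("run")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  st <- cfg$stages
  ref <- reference_data()
  res <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (isTRUE(st[["simulate"]])) res$sim <- run_stage("simulate", {
    specs <- default_genome_specs(cfg$genome_length)
    genomes <- lapply(specs, simulate_genome, seed = cfg$seed, ref = ref)
    profiles <- simulate_community(genomes, cfg$lognormal, cfg$n_samples,
                                   seed = cfg$seed)
    contigs <- shear_contigs(genomes, n_per_genome = cfg$contigs_per_genome,
                             length_distribution = cfg$contig_lengths,
                             seed = cfg$seed)
    reads <- lapply(profiles, function(p)
      simulate_amplicons(genomes, p, read_length = cfg$read_length,
                         error_rate = cfg$error_rate, n_pairs = cfg$n_pairs,
                         seed = cfg$seed))
    write_fasta(setNames(vapply(genomes, `[[`, character(1), "sequence"),
                         names(genomes)),
                file.path(outdir, "genomes.fasta"))
    write_fasta(setNames(contigs$contigs$sequence, contigs$contigs$id),
                file.path(outdir, "contigs.fasta"))
    write_tsv(contigs$truth, file.path(outdir, "contig_truth.tsv"))
    for (i in seq_along(reads)) {
      write_fastq(reads[[i]]$fwd,
                  file.path(outdir, sprintf("reads_s%d_R1.fastq", i)))
      write_fastq(reads[[i]]$rev,
                  file.path(outdir, sprintf("reads_s%d_R2.fastq", i)))
      write_tsv(reads[[i]]$truth,
                file.path(outdir, sprintf("read_truth_s%d.tsv", i)))
    }
    ab <- do.call(rbind, lapply(profiles, function(p)
      data.frame(sample = p$sample_id, genome = names(p$abundance),
                 abundance = as.numeric(p$abundance))))
    write_tsv(ab, file.path(outdir, "community_profiles.tsv"))
    list(genomes = genomes, profiles = profiles, contigs = contigs,
         reads = reads)
  })

  if (isTRUE(st[["classify"]])) res$classify <- run_stage("classify", {
    model <- train_word_model(ref$ref16s, ref$tree)
    per_sample <- list()
    for (i in seq_along(res$sim$reads)) {
      rd <- res$sim$reads[[i]]
      merged <- Filter(Negate(is.null), mapply(
        merge_pairs, rd$fwd, rd$rev,
        MoreArgs = list(min_overlap = cfg$min_overlap), SIMPLIFY = FALSE))
      kept <- filter_sequences(merged, cfg$min_length,
                               cfg$max_expected_error, cfg$min_q)$retained
      per_sample[[sprintf("sample%d", i)]] <- lapply(
        seq_along(kept), function(j)
          escalate_assignment(classify_with_bootstrap(
            model, kept[[j]]$bases, cfg$n_bootstrap,
            seed = derive_seed(cfg$seed, paste0("cls", i, "_", j))),
            cfg$threshold))
    }
    tab <- build_abundance_table(per_sample, rank = "genus",
                                 threshold = cfg$threshold)
    p <- pca_abundance(tab)
    write_tsv(data.frame(taxon = colnames(tab$raw), t(tab$raw)),
              file.path(outdir, "abundance_raw.tsv"))
    write_tsv(data.frame(taxon = colnames(tab$filtered), t(tab$filtered)),
              file.path(outdir, "abundance_filtered.tsv"))
    write_tsv(data.frame(sample = rownames(p$coordinates), p$coordinates),
              file.path(outdir, "pca_coordinates.tsv"))
    list(assignments = per_sample, table = tab, pca = p)
  })

  if (isTRUE(st[["annotate"]])) res$annotate <- run_stage("annotate", {
    ann <- annotate_contigs(res$sim$contigs, ref = ref)
    write_tsv(ann$annotations, file.path(outdir, "annotations.tsv"))
    if (nrow(ann$hits))
      write_tsv(genus_identity_stats(ann$hits),
                file.path(outdir, "genus_identity_stats.tsv"))
    write_fasta(setNames(ann$genes$protein, ann$genes$id),
                file.path(outdir, "proteins.fasta"), type = "protein")
    ann
  })

  if (isTRUE(st[["bin"]])) res$bin <- run_stage("bin", {
    sig <- contig_signatures(res$sim$contigs, k = cfg$kmer,
                             min_length = cfg$bin_min_length)
    emb <- embed_signatures(sig, cfg$intermediate_dims, cfg$perplexity,
                            cfg$theta, seed = cfg$seed)
    bins <- cluster_embedding(emb)
    ann <- res$annotate$annotations
    marker_hits <- ann[nzchar(ann$marker_gene) & ann$genus != "unassigned",
                       c("contig", "genus")]
    fh <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
      flags <- ec_to_function_flag(
        strsplit(ann$ec_labels[i], ";", fixed = TRUE)[[1]])
      if (!length(flags)) return(NULL)
      data.frame(contig = ann$contig[i], flag = flags)
    }))
    if (is.null(fh)) fh <- data.frame(contig = character(0), flag = character(0))
    ## only contigs long enough to be embedded can be overlaid
    marker_hits <- marker_hits[marker_hits$contig %in% rownames(emb), ,
                               drop = FALSE]
    fh <- fh[fh$contig %in% rownames(emb), , drop = FALSE]
    overlay <- overlay_annotations(bins, marker_hits, fh)
    qual <- bin_quality(bins, res$sim$contigs$truth)
    write_tsv(data.frame(contig = rownames(emb), emb),
              file.path(outdir, "embedding.tsv"))
    write_tsv(overlay, file.path(outdir, "bins_overlay.tsv"))
    write_tsv(qual$per_bin, file.path(outdir, "bin_purity.tsv"))
    list(signatures = sig, embedding = emb, bins = bins, overlay = overlay,
         quality = qual)
  })

  if (isTRUE(st[["roles"]])) res$roles <- run_stage("roles", {
    mat <- build_gene_content_matrix(res$annotate$annotations, "taxon")
    roles <- classify_roles(mat)
    net <- build_network(roles)
    write_tsv(roles, file.path(outdir, "roles.tsv"))
    write_tsv(net$edges, file.path(outdir, "network_edges.tsv"))
    list(matrix = mat, assignments = roles, network = net)
  })

  if (isTRUE(st[["protprops"]])) res$protprops <- run_stage("protprops", {
    ann <- res$annotate$annotations
    endo <- ann$gene[grepl("EC:3.2.1.4(;|$)", ann$ec_labels)]
    genes <- res$annotate$genes
    props <- do.call(rbind, lapply(endo, function(g) {
      p <- protein_properties(genes$protein[genes$id == g], pH = cfg$ph)
      data.frame(gene = g, length = p$length,
                 net_charge = p$net_charge, pH = p$pH, pI = p$pI)
    }))
    if (is.null(props))
      props <- data.frame(gene = character(0), length = integer(0),
                          net_charge = numeric(0), pH = numeric(0),
                          pI = numeric(0))
    write_tsv(props, file.path(outdir, "endoglucanase_properties.tsv"))
    props
  })

  manifest <- data.frame(
    key = c("package_version", "seed",
            names(unlist(cfg[setdiff(names(cfg), "stages")]))),
    value = c(as.character(utils::packageVersion("cellucoop")),
              as.character(cfg$seed),
              as.character(unlist(cfg[setdiff(names(cfg), "stages")]))))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(c(res, list(outdir = outdir)))
}
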