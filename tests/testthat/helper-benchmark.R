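## End-to-end parameter-recovery benchmark: one full synthetic study
## (6 genomes, 150 contigs each, 2 samples) per seed, returning role
## recovery, genus-level 16S assignment accuracy and median bin purity.

run_benchmark_seed <- function(seed, n_pairs = 150L) {
  ref <- fix_ref()
  specs <- default_genome_specs()
  genomes <- lapply(specs, simulate_genome, seed = seed, ref = ref)
  profiles <- simulate_community(genomes, list(meanlog = 0, sdlog = 1),
                                 n_samples = 2, seed = seed)
  contigs <- shear_contigs(genomes, n_per_genome = 150, seed = seed)

  ## 16S: simulate, merge, filter, classify
  model <- fixture("word_model", function()
    train_word_model(ref$ref16s, ref$tree))
  correct <- 0L; total <- 0L
  for (p in profiles) {
    am <- simulate_amplicons(genomes, p, n_pairs = n_pairs, seed = seed)
    for (i in seq_len(n_pairs)) {
      m <- merge_pairs(am$fwd[[i]], am$rev[[i]])
      if (is.null(m)) next
      if (length(filter_sequences(list(m))$retained) == 0) next
      a <- escalate_assignment(classify_with_bootstrap(
        model, m$bases, 100,
        seed = derive_seed(seed, paste0("bm", p$sample_id, i))))
      total <- total + 1L
      if (identical(a$accepted_rank, "genus") &&
          identical(a$display, am$truth$genus[i]))
        correct <- correct + 1L
    }
  }

  ## annotation -> gene content -> roles (undetected genera default to
  ## all-false rows so every genome is scored)
  ann <- annotate_contigs(contigs, ref = ref)
  m <- build_gene_content_matrix(ann$annotations, "taxon")
  missing <- setdiff(names(genomes), rownames(m))
  if (length(missing)) {
    add <- matrix(FALSE, length(missing), ncol(m),
                  dimnames = list(missing, colnames(m)))
    m <- rbind(m, add)
  }
  roles <- suppressWarnings(classify_roles(m))
  truth <- data.frame(taxon = names(genomes),
                      role = vapply(genomes, `[[`, character(1), "role"))
  acc <- role_recovery(roles, truth)$accuracy

  ## binning
  sig <- contig_signatures(contigs)
  emb <- embed_signatures(sig)
  bins <- cluster_embedding(emb)
  qual <- bin_quality(bins, contigs$truth)

  list(role_accuracy = acc,
       s16_accuracy = correct / total,
       median_purity = median(qual$per_bin$purity),
       completeness = setNames(qual$per_genome$completeness,
                               qual$per_genome$genus))
}
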