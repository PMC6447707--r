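## Word-model (naive Bayes) taxonomic classifier with bootstrap confidence
## and iterative rank escalation at the 0.5 threshold, plus abundance
## tables and covariance PCA of relative abundances.

distinct_words <- function(seq, word_size) {
  n <- nchar(seq)
  if (n < word_size) stop("sequence shorter than word size")
  unique(substring(seq, 1:(n - word_size + 1L), word_size:n))
}

#' Train the word model from labeled reference 16S sequences
#'
#' Per-genus conditional word probabilities with a frequency-based
#' pseudocount: `P(word | genus) = (m + prior) / (M + 1)` where `m` is the
#' number of the genus's reference sequences containing the word, `M` the
#' genus size, and `prior = (n + 0.5) / (N + 1)` the overall word frequency
#' over all `N` reference sequences.
#'
#' @param reference data.frame with columns `id`, `genus`, `seq`.
#' @param tree `taxonomy_tree` containing every reference genus.
#' @param word_size word length (default 8).
#' @return object of class `word_model`.
#' @export
train_word_model <- function(reference, tree, word_size = 8L) {
  genera <- sort(unique(reference$genus))
  missing <- setdiff(genera, tax_genera(tree))
  if (length(missing))
    stop("genus absent from taxonomy: ", paste(missing, collapse = ", "))
  N <- nrow(reference)
  words_by_seq <- lapply(reference$seq, distinct_words, word_size = word_size)
  all_words <- sort(unique(unlist(words_by_seq)))
  n_word <- table(factor(unlist(lapply(words_by_seq, unique)),
                         levels = all_words))
  prior <- (as.numeric(n_word) + 0.5) / (N + 1)
  M <- table(factor(reference$genus, levels = genera))
  logp <- matrix(NA_real_, length(all_words), length(genera),
                 dimnames = list(all_words, genera))
  for (g in genera) {
    idx <- which(reference$genus == g)
    m <- table(factor(unlist(words_by_seq[idx]), levels = all_words))
    logp[, g] <- log((as.numeric(m) + prior) / (as.numeric(M[g]) + 1))
  }
  ## unseen query words: m = 0 with the minimal prior
  unseen <- log((0.5 / (N + 1)) / (as.numeric(M) + 1))
  names(unseen) <- genera
  structure(list(word_size = as.integer(word_size), genera = genera,
                 logp = logp, unseen = unseen, tree = tree, n_ref = N),
            class = "word_model")
}

#' Classify one sequence with bootstrap confidence
#'
#' Each bootstrap replicate samples one eighth of the sequence's distinct
#' words with replacement and assigns the maximum-likelihood genus (ties
#' broken lexicographically). Genus confidence is the fraction of
#' replicates voting for it; the confidence of a higher-rank node is the
#' sum over its descendant genera.
#'
#' @param model a `word_model`.
#' @param seq base string.
#' @param n_bootstrap number of bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame with columns `rank`, `name`, `confidence`: the
#'   top-confidence candidate at each rank from genus up to phylum, plus
#'   one row per genus with nonzero votes (rank `"genus"` lists only the
#'   top genus; attribute `"votes"` carries the full vote table).
#' @export
classify_with_bootstrap <- function(model, seq, n_bootstrap = 100L, seed = 0L) {
  words <- distinct_words(seq, model$word_size)
  W <- length(words)
  m <- max(1L, W %/% 8L)
  row <- match(words, rownames(model$logp))
  lp <- matrix(NA_real_, W, length(model$genera),
               dimnames = list(NULL, model$genera))
  seen <- !is.na(row)
  lp[seen, ] <- model$logp[row[seen], , drop = FALSE]
  if (any(!seen))
    lp[!seen, ] <- matrix(model$unseen, sum(!seen), length(model$genera),
                          byrow = TRUE)
  votes <- with_seed(derive_seed(seed, "bootstrap"), {
    idx <- matrix(sample.int(W, n_bootstrap * m, replace = TRUE),
                  n_bootstrap, m)
    win <- integer(n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      sc <- colSums(lp[idx[b, ], , drop = FALSE])
      win[b] <- which.max(sc)  # genera sorted: lexicographic tie-break
    }
    tabulate(win, nbins = length(model$genera))
  })
  conf_genus <- setNames(votes / n_bootstrap, model$genera)
  ## aggregate per rank
  ranks <- c("genus", "family", "order", "class", "phylum")
  out <- data.frame(rank = character(0), name = character(0),
                    confidence = numeric(0))
  for (r in ranks) {
    anc <- vapply(model$genera, function(g) tax_ancestor(model$tree, g, r),
                  character(1))
    agg <- tapply(conf_genus, anc, sum)
    top <- which.max(agg)  # ties: first alphabetically (tapply sorts names)
    out[nrow(out) + 1L, ] <- list(r, names(agg)[top], as.numeric(agg[top]))
  }
  attr(out, "votes") <- conf_genus
  out
}

#' Escalate a confidence profile to an accepted rank
#'
#' The accepted rank is the most specific rank (genus towards phylum) whose
#' confidence reaches the threshold. A sequence accepted above genus is
#' displayed as `"<AcceptedName>_<top-genus>-like"` (lower-cased genus),
#' recording both; a sequence failing even at phylum is `"unclassified"`.
#'
#' @param confidences data.frame from [classify_with_bootstrap()].
#' @param threshold confidence threshold (default 0.5).
#' @return object of class `taxon_assignment`: list with `confidences`,
#'   `accepted_rank`, `display`.
#' @export
escalate_assignment <- function(confidences, threshold = 0.5) {
  ranks <- c("genus", "family", "order", "class", "phylum")
  cf <- confidences[match(ranks, confidences$rank), ]
  acc <- which(cf$confidence >= threshold)
  if (!length(acc)) {
    return(structure(list(confidences = confidences,
                          accepted_rank = NA_character_,
                          display = "unclassified"),
                     class = "taxon_assignment"))
  }
  i <- acc[1]
  display <- if (ranks[i] == "genus") cf$name[1] else
    paste0(cf$name[i], "_", tolower(cf$name[1]), "-like")
  structure(list(confidences = confidences, accepted_rank = ranks[i],
                 display = display),
            class = "taxon_assignment")
}

## Taxon label of an assignment at a given rank.
assignment_label <- function(assignment, rank = "genus", threshold = 0.5) {
  if (rank == "genus") return(assignment$display)
  cf <- assignment$confidences
  i <- match(rank, cf$rank)
  if (!is.na(i) && cf$confidence[i] >= threshold) cf$name[i] else "unclassified"
}

#' Build per-sample relative abundance tables
#'
#' Counts assignments at the chosen rank within each sample and normalizes
#' to relative abundance. Taxa observed in exactly one sample are then
#' removed *without* rescaling the remaining columns (the filtered table
#' feeds PCA on relative abundances as-is); both tables are returned.
#'
#' @param assignments_per_sample named list: sample id -> list of
#'   `taxon_assignment`.
#' @param rank rank at which to tabulate (default `"genus"`; genus-level
#'   labels use escalated display names).
#' @param threshold acceptance threshold used for non-genus ranks.
#' @return object of class `abundance_table`: list with `counts`, `raw`
#'   and `filtered` (samples x taxa matrices).
#' @export
build_abundance_table <- function(assignments_per_sample, rank = "genus",
                                  threshold = 0.5) {
  if (length(assignments_per_sample) < 2L) stop("need at least two samples")
  labs <- lapply(assignments_per_sample, function(as_list)
    vapply(as_list, assignment_label, character(1), rank = rank,
           threshold = threshold))
  taxa <- sort(unique(unlist(labs)))
  counts <- do.call(rbind, lapply(labs, function(x)
    as.numeric(table(factor(x, levels = taxa)))))
  dimnames(counts) <- list(names(assignments_per_sample), taxa)
  raw <- counts / rowSums(counts)
  present <- colSums(counts > 0)
  filtered <- raw[, present >= 2L, drop = FALSE]
  structure(list(counts = counts, raw = raw, filtered = filtered),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$raw), "samples x", ncol(x$raw),
      "taxa (", ncol(x$filtered), "after single-sample filter )\n")
  invisible(x)
}

#' Covariance PCA of relative abundances
#'
#' Column-centered principal component analysis of the (filtered) sample x
#' taxon relative abundance matrix; components are ordered by decreasing
#' variance and the sign convention makes the largest-magnitude loading of
#' each component positive.
#'
#' @param table an `abundance_table` or a numeric samples x taxa matrix.
#' @param n_components number of components to keep.
#' @return list with `coordinates` (samples x components), `loadings`,
#'   `variance_fraction`.
#' @export
pca_abundance <- function(table, n_components = 2L) {
  x <- if (inherits(table, "abundance_table")) table$filtered else as.matrix(table)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 taxa")
  tot <- sum(apply(x, 2, stats::var))
  if (tot < .Machine$double.eps) {
    warning("constant abundance table: zero variance")
    k <- min(n_components, nrow(x) - 1L, ncol(x))
    return(list(coordinates = matrix(0, nrow(x), k,
                                     dimnames = list(rownames(x), paste0("PC", seq_len(k)))),
                loadings = matrix(0, ncol(x), k),
                variance_fraction = rep(0, k)))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  coords <- p$x[, seq_len(k), drop = FALSE]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; coords[, j] <- -coords[, j] }
  }
  vf <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k)]
  list(coordinates = coords, loadings = load, variance_fraction = vf)
}
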