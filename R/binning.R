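## Reference-independent contig binning: canonical 5-mer signatures, a
## linear reduction followed by an exact t-distributed stochastic neighbor
## embedding into 2D, density-based cluster extraction, and marker/function
## overlay.

canonical_kmer_map <- function(k = 5L) {
  key <- paste0("canon", k)
  if (!is.null(.cellucoop_cache[[key]])) return(.cellucoop_cache[[key]])
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- ifelse(kmers <= rc, kmers, rc)
  .cellucoop_cache[[key]] <- canon
  canon
}

#' Canonical k-mer frequency signature of a contig
#'
#' Counts sliding-window k-mers, pools each k-mer with its reverse
#' complement under the lexicographically smaller canonical form, and
#' normalizes to sum 1 (512 canonical 5-mers for the default k).
#'
#' @param sequence contig DNA string.
#' @param k k-mer length.
#' @param min_length minimum contig length; shorter contigs return `NULL`.
#' @return named numeric vector over canonical k-mers, or `NULL`.
#' @export
kmer_signature <- function(sequence, k = 5L, min_length = 1000L) {
  if (nchar(sequence) < min_length) return(NULL)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k)
  canon <- canonical_kmer_map(k)
  v <- tapply(as.numeric(counts), canon, sum)
  v <- setNames(as.numeric(v), names(v))
  v / sum(v)
}

#' Signature matrix for a contig set
#'
#' @param contig_set a `contig_set` or data.frame with `id`, `sequence`.
#' @param k k-mer length.
#' @param min_length minimum contig length; shorter contigs are skipped
#'   and listed in the `skipped` attribute.
#' @return matrix (contigs x canonical k-mers) with rownames = contig ids.
#' @export
contig_signatures <- function(contig_set, k = 5L, min_length = 1000L) {
  contigs <- if (inherits(contig_set, "contig_set")) contig_set$contigs
             else contig_set
  ok <- nchar(contigs$sequence) >= min_length
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(contigs$sequence[ok]), width = k)
  canon <- canonical_kmer_map(k)
  folded <- t(rowsum(t(counts), canon))
  out <- folded / rowSums(folded)
  rownames(out) <- contigs$id[ok]
  attr(out, "skipped") <- contigs$id[!ok]
  out
}

## Conditional probabilities at a fixed perplexity: binary search on the
## Gaussian bandwidth per point (standard SNE calibration).
sne_probabilities <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D2[i, -i]
    for (it in 1:60) {
      w <- exp(-Di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { H <- 0; p <- rep(1 / length(Di), length(Di)) }
      else {
        p <- w / sw
        H <- log(sw) + beta * sum(Di * w) / sw
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' Embed contig signatures into 2D
#'
#' A linear (principal component) reduction to at most `intermediate_dims`
#' dimensions is followed by an exact t-distributed stochastic
#' neighbor-preserving embedding into 2D. The map is initialized from the
#' first two principal components (sign-fixed), which makes the embedding
#' deterministic and invariant to contig input order; `theta` is accepted
#' for interface parity with Barnes-Hut implementations but is ignored by
#' this exact implementation.
#'
#' @param signatures contigs x features matrix with rownames.
#' @param intermediate_dims linear reduction target dimensionality.
#' @param perplexity neighborhood size parameter; auto-reduced with a
#'   warning when fewer than `3 * perplexity` points are supplied.
#' @param theta accepted, ignored (exact embedding).
#' @param seed accepted for interface parity; the embedding is
#'   deterministic.
#' @param max_iter gradient-descent iterations.
#' @return matrix (contigs x 2) of embedding coordinates.
#' @export
embed_signatures <- function(signatures, intermediate_dims = 50L,
                             perplexity = 30.0, theta = 0.5, seed = 0L,
                             max_iter = 500L) {
  X0 <- as.matrix(signatures)
  if (nrow(X0) < 5L) stop("need at least 5 contigs to embed")
  ## canonicalize: process rows in name order so the embedding is exactly
  ## invariant to input order, and collapse duplicate signatures onto one
  ## embedded point (the gradient map is numerically chaotic; identical
  ## inputs must land on identical coordinates by construction)
  orig <- rownames(X0)
  if (!is.null(orig)) X0 <- X0[order(orig), , drop = FALSE]
  key <- do.call(paste, c(as.data.frame(X0), sep = "\r"))
  first <- !duplicated(key)
  X <- X0[first, , drop = FALSE]
  n <- nrow(X)
  if (n < 3 * perplexity) {
    perplexity <- max(2, (n - 1) / 3)
    warning("perplexity reduced to ", signif(perplexity, 3),
            " for ", n, " distinct points")
  }
  Xc <- sweep(X, 2, colMeans(X))
  expand <- function(Yu) {
    Y <- Yu[match(key, key[first]), , drop = FALSE]
    rownames(Y) <- rownames(X0)
    if (!is.null(orig)) Y <- Y[orig, , drop = FALSE]
    colnames(Y) <- c("dim1", "dim2")
    Y
  }
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  d <- min(intermediate_dims, rank)
  if (d < 1L) {  # all-identical signatures
    return(expand(matrix(0, n, 2)))
  }
  Z <- sv$u[, seq_len(d), drop = FALSE] %*% diag(sv$d[seq_len(d)], d)
  D2 <- as.matrix(dist(Z))^2
  P <- sne_probabilities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  ## PCA initialization, sign-fixed, scaled to small norm
  init <- Z[, seq_len(min(2L, d)), drop = FALSE]
  if (ncol(init) < 2L) init <- cbind(init, 0)
  for (j in 1:2) {
    i <- which.max(abs(init[, j]))
    if (init[i, j] < 0) init[, j] <- -init[, j]
  }
  Y <- init / max(1e-12, stats::sd(init)) * 1e-4
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- max(100, n / 6)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 125L) 12 else 1
    mom <- if (iter <= 250L) 0.5 else 0.8
    sy <- rowSums(Y^2)
    D2y <- outer(sy, sy, "+") - 2 * tcrossprod(Y)
    Qnum <- 1 / (1 + pmax(D2y, 0)); diag(Qnum) <- 0
    Q <- Qnum / sum(Qnum)
    Q[Q < 1e-12] <- 1e-12
    PQ <- (ex * P - Q) * Qnum
    grad <- 4 * (rowSums(PQ) * Y - PQ %*% Y)
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  expand(Y)
}

#' Density-based clustering of an embedding
#'
#' DBSCAN-style clustering with a single radius parameter defaulting to
#' the 95th percentile of 5-nearest-neighbor distances.
#'
#' @param embedding contigs x 2 coordinate matrix with rownames.
#' @param eps neighborhood radius; `NULL` for the data-driven default.
#' @param min_pts minimum neighborhood size of a core point.
#' @return object of class `bin_set`: list with `bins` (named list of
#'   contig-id vectors) and `noise` (contig ids outside all bins).
#' @export
cluster_embedding <- function(embedding, eps = NULL, min_pts = 5L) {
  n <- nrow(embedding)
  ids <- rownames(embedding)
  if (n == 1L)
    return(structure(list(bins = list(), noise = ids), class = "bin_set"))
  D <- as.matrix(dist(embedding))
  rng <- max(D)
  if (rng < 1e-12) {
    warning("degenerate all-coincident embedding: single bin")
    return(structure(list(bins = list(bin1 = ids), noise = character(0)),
                     class = "bin_set"))
  }
  if (is.null(eps)) {
    kth <- apply(D, 1, function(d) sort(d)[min(n, 6L)])  # 5-NN distance
    eps <- as.numeric(quantile(kth, 0.95))
  }
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  label <- integer(n)  # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (label[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; label[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (q in nb[[j]]) {
        if (label[q] == 0L) {
          label[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  bins <- lapply(seq_len(cl), function(c) ids[label == c])
  names(bins) <- if (cl) paste0("bin", seq_len(cl)) else character(0)
  structure(list(bins = bins, noise = ids[label == 0L]), class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat("bin_set:", length(x$bins), "bins (",
      paste(vapply(x$bins, length, integer(1)), collapse = ", "),
      ") +", length(x$noise), "noise contigs\n")
  invisible(x)
}

ec_to_function_flag <- function(labels) {
  map <- c("EC:3.2.1.4" = "endoglucanase",
           "EC:3.2.1.21" = "beta_glucosidase",
           "EC:3.2.1.86" = "six_phospho_beta_glucosidase",
           "cellobiose_phosphorylase" = "cellobiose_phosphorylase")
  unname(map[labels[labels %in% names(map)]])
}

#' Overlay marker-gene and function annotations on bins
#'
#' Tallies per-bin genus votes from marker genes and per-bin function
#' flags; bins carrying both endoglucanase and a downstream flag become
#' `"helper-candidate"`, downstream-only bins `"beneficiary-candidate"`,
#' others `"unlabeled"`.
#'
#' @param bin_set a `bin_set`.
#' @param marker_hits data.frame with columns `contig`, `genus`.
#' @param function_hits data.frame with columns `contig`, `flag` (values
#'   among the four cellulolytic function flags).
#' @return data.frame, one row per bin: `bin`, `n_contigs`, `top_genus`,
#'   `genus_votes`, `functions`, `candidate`.
#' @export
overlay_annotations <- function(bin_set, marker_hits, function_hits) {
  known <- unlist(bin_set$bins, use.names = FALSE)
  for (df in list(marker_hits, function_hits)) {
    unk <- setdiff(df$contig, c(known, bin_set$noise))
    if (length(unk))
      warning("hits on contig(s) absent from the embedding skipped: ",
              paste(head(unk, 5), collapse = ", "))
  }
  down <- c("beta_glucosidase", "six_phospho_beta_glucosidase",
            "cellobiose_phosphorylase")
  out <- lapply(names(bin_set$bins), function(b) {
    members <- bin_set$bins[[b]]
    mk <- marker_hits[marker_hits$contig %in% members, , drop = FALSE]
    fn <- unique(function_hits$flag[function_hits$contig %in% members])
    votes <- sort(table(mk$genus), decreasing = TRUE)
    cand <- if ("endoglucanase" %in% fn && any(down %in% fn)) "helper-candidate"
            else if (any(down %in% fn)) "beneficiary-candidate"
            else "unlabeled"
    data.frame(bin = b, n_contigs = length(members),
               top_genus = if (length(votes)) names(votes)[1] else NA_character_,
               genus_votes = paste(sprintf("%s:%d", names(votes),
                                           as.integer(votes)), collapse = ";"),
               functions = paste(sort(fn), collapse = ";"),
               candidate = cand)
  })
  do.call(rbind, out)
}

#' Purity and completeness of bins against simulator truth
#'
#' @param bin_set a `bin_set`.
#' @param truth data.frame with columns `contig`, `genus` covering every
#'   binned contig.
#' @return list with `per_bin` (data.frame `bin`, `n`, `purity`,
#'   `majority_genus`) and `per_genome` (data.frame `genus`,
#'   `completeness`).
#' @export
bin_quality <- function(bin_set, truth) {
  lookup <- setNames(truth$genus, truth$contig)
  per_bin <- do.call(rbind, lapply(names(bin_set$bins), function(b) {
    g <- lookup[bin_set$bins[[b]]]
    if (anyNA(g)) stop("truth table does not cover all binned contigs")
    tab <- sort(table(g), decreasing = TRUE)
    data.frame(bin = b, n = length(g),
               purity = as.numeric(tab[1]) / length(g),
               majority_genus = names(tab)[1])
  }))
  ## completeness is judged over the binning universe (binned + noise
  ## contigs), i.e. the contigs long enough to receive a signature
  universe <- c(unlist(bin_set$bins, use.names = FALSE), bin_set$noise)
  truth <- truth[truth$contig %in% universe, , drop = FALSE]
  genera <- unique(truth$genus)
  per_genome <- do.call(rbind, lapply(genera, function(gn) {
    tot <- sum(truth$genus == gn)
    best <- if (length(bin_set$bins))
      max(vapply(bin_set$bins, function(m)
        sum(lookup[m] == gn, na.rm = TRUE), numeric(1))) else 0
    data.frame(genus = gn,
               completeness = if (tot) best / tot else NA_real_)
  }))
  list(per_bin = per_bin, per_genome = per_genome)
}
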