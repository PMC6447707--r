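## Independent oracles used to cross-check the implementation.

## Affine-gap Smith-Waterman dynamic programming, written independently of
## the alignment backend (gap of length L costs open + L * extend).
sw_dp_oracle <- function(query, subject, mat = "BLOSUM62",
                         open = 10, extend = 0.5) {
  if (is.character(mat)) {
    e <- new.env(); data(list = mat, package = "Biostrings", envir = e)
    mat <- get(ls(e), envir = e)
  }
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(s)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in subject
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in query
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
    Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
    sc <- mat[q[i - 1], s[j - 1]]
    M[i, j] <- max(0, sc + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                               Iy[i - 1, j - 1]))
    best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
  }
  best
}

## Direct canonical k-mer counting by substring enumeration.
signature_oracle <- function(sequence, k = 5) {
  n <- nchar(sequence)
  kmers <- substring(sequence, 1:(n - k + 1), k:n)
  rc <- vapply(kmers, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1))
  canon <- ifelse(kmers <= rc, kmers, rc)
  tab <- table(canon)
  tab / sum(tab)
}

## Venn region counts by per-element membership enumeration.
venn_oracle <- function(a, b, c) {
  u <- unique(c(a, b, c))
  pat <- vapply(u, function(x)
    paste0(as.integer(x %in% a), as.integer(x %in% b), as.integer(x %in% c)),
    character(1))
  counts <- table(factor(pat, levels = c("100", "010", "001", "110", "101",
                                         "011", "111")))
  setNames(as.integer(counts),
           c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC"))
}

## pI by exhaustive pH grid search.
pi_grid_oracle <- function(protein, step = 1e-3) {
  grid <- seq(step, 14 - step, by = step)
  ch <- vapply(grid, function(p) net_charge(protein, p), numeric(1))
  grid[which.min(abs(ch))]
}

## Mean silhouette width of labels in a coordinate matrix.
silhouette_mean <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  labs <- unique(labels)
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels[i]
    a <- mean(D[i, labels == own & seq_along(labels) != i])
    b <- min(vapply(setdiff(labs, own), function(l)
      mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
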