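#' @import methods
#' @importFrom stats prcomp rnorm runif quantile sd setNames rlnorm median dist
#' @importFrom utils head tail write.table read.table combn
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

MAX_SEED <- 2147483646L

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library code never
#' perturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' A fixed polynomial hash of the stage name is combined with the master
#' seed, so disabling one pipeline stage never shifts the random stream of
#' another. Result is always a valid 32-bit R seed.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer sub-seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1048573
  as.integer(((abs(as.numeric(seed)) %% 1048573) * 1048573 + h) %%
               as.numeric(MAX_SEED))
}

## --- sequence helpers (plain character representation) ---------------------

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Per-site substitution, never to the same letter; optionally protect sites.
mutate_seq <- function(x, rate, alphabet, protect = integer(0)) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    k <- length(alphabet)
    alts <- t(vapply(seq_len(k), function(i) alphabet[-i], character(k - 1L)))
    r <- sample.int(k - 1L, length(hit), replace = TRUE)
    ch[hit] <- alts[cbind(match(ch[hit], alphabet), r)]
  }
  paste(ch, collapse = "")
}

mutate_dna <- function(x, rate, protect = integer(0))
  mutate_seq(x, rate, c("A", "C", "G", "T"), protect)

#' Mutate a protein copy down to a target identity
#'
#' Per-site substitution at rate `1 - identity`, drawing replacement
#' residues uniformly from the other 19 amino acids.
#'
#' @param x protein string.
#' @param identity target fractional identity in (0, 1].
#' @return mutated protein string.
#' @keywords internal
mutate_protein <- function(x, identity) mutate_seq(x, 1 - identity, AA20)

## GC-biased synonymous reverse translation of a protein (+ stop codon).
reverse_translate <- function(protein, gc = 0.5) {
  code <- Biostrings::GENETIC_CODE
  aas <- c(strsplit(protein, "", fixed = TRUE)[[1]], "*")
  base_w <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codon_w <- vapply(names(code), function(cod) {
    prod(base_w[strsplit(cod, "", fixed = TRUE)[[1]]])
  }, numeric(1))
  out <- character(length(aas))
  for (aa in unique(aas)) {
    cands <- names(code)[code == aa]
    if (!length(cands)) stop("unknown residue: ", aa)
    idx <- which(aas == aa)
    out[idx] <- if (length(cands) == 1L) cands else
      sample(cands, length(idx), replace = TRUE, prob = codon_w[cands])
  }
  paste(c("ATG", out), collapse = "")
}

is_dna <- function(x) grepl("^[ACGTN]*$", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
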