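## Paired-end 16S amplicon simulation, FASTQ IO, read merging and the
## three-rule quality filter.

#' Construct an amplicon read
#'
#' @param id read id.
#' @param bases base string.
#' @param quals integer Phred scores, one per base (0-60).
#' @return object of class `amplicon_read`.
#' @export
amplicon_read <- function(id, bases, quals) {
  if (length(quals) != nchar(bases))
    stop("quality length must equal base length")
  if (any(quals < 0 | quals > 60)) stop("Phred scores must be in [0, 60]")
  structure(list(id = id, bases = bases, quals = as.integer(quals)),
            class = "amplicon_read")
}

qual_to_char <- function(q) intToUtf8(q + 33L)
char_to_qual <- function(s) utf8ToInt(s) - 33L

#' Write amplicon reads as Sanger FASTQ (Phred+33)
#'
#' @param reads list of `amplicon_read`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, character(1), "bases"))
  names(seqs) <- vapply(reads, `[[`, character(1), "id")
  quals <- Biostrings::PhredQuality(vapply(reads, function(r)
    qual_to_char(r$quals), character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a Sanger FASTQ file into amplicon reads
#'
#' @param path FASTQ file.
#' @return list of `amplicon_read`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  lapply(seq_along(x), function(i)
    amplicon_read(names(x)[i], as.character(x[[i]]),
                  char_to_qual(as.character(x@quality[[i]]))))
}

## Locate the amplified region of a genome: forward primer on the plus
## strand, reverse primer on the reverse complement (IUPAC degenerate
## matching). Returns NULL when either primer is absent.
locate_amplicon <- function(sequence, fwd_primer, rev_primer) {
  subj <- Biostrings::DNAString(sequence)
  f <- Biostrings::matchPattern(Biostrings::DNAString(fwd_primer), subj,
                                fixed = FALSE)
  r <- Biostrings::matchPattern(Biostrings::DNAString(rev_primer),
                                Biostrings::reverseComplement(subj),
                                fixed = FALSE)
  if (!length(f) || !length(r)) return(NULL)
  s <- Biostrings::start(f)[1]
  e <- nchar(sequence) - Biostrings::start(r)[1] + 1L
  if (e <= s) return(NULL)
  substr(sequence, s, e)
}

#' Simulate paired-end amplicon reads from a community
#'
#' Reads are drawn per genome proportional to the community profile; each
#' pair covers the inter-primer region (forward read from the 5' end,
#' reverse read as the reverse complement of the 3' end), with Phred
#' qualities from a configured normal profile and independent per-base
#' substitution errors.
#'
#' @param genomes list of `synthetic_genome` objects.
#' @param profile a `community_profile`.
#' @param fwd_primer,rev_primer primer strings (IUPAC degeneracy allowed);
#'   default the packaged v3-v4 primers.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param n_pairs number of read pairs.
#' @param seed integer seed.
#' @param quality_profile list with `mean`, `sd`, `min`, `max` Phred
#'   parameters.
#' @return list with `fwd` and `rev` (lists of `amplicon_read`) and
#'   `truth` (data.frame `id`, `genus`).
#' @export
simulate_amplicons <- function(genomes, profile,
                               fwd_primer = amplicon_primers()["fwd"],
                               rev_primer = amplicon_primers()["rev"],
                               read_length = 250L, error_rate = 0.005,
                               n_pairs = 300L, seed = 0L,
                               quality_profile = list(mean = 38, sd = 1.5,
                                                      min = 2, max = 41)) {
  ids <- vapply(genomes, function(g) g$id, character(1))
  names(genomes) <- ids
  amps <- lapply(genomes, function(g)
    locate_amplicon(g$sequence, fwd_primer, rev_primer))
  ok <- !vapply(amps, is.null, logical(1))
  if (!any(ok)) stop("primer pair not found in any genome")
  if (!all(ok))
    warning("primer pair absent from genome(s): ",
            paste(ids[!ok], collapse = ", "))
  ids <- ids[ok]
  with_seed(derive_seed(seed, paste0("amplicons:", profile$sample_id)), {
    w <- profile$abundance[ids]
    src <- sample(ids, n_pairs, replace = TRUE, prob = w / sum(w))
    fwd <- vector("list", n_pairs); rev <- vector("list", n_pairs)
    genus <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      amp <- amps[[src[i]]]
      L <- nchar(amp)
      rl <- min(read_length, L)
      f_b <- substr(amp, 1L, rl)
      r_b <- revcomp(substr(amp, L - rl + 1L, L))
      if (error_rate > 0) {
        f_b <- mutate_dna(f_b, error_rate)
        r_b <- mutate_dna(r_b, error_rate)
      }
      qp <- quality_profile
      f_q <- pmin(qp$max, pmax(qp$min, round(rnorm(rl, qp$mean, qp$sd))))
      r_q <- pmin(qp$max, pmax(qp$min, round(rnorm(rl, qp$mean, qp$sd))))
      id <- sprintf("%s_read%05d", profile$sample_id, i)
      fwd[[i]] <- amplicon_read(id, f_b, f_q)
      rev[[i]] <- amplicon_read(id, r_b, r_q)
      genus[i] <- genomes[[src[i]]]$genus
    }
    list(fwd = fwd, rev = rev,
         truth = data.frame(id = vapply(fwd, `[[`, character(1), "id"),
                            genus = genus))
  })
}

#' Merge a read pair by best ungapped overlap
#'
#' Aligns the forward read against the reverse-complemented reverse read at
#' every overlap of at least `min_overlap` bases and keeps the overlap with
#' the most matching bases (ties go to the longer overlap). Disagreeing
#' overlap positions take the higher-quality call; agreeing positions take
#' the maximum of the two qualities.
#'
#' @param fwd,rev `amplicon_read` objects.
#' @param min_overlap minimum acceptable overlap in bp.
#' @param max_mismatch_frac reject when the best overlap's mismatch
#'   fraction exceeds this.
#' @return merged `amplicon_read`, or `NULL` when no acceptable overlap
#'   exists (the rejection reason is attached as attribute `"reason"`).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 50L, max_mismatch_frac = 0.25) {
  if (!nchar(fwd$bases) || !nchar(rev$bases)) stop("empty read")
  rc_b <- strsplit(revcomp(rev$bases), "", fixed = TRUE)[[1]]
  rc_q <- base::rev(rev$quals)
  f_b <- strsplit(fwd$bases, "", fixed = TRUE)[[1]]
  f_q <- fwd$quals
  lf <- length(f_b); lr <- length(rc_b)
  o_max <- min(lf, lr)
  if (o_max < min_overlap) return(NULL)
  ## score = matches - mismatches; ties broken towards the longer overlap
  best_o <- NA_integer_; best_s <- -Inf; best_m <- 0L
  for (o in seq(min_overlap, o_max)) {
    m <- sum(f_b[(lf - o + 1L):lf] == rc_b[seq_len(o)])
    s <- 2L * m - o
    if (s >= best_s) { best_s <- s; best_m <- m; best_o <- o }
  }
  if ((best_o - best_m) / best_o > max_mismatch_frac) return(NULL)
  o <- best_o
  fi <- (lf - o + 1L):lf
  ri <- seq_len(o)
  ov_b <- ifelse(f_b[fi] == rc_b[ri], f_b[fi],
                 ifelse(f_q[fi] >= rc_q[ri], f_b[fi], rc_b[ri]))
  ov_q <- pmax(f_q[fi], rc_q[ri])
  bases <- paste(c(f_b[seq_len(lf - o)], ov_b, rc_b[-ri]), collapse = "")
  quals <- c(f_q[seq_len(lf - o)], ov_q, rc_q[-ri])
  amplicon_read(fwd$id, bases, quals)
}

#' Expected error of a read
#'
#' Sum over bases of `10^(-Q/10)`.
#'
#' @param read an `amplicon_read`.
#' @return numeric expected error.
#' @export
expected_error <- function(read) sum(10^(-read$quals / 10))

#' Apply the three-rule 16S quality filter
#'
#' A sequence is retained iff its length is at least `min_length`, its
#' expected error is at most `max_expected_error`, and its mean Phred score
#' exceeds `min_q`. The rules are order-independent; the rejection log
#' names every rule a rejected sequence failed.
#'
#' @param seqs list of `amplicon_read`.
#' @param min_length minimum length in bp.
#' @param max_expected_error maximum expected error.
#' @param min_q minimum mean Phred score (strict inequality).
#' @return list with `retained` (list of reads) and `log` (data.frame
#'   `id`, `rule`).
#' @export
filter_sequences <- function(seqs, min_length = 300L, max_expected_error = 0.5,
                             min_q = 30) {
  keep <- logical(length(seqs))
  log <- list()
  for (i in seq_along(seqs)) {
    r <- seqs[[i]]
    if (is.null(r$quals)) stop("read ", i, " lacks quality scores")
    rules <- character(0)
    if (nchar(r$bases) < min_length) rules <- c(rules, "min_length")
    if (expected_error(r) > max_expected_error)
      rules <- c(rules, "expected_error")
    if (mean(r$quals) <= min_q) rules <- c(rules, "mean_quality")
    keep[i] <- !length(rules)
    if (length(rules))
      log[[length(log) + 1L]] <- data.frame(id = r$id,
                                            rule = paste(rules, collapse = ";"))
  }
  list(retained = seqs[keep],
       log = if (length(log)) do.call(rbind, log)
             else data.frame(id = character(0), rule = character(0)))
}
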