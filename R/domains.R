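## Position-specific scoring profiles for domain and functional-marker
## detection. Profiles are built from small sets of diverged copies of a
## seed protein; per-family score thresholds are calibrated against a
## shuffle null at build time, making significance self-contained (no
## database-relative e-values).

PROFILE_BG <- 0.05  # uniform amino-acid background

#' Build a position-specific scoring profile from a seed protein
#'
#' Generates `n_copies` diverged copies of the seed (per-site substitution
#' to the target identity), tallies per-position residue counts with a
#' pseudocount, and stores log2 odds against a uniform background. The
#' reporting threshold is calibrated from the best-window scores of
#' shuffled seed sequences (mean + 6 SD), floored at 20% of the seed's own
#' score.
#'
#' @param seed protein string.
#' @param n_copies number of diverged training copies.
#' @param identity fractional identity of the training copies to the seed.
#' @param n_null number of shuffles for threshold calibration.
#' @return list with `pssm` (length x 20 matrix of log2 odds), `length`,
#'   and `threshold`.
#' @export
build_profile <- function(seed, n_copies = 8, identity = 0.85, n_null = 60) {
  L <- nchar(seed)
  copies <- c(seed, vapply(seq_len(n_copies - 1L),
                           function(i) mutate_protein(seed, identity),
                           character(1)))
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  counts <- vapply(AA20, function(a) colSums(mat == a),
                   numeric(L))  # L x 20
  pssm <- log2(((counts + 0.5) / (n_copies + 10)) / PROFILE_BG)
  prof <- list(pssm = pssm, length = L, threshold = -Inf,
               seed_words = protein_words(seed))
  self <- profile_best_window(prof, seed)$score
  null <- vapply(seq_len(n_null), function(i) {
    shuf <- paste(sample(strsplit(seed, "", fixed = TRUE)[[1]]), collapse = "")
    profile_best_window(prof, shuf)$score
  }, numeric(1))
  prof$threshold <- max(mean(null) + 6 * sd(null), 0.2 * self)
  prof
}

## distinct peptide words (seeding heuristic for scan prescreens)
protein_words <- function(protein, k = 5L) {
  if (nchar(protein) < k) return(character(0))
  unique(substring(protein, 1:(nchar(protein) - k + 1L), k:nchar(protein)))
}

## Scores of the profile at every ungapped offset along a query protein.
profile_window_scores <- function(profile, protein) {
  Lp <- profile$length
  q <- match(strsplit(protein, "", fixed = TRUE)[[1]], AA20)
  Lq <- length(q)
  if (Lq < Lp) return(numeric(0))
  n_off <- Lq - Lp + 1L
  ## unknown residues (X etc.) contribute 0
  idx <- outer(seq_len(Lp), seq_len(n_off) - 1L, "+")  # Lp x n_off
  aa <- q[idx]
  val <- profile$pssm[cbind(rep(seq_len(Lp), n_off), aa)]
  val[is.na(val)] <- 0
  colSums(matrix(val, nrow = Lp))
}

profile_best_window <- function(profile, protein) {
  s <- profile_window_scores(profile, protein)
  if (!length(s)) return(list(score = -Inf, start = NA_integer_))
  i <- which.max(s)
  list(score = s[i], start = i - 1L)  # 0-based aa offset
}

#' Scan a protein for domain/marker profile hits
#'
#' For each profile, reports the best non-overlapping windows scoring at or
#' above the profile's calibrated threshold (greedy by descending score).
#' Hits of *different* families may overlap.
#'
#' @param protein protein string.
#' @param family_profiles named list of profiles from [build_profile()];
#'   defaults to the full packaged profile set.
#' @param prescreen skip profiles sharing fewer than two 5-residue words
#'   with the query (seeding heuristic; profiles built without seed words
#'   are always scanned).
#' @return data.frame with columns `family`, `start`, `end` (0-based
#'   half-open amino-acid coordinates) and `score`; zero rows if no hit.
#' @export
scan_domains <- function(protein, family_profiles = reference_data()$profiles,
                         prescreen = TRUE) {
  if (!nchar(protein)) stop("empty protein")
  qw <- if (prescreen) protein_words(protein) else NULL
  hits <- list()
  for (f in names(family_profiles)) {
    prof <- family_profiles[[f]]
    if (is.null(prof$pssm)) stop("malformed profile for family ", f)
    if (prescreen && !is.null(prof$seed_words) &&
        sum(prof$seed_words %in% qw) < 2L) next
    s <- profile_window_scores(prof, protein)
    taken <- rep(FALSE, length(s))
    while (length(s)) {
      s_ok <- ifelse(taken, -Inf, s)
      i <- which.max(s_ok)
      if (!length(i) || s_ok[i] < prof$threshold) break
      hits[[length(hits) + 1L]] <- data.frame(
        family = f, start = i - 1L, end = i - 1L + prof$length,
        score = s[i])
      mask <- seq(max(1L, i - prof$length + 1L),
                  min(length(s), i + prof$length - 1L))
      taken[mask] <- TRUE
    }
  }
  if (!length(hits))
    return(data.frame(family = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$family), , drop = FALSE]
}

#' Domain architecture string
#'
#' Joins family labels in N-to-C order with `+`, e.g. `"GH9+CBM30"`.
#'
#' @param domain_hits data.frame as returned by [scan_domains()].
#' @return a single string; `""` when there are no hits.
#' @export
architecture_string <- function(domain_hits) {
  if (!nrow(domain_hits)) return("")
  paste(domain_hits$family[order(domain_hits$start)], collapse = "+")
}

#' Venn region counts for three GH family sets
#'
#' @param setA,setB,setC character vectors of family labels.
#' @return named integer vector of the seven exclusive region counts
#'   (`A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`).
#' @export
gh_family_venn <- function(setA, setB, setC) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  u <- union(union(setA, setB), setC)
  inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
  c(A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
}
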