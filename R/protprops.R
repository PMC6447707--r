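## Pepstats-style protein property analysis: amino-acid composition, net
## charge by Henderson-Hasselbalch summation, isoelectric point by
## bisection, and residue-usage comparison against homologs. Used for the
## alkaline-adaptation argument (alkaline cellulases show pI near 4,
## strongly negative charge, depleted Lys / enriched Glu).

#' Default pKa table (EMBOSS convention)
#'
#' Side-chain and termini pKa values with charge signs as used by EMBOSS
#' pepstats; user-overridable in every property function.
#'
#' @return data.frame with columns `group`, `pka`, `sign`.
#' @export
default_pka_table <- function() {
  data.frame(
    group = c("Nterm", "K", "R", "H", "Cterm", "D", "E", "C", "Y"),
    pka = c(8.6, 10.8, 12.5, 6.5, 3.6, 3.9, 4.1, 8.5, 10.1),
    sign = c(1, 1, 1, 1, -1, -1, -1, -1, -1))
}

validate_pka <- function(pka) {
  stopifnot(all(c("group", "pka", "sign") %in% names(pka)),
            all(pka$pka > 0 & pka$pka < 14),
            all(pka$sign %in% c(1, -1)))
  pka
}

#' Amino-acid composition of a protein
#'
#' @param protein protein string (standard 20-letter alphabet; `X`
#'   tolerated but excluded from fractions with a warning).
#' @return data.frame with columns `residue`, `count`, `fraction`
#'   (fractions over counted residues).
#' @export
aa_composition <- function(protein) {
  if (!nchar(protein)) stop("empty protein")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (any(ch == "X")) {
    warning(sum(ch == "X"), " unknown residue(s) 'X' excluded from fractions")
    ch <- ch[ch != "X"]
  }
  bad <- setdiff(unique(ch), AA20)
  if (length(bad)) stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(ch, levels = AA20))
  data.frame(residue = AA20, count = as.integer(counts),
             fraction = as.numeric(counts) / length(ch))
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch summation over ionizable side chains and both
#' termini: basic groups contribute `1 / (1 + 10^(pH - pKa))`, acidic
#' groups `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param protein protein string.
#' @param pH pH in (0, 14).
#' @param pka pKa table (see [default_pka_table()]).
#' @return signed net charge.
#' @export
net_charge <- function(protein, pH = 7.0, pka = default_pka_table()) {
  stopifnot(pH > 0, pH < 14)
  pka <- validate_pka(pka)
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  total <- 0
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]
    n <- if (g == "Nterm" || g == "Cterm") 1L else sum(ch == g)
    if (!n) next
    total <- total + n * if (pka$sign[i] > 0)
      1 / (1 + 10^(pH - pka$pka[i]))
    else
      -1 / (1 + 10^(pka$pka[i] - pH))
  }
  total
}

#' Isoelectric point by bisection
#'
#' Bisects on pH in [0, 14] until the net charge magnitude falls below
#' `tolerance`. Net charge is strictly decreasing in pH, so the zero
#' crossing is unique whenever both a positive and a negative ionizable
#' group are present (the termini suffice).
#'
#' @param protein protein string.
#' @param pka pKa table.
#' @param tolerance absolute charge tolerance at convergence.
#' @return the pI.
#' @export
isoelectric_point <- function(protein, pka = default_pka_table(),
                              tolerance = 1e-4) {
  lo <- 1e-8; hi <- 14 - 1e-8
  c_lo <- net_charge(protein, lo, pka)
  c_hi <- net_charge(protein, hi, pka)
  if (c_lo <= 0 || c_hi >= 0)
    stop("net charge does not cross zero in (0, 14): pI undefined")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    c_mid <- net_charge(protein, mid, pka)
    if (abs(c_mid) < tolerance) return(mid)
    if (c_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Full property record of a protein
#'
#' @param protein protein string.
#' @param pH pH at which the net charge is reported.
#' @param pka pKa table.
#' @return list with `length`, `composition`, `net_charge`, `pH`, `pI`.
#' @export
protein_properties <- function(protein, pH = 7.0, pka = default_pka_table()) {
  comp <- aa_composition(protein)
  list(length = nchar(protein), composition = comp,
       net_charge = net_charge(protein, pH, pka), pH = pH,
       pI = isoelectric_point(protein, pka))
}

#' Compare residue usage of a query protein against reference homologs
#'
#' Reports per-residue count deltas versus the mean reference count and
#' flags residues `decreased` (count below every reference) and `doubled`
#' (count at least twice the reference mean).
#'
#' @param query protein string.
#' @param references character vector of reference protein strings.
#' @return data.frame (`residue`, `query_count`, `ref_mean`, `delta`,
#'   `decreased`, `doubled`).
#' @export
compare_residue_usage <- function(query, references) {
  if (!length(references)) stop("need at least one reference")
  qc <- aa_composition(query)$count
  rc <- vapply(references, function(r) aa_composition(r)$count,
               integer(length(AA20)))
  ref_mean <- rowMeans(rc)
  ref_min <- apply(rc, 1, min)
  data.frame(residue = AA20, query_count = qc, ref_mean = ref_mean,
             delta = qc - ref_mean,
             decreased = qc < ref_min,
             doubled = qc >= 2 * ref_mean & ref_mean > 0)
}
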