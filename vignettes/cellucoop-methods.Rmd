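---
title: "Methods: classifying cellulolytic helpers and beneficiaries"
author: "cellucoop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying cellulolytic helpers and beneficiaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

In a cellulose-rich niche, cellulose degradation is a cooperative process:
endoglucanases are secreted enzymes whose products — cellodextrins such as
cellobiose — diffuse away from the producer and become a public good. Under
the Black Queen Hypothesis, community evolution tends to split such leaky
functions between *helpers*, which retain the costly secreted function, and
*beneficiaries*, which lose it and cross-feed on the products. `cellucoop`
implements a gene-content route to this classification: profile the
community (16S amplicons), annotate its genes (cellulases, downstream
glucosidases, cellodextrin transporters), corroborate taxon-level calls
with reference-independent contig binning, and classify each taxon's role
from presence/absence of the pathway genes.

# The role model

Let each taxon have boolean indicators over the closed feature set
{endoglucanase, beta-glucosidase, 6-phospho-beta-glucosidase, cellobiose
phosphorylase, PTS cel transporter, ABC ceb transporter}. The rules are:

* **helper** — endoglucanase present AND at least one of the three
  downstream assimilation genes present;
* **beneficiary** — endoglucanase absent AND at least one downstream gene
  present;
* **non-participant** — otherwise.

Transporters do not gate either role: a helper or beneficiary lacking both
characterized cellodextrin transporter families is flagged
`unclassified_possible`, reflecting that only two bacterial cellodextrin
uptake systems have been characterized and a taxon that demonstrably
assimilates cellodextrins most plausibly encodes an uncharacterized one.
An endoglucanase-only taxon has no defined role in the source analyses; we
classify it as a helper with a "no-assimilation" warning, since it still
produces the public good. This is a deliberate design choice, exposed in
the warning rather than hidden.

The classification is row-independent (removing a taxon never changes
another's role) and monotone (adding features never demotes a taxon to
non-participant; adding endoglucanase to a beneficiary always yields a
helper). Both properties are enforced by tests.

# The synthetic study system

The generator emulates the *structure* of a two-sample, cellulose-rich
alkaline community so that every downstream stage can be validated against
known truth:

* **Taxonomy** — six dominant genera spanning three phyla (two
  Bacteroidetes, three Firmicutes, one Proteobacteria) plus one minor
  Actinobacteria genus; six ranks from domain to genus.
* **Genomes** — 50 kb per genome by default: long enough to host the gene
  cassette, ten universal single-copy marker genes and one 16S locus at
  realistic gene density, small enough that a full ten-seed benchmark runs
  on one CPU in minutes. Each genus gets an order-1 Markov backbone whose
  stationary composition matches its GC target and whose dinucleotide
  bias is a fixed function of the genus name — the oligonucleotide
  "genomic signature" that composition binning exploits. GC targets are
  spaced ~0.07 apart (0.30–0.65); this spacing is a design choice to make
  composition binning exercisable at desk scale, not a claim about the
  genera's literal GC contents.
* **Cassettes** — mirror the reported gene content: one helper with the
  full pathway plus PTS transporters, one helper with cellobiose
  phosphorylase but no recognized transporter, three beneficiaries with
  downstream genes plus transporters, one transporter-less beneficiary.
  Two copies of each cassette gene are planted (paralogs are common for
  these functions, and duplication gives full-length genes a realistic
  chance of being contained in a sheared contig). Genes are
  reverse-translated from diverged protein copies using GC-biased
  synonymous codons, so coding regions carry the host genome's
  composition signature, as real codon bias does.
* **Abundances** — i.i.d. log-normal per sample, normalized to 1. The
  source analyses report no abundance model; log-normal is this package's
  choice and is stated as such.
* **Amplicons** — the v3–v4 region bracketed by the two degenerate
  primers, embedded in a 1500 nt 16S scaffold; primer-binding sites are
  conserved (protected from mutation), the inter-primer region diverges
  ~10% between genera and ~1% within. 420 nt amplicons with 250 bp paired
  reads give ~80 bp overlaps. Phred scores are drawn from a configured
  normal profile; substitution errors are independent of the reported
  quality. Indels and chimeras are out of scope.

What passing tests on this generator do **not** show: robustness to
chimeras, indel errors, multi-copy 16S operons, strain-level variation,
horizontally transferred cassettes with alien composition, or taxa absent
from the classifier's reference — all of which complicate real data.

# Stage-by-stage numerical choices

**Merging and filtering.** Pair merging scores every ungapped overlap of at
least 50 bp by matches minus mismatches, breaking ties towards the longer
overlap, and rejects pairs whose best overlap has a mismatch fraction above
0.25. Disagreeing overlap bases take the higher-quality call; agreeing
positions take the maximum quality. The filter retains a merged sequence
iff length ≥ 300, expected error Σ 10^(−Q/10) ≤ 0.5, and mean Q > 30. The
quality rule is interpreted as *mean* Phred over the merged read: a
per-base Q > 30 requirement would discard nearly every read at realistic
error profiles, which cannot be what a filter retaining thousands of
sequences did.

**Classification.** The word model is the classic naive-Bayes 8-mer
classifier: `P(word | genus) = (m + prior) / (M + 1)` with `m` the number
of the genus's reference sequences containing the word, `M` the genus
size, and `prior = (n + 0.5) / (N + 1)` the overall word frequency. Each
of 100 bootstrap replicates samples ⌊W/8⌋ of the W distinct query words
with replacement; genus confidence is the vote fraction, and the
confidence of a higher rank is the sum over its descendant genera, which
makes rank confidence monotone by construction. The published confidence
is per-sequence (a bootstrap vote fraction); an OTU-grouped median would
require OTU clustering, which is out of scope, so "median confidence" is
realized as the per-sequence confidence. Ties in the maximum-likelihood
genus break lexicographically for determinism. Escalation accepts the most
specific rank with confidence ≥ 0.5 and names above-genus acceptances
`<AcceptedName>_<genus>-like`.

**Abundance tables.** Counts are normalized within sample first; taxa
observed in exactly one sample are then removed *without* rescaling the
remaining columns — the filtered relative abundances are what PCA
consumes, so rescaling would change the ordination. Both tables are
returned. PCA is covariance PCA (all columns share the relative-abundance
scale); the sign convention makes each component's largest-magnitude
loading positive.

**Annotation.** The ORF caller reports maximal ATG-to-stop frames with
proteins ≥ 100 aa across six frames, resolving same-strand overlaps to the
longest — a deliberate simplification standing in for a trained gene
finder, adequate because the planted genes are clean single-exon ORFs.
Genus assignment aligns each protein against the packaged per-genus
reference set with Smith–Waterman under BLOSUM62 (gap open 10, extend
0.5); a shared-5-mer-word prefilter (the standard seeding heuristic)
selects candidate references before alignment. The best hit wins by score,
then identity, then lexicographic reference id; hits scoring below 1.0 per
query residue are "unassigned" — a level chosen far above shuffle-null
scores (~0.3–0.4/aa) and far below true-hit scores (~4/aa), verified by a
100-shuffle null test. Domain and functional-marker detection uses
position-specific scoring profiles built from eight diverged copies of
each seed with a +0.5 pseudocount against a uniform background; each
profile's threshold is calibrated at build time as max(shuffle-null mean +
6 SD, 20% of the seed's own score). Profile thresholds therefore travel
with the profiles, making significance self-contained rather than
database-relative.

**Binning.** Canonical (strand-pooled) 5-mer frequencies over contigs
≥ 1000 bp feed a linear reduction to at most 50 dimensions and an exact
t-SNE-style embedding (perplexity 30, 500 gradient iterations, early
exaggeration 12 for 125 iterations, adaptive gains). The
Barnes–Hut `theta` parameter is accepted for interface parity and ignored
by the exact implementation. Two determinism guarantees are enforced by
construction because the gradient map is numerically chaotic: rows are
processed in name order (making the embedding exactly invariant to input
order) and duplicate signatures are collapsed onto a single embedded point
(identical inputs land on identical coordinates). The map is initialized
from the first two principal components, so the embedding is fully
deterministic and the `seed` argument exists for interface parity.
Clusters are extracted by a density method (DBSCAN-style) whose radius
defaults to the 95th percentile of 5-nearest-neighbor distances with a
minimum neighborhood of 5 — the published analysis clustered visually, so
cluster extraction is necessarily this package's own choice. Bin purity is
the majority-genus fraction; genome completeness is the fraction of a
genome's *binnable* (≥ 1000 bp) contigs captured by its best bin.

**Protein properties.** Net charge is the Henderson–Hasselbalch sum over
ionizable side chains and both termini with the EMBOSS default pKa table;
pI is found by bisection to |charge| < 1e-4, which a 1e-3 pH grid oracle
confirms to within 0.01 pH units. Charges are reported at pH 7.0 by
default and the pH is echoed in output headers, because the pH behind
published single-number charges is typically unstated.

# Reference data

All reference material — toy reference proteins per feature and family,
scoring profiles, 16S templates and the labeled training set — is
generated deterministically from a fixed internal seed at first use and
cached. The sequences are synthetic stand-ins reproducing the structure of
curated resources (CAZy-style family seeds, transporter references, an
RDP-style training set), not their content; they make the package
self-contained and its tests hermetic. Cross-genus divergence of reference
proteins (~80% identity to the seed) and within-genus gene divergence
(~90% to the genus reference) put best-hit identities in the 60–90% band
where such assignment is typically exercised.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → classify-16S → annotate → bin → roles
→ protprops, writing every table as TSV plus a manifest of all parameters
and the seed. A single master seed fans out to per-stage sub-seeds through
a fixed hash of the stage name, so disabling one stage never shifts
another's random stream; reruns with the same configuration are
byte-identical. Benchmarks in the test suite use 6 genomes × 150 contigs ×
2 samples × 150 read pairs across ten seeds — sizes chosen so the full
suite validates every claim on one CPU in minutes.

# Known limitations

* The ORF caller misses genes truncated by contig edges and genes using
  non-ATG starts; the benchmark compensates with two planted copies.
* Composition binning cannot separate genera of near-identical genomic
  signatures; the emulated community spaces them deliberately.
* The embedding's `theta` and `seed` parameters are interface parity only.
* E-value semantics of database search tools are replaced by calibrated
  score thresholds; absolute significance levels are not comparable to
  published e-value cutoffs.
* The interaction network is qualitative (presence of produce/consume
  edges); no flux or growth model is implied.
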