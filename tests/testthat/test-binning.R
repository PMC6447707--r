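test_that("signatures are normalized, canonical and strand-invariant", {
  s <- kmer_signature(strrep("A", 1004))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(unname(s["AAAAA"]), 1)
  set.seed(30)
  x <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_equal(kmer_signature(x), kmer_signature(cellucoop:::revcomp(x)),
               tolerance = 1e-12)
  expect_length(kmer_signature(x), 512)
  expect_null(kmer_signature(strrep("A", 999)))
})

test_that("signatures equal the direct counting oracle", {
  set.seed(31)
  x <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  s <- kmer_signature(x)
  o <- signature_oracle(x)
  expect_equal(unname(s[names(o)]), unname(as.numeric(o)), tolerance = 1e-12)
  expect_equal(sum(s > 0), length(o))
})

test_that("batch signatures match the single-contig computation", {
  set.seed(32)
  df <- data.frame(
    id = c("c1", "c2", "c3"),
    sequence = c(paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""),
                 strrep("A", 500),  # below the length threshold
                 paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")))
  m <- contig_signatures(df)
  expect_equal(rownames(m), c("c1", "c3"))
  expect_equal(attr(m, "skipped"), "c2")
  expect_equal(unname(m["c1", ]), unname(kmer_signature(df$sequence[1])),
               tolerance = 1e-12)
})

test_that("distinct-composition contig sets separate in the embedding", {
  genomes <- fix_genomes()
  two <- shear_contigs(genomes[c("Clostridium", "Acetivibrio")],
                       n_per_genome = 100,
                       length_distribution = list(min = 1000, max = 3000,
                                                  frac_long = 1),
                       seed = 33)
  sig <- contig_signatures(two)
  emb <- embed_signatures(sig)
  labels <- two$truth$genus[match(rownames(emb), two$truth$contig)]
  expect_gt(silhouette_mean(emb, labels), 0.5)
})

test_that("embedding is deterministic and order-invariant", {
  genomes <- fix_genomes()
  cs <- shear_contigs(genomes[1:3], n_per_genome = 40,
                      length_distribution = list(min = 1000, max = 2000,
                                                 frac_long = 1),
                      seed = 34)
  sig <- contig_signatures(cs)
  e1 <- embed_signatures(sig, max_iter = 150)
  e2 <- embed_signatures(sig, max_iter = 150)
  expect_identical(e1, e2)
  perm <- sample(nrow(sig))
  e3 <- embed_signatures(sig[perm, ], max_iter = 150)
  expect_equal(e3[rownames(e1), ], e1, tolerance = 1e-6)
})

test_that("duplicated signatures stay near-coincident in the embedding", {
  set.seed(35)
  base <- matrix(runif(40 * 20), 40, 20)
  base <- base / rowSums(base)
  sig <- rbind(base, base[1, , drop = FALSE])
  rownames(sig) <- c(paste0("c", 1:40), "dup")
  expect_warning(emb <- embed_signatures(sig, max_iter = 200), "perplexity")
  rng <- max(dist(emb))
  expect_lt(sqrt(sum((emb["c1", ] - emb["dup", ])^2)), 0.01 * rng)
})

test_that("density clustering separates well-spaced blobs", {
  set.seed(36)
  blob1 <- cbind(rnorm(100), rnorm(100))
  blob2 <- cbind(rnorm(100, 20), rnorm(100))
  emb <- rbind(blob1, blob2)
  rownames(emb) <- paste0("p", 1:200)
  bins <- cluster_embedding(emb)
  expect_equal(length(bins$bins), 2)
  for (b in bins$bins) {
    idx <- as.integer(sub("p", "", b))
    expect_true(all(idx <= 100) || all(idx > 100))
  }
  ## a too-strict radius declares everything noise
  strict <- cluster_embedding(emb, eps = 1e-9)
  expect_equal(length(strict$bins), 0)
  expect_length(strict$noise, 200)
  ## a single point is noise
  single <- cluster_embedding(matrix(0, 1, 2,
                                     dimnames = list("x", NULL)))
  expect_equal(single$noise, "x")
})

test_that("bin quality reports purity and completeness against truth", {
  bins <- structure(list(bins = list(bin1 = c("a1", "a2", "a3", "a4"),
                                     bin2 = c("b1", "b2", "a5", "b3")),
                         noise = "b4"), class = "bin_set")
  truth <- data.frame(contig = c(paste0("a", 1:5), paste0("b", 1:4)),
                      genus = c(rep("A", 5), rep("B", 4)))
  q <- bin_quality(bins, truth)
  expect_equal(q$per_bin$purity, c(1.0, 0.75))
  expect_equal(q$per_genome$completeness[q$per_genome$genus == "A"], 0.8)
  expect_equal(q$per_genome$completeness[q$per_genome$genus == "B"], 0.75)
})

test_that("random assignment of two equal genomes gives purity near half", {
  set.seed(37)
  ids <- paste0("c", 1:400)
  truth <- data.frame(contig = ids, genus = rep(c("A", "B"), each = 200))
  shuffled <- sample(ids)
  bins <- structure(list(bins = list(bin1 = shuffled[1:200],
                                     bin2 = shuffled[201:400]),
                         noise = character(0)), class = "bin_set")
  q <- bin_quality(bins, truth)
  expect_lt(max(abs(q$per_bin$purity - 0.5)), 0.15)
})

test_that("marker and function overlays label candidate bins", {
  bins <- structure(list(bins = list(bin1 = c("x1", "x2"),
                                     bin2 = c("y1", "y2"),
                                     bin3 = "z1"),
                         noise = character(0)), class = "bin_set")
  marker <- data.frame(contig = c("x1", "x2", "y1"),
                       genus = c("Paludibacter", "Paludibacter", "Tolumonas"))
  fn <- data.frame(contig = c("x1", "x2", "y2"),
                   flag = c("endoglucanase", "beta_glucosidase",
                            "beta_glucosidase"))
  ov <- overlay_annotations(bins, marker, fn)
  expect_equal(ov$candidate, c("helper-candidate", "beneficiary-candidate",
                               "unlabeled"))
  expect_equal(ov$top_genus[1], "Paludibacter")
  expect_warning(
    overlay_annotations(bins, data.frame(contig = "nope", genus = "G"), fn),
    "absent from the embedding")
})
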