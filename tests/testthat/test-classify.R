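two_genus_tree <- function() {
  build_taxonomy(data.frame(phylum = c("P1", "P2"), class = c("C1", "C2"),
                            order = c("O1", "O2"), family = c("F1", "F2"),
                            genus = c("Alpha", "Beta")))
}

test_that("word model probabilities follow the pseudocount formula", {
  ## single-word sequences give exact control over word counts
  ref <- data.frame(id = paste0("s", 1:5),
                    genus = c("Alpha", "Alpha", "Alpha", "Beta", "Beta"),
                    seq = c(rep("AAAAAAAA", 3), rep("CCCCCCCC", 2)))
  model <- train_word_model(ref, two_genus_tree())
  N <- 5
  prior_w1 <- (3 + 0.5) / (N + 1)   # word in all Alpha sequences
  prior_w2 <- (2 + 0.5) / (N + 1)
  expect_equal(model$logp["AAAAAAAA", "Alpha"], log((3 + prior_w1) / 4))
  expect_equal(model$logp["AAAAAAAA", "Beta"], log((0 + prior_w1) / 3))
  expect_equal(model$logp["CCCCCCCC", "Beta"], log((2 + prior_w2) / 3))
  ## pseudocount keeps every probability positive
  expect_true(all(is.finite(model$logp)))
  ## determinism
  expect_identical(model, train_word_model(ref, two_genus_tree()))
  ## unknown genus label errors
  bad <- ref; bad$genus[1] <- "Gamma"
  expect_error(train_word_model(bad, two_genus_tree()), "absent")
})

test_that("self-classification against a single-genus model is certain", {
  ref <- data.frame(id = "s1", genus = "Alpha",
                    seq = paste(rep("ACGTTGCA", 8), collapse = ""))
  tree <- build_taxonomy(data.frame(phylum = "P1", class = "C1",
                                    order = "O1", family = "F1",
                                    genus = "Alpha"))
  model <- train_word_model(ref, tree)
  conf <- classify_with_bootstrap(model, ref$seq[1], 100, seed = 1)
  expect_equal(conf$confidence[conf$rank == "genus"], 1.0)
  expect_equal(conf$name[conf$rank == "genus"], "Alpha")
})

test_that("a symmetric two-genus query has confidence near one half", {
  set.seed(3)
  x <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  y <- chartr("ACGT", "CGTA", x)  # same word structure, disjoint words
  ref <- data.frame(id = c("s1", "s2"), genus = c("Alpha", "Beta"),
                    seq = c(x, y))
  model <- train_word_model(ref, two_genus_tree())
  conf <- classify_with_bootstrap(model, paste0(x, y), 100, seed = 7)
  expect_lt(abs(conf$confidence[conf$rank == "genus"] - 0.5),
            3 * sqrt(0.25 / 100) + 0.1)
})

test_that("rank confidence is monotone from genus to phylum", {
  model <- train_word_model(fix_ref()$ref16s, fix_ref()$tree)
  genomes <- fix_genomes()
  prof <- structure(list(sample_id = "s1",
                         abundance = setNames(rep(1 / 6, 6), names(genomes))),
                    class = "community_profile")
  am <- simulate_amplicons(genomes, prof, n_pairs = 12, seed = 6)
  for (i in 1:12) {
    m <- merge_pairs(am$fwd[[i]], am$rev[[i]])
    conf <- classify_with_bootstrap(model, m$bases, 50, seed = i)
    v <- setNames(conf$confidence, conf$rank)
    expect_true(v["family"] >= v["genus"] - 1e-12)
    expect_true(v["order"] >= v["family"] - 1e-12)
    expect_true(v["class"] >= v["order"] - 1e-12)
    expect_true(v["phylum"] >= v["class"] - 1e-12)
  }
  expect_error(classify_with_bootstrap(model, "ACGT", 10, 1), "shorter")
})

test_that("rank escalation follows the 0.5 threshold with display naming", {
  mk_conf <- function(g, f, o, c, p) {
    data.frame(rank = c("genus", "family", "order", "class", "phylum"),
               name = c("Clostridium", "Clostridiaceae", "Clostridiales",
                        "Clostridia", "Firmicutes"),
               confidence = c(g, f, o, c, p))
  }
  a1 <- escalate_assignment(mk_conf(0.6, 0.7, 0.8, 0.9, 1.0))
  expect_equal(a1$accepted_rank, "genus")
  expect_equal(a1$display, "Clostridium")
  a2 <- escalate_assignment(mk_conf(0.4, 0.8, 0.9, 0.9, 1.0))
  expect_equal(a2$accepted_rank, "family")
  expect_equal(a2$display, "Clostridiaceae_clostridium-like")
  a3 <- escalate_assignment(mk_conf(0.1, 0.1, 0.1, 0.1, 0.1))
  expect_equal(a3$display, "unclassified")
  ## boundary: exactly at threshold is accepted
  a4 <- escalate_assignment(mk_conf(0.5, 0.9, 0.9, 0.9, 1.0))
  expect_equal(a4$accepted_rank, "genus")
})

test_that("in-reference amplicons are accepted at genus with correct label", {
  model <- train_word_model(fix_ref()$ref16s, fix_ref()$tree)
  genomes <- fix_genomes()
  prof <- structure(list(sample_id = "s1",
                         abundance = setNames(rep(1 / 6, 6), names(genomes))),
                    class = "community_profile")
  am <- simulate_amplicons(genomes, prof, n_pairs = 100, seed = 17)
  ok <- 0
  for (i in 1:100) {
    m <- merge_pairs(am$fwd[[i]], am$rev[[i]])
    if (is.null(m)) next
    a <- escalate_assignment(
      classify_with_bootstrap(model, m$bases, 100, seed = i))
    if (identical(a$accepted_rank, "genus") &&
        identical(a$display, am$truth$genus[i])) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.95)
})

test_that("abundance tables normalize and drop single-sample taxa", {
  s1 <- c(rep("A", 50), rep("B", 30), rep("C", 20))
  s2 <- c(rep("A", 60), rep("B", 40))
  tab <- build_abundance_table(list(
    sample1 = lapply(s1, fake_assignment),
    sample2 = lapply(s2, fake_assignment)))
  expect_equal(unname(tab$raw["sample1", c("A", "B", "C")]),
               c(0.5, 0.3, 0.2))
  ## C appears only in sample 1: dropped after normalization, no rescale
  expect_false("C" %in% colnames(tab$filtered))
  expect_equal(unname(rowSums(tab$filtered)), c(0.8, 1.0))
  expect_true("C" %in% colnames(tab$raw))
  expect_equal(unname(rowSums(tab$raw)), c(1, 1), tolerance = 1e-9)
  ## one shared taxon, two samples
  tab1 <- build_abundance_table(list(
    a = lapply(rep("X", 5), fake_assignment),
    b = lapply(rep("X", 9), fake_assignment)))
  expect_equal(unname(tab1$filtered[, "X"]), c(1, 1))
  expect_error(build_abundance_table(list(a = list(fake_assignment("X")))),
               "two samples")
})

test_that("PCA matches the eigendecomposition oracle", {
  set.seed(5)
  x <- matrix(runif(6 * 20), 6, 20,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:20)))
  x <- x / rowSums(x)
  p <- pca_abundance(x, n_components = 3)
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  for (j in 1:3) {
    v <- ev$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_equal(unname(p$coordinates[, j]), unname(as.numeric(xc %*% v)),
                 tolerance = 1e-8)
    expect_equal(p$variance_fraction[j],
                 ev$values[j] / sum(pmax(ev$values, 0)), tolerance = 1e-8)
  }
})

test_that("PCA handles rank-1, duplicated and reordered inputs", {
  x2 <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("t1", "t2")))
  p2 <- pca_abundance(x2)
  expect_equal(p2$variance_fraction[1], 1.0)
  ## duplicated sample rows coincide
  x3 <- rbind(x2, b2 = x2[2, ])
  p3 <- pca_abundance(x3)
  expect_equal(unname(p3$coordinates[2, ]), unname(p3$coordinates[3, ]),
               tolerance = 1e-10)
  ## taxon column order only affects coordinates up to sign
  set.seed(9)
  x <- matrix(runif(5 * 12), 5, 12,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:12)))
  pa <- pca_abundance(x)
  pb <- pca_abundance(x[, sample(ncol(x))])
  for (j in 1:2)
    expect_equal(abs(unname(pa$coordinates[, j])),
                 abs(unname(pb$coordinates[, j])), tolerance = 1e-8)
  ## constant table warns and returns zeros
  expect_warning(pc <- pca_abundance(matrix(0.5, 3, 4)), "zero variance")
  expect_true(all(pc$coordinates == 0))
})
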