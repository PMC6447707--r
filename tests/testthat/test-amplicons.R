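test_that("error-free read pairs reconstruct the amplified region exactly", {
  genomes <- fix_genomes()
  prof <- structure(list(sample_id = "s1",
                         abundance = setNames(rep(1 / 6, 6), names(genomes))),
                    class = "community_profile")
  am <- simulate_amplicons(genomes, prof, error_rate = 0, n_pairs = 20,
                           seed = 4)
  primers <- amplicon_primers()
  for (i in 1:20) {
    m <- merge_pairs(am$fwd[[i]], am$rev[[i]])
    expect_false(is.null(m))
    src <- am$truth$genus[i]
    tmpl <- cellucoop:::locate_amplicon(
      genomes[[src]]$sequence, primers["fwd"], primers["rev"])
    expect_identical(m$bases, tmpl)
  }
  ## truth table is total
  expect_equal(nrow(am$truth), 20)
})

test_that("degenerate primer bases match per IUPAC definition", {
  ## primer base M matches A and C but not G or T
  mk <- function(base) paste0(strrep("T", 40), "GGAA", base, "GGCC",
                              strrep("T", 60), "CCTTGG", strrep("A", 40))
  fwd <- "GGAAMGGCC"
  rev <- "CCAAGG"  # reverse primer; template carries its reverse complement
  for (b in c("A", "C"))
    expect_false(is.null(cellucoop:::locate_amplicon(mk(b), fwd, rev)))
  for (b in c("G", "T"))
    expect_null(cellucoop:::locate_amplicon(mk(b), fwd, rev))
})

test_that("substitution errors accumulate at the configured rate", {
  genomes <- fix_genomes()
  prof <- structure(list(sample_id = "s1",
                         abundance = setNames(rep(1 / 6, 6), names(genomes))),
                    class = "community_profile")
  n <- 400
  am <- simulate_amplicons(genomes, prof, error_rate = 0.01, n_pairs = n,
                           seed = 5)
  primers <- amplicon_primers()
  tmpl <- lapply(genomes, function(g)
    cellucoop:::locate_amplicon(g$sequence, primers["fwd"], primers["rev"]))
  mism <- 0; tot <- 0
  for (i in seq_len(n)) {
    t_i <- substr(tmpl[[am$truth$genus[i]]], 1, 250)
    r_i <- am$fwd[[i]]$bases
    mism <- mism + sum(strsplit(r_i, "")[[1]] != strsplit(t_i, "")[[1]])
    tot <- tot + nchar(r_i)
  }
  expect_lt(abs(mism / tot - 0.01), 3 * sqrt(0.01 * 0.99 / tot))
})

test_that("merging uses best overlap with exact length arithmetic", {
  set.seed(8)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 340, TRUE), collapse = "")
  fwd <- read_q(substr(tmpl, 1, 200), 38)
  rev <- read_q(cellucoop:::revcomp(substr(tmpl, 141, 340)), 38)
  m <- merge_pairs(fwd, rev, min_overlap = 50)
  expect_equal(nchar(m$bases), 200 + 200 - 60)
  expect_identical(m$bases, tmpl)
  ## overlap of 49 is rejected at the 50 bp minimum
  rev49 <- read_q(cellucoop:::revcomp(substr(tmpl, 152, 340)), 38)
  expect_null(merge_pairs(fwd, rev49, min_overlap = 50))
  ## but accepted when the minimum allows it
  expect_false(is.null(merge_pairs(fwd, rev49, min_overlap = 49)))
})

test_that("overlap disagreements resolve to the higher-quality base", {
  set.seed(21)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  fwd_b <- substr(tmpl, 1, 130)
  rev_region <- substr(tmpl, 71, 200)
  ## corrupt one overlap position in the forward read and mark it Q10
  orig <- substr(fwd_b, 100, 100)
  substr(fwd_b, 100, 100) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  fwd <- amplicon_read("r", fwd_b, c(rep(40, 99), 10, rep(40, 30)))
  rev <- read_q(cellucoop:::revcomp(rev_region), 40)
  m <- merge_pairs(fwd, rev)
  expect_identical(m$bases, tmpl)          # Q40 call wins over Q10
  expect_equal(nchar(m$bases), 200)
  ## agreement positions carry the max of the two qualities
  fwd2 <- read_q(substr(tmpl, 1, 130), 20)
  m2 <- merge_pairs(fwd2, rev)
  expect_true(all(m2$quals[71:130] == 40))
  expect_true(all(m2$quals[1:70] == 20))
})

test_that("the three filter rules fire exactly on boundary cases", {
  r299 <- read_q(strrep("A", 299), 40, "short")   # short, perfect quality
  r300_40 <- read_q(strrep("A", 300), 40, "good") # EE = 300e-4 = 0.03
  r300_20 <- read_q(strrep("A", 300), 20, "noisy") # EE = 3.0
  out <- filter_sequences(list(r299, r300_40, r300_20))
  expect_length(out$retained, 1)
  expect_identical(out$retained[[1]]$id, "good")
  expect_equal(expected_error(r300_40), 300 * 10^(-4))
  expect_equal(expected_error(r300_20), 3.0)
  expect_match(out$log$rule[out$log$id == "short"], "min_length")
  expect_match(out$log$rule[out$log$id == "noisy"], "expected_error")
})

test_that("the filter is order-independent (pure conjunction of rules)", {
  set.seed(13)
  reads <- lapply(1:50, function(i) {
    n <- sample(250:450, 1)
    amplicon_read(paste0("x", i),
                  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
                  sample(15:41, n, TRUE))
  })
  out <- filter_sequences(reads)
  manual <- Filter(function(r)
    nchar(r$bases) >= 300 && expected_error(r) <= 0.5 && mean(r$quals) > 30,
    reads)
  expect_identical(vapply(out$retained, `[[`, character(1), "id"),
                   vapply(manual, `[[`, character(1), "id"))
})

test_that("FASTQ round-trips through Sanger Phred+33", {
  reads <- list(read_q("ACGTACGTAC", 35, "a"),
                amplicon_read("b", "GGTTAACC", c(2, 10, 20, 30, 40, 41, 5, 0)))
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(length(back), 2)
  expect_identical(back[[2]]$bases, "GGTTAACC")
  expect_identical(back[[2]]$quals, c(2L, 10L, 20L, 30L, 40L, 41L, 5L, 0L))
})
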