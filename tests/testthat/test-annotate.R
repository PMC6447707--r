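test_that("a single embedded ORF is called exactly", {
  set.seed(2)
  flank1 <- paste(sample(c("C", "G", "T"), 210, TRUE), collapse = "")
  flank2 <- paste(sample(c("C", "G", "T"), 180, TRUE), collapse = "")
  gene <- paste0("ATG", strrep("GGC", 150), "TAA")  # Met + 150 Gly
  contig <- paste0(flank1, gene, flank2)
  orfs <- find_orfs(contig, min_protein_length = 100)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$protein[1], paste0("M", strrep("G", 150)))
  expect_equal(orfs$strand[1], "+")
  expect_equal(orfs$start[1], 210)
  expect_equal(orfs$end[1], 210 + nchar(gene))
  expect_equal((orfs$end[1] - orfs$start[1]) %% 3, 0)
})

test_that("reverse-strand ORFs equal forward calls on the complement", {
  set.seed(4)
  flank1 <- paste(sample(c("C", "G", "T"), 150, TRUE), collapse = "")
  flank2 <- paste(sample(c("C", "G", "T"), 99, TRUE), collapse = "")
  gene <- paste0("ATG", strrep("GCC", 120), "TAG")
  contig <- paste0(flank1, gene, flank2)
  fwd <- find_orfs(contig)
  rev <- find_orfs(cellucoop:::revcomp(contig))
  expect_equal(nrow(rev), 1)
  expect_identical(rev$protein, fwd$protein)
  expect_equal(rev$strand[1], "-")
  ## forward-coordinate interval maps to the mirrored position
  L <- nchar(contig)
  expect_equal(rev$start[1], L - fwd$end[1])
  expect_equal(rev$end[1], L - fwd$start[1])
})

test_that("stop-saturated and invalid contigs are handled", {
  expect_equal(nrow(find_orfs(strrep("TAA", 150))), 0)
  expect_error(find_orfs("ACGTQQQ"), "non-ACGTN")
})

test_that("local alignment scores and identities behave canonically", {
  set.seed(6)
  p <- random_p <- paste(sample(cellucoop:::AA20, 80, TRUE), collapse = "")
  a <- align_proteins(p, p)
  expect_equal(a$identity, 100)
  q <- paste(sample(cellucoop:::AA20, 60, TRUE), collapse = "")
  expect_equal(align_proteins(p, q)$score, align_proteins(q, p)$score)
  expect_error(align_proteins("", p), "empty")
})

test_that("Smith-Waterman agrees with the brute-force DP oracle", {
  set.seed(10)
  for (i in 1:25) {
    q <- paste(sample(cellucoop:::AA20, sample(2:5, 1), TRUE), collapse = "")
    s <- paste(sample(cellucoop:::AA20, sample(2:5, 1), TRUE), collapse = "")
    expect_equal(align_proteins(q, s)$score, sw_dp_oracle(q, s),
                 info = paste(q, s))
  }
})

test_that("best-hit genus assignment recovers verbatim copies and ties", {
  ref <- fix_ref()
  row <- ref$refdb[ref$refdb$id == "Clostridium|endoglucanase", ]
  hit <- assign_genus(row$protein, ref$refdb)
  expect_equal(hit$genus, "Clostridium")
  expect_equal(hit$identity, 100)
  ## two equal-score hits: lexicographically lower reference id wins
  p <- paste(sample(cellucoop:::AA20, 120, TRUE), collapse = "")
  db <- data.frame(id = c("zref", "aref"), genus = c("Gz", "Ga"),
                   protein = c(p, p))
  expect_equal(assign_genus(p, db)$ref_id, "aref")
  expect_equal(assign_genus(p, db)$genus, "Ga")
})

test_that("shuffled proteins fall below the assignment threshold", {
  ref <- fix_ref()
  seed_p <- ref$refdb$protein[1]
  set.seed(12)
  assigned <- 0
  for (i in 1:100) {
    shuf <- paste(sample(strsplit(seed_p, "")[[1]]), collapse = "")
    if (!is.null(assign_genus(shuf, ref$refdb))) assigned <- assigned + 1
  }
  expect_lte(assigned / 100, 0.05)
})

test_that("per-genus identity statistics use the sample SD", {
  hits <- data.frame(genus = c("A", "A", "A", "B"),
                     identity = c(60, 70, 80, 99))
  st <- genus_identity_stats(hits)
  expect_equal(st$genus, c("A", "B"))  # sorted by descending n
  expect_equal(st$mean_identity[1], 70)
  expect_equal(st$sd_identity[1], 10)
  expect_equal(st$sd_identity[2], 0)
  expect_true(st$single_hit[2])
  same <- genus_identity_stats(data.frame(genus = "C",
                                          identity = c(75, 75, 75)))
  expect_equal(same$sd_identity, 0)
})

test_that("functional labels follow the marker + domain rules", {
  dh_gh5 <- data.frame(family = "GH5", start = 0L, end = 200L, score = 100)
  mh_endo <- data.frame(family = "EC:3.2.1.4", start = 0L, end = 100L,
                        score = 80)
  a <- assign_function_labels("g1", "Clostridium", dh_gh5, mh_endo)
  expect_match(a$ec_labels, "EC:3.2.1.4")
  ## beta-glucosidase marker alone never yields an endoglucanase label
  mh_bgl <- data.frame(family = "EC:3.2.1.21", start = 0L, end = 100L,
                       score = 80)
  b <- assign_function_labels("g2", "X", dh_gh5[0, ], mh_bgl)
  expect_equal(b$ec_labels, "EC:3.2.1.21")
  ## endoglucanase marker without a cellulase-family domain is not labeled
  c1 <- assign_function_labels("g3", "X", dh_gh5[0, ], mh_endo)
  expect_false(grepl("EC:3.2.1.4", c1$ec_labels))
  ## transporter markers map directly
  mh_pts <- data.frame(family = "PTS_CelB", start = 0L, end = 100L,
                       score = 80)
  d <- assign_function_labels("g4", "X", dh_gh5[0, ], mh_pts)
  expect_equal(d$transporters, "PTS_CelB")
})

test_that("the Venn of GH family sets matches enumeration", {
  f <- cellulase_families()
  same <- gh_family_venn(f, f, f)
  expect_equal(unname(same["ABC"]), 13)
  expect_equal(sum(same), 13)
  dis <- gh_family_venn(c("GH1", "GH2"), c("GH3"), c("GH4", "GH5", "GH6"))
  expect_equal(unname(dis[c("A_only", "B_only", "C_only")]), c(2, 1, 3))
  expect_equal(sum(dis[c("AB", "AC", "BC", "ABC")]), 0)
  set.seed(14)
  pool <- paste0("GH", 1:40)
  for (i in 1:10) {
    a <- sample(pool, sample(5:20, 1)); b <- sample(pool, sample(5:20, 1))
    c3 <- sample(pool, sample(5:20, 1))
    expect_equal(gh_family_venn(a, b, c3), venn_oracle(a, b, c3))
    ## permutation invariance up to region relabeling
    swapped <- gh_family_venn(b, a, c3)
    expect_equal(unname(swapped[c("B_only", "A_only", "C_only", "AB", "BC",
                                  "AC", "ABC")]),
                 unname(gh_family_venn(a, b, c3)[c("A_only", "B_only",
                                                   "C_only", "AB", "AC",
                                                   "BC", "ABC")]))
  }
})

test_that("alignment is invariant to sequence naming and order", {
  ref <- fix_ref()
  db <- ref$refdb[1:10, ]
  attr(db, "wordsets") <- NULL
  p <- cellucoop:::mutate_protein(db$protein[4], 0.9)
  h1 <- assign_genus(p, db)
  db2 <- db[sample(nrow(db)), ]
  h2 <- assign_genus(p, db2)
  expect_equal(h1$ref_id, h2$ref_id)
  expect_equal(h1$score, h2$score)
})
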