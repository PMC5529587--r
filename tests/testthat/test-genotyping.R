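test_that("genotyping score matches closed-form boundary cases", {
  expect_equal(genotyping_score(3, m = 1, t = 3), 1.0)
  expect_equal(genotyping_score(2, m = 1, t = 3), 0.0)
  # two alleles, one read each required: 2 of the 4 equally likely
  # assignments of 2 reads cover both alleles
  expect_equal(genotyping_score(2, m = 2, t = 1), 0.5)
})

test_that("genotyping score is monotone in T and decreasing in m and t", {
  sc <- genotyping_score(20:60, m = 4, t = 2)
  expect_true(all(diff(sc) >= 0))
  expect_true(genotyping_score(40, m = 5, t = 2) <=
                genotyping_score(40, m = 4, t = 2))
  expect_true(genotyping_score(40, m = 4, t = 3) <=
                genotyping_score(40, m = 4, t = 2))
})

test_that("genotyping score equals exhaustive multinomial enumeration", {
  for (m in 1:3) for (t in 1:2) for (T in 0:12) {
    expect_equal(genotyping_score(T, m = m, t = t), score_oracle(T, m, t),
                 tolerance = 1e-12,
                 info = sprintf("T=%d m=%d t=%d", T, m, t))
  }
})

test_that("minimum read threshold brackets the confidence level", {
  expect_identical(min_reads_for_score(m = 1, t = 3, confidence = 0.9), 3L)
  expect_identical(min_reads_for_score(m = 2, t = 1, confidence = 0.5), 2L)
  Tstar <- min_reads_for_score(m = 4, t = 2, confidence = 0.99)
  expect_lt(genotyping_score(Tstar - 1, m = 4, t = 2), 0.99)
  expect_gte(genotyping_score(Tstar, m = 4, t = 2), 0.99)
})

test_that("demultiplex assigns by exact tag and requires complete primers", {
  fwd <- "GTCTCC"; rev <- "TGCGCT"
  tag_map <- data.frame(tag = c("AAAA", "CCCC"), sample = c("s1", "s2"))
  insert <- "ACGTACGTAC"
  reads <- c(paste0("AAAA", fwd, insert, rev),       # valid s1
             paste0("CCCC", fwd, insert, rev),       # valid s2
             paste0("GGGG", fwd, insert, rev),       # unknown tag
             paste0("AAAA", "GTCTCG", insert, rev))  # primer mismatch
  m <- demultiplex(reads, tag_map, fwd, rev)
  expect_equal(sum(m$counts), 2)
  expect_equal(attr(m, "dropped"), 2L)
  expect_equal(unname(m$seqs[colnames(m$counts)[m$counts["s1", ] > 0]]),
               insert)
  # one mismatch tolerated when allowed
  m2 <- demultiplex(reads, tag_map, fwd, rev, max_primer_mismatch = 1)
  expect_equal(sum(m2$counts), 3)
  expect_error(demultiplex(reads, data.frame(tag = c("AAAA", "AAAA"),
                                             sample = c("s1", "s2")),
                           fwd, rev), "duplicate")
})

test_that("merge_identical sums counts of identical sequences and is idempotent", {
  m <- tiny_matrix(list(s1 = c(v1 = 5L, v2 = 7L, v3 = 2L)),
                   c(v1 = "ACGT", v2 = "ACGT", v3 = "TTTT"))
  merged <- merge_identical(m)
  expect_equal(ncol(merged$counts), 2)
  expect_equal(unname(merged$counts[1, "v1"]), 12)
  again <- merge_identical(merged)
  expect_identical(again$counts, merged$counts)
})

test_that("low-abundance filter removes cells under 3 reads and keeps accounting", {
  m <- tiny_matrix(list(s1 = c(v1 = 2L, v2 = 3L), s2 = c(v1 = 10L)),
                   c(v1 = "ACGT", v2 = "TTTT"))
  f <- filter_low_abundance(m)
  expect_equal(unname(f$counts["s1", "v1"]), 0)
  expect_equal(unname(f$counts["s1", "v2"]), 3)
  expect_equal(sum(m$counts) - sum(f$counts), 2)
  expect_error(filter_low_abundance(m, 0), "min_reads")
})

test_that("coverage filter fails samples below threshold at the exact boundary", {
  m <- tiny_matrix(list(s1 = c(v1 = 103L), s2 = c(v1 = 104L)),
                   c(v1 = "ACGT"))
  r <- filter_sample_coverage(m, 104)
  expect_identical(r$failed, "s1")
  expect_identical(rownames(r$matrix$counts), "s2")
  expect_length(filter_sample_coverage(m, 0)$failed, 0)
})

test_that("within-sample frequency filter uses single-pass totals", {
  m <- tiny_matrix(list(s1 = c(v1 = 5L, v2 = 7L, v3 = 288L)),
                   c(v1 = "AAAA", v2 = "CCCC", v3 = "GGGG"))
  f <- filter_within_sample_frequency(m)  # total 300: 5 = 1.7%, 7 = 2.3%
  expect_false("v1" %in% colnames(f$counts))
  expect_true(all(c("v2", "v3") %in% colnames(f$counts)))
  # single-variant sample is its own 100%
  m2 <- tiny_matrix(list(s1 = c(v1 = 1L)), c(v1 = "AAAA"))
  expect_equal(ncol(filter_within_sample_frequency(m2)$counts), 1)
})

test_that("occurrence filter needs two independent PCRs; replicates count", {
  si <- data.frame(sample = c("a_1", "a_2", "b_1"),
                   individual = c("a", "a", "b"))
  m <- tiny_matrix(list(a_1 = c(v1 = 9L, v2 = 4L), a_2 = c(v1 = 9L),
                        b_1 = c(v3 = 5L)),
                   c(v1 = "AAAA", v2 = "CCCC", v3 = "GGGG"),
                   sample_info = si)
  f <- filter_min_occurrence(m)
  expect_true("v1" %in% colnames(f$counts))    # sample + its replicate = 2 PCRs
  expect_false("v2" %in% colnames(f$counts))   # one sample only
  expect_false("v3" %in% colnames(f$counts))
})

test_that("length/frame filter applies the range and the mod-3 rule", {
  seqs <- c(v222 = rand_dna(222), v225 = rand_dna(225), v221 = rand_dna(221),
            v224 = rand_dna(224))
  m <- tiny_matrix(list(s1 = c(v222 = 5L, v225 = 5L, v221 = 5L, v224 = 5L)),
                   seqs)
  f <- filter_length_and_frame(m)
  expect_setequal(colnames(f$counts), c("v222", "v225"))
  # without the frame rule, 224 passes the plain range
  f2 <- filter_length_and_frame(m, frame_rule = FALSE)
  expect_setequal(colnames(f2$counts), c("v222", "v225", "v224"))
})

test_that("artifact detector flags chimeras and 1-bp variants, spares parents", {
  pA <- "ACGTACGT"; pB <- "TTGTATTT"; chim <- "ACGTATTT"
  m <- tiny_matrix(list(s1 = c(a = 1000L, b = 900L, c = 12L),
                        s2 = c(a = 800L, b = 700L)),
                   c(a = pA, b = pB, c = chim))
  art <- detect_artifacts(m, audit = TRUE)
  expect_equal(art$flag[art$variant == "c"], "chimera")
  expect_equal(art$flag[art$variant %in% c("a", "b")], c("clean", "clean"))

  one <- sub("^A", "C", pA)
  m2 <- tiny_matrix(list(s1 = c(a = 1000L, x = 20L)), c(a = pA, x = one))
  art2 <- detect_artifacts(m2, audit = TRUE)
  expect_equal(art2$flag[art2$variant == "x"], "one_bp")

  # equal-frequency distinct variants: no dominant parent, both clean
  m3 <- tiny_matrix(list(s1 = c(a = 100L, b = 100L)), c(a = pA, b = pB))
  expect_true(all(detect_artifacts(m3, audit = TRUE)$flag == "clean"))
})

test_that("co-occurrence guard protects rare true alleles seen without the parent", {
  pA <- "ACGTACGT"; one <- sub("^A", "C", pA)
  # x occurs in a sample where a is absent: not a plausible substitution of a
  m <- tiny_matrix(list(s1 = c(a = 1000L, x = 10L), s2 = c(x = 10L)),
                   c(a = pA, x = one))
  art <- detect_artifacts(m, audit = TRUE)
  expect_equal(art$flag[art$variant == "x"], "clean")
  # with the plain run-wide rule it would be flagged
  art2 <- detect_artifacts(m, audit = TRUE, require_cooccurrence = FALSE)
  expect_equal(art2$flag[art2$variant == "x"], "one_bp")
})

test_that("constructed chimera triads are flagged and parents never are", {
  set.seed(42)
  for (i in 1:100) {
    L <- sample(30:60, 1)
    p1 <- rand_dna(L)
    p2 <- rand_dna(L)
    bp <- sample(L - 1, 1)
    chi <- paste0(substring(p1, 1, bp), substring(p2, bp + 1))
    if (chi == p1 || chi == p2) next  # degenerate breakpoint
    m <- tiny_matrix(list(s1 = c(a = 500L, b = 500L, c = 5L)),
                     c(a = p1, b = p2, c = chi))
    art <- detect_artifacts(m, audit = TRUE)
    expect_true(art$flag[art$variant == "c"] %in% c("chimera", "one_bp"),
                info = paste("triad", i))
    expect_equal(art$flag[art$variant %in% c("a", "b")], c("clean", "clean"),
                 info = paste("triad parents", i))
  }
})

test_that("filter cascade is deterministic and report counts never increase", {
  cfg <- sim_config(seed = 11, n_aviaries = 4)
  pop <- simulate_population(cfg)
  runs <- simulate_reads(pop, cfg)
  g1 <- call_genotypes(runs[[1]])
  g2 <- call_genotypes(runs[[1]])
  expect_identical(g1$calls, g2$calls)
  expect_true(all(g1$report$variants_out <= g1$report$variants_in))
  expect_true(all(g1$report$reads_out <= g1$report$reads_in))
  expect_identical(g1$threshold, 104L)
})
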