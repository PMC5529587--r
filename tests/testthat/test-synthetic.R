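test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(seed = 42, n_aviaries = 3)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$individuals, p2$individuals)
  expect_identical(p1$genotypes, p2$genotypes)
  r1 <- simulate_reads(p1, cfg)
  r2 <- simulate_reads(p2, cfg)
  expect_identical(r1[[1]]$counts, r2[[1]]$counts)
})

test_that("pedigree structure obeys Mendelian transmission and nesting", {
  cfg <- sim_config(seed = 6, n_aviaries = 4)
  pop <- simulate_population(cfg)
  ind <- pop$individuals
  for (i in sample(nrow(ind), 40)) {
    o <- ind[i, ]
    offspring <- pop$genotypes[[o$id]]
    parental <- union(pop$genotypes[[o$mother]], pop$genotypes[[o$father]])
    expect_true(all(offspring %in% parental))
    expect_lte(length(offspring), 8)
    expect_gte(length(offspring), 1)
  }
  # survival nesting: day 12 implies day 6 implies day 1
  expect_true(all(ind$survived_d12 <= ind$survived_d6))
  expect_true(all(ind$survived_d6 <= ind$survived_d1))
  # phenotypes missing for the dead
  expect_true(all(is.na(ind$mass_d6[ind$survived_d6 == 0])))
  expect_true(all(is.na(ind$tarsus_d12[ind$survived_d12 == 0])))
})

test_that("null-effect configuration survives everyone with a huge intercept", {
  cfg <- sim_config(seed = 2, n_aviaries = 2,
                    effects = list(survival_d1 = list(intercept = 50),
                                   survival_d6 = list(intercept = 50),
                                   survival_d12 = list(intercept = 50)))
  pop <- simulate_population(cfg)
  expect_true(all(pop$individuals$survived_d12 == 1))
  expect_true(all(!is.na(pop$individuals$mass_d12)))
})

test_that("a planted allele effect shifts death rates by the logistic margin", {
  cfg <- sim_config(seed = 13, n_aviaries = 60,
                    effects = list(survival_d6 = list(
                      intercept = 1.5, coef = c(FA001 = -1.0))))
  pop <- simulate_population(cfg)
  ind <- pop$individuals[pop$individuals$survived_d1 == 1, ]
  carrier <- vapply(ind$id, function(i)
    "FA001" %in% pop$fa_map[pop$genotypes[[i]]], logical(1))
  p_carrier <- mean(ind$survived_d6[carrier])
  p_other <- mean(ind$survived_d6[!carrier])
  expect_gt(sum(carrier), 200)
  se <- sqrt(p_carrier * (1 - p_carrier) / sum(carrier) +
               p_other * (1 - p_other) / sum(!carrier))
  expected_gap <- stats::plogis(1.5) - stats::plogis(0.5)
  expect_lt(abs((p_other - p_carrier) - expected_gap), 3 * se + 0.01)
})

test_that("noiseless reads contain only true alleles of each sample", {
  cfg <- sim_config(seed = 3, n_aviaries = 2,
                    read_sim = list(error_rate = 0, chimera_rate = 0))
  pop <- simulate_population(cfg)
  runs <- simulate_reads(pop, cfg)
  m <- runs[[1]]
  truth <- attr(m, "truth")
  for (s in rownames(m$counts)) {
    present <- colnames(m$counts)[m$counts[s, ] > 0]
    expect_true(all(present %in% truth[[s]]), info = s)
  }
})

test_that("chimeric reads are single-breakpoint recombinants of sample alleles", {
  cfg <- sim_config(seed = 4, n_aviaries = 2,
                    read_sim = list(error_rate = 0, chimera_rate = 0.05))
  pop <- simulate_population(cfg)
  m <- simulate_reads(pop, cfg)[[1]]
  art_ids <- setdiff(colnames(m$counts), names(pop$alleles))
  expect_gt(length(art_ids), 0)
  alleles <- pop$alleles
  is_recombinant <- function(v) {
    L <- nchar(v)
    for (a in alleles) for (b in alleles) {
      if (identical(a, b) || nchar(a) != L || nchar(b) != L) next
      pre <- mhcnest:::lcp_len(v, a); suf <- mhcnest:::lcs_len(v, b)
      if (pre >= 1 && suf >= 1 && min(pre, L - 1) >= L - min(suf, L - 1))
        return(TRUE)
    }
    FALSE
  }
  for (vid in sample(art_ids, min(10, length(art_ids))))
    expect_true(is_recombinant(m$seqs[[vid]]), info = vid)
})

test_that("per-sample coverage centres on the configured mean", {
  cfg <- sim_config(seed = 10, n_aviaries = 6)
  pop <- simulate_population(cfg)
  m <- simulate_reads(pop, cfg)[[1]]
  totals <- rowSums(m$counts)
  n <- length(totals)
  expect_gt(n, 100)
  se <- stats::sd(totals) / sqrt(n)
  expect_lt(abs(mean(totals) - 300), 3 * se)
})

test_that("fixtures round-trip through the package readers", {
  cfg <- sim_config(seed = 5, n_aviaries = 2)
  pop <- simulate_population(cfg)
  runs <- simulate_reads(pop, cfg)
  dir <- withr::local_tempdir()
  manifest <- write_fixtures(pop, runs, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))

  alleles <- read_alleles_fasta(file.path(dir, "alleles.fasta"))
  expect_identical(alleles, pop$alleles)
  expect_length(alleles, 85)

  counts <- read_counts_tsv(file.path(dir, "counts_R1.tsv"))
  expect_identical(counts, runs[[1]]$counts)

  geno <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  expect_identical(geno[names(pop$genotypes)], pop$genotypes)

  ms <- read_microsats_tsv(file.path(dir, "microsats.tsv"))
  id <- names(pop$microsats)[1]
  expect_equal(ms[[id]]$a1, pop$microsats[[id]]$a1)

  ped <- utils::read.delim(file.path(dir, "pedigree.tsv"))
  expect_equal(nrow(ped), nrow(pop$individuals))

  tr <- ape::read.tree(file.path(dir, "allele_tree.nwk"))
  expect_setequal(tr$tip.label, names(pop$alleles))

  # checksums change iff content changes
  before <- manifest$md5[manifest$file == "genotypes.tsv"]
  cat("x", file = file.path(dir, "genotypes.tsv"), append = TRUE)
  after <- tools::md5sum(file.path(dir, "genotypes.tsv"))
  expect_false(unname(after) == before)
})

test_that("study template reproduces the planted bookkeeping deterministically", {
  pop <- study_template_population(seed = 1)
  ind <- pop$individuals
  expect_equal(nrow(ind), 293)
  expect_equal(sum(ind$survived_d1 == 0), 31)
  expect_equal(sum(ind$survived_d1 == 1), 262)
  expect_equal(sum(ind$survived_d1 == 1 & ind$survived_d6 == 0), 49)
  expect_equal(sum(ind$survived_d6 == 0 & !is.na(ind$death_natural) &
                     !ind$death_natural), 11)
  expect_equal(sum(ind$survived_d6 == 1), 213)
  expect_equal(sum(ind$survived_d6 == 1 & ind$survived_d12 == 0), 25)
  expect_equal(as.vector(table(ind$clutch_order)), c(140, 75, 66, 12))
  expect_equal(length(unique(ind$mother)), 59)
  expect_equal(length(unique(ind$aviary)), 14)
  # identical under the same seed
  pop2 <- study_template_population(seed = 1)
  expect_identical(pop$individuals, pop2$individuals)
})
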