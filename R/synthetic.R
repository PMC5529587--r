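#' Synthetic MHC class I exon 3 allele panel
#'
#' Deterministically constructs a panel of DNA alleles with a designed
#' collapse structure: \code{n_dna} DNA alleles translating to \code{n_aa}
#' unique amino-acid sequences which collapse to \code{n_fa} functional
#' alleles on the default PBR positions (defaults 85 / 78 / 59, the structure
#' reported for the study population this generator emulates). Synonymous DNA
#' variants differ at codon third positions; amino-acid variants within one
#' functional allele differ only outside the PBR; functional alleles differ
#' at exactly one PBR position from the panel base sequence. All sequences
#' are 222 bp, stop-free, and carry \code{Pado-UA_S}-style synthetic ids.
#'
#' @param n_dna,n_aa,n_fa panel sizes; require n_fa <= n_aa <= n_dna
#' @param positions PBR positions used for the designed collapse
#' @return list: \code{alleles} named character vector of DNA sequences,
#'   \code{fa_of} named vector DNA id -> designed functional-allele id,
#'   \code{aa_of} DNA id -> designed amino-acid allele id
#' @export
synthetic_allele_panel <- function(n_dna = 85L, n_aa = 78L, n_fa = 59L,
                                   positions = default_pbr_positions()) {
  if (!(n_fa <= n_aa && n_aa <= n_dna)) stop("require n_fa <= n_aa <= n_dna")
  res20 <- rownames(z_scale_table())
  n_res <- 74L
  base_aa <- strsplit(paste(rep("GAVLISTDEKRNQHFYW", 5), collapse = ""),
                      "")[[1]][seq_len(n_res)]

  # one codon per residue for reverse translation, plus one synonymous
  # alternative per residue (third-base wobble)
  gc <- Biostrings::GENETIC_CODE
  codons_of <- split(names(gc), gc)
  codon1 <- vapply(res20, function(a) codons_of[[a]][1], character(1))
  codon2 <- vapply(res20, function(a) {
    cs <- codons_of[[a]]
    if (length(cs) > 1) cs[2] else cs[1]
  }, character(1))

  # functional alleles: base PBR plus single-position substitutions
  fa_variants <- list(base_aa)
  alt_pool <- expand.grid(pos = positions, res = res20,
                          stringsAsFactors = FALSE)
  i <- 1L
  while (length(fa_variants) < n_fa) {
    v <- base_aa
    if (v[alt_pool$pos[i]] != alt_pool$res[i]) {
      v[alt_pool$pos[i]] <- alt_pool$res[i]
      fa_variants[[length(fa_variants) + 1L]] <- v
    }
    i <- i + 1L
  }

  # amino-acid alleles: each FA's representative, plus extras differing at
  # non-PBR sites; first FAs receive the extra members
  non_pbr <- setdiff(seq_len(n_res), positions)
  aa_seqs <- fa_variants
  fa_idx <- seq_len(n_fa)
  extra <- n_aa - n_fa
  j <- 1L
  for (e in seq_len(extra)) {
    host <- ((e - 1L) %% min(extra, n_fa)) %/% 1L + 1L
    v <- fa_variants[[host]]
    site <- non_pbr[(e - 1L) %% length(non_pbr) + 1L]
    repl <- res20[res20 != v[site]][(e - 1L) %% 19L + 1L]
    v[site] <- repl
    aa_seqs[[length(aa_seqs) + 1L]] <- v
    fa_idx <- c(fa_idx, host)
    j <- j + 1L
  }

  # DNA alleles: each AA allele reverse-translated, plus synonymous extras
  to_dna <- function(v, wobble_at = 0L) {
    cs <- codon1[v]
    if (wobble_at > 0L) cs[wobble_at] <- codon2[v[wobble_at]]
    paste(cs, collapse = "")
  }
  dna <- vapply(aa_seqs, to_dna, character(1))
  aa_idx <- seq_len(n_aa)
  syn <- n_dna - n_aa
  for (s in seq_len(syn)) {
    host <- (s - 1L) %% n_aa + 1L
    w <- which(codon1[aa_seqs[[host]]] != codon2[aa_seqs[[host]]])[
      (s - 1L) %/% n_aa + 1L]
    dna <- c(dna, to_dna(aa_seqs[[host]], wobble_at = w))
    aa_idx <- c(aa_idx, host)
  }
  stopifnot(!anyDuplicated(dna))

  ids <- sprintf("Pado-UA_S%03d", seq_len(n_dna))
  fa_ids <- sprintf("FA%03d", fa_idx[aa_idx])
  aa_ids <- sprintf("AA%03d", aa_idx)
  list(alleles = stats::setNames(dna, ids),
       fa_of = stats::setNames(fa_ids, ids),
       aa_of = stats::setNames(aa_ids, ids))
}

#' Simulation configuration
#'
#' Defaults emulate the aviary study design this package targets: 14
#' aviaries with 4-5 breeding pairs each, 1-4 clutches per female (mean
#' clutch around 5 eggs), an 85-allele panel collapsing to 59 functional
#' alleles of which about ten are common, individuals carrying 1-8 alleles,
#' and 454-style reads at a mean coverage of 300 per sample across two runs
#' with 12-15 percent technical replicates.
#'
#' @param seed integer seed driving all randomness downstream
#' @param n_aviaries number of aviaries
#' @param pairs_per_aviary integer vector sampled per aviary
#' @param clutch_prob probability of 1..4 clutches per female
#' @param clutch_size_mean mean clutch size (truncated Poisson, 1..8)
#' @param panel allele panel (default \code{\link{synthetic_allele_panel}()})
#' @param haplotype_sizes probability of 1..4 alleles per haplotype
#' @param effects list of per-response effect specifications; each element is
#'   a list with \code{intercept}, optional \code{sd} (Gaussian responses) and
#'   \code{coef}, a named vector over predictor columns or functional-allele
#'   ids (e.g. \code{c(FA001 = -1, clutch_order = -0.1)})
#' @param sharing_effect coefficient of parental proportion-shared (percent)
#'   on the day-6 survival logit
#' @param nonnatural_prob probability a day-1-to-6 death is flagged
#'   non-natural (excluded from survival analyses); default 11/49
#' @param read_sim read-simulation settings: \code{mean_coverage},
#'   \code{dispersion} (negative-binomial size), \code{error_rate} (per base),
#'   \code{chimera_rate} (per read), \code{amp_sd} (log-normal amplification
#'   skew), \code{runs}, \code{replicate_fraction}
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(seed = 1L,
                       n_aviaries = 14L,
                       pairs_per_aviary = 4:5,
                       clutch_prob = c(0.35, 0.25, 0.3, 0.1),
                       clutch_size_mean = 5,
                       panel = synthetic_allele_panel(),
                       haplotype_sizes = c(0.15, 0.35, 0.35, 0.15),
                       effects = list(),
                       sharing_effect = 0,
                       nonnatural_prob = 11 / 49,
                       read_sim = list()) {
  if (length(clutch_prob) != 4 || any(clutch_prob < 0) ||
      abs(sum(clutch_prob) - 1) > 1e-8)
    stop("clutch_prob must be 4 non-negative probabilities summing to 1")
  if (length(haplotype_sizes) != 4 || abs(sum(haplotype_sizes) - 1) > 1e-8)
    stop("haplotype_sizes must be 4 probabilities summing to 1")
  eff_default <- list(
    survival_d1 = list(intercept = 2.13, coef = c(clutch_order = 0)),
    survival_d6 = list(intercept = 1.72, coef = c(sex = 0)),
    survival_d12 = list(intercept = 2.02, coef = c(clutch_size = 0)),
    mass_d6 = list(intercept = 14.5, sd = 2.0, coef = c(clutch_size = 0)),
    mass_d12 = list(intercept = 24.0, sd = 2.5, coef = c(clutch_order = 0)),
    tarsus_d6 = list(intercept = 12.3, sd = 1.0, coef = c(clutch_order = 0)),
    tarsus_d12 = list(intercept = 18.0, sd = 1.0, coef = c(clutch_order = 0)))
  for (nm in names(effects))
    eff_default[[nm]] <- utils::modifyList(eff_default[[nm]], effects[[nm]])
  rs <- utils::modifyList(
    list(mean_coverage = 300, dispersion = 10, error_rate = 1e-3,
         chimera_rate = 0.02, amp_sd = 0.5, runs = 2L,
         replicate_fraction = 0.13), read_sim)
  if (rs$mean_coverage <= 0) stop("mean_coverage must be positive")
  structure(list(seed = as.integer(seed), n_aviaries = n_aviaries,
                 pairs_per_aviary = pairs_per_aviary,
                 clutch_prob = clutch_prob,
                 clutch_size_mean = clutch_size_mean, panel = panel,
                 haplotype_sizes = haplotype_sizes, effects = eff_default,
                 sharing_effect = sharing_effect,
                 nonnatural_prob = nonnatural_prob, read_sim = rs),
            class = "sim_config")
}

# allele frequencies for the panel: members of the first ten functional
# alleles are common so that about ten FAs exceed the 10% carrier cutoff
panel_frequencies <- function(panel) {
  ids <- names(panel$alleles)
  fa <- panel$fa_of[ids]
  common_fa <- sprintf("FA%03d", 1:10)
  w <- ifelse(fa %in% common_fa, 6, 0.6)
  stats::setNames(w / sum(w), ids)
}

# linear predictor from a named coefficient vector over covariate columns
# and functional-allele ids
linpred <- function(coef, covars, fa_sets) {
  out <- rep(0, nrow(covars))
  for (v in names(coef)) {
    out <- out + coef[[v]] *
      if (v %in% colnames(covars)) covars[[v]]
      else vapply(fa_sets, function(s) as.numeric(v %in% s), numeric(1))
  }
  out
}

#' Simulate a pedigreed population with MHC genotypes and fitness outcomes
#'
#' Parents carry two haplotypes of 1-4 panel alleles; each meiosis transmits
#' one haplotype, so offspring carry 1-8 distinct alleles. Survival at days
#' 1, 6 and 12 is generated sequentially from logistic models (effects from
#' the configuration, including per-functional-allele effects and the
#' parental-sharing effect at day 6); mass and tarsus from Gaussian models
#' for survivors. Deaths in the day-1-to-6 window are flagged non-natural
#' with the configured probability. Microsatellite genotypes are drawn at 10
#' neutral loci. Fully reproducible for a fixed seed.
#'
#' @param config \code{\link{sim_config}}
#' @return list of class \code{true_population}: \code{individuals}
#'   data.frame (one row per offspring), \code{parents} data.frame,
#'   \code{pairs}, \code{genotypes} (named list over all individuals),
#'   \code{microsats}, \code{alleles}, \code{fa_map}, \code{config}
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  freqs <- panel_frequencies(panel)
  ids <- names(panel$alleles)

  draw_haplotype <- function() {
    k <- sample(1:4, 1, prob = config$haplotype_sizes)
    sample(ids, k, prob = freqs)
  }
  n_loci <- 10L
  draw_microsat <- function() {
    data.frame(locus = paste0("L", seq_len(n_loci)),
               a1 = sample(150:157, n_loci, replace = TRUE),
               a2 = sample(150:157, n_loci, replace = TRUE))
  }

  parents <- list(); pairs <- list(); genotypes <- list(); haplos <- list()
  microsats <- list()
  pid <- 0L
  for (av in seq_len(config$n_aviaries)) {
    npair <- if (length(config$pairs_per_aviary) > 1)
      sample(config$pairs_per_aviary, 1) else config$pairs_per_aviary
    for (pr in seq_len(npair)) {
      pid <- pid + 1L
      m_id <- sprintf("M%03d", pid); f_id <- sprintf("F%03d", pid)
      for (id in c(m_id, f_id)) {
        h <- list(draw_haplotype(), draw_haplotype())
        haplos[[id]] <- h
        genotypes[[id]] <- sort(unique(unlist(h)))
        microsats[[id]] <- draw_microsat()
        parents[[id]] <- data.frame(id = id, sex = if (id == m_id) 1L else 0L,
                                    aviary = av)
      }
      pairs[[pid]] <- data.frame(male = m_id, female = f_id, aviary = av)
    }
  }
  pairs <- do.call(rbind, pairs)
  parents_df <- do.call(rbind, parents); rownames(parents_df) <- NULL

  # offspring: accumulate plain vectors, assemble one frame at the end
  acc <- list(aviary = integer(0), mother = character(0),
              father = character(0), clutch_id = character(0),
              clutch_order = integer(0), clutch_size = integer(0),
              pshare = numeric(0))
  oid <- 0L
  for (pr in seq_len(nrow(pairs))) {
    m <- pairs$male[pr]; f <- pairs$female[pr]
    pshare <- proportion_shared(unique(unname(panel$fa_of[genotypes[[m]]])),
                                unique(unname(panel$fa_of[genotypes[[f]]])))
    n_clutch <- sample(1:4, 1, prob = config$clutch_prob)
    for (cl in seq_len(n_clutch)) {
      csize <- max(1L, min(8L, stats::rpois(1, config$clutch_size_mean)))
      for (egg in seq_len(csize)) {
        oid <- oid + 1L
        id <- sprintf("O%04d", oid)
        genotypes[[id]] <- sort(unique(c(haplos[[m]][[sample(2, 1)]],
                                         haplos[[f]][[sample(2, 1)]])))
        microsats[[id]] <- draw_microsat()
        acc$aviary <- c(acc$aviary, pairs$aviary[pr])
        acc$mother <- c(acc$mother, f); acc$father <- c(acc$father, m)
        acc$clutch_id <- c(acc$clutch_id, sprintf("%s_c%d", f, cl))
        acc$clutch_order <- c(acc$clutch_order, cl)
        acc$clutch_size <- c(acc$clutch_size, csize)
        acc$pshare <- c(acc$pshare, pshare)
      }
    }
  }
  ind <- data.frame(id = sprintf("O%04d", seq_len(oid)),
                    sex = stats::rbinom(oid, 1, 0.5),
                    aviary = acc$aviary, mother = acc$mother,
                    father = acc$father, clutch_id = acc$clutch_id,
                    clutch_order = acc$clutch_order,
                    clutch_size = acc$clutch_size,
                    proportion_shared_true = acc$pshare,
                    stringsAsFactors = FALSE)

  fa_sets <- lapply(ind$id, function(i)
    unique(unname(panel$fa_of[genotypes[[i]]])))
  covars <- ind[, c("sex", "clutch_order", "clutch_size")]
  covars$fa_count <- vapply(fa_sets, length, integer(1))

  eff <- config$effects
  lp1 <- eff$survival_d1$intercept + linpred(eff$survival_d1$coef, covars, fa_sets)
  lp6 <- eff$survival_d6$intercept + linpred(eff$survival_d6$coef, covars, fa_sets) +
    config$sharing_effect * ind$proportion_shared_true
  lp12 <- eff$survival_d12$intercept + linpred(eff$survival_d12$coef, covars, fa_sets)
  n <- nrow(ind)
  s1 <- stats::rbinom(n, 1, stats::plogis(lp1))
  s6 <- ifelse(s1 == 1, stats::rbinom(n, 1, stats::plogis(lp6)), 0L)
  s12 <- ifelse(s6 == 1, stats::rbinom(n, 1, stats::plogis(lp12)), 0L)
  ind$survived_d1 <- s1
  ind$survived_d6 <- s6
  ind$survived_d12 <- s12
  died_mid <- s1 == 1 & s6 == 0
  ind$death_natural <- NA
  ind$death_natural[died_mid] <-
    stats::runif(sum(died_mid)) >= config$nonnatural_prob
  ind$death_natural[s1 == 0] <- TRUE

  gauss <- function(spec) spec$intercept +
    linpred(spec$coef, covars, fa_sets) + stats::rnorm(n, 0, spec$sd)
  ind$mass_d6 <- ifelse(s6 == 1, gauss(eff$mass_d6), NA_real_)
  ind$tarsus_d6 <- ifelse(s6 == 1, gauss(eff$tarsus_d6), NA_real_)
  ind$mass_d12 <- ifelse(s12 == 1, gauss(eff$mass_d12), NA_real_)
  ind$tarsus_d12 <- ifelse(s12 == 1, gauss(eff$tarsus_d12), NA_real_)

  structure(list(individuals = ind, parents = parents_df, pairs = pairs,
                 genotypes = genotypes, microsats = microsats,
                 alleles = panel$alleles, fa_map = panel$fa_of,
                 config = config),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf("<true_population: %d offspring, %d pairs, %d aviaries, %d panel alleles>\n",
              nrow(x$individuals), nrow(x$pairs),
              length(unique(x$pairs$aviary)), length(x$alleles)))
  invisible(x)
}

# mutate one random base of a sequence
mutate1 <- function(seq) {
  pos <- sample(nchar(seq), 1)
  old <- substring(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  paste0(substring(seq, 1, pos - 1), new, substring(seq, pos + 1))
}

#' Simulate per-run amplicon read-count matrices
#'
#' Individuals (parents and offspring) are split across the configured number
#' of runs; a fraction receive a technical replicate sample within their run.
#' Per-sample totals are negative-binomial around the mean coverage; reads
#' fall on the individual's true alleles with log-normal amplification
#' weights. The error process turns reads into 1-bp substitution variants
#' (per-base error rate); the chimera process emits single-breakpoint
#' recombinants of two sampled alleles. All variants, true and artifactual,
#' enter the count matrix with their sequences.
#'
#' @param pop \code{true_population}
#' @param config \code{sim_config} (default the population's own)
#' @return list of \code{run_matrix} objects (one per run); each carries an
#'   attribute \code{truth}: named list sample -> true allele ids
#' @export
simulate_reads <- function(pop, config = pop$config) {
  rs <- config$read_sim
  set.seed(config$seed + 1L)
  inds <- c(pop$parents$id, pop$individuals$id)
  run_of <- rep(seq_len(rs$runs), length.out = length(inds))
  out <- vector("list", rs$runs)

  for (r in seq_len(rs$runs)) {
    members <- inds[run_of == r]
    reps <- members[stats::runif(length(members)) < rs$replicate_fraction]
    samples <- c(stats::setNames(members, paste0(members, "_a")),
                 stats::setNames(reps, paste0(reps, "_b")))
    seq_dict <- new.env(parent = emptyenv())
    for (a in names(pop$alleles)) assign(pop$alleles[[a]], a, envir = seq_dict)
    next_var <- 0L
    id_of_seq <- function(s) {
      if (!is.null(v <- mget(s, envir = seq_dict, ifnotfound = list(NULL))[[1]]))
        return(v)
      next_var <<- next_var + 1L
      v <- sprintf("R%d_v%04d", r, next_var)
      assign(s, v, envir = seq_dict)
      v
    }

    cells <- list()
    for (s in names(samples)) {
      alleles <- pop$genotypes[[samples[[s]]]]
      total <- stats::rnbinom(1, mu = rs$mean_coverage, size = rs$dispersion)
      if (total == 0) next
      n_chi <- if (length(alleles) >= 2) stats::rbinom(1, total, rs$chimera_rate) else 0L
      w <- stats::rlnorm(length(alleles), 0, rs$amp_sd)
      counts <- as.vector(stats::rmultinom(1, total - n_chi, w))
      names(counts) <- alleles
      tally <- list()
      bump <- function(vid, k) tally[[vid]] <<- (tally[[vid]] %||% 0L) + k
      p_err <- 1 - (1 - rs$error_rate)^nchar(pop$alleles[[alleles[1]]])
      for (a in alleles) {
        n_err <- stats::rbinom(1, counts[[a]], p_err)
        bump(a, counts[[a]] - n_err)
        for (e in seq_len(n_err)) bump(id_of_seq(mutate1(pop$alleles[[a]])), 1L)
      }
      for (ch in seq_len(n_chi)) {
        ab <- sample(alleles, 2, prob = w)
        s1 <- pop$alleles[[ab[1]]]; s2 <- pop$alleles[[ab[2]]]
        bp <- sample(min(nchar(s1), nchar(s2)) - 1L, 1)
        bump(id_of_seq(paste0(substring(s1, 1, bp), substring(s2, bp + 1))), 1L)
      }
      cells[[s]] <- unlist(tally)
    }

    vids <- unique(unlist(lapply(cells, names)))
    counts <- matrix(0L, nrow = length(samples), ncol = length(vids),
                     dimnames = list(names(samples), vids))
    for (s in names(cells)) counts[s, names(cells[[s]])] <- cells[[s]]
    seqs <- stats::setNames(character(length(vids)), vids)
    for (sq in ls(seq_dict)) {
      v <- get(sq, envir = seq_dict)
      if (v %in% vids) seqs[[v]] <- sq
    }
    info <- data.frame(sample = names(samples),
                       individual = unname(samples),
                       stringsAsFactors = FALSE)
    m <- run_matrix(counts, seqs, run_id = paste0("R", r), sample_info = info)
    attr(m, "truth") <- lapply(samples, function(i) pop$genotypes[[i]])
    out[[r]] <- m
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build fixture trees from the allele panel
#'
#' Simple distance trees for testing and fixtures only (real analyses take
#' externally inferred trees as Newick input): average-linkage clustering on
#' nucleotide mismatch counts for the allele tree, and on Euclidean distance
#' between flattened PBR z-descriptor matrices for the functional-allele
#' tree. Both are rooted with positive branch lengths.
#'
#' @param pop \code{true_population} (or any list with \code{alleles},
#'   \code{fa_map})
#' @param positions PBR positions for the functional tree
#' @return list with \code{allele_tree} and \code{fa_tree} (\code{phylo})
#' @export
fixture_trees <- function(pop, positions = default_pbr_positions()) {
  seqs <- pop$alleles
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  d <- as.dist(outer(seq_len(nrow(mat)), seq_len(nrow(mat)),
                     Vectorize(function(i, j) sum(mat[i, ] != mat[j, ]))))
  attr(d, "Labels") <- names(seqs)
  allele_tree <- ape::as.phylo(stats::hclust(d, method = "average"))

  fa_ids <- unique(unname(pop$fa_map))
  rep_allele <- names(pop$fa_map)[match(fa_ids, pop$fa_map)]
  zmat <- t(vapply(rep_allele, function(a) {
    as.vector(encode_z(extract_pbr(translate_allele(seqs[[a]]), positions)))
  }, numeric(5 * length(positions))))
  rownames(zmat) <- fa_ids
  fa_tree <- ape::as.phylo(stats::hclust(stats::dist(zmat), method = "average"))
  list(allele_tree = allele_tree, fa_tree = fa_tree)
}

#' Write synthetic fixtures to a directory
#'
#' Emits plain-text fixtures that round-trip through the package readers:
#' allele FASTA, pedigree/phenotype TSV, microsatellite TSV, per-run count
#' matrices (TSV), tag map TSV, Newick trees, optionally tagged read FASTA
#' files, and a checksum manifest.
#'
#' @param pop \code{true_population}
#' @param runs output of \code{\link{simulate_reads}} (optional)
#' @param dir output directory (created if needed)
#' @param write_reads also emit per-run read FASTA files (large; default
#'   FALSE)
#' @return invisibly, the manifest data.frame (file, md5)
#' @export
write_fixtures <- function(pop, runs = NULL, dir, write_reads = FALSE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  wtsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pop$alleles),
                              file.path(dir, "alleles.fasta"))
  wtsv(pop$individuals, "pedigree.tsv")
  ms <- do.call(rbind, lapply(names(pop$microsats), function(i)
    cbind(individual = i, pop$microsats[[i]])))
  wtsv(ms, "microsats.tsv")
  geno <- data.frame(individual = names(pop$genotypes),
                     alleles = vapply(pop$genotypes, paste,
                                      character(1), collapse = ","))
  wtsv(geno, "genotypes.tsv")
  trees <- fixture_trees(pop)
  ape::write.tree(trees$allele_tree, file.path(dir, "allele_tree.nwk"))
  ape::write.tree(trees$fa_tree, file.path(dir, "fa_tree.nwk"))

  if (!is.null(runs)) {
    for (m in runs) {
      wtsv(data.frame(sample = rownames(m$counts), m$counts,
                      check.names = FALSE),
           sprintf("counts_%s.tsv", m$run_id))
      wtsv(m$sample_info, sprintf("tagmap_%s.tsv", m$run_id))
      if (write_reads) {
        con <- file(file.path(dir, sprintf("reads_%s.fasta", m$run_id)), "w")
        k <- 0L
        for (s in rownames(m$counts)) for (v in colnames(m$counts)) {
          n <- m$counts[s, v]
          for (i in seq_len(n)) {
            k <- k + 1L
            writeLines(c(sprintf(">%s|read%d", s, k), m$seqs[[v]]), con)
          }
        }
        close(con)
      }
    }
  }

  files <- list.files(dir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  wtsv(manifest, "manifest.tsv")
  invisible(manifest)
}
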