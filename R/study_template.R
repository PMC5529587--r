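#' Deterministic synthetic study-template population
#'
#' A synthetic stand-in for the study's deposited genotype-phenotype table,
#' built to the published bookkeeping rather than simulated stochastically:
#' 293 offspring from 59 families in 14 aviaries with clutch-order offspring
#' counts 140/75/66/12; exactly 31 unhatched embryos; of the 262 hatched
#' nestlings exactly 49 die before day 6, 11 of them flagged non-natural
#' (excluded from survival analyses); of the 213 alive at day 6 exactly 25
#' die before day 12. Three offspring are left ungenotyped (290 genotyped);
#' among the genotyped, 42 carry the first focal functional allele
#' (42/290 = 14.48 percent) and 44 the second (44/290 = 15.17 percent, the
#' closest integer count to the emulated 15.15). Which individuals receive
#' which fate is randomised by \code{seed}; the counts are fixed.
#'
#' This object is synthetic: it validates the analysis-table bookkeeping and
#' frequency machinery, not the study data themselves.
#'
#' @param seed integer seed for the within-template assignments
#' @return \code{true_population} (see \code{\link{simulate_population}})
#' @export
study_template_population <- function(seed = 1L) {
  set.seed(seed)
  panel <- synthetic_allele_panel()
  freqs <- panel_frequencies(panel)
  ids <- names(panel$alleles)
  fa1_members <- ids[panel$fa_of == "FA001"]
  fa2_members <- ids[panel$fa_of == "FA002"]

  # 59 families across 14 aviaries; offspring per clutch order 140/75/66/12
  n_fam <- 59L
  aviary <- rep(seq_len(14L), length.out = n_fam)
  per_order <- c(140L, 75L, 66L, 12L)
  # families holding a clutch of each order: all 59 have order 1; fewer later
  fams_of_order <- list(seq_len(59L), seq_len(30L), seq_len(25L), seq_len(6L))

  rows <- list(); oid <- 0L
  genotypes <- list(); microsats <- list()
  n_loci <- 10L
  draw_microsat <- function() data.frame(
    locus = paste0("L", seq_len(n_loci)),
    a1 = sample(150:157, n_loci, replace = TRUE),
    a2 = sample(150:157, n_loci, replace = TRUE))

  parents <- list(); pairs <- list()
  for (f in seq_len(n_fam)) {
    m_id <- sprintf("M%03d", f); f_id <- sprintf("F%03d", f)
    for (id in c(m_id, f_id)) {
      genotypes[[id]] <- sort(unique(sample(ids, sample(2:8, 1), prob = freqs)))
      microsats[[id]] <- draw_microsat()
      parents[[id]] <- data.frame(id = id, sex = as.integer(id == m_id),
                                  aviary = aviary[f])
    }
    pairs[[f]] <- data.frame(male = m_id, female = f_id, aviary = aviary[f])
  }

  for (ord in 1:4) {
    fams <- fams_of_order[[ord]]
    sizes <- rep(per_order[ord] %/% length(fams), length(fams))
    extra <- per_order[ord] - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    for (k in seq_along(fams)) {
      f <- fams[k]
      if (sizes[k] == 0L) next
      clutch_id <- sprintf("F%03d_c%d", f, ord)
      for (egg in seq_len(sizes[k])) {
        oid <- oid + 1L
        rows[[oid]] <- data.frame(
          id = sprintf("O%04d", oid), sex = stats::rbinom(1, 1, 0.5),
          aviary = aviary[f], mother = sprintf("F%03d", f),
          father = sprintf("M%03d", f), clutch_id = clutch_id,
          clutch_order = ord, clutch_size = sizes[k],
          proportion_shared_true = NA_real_)
      }
    }
  }
  ind <- do.call(rbind, rows)
  stopifnot(nrow(ind) == 293L)

  # planted survival bookkeeping
  unhatched <- sample(ind$id, 31L)
  hatched <- setdiff(ind$id, unhatched)
  dead_d6 <- sample(hatched, 49L)
  nonnatural <- sample(dead_d6, 11L)
  alive_d6 <- setdiff(hatched, dead_d6)
  dead_d12 <- sample(alive_d6, 25L)
  ind$survived_d1 <- as.integer(!(ind$id %in% unhatched))
  ind$survived_d6 <- as.integer(ind$survived_d1 == 1 & !(ind$id %in% dead_d6))
  ind$survived_d12 <- as.integer(ind$survived_d6 == 1 & !(ind$id %in% dead_d12))
  ind$death_natural <- NA
  ind$death_natural[ind$id %in% dead_d6] <- TRUE
  ind$death_natural[ind$id %in% nonnatural] <- FALSE
  ind$death_natural[ind$survived_d1 == 0] <- TRUE
  ind$death_natural[ind$id %in% dead_d12] <- TRUE

  # genotypes: 290 genotyped offspring; planted carrier counts for the two
  # focal functional alleles
  ungeno <- sample(ind$id, 3L)
  geno_ids <- setdiff(ind$id, ungeno)
  fa1_carriers <- sample(geno_ids, 42L)
  fa2_carriers <- sample(geno_ids, 44L)
  other_ids <- setdiff(ids, c(fa1_members, fa2_members))
  other_freqs <- freqs[other_ids] / sum(freqs[other_ids])
  for (id in geno_ids) {
    g <- sample(other_ids, sample(1:6, 1), prob = other_freqs)
    if (id %in% fa1_carriers) g <- c(g, sample(fa1_members, 1))
    if (id %in% fa2_carriers) g <- c(g, sample(fa2_members, 1))
    genotypes[[id]] <- sort(unique(g))
    microsats[[id]] <- draw_microsat()
  }

  # parental sharing, recorded per pair
  for (f in seq_len(n_fam)) {
    m <- sprintf("M%03d", f); fe <- sprintf("F%03d", f)
    ps <- proportion_shared(unique(unname(panel$fa_of[genotypes[[m]]])),
                            unique(unname(panel$fa_of[genotypes[[fe]]])))
    ind$proportion_shared_true[ind$mother == fe] <- ps
  }

  # growth phenotypes for survivors
  n <- nrow(ind)
  ind$mass_d6 <- ifelse(ind$survived_d6 == 1,
                        14.5 - 0.5 * ind$clutch_size + stats::rnorm(n, 0, 2), NA)
  ind$tarsus_d6 <- ifelse(ind$survived_d6 == 1,
                          12.3 - 0.3 * ind$clutch_order + stats::rnorm(n, 0, 1), NA)
  ind$mass_d12 <- ifelse(ind$survived_d12 == 1,
                         24 - 1 * ind$clutch_order + stats::rnorm(n, 0, 2.5), NA)
  ind$tarsus_d12 <- ifelse(ind$survived_d12 == 1,
                           18 - 0.4 * ind$clutch_order + stats::rnorm(n, 0, 1), NA)

  genotypes[ungeno] <- NULL
  structure(list(individuals = ind, parents = do.call(rbind, parents),
                 pairs = do.call(rbind, pairs), genotypes = genotypes,
                 microsats = microsats, alleles = panel$alleles,
                 fa_map = panel$fa_of,
                 config = sim_config(seed = seed)),
            class = "true_population")
}
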