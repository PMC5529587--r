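#' Assemble the offspring analysis frame
#'
#' Joins phenotypes, pedigree structure, genotype-derived MHC covariates
#' (functional-allele count and presence/absence of the common functional
#' alleles), microsatellite heterozygosity and parental similarity measures
#' into one row per offspring. Genotypes default to the population's true
#' allele sets but can be replaced by called genotypes from the filtering
#' cascade.
#'
#' @param pop \code{true_population} (see \code{\link{simulate_population}})
#' @param genotypes named list individual -> DNA allele ids (default
#'   \code{pop$genotypes})
#' @param fa_cutoff population-frequency cutoff for common functional alleles
#'   (default 0.10); frequencies are taken over genotyped offspring
#' @param allele_tree,fa_tree optional \code{phylo} trees for the parental
#'   distance measures; when absent the distance columns are NA and excluded
#'   from the default predictor lists
#' @return data.frame, one row per offspring, with attributes
#'   \code{predictors_growth} and \code{predictors_survival} (ordered
#'   candidate-variable lists) and \code{common_fa}
#' @export
build_analysis_frame <- function(pop, genotypes = pop$genotypes,
                                 fa_cutoff = 0.10,
                                 allele_tree = NULL, fa_tree = NULL) {
  ind <- pop$individuals
  off_ids <- ind$id[ind$id %in% names(genotypes)]
  pres <- fa_presence_and_frequency(genotypes[off_ids], pop$fa_map,
                                    cutoff = fa_cutoff)
  tab <- ind
  tab$genotyped <- tab$id %in% off_ids
  tab$fa_count <- NA_integer_
  tab$fa_count[match(off_ids, tab$id)] <- pres$fa_count
  for (f in colnames(pres$presence)) {
    tab[[f]] <- NA_integer_
    tab[[f]][match(off_ids, tab$id)] <- pres$presence[, f]
  }

  tab$het <- vapply(tab$id, function(i) {
    g <- pop$microsats[[i]]
    if (is.null(g)) NA_real_ else multilocus_heterozygosity(g)
  }, numeric(1))

  # parental similarity, one value per breeding pair, repeated per offspring
  pg <- pop$genotypes
  key <- paste(tab$father, tab$mother)
  upairs <- unique(data.frame(male = tab$father, female = tab$mother,
                              stringsAsFactors = FALSE))
  fm <- lapply(upairs$male, function(i) unique(unname(pop$fa_map[pg[[i]]])))
  ff <- lapply(upairs$female, function(i) unique(unname(pop$fa_map[pg[[i]]])))
  ps <- mapply(proportion_shared, fm, ff)
  upairs$proportion_shared <- ps
  if (!is.null(allele_tree) && !is.null(fa_tree)) {
    sim <- pair_similarities(upairs[, c("male", "female")], pg, pop$fa_map,
                             allele_tree, fa_tree)
    upairs$allele_distance <- sim$allele_distance
    upairs$fa_distance <- sim$fa_distance
  } else {
    upairs$allele_distance <- NA_real_
    upairs$fa_distance <- NA_real_
  }
  idx <- match(key, paste(upairs$male, upairs$female))
  tab$proportion_shared <- upairs$proportion_shared[idx]
  tab$allele_distance <- upairs$allele_distance[idx]
  tab$fa_distance <- upairs$fa_distance[idx]

  base <- c("clutch_size", "clutch_order", "sex", "het", "fa_count",
            colnames(pres$presence))
  sim_vars <- c("proportion_shared",
                if (!is.null(allele_tree)) c("allele_distance", "fa_distance"))
  attr(tab, "predictors_growth") <- base
  attr(tab, "predictors_survival") <- c(base, sim_vars)
  attr(tab, "common_fa") <- colnames(pres$presence)
  tab
}

#' Select rows and response for one analysis
#'
#' Applies the survival bookkeeping filters: the day-1 analysis uses all
#' offspring (hatching success); the day-6 analysis uses hatched nestlings,
#' excluding individuals whose death in the window was flagged non-natural;
#' the day-12 analysis uses nestlings alive at day 6. Growth analyses use
#' nestlings alive (and measured) on the focal day. Rows lacking the response
#' or any predictor are dropped.
#'
#' @param tab frame from \code{\link{build_analysis_frame}}
#' @param response one of \code{survival_d1}, \code{survival_d6},
#'   \code{survival_d12}, \code{mass_d6}, \code{mass_d12}, \code{tarsus_d6},
#'   \code{tarsus_d12}
#' @return data.frame with a \code{y} response column; attribute
#'   \code{predictors} the ordered candidate list for this response
#' @export
analysis_subset <- function(tab, response) {
  pick <- switch(response,
    survival_d1 = {
      tab$y <- tab$survived_d1
      rep(TRUE, nrow(tab))
    },
    survival_d6 = {
      tab$y <- tab$survived_d6
      tab$survived_d1 == 1 &
        !(tab$survived_d6 == 0 & !is.na(tab$death_natural) & !tab$death_natural)
    },
    survival_d12 = {
      tab$y <- tab$survived_d12
      tab$survived_d1 == 1 & tab$survived_d6 == 1 &
        !(tab$survived_d12 == 0 & !is.na(tab$death_natural) & !tab$death_natural)
    },
    mass_d6 = { tab$y <- tab$mass_d6; tab$survived_d6 == 1 },
    mass_d12 = { tab$y <- tab$mass_d12; tab$survived_d12 == 1 },
    tarsus_d6 = { tab$y <- tab$tarsus_d6; tab$survived_d6 == 1 },
    tarsus_d12 = { tab$y <- tab$tarsus_d12; tab$survived_d12 == 1 },
    stop("unknown response: ", response))
  preds <- if (startsWith(response, "survival"))
    attr(tab, "predictors_survival") else attr(tab, "predictors_growth")
  out <- tab[pick & !is.na(tab$y) & tab$genotyped, , drop = FALSE]
  complete <- stats::complete.cases(out[, preds, drop = FALSE])
  out <- out[complete, , drop = FALSE]
  attr(out, "predictors") <- preds
  out
}

#' Aggregate an analysis table to the clutch level
#'
#' When per-individual logistic mixed models fail to converge, analyses fall
#' back to clutch means: every variable (response included) is replaced by
#' its arithmetic mean within the clutch, so a binary survival becomes the
#' clutch survival proportion and sex becomes the clutch sex ratio. Grouping
#' reduces to female within aviary.
#'
#' @param tab output of \code{\link{analysis_subset}}
#' @param vars columns to average (default: \code{y} plus the table's
#'   predictor attribute)
#' @return one row per clutch with columns \code{clutch_id}, \code{aviary},
#'   \code{female}, \code{n_in_clutch} and the averaged variables; attribute
#'   \code{predictors} carried over
#' @export
aggregate_by_clutch <- function(tab, vars = NULL) {
  if (is.null(vars)) vars <- c("y", attr(tab, "predictors"))
  split_idx <- split(seq_len(nrow(tab)), tab$clutch_id)
  rows <- lapply(split_idx, function(ix) {
    r <- tab[ix[1], c("clutch_id", "aviary", "mother")]
    names(r)[3] <- "female"
    r$n_in_clutch <- length(ix)
    for (v in vars) r[[v]] <- mean(tab[[v]][ix])
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictors") <- attr(tab, "predictors")
  out
}

#' Run the selection procedure for one response
#'
#' Convenience wrapper: subsets the analysis frame, aggregates to clutch
#' level for binary responses (default), and runs the iterative RVI
#' selection.
#'
#' @param tab frame from \code{\link{build_analysis_frame}}
#' @param response response name (see \code{\link{analysis_subset}})
#' @param backend fitting backend (default "lm"; use "lmer" for nested
#'   random intercepts)
#' @param aggregate aggregate binary responses to clutch level (default TRUE)
#' @param ... passed to \code{\link{iterative_rvi_selection}}
#' @return \code{rvi_selection}
#' @export
fit_response <- function(tab, response, backend = "lm", aggregate = TRUE,
                         ...) {
  sub <- analysis_subset(tab, response)
  preds <- attr(sub, "predictors")
  is_binary <- startsWith(response, "survival")
  weights <- NULL
  if (is_binary && aggregate) {
    sub <- aggregate_by_clutch(sub)
    # a clutch mean of n binary outcomes has residual variance ~ 1/n
    weights <- sub$n_in_clutch
    random <- "(1 | aviary/female)"
  } else {
    random <- "(1 | aviary/mother/clutch_id)"
  }
  be_random <- if (backend == "lmer") random else NULL
  if (is_binary && !aggregate && backend != "glm")
    backend <- "glm"
  iterative_rvi_selection(sub, "y", preds, backend = backend,
                          random = be_random, weights = weights, ...)
}
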