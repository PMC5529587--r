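#' Proportion of functional alleles shared between parents
#'
#' Computed as 100 / (number of alleles in male + number in female) times the
#' number of shared alleles, with inputs treated as sets and each shared
#' allele counted once (so identical parental sets score 50, not 100). The
#' totals in the denominator are plain set-size sums without cross-parent
#' deduplication. \code{count_both = TRUE} counts a shared allele once per
#' parent instead, doubling the score.
#'
#' @param male,female character vectors of allele ids (duplicates ignored)
#' @param count_both count shared alleles in both parents (default FALSE)
#' @return percentage; in [0, 50] under the default counting
#' @export
proportion_shared <- function(male, female, count_both = FALSE) {
  male <- unique(male); female <- unique(female)
  if (!length(male) || !length(female))
    stop("both parents need a non-empty allele set")
  shared <- length(intersect(male, female))
  if (count_both) shared <- 2L * shared
  100 / (length(male) + length(female)) * shared
}

# branch lengths classified by which query set has descendant leaves below
unifrac_partition <- function(tree, set_a, set_b) {
  tips <- tree$tip.label
  missing <- setdiff(union(set_a, set_b), tips)
  if (length(missing))
    stop("leaf ids not in tree: ", paste(missing, collapse = ", "))
  ntip <- length(tips)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tr$Nnode
  inA <- logical(nnode); inB <- logical(nnode)
  inA[match(set_a, tips)] <- TRUE
  inB[match(set_b, tips)] <- TRUE
  # postorder: children visited before parents
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
    inA[par] <- inA[par] || inA[chi]
    inB[par] <- inB[par] || inB[chi]
  }
  len <- if (is.null(tr$edge.length)) rep(1, nrow(tr$edge)) else tr$edge.length
  chi <- tr$edge[, 2]
  both <- inA[chi] & inB[chi]
  only <- xor(inA[chi], inB[chi])
  c(unique = sum(len[only]), observed = sum(len[only | both]))
}

#' Unweighted UniFrac distance between two leaf sets
#'
#' Fraction of the branch length leading to any queried leaf that is unique
#' to one of the two sets: branches ancestral only to A-leaves or only to
#' B-leaves, divided by branches ancestral to any leaf of the union.
#' Presence/absence only; branch lengths of zero contribute nothing;
#' multifurcations are allowed.
#'
#' @param tree rooted \code{ape::phylo} tree with branch lengths
#' @param set_a,set_b character vectors of tip labels
#' @return distance in [0, 1]; 0 when the sets have identical leaves
#' @export
unifrac_distance <- function(tree, set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  part <- unifrac_partition(tree, set_a, set_b)
  if (part["observed"] == 0) return(0)
  unname(part["unique"] / part["observed"])
}

#' Parental MHC similarity records
#'
#' For each breeding pair: percentage of functional alleles shared, tree
#' distance of the DNA/AA alleles, and tree distance of the functional
#' alleles (both unweighted UniFrac on the supplied trees).
#'
#' @param pairs data.frame with columns \code{male} and \code{female}
#'   (individual ids)
#' @param genotypes named list individual -> DNA allele ids
#' @param fa_map named vector DNA allele id -> functional-allele id
#' @param allele_tree \code{phylo} with DNA/AA allele ids as tips
#' @param fa_tree \code{phylo} with functional-allele ids as tips
#' @return data.frame keyed by \code{male}, \code{female} with
#'   \code{proportion_shared}, \code{allele_distance}, \code{fa_distance}
#' @export
pair_similarities <- function(pairs, genotypes, fa_map, allele_tree, fa_tree) {
  all_alleles <- unique(unlist(genotypes[unique(c(pairs$male, pairs$female))]))
  gaps <- setdiff(all_alleles, allele_tree$tip.label)
  if (length(gaps))
    stop("allele tree missing tips: ", paste(gaps, collapse = ", "))
  all_fas <- unique(unname(fa_map[all_alleles]))
  gaps <- setdiff(all_fas, fa_tree$tip.label)
  if (length(gaps))
    stop("functional-allele tree missing tips: ", paste(gaps, collapse = ", "))

  one <- function(m, f) {
    gm <- genotypes[[m]]; gf <- genotypes[[f]]
    fm <- unique(unname(fa_map[gm])); ff <- unique(unname(fa_map[gf]))
    c(proportion_shared = proportion_shared(fm, ff),
      allele_distance = unifrac_distance(allele_tree, gm, gf),
      fa_distance = unifrac_distance(fa_tree, fm, ff))
  }
  res <- t(mapply(one, pairs$male, pairs$female))
  data.frame(male = pairs$male, female = pairs$female, res,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multilocus microsatellite heterozygosity
#'
#' Proportion of typed loci at which the two alleles differ; loci with any
#' missing allele are excluded from numerator and denominator.
#' @param genotype data.frame with columns \code{a1}, \code{a2} (one row per
#'   locus; NA = missing)
#' @return proportion in [0, 1]
#' @export
multilocus_heterozygosity <- function(genotype) {
  typed <- !is.na(genotype$a1) & !is.na(genotype$a2)
  if (!any(typed)) stop("no typed loci")
  mean(genotype$a1[typed] != genotype$a2[typed])
}
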