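#' Translate an MHC exon 3 allele to amino acids
#'
#' Standard genetic code, frame anchored at position 1 of the 222-bp reference
#' frame. Sequences whose length is not a multiple of three or that contain an
#' internal stop codon are rejected.
#' @param dna DNA string (A/C/G/T)
#' @return amino-acid string
#' @export
translate_allele <- function(dna) {
  dna <- toupper(dna)
  amb <- regexpr("[^ACGT]", dna)
  if (amb > 0) stop("ambiguous base at position ", amb)
  if (nchar(dna) %% 3L != 0L)
    stop("length ", nchar(dna), " is not a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           no.init.codon = TRUE))
  if (grepl("\\*", aa)) stop("internal stop codon in translation")
  aa
}

#' Collapse DNA alleles into amino-acid alleles
#'
#' Groups DNA alleles by identical translation (synonymous alleles merge).
#' @param dna_alleles named character vector of DNA sequences
#' @return data.frame with columns \code{aa_id}, \code{aa_seq},
#'   \code{members} (comma-joined DNA allele ids); attribute \code{map}
#'   is the named vector DNA allele id -> aa_id
#' @export
collapse_aa <- function(dna_alleles) {
  if (!length(dna_alleles))
    return(structure(data.frame(aa_id = character(0), aa_seq = character(0),
                                members = character(0)),
                     map = stats::setNames(character(0), character(0))))
  aa <- vapply(dna_alleles, translate_allele, character(1))
  uaa <- unique(aa)
  aa_id <- paste0("AA", sprintf("%03d", seq_along(uaa)))
  map <- stats::setNames(aa_id[match(aa, uaa)], names(dna_alleles))
  members <- vapply(uaa, function(s)
    paste(names(dna_alleles)[aa == s], collapse = ","), character(1))
  structure(data.frame(aa_id = aa_id, aa_seq = uaa, members = unname(members),
                       stringsAsFactors = FALSE),
            map = map)
}

#' Extract the peptide-binding-region residues
#' @param aa amino-acid string
#' @param positions strictly increasing 1-based residue positions
#'   (default \code{\link{default_pbr_positions}})
#' @return string of \code{length(positions)} residues, order preserved
#' @export
extract_pbr <- function(aa, positions = default_pbr_positions()) {
  positions <- check_pbr_positions(positions, nchar(aa))
  paste(strsplit(aa, "")[[1]][positions], collapse = "")
}

#' Encode a PBR string as a z-descriptor matrix
#' @param pbr_string residue string (standard one-letter codes)
#' @param table descriptor table from \code{\link{z_scale_table}}
#' @return \code{nchar(pbr_string)} x 5 numeric matrix
#' @export
encode_z <- function(pbr_string, table = z_scale_table()) {
  res <- strsplit(pbr_string, "")[[1]]
  bad <- !(res %in% rownames(table))
  if (any(bad)) stop("non-standard residue(s): ",
                     paste(unique(res[bad]), collapse = ", "))
  m <- table[res, , drop = FALSE]
  rownames(m) <- paste0("p", seq_along(res))
  m
}

#' Collapse amino-acid alleles into functional alleles
#'
#' Functional-allele identity is exact equality of the PBR residue string
#' (equivalently, of the 16 x 5 z-descriptor matrix, since descriptor rows are
#' distinct). Alleles with identical antigen-contacting residues are treated
#' as functionally interchangeable even if they differ elsewhere.
#' @param aa_tab result of \code{\link{collapse_aa}} (or a data.frame with
#'   \code{aa_id}, \code{aa_seq})
#' @param positions PBR positions
#' @return data.frame with \code{fa_id}, \code{pbr} and \code{members}
#'   (comma-joined aa ids); attribute \code{map}: aa_id -> fa_id
#' @export
collapse_functional <- function(aa_tab, positions = default_pbr_positions()) {
  if (!nrow(aa_tab))
    return(structure(data.frame(fa_id = character(0), pbr = character(0),
                                members = character(0)),
                     map = stats::setNames(character(0), character(0))))
  pbr <- vapply(aa_tab$aa_seq, extract_pbr, character(1), positions = positions)
  upbr <- unique(pbr)
  fa_id <- paste0("FA", sprintf("%03d", seq_along(upbr)))
  map <- stats::setNames(fa_id[match(pbr, upbr)], aa_tab$aa_id)
  members <- vapply(upbr, function(s)
    paste(aa_tab$aa_id[pbr == s], collapse = ","), character(1))
  structure(data.frame(fa_id = fa_id, pbr = upbr, members = unname(members),
                       stringsAsFactors = FALSE),
            map = map)
}

#' Compose the DNA-allele -> functional-allele map
#' @param dna_alleles named character vector of DNA sequences
#' @param positions PBR positions
#' @return list with \code{aa} and \code{fa} tables and the combined
#'   \code{map} (DNA allele id -> fa_id)
#' @export
functional_allele_map <- function(dna_alleles,
                                  positions = default_pbr_positions()) {
  aa <- collapse_aa(dna_alleles)
  fa <- collapse_functional(aa, positions)
  dna2aa <- attr(aa, "map")
  aa2fa <- attr(fa, "map")
  list(aa = aa, fa = fa,
       map = stats::setNames(unname(aa2fa[dna2aa]), names(dna2aa)))
}

#' Per-individual functional-allele sets, frequencies and common-FA matrix
#'
#' @param genotypes named list: individual -> character vector of DNA allele
#'   ids
#' @param fa_map named vector DNA allele id -> functional-allele id
#' @param cutoff population-frequency cutoff defining "common" functional
#'   alleles (default 0.10)
#' @return list: \code{fa_sets} per individual, \code{frequency} named vector
#'   (carriers / individuals), \code{common} ids above the cutoff,
#'   \code{presence} individuals x common-FA 0/1 matrix, \code{fa_count}
#'   per-individual number of distinct functional alleles
#' @export
fa_presence_and_frequency <- function(genotypes, fa_map, cutoff = 0.10) {
  missing <- setdiff(unique(unlist(genotypes)), names(fa_map))
  if (length(missing))
    stop("alleles without functional-allele assignment: ",
         paste(missing, collapse = ", "))
  fa_sets <- lapply(genotypes, function(g) sort(unique(unname(fa_map[g]))))
  fas <- sort(unique(unlist(fa_sets)))
  n <- length(genotypes)
  carriers <- vapply(fas, function(f)
    sum(vapply(fa_sets, function(s) f %in% s, logical(1))), numeric(1))
  freq <- carriers / n
  common <- fas[freq > cutoff]
  presence <- matrix(0L, nrow = n, ncol = length(common),
                     dimnames = list(names(genotypes), common))
  for (i in seq_len(n))
    presence[i, ] <- as.integer(common %in% fa_sets[[i]])
  list(fa_sets = fa_sets, frequency = freq, common = common,
       presence = presence,
       fa_count = vapply(fa_sets, length, integer(1)))
}
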