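#' Five-descriptor z-scales for the 20 standard amino acids
#'
#' Returns the published five-dimensional physicochemical descriptor table used
#' to encode peptide-binding-region residues: z1 (hydrophobicity), z2 (steric
#' bulk / polarizability), z3 (polarity), z4 and z5 (electronic effects).
#' Rows are the 20 standard residues in one-letter code; values are fixed
#' constants of the extended z-scale descriptor set.
#'
#' @return A 20 x 5 numeric matrix with rownames the one-letter amino-acid
#'   codes and colnames \code{z1..z5}.
#' @examples
#' z_scale_table()["A", ]
#' @export
z_scale_table <- function() {
  vals <- c(
    # z1      z2      z3      z4      z5
     0.24,  -2.32,   0.60,  -0.14,   1.30,  # A
     3.52,   2.50,  -3.50,   1.99,  -0.17,  # R
     3.05,   1.62,   1.04,  -1.15,   1.61,  # N
     3.98,   0.93,   1.93,  -2.46,   0.75,  # D
     0.84,  -1.67,   3.71,   0.18,  -2.65,  # C
     1.75,   0.50,  -1.44,  -1.34,   0.66,  # Q
     3.11,   0.26,  -0.11,  -3.04,  -0.25,  # E
     2.05,  -4.06,   0.36,  -0.82,  -0.38,  # G
     2.47,   1.95,   0.26,   3.90,   0.09,  # H
    -3.89,  -1.73,  -1.71,  -0.84,   0.26,  # I
    -4.28,  -1.30,  -1.49,  -0.72,   0.84,  # L
     2.29,   0.89,  -2.49,   1.49,   0.31,  # K
    -2.85,  -0.22,   0.47,   1.94,  -0.98,  # M
    -4.22,   1.94,   1.06,   0.54,  -0.62,  # F
    -1.66,   0.27,   1.84,   0.70,   2.00,  # P
     2.39,  -1.07,   1.15,  -1.39,   0.67,  # S
     0.75,  -2.18,  -1.12,  -1.46,  -0.40,  # T
    -4.36,   3.94,   0.59,   3.44,  -1.59,  # W
    -2.54,   2.44,   0.43,   0.04,  -1.47,  # Y
    -2.59,  -2.64,  -1.54,  -0.85,  -0.02   # V
  )
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  matrix(vals, nrow = 20, byrow = TRUE,
         dimnames = list(aa, paste0("z", 1:5)))
}

#' Default peptide-binding-region positions for MHC class I exon 3
#'
#' The 16 residue positions (1-based within the 74-codon exon 3 amplicon,
#' 222 bp frame) homologous to the antigen-contacting positions of the chicken
#' MHC class I structure. These positions define functional-allele identity:
#' alleles with identical residues at all 16 positions form one functional
#' allele. The list ships as data, not code; supply your own ordered integer
#' vector to any function that accepts \code{positions} if your amplicon or
#' reference structure differs.
#'
#' @return Strictly increasing integer vector of length 16.
#' @export
default_pbr_positions <- function() {
  c(2L, 5L, 9L, 12L, 16L, 20L, 24L, 33L, 35L, 45L, 56L, 59L, 62L, 66L, 69L, 73L)
}

#' Validate a PBR position vector against a sequence length
#' @param positions integer vector of 1-based residue positions
#' @param seq_len length of the amino-acid sequence they index into
#' @keywords internal
check_pbr_positions <- function(positions, seq_len = Inf) {
  positions <- as.integer(positions)
  if (anyNA(positions) || any(positions < 1L))
    stop("PBR positions must be positive integers")
  if (is.unsorted(positions, strictly = TRUE))
    stop("PBR positions must be strictly increasing")
  if (any(positions > seq_len))
    stop("PBR position out of bounds: ",
         paste(positions[positions > seq_len], collapse = ", "))
  positions
}
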