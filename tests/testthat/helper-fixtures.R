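# shared builders for small in-code fixtures

# tiny run matrix from explicit cells: list(sample = c(variant = count))
tiny_matrix <- function(cells, seqs, run_id = "R1", sample_info = NULL) {
  samples <- names(cells)
  variants <- names(seqs)
  m <- matrix(0L, length(samples), length(variants),
              dimnames = list(samples, variants))
  for (s in samples) m[s, names(cells[[s]])] <- cells[[s]]
  run_matrix(m, seqs, run_id = run_id, sample_info = sample_info)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# exhaustive multinomial genotyping-score oracle: enumerate all count
# compositions of T reads over m alleles and sum probabilities where every
# allele has >= t reads
score_oracle <- function(T, m, t) {
  if (m == 1) return(as.numeric(T >= t))
  comps <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (x in 0:total) out <- rbind(out, cbind(x, comps(total - x, parts - 1)))
    out
  }
  cc <- comps(T, m)
  ok <- rowSums(cc >= t) == m
  if (!any(ok)) return(0)
  sum(apply(cc[ok, , drop = FALSE], 1, function(x)
    stats::dmultinom(x, prob = rep(1 / m, m))))
}

# brute-force unweighted UniFrac: union of root-to-leaf edge sets
unifrac_oracle <- function(tree, set_a, set_b) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  edges_to_root <- function(tip) {
    node <- match(tip, tree$tip.label)
    out <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      out <- c(out, e)
      node <- tree$edge[e, 1]
    }
    out
  }
  ea <- unique(unlist(lapply(set_a, edges_to_root)))
  eb <- unique(unlist(lapply(set_b, edges_to_root)))
  len <- tree$edge.length
  uniq <- sum(len[setdiff(ea, eb)]) + sum(len[setdiff(eb, ea)])
  obs <- sum(len[union(ea, eb)])
  if (obs == 0) 0 else uniq / obs
}
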