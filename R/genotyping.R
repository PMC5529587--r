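#' Construct a per-run read-count matrix
#'
#' The genotyping substrate: a sample x variant matrix of read counts for one
#' sequencing run, together with the variant sequences and the mapping of
#' samples to individuals (technical replicates of an individual are separate
#' samples pointing at the same individual). Runs are always filtered
#' separately; genotypes are merged per individual afterwards.
#'
#' @param counts non-negative integer matrix, rownames = sample ids,
#'   colnames = variant ids
#' @param seqs named character vector of variant DNA sequences (A/C/G/T),
#'   names matching \code{colnames(counts)}
#' @param run_id run label
#' @param sample_info data.frame with columns \code{sample} and
#'   \code{individual}; defaults to each sample being its own individual
#' @return object of class \code{run_matrix}
#' @export
run_matrix <- function(counts, seqs, run_id = "R1", sample_info = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and variant colnames")
  if (anyDuplicated(colnames(counts))) stop("variant ids must be unique within a run")
  seqs <- seqs[colnames(counts)]
  if (anyNA(seqs)) stop("every variant needs a sequence")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) stop("non-ACGT characters in variants: ",
                     paste(colnames(counts)[bad], collapse = ", "))
  if (is.null(sample_info))
    sample_info <- data.frame(sample = rownames(counts),
                              individual = rownames(counts),
                              stringsAsFactors = FALSE)
  if (!all(rownames(counts) %in% sample_info$sample))
    stop("sample_info must cover every sample")
  structure(list(counts = counts, seqs = seqs, run_id = run_id,
                 sample_info = sample_info),
            class = "run_matrix")
}

#' @export
print.run_matrix <- function(x, ...) {
  cat(sprintf("<run_matrix %s: %d samples x %d variants, %d reads>\n",
              x$run_id, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# drop all-zero variant columns, preserving at least a 0-column matrix
drop_empty_variants <- function(m) {
  keep <- colSums(m$counts) > 0
  m$counts <- m$counts[, keep, drop = FALSE]
  m$seqs <- m$seqs[keep]
  m
}

#' Demultiplex tagged amplicon reads into a run matrix
#'
#' Assigns reads to samples by exact match of the sample tag at the read
#' start, then requires both amplification primers to be present (exact match
#' by default); tag and primers are stripped from the retained insert. Reads
#' lacking a complete tag or either primer are dropped and counted.
#'
#' @param reads character vector of read sequences (or a named vector; names
#'   are ignored)
#' @param tag_map data.frame with columns \code{tag}, \code{sample}, and
#'   optionally \code{individual} (defaults to sample id)
#' @param fwd_primer,rev_primer primer sequences flanking the insert as they
#'   appear in the read (tag + fwd_primer + insert + rev_primer)
#' @param max_primer_mismatch allowed mismatches in each primer (default 0,
#'   exact match)
#' @param run_id run label
#' @return \code{run_matrix}; attribute \code{dropped} holds the number of
#'   discarded reads
#' @export
demultiplex <- function(reads, tag_map, fwd_primer, rev_primer,
                        max_primer_mismatch = 0L, run_id = "R1") {
  if (anyDuplicated(tag_map$tag)) stop("duplicate tags in tag map")
  if (is.null(tag_map$individual)) tag_map$individual <- tag_map$sample
  tags <- tag_map$tag
  nf <- nchar(fwd_primer); nr <- nchar(rev_primer)

  mism <- function(a, b) {  # mismatch count between equal-length strings
    if (nchar(a) != nchar(b)) return(Inf)
    sum(utils::head(strsplit(a, "")[[1]] != strsplit(b, "")[[1]], nchar(a)))
  }

  assigned <- character(0); inserts <- character(0); dropped <- 0L
  for (rd in reads) {
    hit <- NA_integer_
    for (i in seq_along(tags)) {
      if (startsWith(rd, tags[i])) { hit <- i; break }
    }
    if (is.na(hit)) { dropped <- dropped + 1L; next }
    body <- substring(rd, nchar(tags[hit]) + 1L)
    if (nchar(body) < nf + nr + 1L) { dropped <- dropped + 1L; next }
    fp <- substring(body, 1L, nf)
    rp <- substring(body, nchar(body) - nr + 1L)
    if (mism(fp, fwd_primer) > max_primer_mismatch ||
        mism(rp, rev_primer) > max_primer_mismatch) {
      dropped <- dropped + 1L; next
    }
    assigned <- c(assigned, tag_map$sample[hit])
    inserts <- c(inserts, substring(body, nf + 1L, nchar(body) - nr))
  }

  samples <- tag_map$sample
  useqs <- unique(inserts)
  vid <- if (length(useqs)) paste0("V", seq_along(useqs)) else character(0)
  counts <- matrix(0L, nrow = length(samples), ncol = length(useqs),
                   dimnames = list(samples, vid))
  if (length(inserts)) {
    idx <- table(factor(assigned, levels = samples),
                 factor(match(inserts, useqs), levels = seq_along(useqs)))
    counts[] <- as.integer(idx)
  }
  m <- run_matrix(counts, stats::setNames(useqs, vid), run_id = run_id,
                  sample_info = tag_map[, c("sample", "individual")])
  attr(m, "dropped") <- dropped
  m
}

#' Merge identical variant sequences
#'
#' Within each sample, read counts of identical (post-trim) sequences are
#' summed and the run-wide variant set is deduplicated. Idempotent.
#' @param m \code{run_matrix}
#' @return \code{run_matrix}
#' @export
merge_identical <- function(m) {
  grp <- match(m$seqs, unique(m$seqs))
  if (max(grp) == ncol(m$counts)) return(m)
  keep <- !duplicated(grp)
  newc <- t(rowsum(t(m$counts), group = grp))
  colnames(newc) <- colnames(m$counts)[keep]
  m$counts <- newc
  m$seqs <- m$seqs[keep]
  m
}

#' Delete low-abundance variant cells
#'
#' Sets to zero any sample x variant cell with fewer than \code{min_reads}
#' reads (default 3: variants seen fewer than three times in a sample are
#' treated as sequencing noise), then drops variants left with no reads.
#' @param m \code{run_matrix}
#' @param min_reads minimum per-sample read count to retain a variant cell
#' @return \code{run_matrix}
#' @export
filter_low_abundance <- function(m, min_reads = 3L) {
  if (min_reads < 1) stop("min_reads must be >= 1")
  m$counts[m$counts < min_reads] <- 0L
  drop_empty_variants(m)
}

#' Genotyping score: coverage confidence under equal multinomial amplification
#'
#' Probability that each of \code{m} equally amplified alleles receives at
#' least \code{t} of \code{T} total reads, the reads falling on alleles as an
#' equal-probability multinomial. Computed exactly by conditioning one allele's
#' binomial count at a time (equivalent to inclusion-exclusion over missed
#' alleles, but numerically stable). Non-decreasing in \code{T}, non-increasing
#' in \code{m} and \code{t}.
#'
#' @param total_reads total reads T for the sample (scalar or vector)
#' @param m number of alleles assumed present (default 8, the species maximum)
#' @param t minimum reads per allele (default 3, matching the low-abundance
#'   filter)
#' @return probability in [0, 1], vectorised over \code{total_reads}
#' @export
genotyping_score <- function(total_reads, m = 8L, t = 3L) {
  if (m < 1 || t < 1) stop("m and t must be >= 1")
  vapply(total_reads, function(T) {
    if (T < m * t) return(0)
    f <- as.numeric(seq.int(0L, T) >= t)          # one allele, s reads
    if (m > 1) for (k in 2:m) {
      g <- numeric(T + 1L)
      for (s in (k * t):T) {
        cc <- t:(s - t * (k - 1L))
        g[s + 1L] <- sum(stats::dbinom(cc, s, 1 / k) * f[s - cc + 1L])
      }
      f <- g
    }
    f[T + 1L]
  }, numeric(1))
}

#' Minimum per-sample read total for a target genotyping score
#'
#' Smallest T with \code{genotyping_score(T, m, t) >= confidence}, found by
#' upward scan from the feasibility bound \code{m * t}.
#' @param m,t see \code{\link{genotyping_score}}
#' @param confidence target probability (default 0.999)
#' @return integer threshold T*
#' @export
min_reads_for_score <- function(m = 8L, t = 3L, confidence = 0.999) {
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0,1)")
  T <- as.integer(m * t)
  # tolerance absorbs float error in the DP at exact-boundary cases
  while (genotyping_score(T, m, t) < confidence - 1e-9) T <- T + 1L
  T
}

#' Remove samples below the coverage threshold
#'
#' Samples whose total retained reads fall below \code{threshold} cannot be
#' genotyped confidently; they are removed and reported as failed.
#' @param m \code{run_matrix}
#' @param threshold minimum total reads per sample (e.g. from
#'   \code{\link{min_reads_for_score}})
#' @return list with the filtered \code{matrix} and the character vector
#'   \code{failed} of removed sample ids
#' @export
filter_sample_coverage <- function(m, threshold) {
  totals <- rowSums(m$counts)
  failed <- rownames(m$counts)[totals < threshold]
  m$counts <- m$counts[totals >= threshold, , drop = FALSE]
  m <- drop_empty_variants(m)
  list(matrix = m, failed = failed)
}

#' Remove variants below a within-sample frequency
#'
#' A cell is removed when its reads are less than \code{min_frac} of the
#' sample total. Totals are taken once, before any removal (single pass), so
#' the decision for each cell is independent of processing order.
#' @param m \code{run_matrix}
#' @param min_frac minimum within-sample frequency (default 0.02)
#' @return \code{run_matrix}
#' @export
filter_within_sample_frequency <- function(m, min_frac = 0.02) {
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0,1]")
  totals <- rowSums(m$counts)
  frac <- sweep(m$counts, 1, pmax(totals, 1), "/")
  m$counts[frac < min_frac] <- 0L
  drop_empty_variants(m)
}

#' Require each variant in at least two independent PCRs
#'
#' Variants observed in fewer than \code{min_samples} distinct samples of the
#' run are dropped run-wide. Technical replicates of one individual are
#' independent PCRs and each counts.
#' @param m \code{run_matrix}
#' @param min_samples minimum number of samples (default 2)
#' @return \code{run_matrix}
#' @export
filter_min_occurrence <- function(m, min_samples = 2L) {
  occ <- colSums(m$counts > 0)
  m$counts[, occ < min_samples] <- 0L
  drop_empty_variants(m)
}

#' Length and reading-frame filter
#'
#' Drops variants outside the expected amplicon length range and variants
#' whose length deviation from the 222-bp reference frame is not a multiple
#' of three (an indel that shifts frame).
#' @param m \code{run_matrix}
#' @param allowed_lengths retained lengths in bp (default 222:225)
#' @param ref_length reference length anchoring the frame (default 222)
#' @param frame_rule apply the mod-3 deviation rule (default TRUE)
#' @return \code{run_matrix}
#' @export
filter_length_and_frame <- function(m, allowed_lengths = 222:225,
                                    ref_length = 222L, frame_rule = TRUE) {
  len <- nchar(m$seqs)
  ok <- len %in% allowed_lengths
  if (frame_rule) ok <- ok & ((len - ref_length) %% 3L == 0L)
  m$counts[, !ok] <- 0L
  drop_empty_variants(m)
}

# longest common prefix / suffix lengths of v against each of us
lcp_len <- function(v, us) {
  vapply(us, function(u) {
    n <- min(nchar(v), nchar(u)); i <- 0L
    while (i < n && substring(v, i + 1L, i + 1L) == substring(u, i + 1L, i + 1L))
      i <- i + 1L
    i
  }, integer(1))
}
lcs_len <- function(v, us) {
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  lcp_len(rev1(v), vapply(us, rev1, character(1)))
}

#' Flag PCR chimeras and 1-bp substitution artifacts
#'
#' Examines variants from the lowest population-level frequency upward. A
#' variant is a \code{one_bp} artifact when an unflagged variant of equal
#' length sits at Hamming distance 1 and dominates it within every sample in
#' which the variant occurs (at least \code{ratio} times its reads, sample by
#' sample): a polymerase or sequencing substitution can only arise where its
#' source allele is present and is generated at a small per-read rate, so it
#' is always a minor fraction of its parent. A rare true allele, by
#' contrast, occurs in samples lacking its near neighbour or amplifies at
#' comparable depth beside it. A \code{chimera} is a variant equal to
#' prefix + suffix of two distinct unflagged parents at a single breakpoint,
#' both parents dominating it the same way. Flagged variants cannot serve as
#' parents.
#' Variants at population frequency >= \code{exempt_freq} are assumed true
#' alleles and never flagged (set \code{audit = TRUE} to examine everything).
#'
#' @param m \code{run_matrix}
#' @param ratio parent-to-variant abundance ratio (default 10)
#' @param exempt_freq population frequency (fraction of samples carrying the
#'   variant) above which variants are exempt (default 0.02)
#' @param audit if TRUE, exempt variants are still examined and flagged
#' @param require_cooccurrence apply the within-sample dominance condition
#'   (default TRUE; FALSE gives the plain run-wide ratio rule)
#' @return data.frame with columns \code{variant}, \code{flag} (clean /
#'   one_bp / chimera), \code{pop_freq}, \code{reads}
#' @export
detect_artifacts <- function(m, ratio = 10, exempt_freq = 0.02, audit = FALSE,
                             require_cooccurrence = TRUE) {
  nv <- ncol(m$counts)
  vid <- colnames(m$counts)
  reads <- colSums(m$counts)
  popfreq <- if (nrow(m$counts)) colMeans(m$counts > 0) else numeric(nv)
  ord <- order(popfreq, reads)                    # lowest frequency first
  flag <- stats::setNames(rep("clean", nv), vid)

  pres <- m$counts > 0
  for (i in ord) {
    if (!audit && popfreq[i] >= exempt_freq) next
    v <- m$seqs[i]
    parents <- which(flag == "clean" & reads >= ratio * reads[i] &
                       seq_len(nv) != i)
    if (require_cooccurrence && length(parents) && nrow(pres)) {
      vs <- which(pres[, i])
      parents <- parents[vapply(parents, function(u)
        all(m$counts[vs, u] >= ratio * m$counts[vs, i]), logical(1))]
    }
    if (!length(parents)) next
    same_len <- parents[nchar(m$seqs[parents]) == nchar(v)]
    if (length(same_len)) {
      hd <- vapply(same_len, function(j) {
        a <- strsplit(v, "")[[1]]; b <- strsplit(m$seqs[j], "")[[1]]
        sum(a != b)
      }, numeric(1))
      if (any(hd == 1)) { flag[i] <- "one_bp"; next }
      pre <- lcp_len(v, m$seqs[same_len])
      suf <- lcs_len(v, m$seqs[same_len])
      L <- nchar(v)
      is_chim <- FALSE
      for (a in seq_along(same_len)) {
        if (pre[a] < 1L) next
        for (b in seq_along(same_len)) {
          if (a == b || suf[b] < 1L) next
          # breakpoint k exists iff prefix of parent a covers [1..k] and
          # suffix of parent b covers [k+1..L] for some 1 <= k <= L-1
          if (min(pre[a], L - 1L) >= L - min(suf[b], L - 1L)) { is_chim <- TRUE; break }
        }
        if (is_chim) break
      }
      if (is_chim) flag[i] <- "chimera"
    }
  }
  data.frame(variant = vid, flag = unname(flag[vid]),
             pop_freq = unname(popfreq), reads = unname(reads),
             stringsAsFactors = FALSE)
}

#' Run the full genotyping filter cascade for one run
#'
#' Applies, in order: merge identical sequences, delete cells with < 3 reads,
#' remove samples below the coverage threshold, delete variants below 2% of
#' the sample total, require each variant in at least two independent PCRs,
#' length/reading-frame filter, and chimera / 1-bp artifact removal. Replicate
#' samples of one individual are then reconciled (union by default) into one
#' genotype call per individual.
#'
#' @param m \code{run_matrix} of raw (demultiplexed) counts
#' @param params list of filter parameters; recognised entries
#'   \code{min_reads} (3), \code{max_alleles} (8), \code{confidence} (0.999),
#'   \code{threshold} (computed from the score model when NULL),
#'   \code{min_frac} (0.02), \code{min_samples} (2), \code{allowed_lengths}
#'   (222:225), \code{artifact_ratio} (10), \code{replicate_mode}
#'   ("union" or "intersection")
#' @return list of class \code{genotype_calls}: \code{calls} named list per
#'   individual (character vectors of accepted variant ids), \code{status}
#'   per-sample passed/failed_coverage, \code{report} the per-step
#'   \code{FilterReport} data.frame, \code{seqs} accepted variant sequences,
#'   \code{artifacts} the artifact audit table
#' @export
call_genotypes <- function(m, params = list()) {
  p <- utils::modifyList(list(min_reads = 3L, max_alleles = 8L,
                              confidence = 0.999, threshold = NULL,
                              min_frac = 0.02, min_samples = 2L,
                              allowed_lengths = 222:225, artifact_ratio = 10,
                              replicate_mode = "union"), params)
  if (is.null(p$threshold))
    p$threshold <- min_reads_for_score(p$max_alleles, p$min_reads, p$confidence)

  report <- data.frame(step = character(0), variants_in = integer(0),
                       variants_out = integer(0), reads_in = integer(0),
                       reads_out = integer(0))
  log_step <- function(name, before, after) {
    rbind(report, data.frame(step = name,
                             variants_in = ncol(before$counts),
                             variants_out = ncol(after$counts),
                             reads_in = sum(before$counts),
                             reads_out = sum(after$counts)))
  }

  m0 <- m
  m1 <- merge_identical(m0);               report <- log_step("merge_identical", m0, m1)
  m2 <- filter_low_abundance(m1, p$min_reads)
  report <- log_step("low_abundance", m1, m2)
  cov <- filter_sample_coverage(m2, p$threshold)
  m3 <- cov$matrix;                        report <- log_step("sample_coverage", m2, m3)
  m4 <- filter_within_sample_frequency(m3, p$min_frac)
  report <- log_step("within_sample_frequency", m3, m4)
  m5 <- filter_min_occurrence(m4, p$min_samples)
  report <- log_step("min_occurrence", m4, m5)
  m6 <- filter_length_and_frame(m5, p$allowed_lengths)
  report <- log_step("length_frame", m5, m6)
  art <- detect_artifacts(m6, ratio = p$artifact_ratio)
  m7 <- m6
  bad <- art$variant[art$flag != "clean"]
  m7$counts[, colnames(m7$counts) %in% bad] <- 0L
  m7 <- drop_empty_variants(m7)
  report <- log_step("artifact_removal", m6, m7)

  # per-sample accepted sets, then replicate reconciliation per individual
  sample_sets <- lapply(rownames(m7$counts), function(s)
    colnames(m7$counts)[m7$counts[s, ] > 0])
  names(sample_sets) <- rownames(m7$counts)
  info <- m$sample_info
  ind_of <- stats::setNames(info$individual, info$sample)
  passed <- names(sample_sets)
  inds <- unique(ind_of[passed])
  calls <- lapply(inds, function(id) {
    ss <- sample_sets[passed[ind_of[passed] == id]]
    out <- if (p$replicate_mode == "intersection" && length(ss) > 1)
      Reduce(intersect, ss) else Reduce(union, ss)
    sort(out)
  })
  names(calls) <- inds
  over <- vapply(calls, length, integer(1)) > p$max_alleles
  if (any(over))
    warning("individuals exceed max_alleles: ", paste(inds[over], collapse = ", "))

  status <- stats::setNames(rep("passed", nrow(m$counts)), rownames(m$counts))
  status[cov$failed] <- "failed_coverage"
  structure(list(calls = calls, status = status, report = report,
                 seqs = m7$seqs, artifacts = art, threshold = p$threshold,
                 run_id = m$run_id),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("<genotype_calls %s: %d individuals called, %d samples failed coverage (threshold %d reads)>\n",
              x$run_id, length(x$calls), sum(x$status == "failed_coverage"),
              x$threshold))
  invisible(x)
}

#' Merge genotype calls across runs
#'
#' Per-run filtering is independent; an individual genotyped in several runs
#' receives the union of its accepted allele sets.
#' @param ... \code{genotype_calls} objects
#' @return named list of accepted variant-id sets per individual
#' @export
merge_run_calls <- function(...) {
  runs <- list(...)
  inds <- unique(unlist(lapply(runs, function(r) names(r$calls))))
  out <- lapply(inds, function(id)
    sort(Reduce(union, lapply(runs, function(r) r$calls[[id]]))))
  names(out) <- inds
  out[!vapply(out, is.null, logical(1))]
}
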