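#' Read an allele FASTA
#' @param path FASTA file
#' @return named character vector of DNA sequences
#' @export
read_alleles_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a sample x variant count matrix TSV
#' @param path TSV with first column \code{sample}
#' @return integer matrix
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a genotypes TSV (individual, comma-joined allele ids)
#' @param path TSV file
#' @return named list individual -> character vector
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(strsplit(d$alleles, ","), d$individual)
}

#' Read a long-format microsatellite TSV
#' @param path TSV with columns individual, locus, a1, a2 (blank = missing)
#' @return named list individual -> data.frame(locus, a1, a2)
#' @export
read_microsats_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(d[, c("locus", "a1", "a2")], d$individual), function(x) {
    rownames(x) <- NULL; x
  })
}

#' Validate pipeline input files
#'
#' Schema and alphabet checks for the pipeline's file formats: allele FASTA
#' (A/C/G/T only), pedigree/phenotype TSV (required columns), microsatellite
#' TSV, Newick trees (readable, tips unique).
#'
#' @param paths named list; recognised names \code{alleles},
#'   \code{pedigree}, \code{microsats}, \code{allele_tree}, \code{fa_tree}
#' @return character vector of issues (empty when clean)
#' @export
validate_inputs <- function(paths) {
  issues <- character(0)
  note <- function(...) issues <<- c(issues, sprintf(...))
  if (!is.null(paths$alleles)) {
    a <- tryCatch(read_alleles_fasta(paths$alleles), error = function(e) NULL)
    if (is.null(a)) note("alleles: unreadable FASTA %s", paths$alleles)
    else {
      bad <- grepl("[^ACGT]", a)
      if (any(bad)) note("alleles: non-ACGT characters in %s",
                         paste(names(a)[bad], collapse = ", "))
    }
  }
  if (!is.null(paths$pedigree)) {
    p <- tryCatch(utils::read.delim(paths$pedigree), error = function(e) NULL)
    req <- c("id", "mother", "father", "clutch_id", "clutch_order",
             "clutch_size", "sex", "aviary")
    if (is.null(p)) note("pedigree: unreadable %s", paths$pedigree)
    else for (col in setdiff(req, colnames(p)))
      note("pedigree: missing column %s", col)
  }
  if (!is.null(paths$microsats)) {
    m <- tryCatch(utils::read.delim(paths$microsats), error = function(e) NULL)
    if (is.null(m) || !all(c("individual", "locus", "a1", "a2") %in% colnames(m)))
      note("microsats: missing columns in %s", paths$microsats)
  }
  for (tr in c("allele_tree", "fa_tree")) {
    if (is.null(paths[[tr]])) next
    t <- tryCatch(ape::read.tree(paths[[tr]]), error = function(e) NULL)
    if (is.null(t)) note("%s: unreadable Newick %s", tr, paths[[tr]])
    else if (anyDuplicated(t$tip.label)) note("%s: duplicate tip labels", tr)
  }
  issues
}

#' Run the full pipeline on a synthetic population
#'
#' Orchestrates simulate -> genotype (per-run filter cascade, merged across
#' runs) -> functional-allele coding -> parental similarity -> iterative
#' AICc/RVI selection for every response, and returns the result tables plus
#' a run manifest. Identical config and seed reproduce identical output.
#'
#' @param config \code{\link{sim_config}}; its seed drives all stages
#' @param responses responses to analyse (default all seven)
#' @param use_called_genotypes genotype offspring from simulated reads via
#'   the filter cascade (TRUE) or use true genotypes directly (FALSE, faster)
#' @param backend fitting backend for the selection stage
#' @param out_dir optional directory for TSV artifacts
#' @return list of class \code{pipeline_run}: \code{results} (named
#'   \code{rvi_selection} list), \code{frame}, \code{population},
#'   \code{calls} (when genotyping ran), \code{manifest}
#' @export
run_pipeline <- function(config = sim_config(),
                         responses = c("survival_d1", "survival_d6",
                                       "survival_d12", "mass_d6", "mass_d12",
                                       "tarsus_d6", "tarsus_d12"),
                         use_called_genotypes = FALSE,
                         backend = "lm", out_dir = NULL) {
  manifest <- list()
  stamp <- function(stage, ...) {
    manifest[[stage]] <<- list(..., time = unname(proc.time()["elapsed"]))
  }

  pop <- simulate_population(config)
  stamp("simulate", n_offspring = nrow(pop$individuals),
        n_pairs = nrow(pop$pairs))

  calls <- NULL
  genotypes <- pop$genotypes
  if (use_called_genotypes) {
    runs <- simulate_reads(pop, config)
    per_run <- lapply(runs, call_genotypes)
    genotypes_called <- do.call(merge_run_calls, per_run)
    # surviving artifact variants have no functional-allele assignment;
    # drop them (they are rare by the cascade's false-allele guarantee)
    genotypes_called <- lapply(genotypes_called, intersect, names(pop$fa_map))
    genotypes <- genotypes_called[vapply(genotypes_called, length,
                                         integer(1)) > 0]
    calls <- per_run
    stamp("genotype", n_called = length(genotypes))
  }

  trees <- fixture_trees(pop)
  frame <- build_analysis_frame(pop, genotypes = genotypes,
                                allele_tree = trees$allele_tree,
                                fa_tree = trees$fa_tree)
  stamp("frame", n_rows = nrow(frame),
        n_common_fa = length(attr(frame, "common_fa")))

  results <- list()
  for (r in responses)
    results[[r]] <- fit_response(frame, r, backend = backend)
  stamp("select", n_responses = length(results))

  if (!is.null(out_dir)) {
    report_tables(results, out_dir)
    stamp("write", dir = out_dir)
  }
  structure(list(results = results, frame = frame, population = pop,
                 calls = calls, manifest = manifest, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d responses, %d offspring, seed %d>\n",
              length(x$results), nrow(x$population$individuals),
              x$config$seed))
  for (nm in names(x$results)) {
    rel <- x$results[[nm]]$table
    rel <- rel$variable[!is.na(rel$rvi) & rel$relevant]
    cat(sprintf("  %-12s relevant: %s\n", nm,
                if (length(rel)) paste(rel, collapse = ", ") else "(none)"))
  }
  invisible(x)
}
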