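#' Sort an amplicon read set into gene and species groups
#'
#' The full pipeline: load (or accept) reads, sample comparison batches, score
#' read pairs within each batch, keep each read's best match, build gene
#' groups from overlapping best pairs, fuse gene groups whose 50-read
#' consensuses agree, then sort every gene group into species groups with the
#' iterative threshold-relaxation loop and write the output files.
#'
#' All sampling is driven by `config$rng_seed`; given the same input, flags
#' and seed the results are identical across runs and across worker counts
#' (workers only parallelise pair scoring, which consumes no randomness).
#'
#' @param input path to a FASTA/FASTQ file, or an `amplicon_reads` data frame
#'   (e.g. from [make_pool()]).
#' @param outdir output directory; `NULL` skips writing files.
#' @param min_length,max_length read-length window applied at load time
#'   (ignored when `input` is already a data frame).
#' @param fmt output format, `"fasta"` (default) or `"fastq"`.
#' @param config a [sorter_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `amplicon_sort`: a list with `groups` (gene
#'   groups, each carrying its final `species` list and `unassigned` serials),
#'   `reads`, `report` (a run report with reconciled counts and per-stage
#'   timings), and `paths` (files written).
#' @export
#' @examples
#' set.seed(1)
#' ref <- make_reference(500)
#' pool <- make_pool(c(spA = ref), 1, 120, error_model(), strand_mix = 0.5)
#' res <- sort_amplicons(pool$reads, config = sorter_config(rng_seed = 1))
#' length(res$groups)
sort_amplicons <- function(input, outdir = NULL, min_length = 1L,
                           max_length = 1000000L, fmt = c("fasta", "fastq"),
                           config = sorter_config(), quiet = FALSE) {
  fmt <- match.arg(fmt)
  cfg <- config
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  set.seed(cfg$rng_seed)
  tic <- function() proc.time()[["elapsed"]]
  elapsed <- list()
  t0 <- tic()
  reads <- if (is.data.frame(input)) input else
    load_reads(input, min_length, max_length)
  elapsed$load <- tic() - t0
  n_dropped <- attr(reads, "n_dropped")
  if (is.null(n_dropped)) n_dropped <- 0L
  say("loaded %d reads (%d outside length window dropped)",
      nrow(reads), n_dropped)

  t0 <- tic()
  batches <- sample_reads(reads, cfg)
  sampled <- unique(unlist(batches))
  n_pairs <- sum(vapply(batches, function(b) choose(length(b), 2), 1))
  say("sampled %d distinct reads in %d batch(es); up to %.0f pairwise comparisons",
      length(sampled), length(batches), n_pairs)
  edges <- do.call(rbind, lapply(batches, score_batch, reads = reads, cfg = cfg))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(a = integer(0), b = integer(0),
                        similarity = numeric(0), rc = logical(0))
  } else {
    # random mode can score the same pair in two batches: keep the best
    edges <- edges[order(edges$a, edges$b, -edges$similarity), , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  elapsed$score <- tic() - t0
  say("retained %d edges >= %g%% similarity", nrow(edges), cfg$edge_min_sim)

  t0 <- tic()
  bp <- best_pairs(edges)
  groups <- build_groups(bp, edges)
  n_groups_initial <- length(groups)
  groups <- fuse_gene_groups(groups, reads, cfg)
  elapsed$group <- tic() - t0
  say("gene groups: %d before fusion, %d after", n_groups_initial,
      length(groups))

  t0 <- tic()
  for (i in seq_along(groups)) {
    res <- sort_gene_group(groups[[i]], reads, cfg)
    groups[[i]]$species <- res$species
    groups[[i]]$unassigned <- res$unassigned
    say("gene group %d (%d reads): %d species group(s) [%s], %d unassigned",
        groups[[i]]$group_id, length(groups[[i]]$members),
        length(res$species),
        paste(vapply(res$species, function(s) length(s$members), 1L),
              collapse = ", "),
        length(res$unassigned))
  }
  elapsed$species <- tic() - t0

  assigned <- sum(vapply(groups, function(g)
    sum(vapply(g$species, function(s) length(s$members), 1L)), 1))
  unassigned <- sum(vapply(groups, function(g) length(g$unassigned), 1))
  singletons <- length(sampled) - assigned - unassigned
  report <- list(
    reads_loaded = nrow(reads),
    reads_dropped = n_dropped,
    reads_sampled_distinct = length(sampled),
    n_batches = length(batches),
    max_comparisons = n_pairs,
    edges_retained = nrow(edges),
    gene_groups_initial = n_groups_initial,
    gene_groups = length(groups),
    species_per_group = lapply(groups, function(g)
      vapply(g$species, function(s) length(s$members), 1L)),
    reads_assigned = assigned,
    reads_unassigned = unassigned,
    reads_ungrouped = singletons,
    elapsed = elapsed)
  say("reconciliation: %d sampled = %d assigned + %d unassigned + %d ungrouped",
      length(sampled), assigned, unassigned, singletons)

  paths <- character(0)
  if (!is.null(outdir)) {
    paths <- write_species_outputs(groups, reads, outdir, fmt)
    summ <- do.call(rbind, lapply(groups, function(g) {
      if (length(g$species) == 0L) {
        return(data.frame(gene_group = g$group_id, species_group = NA_integer_,
                          n_reads = 0L, consensus_length = NA_integer_))
      }
      data.frame(gene_group = g$group_id,
                 species_group = vapply(g$species, `[[`, 1L, "species_id"),
                 n_reads = vapply(g$species, function(s) length(s$members), 1L),
                 consensus_length = vapply(g$species, function(s)
                   nchar(s$consensus), 1L))
    }))
    utils::write.table(summ, file.path(outdir, "run_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(log_lines, file.path(outdir, "run.log"))
    paths <- c(paths, file.path(outdir, c("run_summary.tsv", "run.log")))
  }
  structure(list(groups = groups, reads = reads, report = report,
                 config = cfg, paths = paths),
            class = "amplicon_sort")
}

#' @export
print.amplicon_sort <- function(x, ...) {
  r <- x$report
  cat("<amplicon_sort>\n")
  cat(sprintf("  %d reads loaded (%d dropped), %d sampled, %d edges\n",
              r$reads_loaded, r$reads_dropped, r$reads_sampled_distinct,
              r$edges_retained))
  cat(sprintf("  %d gene group(s) (from %d before fusion)\n",
              r$gene_groups, r$gene_groups_initial))
  for (g in x$groups) {
    cat(sprintf("  gene group %d: %d reads, %d species group(s)%s\n",
                g$group_id, length(g$members), length(g$species),
                if (length(g$species))
                  paste0(" of sizes ",
                         paste(vapply(g$species, function(s)
                           length(s$members), 1L), collapse = ", "))
                else ""))
  }
  cat(sprintf("  assigned %d, unassigned %d, ungrouped %d\n",
              r$reads_assigned, r$reads_unassigned, r$reads_ungrouped))
  invisible(x)
}

#' Consensus sequences of a finished run
#'
#' @param x an `amplicon_sort` object.
#' @return named character vector `"<g>_<s>(<n>)"` -> consensus.
#' @export
consensus_sequences <- function(x) {
  stopifnot(inherits(x, "amplicon_sort"))
  out <- character(0)
  for (g in x$groups) {
    for (s in g$species) {
      out[sprintf("%d_%d(%d)", g$group_id, s$species_id,
                  length(s$members))] <- s$consensus
    }
  }
  out
}
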