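#' Random reference sequence
#'
#' I.i.d. DNA with the requested expected GC content. Uses the current R RNG
#' stream (call `set.seed()` first for reproducibility).
#'
#' @param length sequence length in bp.
#' @param gc expected GC fraction in (0, 1).
#' @return a DNA string.
#' @export
make_reference <- function(length, gc = 0.5) {
  stopifnot(length > 0, gc > 0, gc < 1)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Mutate a reference to a target identity
#'
#' Produces a diverged copy of `ref` whose [similarity()] to it lies within
#' +/- 0.5 of `target_identity`, emulating a related species' version of the
#' same locus. 90% of the edits are substitutions and 10% single-base indels
#' (split evenly). The realized identity is verified with the real metric and
#' the edit count adjusted iteratively until the target band is hit.
#'
#' @param ref reference DNA string.
#' @param target_identity desired similarity percent in `[50, 100]`.
#' @param max_iter attempts before giving up.
#' @return the mutated sequence.
#' @export
mutate_to_identity <- function(ref, target_identity, max_iter = 60L) {
  stopifnot(target_identity >= 50, target_identity <= 100)
  if (target_identity == 100) return(ref)
  L <- nchar(ref)
  k <- max(1L, round(L * (100 - target_identity) / 100))
  for (iter in seq_len(max_iter)) {
    v <- strsplit(ref, "")[[1]]
    n_ind <- max(0L, round(0.1 * k))
    n_sub <- k - n_ind
    pos <- sample(L, min(L, n_sub))
    v[pos] <- vapply(v[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    if (n_ind > 0L) {
      n_del <- n_ind %/% 2L
      n_ins <- n_ind - n_del
      if (n_del > 0L) v[sample(length(v), n_del)] <- ""
      if (n_ins > 0L) {
        at <- sample(length(v), n_ins)
        v[at] <- paste0(v[at], sample(c("A", "C", "G", "T"), n_ins,
                                      replace = TRUE))
      }
    }
    mut <- paste(v, collapse = "")
    s <- similarity(ref, mut)
    if (abs(s - target_identity) <= 0.5) return(mut)
    # adjust the edit budget by the observed miss and retry
    k <- max(1L, k + round((s - target_identity) / 100 * L))
  }
  stop("could not reach target identity ", target_identity,
       " within ", max_iter, " attempts")
}

#' Nanopore-like error model
#'
#' Per-base substitution/insertion/deletion probabilities, with the deletion
#' probability multiplied inside homopolymer runs of length >= 3 — the
#' dominant residual error signature of nanopore reads (consensus homopolymer
#' underestimation). The default 2/1/2% rates with a 2x homopolymer deletion
#' boost emulate high-accuracy basecalled reads whose identity to the true
#' sequence is roughly 95%.
#'
#' @param sub_rate,ins_rate,del_rate per-base event probabilities
#'   (their sum must stay below 1).
#' @param homopolymer_del_multiplier factor (>= 1) applied to `del_rate`
#'   inside homopolymer runs of length >= 3.
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.01, del_rate = 0.02,
                        homopolymer_del_multiplier = 2) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 1,
            homopolymer_del_multiplier >= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_del_multiplier = homopolymer_del_multiplier,
                 total = sub_rate + ins_rate + del_rate),
            class = "error_model")
}

# per-position deletion-rate multiplier: positions inside homopolymer runs of
# length >= 3 get model$homopolymer_del_multiplier
hp_multiplier <- function(refv, mult) {
  r <- rle(refv)
  rep(ifelse(r$lengths >= 3L, mult, 1), r$lengths)
}

#' Simulate noisy reads from one reference
#'
#' Each read independently corrupts the reference according to the error
#' model (per-base substitution, 1-bp insertion, deletion; deletions boosted
#' inside homopolymer runs), is reverse-complemented with probability
#' `strand_mix`, and carries a flat quality string consistent with the
#' model's total error rate.
#'
#' @param ref reference DNA string.
#' @param n number of reads.
#' @param model an [error_model()].
#' @param strand_mix probability that a read is emitted reverse-complemented.
#' @param species label recorded in the truth table.
#' @param name_prefix read-name prefix.
#' @return a data frame with columns `name`, `seq`, `qual`, `species`,
#'   `strand` (`+`/`-`) and `ref_id`.
#' @export
simulate_reads <- function(ref, n, model = error_model(), strand_mix = 0.5,
                           species = "sp1", name_prefix = species) {
  stopifnot(n > 0, strand_mix >= 0, strand_mix <= 1)
  refv <- strsplit(ref, "")[[1]]
  L <- length(refv)
  p_del <- model$del_rate * hp_multiplier(refv, model$homopolymer_del_multiplier)
  p_sub <- model$sub_rate
  p_ins <- model$ins_rate
  q <- max(2L, min(40L, round(-10 * log10(max(model$total, 1e-4)))))
  qchar <- intToUtf8(q + 33L)
  alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                nrow = 4, byrow = TRUE)
  refi <- match(refv, c("A", "C", "G", "T"))
  seqs <- character(n)
  for (i in seq_len(n)) {
    u <- runif(L)
    pieces <- refv
    is_sub <- u < p_sub
    is_ins <- !is_sub & u < p_sub + p_ins
    is_del <- !is_sub & !is_ins & u < p_sub + p_ins + p_del
    if (any(is_sub)) {
      pieces[is_sub] <- alt[cbind(refi[is_sub], sample(3L, sum(is_sub),
                                                       replace = TRUE))]
    }
    if (any(is_ins)) {
      pieces[is_ins] <- paste0(pieces[is_ins],
                               sample(c("A", "C", "G", "T"), sum(is_ins),
                                      replace = TRUE))
    }
    if (any(is_del)) pieces[is_del] <- ""
    seqs[i] <- paste(pieces, collapse = "")
  }
  minus <- runif(n) < strand_mix
  seqs[minus] <- reverse_complement(seqs[minus])
  data.frame(name = sprintf("%s_read%04d", name_prefix, seq_len(n)),
             seq = seqs,
             qual = vapply(nchar(seqs), function(k) strrep(qchar, k), ""),
             species = species,
             strand = ifelse(minus, "-", "+"),
             ref_id = species,
             stringsAsFactors = FALSE)
}

#' Simulate a mixed-species amplicon pool
#'
#' Allocates `total_reads` across species by a multinomial draw on the given
#' abundances, simulates each species' reads, interleaves them in random
#' order, and assigns serial numbers `0..N-1` in that final order. Optionally
#' writes a FASTQ file and a tab-separated truth table
#' (`serial`, `species`, `strand`, `ref_id`).
#'
#' @param refs named character vector of reference sequences (names are the
#'   species labels).
#' @param abundances fractions summing to 1 (within 1e-9), parallel to
#'   `refs`.
#' @param total_reads pool size.
#' @param model an [error_model()] shared by all species, or a list of one
#'   model per species.
#' @param strand_mix probability of a reverse-complemented read.
#' @param fastq_path,truth_path optional output paths.
#' @return list with `reads` (an `amplicon_reads`-compatible data frame with
#'   serials) and `truth` (serial, species, strand, ref_id).
#' @export
make_pool <- function(refs, abundances, total_reads, model = error_model(),
                      strand_mix = 0.5, fastq_path = NULL, truth_path = NULL) {
  stopifnot(length(refs) == length(abundances), total_reads > 0)
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must sum to 1 (got ", sum(abundances), ")")
  }
  if (is.null(names(refs))) names(refs) <- paste0("sp", seq_along(refs))
  if (inherits(model, "error_model")) {
    model <- rep(list(model), length(refs))
  }
  counts <- as.vector(rmultinom(1, total_reads, abundances))
  parts <- lapply(seq_along(refs), function(i) {
    if (counts[i] == 0L) return(NULL)
    simulate_reads(refs[[i]], counts[i], model[[i]], strand_mix,
                   species = names(refs)[i])
  })
  pool <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
  pool <- pool[sample(nrow(pool)), , drop = FALSE]
  pool$serial <- seq_len(nrow(pool)) - 1L
  rownames(pool) <- NULL
  reads <- pool[, c("serial", "name", "seq", "qual")]
  attr(reads, "format") <- "fastq"
  attr(reads, "stem") <- "pool"
  class(reads) <- c("amplicon_reads", "data.frame")
  truth <- pool[, c("serial", "species", "strand", "ref_id")]
  if (!is.null(fastq_path)) {
    write_records(fastq_path, reads$name, reads$seq, reads$qual, "fastq")
    attr(reads, "stem") <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                               basename(fastq_path), ignore.case = TRUE)
  }
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}
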