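#' Sorter configuration
#'
#' Collects every numeric threshold and sampling parameter of the sorting
#' algorithm in one place. The defaults are the algorithm's standard settings:
#' 10,000 reads analysed in batches of 1,000; a 5% read-length gate and an 80%
#' similarity floor for recording read pairs, with reverse-complement rescue
#' when same-strand similarity falls below 50%; gene-group fusion from 50-read
#' consensuses (8% length gate, 60% similarity); species seeding at 93%
#' similarity, read assignment from 95% down to 85% in 1% steps with at most 3
#' passes per level, and species-consensus merging at 96% (8% length gate)
#' every other cycle; final consensus from 200 random reads.
#'
#' @param max_reads maximum number of reads sampled for analysis.
#' @param batch_size reads per comparison batch in the default (batched) mode.
#' @param all_mode compare all sampled reads with each other instead of
#'   batching (computation-intensive; discouraged beyond ~100,000 reads).
#' @param random_mode sample batches randomly from the input instead of taking
#'   reads in file order. Batches are drawn independently, so with
#'   `max_reads` above the read count a read can be sampled several times.
#' @param len_gate_reads maximum relative length difference for read-read
#'   comparisons (fraction of the longer read).
#' @param edge_min_sim minimum similarity percent for recording a read pair.
#' @param rc_trigger similarity percent below which the reverse complement of
#'   one sequence is also tried.
#' @param group_fuse_sample reads sampled per gene group for the fusion
#'   consensus.
#' @param len_gate_groups length gate for comparing gene-group consensuses.
#' @param group_fuse_min_sim similarity percent at or above which two
#'   gene-group consensuses cause their groups to merge.
#' @param species_seed_sim similarity percent for seeding species groups
#'   (the `--similar_species_groups` knob).
#' @param species_add_start,species_add_floor start and floor of the falling
#'   threshold at which remaining reads are added to species groups.
#' @param species_len_gate length gate for read-vs-species-consensus
#'   comparisons.
#' @param species_merge_sim similarity percent at or above which two species
#'   consensuses cause their groups to merge (the `--similar_consensus` knob).
#' @param species_merge_len_gate length gate for species-consensus
#'   comparisons.
#' @param max_cycles_per_level maximum assignment passes at one threshold
#'   level.
#' @param final_consensus_sample reads sampled for consensus building.
#' @param rng_seed integer seed controlling all sampling.
#' @param n_workers worker processes for pair scoring.
#'
#' @return an object of class `sorter_config` (a validated list).
#' @export
#' @examples
#' cfg <- sorter_config(max_reads = 2000, rng_seed = 7)
#' cfg$edge_min_sim
sorter_config <- function(max_reads = 10000L,
                          batch_size = 1000L,
                          all_mode = FALSE,
                          random_mode = FALSE,
                          len_gate_reads = 0.05,
                          edge_min_sim = 80,
                          rc_trigger = 50,
                          group_fuse_sample = 50L,
                          len_gate_groups = 0.08,
                          group_fuse_min_sim = 60,
                          species_seed_sim = 93,
                          species_add_start = 95,
                          species_add_floor = 85,
                          species_len_gate = 0.05,
                          species_merge_sim = 96,
                          species_merge_len_gate = 0.08,
                          max_cycles_per_level = 3L,
                          final_consensus_sample = 200L,
                          rng_seed = 42L,
                          n_workers = 1L) {
  cfg <- list(max_reads = as.integer(max_reads),
              batch_size = as.integer(batch_size),
              all_mode = isTRUE(all_mode),
              random_mode = isTRUE(random_mode),
              len_gate_reads = len_gate_reads,
              edge_min_sim = edge_min_sim,
              rc_trigger = rc_trigger,
              group_fuse_sample = as.integer(group_fuse_sample),
              len_gate_groups = len_gate_groups,
              group_fuse_min_sim = group_fuse_min_sim,
              species_seed_sim = species_seed_sim,
              species_add_start = species_add_start,
              species_add_floor = species_add_floor,
              species_len_gate = species_len_gate,
              species_merge_sim = species_merge_sim,
              species_merge_len_gate = species_merge_len_gate,
              max_cycles_per_level = as.integer(max_cycles_per_level),
              final_consensus_sample = as.integer(final_consensus_sample),
              rng_seed = as.integer(rng_seed),
              n_workers = as.integer(n_workers))
  if (cfg$max_reads <= 0L) stop("max_reads must be positive")
  if (cfg$batch_size <= 0L) stop("batch_size must be positive")
  thr <- c("edge_min_sim", "rc_trigger", "group_fuse_min_sim",
           "species_seed_sim", "species_add_start", "species_add_floor",
           "species_merge_sim")
  for (p in thr) {
    if (!(cfg[[p]] > 0 && cfg[[p]] <= 100)) {
      stop(p, " must be in (0, 100]")
    }
  }
  frc <- c("len_gate_reads", "len_gate_groups", "species_len_gate",
           "species_merge_len_gate")
  for (p in frc) {
    if (!(cfg[[p]] > 0 && cfg[[p]] < 1)) stop(p, " must be in (0, 1)")
  }
  if (cfg$species_add_floor > cfg$species_add_start) {
    stop("species_add_floor must not exceed species_add_start")
  }
  if (cfg$species_seed_sim > cfg$species_merge_sim) {
    stop("species_seed_sim must not exceed species_merge_sim")
  }
  if (cfg$max_cycles_per_level < 1L) stop("max_cycles_per_level must be >= 1")
  if (cfg$final_consensus_sample < 1L) stop("final_consensus_sample must be >= 1")
  if (cfg$n_workers < 1L) stop("n_workers must be >= 1")
  structure(cfg, class = "sorter_config")
}

#' @export
print.sorter_config <- function(x, ...) {
  cat("<sorter_config>\n")
  cat(sprintf("  sampling: max_reads=%d, batch_size=%d, all=%s, random=%s\n",
              x$max_reads, x$batch_size, x$all_mode, x$random_mode))
  cat(sprintf("  read pairs: length gate %.0f%%, similarity >= %g%%, RC below %g%%\n",
              100 * x$len_gate_reads, x$edge_min_sim, x$rc_trigger))
  cat(sprintf("  gene fusion: %d-read consensus, gate %.0f%%, merge >= %g%%\n",
              x$group_fuse_sample, 100 * x$len_gate_groups, x$group_fuse_min_sim))
  cat(sprintf("  species: seed >= %g%%, add %g%% -> %g%% (max %d passes/level), merge >= %g%%\n",
              x$species_seed_sim, x$species_add_start, x$species_add_floor,
              x$max_cycles_per_level, x$species_merge_sim))
  cat(sprintf("  consensus sample: %d reads; seed %d; workers %d\n",
              x$final_consensus_sample, x$rng_seed, x$n_workers))
  invisible(x)
}
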