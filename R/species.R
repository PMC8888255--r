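#' Seed species groups from high-similarity read pairs
#'
#' Within one gene group, the retained edges with similarity at or above
#' `species_seed_sim` (default 93%) are taken; their connected components
#' become the initial species groups (components sharing reads are merged by
#' construction) and each gets a consensus from its members. Reads in no
#' qualifying edge remain unassigned for the assignment loop.
#'
#' @param group a gene group (from [build_groups()]/[fuse_gene_groups()])
#'   with a retained edge list.
#' @param reads the `amplicon_reads` data frame.
#' @param cfg a [sorter_config()].
#' @return list of species groups, each with `species_id` (1-based, by
#'   decreasing size), `members`, `orientation` (relative to the gene-group
#'   strand), `consensus`, and `history` (member count after each pass).
#' @export
seed_species_groups <- function(group, reads, cfg = sorter_config()) {
  e <- group$edges
  e <- e[e$similarity >= cfg$species_seed_sim, , drop = FALSE]
  if (is.null(e) || nrow(e) == 0L) return(list())
  comps <- edge_components(e$a, e$b)
  species <- lapply(comps, function(mem) {
    ori <- group$orientation[match(mem, group$members)]
    list(members = mem, orientation = ori,
         consensus = build_consensus(oriented_seqs(reads, mem, ori),
                                     cfg$final_consensus_sample),
         history = length(mem))
  })
  for (i in seq_along(species)) species[[i]]$species_id <- i
  species
}

#' Assign remaining reads to species groups at one threshold
#'
#' Every still-unassigned member of the gene group is compared (with
#' reverse-complement rescue) to every species consensus within the 5% length
#' gate, and joins the species to which it is most similar provided that
#' similarity reaches `threshold` (ties go to the lower species id). Species
#' that gained members rebuild their consensus from up to
#' `final_consensus_sample` members.
#'
#' @param group the gene group.
#' @param species current list of species groups.
#' @param reads the `amplicon_reads` data frame.
#' @param threshold similarity percent required to join.
#' @param cfg a [sorter_config()].
#' @param cache optional environment memoising read-vs-consensus similarities
#'   across passes (a consensus string seen before is never re-scored against
#'   the same read; results are identical with or without the cache).
#' @return list with `species` (updated) and `added` (reads assigned in this
#'   pass).
#' @export
assign_reads <- function(group, species, reads, threshold, cfg = sorter_config(),
                         cache = NULL) {
  if (length(species) == 0L) return(list(species = species, added = 0L))
  assigned <- unlist(lapply(species, `[[`, "members"))
  un <- setdiff(group$members, assigned)
  if (length(un) == 0L) return(list(species = species, added = 0L))
  uori <- group$orientation[match(un, group$members)]
  rseqs <- oriented_seqs(reads, un, uori)
  cons <- vapply(species, `[[`, "", "consensus")
  nN <- nrow(reads)
  sim <- matrix(NA_real_, length(un), length(species))
  rcm <- matrix(0L, length(un), length(species))
  for (j in seq_along(species)) {
    slot <- NULL
    if (!is.null(cache)) {
      key <- paste0("c", cons[j])
      slot <- cache[[key]]
      if (is.null(slot)) {
        slot <- list(done = logical(nN), sim = rep(NA_real_, nN),
                     rc = integer(nN))
      }
      hit <- slot$done[un + 1L]
    } else {
      hit <- rep(FALSE, length(un))
    }
    if (any(!hit)) {
      cs <- cross_sim_cpp(rseqs[!hit], cons[j], reverse_complement(cons[j]),
                          cfg$species_len_gate, cfg$rc_trigger)
      if (!is.null(cache)) {
        idx <- un[!hit] + 1L
        slot$done[idx] <- TRUE
        slot$sim[idx] <- cs$similarity[, 1L]
        slot$rc[idx] <- cs$rc[, 1L]
      } else {
        sim[!hit, j] <- cs$similarity[, 1L]
        rcm[!hit, j] <- cs$rc[, 1L]
      }
    }
    if (!is.null(cache)) {
      cache[[key]] <- slot
      sim[, j] <- slot$sim[un + 1L]
      rcm[, j] <- slot$rc[un + 1L]
    }
  }
  sim[is.na(sim)] <- -Inf
  bestj <- max.col(sim, ties.method = "first")
  bests <- sim[cbind(seq_along(un), bestj)]
  take <- is.finite(bests) & bests >= threshold
  if (!any(take)) return(list(species = species, added = 0L))
  for (j in unique(bestj[take])) {
    sel <- take & bestj == j
    add <- un[sel]
    addori <- xor(uori[sel], as.logical(rcm[cbind(which(sel), rep(j, sum(sel)))]))
    o <- order(c(species[[j]]$members, add))
    mem <- c(species[[j]]$members, add)[o]
    ori <- c(species[[j]]$orientation, addori)[o]
    species[[j]]$members <- mem
    species[[j]]$orientation <- ori
    species[[j]]$consensus <- build_consensus(oriented_seqs(reads, mem, ori),
                                              cfg$final_consensus_sample)
  }
  list(species = species, added = sum(take))
}

#' Merge species groups with convergent consensuses
#'
#' All species-consensus pairs within an 8% length difference are compared;
#' pairs at or above `species_merge_sim` (default 96%) are merged (transitive
#' closure), merged groups rebuild their consensus, and ids are reassigned by
#' decreasing size. This is what bounds the separation limit: two species
#' whose true sequences are more than ~96% identical will see their groups
#' merged and averaged into one consensus.
#'
#' @param species list of species groups.
#' @param reads the `amplicon_reads` data frame.
#' @param cfg a [sorter_config()].
#' @return the merged list of species groups.
#' @export
merge_species_groups <- function(species, reads, cfg = sorter_config()) {
  k <- length(species)
  if (k <= 1L) return(species)
  cons <- vapply(species, `[[`, "", "consensus")
  dsu <- dsu_new(k)
  any_merge <- FALSE
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (!length_compatible(nchar(cons[i]), nchar(cons[j]),
                             cfg$species_merge_len_gate)) next
      os <- oriented_similarity(cons[i], cons[j], cfg$rc_trigger)
      if (os$similarity >= cfg$species_merge_sim) {
        dsu_union(dsu, i, j, identical(os$orientation, "opposite"))
        any_merge <- TRUE
      }
    }
  }
  if (!any_merge) return(species)
  roots <- vapply(seq_len(k), function(i) dsu_find(dsu, i)$root, 1L)
  merged <- lapply(unique(roots), function(r) {
    ids <- which(roots == r)
    if (length(ids) == 1L) return(species[[ids]])
    mem <- integer(0); ori <- logical(0); hist <- integer(0)
    for (i in ids) {
      par <- dsu_find(dsu, i)$parity
      mem <- c(mem, species[[i]]$members)
      ori <- c(ori, xor(species[[i]]$orientation, par))
      if (length(species[[i]]$history) > length(hist)) {
        hist <- species[[i]]$history
      }
    }
    o <- order(mem)
    mem <- mem[o]; ori <- ori[o]
    list(members = mem, orientation = ori,
         consensus = build_consensus(oriented_seqs(reads, mem, ori),
                                     cfg$final_consensus_sample),
         history = c(hist, length(mem)))
  })
  ord <- order(-vapply(merged, function(s) length(s$members), 1L),
               vapply(merged, function(s) min(s$members), 1L))
  merged <- merged[ord]
  for (i in seq_along(merged)) merged[[i]]$species_id <- i
  merged
}

#' Sort one gene group into species groups
#'
#' The full stage-2 loop: species groups are seeded once at
#' `species_seed_sim`; then for each threshold level from `species_add_start`
#' down to `species_add_floor` (1% steps) assignment passes run until a pass
#' adds no read or `max_cycles_per_level` passes have run. A global cycle
#' counter is incremented at every pass and species-consensus merging runs on
#' every second cycle. Reads still unassigned when the floor level completes
#' are returned separately (they end up in the "unique sequences" file).
#' Unassigned reads are re-examined at every level, so a read that misses the
#' 95% bar can still join once the threshold has fallen towards 85%, against a
#' consensus that has meanwhile become more accurate.
#'
#' @param group the gene group.
#' @param reads the `amplicon_reads` data frame.
#' @param cfg a [sorter_config()].
#' @return list with `species` (final species groups) and `unassigned`
#'   (serials).
#' @export
sort_gene_group <- function(group, reads, cfg = sorter_config()) {
  species <- seed_species_groups(group, reads, cfg)
  cycle <- 0L
  cache <- new.env(parent = emptyenv())
  for (t in seq(cfg$species_add_start, cfg$species_add_floor, by = -1)) {
    passes <- 0L
    repeat {
      passes <- passes + 1L
      res <- assign_reads(group, species, reads, t, cfg, cache = cache)
      species <- res$species
      cycle <- cycle + 1L
      if (cycle %% 2L == 0L) {
        species <- merge_species_groups(species, reads, cfg)
      }
      species <- lapply(species, function(s) {
        s$history <- c(s$history, length(s$members))
        s
      })
      if (res$added == 0L || passes >= cfg$max_cycles_per_level) break
    }
  }
  ord <- order(-vapply(species, function(s) length(s$members), 1L),
               vapply(species, function(s) if (length(s$members)) min(s$members) else NA_integer_, 1L))
  species <- species[ord]
  for (i in seq_along(species)) species[[i]]$species_id <- i
  assigned <- unlist(lapply(species, `[[`, "members"))
  list(species = species,
       unassigned = setdiff(group$members, assigned))
}
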