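#' Sample reads into comparison batches
#'
#' Stage-1 sampling. In all-vs-all mode a single batch of
#' `min(max_reads, N)` serials is returned. Otherwise, when fewer than 1,000
#' reads are loaded all of them form one batch; in the default (ordered) mode
#' consecutive slices of `batch_size` reads are taken up to `max_reads`; in
#' random mode each batch is drawn independently and uniformly with
#' replacement (duplicates inside a batch are collapsed, so serials are
#' distinct within a batch), so `max_reads` may exceed the number of available
#' reads and a read can be compared in several batches while others are never
#' sampled.
#'
#' @param reads an `amplicon_reads` data frame.
#' @param cfg a [sorter_config()].
#' @return a list of integer vectors of read serials.
#' @export
sample_reads <- function(reads, cfg = sorter_config()) {
  n <- nrow(reads)
  if (n == 0L) stop("no reads to sample")
  if (cfg$max_reads <= 0L) stop("max_reads must be positive")
  serials <- reads$serial
  if (cfg$all_mode) {
    k <- min(cfg$max_reads, n)
    sel <- if (cfg$random_mode) sort(sample(serials, k)) else serials[seq_len(k)]
    return(list(sel))
  }
  if (n < 1000L) {
    return(list(serials))
  }
  if (cfg$random_mode) {
    nb <- ceiling(cfg$max_reads / cfg$batch_size)
    sizes <- rep(cfg$batch_size, nb)
    sizes[nb] <- cfg$max_reads - (nb - 1L) * cfg$batch_size
    # each draw is uniform with replacement; duplicates within a batch are
    # collapsed (a read is compared once per batch), so sampling N reads from
    # N leaves ~1 - (1 - 1/N)^N ~ 63% of reads ever sampled
    lapply(sizes, function(sz) sort(unique(sample(serials, sz, replace = TRUE))))
  } else {
    k <- min(cfg$max_reads, n)
    unname(split(serials[seq_len(k)],
                 ceiling(seq_len(k) / cfg$batch_size)))
  }
}

# split the triangular i-loop 1..(n-1) into `nw` contiguous ranges with
# roughly equal pair counts
chunk_ranges <- function(n, nw) {
  if (n < 2L) return(list())
  i <- seq_len(n - 1L)
  w <- cumsum(n - i)
  grp <- pmin(nw, 1L + floor(nw * (w - (n - i)) / w[length(w)]))
  lapply(split(i, grp), range)
}

#' Score all read pairs within a batch
#'
#' Every unordered pair whose lengths pass the 5% gate is scored with
#' [oriented_similarity()] (reverse-complement rescue below `rc_trigger`); an
#' edge is recorded when the similarity reaches `edge_min_sim` (default 80%).
#' The full edge list is retained for reuse when seeding species groups.
#'
#' @param batch integer vector of read serials.
#' @param reads the `amplicon_reads` data frame.
#' @param cfg a [sorter_config()]; `n_workers` > 1 chunks the pair loop over
#'   forked workers (results are reassembled in a canonical order, so the
#'   outcome does not depend on the worker count).
#' @return a data frame with columns `a`, `b` (serials, `a < b`),
#'   `similarity`, and `rc` (scored against the reverse complement).
#' @export
score_batch <- function(batch, reads, cfg = sorter_config()) {
  empty <- data.frame(a = integer(0), b = integer(0),
                      similarity = numeric(0), rc = logical(0))
  n <- length(batch)
  if (n < 2L) return(empty)
  seqs <- reads$seq[match(batch, reads$serial)]
  if (anyNA(seqs)) stop("batch contains serials not present in reads")
  rcs <- reverse_complement(seqs)
  nw <- cfg$n_workers
  if (nw > 1L && .Platform$OS.type != "windows") {
    parts <- parallel::mclapply(
      chunk_ranges(n, 4L * nw),
      function(rg) pair_edges_cpp(seqs, rcs, cfg$len_gate_reads,
                                  cfg$edge_min_sim, cfg$rc_trigger,
                                  rg[1], rg[2]),
      mc.cores = nw)
    res <- list(a = unlist(lapply(parts, `[[`, "a")),
                b = unlist(lapply(parts, `[[`, "b")),
                similarity = unlist(lapply(parts, `[[`, "similarity")),
                rc = unlist(lapply(parts, `[[`, "rc")))
  } else {
    res <- pair_edges_cpp(seqs, rcs, cfg$len_gate_reads, cfg$edge_min_sim,
                          cfg$rc_trigger, 1L, n - 1L)
  }
  if (length(res$a) == 0L) return(empty)
  sa <- batch[res$a]
  sb <- batch[res$b]
  out <- data.frame(a = pmin(sa, sb), b = pmax(sa, sb),
                    similarity = res$similarity, rc = as.logical(res$rc))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Best match per read
#'
#' For each read appearing in the edge list, keeps only the neighbour with
#' the highest similarity (ties broken towards the smaller neighbour serial),
#' yielding the high-similarity pairs that gene groups are built from.
#'
#' @param edges an edge data frame from [score_batch()].
#' @return a data frame with one row per read: `serial`, `best`,
#'   `similarity`, `rc`.
#' @export
best_pairs <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(serial = integer(0), best = integer(0),
                      similarity = numeric(0), rc = logical(0)))
  }
  long <- data.frame(serial = c(edges$a, edges$b),
                     best = c(edges$b, edges$a),
                     similarity = rep(edges$similarity, 2L),
                     rc = rep(edges$rc, 2L))
  long <- long[order(long$serial, -long$similarity, long$best), , drop = FALSE]
  out <- long[!duplicated(long$serial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# connected components of an undirected edge set (serial pairs); returns a
# list of sorted integer vectors, largest first (ties: smallest serial first)
edge_components <- function(a, b) {
  verts <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(a), to = as.character(b)),
    directed = FALSE, vertices = data.frame(name = as.character(verts)))
  comp <- igraph::components(g)
  members <- split(verts, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, 1L),
               vapply(members, min, 1L))
  unname(members[ord])
}

# breadth-first orientation assignment within one component: the smallest
# serial defines the reference strand; each edge's rc flag flips orientation
orient_component <- function(members, a, b, rc) {
  key <- function(s) as.character(s)
  adj <- new.env(parent = emptyenv())
  for (i in seq_along(a)) {
    for (xy in list(c(a[i], b[i]), c(b[i], a[i]))) {
      k <- key(xy[1])
      cur <- if (is.null(adj[[k]])) list() else adj[[k]]
      cur[[length(cur) + 1L]] <- c(xy[2], rc[i])
      adj[[k]] <- cur
    }
  }
  ori <- rep(NA, length(members))
  names(ori) <- key(members)
  root <- key(min(members))
  ori[root] <- FALSE
  queue <- min(members)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[key(v)]]) {
      w <- key(nb[1])
      if (is.na(ori[w])) {
        ori[w] <- xor(ori[key(v)], as.logical(nb[2]))
        queue <- c(queue, nb[1])
      }
    }
  }
  ori[is.na(ori)] <- FALSE
  unname(ori[key(members)])
}

#' Build gene groups from best-match pairs
#'
#' Treats each (read, best match) pair as an undirected edge and returns the
#' connected components as gene groups; reads with no surviving edge belong to
#' no group. The smallest serial of each component defines the group's
#' reference strand and every member stores the orientation (composed along
#' the best-pair edges) that maps it onto that strand.
#'
#' @param best the best-pair data frame from [best_pairs()].
#' @param edges optionally, the full retained edge list from [score_batch()];
#'   each group keeps the edges among its members (needed later to seed
#'   species groups).
#' @return a list of gene groups, each a list with `group_id` (1-based, by
#'   decreasing size), `members` (sorted serials), `orientation` (logical,
#'   parallel to `members`; `TRUE` = reverse-complemented relative to the
#'   group strand) and `edges`.
#' @export
build_groups <- function(best, edges = NULL) {
  if (nrow(best) == 0L) return(list())
  ua <- pmin(best$serial, best$best)
  ub <- pmax(best$serial, best$best)
  dup <- duplicated(paste(ua, ub))
  ua <- ua[!dup]; ub <- ub[!dup]; urc <- best$rc[!dup]
  comps <- edge_components(ua, ub)
  groups <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    mem <- comps[[k]]
    sel <- ua %in% mem & ub %in% mem
    ori <- orient_component(mem, ua[sel], ub[sel], urc[sel])
    ge <- if (is.null(edges)) {
      data.frame(a = ua[sel], b = ub[sel],
                 similarity = best$similarity[!dup][sel], rc = urc[sel])
    } else {
      edges[edges$a %in% mem & edges$b %in% mem, , drop = FALSE]
    }
    groups[[k]] <- list(group_id = k, members = mem, orientation = ori,
                        edges = ge)
  }
  groups
}

# union-find with strand parity: parity[x] is the orientation of x relative
# to its root
dsu_new <- function(n) {
  env <- new.env(parent = emptyenv())
  env$parent <- seq_len(n)
  env$parity <- rep(FALSE, n)
  env
}
dsu_find <- function(env, x) {
  p <- FALSE
  while (env$parent[x] != x) {
    p <- xor(p, env$parity[x])
    x <- env$parent[x]
  }
  list(root = x, parity = p)
}
dsu_union <- function(env, x, y, rel) {
  fx <- dsu_find(env, x)
  fy <- dsu_find(env, y)
  if (fx$root != fy$root) {
    env$parent[fy$root] <- fx$root
    # parity so that parity(x) XOR parity(y) == rel
    env$parity[fy$root] <- xor(xor(fx$parity, fy$parity), rel)
  }
  invisible(env)
}

#' Fuse gene groups with agreeing consensuses
#'
#' Several gene groups can represent the same gene. Each group builds a
#' consensus from up to 50 randomly sampled member reads; all consensus pairs
#' within an 8% length difference are compared, groups whose consensuses are
#' at least 60% similar are merged (transitively), and group ids are
#' reassigned 1..K by decreasing size.
#'
#' @param groups list of gene groups from [build_groups()].
#' @param reads the `amplicon_reads` data frame.
#' @param cfg a [sorter_config()].
#' @return the fused list of gene groups.
#' @export
fuse_gene_groups <- function(groups, reads, cfg = sorter_config()) {
  k <- length(groups)
  if (k <= 1L) return(groups)
  cons <- vapply(groups, function(g) {
    build_consensus(oriented_seqs(reads, g$members, g$orientation),
                    cfg$group_fuse_sample)
  }, "")
  dsu <- dsu_new(k)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (!length_compatible(nchar(cons[i]), nchar(cons[j]),
                             cfg$len_gate_groups)) next
      os <- oriented_similarity(cons[i], cons[j], cfg$rc_trigger)
      if (os$similarity >= cfg$group_fuse_min_sim) {
        dsu_union(dsu, i, j, identical(os$orientation, "opposite"))
      }
    }
  }
  roots <- vapply(seq_len(k), function(i) dsu_find(dsu, i)$root, 1L)
  fused <- lapply(unique(roots), function(r) {
    ids <- which(roots == r)
    mem <- integer(0); ori <- logical(0); ge <- list()
    for (i in ids) {
      par <- dsu_find(dsu, i)$parity
      mem <- c(mem, groups[[i]]$members)
      ori <- c(ori, xor(groups[[i]]$orientation, par))
      ge[[length(ge) + 1L]] <- groups[[i]]$edges
    }
    o <- order(mem)
    list(members = mem[o], orientation = ori[o],
         edges = do.call(rbind, ge))
  })
  ord <- order(-vapply(fused, function(g) length(g$members), 1L),
               vapply(fused, function(g) min(g$members), 1L))
  fused <- fused[ord]
  for (i in seq_along(fused)) fused[[i]]$group_id <- i
  fused
}
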