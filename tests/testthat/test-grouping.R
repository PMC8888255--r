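fake_reads <- function(seqs) {
  rd <- data.frame(serial = seq_along(seqs) - 1L,
                   name = sprintf("r%d", seq_along(seqs)),
                   seq = seqs, qual = NA_character_,
                   stringsAsFactors = FALSE)
  attr(rd, "format") <- "fasta"
  attr(rd, "stem") <- "fake"
  class(rd) <- c("amplicon_reads", "data.frame")
  rd
}

test_that("batched sampling follows the 10,000/1,000 contract", {
  set.seed(301)
  rd <- fake_reads(rep("ACGT", 2500))
  b <- sample_reads(rd, sorter_config())
  expect_equal(vapply(b, length, 1L), c(1000L, 1000L, 500L))
  expect_equal(unlist(b), 0:2499)  # input order, consecutive slices
  # fewer than 1000 reads: all reads, one batch
  rd2 <- fake_reads(rep("ACGT", 800))
  b2 <- sample_reads(rd2, sorter_config())
  expect_equal(b2, list(0:799))
  # all mode: a single batch capped at max_reads
  b3 <- sample_reads(rd, sorter_config(all_mode = TRUE, max_reads = 1200))
  expect_equal(b3, list(0:1199))
})

test_that("random sampling hits the with-replacement coverage expectation", {
  set.seed(302)
  n <- 10000L
  rd <- fake_reads(rep("ACGT", n))
  b <- sample_reads(rd, sorter_config(random_mode = TRUE, max_reads = n))
  expect_length(b, 10L)
  expect_true(all(vapply(b, function(x) !any(duplicated(x)), TRUE)))
  frac <- length(unique(unlist(b))) / n
  expect_lt(abs(frac - (1 - (1 - 1 / n)^n)), 0.02)  # ~63.2%
})

test_that("score_batch gates by length and scores oriented similarity", {
  set.seed(303)
  repeat { # forward similarity to the RC twin must sit below the 50% trigger
    a <- random_seq(700)
    if (similarity(a, reverse_complement(a)) < 50) break
  }
  rd <- fake_reads(c(a, a, random_seq(600)))
  e <- score_batch(0:2, rd, sorter_config())
  # identical pair scored; 700-vs-600 never compared (100/700 > 5%)
  expect_equal(nrow(e), 1L)
  expect_equal(e$a, 0L)
  expect_equal(e$b, 1L)
  expect_equal(e$similarity, 100)
  expect_false(e$rc)
  # reverse-complemented twin is rescued and flagged
  rd2 <- fake_reads(c(a, reverse_complement(a)))
  e2 <- score_batch(0:1, rd2, sorter_config())
  expect_equal(e2$similarity, 100)
  expect_true(e2$rc)
})

test_that("simulated same-species reads all pair above the 80% floor", {
  set.seed(304)
  ref <- make_reference(700)
  sim <- simulate_reads(ref, 20, error_model(), strand_mix = 0.5)
  rd <- fake_reads(sim$seq)
  e <- score_batch(rd$serial, rd, sorter_config())
  gated <- sum(outer(nchar(rd$seq), nchar(rd$seq), function(x, y)
    abs(x - y) / pmax(x, y) < 0.05)[upper.tri(diag(20))])
  expect_equal(nrow(e), gated)  # every gated pair is an edge
  expect_true(all(e$similarity >= 80))
})

test_that("best_pairs keeps the strongest neighbour with deterministic ties", {
  e <- data.frame(a = c(1L, 1L), b = c(2L, 3L), similarity = c(95, 90),
                  rc = c(FALSE, FALSE))
  bp <- best_pairs(e)
  expect_equal(bp$best[match(c(1, 2, 3), bp$serial)], c(2L, 1L, 1L))
  e2 <- data.frame(a = c(1L, 1L), b = c(2L, 3L), similarity = c(90, 90),
                   rc = c(FALSE, FALSE))
  expect_equal(best_pairs(e2)$best[best_pairs(e2)$serial == 1L], 2L)
})

test_that("best_pairs agrees with a brute-force argmax on random graphs", {
  set.seed(305)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (!any(keep)) next
    e <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                    similarity = round(runif(sum(keep), 80, 100), 3),
                    rc = FALSE)
    bp <- best_pairs(e)
    for (v in unique(c(e$a, e$b))) {
      nb <- rbind(data.frame(o = e$b[e$a == v], s = e$similarity[e$a == v]),
                  data.frame(o = e$a[e$b == v], s = e$similarity[e$b == v]))
      want <- min(nb$o[nb$s == max(nb$s)])
      expect_equal(bp$best[bp$serial == v], want)
    }
  }
})

test_that("build_groups merges overlapping best pairs into components", {
  bp <- data.frame(serial = c(1L, 2L, 3L), best = c(2L, 1L, 2L),
                   similarity = c(95, 95, 90), rc = FALSE)
  g <- build_groups(bp)
  expect_length(g, 1L)
  expect_equal(g[[1]]$members, 1:3)
  bp2 <- data.frame(serial = c(1L, 3L), best = c(2L, 4L),
                    similarity = c(95, 90), rc = FALSE)
  g2 <- build_groups(bp2)
  expect_length(g2, 2L)
  expect_equal(lapply(g2, `[[`, "members"), list(c(1L, 2L), c(3L, 4L)))
})

test_that("build_groups components match a union-find oracle", {
  set.seed(306)
  for (rep in 1:25) {
    n <- sample(5:25, 1)
    m <- sample(2:20, 1)
    a <- sample(n, m, replace = TRUE)
    b <- sample(n, m, replace = TRUE)
    ok <- a != b
    if (!any(ok)) next
    bp <- data.frame(serial = pmin(a, b)[ok], best = pmax(a, b)[ok],
                     similarity = 90, rc = FALSE)
    got <- lapply(build_groups(bp), `[[`, "members")
    expect_identical(got, unname(uf_components(bp$serial, bp$best)))
  }
})

test_that("orientation flags compose along best-pair edges", {
  set.seed(307)
  ref <- random_seq(300)
  # read 1 forward, read 2 reverse-complemented, read 3 forward
  rd <- fake_reads(c(substitute_k(ref, 3),
                     reverse_complement(substitute_k(ref, 4)),
                     substitute_k(ref, 5)))
  e <- score_batch(0:2, rd, sorter_config())
  g <- build_groups(best_pairs(e), e)
  expect_length(g, 1L)
  ori <- g[[1]]$orientation
  expect_identical(ori, c(FALSE, TRUE, FALSE))
  # all members agree once flipped to the group strand
  seqs <- rd$seq
  seqs[ori] <- reverse_complement(seqs[ori])
  expect_true(all(combn(3, 2, function(ij)
    similarity(seqs[ij[1]], seqs[ij[2]])) > 95))
})

test_that("gene groups from the same reference fuse; a single group is unchanged", {
  set.seed(308)
  ref <- make_reference(700)
  sim <- simulate_reads(ref, 40, error_model(), strand_mix = 0)
  rd <- fake_reads(sim$seq)
  cfg <- sorter_config()
  # force two artificial groups from the same species
  e <- score_batch(rd$serial, rd, cfg)
  gA <- group_from_edges(0:19, e[e$a < 20 & e$b < 20, ])
  gB <- group_from_edges(20:39, e[e$a >= 20 & e$b >= 20, ])
  gB$group_id <- 2L
  fused <- fuse_gene_groups(list(gA, gB), rd, cfg)
  expect_length(fused, 1L)
  expect_equal(fused[[1]]$members, 0:39)
  expect_identical(fuse_gene_groups(list(gA), rd, cfg), list(gA))
})

test_that("fusion preserves the partition of members", {
  set.seed(309)
  refs <- c(make_reference(700), make_reference(2800))
  s1 <- simulate_reads(refs[1], 30, error_model(), 0, species = "a")
  s2 <- simulate_reads(refs[2], 30, error_model(), 0, species = "b")
  rd <- fake_reads(c(s1$seq, s2$seq))
  cfg <- sorter_config()
  e <- score_batch(rd$serial, rd, cfg)
  groups <- build_groups(best_pairs(e), e)
  before <- sort(unlist(lapply(groups, `[[`, "members")))
  fused <- fuse_gene_groups(groups, rd, cfg)
  after <- unlist(lapply(fused, `[[`, "members"))
  expect_identical(sort(after), before)      # same universe
  expect_false(any(duplicated(after)))       # still disjoint
  # 700 bp vs 2800 bp groups can never be compared, let alone fused
  expect_gte(length(fused), 2L)
})
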