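# independent oracles and small fixture builders used across the test files

# quadratic-DP global edit distance, written independently of the package's
# bit-parallel implementation
dp_edit_dist <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- c(i, rep(0, length(B)))
    for (j in seq_along(B)) {
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]),
                        prev[j + 1] + 1,
                        cur[j] + 1)
    }
    prev <- cur
  }
  prev[length(B) + 1]
}

dp_similarity <- function(a, b) {
  100 * (1 - dp_edit_dist(a, b) / max(nchar(a), nchar(b)))
}

# plain union-find oracle for connected components of an undirected edge set
uf_components <- function(a, b) {
  verts <- sort(unique(c(a, b)))
  parent <- seq_along(verts)
  findr <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_along(a)) {
    ra <- findr(match(a[i], verts))
    rb <- findr(match(b[i], verts))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(verts), findr, 1L)
  comps <- lapply(split(verts, roots), sort)
  comps[order(-vapply(comps, length, 1L), vapply(comps, min, 1L))]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k distinct positions (never back to the original base)
substitute_k <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), k)
  v[idx] <- vapply(v[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

write_tmp_fastq <- function(seqs, names = sprintf("r%d", seq_along(seqs)),
                            quals = vapply(nchar(seqs), function(k) strrep("I", k), "")) {
  f <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)), f)
  f
}

write_tmp_fasta <- function(seqs, names = sprintf("r%d", seq_along(seqs))) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), f)
  f
}

# gene group fixture built directly from an edge table (bypasses scoring)
group_from_edges <- function(members, edges) {
  list(group_id = 1L, members = sort(members),
       orientation = rep(FALSE, length(members)),
       edges = edges)
}
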