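#' Load amplicon reads from FASTA or FASTQ
#'
#' Reads an input file (format auto-detected from the first character:
#' `>` FASTA, `@` FASTQ), applies the read-length window, and assigns every
#' surviving read a dense serial number `0..N-1` in file order. Reads outside
#' the window are counted (attribute `n_dropped`) but not returned. Sequences
#' are uppercased; IUPAC ambiguity letters other than `N` are rejected with an
#' error naming the offending record.
#'
#' @param path input file path (plain or gzipped FASTA/FASTQ).
#' @param min_length,max_length inclusive read-length window in bp.
#' @return a data frame of class `amplicon_reads` with columns `serial`,
#'   `name`, `seq` and `qual` (`NA` for FASTA input), plus attributes
#'   `format`, `n_dropped` and `stem` (input file stem used to name outputs).
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGTAA", "+", "IIIIIIIIII"), fq)
#' load_reads(fq, 5, 20)
load_reads <- function(path, min_length = 1L, max_length = 1000000L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read input file: ", path)
  }
  stopifnot(min_length > 0, min_length <= max_length)
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L) stop("input file is empty: ", path)
  lead <- substr(trimws(first), 1, 1)
  fmt <- if (lead == ">") "fasta" else if (lead == "@") "fastq" else
    stop("malformed record 1: input is neither FASTA ('>') nor FASTQ ('@')")
  x <- tryCatch(
    readBStringSet(path, format = fmt,
                   with.qualities = identical(fmt, "fastq")),
    error = function(e) {
      stop("parse error reading ", fmt, " input (",
           conditionMessage(e), ")", call. = FALSE)
    })
  if (length(x) == 0L) stop("no records found in ", path)
  seqs <- toupper(as.character(x))
  names(seqs) <- NULL
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("record ", i, " ('", names(x)[i],
         "') contains IUPAC ambiguity codes other than N; ",
         "only A/C/G/T/N are accepted")
  }
  quals <- if (identical(fmt, "fastq")) {
    as.character(mcols(x)$qualities)
  } else {
    rep(NA_character_, length(x))
  }
  if (identical(fmt, "fastq") && any(nchar(quals) != nchar(seqs))) {
    i <- which(nchar(quals) != nchar(seqs))[1]
    stop("malformed record ", i, ": quality and sequence lengths differ")
  }
  keep <- nchar(seqs) >= min_length & nchar(seqs) <= max_length
  if (!any(keep)) {
    stop("zero reads in window: no read has length within [",
         min_length, ", ", max_length, "]")
  }
  out <- data.frame(serial = seq_len(sum(keep)) - 1L,
                    name = names(x)[keep],
                    seq = seqs[keep],
                    qual = quals[keep],
                    stringsAsFactors = FALSE)
  attr(out, "format") <- fmt
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "stem") <- sub("\\.(fasta|fa|fna|fastq|fq)(\\.gz)?$", "",
                           basename(path), ignore.case = TRUE)
  class(out) <- c("amplicon_reads", "data.frame")
  out
}

# sequences of the given serials, flipped to the reference strand where the
# orientation flag says reverse-complemented
oriented_seqs <- function(reads, serials, orientation) {
  s <- reads$seq[match(serials, reads$serial)]
  if (any(orientation)) {
    s[orientation] <- reverse_complement(s[orientation])
  }
  s
}

str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

write_records <- function(path, names, seqs, quals = NULL, fmt = "fasta") {
  if (identical(fmt, "fastq")) {
    writeXStringSet(`names<-`(DNAStringSet(seqs), names), path,
                    format = "fastq", qualities = BStringSet(quals))
  } else {
    # unwrapped single-line sequences
    writeXStringSet(`names<-`(DNAStringSet(seqs), names), path,
                    format = "fasta", width = max(nchar(seqs), 1L))
  }
  path
}

#' Write species-group output files
#'
#' Writes one file per species group named `<stem>_<g>_<s>.<fmt>` (1-based
#' gene-group index `g`, species index `s`) holding the member reads
#' co-oriented with the group consensus; in FASTA mode the consensus record is
#' appended with the member count in its header. Also writes
#' `<stem>_consensussequences.fasta` with every consensus (member count in
#' brackets) and, per gene group with unassigned reads, a
#' `<stem>_<g>_unique.<fmt>` "unique sequences" file.
#'
#' @param result a pipeline result (list of gene groups, each with a `species`
#'   list and `unassigned` serials), as produced by [sort_amplicons()] (its
#'   `$groups` element) or assembled from [sort_gene_group()] output.
#' @param reads the `amplicon_reads` data frame the serials refer to.
#' @param outdir output directory (created if needed).
#' @param fmt `"fasta"` or `"fastq"`. FASTQ output requires FASTQ input;
#'   otherwise the writer falls back to FASTA with a warning. A consensus has
#'   no per-base qualities, so in FASTQ mode consensuses appear only in the
#'   FASTA summary file.
#' @return (invisibly) the paths written.
#' @export
write_species_outputs <- function(result, reads, outdir, fmt = c("fasta", "fastq")) {
  fmt <- match.arg(fmt)
  if (identical(fmt, "fastq") && !identical(attr(reads, "format"), "fastq")) {
    warning("fastq output requested for FASTA input; falling back to fasta ",
            "(consensus records carry no qualities)")
    fmt <- "fasta"
  }
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir)
  }
  stem <- attr(reads, "stem")
  if (is.null(stem)) stem <- "reads"
  paths <- character(0)
  cons_names <- character(0)
  cons_seqs <- character(0)
  for (gg in result) {
    g <- gg$group_id
    for (sp in gg$species) {
      s <- sp$species_id
      idx <- match(sp$members, reads$serial)
      if (anyNA(idx)) stop("species group member serial not found among loaded reads")
      seqs <- oriented_seqs(reads, sp$members, sp$orientation)
      nms <- reads$name[idx]
      p <- file.path(outdir, sprintf("%s_%d_%d.%s", stem, g, s, fmt))
      if (identical(fmt, "fastq")) {
        q <- reads$qual[idx]
        q[sp$orientation] <- str_rev(q[sp$orientation])
        write_records(p, nms, seqs, q, "fastq")
      } else {
        write_records(p, c(nms, sprintf("consensus_%d_%d(%d)", g, s,
                                        length(sp$members))),
                      c(seqs, sp$consensus), fmt = "fasta")
      }
      paths <- c(paths, p)
      cons_names <- c(cons_names, sprintf("%s_%d_%d(%d)", stem, g, s,
                                          length(sp$members)))
      cons_seqs <- c(cons_seqs, sp$consensus)
    }
    if (length(gg$unassigned) > 0) {
      idx <- match(gg$unassigned, reads$serial)
      p <- file.path(outdir, sprintf("%s_%d_unique.%s", stem, g, fmt))
      if (identical(fmt, "fastq")) {
        write_records(p, reads$name[idx], reads$seq[idx], reads$qual[idx],
                      "fastq")
      } else {
        write_records(p, reads$name[idx], reads$seq[idx], fmt = "fasta")
      }
      paths <- c(paths, p)
    }
  }
  if (length(cons_seqs) > 0) {
    p <- file.path(outdir, sprintf("%s_consensussequences.fasta", stem))
    write_records(p, cons_names, cons_seqs, fmt = "fasta")
    paths <- c(paths, p)
  }
  invisible(paths)
}
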