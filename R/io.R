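#' Read sequences from FASTA or FASTQ
#'
#' Format is sniffed from the first record character; gzip input is handled
#' transparently by R's file connections. Record order and identifiers are
#' preserved verbatim. FASTQ records are validated (4-line records, matching
#' sequence/quality lengths) and malformed records raise an error naming the
#' offending line.
#'
#' @param path Path to a FASTA or FASTQ file, plain or gzipped.
#' @return A data frame with columns `id`, `seq`, `qual` (`NA` for FASTA) and
#'   attribute `format` ("fasta" or "fastq").
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (length(lines) == 0) {
    out <- data.frame(id = character(0), seq = character(0), qual = character(0))
    attr(out, "format") <- "fasta"
    return(out)
  }
  first <- substr(lines[1], 1, 1)
  if (first == ">") {
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    if (any(grp == 0)) stop("malformed FASTA: line 1 is not a header")
    ids <- sub("^>", "", lines[hdr])
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) toupper(paste(x, collapse = "")), character(1))
    # headers with no sequence lines still count, as empty records
    seq_full <- character(length(ids))
    seq_full[as.integer(names(seqs))] <- seqs
    out <- data.frame(id = ids, seq = seq_full, qual = NA_character_,
                      stringsAsFactors = FALSE)
    attr(out, "format") <- "fasta"
    out
  } else if (first == "@") {
    n <- length(lines)
    if (n %% 4 != 0)
      stop(sprintf("malformed FASTQ: truncated record near line %d", n))
    i1 <- seq(1, n, by = 4)
    bad <- which(substr(lines[i1], 1, 1) != "@")
    if (length(bad))
      stop(sprintf("malformed FASTQ: expected '@' at line %d", i1[bad[1]]))
    bad <- which(substr(lines[i1 + 2], 1, 1) != "+")
    if (length(bad))
      stop(sprintf("malformed FASTQ: expected '+' at line %d", i1[bad[1]] + 2))
    seqs <- lines[i1 + 1]
    quals <- lines[i1 + 3]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop(sprintf("malformed FASTQ: sequence/quality length mismatch at line %d",
                   i1[bad[1]] + 3))
    out <- data.frame(id = sub("^@", "", lines[i1]), seq = toupper(seqs),
                      qual = quals, stringsAsFactors = FALSE)
    attr(out, "format") <- "fastq"
    out
  } else {
    stop("unrecognised sequence format: first line starts with neither '>' nor '@'")
  }
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param records Data frame with `id`, `seq` and (for FASTQ) `qual` columns.
#' @param path Output path.
#' @param format "fasta" or "fastq"; default taken from the records'
#'   `format` attribute.
#' @param width Line-wrap width for FASTA (fixed at 80 by convention).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = NULL, width = 80L) {
  if (is.null(format)) format <- attr(records, "format")
  if (is.null(format)) format <- if (all(is.na(records$qual))) "fasta" else "fastq"
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (i in seq_len(nrow(records))) {
      writeLines(paste0(">", records$id[i]), con)
      s <- records$seq[i]
      n <- nchar(s)
      if (n == 0) next
      writeLines(substring(s, seq(1, n, by = width),
                           pmin(seq(1, n, by = width) + width - 1L, n)), con)
    }
  } else {
    writeLines(rbind(paste0("@", records$id), records$seq, "+",
                     records$qual), con)
  }
  invisible(path)
}

#' Write corrected reads in the input's format and order
#'
#' The corrected sequence replaces the read sequence record by record;
#' unaligned reads are written unchanged. Qualities are passed through,
#' trimmed or padded with 'I' where an indel changed the corrected length.
#'
#' @param records The input records (from [read_sequences()]).
#' @param results Alignment results from [align_reads()], one row per record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corrected <- function(records, results, path) {
  if (nrow(records) != nrow(results))
    stop("records and results differ in cardinality")
  out <- records
  repl <- results$aligned
  out$seq[repl] <- results$corrected[repl]
  if (!all(is.na(out$qual))) {
    n_new <- nchar(out$seq)
    n_old <- nchar(records$seq)
    fix <- which(!is.na(out$qual) & n_new != n_old)
    for (i in fix) {
      q <- substr(out$qual[i], 1L, n_new[i])
      if (nchar(q) < n_new[i]) q <- paste0(q, strrep("I", n_new[i] - nchar(q)))
      out$qual[i] <- q
    }
  }
  write_sequences(out, path, format = attr(records, "format"))
}

#' Write a graph to GFA1
#'
#' Unitigs become S-lines (with an `ml` tag for multiplicity when annotated)
#' and arcs become L-lines with a k-1 overlap CIGAR; one L-line per
#' mirror-pair of arcs. The word length k is stored on the header as a `kl`
#' tag.
#'
#' @param graph A `dbg_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tkl:i:%d", graph$k), con)
  for (u in seq_along(graph$seq)) {
    tag <- if (!is.null(graph$mult)) sprintf("\tml:i:%d", graph$mult[u]) else ""
    writeLines(sprintf("S\t%d\t%s%s", u, graph$seq[u], tag), con)
  }
  if (nrow(graph$arcs) > 0) {
    a <- graph$arcs
    # emit one representative per mirror pair (a,b) ~ (-b,-a)
    keep <- (a[, 1] < -a[, 2]) | (a[, 1] == -a[, 2] & a[, 2] <= -a[, 1])
    a <- a[keep, , drop = FALSE]
    orient <- function(v) ifelse(v > 0, "+", "-")
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t%dM", abs(a[, 1]), orient(a[, 1]),
                       abs(a[, 2]), orient(a[, 2]), graph$k - 1L), con)
  }
  invisible(path)
}

#' Read a graph from GFA1 written by [write_gfa()]
#'
#' Rebuilds the adjacency structures and the k-mer index from the S- and
#' L-lines; mirror arcs are restored automatically.
#'
#' @param path Path to a GFA file.
#' @return A `dbg_graph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  typ <- substr(lines, 1, 1)
  hdr <- lines[typ == "H"][1]
  km <- regmatches(hdr, regexpr("kl:i:[0-9]+", hdr))
  if (length(km) == 0) stop("GFA header lacks the kl (word length) tag")
  k <- as.integer(sub("kl:i:", "", km))
  sl <- strsplit(lines[typ == "S"], "\t", fixed = TRUE)
  ids <- vapply(sl, `[[`, character(1), 2L)
  seqs <- vapply(sl, `[[`, character(1), 3L)
  ord <- order(as.integer(ids))
  seqs <- seqs[ord]
  mult <- rep(NA_integer_, length(seqs))
  has_ml <- vapply(sl, function(x) any(grepl("^ml:i:", x)), logical(1))[ord]
  if (all(has_ml)) {
    mult <- vapply(sl[ord], function(x)
      as.integer(sub("ml:i:", "", grep("^ml:i:", x, value = TRUE)[1])),
      integer(1))
  } else mult <- NULL

  ll <- strsplit(lines[typ == "L"], "\t", fixed = TRUE)
  arcs <- matrix(integer(0), ncol = 2)
  if (length(ll) > 0) {
    from <- vapply(ll, function(x)
      as.integer(x[2]) * ifelse(x[3] == "+", 1L, -1L), integer(1))
    to <- vapply(ll, function(x)
      as.integer(x[4]) * ifelse(x[5] == "+", 1L, -1L), integer(1))
    arcs <- unique(rbind(cbind(from, to), cbind(-to, -from)))
    arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]
  }
  colnames(arcs) <- c("from", "to")
  adj <- new.env(parent = emptyenv())
  if (nrow(arcs) > 0) {
    sp <- split(arcs[, 2], arcs[, 1])
    for (nm in names(sp)) assign(nm, sort(sp[[nm]]), envir = adj)
  }
  g <- structure(list(
    k = k, seq = seqs, rcseq = rc_cpp(seqs), len = nchar(seqs),
    arcs = arcs, mult = mult, adj = adj,
    kidx = NULL, cache = new.env(parent = emptyenv())
  ), class = "dbg_graph")
  index_kmers(g)
}
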