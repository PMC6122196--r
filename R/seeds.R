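#' Find exact k-mer seeds of a read in the graph
#'
#' Looks up every k-mer of the read in the graph's canonical k-mer index and
#' merges hits that are contiguous in both the read and the same oriented
#' unitig into maximal runs. Merged seeds never cross a unitig boundary;
#' carrying an alignment across arcs is the extension phase's job. Seeds are
#' sorted by decreasing length, ties broken by smaller read offset, then
#' smaller signed node id.
#'
#' @param read DNA string (length >= k for any seed to be found).
#' @param graph A `dbg_graph`.
#' @return A data frame with one row per merged seed: `read_start` (0-based
#'   offset in the read), `node` (signed id), `offset` (0-based offset in the
#'   oriented node sequence), `length`, `exact` (TRUE for k-mer chain seeds).
#'   Zero rows when no read k-mer occurs in the graph.
#' @export
find_seeds <- function(read, graph) {
  s <- find_seeds_core(read, graph)
  out <- data.frame(read_start = s$read_start, node = s$node,
                    offset = s$offset, length = s$length,
                    exact = rep(TRUE, length(s$node)))
  out
}

# Plain-vector workhorse behind find_seeds(): k-mer lookup and run merging
# happen in C++; only the ordering contract lives here.
find_seeds_core <- function(read, graph) {
  if (nchar(read) < graph$k) {
    return(list(read_start = integer(0), node = integer(0),
                offset = integer(0), length = integer(0)))
  }
  m <- seed_runs_cpp(graph$kidx, read, graph$len, graph$k)
  o <- order(-m[, 4L], m[, 1L], m[, 2L])
  list(read_start = m[o, 1L], node = m[o, 2L], offset = m[o, 3L],
       length = m[o, 4L])
}

# Lazily built hash index of all min_mem-mers of the stored unitig sequences,
# cached on the graph. Values are lists of c(node, offset) integer pairs.
mem_index <- function(graph, min_mem) {
  key <- paste0("mem", min_mem)
  cached <- get0(key, envir = graph$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  env <- new.env(parent = emptyenv())
  for (u in seq_along(graph$seq)) {
    n <- graph$len[u]
    if (n < min_mem) next
    mers <- substring(graph$seq[u], 1:(n - min_mem + 1L), min_mem:n)
    for (i in seq_along(mers)) {
      cur <- get0(mers[i], envir = env, inherits = FALSE)
      entry <- c(u, i - 1L)
      assign(mers[i], c(cur, list(entry)), envir = env)
    }
  }
  assign(key, env, envir = graph$cache)
  env
}

# extend an exact match maximally in both directions within one unitig
extend_match <- function(rseq, useq, r0, u0, len) {
  while (r0 > 1L && u0 > 1L &&
         substr(rseq, r0 - 1L, r0 - 1L) == substr(useq, u0 - 1L, u0 - 1L)) {
    r0 <- r0 - 1L; u0 <- u0 - 1L; len <- len + 1L
  }
  nr <- nchar(rseq); nu <- nchar(useq)
  while (r0 + len <= nr && u0 + len <= nu &&
         substr(rseq, r0 + len, r0 + len) == substr(useq, u0 + len, u0 + len)) {
    len <- len + 1L
  }
  c(r0, u0, len)
}

#' Find maximal exact matches between a read and the unitigs
#'
#' Fallback seeding for reads that share no k-mer with the graph: returns all
#' maximal exact matches (MEMs) of length at least `min_mem` between the read
#' and any unitig on either strand. A MEM is maximal in both the read and the
#' unitig: it cannot be extended by one base on either side. Sorted by
#' decreasing length, ties by read offset then signed node id.
#'
#' @param read DNA string.
#' @param graph A `dbg_graph`.
#' @param min_mem Minimum MEM length to report (default 15).
#' @return A data frame in the same layout as [find_seeds()], with
#'   `exact = FALSE`.
#' @export
find_mems <- function(read, graph, min_mem = 15L) {
  min_mem <- as.integer(min_mem)
  env <- mem_index(graph, min_mem)
  L <- nchar(read)
  out <- list()
  if (L >= min_mem) {
    for (strand in c(1L, -1L)) {
      r <- if (strand > 0L) read else rc_cpp(read)
      mers <- substring(r, 1:(L - min_mem + 1L), min_mem:L)
      hits <- mget(mers, envir = env, ifnotfound = list(NULL))
      seen <- character(0)
      for (i in which(!vapply(hits, is.null, logical(1)))) {
        for (h in hits[[i]]) {
          u <- h[1L]
          ext <- extend_match(r, graph$seq[u], i, h[2L] + 1L, min_mem)
          id <- paste(strand, u, ext[1L], ext[2L], ext[3L])
          if (id %in% seen) next
          seen <- c(seen, id)
          len <- ext[3L]
          if (strand > 0L) {
            out[[length(out) + 1L]] <- c(ext[1L] - 1L, u, ext[2L] - 1L, len)
          } else {
            # match of rc(read)[a, a+len) at node u offset o corresponds to
            # read[L - a - len + 1, ...) matching -u at oriented offset
            # len(u) - o - len
            a <- ext[1L] - 1L; o <- ext[2L] - 1L
            out[[length(out) + 1L]] <-
              c(L - a - len, -u, graph$len[u] - o - len, len)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(read_start = integer(0), node = integer(0),
                      offset = integer(0), length = integer(0),
                      exact = logical(0)))
  }
  m <- do.call(rbind, out)
  res <- data.frame(read_start = m[, 1L], node = m[, 2L], offset = m[, 3L],
                    length = m[, 4L], exact = FALSE)
  res <- unique(res)
  res <- res[res$length >= min_mem, , drop = FALSE]
  res[order(-res$length, res$read_start, res$node), , drop = FALSE]
}
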