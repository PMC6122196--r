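# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ kernels and search code: the DP is a different
# (vectorised scan) formulation, the best-chain oracle is a plain recursive
# enumeration, and MEM finding is a quadratic diagonal scan.

oracle_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# One DP row update: row[n] = best global score of path-prefix vs s[1:n],
# after appending character `ch` to the path. Linear gaps allow the
# left-moves to be folded into a running max: with w = u - g*col,
# row = cummax(w) + g*col.
oracle_step_row <- function(row, ch, s_chars, m, x, g) {
  L <- length(s_chars)
  if (L == 0) return(row + g)
  diag <- row[1:L] + ifelse(s_chars == ch, m, x)
  up <- row[2:(L + 1)] + g
  t <- pmax(diag, up)
  u <- c(row[1] + g, t)
  cols <- 0:L
  cummax(u - g * cols) + g * cols
}

oracle_rows <- function(path, s, m = 1, x = -1, g = -3) {
  s_chars <- strsplit(s, "")[[1]]
  L <- length(s_chars)
  row <- g * (0:L)
  rows <- list(row)
  for (ch in strsplit(path, "")[[1]]) {
    row <- oracle_step_row(row, ch, s_chars, m, x, g)
    rows[[length(rows) + 1]] <- row
  }
  rows
}

# max over prefix lengths n of NW(path, s[1:n]), with the largest argmax
oracle_prefix_score <- function(path, s, m = 1, x = -1, g = -3) {
  rows <- oracle_rows(path, s, m, x, g)
  fin <- rows[[length(rows)]]
  list(score = max(fin), prefix_end = max(which(fin == max(fin))) - 1L)
}

# Exhaustive enumeration of the extension search universe: all chains from v
# whose spelled sequence (past `from`) stays below length |s| + slack, scored
# by the best complete-alignment cell max_p D[p][|s|] (including the
# align-nothing cell D[0][|s|]). Uses only the graph's data fields.
oracle_best_extension <- function(graph, v, s, m = 1, x = -1, g = -3,
                                  from = 0L, slack = 8L) {
  L <- nchar(s)
  if (L == 0) return(0L)
  s_chars <- strsplit(s, "")[[1]]
  k <- graph$k
  oseq <- function(v) if (v > 0) graph$seq[v] else graph$rcseq[-v]
  succs <- function(v) sort(graph$arcs[graph$arcs[, 1] == v, 2])
  best <- g * L
  feed <- function(row, chunk) {
    for (ch in strsplit(chunk, "")[[1]]) {
      row <- oracle_step_row(row, ch, s_chars, m, x, g)
      best <<- max(best, row[L + 1])
    }
    row
  }
  rec <- function(v, row, plen) {
    if (plen >= L + slack) return()
    for (w in succs(v)) {
      chunk <- substring(oseq(w), k)
      room <- L + slack - plen      # same horizon truncation as the search
      if (nchar(chunk) > room) chunk <- substr(chunk, 1, room)
      row2 <- feed(row, chunk)   # eager: feed() records complete alignments
      rec(w, row2, plen + nchar(chunk))
    }
  }
  root_tail <- substring(oseq(v), from + 1L)
  if (nchar(root_tail) > L + slack) root_tail <- substr(root_tail, 1, L + slack)
  row <- feed(g * (0:L), root_tail)
  rec(v, row, nchar(root_tail))
  best
}

# All maximal exact matches of length >= min_len between `read` and any
# unitig on either strand, by quadratic diagonal scanning.
oracle_mems <- function(read, graph, min_len) {
  out <- list()
  rch <- strsplit(read, "")[[1]]
  L <- length(rch)
  for (u in seq_along(graph$seq)) {
    for (strand in c(1L, -1L)) {
      useq <- if (strand > 0) graph$seq[u] else graph$rcseq[u]
      uch <- strsplit(useq, "")[[1]]
      U <- length(uch)
      for (d in (-(U - 1)):(L - 1)) {
        # diagonal: read position = unitig position + d
        lo <- max(1L, 1L + d); hi <- min(L, U + d)
        if (hi - lo + 1L < min_len) next
        eq <- rch[lo:hi] == uch[(lo - d):(hi - d)]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (i in which(r$values & r$lengths >= min_len)) {
          rs <- lo + starts[i] - 1L
          # scanning the oriented sequence directly, so the offset is already
          # in the oriented-node convention used by find_mems
          out[[length(out) + 1L]] <- data.frame(
            read_start = rs - 1L, node = strand * u,
            offset = rs - d - 1L, length = r$lengths[i])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(read_start = integer(0), node = integer(0),
                      offset = integer(0), length = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res[order(-res$length, res$read_start, res$node), , drop = FALSE]
}

# Random small test instance: a genome with a planted short repeat, its
# graph, and an anchored extension problem (node, from-offset, remainder)
# with one of four error patterns applied to the remainder.
rand_instance <- function(seed, pattern = c("none", "sub", "indel", "mixed"),
                          k = 11L) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  bg <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  rep_seq <- bg(k + sample(3:8, 1))
  genome <- paste0(bg(60), rep_seq, bg(40), rep_seq, bg(40),
                   if (runif(1) < 0.5) paste0(rep_seq, bg(30)) else bg(30))
  graph <- build_graph(genome, k = k, multiplicities = FALSE)
  if (length(graph$seq) > 30) return(NULL)
  # anchor: a genome k-mer, remainder follows it
  G <- nchar(genome)
  slen <- sample(15:60, 1)
  p <- sample(seq_len(G - k - slen), 1)
  hit <- lookup_kmer(graph, substr(genome, p, p + k - 1))
  s <- substr(genome, p + k, p + k + slen - 1)
  mutate <- function(s, n_sub = 0, n_indel = 0) {
    ch <- strsplit(s, "")[[1]]
    for (i in sample(seq_along(ch), min(n_sub, length(ch)))) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1)
    }
    for (j in seq_len(n_indel)) {
      p2 <- sample(seq_along(ch), 1)
      ch <- if (runif(1) < 0.5) ch[-p2] else append(ch, sample(bases, 1), p2)
    }
    paste(ch, collapse = "")
  }
  s <- switch(pattern,
              none = s,
              sub = mutate(s, n_sub = sample(1:3, 1)),
              indel = mutate(s, n_indel = sample(1:2, 1)),
              mixed = mutate(s, n_sub = sample(1:2, 1), n_indel = 1))
  list(graph = graph, v = hit$node, from = hit$offset + k, s = s,
       genome = genome)
}
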