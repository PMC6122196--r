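#' Alignment scoring scheme
#'
#' Linear-gap Needleman-Wunsch scores. Defaults are match +1, mismatch -1,
#' gap -3.
#'
#' @param match Positive match score.
#' @param mismatch Mismatch score, less than `match`.
#' @param gap Negative linear gap score per base.
#' @return A list of class `dbg_scoring`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap = -3L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  stopifnot(match > 0L, mismatch < match, gap < 0L)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "dbg_scoring")
}

#' Best alignment of a path sequence against read prefixes
#'
#' Computes the global alignment score of `path_seq` against every prefix of
#' `s` and returns the maximum over prefix lengths n, together with the
#' largest maximizing n. This is the score a partial graph path contributes
#' while the rest of the read is still unconsumed: for an identical pair the
#' score is match * length, since a read aligned to itself scores m*l.
#'
#' @param path_seq Spelled sequence of a (partial) graph walk.
#' @param s The read (or its unaligned remainder).
#' @param scheme A [scoring_scheme()].
#' @return List with `score` and `prefix_end` (read bases consumed at the
#'   best cell). `("", s)` gives score 0 at prefix 0.
#' @export
nw_prefix_score <- function(path_seq, s, scheme = scoring_scheme()) {
  L <- nchar(s)
  row <- dp_init_row(L, scheme$gap)
  if (nchar(path_seq) == 0) {
    return(list(score = 0L, prefix_end = 0L))
  }
  res <- dp_extend_row(row, path_seq, s, scheme$match, scheme$mismatch, scheme$gap)
  list(score = res$prio, prefix_end = res$prefix_end)
}

#' Upper bound on the completed score of a partial alignment
#'
#' Given the score of a path aligned to the first n bases of an l-base read,
#' the best any completed extension can do is gain a match on every remaining
#' base: currentScore + m * (l - n). Branch-and-bound search discards a
#' partial path when no prefix cell of its DP row can beat the incumbent
#' complete alignment under this bound.
#'
#' @param current_score Alignment score of the path against `s[1:n]`.
#' @param n Read bases consumed.
#' @param l Read length.
#' @param m Match score.
#' @return The bound, an integer.
#' @export
upper_bound <- function(current_score, n, l, m) {
  stopifnot(n >= 0, n <= l)
  as.integer(current_score + m * (l - n))
}

# Maximum extra spelled path length beyond the read remainder before a chain
# stops being extended. Each surplus path base past the read end costs at
# least one gap, so an optimum using more than this many surplus bases would
# have to beat alternatives by an implausible margin; the same cap defines
# the search universe for both the pruned and the unpruned search (and for
# the enumeration oracle in the tests).
EXTENSION_SLACK <- 8L

#' Branch-and-bound extension of a seed through the graph
#'
#' Best-first search over walks starting at node `v`: a priority queue holds
#' partial chains keyed by their best prefix-alignment score against the
#' unaligned read remainder `s`; the highest-priority chain is popped,
#' extended along every arc (optionally only along transitions the Markov
#' model allows), and a subtree is discarded when an admissible upper bound on
#' its completed score cannot beat the best complete alignment found so far.
#' With pruning enabled the result is still the exact optimum: pruning uses
#' only the bound. A complete alignment is the best DP cell in which the whole
#' remainder has been consumed by some prefix of the spelled chain; the chain
#' is trimmed to the node containing that cell.
#'
#' @param graph A `dbg_graph`.
#' @param v Signed id of the seed's final node.
#' @param s Unaligned remainder of the read past the seed.
#' @param scheme A [scoring_scheme()].
#' @param mm A trained Markov model, or `NULL` for an unrestricted search.
#' @param history Signed node ids preceding `v` in the walk so far (used only
#'   for Markov-model context).
#' @param from 0-based offset in the oriented sequence of `v` at which the
#'   remainder starts; the tail of `v` past `from` is part of the spelled
#'   path. Default 0 spells all of `v`.
#' @param use_bound Disable to obtain the exhaustive (unpruned) search; the
#'   score is identical, only the number of visited states changes.
#' @param budget Maximum number of queue pops before the search stops and
#'   returns its best-so-far (flagged `exhausted`).
#' @return List with `chain` (trimmed walk from `v`), `score`, `corrected`
#'   (spelled sequence of the aligned span), `visited` (states expanded) and
#'   `exhausted`. For empty `s`, `chain = v` and score 0.
#' @export
branch_and_bound_extend <- function(graph, v, s, scheme = scoring_scheme(),
                                    mm = NULL, history = integer(0), from = 0L,
                                    use_bound = TRUE, budget = Inf) {
  l <- nchar(s)
  if (l == 0L) {
    return(list(chain = as.integer(v), score = 0L, corrected = "",
                visited = 0L, exhausted = FALSE))
  }
  m <- scheme$match
  k <- graph$k
  max_path <- l + EXTENSION_SLACK
  row0 <- dp_init_row(l, scheme$gap)

  # incumbent: "align nothing" is always available (whole remainder gapped)
  best_score <- row0[l + 1L]
  best_chain <- as.integer(v)
  best_spelled <- ""
  best_pos <- 0L

  # Only the first l + slack spelled bases of any chain can hold the optimum
  # under the search horizon, so node tails are truncated to the remaining
  # room; a truncated node ends its chain exactly at the horizon.
  root_tail <- substring(node_seq(graph, v), from + 1L)
  if (nchar(root_tail) > max_path) root_tail <- substr(root_tail, 1L, max_path)
  mk_state <- function(chain, spelled, res) {
    list(chain = chain, spelled = spelled, row = res$row, prio = res$prio,
         pe = res$prefix_end, bound = res$bound, plen = nchar(spelled))
  }
  consider_solution <- function(res, chain, spelled, plen_before) {
    if (res$best_col > best_score) {
      best_score <<- res$best_col
      best_chain <<- chain
      best_spelled <<- spelled
      best_pos <<- plen_before + res$best_col_row
    }
  }

  res0 <- dp_extend_row(row0, root_tail, s, scheme$match, scheme$mismatch, scheme$gap)
  consider_solution(res0, as.integer(v), root_tail, 0L)
  queue <- list(mk_state(as.integer(v), root_tail, res0))
  visited <- 0L
  exhausted <- FALSE

  while (length(queue) > 0L) {
    # pop: highest priority, then longer prefix_end, then lexicographically
    # smaller chain
    prio <- vapply(queue, `[[`, integer(1), "prio")
    top <- which(prio == max(prio))
    if (length(top) > 1L) {
      pe <- vapply(queue[top], `[[`, integer(1), "pe")
      top <- top[pe == max(pe)]
      if (length(top) > 1L) {
        keys <- vapply(queue[top], function(st) paste(st$chain, collapse = ","),
                       character(1))
        top <- top[order(keys)]
      }
    }
    i <- top[1L]
    st <- queue[[i]]
    queue[[i]] <- NULL

    if (visited >= budget) { exhausted <- TRUE; break }
    visited <- visited + 1L
    if (use_bound && st$bound < best_score) next
    if (st$plen >= max_path) next

    succs <- arcs_from(graph, st$chain[length(st$chain)])
    for (w in succs) {
      if (!is.null(mm) &&
          !is_transition_valid(mm, c(history, st$chain), w)) next
      chunk <- substring(node_seq(graph, w), k)
      room <- max_path - st$plen
      if (nchar(chunk) > room) chunk <- substr(chunk, 1L, room)
      res <- dp_extend_row(st$row, chunk, s, scheme$match, scheme$mismatch,
                           scheme$gap)
      chain2 <- c(st$chain, w)
      spelled2 <- paste0(st$spelled, chunk)
      consider_solution(res, chain2, spelled2, st$plen)
      if (use_bound && res$bound < best_score) next
      queue[[length(queue) + 1L]] <- mk_state(chain2, spelled2, res)
    }
  }

  list(chain = best_chain, score = as.integer(best_score),
       corrected = substr(best_spelled, 1L, best_pos),
       visited = visited, exhausted = exhausted)
}

#' Align one read to the graph
#'
#' Seed-and-extend alignment: exact k-mer seeds (merged runs) are tried
#' longest-first, with a maximal-exact-match fallback when the read shares no
#' k-mer with the graph. For each seed the read remainder to the right of the
#' seed is extended with [branch_and_bound_extend()]; the left remainder is
#' extended by the same search on the reverse-complement strand from the
#' mirrored seed node, so one code path serves both directions. Reverse-strand
#' reads are handled by the canonical k-mer index: their seeds carry negative
#' node ids and the whole search runs on the mirrored strand, which is
#' exactly the alignment of the reverse-complemented read.
#'
#' The reported score and identity are recomputed from the corrected sequence
#' against the read by a full global alignment, so `score` always equals the
#' Needleman-Wunsch similarity of `corrected` vs the read.
#'
#' @param graph A `dbg_graph`.
#' @param read DNA string.
#' @param scheme A [scoring_scheme()].
#' @param mm Optional trained Markov model guiding the extension.
#' @param config An [aligner_config()].
#' @param use_bound Disable to run the unpruned search (identical scores).
#' @return A list of class `dbg_alignment`: `chain`, `score`, `identity`,
#'   `corrected` (the read itself when unaligned), `aligned`, `n_nodes`,
#'   `visited`, `exhausted`.
#' @export
align_read <- function(graph, read, scheme = scoring_scheme(), mm = NULL,
                       config = aligner_config(), use_bound = TRUE) {
  read <- toupper(read)
  l <- nchar(read)
  if (l == 0L) stop("empty read")
  m <- scheme$match

  seeds <- find_seeds_core(read, graph)
  if (length(seeds$node) == 0L) {
    mems <- find_mems(read, graph, config$min_mem_length)
    seeds <- list(read_start = mems$read_start, node = mems$node,
                  offset = mems$offset, length = mems$length)
  }
  unaligned <- list(chain = integer(0), score = NA_integer_,
                    identity = NA_real_, corrected = read, aligned = FALSE,
                    n_nodes = 0L, visited = 0L, exhausted = FALSE)
  n_seeds <- length(seeds$node)
  if (n_seeds == 0L) return(structure(unaligned, class = "dbg_alignment"))

  best <- NULL
  budget_left <- config$node_visit_budget
  exhausted_any <- FALSE
  stop_score <- m * l - config$seed_stop_slack

  for (si in seq_len(min(n_seeds, config$seed_retry_cap))) {
    v <- seeds$node[si]; a <- seeds$read_start[si]
    len <- seeds$length[si]; off <- seeds$offset[si]
    # fast path: the seed covers the whole read exactly
    if (len == l) {
      best <- list(chain = as.integer(v), corrected = read,
                   score = m * l, visited = 0L)
      break
    }
    s_right <- substring(read, a + len + 1L)
    ext_r <- branch_and_bound_extend(graph, v, s_right, scheme, mm,
                                     history = integer(0), from = off + len,
                                     use_bound = use_bound,
                                     budget = budget_left)
    budget_left <- budget_left - ext_r$visited
    s_left <- if (a > 0L) rc_cpp(substr(read, 1L, a)) else ""
    hist_l <- rev(-ext_r$chain[-1L])
    ext_l <- branch_and_bound_extend(graph, -v, s_left, scheme, mm,
                                     history = hist_l,
                                     from = graph$len[abs(v)] - off,
                                     use_bound = use_bound,
                                     budget = budget_left)
    budget_left <- budget_left - ext_l$visited
    exhausted_any <- exhausted_any || ext_r$exhausted || ext_l$exhausted

    chain <- c(rev(-ext_l$chain), ext_r$chain[-1L])
    seed_seq <- substr(node_seq(graph, v), off + 1L, off + len)
    corrected <- paste0(rc_cpp(ext_l$corrected), seed_seq, ext_r$corrected)
    cand <- list(chain = chain, corrected = corrected,
                 score = ext_l$score + m * len + ext_r$score,
                 visited = ext_r$visited + ext_l$visited)
    if (is.null(best) || cand$score > best$score) best <- cand
    if (best$score >= stop_score || budget_left <= 0L) break
  }

  stats <- if (best$corrected == read) {
    list(score = m * l, matches = l, columns = l)
  } else {
    nw_stats_cpp(best$corrected, read, scheme$match, scheme$mismatch,
                 scheme$gap)
  }
  identity <- if (stats$columns > 0) stats$matches / stats$columns else 0
  aligned <- identity >= config$min_identity
  structure(list(
    chain = if (aligned) best$chain else integer(0),
    score = as.integer(stats$score),
    identity = identity,
    corrected = if (aligned) best$corrected else read,
    aligned = aligned,
    n_nodes = if (aligned) length(best$chain) else 0L,
    visited = config$node_visit_budget - budget_left,
    exhausted = exhausted_any
  ), class = "dbg_alignment")
}

#' Align a batch of reads
#'
#' @param graph A `dbg_graph`.
#' @param reads Character vector of reads, or a data frame with a `seq`
#'   column (as returned by [read_sequences()] or [simulate_reads()]).
#' @inheritParams align_read
#' @return A data frame with one row per read, in input order: `id`, `aligned`,
#'   `score`, `identity`, `n_nodes`, `visited`, `exhausted`, `corrected`,
#'   `chain` (comma-separated signed node ids).
#' @export
align_reads <- function(graph, reads, scheme = scoring_scheme(), mm = NULL,
                        config = aligner_config(), use_bound = TRUE) {
  if (is.data.frame(reads)) {
    ids <- if (!is.null(reads$id)) reads$id else as.character(seq_len(nrow(reads)))
    seqs <- reads$seq
  } else {
    ids <- if (!is.null(names(reads))) names(reads) else as.character(seq_along(reads))
    seqs <- as.character(reads)
  }
  n <- length(seqs)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- align_read(graph, seqs[i], scheme, mm, config, use_bound)
  }
  data.frame(
    id = ids,
    aligned = vapply(res, `[[`, logical(1), "aligned"),
    score = vapply(res, `[[`, integer(1), "score"),
    identity = vapply(res, `[[`, numeric(1), "identity"),
    n_nodes = vapply(res, `[[`, integer(1), "n_nodes"),
    visited = vapply(res, `[[`, integer(1), "visited"),
    exhausted = vapply(res, `[[`, logical(1), "exhausted"),
    corrected = vapply(res, `[[`, character(1), "corrected"),
    chain = vapply(res, function(r) paste(r$chain, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}
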