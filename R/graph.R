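#' Reverse complement of DNA strings
#'
#' Thin wrapper around the package's C++ reverse-complement kernel, used in
#' hot loops where per-call [Biostrings::reverseComplement()] overhead would
#' dominate.
#'
#' @param x Character vector of DNA strings (A/C/G/T; other letters map to N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  rc_cpp(as.character(x))
}

#' Canonical form of k-mers
#'
#' The canonical representative of a k-mer is the lexicographic minimum of the
#' k-mer and its reverse complement. Only odd k is supported throughout the
#' package, so a k-mer is never its own reverse complement and the strand of
#' the canonical form is always well defined.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @keywords internal
canonical_kmer <- function(x) {
  pmin(x, rc_cpp(x))
}

# Split sequences into A/C/G/T-only fragments (non-ACGT characters such as N
# runs split the input rather than erroring) and drop fragments shorter than k.
split_fragments <- function(reference, k) {
  reference <- toupper(as.character(reference))
  frags <- unlist(strsplit(reference, "[^ACGT]+"))
  frags <- frags[!is.na(frags) & nchar(frags) >= k]
  frags
}

#' Build a unitig-compacted de Bruijn graph from a reference
#'
#' Constructs the bidirected de Bruijn graph of the reference at word length
#' `k`: nodes are maximal non-branching runs of k-mers (unitigs), arcs carry a
#' k-1 base overlap, and each canonical k-mer occurs in exactly one unitig at
#' one offset. One unitig sequence is stored per canonical orientation
#' (lexicographic minimum of the sequence and its reverse complement); signed
#' node identifiers select the orientation, so reverse-complement reads are
#' first-class. Arcs are those k-mer adjacencies actually observed in the
#' reference (on either strand), which makes the graph complete and error-free
#' with respect to the reference: every reference substring of length >= k
#' spells a walk.
#'
#' @param reference Character vector of one or more DNA sequences. Characters
#'   outside A/C/G/T split a sequence into independent fragments.
#' @param k Odd integer word length >= 3 (odd k avoids palindromic k-mers).
#' @param multiplicities If `TRUE` (default), annotate each unitig with the
#'   number of times its sequence occurs in the reference (either strand).
#'   Diagnostic only; the aligner does not consume it.
#' @return An object of class `dbg_graph` with elements `k`, `seq` (stored
#'   unitig sequences), `len`, `arcs` (two-column signed integer matrix),
#'   `mult`, plus internal adjacency and k-mer index structures.
#' @examples
#' g <- build_graph("AAGCTTCCGGA", k = 5)
#' g$seq
#' @export
build_graph <- function(reference, k = 31L, multiplicities = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L)
    stop("k must be an odd integer >= 3")
  if (length(reference) == 0 || all(!nzchar(reference)))
    stop("empty reference")
  frags <- split_fragments(reference, k)
  if (length(frags) == 0)
    stop("reference contains no A/C/G/T fragment of length >= k")

  ## --- k-mer layer -------------------------------------------------------
  km_by_frag <- lapply(frags, function(f) {
    n <- nchar(f)
    substring(f, 1:(n - k + 1L), k:n)
  })
  all_km <- unlist(km_by_frag, use.names = FALSE)
  rck <- rc_cpp(all_km)
  canon <- pmin(all_km, rck)
  ucanon <- sort(unique(canon))
  N <- length(ucanon)
  idx <- match(canon, ucanon)
  orient <- ifelse(all_km == canon, 1L, -1L)
  # oriented id in 1..2N: forward = idx, reverse = idx + N
  o_id <- ifelse(orient > 0L, idx, idx + N)

  # consecutive k-mer edges within fragments, closed under strand mirroring
  lens <- vapply(km_by_frag, length, integer(1))
  ends <- cumsum(lens)
  keep <- rep(TRUE, length(o_id))
  keep[ends] <- FALSE
  mirror <- function(o) ifelse(o > N, o - N, o + N)
  e_from <- o_id[keep]
  e_to <- o_id[which(keep) + 1L]
  ef <- c(e_from, mirror(e_to))
  et <- c(e_to, mirror(e_from))
  dup <- duplicated(as.numeric(ef) * (2 * N + 1) + et)
  ef <- ef[!dup]; et <- et[!dup]

  outdeg <- tabulate(ef, nbins = 2L * N)
  indeg <- outdeg[mirror(seq_len(2L * N))]
  succ <- rep(NA_integer_, 2L * N)
  single <- which(outdeg == 1L)
  succ[ef[ef %in% single]] <- et[ef %in% single]

  ## --- unitig compaction -------------------------------------------------
  # x starts a unitig unless it has exactly one predecessor whose only
  # successor is x (then the two merge).
  pred <- rep(NA_integer_, 2L * N)
  has_pred <- indeg == 1L
  pred[has_pred] <- mirror(succ[mirror(which(has_pred))])
  is_start <- rep(TRUE, 2L * N)
  mergeable <- which(has_pred & !is.na(pred))
  is_start[mergeable] <- outdeg[pred[mergeable]] != 1L
  # a node whose only predecessor is its own mirror sits at a hairpin fold
  # and must open its own unitig
  fold <- mergeable[pred[mergeable] == mirror(mergeable)]
  is_start[fold] <- TRUE

  okm <- c(ucanon, rc_cpp(ucanon))  # oriented k-mer strings

  visited <- logical(2L * N)
  paths <- vector("list", N)
  n_paths <- 0L
  buf <- integer(N)
  walk_from <- function(x0) {
    m <- 1L
    buf[1L] <<- x0
    visited[x0] <<- TRUE
    cur <- x0
    repeat {
      if (outdeg[cur] != 1L) break
      nxt <- succ[cur]
      # the mirror check stops hairpin folds (a walk entering the reverse
      # complement of a k-mer already in this unitig would double-cover it)
      if (indeg[nxt] != 1L || visited[nxt] || is_start[nxt] ||
          visited[mirror(nxt)]) break
      m <- m + 1L
      buf[m] <<- nxt
      visited[nxt] <<- TRUE
      cur <- nxt
    }
    p <- buf[seq_len(m)]
    visited[mirror(p)] <<- TRUE
    p
  }
  for (x in which(is_start)) {
    if (visited[x]) next
    n_paths <- n_paths + 1L
    paths[[n_paths]] <- walk_from(x)
  }
  # isolated perfect cycles (every member mergeable): start anywhere
  for (x in seq_len(2L * N)) {
    if (visited[x]) next
    n_paths <- n_paths + 1L
    paths[[n_paths]] <- walk_from(x)
  }
  paths <- paths[seq_len(n_paths)]

  spell_kmer_path <- function(p) {
    if (length(p) == 1L) return(okm[p])
    paste0(okm[p[1L]], paste(substr(okm[p[-1L]], k, k), collapse = ""))
  }
  useq_raw <- vapply(paths, spell_kmer_path, character(1))
  useq_rc <- rc_cpp(useq_raw)
  useq <- pmin(useq_raw, useq_rc)         # canonical stored orientation
  ord <- order(useq)                      # deterministic node ids
  useq <- useq[ord]
  M <- length(useq)
  ulen <- nchar(useq)

  ## --- k-mer index -------------------------------------------------------
  node_of <- integer(N); off_of <- integer(N); strand_of <- integer(N)
  for (u in seq_len(M)) {
    s <- useq[u]
    n <- ulen[u]
    kms <- substring(s, 1:(n - k + 1L), k:n)
    cn <- pmin(kms, rc_cpp(kms))
    ci <- match(cn, ucanon)
    if (anyNA(ci) || anyDuplicated(ci) || any(node_of[ci] != 0L))
      stop("internal error: inconsistent unitig k-mer index")
    node_of[ci] <- u
    off_of[ci] <- seq_along(ci) - 1L
    strand_of[ci] <- ifelse(kms == cn, 1L, -1L)
  }
  if (any(node_of == 0L))
    stop("internal error: k-mer missing from unitig index")

  ## --- arcs between unitigs ---------------------------------------------
  # map oriented k-mer id -> (signed unitig, oriented offset)
  o_to_signed <- function(o) {
    ci <- ifelse(o > N, o - N, o)
    sa <- ifelse(o > N, -1L, 1L)
    ta <- sa * strand_of[ci]
    ta * node_of[ci]
  }
  o_to_ooff <- function(o) {
    ci <- ifelse(o > N, o - N, o)
    sa <- ifelse(o > N, -1L, 1L)
    ta <- sa * strand_of[ci]
    ifelse(ta > 0L, off_of[ci], ulen[node_of[ci]] - k - off_of[ci])
  }
  ua <- o_to_signed(ef); oa <- o_to_ooff(ef)
  vb <- o_to_signed(et); ob <- o_to_ooff(et)
  la <- ulen[abs(ua)]
  sel <- (oa == la - k) & (ob == 0L)
  arcs <- cbind(from = ua[sel], to = vb[sel])
  arcs <- arcs[!duplicated(as.numeric(arcs[, 1]) * (2 * M + 1) + arcs[, 2]), , drop = FALSE]
  arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]

  adj <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(arcs)))
  if (nrow(arcs) > 0) {
    sp <- split(arcs[, 2], arcs[, 1])
    for (nm in names(sp)) assign(nm, sort(sp[[nm]]), envir = adj)
  }

  kidx <- build_kindex_cpp(useq, k)

  g <- structure(list(
    k = k,
    seq = useq,
    rcseq = rc_cpp(useq),
    len = ulen,
    arcs = arcs,
    mult = NULL,
    adj = adj,
    kidx = kidx,
    cache = new.env(parent = emptyenv())
  ), class = "dbg_graph")

  if (isTRUE(multiplicities)) g$mult <- unitig_multiplicities(g, frags)
  g
}

# Occurrence count of each stored unitig sequence in the reference fragments,
# counting both orientations (a palindromic sequence is counted once).
unitig_multiplicities <- function(graph, frags) {
  subject <- Biostrings::DNAStringSet(frags)
  count_all <- function(pat) sum(Biostrings::vcountPattern(pat, subject))
  n_f <- vapply(graph$seq, count_all, integer(1), USE.NAMES = FALSE)
  n_r <- vapply(graph$rcseq, count_all, integer(1), USE.NAMES = FALSE)
  as.integer(ifelse(graph$seq == graph$rcseq, n_f, n_f + n_r))
}

#' @export
print.dbg_graph <- function(x, ...) {
  cat(sprintf("de Bruijn graph (k = %d): %d unitigs, %d arcs, total length %d\n",
              x$k, length(x$seq), nrow(x$arcs), sum(x$len)))
  invisible(x)
}

#' Oriented sequence of a signed node
#'
#' @param graph A `dbg_graph`.
#' @param v Signed node id: positive for the stored orientation, negative for
#'   its reverse complement.
#' @return The oriented unitig sequence.
#' @export
node_seq <- function(graph, v) {
  if (v > 0) graph$seq[v] else graph$rcseq[-v]
}

# successors of a signed node (sorted); integer(0) if none
arcs_from <- function(graph, v) {
  res <- get0(as.character(v), envir = graph$adj, inherits = FALSE)
  if (is.null(res)) integer(0) else res
}

has_arc <- function(graph, from, to) {
  to %in% arcs_from(graph, from)
}

#' Rebuild the k-mer index of a graph
#'
#' Indexes every k-mer occurring in any unitig under its canonical form, so
#' that a lookup resolves to (node, offset, orientation) on either strand.
#' [build_graph()] indexes automatically; this is exposed for graphs loaded
#' from GFA.
#'
#' @param graph A `dbg_graph`.
#' @return The graph with a fresh k-mer index environment.
#' @export
index_kmers <- function(graph) {
  graph$kidx <- build_kindex_cpp(graph$seq, graph$k)
  graph
}

#' Look up a k-mer in the graph index
#'
#' @param graph A `dbg_graph`.
#' @param kmer A single k-mer string (either strand).
#' @return `NULL` if the k-mer does not occur in the graph, otherwise a list
#'   with `node` (signed id of the oriented unitig on which the query k-mer
#'   reads forward), `offset` (0-based offset in that oriented sequence), and
#'   `strand` (+1 if the query matches the stored strand, -1 otherwise).
#' @export
lookup_kmer <- function(graph, kmer) {
  stopifnot(nchar(kmer) == graph$k)
  hit <- lookup_kmer_cpp(graph$kidx, toupper(kmer), graph$len)
  if (length(hit) == 0) return(NULL)
  list(node = hit[1L], offset = hit[2L], strand = hit[3L])
}

#' Spell the sequence of a walk
#'
#' Concatenates the oriented node sequences of a chain, collapsing the k-1
#' base overlap at every arc. Errors if two consecutive chain elements are not
#' connected by an arc (invalid walk).
#'
#' @param graph A `dbg_graph`.
#' @param chain Integer vector of signed node ids.
#' @return The spelled DNA sequence.
#' @export
spell_path <- function(graph, chain) {
  chain <- as.integer(chain)
  if (length(chain) == 0) stop("empty chain")
  if (length(chain) > 1) {
    for (i in seq_len(length(chain) - 1L)) {
      if (!has_arc(graph, chain[i], chain[i + 1L]))
        stop(sprintf("invalid walk: no arc %d -> %d", chain[i], chain[i + 1L]))
    }
  }
  parts <- c(node_seq(graph, chain[1L]),
             vapply(chain[-1L], function(v) substring(node_seq(graph, v), graph$k),
                    character(1)))
  paste(parts, collapse = "")
}

# Spelled length of a walk without building the string.
chain_spell_length <- function(node_len, k, chain) {
  ids <- abs(chain)
  node_len[ids[1L]] + sum(node_len[ids[-1L]] - (k - 1L))
}
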