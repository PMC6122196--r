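# A small genome realising the classic branch-and-rejoin repeat topology:
#
#   F \           / D        true paths:  F-B-A-D,  G-B-A-E,  C-A-E
#      B -- A ---E
#   G /    C ---/
#
# Three records contain the true paths; a fourth "cutter" record gives the
# f, g, c and d blocks a second, unrelated context so that the unitigs near
# the branch stay short (a usable Markov state needs the whole (state+head)
# path to fit inside a read). The figure's F, G, C and D nodes are then the
# short junction unitigs adjacent to the branch; they are located by looking
# up a k-mer spanning the corresponding block boundary, while A, B and E are
# located by the k-mer at their block centre. Block contents are random under
# a seed that is bumped deterministically until the topology is realised.
branch_rejoin_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    k <- 11L; block <- 14L; flank <- 80L; spacer <- 45L
    bases <- c("A", "C", "G", "T")
    for (seed in 1:200) {
      set.seed(seed)
      bg <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
      bl <- list(f = bg(block), g = bg(block), c = bg(block), d = bg(block),
                 e = bg(block), b = bg(block), a = bg(block))
      U <- replicate(6, bg(flank))
      V <- replicate(5, bg(spacer))
      recs <- c(
        paste0(U[1], bl$f, bl$b, bl$a, bl$d, U[2]),
        paste0(U[3], bl$g, bl$b, bl$a, bl$e, U[4]),
        paste0(U[5], bl$c, bl$a, bl$e, U[6]),
        paste0(V[1], bl$f, V[2], bl$g, V[3], bl$c, V[4], bl$d, V[5])
      )
      graph <- tryCatch(build_graph(recs, k = k, multiplicities = FALSE),
                        error = function(e) NULL)
      if (is.null(graph)) next
      # k-mer centred on position p of record r
      at <- function(r, p) substr(recs[r], p - k %/% 2, p - k %/% 2 + k - 1L)
      mid <- function(off, nrec) at(nrec, off + block %/% 2)
      # block start offsets (1-based position of last base before the block)
      f1 <- flank; b1 <- flank + block; a1 <- flank + 2L * block
      d1 <- flank + 3L * block
      g2 <- flank; b2 <- flank + block
      c3 <- flank; a3 <- flank + block
      probes <- list(
        A = mid(a1, 1L), B = mid(b1, 1L), E = mid(a3 + block, 3L),
        FF = at(1L, b1), G = at(2L, b2), C = at(3L, a3), D = at(1L, d1 + 1L)
      )
      hits <- lapply(probes, function(m) tryCatch(lookup_kmer(graph, m),
                                                  error = function(e) NULL))
      if (any(vapply(hits, is.null, logical(1)))) next
      nd <- vapply(hits, function(h) as.integer(h$node), integer(1))
      names(nd) <- c("A", "B", "E", "F", "G", "C", "D")
      if (length(unique(abs(nd))) != 7L) next
      arc <- function(x, y) nd[[y]] %in% graph$arcs[graph$arcs[, 1] == nd[[x]], 2]
      topo <- arc("F", "B") && arc("G", "B") && arc("B", "A") &&
        arc("C", "A") && arc("A", "D") && arc("A", "E")
      if (!topo) next
      # every asserted (state+head) path must be usable at 25x / 150 bp
      paths <- list(c(nd[["F"]], nd[["B"]], nd[["A"]], nd[["D"]]),
                    c(nd[["G"]], nd[["B"]], nd[["A"]], nd[["E"]]),
                    c(nd[["C"]], nd[["A"]], nd[["E"]]),
                    c(nd[["C"]], nd[["A"]], nd[["D"]]),
                    c(nd[["B"]], nd[["A"]], nd[["D"]]),
                    c(nd[["B"]], nd[["A"]], nd[["E"]]))
      M <- vapply(paths, function(ch) as.numeric(
        dbgalign:::chain_spell_length(graph$len, k, ch)), numeric(1))
      if (any(expected_coverage(150, M, 25) < 10)) next
      cache <<- list(records = recs, graph = graph, nodes = nd, blocks = bl,
                     seed = seed, k = k,
                     block = block, flank = flank)
      return(cache)
    }
    stop("could not realise the branch-and-rejoin fixture")
  }
})

# Error-free 150 bp reads at 25x over the fixture records.
branch_rejoin_reads <- function(fx, seed = 5) {
  simulate_reads(fx$records, read_length = 150, coverage = 25,
                 sub_rate = 0, indel_rate = 0, seed = seed)
}

# A chimeric 150 bp read walking C -> A -> D: the left half follows record 3
# up to the end of the a block, the right half jumps to record 1 from the
# start of the d block.
branch_rejoin_chimera <- function(fx) {
  a_end3 <- fx$flank + 2L * fx$block        # end of a block in record 3
  d_start1 <- fx$flank + 3L * fx$block + 1L # start of d block in record 1
  left <- substr(fx$records[3], a_end3 - 74L, a_end3)
  right <- substr(fx$records[1], d_start1, d_start1 + 74L)
  paste0(left, right)
}
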