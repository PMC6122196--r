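# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with planted repeats
#'
#' An i.i.d.-uniform background sequence with `repeat_copies` planted copies
#' of one random repeat at non-overlapping positions, each with its own
#' (random, hence distinct) flanking context — the branch-and-rejoin topology
#' that makes a de Bruijn graph ambiguous. In `"near-identical"` mode each
#' copy is independently mutated at rate `divergence`, which fragments the
#' repeat into shared segments and copy-private bubbles, the structure on
#' which higher-order path context is informative. Deterministic under `seed`.
#'
#' @param genome_length Total length in bases.
#' @param repeat_length Length of the planted repeat (0 copies for none).
#' @param repeat_copies Number of planted copies.
#' @param repeat_mode `"exact"` or `"near-identical"`.
#' @param divergence Per-base substitution rate applied to each copy in
#'   near-identical mode (0 to 0.05).
#' @param seed RNG seed.
#' @param min_gap Minimum separation between planted copies.
#' @return A single DNA string with attributes `repeat_starts` (1-based) and
#'   `repeat_seq`.
#' @export
generate_genome <- function(genome_length = 50000L, repeat_length = 300L,
                            repeat_copies = 4L,
                            repeat_mode = c("near-identical", "exact"),
                            divergence = 0.008, seed = 1L,
                            min_gap = 500L) {
  repeat_mode <- match.arg(repeat_mode)
  stopifnot(divergence >= 0, divergence <= 0.05)
  if (repeat_copies > 0 && repeat_length * repeat_copies >= genome_length)
    stop("repeats do not fit in the genome")
  with_seed(seed, {
    g <- random_dna(genome_length)
    starts <- integer(0)
    rep_seq <- NULL
    if (repeat_copies > 0) {
      rep_seq <- random_dna(repeat_length)
      # one copy per equal-width band, jittered, to guarantee separation
      band <- genome_length %/% repeat_copies
      if (band < repeat_length + min_gap)
        stop("infeasible repeat placement")
      offs <- sample.int(band - repeat_length - min_gap, repeat_copies,
                         replace = TRUE)
      starts <- (seq_len(repeat_copies) - 1L) * band + offs + min_gap %/% 2L
      for (s in starts) {
        cp <- rep_seq
        if (repeat_mode == "near-identical" && divergence > 0) {
          muts <- which(stats::runif(repeat_length) < divergence)
          for (p in muts) {
            old <- substr(cp, p, p)
            substr(cp, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          }
        }
        substr(g, s, s + repeat_length - 1L) <- cp
      }
    }
    attr(g, "repeat_starts") <- starts
    attr(g, "repeat_seq") <- rep_seq
    g
  })
}

#' Simulate Illumina-style reads with error-free twins
#'
#' Fixed-length reads sampled uniformly from both strands of the genome, with
#' independent per-base substitution errors (uniform over the three
#' alternative bases) and optional per-base indels. Each read is paired with
#' its error-free twin — the exact genome substring at its origin, in read
#' orientation — in matching order, the ground truth for the corrected-read
#' accuracy metric. The read count is `round(coverage * genome_length /
#' read_length)`; for a multi-sequence genome, records are sampled
#' proportionally to length. Qualities are constant Q40 ('I'): the aligner is
#' quality-blind.
#'
#' @param genome Character vector of one or more DNA sequences.
#' @param read_length Read length in bases.
#' @param coverage Fold coverage.
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability (insertion or deletion with
#'   equal chance).
#' @param seed RNG seed.
#' @return A data frame: `id`, `seq` (the erroneous read), `error_free`,
#'   `qual`, `origin` (record index), `start` (1-based), `strand`.
#' @export
simulate_reads <- function(genome, read_length = 150L, coverage = 25,
                           sub_rate = 0.01, indel_rate = 0, seed = 1L) {
  genome <- as.character(genome)
  glen <- nchar(genome)
  if (any(glen < read_length)) stop("read_length exceeds a genome sequence")
  total <- sum(glen)
  n_reads <- as.integer(round(coverage * total / read_length))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rec <- if (length(genome) == 1L) rep(1L, n_reads) else
      sample.int(length(genome), n_reads, replace = TRUE,
                 prob = glen - read_length + 1)
    start <- vapply(rec, function(r)
      sample.int(glen[r] - read_length + 1L, 1L), integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    twin <- substr(rep(genome[rec], 1L), start, start + read_length - 1L)
    twin <- ifelse(strand == "-", rc_cpp(twin), twin)
    reads <- twin
    if (sub_rate > 0 || indel_rate > 0) {
      for (i in seq_len(n_reads)) {
        r <- reads[i]
        if (sub_rate > 0) {
          muts <- which(stats::runif(read_length) < sub_rate)
          for (p in muts) {
            old <- substr(r, p, p)
            substr(r, p, p) <- sample(setdiff(bases, old), 1L)
          }
        }
        if (indel_rate > 0) {
          pos <- which(stats::runif(nchar(r)) < indel_rate)
          for (p in rev(pos)) {  # right-to-left keeps earlier positions valid
            if (stats::runif(1) < 0.5) {
              r <- paste0(substr(r, 1L, p - 1L), substr(r, p + 1L, nchar(r)))
            } else {
              r <- paste0(substr(r, 1L, p), sample(bases, 1L),
                          substr(r, p + 1L, nchar(r)))
            }
          }
        }
        reads[i] <- r
      }
    }
    data.frame(
      id = sprintf("read_%06d", seq_len(n_reads)),
      seq = reads,
      error_free = twin,
      qual = vapply(nchar(reads), function(n) strrep("I", n), character(1)),
      origin = rec,
      start = start,
      strand = strand,
      stringsAsFactors = FALSE
    )
  })
}

#' Corrected-read accuracy against error-free twins
#'
#' A read counts as correctly aligned iff its corrected sequence is identical
#' to its error-free twin; an unaligned read (emitted unchanged) is therefore
#' only correct if it happened to contain no errors. When per-read chain node
#' counts are supplied, the report also covers the stratum of reads whose
#' walk spans at least two nodes — the reads for which path choice in the
#' graph actually matters.
#'
#' @param corrected Character vector of corrected reads (or a FASTQ/FASTA
#'   path).
#' @param truth Character vector of error-free twins (or a file path), same
#'   cardinality and order.
#' @param n_nodes Optional integer vector of chain node counts per read.
#' @return A list: `n`, `n_correct`, `pct_correct`, and (when `n_nodes` is
#'   given) `multi` with the same fields restricted to multi-node reads.
#' @export
evaluate_alignments <- function(corrected, truth, n_nodes = NULL) {
  if (length(corrected) == 1 && file.exists(corrected))
    corrected <- read_sequences(corrected)$seq
  if (length(truth) == 1 && file.exists(truth))
    truth <- read_sequences(truth)$seq
  if (length(corrected) != length(truth))
    stop("corrected and truth differ in cardinality")
  ok <- corrected == truth
  out <- list(n = length(ok), n_correct = sum(ok),
              pct_correct = if (length(ok)) 100 * mean(ok) else NA_real_)
  if (!is.null(n_nodes)) {
    if (length(n_nodes) != length(ok))
      stop("n_nodes has wrong cardinality")
    sel <- n_nodes >= 2L
    out$multi <- list(n = sum(sel), n_correct = sum(ok[sel]),
                      pct_correct = if (any(sel)) 100 * mean(ok[sel]) else NA_real_)
  }
  out
}
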