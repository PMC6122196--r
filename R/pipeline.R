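#' Aligner configuration
#'
#' All tunable parameters with their defaults: word length k = 31, scores
#' +1/-1/-3, Markov model maxOrder = 10 with likelihood-ratio threshold 1e5
#' and minimum chain coverage 10, identity threshold 0.75 for reporting a
#' read as aligned, MEM floor 15, up to 10 seeds tried per read, and a
#' 10,000-state search budget per read.
#'
#' @param k Word length (odd).
#' @param match,mismatch,gap Alignment scores.
#' @param max_order Maximum Markov model order.
#' @param min_likelihood_ratio Pruning threshold for observed transitions.
#' @param min_chain_cov Minimum expected coverage for a usable state.
#' @param min_identity Minimum identity for a read to count as aligned.
#' @param min_mem_length Minimum MEM length for fallback seeding.
#' @param seed_retry_cap Maximum seeds tried per read, longest first.
#' @param seed_stop_slack Stop trying further seeds once the best score is
#'   within this many points of the perfect score (a cheap anchor-confidence
#'   heuristic; the per-seed search itself remains exact).
#' @param node_visit_budget Maximum search states per read; a read that
#'   exhausts it keeps its best-so-far alignment and is flagged.
#' @param rng_seed Optional seed recorded for run logs.
#' @param workers Worker count (the contract is order-preserving,
#'   deterministic output whatever its value).
#' @return A list of class `dbg_config`.
#' @export
aligner_config <- function(k = 31L, match = 1L, mismatch = -1L, gap = -3L,
                           max_order = 10L, min_likelihood_ratio = 1e5,
                           min_chain_cov = 10, min_identity = 0.75,
                           min_mem_length = 15L, seed_retry_cap = 10L,
                           seed_stop_slack = 4L,
                           node_visit_budget = 10000L, rng_seed = NULL,
                           workers = 1L) {
  structure(list(k = as.integer(k), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap),
                 max_order = as.integer(max_order),
                 min_likelihood_ratio = min_likelihood_ratio,
                 min_chain_cov = min_chain_cov,
                 min_identity = min_identity,
                 min_mem_length = as.integer(min_mem_length),
                 seed_retry_cap = as.integer(seed_retry_cap),
                 seed_stop_slack = as.integer(seed_stop_slack),
                 node_visit_budget = as.integer(node_visit_budget),
                 rng_seed = rng_seed, workers = as.integer(workers)),
            class = "dbg_config")
}

config_scheme <- function(config) {
  scoring_scheme(config$match, config$mismatch, config$gap)
}

config_mm_params <- function(config) {
  mm_params(config$max_order, config$min_likelihood_ratio, config$min_chain_cov)
}

#' Two-pass alignment pipeline
#'
#' Pass 1 aligns every read without path restrictions and trains the
#' higher-order Markov model from the resulting walks; pass 2 realigns under
#' the model's guidance. Only reads whose first-pass walk spans at least
#' three nodes are realigned: the model cannot restrict shorter walks
#' (every 1- and 2-node path is unconditionally valid), so their
#' unrestricted optimum stands. With `use_mm = FALSE` the pipeline collapses
#' to the single unrestricted pass. Output order always equals input order.
#'
#' @param graph A `dbg_graph` or path to a GFA file.
#' @param reads A data frame from [read_sequences()]/[simulate_reads()], a
#'   character vector of read sequences, or a path to a FASTA/FASTQ file.
#' @param config An [aligner_config()].
#' @param use_mm Train and apply the Markov model (default TRUE).
#' @param use_bound Branch-and-bound pruning (identical scores either way).
#' @param mm A pre-trained model to use instead of training (implies two-pass
#'   guidance without the training pass).
#' @param out Optional path: corrected reads are written here in the input's
#'   format and order.
#' @return A list: `results` (per-read table as from [align_reads()]), `mm`
#'   (the trained model or NULL), and `report` (run summary: read counts,
#'   aligned counts, multi-node fraction, visited-state stats, model sizes,
#'   and the resolved configuration).
#' @export
run_pipeline <- function(graph, reads, config = aligner_config(),
                         use_mm = TRUE, use_bound = TRUE, mm = NULL,
                         out = NULL) {
  if (is.character(graph) && length(graph) == 1L) graph <- read_gfa(graph)
  records <- NULL
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    records <- read_sequences(reads)
    reads <- records
  } else if (is.data.frame(reads)) {
    records <- reads
  }
  scheme <- config_scheme(config)

  pass1 <- align_reads(graph, reads, scheme, mm = mm, config = config,
                       use_bound = use_bound)
  results <- pass1
  model <- mm
  if (use_mm && is.null(mm)) {
    model <- markov_from_pass(graph, pass1, config_mm_params(config))
    redo <- which(pass1$aligned & pass1$n_nodes >= 3L)
    if (length(redo) > 0) {
      seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
      for (i in redo) {
        r2 <- align_read(graph, seqs[i], scheme, mm = model, config = config,
                         use_bound = use_bound)
        results$aligned[i] <- r2$aligned
        results$score[i] <- r2$score
        results$identity[i] <- r2$identity
        results$n_nodes[i] <- r2$n_nodes
        results$visited[i] <- results$visited[i] + r2$visited
        results$exhausted[i] <- results$exhausted[i] || r2$exhausted
        results$corrected[i] <- r2$corrected
        results$chain[i] <- paste(r2$chain, collapse = ",")
      }
    }
  }

  if (!is.null(out)) {
    if (is.null(records)) {
      seqs <- as.character(reads)
      records <- data.frame(id = results$id, seq = seqs,
                            qual = NA_character_, stringsAsFactors = FALSE)
      attr(records, "format") <- "fasta"
    }
    write_corrected(records, results, out)
  }

  report <- list(
    n_reads = nrow(results),
    n_aligned = sum(results$aligned),
    pct_multi_node = if (nrow(results)) 100 * mean(results$n_nodes >= 2) else NA,
    visited_total = sum(results$visited),
    visited_max = if (nrow(results)) max(results$visited) else 0L,
    n_exhausted = sum(results$exhausted),
    mm_states = if (!is.null(model))
      vapply(model$tables, function(e) length(ls(e)), integer(1)) else NULL,
    config = config
  )
  list(results = results, mm = model, report = report)
}
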