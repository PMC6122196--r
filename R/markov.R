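#' Markov model parameters
#'
#' @param max_order Maximum model order (state length in nodes); default 10.
#' @param min_likelihood_ratio Poisson likelihood-ratio threshold above which
#'   an observed transition is pruned as spurious; default 1e5.
#' @param min_chain_cov Minimum expected path coverage for a state to be
#'   consulted at all; default 10.
#' @return A list of class `dbg_mm_params`.
#' @export
mm_params <- function(max_order = 10L, min_likelihood_ratio = 1e5,
                      min_chain_cov = 10) {
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 2L, min_likelihood_ratio > 0, min_chain_cov > 0)
  structure(list(max_order = max_order,
                 min_likelihood_ratio = min_likelihood_ratio,
                 min_chain_cov = min_chain_cov),
            class = "dbg_mm_params")
}

#' Expected number of reads covering a path
#'
#' For sequencing coverage c and read length l, the expected number of reads
#' that fully contain a sequence of length M (occurring once in the genome)
#' is c * (l - M + 1) / l: of the l start positions that put a read over a
#' given base, l - M + 1 also cover the whole stretch. C_1 = c by definition
#' and the value is floored at 0 for M > l.
#'
#' @param l Read length in bases (> 0).
#' @param M Path sequence length in bases (>= 1).
#' @param c Fold coverage (>= 0).
#' @return Expected coverage C_M.
#' @export
expected_coverage <- function(l, M, c) {
  if (any(l <= 0)) stop("read length l must be positive")
  stopifnot(all(M >= 1), all(c >= 0))
  pmax(0, c * (l - M + 1) / l)
}

#' Poisson likelihood ratio for an observed path frequency
#'
#' Tests whether an observed path is spurious: under H0 the path has
#' multiplicity zero in the genome and its observations are misalignments
#' (frequency ~ Poisson(1)); under H1 it has multiplicity at least one
#' (frequency ~ Poisson(C_M)). The ratio P(freq|H0)/P(freq|H1) simplifies to
#' exp(C_M - 1) * C_M^(-freq), computed in log space. Large values indicate a
#' spurious path; transitions at or above `minLikelihoodRatio` are pruned.
#'
#' @param freq Observed path count (>= 1; only observed paths are tested).
#' @param C_M Expected coverage of the path (> 0).
#' @return The likelihood ratio.
#' @export
likelihood_ratio <- function(freq, C_M) {
  stopifnot(all(freq >= 1))
  if (any(C_M <= 0)) stop("C_M must be positive (gating should exclude this)")
  exp((C_M - 1) - freq * log(C_M))
}

mm_state_key <- function(state) paste(state, collapse = ",")

#' Train the higher-order Markov model from read alignments
#'
#' First-pass read alignments imply walks in the graph; every contiguous
#' (n+1)-node subwalk, for each order n from 2 to `max_order`, contributes an
#' observation with the first n nodes as the state and the final node as the
#' continuation (head). A walk and its reverse-complement mirror contribute to
#' mirrored states, so querying is strand-symmetric. Observed transitions
#' whose Poisson likelihood ratio exceeds the threshold are pruned as
#' misalignment artefacts; surviving counts are converted to probabilities. A
#' state is only consulted at alignment time when the expected coverage of the
#' queried (state + head) path reaches `min_chain_cov`.
#'
#' @param graph A `dbg_graph`.
#' @param chains List of integer vectors: the alignment walk of each aligned
#'   read (unaligned reads contribute nothing).
#' @param l Read length used in the coverage model (modal input read length).
#' @param coverage Fold-coverage estimate c (aligned bases / graph length).
#' @param params An [mm_params()].
#' @return An object of class `dbg_markov`.
#' @export
markov_from_chains <- function(graph, chains, l, coverage,
                               params = mm_params()) {
  chains <- chains[vapply(chains, length, integer(1)) >= 3L]
  counts <- lapply(2:params$max_order, function(n) new.env(parent = emptyenv()))
  names(counts) <- as.character(2:params$max_order)
  observe <- function(chain) {
    cl <- length(chain)
    for (n in 2:min(params$max_order, cl - 1L)) {
      for (i in seq_len(cl - n)) {
        key <- mm_state_key(chain[i:(i + n - 1L)])
        head <- as.character(chain[i + n])
        env <- counts[[as.character(n)]]
        tab <- get0(key, envir = env, inherits = FALSE)
        if (is.null(tab)) tab <- integer(0)
        tab[head] <- (if (head %in% names(tab)) tab[[head]] else 0L) + 1L
        assign(key, tab, envir = env)
      }
    }
  }
  for (ch in chains) {
    observe(ch)
    observe(rev(-ch))
  }

  node_len <- graph$len
  k <- graph$k
  tables <- lapply(names(counts), function(nc) {
    env <- counts[[nc]]
    out <- new.env(parent = emptyenv())
    for (key in ls(env)) {
      tab <- get(key, envir = env)
      state <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      heads <- as.integer(names(tab))
      M <- vapply(heads, function(h)
        chain_spell_length(node_len, k, c(state, h)), numeric(1))
      C_M <- expected_coverage(l, M, coverage)
      lr <- ifelse(C_M > 0, likelihood_ratio(as.numeric(tab), pmax(C_M, 1e-12)), 0)
      pruned <- C_M > 0 & lr >= params$min_likelihood_ratio
      keep <- !pruned
      # a state is kept even when every observed continuation is pruned: an
      # observed state whose continuations are all spurious rejects any
      # candidate head (subject to the usability gate at query time)
      probs <- if (any(keep)) as.numeric(tab[keep]) / sum(tab[keep]) else numeric(0)
      assign(key, list(heads = heads[keep], counts = as.integer(tab[keep]),
                       probs = probs, pruned = heads[pruned]),
             envir = out)
    }
    out
  })
  names(tables) <- names(counts)

  structure(list(tables = tables, params = params, l = l, c = coverage,
                 k = k, node_len = node_len),
            class = "dbg_markov")
}

#' Two-pass training of the Markov model
#'
#' Aligns every read without path restrictions (the first pass), estimates
#' coverage as aligned bases over total graph length, and builds the model
#' from the resulting walks with [markov_from_chains()].
#'
#' @param graph A `dbg_graph`.
#' @param reads Character vector of reads or data frame with a `seq` column.
#' @param scheme A [scoring_scheme()].
#' @param params An [mm_params()].
#' @param config An [aligner_config()].
#' @return A `dbg_markov` model. With zero aligned reads an empty,
#'   never-restricting model is returned with a warning.
#' @export
train_markov_model <- function(graph, reads, scheme = scoring_scheme(),
                               params = mm_params(), config = aligner_config()) {
  pass1 <- align_reads(graph, reads, scheme, mm = NULL, config = config)
  markov_from_pass(graph, pass1, params)
}

#' Build the Markov model from an existing first-pass alignment table
#'
#' Equivalent to [train_markov_model()] when the unrestricted alignments have
#' already been computed (avoids re-running pass 1): estimates the read
#' length (mode) and coverage (aligned bases over graph length) from the
#' table and trains on the aligned reads' walks.
#'
#' @param graph A `dbg_graph`.
#' @param pass1 Alignment table from [align_reads()] run with `mm = NULL`.
#' @param params An [mm_params()].
#' @return A `dbg_markov` model.
#' @export
markov_from_pass <- function(graph, pass1, params = mm_params()) {
  aligned <- pass1[pass1$aligned, , drop = FALSE]
  if (nrow(aligned) == 0L) {
    warning("no aligned reads; Markov model is empty and restricts nothing")
    return(markov_from_chains(graph, list(), l = 1, coverage = 0, params))
  }
  chains <- lapply(strsplit(aligned$chain, ",", fixed = TRUE), as.integer)
  lens <- nchar(aligned$corrected)
  l_tab <- table(lens)
  l <- as.integer(names(l_tab)[which.max(l_tab)])  # modal read length
  coverage <- sum(lens) / sum(graph$len)
  markov_from_chains(graph, chains, l = l, coverage = coverage, params)
}

#' @export
print.dbg_markov <- function(x, ...) {
  sizes <- vapply(x$tables, function(e) length(ls(e)), integer(1))
  cat(sprintf("higher-order Markov model: orders 2..%d, l = %d, c = %.2f\n",
              x$params$max_order, x$l, x$c))
  cat("states per order:", paste(sprintf("%s:%d", names(sizes), sizes),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Is a graph transition allowed by the Markov model?
#'
#' Orders are examined from the highest available down to 2: the last n nodes
#' of the history form the state; if the expected coverage of the
#' (state + head) path reaches `min_chain_cov` and the state was observed in
#' training, the answer is whether `head` survives as a continuation of that
#' state. If no order yields a usable, observed state the transition is
#' allowed (the model restricts nothing it knows nothing about).
#'
#' @param mm A `dbg_markov` model.
#' @param history Signed node ids of the walk so far (non-empty).
#' @param head Candidate next signed node id.
#' @return `TRUE` if the extension is allowed.
#' @export
is_transition_valid <- function(mm, history, head) {
  hl <- length(history)
  if (hl < 2L) return(TRUE)
  head_chr <- as.character(head)
  for (n in seq(min(mm$params$max_order, hl), 2L)) {
    state <- history[(hl - n + 1L):hl]
    tab <- get0(mm_state_key(state), envir = mm$tables[[as.character(n)]],
                inherits = FALSE)
    if (is.null(tab)) next
    M <- chain_spell_length(mm$node_len, mm$k, c(state, head))
    C_M <- expected_coverage(mm$l, M, mm$c)
    if (C_M < mm$params$min_chain_cov) next
    return(head %in% tab$heads)
  }
  TRUE
}

#' Write a Markov model to a tab-separated sidecar file
#'
#' Header comment lines carry the coverage model (k, l, c, thresholds); each
#' row is order, comma-separated state, head, count, probability, and a
#' surviving flag (pruned transitions are written with flag 0).
#'
#' @param mm A `dbg_markov` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markov_model <- function(mm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d\tl=%d\tc=%.10g\tmax_order=%d\tmin_likelihood_ratio=%.10g\tmin_chain_cov=%.10g",
                     mm$k, mm$l, mm$c, mm$params$max_order,
                     mm$params$min_likelihood_ratio, mm$params$min_chain_cov),
             con)
  writeLines(paste0("#node_len=", paste(mm$node_len, collapse = ",")), con)
  writeLines("order\tstate\thead\tcount\tprob\tsurvives", con)
  for (nc in names(mm$tables)) {
    env <- mm$tables[[nc]]
    for (key in sort(ls(env))) {
      tab <- get(key, envir = env)
      for (i in seq_along(tab$heads)) {
        writeLines(sprintf("%s\t%s\t%d\t%d\t%.10g\t1", nc, key, tab$heads[i],
                           tab$counts[i], tab$probs[i]), con)
      }
      for (h in tab$pruned) {
        writeLines(sprintf("%s\t%s\t%d\t0\t0\t0", nc, key, h), con)
      }
    }
  }
  invisible(path)
}

#' Read a Markov model written by [write_markov_model()]
#'
#' @param path Path to the sidecar file.
#' @return A `dbg_markov` model.
#' @export
read_markov_model <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  kv <- do.call(rbind, strsplit(hdr, "=", fixed = TRUE))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  node_len <- as.integer(strsplit(sub("^#node_len=", "", lines[2]), ",")[[1]])
  params <- mm_params(max_order = vals[["max_order"]],
                      min_likelihood_ratio = vals[["min_likelihood_ratio"]],
                      min_chain_cov = vals[["min_chain_cov"]])
  body <- lines[-(1:3)]
  tables <- lapply(2:params$max_order, function(n) new.env(parent = emptyenv()))
  names(tables) <- as.character(2:params$max_order)
  if (length(body) > 0) {
    f <- utils::read.table(text = body, sep = "\t", col.names =
      c("order", "state", "head", "count", "prob", "survives"),
      colClasses = c("integer", "character", "integer", "integer",
                     "numeric", "integer"))
    for (grp in split(f, list(f$order, f$state), drop = TRUE)) {
      surv <- grp$survives == 1L
      assign(grp$state[1],
             list(heads = grp$head[surv], counts = grp$count[surv],
                  probs = grp$prob[surv], pruned = grp$head[!surv]),
             envir = tables[[as.character(grp$order[1])]])
    }
  }
  structure(list(tables = tables, params = params, l = as.integer(vals[["l"]]),
                 c = vals[["c"]], k = as.integer(vals[["k"]]),
                 node_len = node_len),
            class = "dbg_markov")
}
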