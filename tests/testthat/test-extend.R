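test_that("prefix DP matches its printed examples and the empty case", {
  expect_equal(nw_prefix_score("ACGT", "ACGT"), list(score = 4L, prefix_end = 4L))
  expect_equal(nw_prefix_score("ACTT", "ACGT")$score, 2L)  # 3 matches, 1 mismatch
  expect_equal(nw_prefix_score("", "ACGTACGT"), list(score = 0L, prefix_end = 0L))
})

test_that("prefix DP equals the reference full-matrix oracle on random pairs", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (i in 1:300) {
    a <- paste(sample(bases, sample(0:80, 1), TRUE), collapse = "")
    b <- paste(sample(bases, sample(1:80, 1), TRUE), collapse = "")
    got <- nw_prefix_score(a, b)
    want <- oracle_prefix_score(a, b)
    expect_identical(got$score, as.integer(want$score))
    expect_identical(got$prefix_end, as.integer(want$prefix_end))
  }
})

test_that("upper_bound implements the remaining-match bound", {
  expect_equal(upper_bound(40, 50, 100, 1), 90)
  expect_equal(upper_bound(100, 100, 100, 1), 100)  # no slack at n = l
  expect_error(upper_bound(10, 101, 100, 1))
})

test_that("the search bound over-estimates every strict extension", {
  # The per-state bound prunes only future extensions: every complete
  # alignment of a chain that strictly extends the state crosses the state's
  # final DP row at some column n with score <= row[n] + m*(L - n), so the
  # max over n dominates all of them. Alignments ending inside the state's
  # own spelled tail are recorded as solutions before pruning and need no
  # bound.
  pats <- c("none", "sub", "indel", "mixed")
  n_inst <- 0
  for (i in 1:40) {
    inst <- rand_instance(7000 + i, pats[(i %% 4) + 1])
    if (is.null(inst)) next
    g <- inst$graph
    L <- nchar(inst$s)
    s_chars <- strsplit(inst$s, "")[[1]]
    oseq <- function(v) if (v > 0) g$seq[v] else g$rcseq[-v]
    succs <- function(v) sort(g$arcs[g$arcs[, 1] == v, 2])
    root_tail <- substring(oseq(inst$v), inst$from + 1)
    if (nchar(root_tail) > L + 8) root_tail <- substr(root_tail, 1, L + 8)
    row <- -3 * (0:L)
    for (ch in strsplit(root_tail, "")[[1]])
      row <- oracle_step_row(row, ch, s_chars, 1, -1, -3)
    bound <- max(row + (L - 0:L))
    # best complete alignment among strict extensions of the root state
    best_ext <- -Inf
    rec <- function(v, row, plen) {
      if (plen >= L + 8) return()
      for (w in succs(v)) {
        chunk <- substring(oseq(w), g$k)
        room <- L + 8 - plen
        if (nchar(chunk) > room) chunk <- substr(chunk, 1, room)
        r2 <- row
        for (ch in strsplit(chunk, "")[[1]]) {
          r2 <- oracle_step_row(r2, ch, s_chars, 1, -1, -3)
          best_ext <<- max(best_ext, r2[L + 1])
        }
        rec(w, r2, plen + nchar(chunk))
      }
    }
    rec(inst$v, row, nchar(root_tail))
    if (!is.finite(best_ext)) next
    n_inst <- n_inst + 1
    expect_gte(bound, best_ext)
  }
  expect_gte(n_inst, 15)
})

test_that("branch-and-bound equals exhaustive enumeration, pruned or not", {
  pats <- c("none", "sub", "indel", "mixed")
  n <- 0
  for (i in 1:60) {
    inst <- rand_instance(3000 + i, pats[(i %% 4) + 1])
    if (is.null(inst)) next
    n <- n + 1
    bb <- branch_and_bound_extend(inst$graph, inst$v, inst$s, from = inst$from,
                                  use_bound = TRUE)
    nb <- branch_and_bound_extend(inst$graph, inst$v, inst$s, from = inst$from,
                                  use_bound = FALSE)
    oc <- oracle_best_extension(inst$graph, inst$v, inst$s, from = inst$from)
    expect_identical(bb$score, as.integer(oc))
    expect_identical(nb$score, as.integer(oc))
    expect_lte(bb$visited, nb$visited)
  }
  expect_gte(n, 40)
})

test_that("empty remainders return the root only", {
  g <- build_graph(strrep("ACGGTCAATCGGA", 10), k = 11, multiplicities = FALSE)
  r <- branch_and_bound_extend(g, 1L, "")
  expect_equal(r$chain, 1L)
  expect_equal(r$score, 0L)
  expect_equal(r$corrected, "")
})

test_that("align_read recovers clean, erroneous and foreign reads correctly", {
  set.seed(23)
  ref <- as.character(generate_genome(6000, 150, 2, "exact", seed = 77))
  g <- build_graph(ref, k = 31, multiplicities = FALSE)
  cfg <- aligner_config()

  rd <- substr(ref, 2001, 2150)
  a <- align_read(g, rd, config = cfg)
  expect_true(a$aligned)
  expect_equal(a$identity, 1)
  expect_identical(a$corrected, rd)
  expect_equal(a$score, 150L)

  # one substitution mid-unitig: corrected to the reference substring
  rd2 <- rd
  substr(rd2, 80, 80) <- setdiff(c("A", "C", "G", "T"), substr(rd, 80, 80))[1]
  a2 <- align_read(g, rd2, config = cfg)
  expect_true(a2$aligned)
  expect_identical(a2$corrected, rd)         # error corrected
  expect_equal(a2$score, 149L * 1L - 1L)     # m*(l-1) + mismatch
  # score recomputes exactly from corrected vs read
  st <- dbgalign:::nw_stats_cpp(a2$corrected, rd2, 1L, -1L, -3L)
  expect_equal(a2$score, st$score)

  # a read from elsewhere: unaligned, emitted unchanged
  set.seed(24)
  foreign <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  a3 <- align_read(g, foreign, config = cfg)
  expect_false(a3$aligned)
  expect_identical(a3$corrected, foreign)
})

test_that("alignment is strand-symmetric", {
  set.seed(25)
  ref <- as.character(generate_genome(4000, 120, 2, "exact", seed = 31))
  g <- build_graph(ref, k = 31, multiplicities = FALSE)
  rd <- substr(ref, 1501, 1680)
  substr(rd, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(rd, 60, 60))[1]
  a_f <- align_read(g, rd)
  a_r <- align_read(g, revcomp(rd))
  expect_equal(a_r$score, a_f$score)
  expect_identical(a_r$corrected, revcomp(a_f$corrected))
  expect_equal(a_r$chain, rev(-a_f$chain))
})

test_that("a guiding model steers equal-score branch choices", {
  fx <- branch_rejoin_fixture()
  g <- fx$graph
  nd <- fx$nodes
  cfg <- aligner_config(k = fx$k)
  mm <- train_markov_model(g, branch_rejoin_reads(fx), config = cfg)
  # read covering f-b-a then a tail equally dissimilar to both branches
  pathA <- spell_path(g, c(nd[["F"]], nd[["B"]], nd[["A"]]))
  contD <- spell_path(g, c(nd[["F"]], nd[["B"]], nd[["A"]], nd[["D"]]))
  contE <- spell_path(g, c(nd[["F"]], nd[["B"]], nd[["A"]], nd[["E"]]))
  nA <- nchar(pathA)
  dtail <- strsplit(substr(contD, nA + 1, nA + 8), "")[[1]]
  etail <- strsplit(substr(contE, nA + 1, nA + 8), "")[[1]]
  tail8 <- vapply(1:8, function(i)
    setdiff(c("A", "C", "G", "T"), c(dtail[i], etail[i]))[1], character(1))
  rd <- paste0(pathA, paste(tail8, collapse = ""))
  a_guided <- align_read(g, rd, mm = mm, config = cfg)
  a_free <- align_read(g, rd, config = cfg)
  expect_equal(a_guided$score, a_free$score)  # guidance never costs score here
  expect_true(nd[["D"]] %in% a_guided$chain)  # 3-MM forces the D branch
  expect_false(nd[["E"]] %in% a_guided$chain)
})

test_that("the node-visit budget caps the search and flags the result", {
  fx <- branch_rejoin_fixture()
  rd <- paste0(spell_path(fx$graph, c(fx$nodes[["F"]], fx$nodes[["B"]])),
               strrep("A", 40))
  a <- align_read(fx$graph, rd,
                  config = aligner_config(k = fx$k, node_visit_budget = 2L))
  expect_true(a$exhausted)
  expect_lte(a$visited, 2L + 2L)  # per-extension budgets are sequential
})
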