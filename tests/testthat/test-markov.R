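test_that("expected coverage follows the closed form and its recurrence", {
  expect_equal(expected_coverage(150, 1, 25), 25)       # C_1 = c by definition
  expect_equal(expected_coverage(150, 31, 25), 20)      # 25 * 120 / 150
  expect_equal(expected_coverage(100, 101, 50), 0)      # path longer than read
  expect_error(expected_coverage(0, 10, 25))
  for (l in c(100, 150, 239)) {
    c0 <- 25
    C <- expected_coverage(l, 1:l, c0)
    for (M in 2:l) {
      expect_equal(C[M], C[M - 1] * (l - M + 1) / (l - M + 2), tolerance = 1e-12)
    }
    expect_equal(C[1], c0)
  }
})

test_that("likelihood ratio equals the Poisson pmf ratio and closed form", {
  for (C_M in c(2, 10, 20, 50)) {
    for (freq in 1:50) {
      lr <- likelihood_ratio(freq, C_M)
      direct <- stats::dpois(freq, 1) / stats::dpois(freq, C_M)
      expect_equal(lr, direct, tolerance = 1e-9)
      expect_equal(lr, exp(C_M - 1) * C_M^(-freq), tolerance = 1e-9)
    }
  }
  # decision boundary at the default threshold
  expect_lt(likelihood_ratio(1, 10), 1e5)   # e^9/10  ~ 810: kept
  expect_gte(likelihood_ratio(1, 20), 1e5)  # e^19/20 ~ 8.9e6: pruned
  expect_lt(likelihood_ratio(10, 10), 1e5)  # well-covered path: kept
  expect_error(likelihood_ratio(1, 0))
  expect_error(likelihood_ratio(0, 10))
})

test_that("training on the branch-and-rejoin fixture recovers the tables", {
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  cfg <- aligner_config(k = fx$k)
  mm <- train_markov_model(fx$graph, branch_rejoin_reads(fx), config = cfg)
  key <- function(v) paste(v, collapse = ",")
  t2 <- mm$tables[["2"]]
  t3 <- mm$tables[["3"]]
  expect_identical(get(key(c(nd[["C"]], nd[["A"]])), envir = t2)$heads,
                   nd[["E"]])
  expect_setequal(get(key(c(nd[["B"]], nd[["A"]])), envir = t2)$heads,
                  c(nd[["D"]], nd[["E"]]))
  expect_identical(get(key(c(nd[["F"]], nd[["B"]], nd[["A"]])), envir = t3)$heads,
                   nd[["D"]])
  expect_identical(get(key(c(nd[["G"]], nd[["B"]], nd[["A"]])), envir = t3)$heads,
                   nd[["E"]])
  # probabilities of surviving heads sum to one
  for (k2 in ls(t2)) {
    tab <- get(k2, envir = t2)
    if (length(tab$probs)) expect_equal(sum(tab$probs), 1)
  }
  # soundness: every surviving order-2 transition spells a genomic substring
  genome_text <- paste(c(fx$records, revcomp(fx$records)), collapse = " ")
  for (k2 in sample(ls(t2), min(10, length(ls(t2))))) {
    st <- as.integer(strsplit(k2, ",")[[1]])
    for (h in get(k2, envir = t2)$heads) {
      sp <- spell_path(fx$graph, c(st, h))
      expect_true(grepl(sp, genome_text, fixed = TRUE))
    }
  }
})

test_that("transition queries use the highest usable order and default open", {
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  cfg <- aligner_config(k = fx$k)
  mm <- train_markov_model(fx$graph, branch_rejoin_reads(fx), config = cfg)
  # 2-MM: C,A context forbids D, allows E
  expect_false(is_transition_valid(mm, c(nd[["C"]], nd[["A"]]), nd[["D"]]))
  expect_true(is_transition_valid(mm, c(nd[["C"]], nd[["A"]]), nd[["E"]]))
  # 3-MM resolves what the 2-MM cannot: B,A allows both, F/G context decides
  expect_true(is_transition_valid(mm, c(nd[["B"]], nd[["A"]]), nd[["D"]]))
  expect_true(is_transition_valid(mm, c(nd[["B"]], nd[["A"]]), nd[["E"]]))
  expect_false(is_transition_valid(mm, c(nd[["F"]], nd[["B"]], nd[["A"]]), nd[["E"]]))
  expect_true(is_transition_valid(mm, c(nd[["F"]], nd[["B"]], nd[["A"]]), nd[["D"]]))
  expect_false(is_transition_valid(mm, c(nd[["G"]], nd[["B"]], nd[["A"]]), nd[["D"]]))
  # a state never observed restricts nothing
  expect_true(is_transition_valid(mm, c(999L, 998L), nd[["D"]]))
  # short history restricts nothing (a 1-MM is uninformative)
  expect_true(is_transition_valid(mm, nd[["A"]], nd[["D"]]))
})

test_that("a single chimeric observation is pruned by the likelihood-ratio test", {
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  cfg <- aligner_config(k = fx$k)
  rd <- branch_rejoin_reads(fx)
  chim <- branch_rejoin_chimera(fx)
  rd2 <- rbind(rd, data.frame(id = "chimera", seq = chim, error_free = chim,
                              qual = strrep("I", nchar(chim)), origin = 1L,
                              start = 1L, strand = "+"))
  mm0 <- train_markov_model(fx$graph, rd, config = cfg)
  mm1 <- train_markov_model(fx$graph, rd2, config = cfg)
  key <- paste(c(nd[["C"]], nd[["A"]]), collapse = ",")
  tab <- get(key, envir = mm1$tables[["2"]])
  expect_identical(tab$heads, nd[["E"]])       # table equals error-free table
  expect_true(nd[["D"]] %in% tab$pruned)       # chimeric transition pruned
  expect_false(is_transition_valid(mm1, c(nd[["C"]], nd[["A"]]), nd[["D"]]))
})

test_that("low coverage disables the model entirely", {
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  cfg <- aligner_config(k = fx$k)
  lo <- simulate_reads(fx$records, read_length = 150, coverage = 2,
                       sub_rate = 0, indel_rate = 0, seed = 8)
  mm <- train_markov_model(fx$graph, lo, config = cfg)
  # every multi-node genomic context falls below minChainCov: nothing is
  # restricted anywhere
  for (st in list(c(nd[["C"]], nd[["A"]]), c(nd[["F"]], nd[["B"]], nd[["A"]]))) {
    for (h in c(nd[["D"]], nd[["E"]])) {
      expect_true(is_transition_valid(mm, st, h))
    }
  }
})

test_that("an empty training set warns and restricts nothing", {
  fx <- branch_rejoin_fixture()
  foreign <- data.frame(id = "x", seq = strrep("A", 60), error_free = strrep("A", 60),
                        qual = strrep("I", 60), origin = 1L, start = 1L,
                        strand = "+")
  expect_warning(
    mm <- train_markov_model(fx$graph, foreign,
                             config = aligner_config(k = fx$k)),
    "no aligned reads")
  expect_true(is_transition_valid(mm, c(1L, 2L), 3L))
})

test_that("mirrored walks train mirrored states", {
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  mm <- train_markov_model(fx$graph, branch_rejoin_reads(fx),
                           config = aligner_config(k = fx$k))
  # the reverse-complement walk E -> A -> {B or C} trains the mirrored state
  key <- paste(c(-nd[["E"]], -nd[["A"]]), collapse = ",")
  tab <- get0(key, envir = mm$tables[["2"]])
  expect_false(is.null(tab))
  expect_true(-nd[["C"]] %in% tab$heads)
})

test_that("model serialization round-trips", {
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  mm <- train_markov_model(fx$graph, branch_rejoin_reads(fx),
                           config = aligner_config(k = fx$k))
  path <- tempfile(fileext = ".tsv")
  write_markov_model(mm, path)
  mm2 <- read_markov_model(path)
  expect_equal(mm2$l, mm$l)
  expect_equal(mm2$c, mm$c, tolerance = 1e-9)
  expect_equal(mm2$node_len, mm$node_len)
  for (ord in names(mm$tables)) {
    expect_setequal(ls(mm$tables[[ord]]), ls(mm2$tables[[ord]]))
    for (k2 in ls(mm$tables[[ord]])) {
      a <- get(k2, envir = mm$tables[[ord]])
      b <- get(k2, envir = mm2$tables[[ord]])
      o1 <- order(a$heads); o2 <- order(b$heads)
      expect_equal(a$heads[o1], b$heads[o2])
      expect_equal(a$counts[o1], b$counts[o2])
      expect_equal(sort(a$pruned), sort(b$pruned))
    }
  }
  # behavioural equivalence on the figure's queries
  for (st in list(c(nd[["C"]], nd[["A"]]), c(nd[["F"]], nd[["B"]], nd[["A"]]))) {
    for (h in c(nd[["D"]], nd[["E"]])) {
      expect_identical(is_transition_valid(mm2, st, h),
                       is_transition_valid(mm, st, h))
    }
  }
})

test_that("redundant higher-order rows never change query outcomes", {
  # a higher-order state whose lower-order suffix already uniquely determines
  # the continuation is redundant: removing it must not change any answer
  fx <- branch_rejoin_fixture()
  nd <- fx$nodes
  mm <- train_markov_model(fx$graph, branch_rejoin_reads(fx),
                           config = aligner_config(k = fx$k))
  key3 <- paste(c(nd[["C"]], nd[["A"]]), collapse = ",")
  # find order-3 states ending in (C, A): their info is already in the 2-MM
  t3 <- mm$tables[["3"]]
  redundant <- grep(paste0(",", key3, "$"), ls(t3), value = TRUE)
  expect_gt(length(redundant), 0)
  mm_min <- mm
  mm_min$tables <- lapply(mm$tables, function(e) {
    e2 <- new.env(parent = emptyenv())
    for (k2 in ls(e)) assign(k2, get(k2, envir = e), envir = e2)
    e2
  })
  names(mm_min$tables) <- names(mm$tables)
  for (k2 in redundant) {
    tab <- get(k2, envir = t3)
    suffix <- get(key3, envir = mm$tables[["2"]])
    if (identical(sort(tab$heads), sort(suffix$heads)))
      rm(list = k2, envir = mm_min$tables[["3"]])
  }
  histories <- c(list(c(nd[["C"]], nd[["A"]]),
                      c(nd[["B"]], nd[["A"]]),
                      c(nd[["F"]], nd[["B"]], nd[["A"]]),
                      c(nd[["G"]], nd[["B"]], nd[["A"]])),
                 lapply(redundant, function(k2)
                   as.integer(strsplit(k2, ",")[[1]])))
  for (hist in histories) {
    for (h in c(nd[["D"]], nd[["E"]])) {
      expect_identical(is_transition_valid(mm_min, hist, h),
                       is_transition_valid(mm, hist, h))
    }
  }
})
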