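# deterministic two-gene system: A holds itself, B copies A
copy_series <- function(n_steps = 4) {
  rules <- read_boolnet("targets, factors\nA, A\nB, A")
  generate_timeseries(rules, exhaustive_initial_states(c("A", "B")), n_steps)
}

test_that("confidence counts condition-outcome co-occurrence over transitions", {
  s <- copy_series()
  expect_identical(confidence_measure(s, "B", c(A = TRUE), 1)$confidence, 1)
  expect_identical(confidence_measure(s, "B", c(A = TRUE), 0)$confidence, 0)

  # hand-written: 3 matched transitions, 2 co-occurrences -> 2/3
  m1 <- rbind(A = c(1L, 1L, 0L), B = c(0L, 0L, 1L))
  m2 <- rbind(A = c(1L, 0L, 0L), B = c(0L, 1L, 0L))
  hs <- boolean_timeseries(list(m1, m2))
  cm <- confidence_measure(hs, "B", c(A = TRUE, B = FALSE), 1)
  expect_identical(cm$matched, 3L)
  expect_identical(cm$co_occurrence, 2L)
  expect_equal(cm$confidence, 2 / 3)
  expect_error(confidence_measure(hs, "B", c(Z = TRUE), 1), "unknown gene")
})

test_that("counter-confidence matches a brute-force reverse count", {
  s <- copy_series()
  for (cond in list(c(A = TRUE), c(A = FALSE), c(A = TRUE, B = TRUE))) {
    for (kind in c("activation", "inhibition")) {
      expect_equal(counter_confidence_measure(s, "B", cond, kind),
                   oracle_counter(s, "B", cond, kind))
    }
  }
  # condition never satisfied at t+1
  never <- boolean_timeseries(list(matrix(c(1L, 1L, 1L, 1L), 2,
                                          dimnames = list(c("A", "B"), NULL))))
  expect_identical(counter_confidence_measure(never, "B", c(A = FALSE),
                                              "activation"), 0)
  # target never in the required prior state
  expect_identical(counter_confidence_measure(never, "B", c(A = TRUE),
                                              "inhibition"), 0)
})

test_that("support divides co-occurrences by the total transition count", {
  s2 <- random_series(2, n_samples = 2, n_steps = 3, seed = 3)
  expect_identical(transition_count(s2), 4L)
  full <- boolean_timeseries(list(matrix(1L, 2, 5,
                                         dimnames = list(c("A", "B"), NULL))))
  expect_identical(support_measure(full, "B", c(A = TRUE), 1), 1)
  # 2 co-occurrences out of aleph = 8
  m <- matrix(0L, 2, 9, dimnames = list(c("A", "B"), NULL))
  m[1, c(1, 4)] <- 1L
  m[2, c(2, 5)] <- 1L
  s8 <- boolean_timeseries(list(m))
  expect_equal(support_measure(s8, "B", c(A = TRUE), 1), 0.25)
})

test_that("the causality ratio follows its division conventions", {
  expect_identical(causality_test(1.0, 0.5), 2.0)
  expect_identical(causality_test(0.8, 0.8), 1.0)
  expect_identical(causality_test(0.9, 0), Inf)
  expect_identical(causality_test(0, 0), 0)
  expect_error(causality_test(1.2, 0.5), "\\[0, 1\\]")
})

test_that("entropy and mutual information behave on binary sequences", {
  expect_identical(shannon_entropy(c(1, 0, 1, 0)), 1)
  expect_identical(shannon_entropy(rep(1, 5)), 0)
  set.seed(8)
  x <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  expect_equal(mutual_information(x, x), shannon_entropy(x))
  expect_gte(mutual_information(x, rev(x)), 0)
  expect_equal(mutual_information(x, !x), shannon_entropy(x))
  expect_error(mutual_information(x, x[-1]), "equal length")
})

test_that("chi-square screening keeps associated genes, prunes the rest", {
  s <- copy_series(n_steps = 6)
  expect_true("A" %in% chi_square_prune(s, "B"))

  # an independent coin-flip gene is pruned with high probability at large n
  set.seed(21)
  n <- 400
  a <- sample(0:1, n + 1, replace = TRUE)
  m <- rbind(A = a, B = c(0L, a[-(n + 1)]), C = sample(0:1, n + 1, replace = TRUE))
  s2 <- boolean_timeseries(list(m))
  kept <- chi_square_prune(s2, "B")
  expect_true("A" %in% kept)
  expect_false("C" %in% kept)

  # constant gene -> degenerate table -> pruned with a warning
  m3 <- rbind(A = c(0L, 1L, 0L, 1L), B = c(1L, 0L, 1L, 0L), K = rep(1L, 4))
  expect_warning(kept3 <- chi_square_prune(boolean_timeseries(list(m3)), "A"),
                 "degenerate")
  expect_false("K" %in% kept3)
})

test_that("the cube builds one tree per target with capped depth", {
  s <- random_series(3, n_samples = 2, n_steps = 6, seed = 5)
  cube <- build_cube(s, maxK = 2, alpha = 1)
  expect_length(cube$trees, 3L)
  expect_identical(names(cube$trees), s$genes)
  one <- build_cube(s, maxK = 1, alpha = 1)
  expect_true(all(one$trees$G1$nodes$depth == 1L))
  expect_error(build_cube(s, maxK = 0), "maxK")
})

test_that("pairwise dimensions are complementary: P(TT)=1-P(FT), P(TF)=1-P(FF)", {
  for (seed in 1:5) {
    s <- random_series(3, n_samples = 3, n_steps = 5, seed = 600 + seed)
    mm <- cube_measures(build_cube(s, maxK = 3, alpha = 1))
    key <- paste(mm$target, mm$condition)
    tt <- mm[mm$dim == "TT", ]
    ft <- mm[mm$dim == "FT", ]
    ft <- ft[match(paste(tt$target, tt$condition), paste(ft$target, ft$condition)), ]
    nz <- tt$matched > 0L
    expect_equal(tt$confidence[nz], 1 - ft$confidence[nz])
    tf <- mm[mm$dim == "TF", ]
    ff <- mm[mm$dim == "FF", ]
    ff <- ff[match(paste(tf$target, tf$condition), paste(ff$target, ff$condition)), ]
    nz <- tf$matched > 0L
    expect_equal(tf$confidence[nz], 1 - ff$confidence[nz])
    # the stored error measure is the paired opposite-outcome confidence
    expect_equal(tt$error[tt$matched > 0L], ft$confidence[tt$matched > 0L])
  }
})

test_that("every cube node agrees with the naive counting oracle", {
  for (seed in 1:4) {
    s <- random_series(3, n_samples = 2, n_steps = 6, seed = 700 + seed)
    cube <- build_cube(s, maxK = 3, alpha = 1)
    mm <- cube_measures(cube)
    set.seed(seed)
    for (i in sample(nrow(mm), 40)) {
      cond <- fbmnet:::condition_to_literals(mm$condition[i])
      o <- oracle_counts(s, mm$target[i], cond, mm$outcome[i])
      expect_identical(mm$matched[i], o$matched, info = mm$condition[i])
      expect_identical(mm$co_occurrence[i], o$co, info = mm$condition[i])
      expect_equal(mm$confidence[i], o$confidence, info = mm$condition[i])
      expect_equal(mm$support[i], o$co / transition_count(s))
    }
  }
})

test_that("building target subsets reproduces the joint build exactly", {
  s <- random_series(3, n_samples = 2, n_steps = 6, seed = 9)
  all3 <- build_cube(s, maxK = 3, alpha = 1)
  for (g in s$genes) {
    solo <- build_cube(s, maxK = 3, alpha = 1, targets = g)
    expect_identical(solo$trees[[g]], all3$trees[[g]])
  }
  par2 <- build_cube(s, maxK = 3, alpha = 1, n_jobs = 2)
  expect_identical(par2$trees, all3$trees)
})

test_that("child nodes never match more transitions than their parent", {
  s <- random_series(4, n_samples = 2, n_steps = 6, seed = 10)
  cube <- build_cube(s, maxK = 3, alpha = 1)
  for (tree in cube$trees) {
    nd <- tree$nodes
    for (i in which(nd$depth > 1L)) {
      pre <- strsplit(nd$prefix[i], "&", fixed = TRUE)[[1]]
      last <- pre[length(pre)]
      parent_prefix <- paste(pre[-length(pre)], collapse = "&")
      kv <- strsplit(last, "=", fixed = TRUE)[[1]]
      p <- which(nd$prefix == parent_prefix & nd$gene == kv[1])
      expect_length(p, 1L)
      parent_matched <- if (kv[2] == "1") nd$n1[p] else nd$n0[p]
      expect_lte(nd$n1[i] + nd$n0[i], parent_matched)
    }
  }
})

test_that("cube JSON-lines files round-trip", {
  s <- random_series(3, n_samples = 2, n_steps = 5, seed = 12)
  cube <- build_cube(s, maxK = 2, alpha = 1)
  path <- tempfile(fileext = ".jsonl")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$genes, cube$genes)
  expect_identical(back$aleph, cube$aleph)
  for (g in cube$targets) {
    a <- cube$trees[[g]]$nodes
    b <- back$trees[[g]]$nodes
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
    expect_identical(back$trees[[g]]$survivors, cube$trees[[g]]$survivors)
  }
  empty <- tempfile()
  file.create(empty)
  expect_error(read_cube(empty), "empty")
})
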