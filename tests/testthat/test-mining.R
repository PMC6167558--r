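# exhaustive series for: A holds itself, B copies A
copy_cube <- function(maxK = 2) {
  rules <- read_boolnet("targets, factors\nA, A\nB, A")
  s <- generate_timeseries(rules, exhaustive_initial_states(c("A", "B")), 5)
  build_cube(s, maxK = maxK, alpha = 1)
}

test_that("mining recovers activation and inhibition of a copied gene", {
  net <- mine_network(copy_cube(), mining_config())
  expect_setequal(sorted_terms(net$activators$B), "A")
  expect_setequal(sorted_terms(net$inhibitors$B), "!A")
  expect_setequal(sorted_terms(net$activators$A), "A")
  expect_identical(validate_network(net), character(0))
})

test_that("non-essential literals collapse to the shorter condition", {
  # B copies A; C independently holds itself: A&C and A&!C are non-essential
  rules <- read_boolnet("targets, factors\nA, A\nB, A\nC, C")
  s <- generate_timeseries(rules, exhaustive_initial_states(c("A", "B", "C")), 5)
  cube <- build_cube(s, maxK = 3, alpha = 1)
  cand <- mine_candidates(cube, mining_config(), cap = FALSE)
  bact <- cand[cand$target == "B" & cand$kind == "activation", ]
  expect_identical(bact$condition, "A=1")
  net <- mine_network(cube, mining_config())
  expect_setequal(sorted_terms(net$activators$B), "A")
})

test_that("candidates below any threshold are rejected", {
  cube <- copy_cube()
  strict <- mining_config(confidence_threshold = 0.999)
  cand <- mine_candidates(cube, strict, cap = FALSE)
  expect_true(all(cand$confidence > 0.999))
  # an unsatisfiable causality floor rejects everything
  none <- mine_candidates(cube, mining_config(causality_min = Inf), cap = FALSE)
  expect_true(is.null(none) || nrow(none) == 0L)
})

test_that("mined functions satisfy every configured threshold post hoc", {
  for (seed in 1:5) {
    net0 <- decomposed_fbn(random_rules(3, seed = 800 + seed))
    s <- generate_timeseries(net0, exhaustive_initial_states(net0$genes), 6)
    cube <- build_cube(s, maxK = 3, alpha = 1)
    cfg <- mining_config()
    cand <- mine_candidates(cube, cfg)
    if (is.null(cand) || !nrow(cand)) next
    expect_true(all(cand$confidence > cfg$confidence_threshold))
    expect_true(all(cand$causality >= cfg$causality_min))
    expect_true(all(1 - fbmnet:::binary_entropy(cand$confidence) >=
                      cfg$mi_threshold - 1e-12))
    counts <- table(paste(cand$target, cand$kind))
    expect_true(all(counts <= cfg$max_functions))
  }
})

test_that("the function cap truncates each target-kind list", {
  cube <- copy_cube(maxK = 2)
  capped <- mine_candidates(cube, mining_config(max_functions = 1), cap = TRUE)
  counts <- table(paste(capped$target, capped$kind))
  expect_true(all(counts <= 1L))
  uncapped <- mine_candidates(cube, mining_config(max_functions = 1), cap = FALSE)
  expect_gte(nrow(uncapped), nrow(capped))
})

test_that("mining is a pure function of cube and config", {
  cube <- copy_cube()
  n1 <- serialize_fbn(mine_network(cube, mining_config()))
  n2 <- serialize_fbn(mine_network(cube, mining_config()))
  expect_identical(n1, n2)
  # mining a reloaded cube gives the same network
  path <- tempfile(fileext = ".jsonl")
  write_cube(cube, path)
  expect_identical(serialize_fbn(mine_network(read_cube(path), mining_config())),
                   n1)
})

test_that("constant genes are handled explicitly", {
  # Z is always on at t+1 (tautology rule), Y always off
  rules <- read_boolnet("targets, factors\nZ, Z | !Z\nY, Y & !Y\nA, A")
  s <- generate_timeseries(rules, exhaustive_initial_states(c("Z", "Y", "A")), 5)
  cube <- build_cube(s, maxK = 2, alpha = 1)
  expect_message(net <- mine_network(cube, mining_config()), "constant-on")
  expect_length(net$activators$Z, 2L)
  expect_setequal(sorted_terms(net$activators$Z), c("Z", "!Z"))
  expect_length(net$activators$Y, 0L)
  recon <- reconstruct_timeseries(net, s)
  expect_identical(recon$samples, s$samples)
})

test_that("subsumed longer rules with equal confidence are dropped", {
  cube <- copy_cube(maxK = 2)
  cand <- mine_candidates(cube, mining_config(), cap = FALSE)
  bact <- cand[cand$target == "B" & cand$kind == "activation", ]
  # A=1 subsumes A=1&B=*, which must not survive
  expect_false(any(grepl("B=", bact$condition)))
})
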