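test_that("the decay gate enforces the tolerance window", {
  expect_false(decay_gate(1, tau = 1, theta = 1))  # one-step decay
  expect_true(decay_gate(1, tau = 1, theta = 2))   # two-step persistence
  expect_false(decay_gate(0, tau = 1, theta = 1))  # an off gene stays off
  expect_false(decay_gate(1, tau = 2, theta = 2))
  expect_error(decay_gate(1, tau = 1, theta = 0), "positive")
})

test_that("the stochastic gate passes iff the draw is below the confidence", {
  expect_true(all(stochastic_gate(1, c(0, 0.5, 0.999))))
  expect_false(any(stochastic_gate(0, c(0, 0.5, 0.999))))
  expect_identical(stochastic_gate(0.5, c(0.2, 0.7)), c(TRUE, FALSE))
  expect_error(stochastic_gate(1.5, 0.2), "\\[0, 1\\]")
})

test_that("seeded gate frequency matches its confidence", {
  set.seed(11)
  draws <- runif(10000)
  expect_lt(abs(mean(stochastic_gate(0.7, draws)) - 0.7), 0.02)
})

test_that("single synchronous steps reproduce the two-gene equilibrium", {
  net <- two_gene_fbn()
  s <- fbn_step(net, c(A = 1, B = 1))
  expect_identical(unname(s$values), c(0L, 1L))   # A inhibited, B boosted
  s2 <- fbn_step(net, c(A = 0, B = 0))
  expect_identical(unname(s2$values), c(0L, 0L))  # trapped in the simple loop
})

test_that("the quiescence state of the cell-cycle network is a fixed point", {
  net <- cell_cycle_fbn()
  st <- stats::setNames(rep(0L, 10), net$genes)
  st[c("Rb", "p27", "Cdh1")] <- 1L
  s <- fbn_step(net, st)
  expect_identical(s$values, st)
  traj <- fbn_simulate(net, st, 10)
  expect_true(all(traj == st))
})

test_that("trajectories have the requested length and start state", {
  net <- two_gene_fbn()
  traj <- fbn_simulate(net, c(A = 1, B = 0), 3)
  expect_identical(unname(traj), matrix(c(1L, 0L, 0L, 1L, 0L, 0L), 2))
  one <- fbn_simulate(net, c(A = 1, B = 1), 1)
  expect_identical(unname(one[, 1]), c(1L, 1L))
  expect_identical(ncol(one), 1L)
  expect_error(fbn_simulate(net, c(A = 1, B = 0), 0), "n_steps")
})

test_that("deterministic simulation is reproducible, stochastic under a seed", {
  net <- cell_cycle_fbn()
  init <- stats::setNames(as.integer(intToBits(357))[1:10], net$genes)
  expect_identical(fbn_simulate(net, init, 20), fbn_simulate(net, init, 20))

  noisy <- fbn(c("A", "B"),
               list(fbn_function("B", "activation", c(A = TRUE), confidence = 0.5),
                    fbn_function("A", "activation", c(A = TRUE), confidence = 1)))
  t1 <- fbn_simulate(noisy, c(A = 1, B = 0), 30, seed = 9)
  t2 <- fbn_simulate(noisy, c(A = 1, B = 0), 30, seed = 9)
  expect_identical(t1, t2)
})

test_that("inhibition dominates activation on random networks and states", {
  for (seed in 1:10) {
    net <- decomposed_fbn(random_rules(4, seed = 300 + seed))
    set.seed(seed)
    st <- stats::setNames(sample(0:1, 4, replace = TRUE), net$genes)
    nxt <- fbn_step(net, st)
    env <- as.list(st == 1L)
    fires <- function(f) all(vapply(names(f$inputs), function(g) {
      env[[g]] == f$inputs[[g]]
    }, logical(1)))
    for (g in net$genes) {
      if (any(vapply(net$inhibitors[[g]], fires, logical(1)))) {
        expect_identical(nxt$values[[g]], 0L,
                         info = sprintf("seed %d gene %s", seed, g))
      }
    }
  }
})

test_that("an untouched gene stays on for exactly the decay window", {
  for (theta in 1:3) {
    net <- fbn("A", list(), decay = theta)
    traj <- fbn_simulate(net, c(A = 1), theta + 2L)
    expect_identical(unname(traj[1, ]),
                     c(rep(1L, theta), rep(0L, 2L)), info = paste("theta", theta))
  }
})

test_that("reconstruction reproduces series generated by the same network", {
  net <- two_gene_fbn()
  series <- generate_timeseries(net, exhaustive_initial_states(c("A", "B")), 4)
  recon <- reconstruct_timeseries(net, series)
  expect_identical(recon$samples, series$samples)

  one <- boolean_timeseries(list(matrix(c(1L, 0L), 2,
                                        dimnames = list(c("A", "B"), NULL))))
  expect_identical(reconstruct_timeseries(net, one)$samples, one$samples)
})

test_that("decomposed FBNs reproduce the compressed rules' trajectories", {
  for (seed in 1:10) {
    rules <- random_rules(4, seed = 500 + seed)
    net <- decomposed_fbn(rules)
    inits <- exhaustive_initial_states(rules$genes)
    expect_identical(generate_timeseries(net, inits, 6)$samples,
                     generate_timeseries(rules, inits, 6)$samples,
                     info = paste("seed", seed))
  }
})

test_that("hidden intermediate steps are recovered from state pairs", {
  net <- two_gene_fbn()
  expect_identical(infer_hidden_steps(net, c(A = 1, B = 0), c(A = 0, B = 1)),
                   list())
  hid <- infer_hidden_steps(net, c(A = 1, B = 0), c(A = 0, B = 0))
  expect_length(hid, 1L)
  expect_identical(unname(hid[[1]]), c(0L, 1L))
  expect_null(infer_hidden_steps(net, c(A = 0, B = 0), c(A = 1, B = 1),
                                 max_steps = 5))
  cc <- cell_cycle_fbn()
  fp <- stats::setNames(rep(0L, 10), cc$genes)
  fp[c("Rb", "p27", "Cdh1")] <- 1L
  expect_identical(infer_hidden_steps(cc, fp, fp), list())
})

test_that("attractor cycles are closed under the update", {
  net <- cell_cycle_fbn()
  at <- find_attractors(net)
  for (a in at) {
    k <- ncol(a$states)
    for (j in seq_len(k)) {
      nxt <- fbn_step(net, a$states[, j])
      expect_identical(unname(nxt$values), unname(a$states[, (j %% k) + 1L]))
    }
  }
  expect_identical(sum(vapply(at, `[[`, 0L, "basin")), 1024L)
})

test_that("the two-gene network has a single all-off fixed point", {
  at <- find_attractors(two_gene_fbn())
  expect_length(at, 1L)
  expect_identical(at[[1]]$kind, "fixed-point")
  expect_identical(unname(at[[1]]$states[, 1]), c(0L, 0L))
  expect_identical(at[[1]]$basin, 4L)
})

test_that("stochastic networks are rejected where determinism is required", {
  noisy <- fbn(c("A", "B"),
               list(fbn_function("B", "activation", c(A = TRUE), confidence = 0.5)))
  expect_error(find_attractors(noisy), "deterministic")
  expect_error(infer_hidden_steps(noisy, c(A = 1, B = 0), c(A = 0, B = 0)),
               "deterministic")
})

test_that("per-function time steps beyond 1 are stored but not simulated", {
  f <- fbn_function("A", "activation", c(A = TRUE), timestep = 2L)
  net <- fbn("A", list(f))
  expect_identical(net$activators$A[[1]]$timestep, 2L)
  expect_error(fbn_simulate(net, c(A = 1), 3), "timestep = 1")
})
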