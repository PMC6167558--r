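#' Protein decay gate
#'
#' In the fundamental Boolean model an unregulated gene does not switch off
#' immediately: it persists within a tolerated decay window. The gate keeps a
#' gene on at `t + 1` when it was on at `t` and the number of steps since a
#' fundamental function last affected it is still inside the window. The
#' counter `tau` is incremented before the gate is evaluated, so `tau >= 1`
#' here; with `theta = 1` an unrefreshed gene turns off at the next step, with
#' `theta = 2` it persists exactly one extra step.
#'
#' @param prev_value the gene's Boolean state at `t` (0/1 or logical).
#' @param tau steps elapsed since the last function effect, after the
#'   increment for the current transition.
#' @param theta positive integer decay window \eqn{\vartheta}.
#' @return logical: the decay contribution to the state at `t + 1`.
#' @export
decay_gate <- function(prev_value, tau, theta) {
  theta <- as.integer(theta)
  if (is.na(theta) || theta < 1L) {
    stop("decay window theta must be a positive integer", call. = FALSE)
  }
  as.logical(prev_value) & (tau < theta)
}

#' Stochastic confidence gate
#'
#' A fundamental function with confidence `c` fires only with probability `c`
#' when its condition is met: the gate passes iff a uniform draw `mu` is below
#' `c`. With confidence 1 the gate always passes.
#'
#' @param confidence real in `[0, 1]`.
#' @param mu uniform random draw(s) in `[0, 1)`.
#' @return logical vector, `TRUE` where `mu < confidence`.
#' @export
stochastic_gate <- function(confidence, mu) {
  if (any(is.na(confidence)) || any(confidence < 0) || any(confidence > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  mu < confidence
}

# Compiled view of an FBN for the simulation engine: per gene, the function
# list with input column indices, polarities and confidences.
compile_fbn <- function(net) {
  gidx <- stats::setNames(seq_along(net$genes), net$genes)
  compile_one <- function(f) {
    list(idx = unname(gidx[names(f$inputs)]),
         pol = as.integer(unname(f$inputs)),
         confidence = f$confidence)
  }
  stochastic <- FALSE
  for (f in fbn_all_functions(net)) {
    if (f$timestep != 1L) {
      stop("the synchronous engine supports timestep = 1 only", call. = FALSE)
    }
    if (f$confidence < 1) stochastic <- TRUE
  }
  list(genes = net$genes,
       theta = net$decay,
       stochastic = stochastic,
       activators = lapply(net$activators, function(fs) lapply(fs, compile_one)),
       inhibitors = lapply(net$inhibitors, function(fs) lapply(fs, compile_one)))
}

# One synchronous ensemble transition. S: n x genes integer matrix of values;
# C: n x genes integer counter matrix. Returns list(S, C). Random draws (one
# uniform vector per stochastic function, consumed in network order,
# activators before inhibitors) come from R's RNG stream.
fbn_ensemble_step <- function(cm, S, C) {
  n <- nrow(S)
  g <- length(cm$genes)
  Snew <- matrix(0L, n, g)
  Cnew <- matrix(0L, n, g)
  fires <- function(fun) {
    v <- rep(TRUE, n)
    for (j in seq_along(fun$idx)) {
      v <- v & (S[, fun$idx[j]] == fun$pol[j])
    }
    if (fun$confidence < 1) {
      v <- v & stochastic_gate(fun$confidence, stats::runif(n))
    }
    v
  }
  for (i in seq_len(g)) {
    act <- rep(FALSE, n)
    for (fun in cm$activators[[i]]) act <- act | fires(fun)
    inh <- rep(FALSE, n)
    any_fire <- act
    for (fun in cm$inhibitors[[i]]) {
      v <- fires(fun)
      inh <- inh | v
      any_fire <- any_fire | v
    }
    tau <- C[, i] + 1L
    decay <- (S[, i] == 1L) & (tau < cm$theta)
    Snew[, i] <- as.integer((decay | act) & !inh)
    Cnew[, i] <- ifelse(any_fire, 0L, pmin(tau, cm$theta))
  }
  list(S = Snew, C = Cnew)
}

# Ensemble simulation; returns n x genes x n_steps integer array of values.
# Initial counters are 0 (the initial observation is treated as a fresh
# function effect).
fbn_simulate_ensemble <- function(net, initial_states, n_steps, seed = NULL) {
  cm <- compile_fbn(net)
  S <- align_states(initial_states, net$genes)
  if (cm$stochastic && !is.null(seed)) set.seed(seed)
  n <- nrow(S)
  C <- matrix(0L, n, length(cm$genes))
  arr <- array(0L, dim = c(n, length(cm$genes), n_steps),
               dimnames = list(NULL, cm$genes, NULL))
  arr[, , 1L] <- S
  if (n_steps > 1L) {
    for (s in 2L:n_steps) {
      st <- fbn_ensemble_step(cm, S, C)
      S <- st$S
      C <- st$C
      arr[, , s] <- S
    }
  }
  arr
}

#' One synchronous step of the fundamental Boolean model
#'
#' Applies the FBM update to every gene simultaneously: a function fires iff
#' all its input literals are satisfied by the current values and its
#' confidence gate passes; the next value is
#' `(decay_gate OR any activator fires) AND NOT (any inhibitor fires)` --
#' inhibition dominates activation. Counters reset to 0 for genes where at
#' least one function (of either kind) fired, and increment (saturating at
#' the decay window) otherwise.
#'
#' @param net an [fbn()] object.
#' @param state named 0/1 vector of gene values, or a list with elements
#'   `values` and `counters` (as returned by this function).
#' @param seed optional seed for the confidence gates of a stochastic network.
#' @return a list with `values` (named integer vector) and `counters` (named
#'   integer vector).
#' @export
fbn_step <- function(net, state, seed = NULL) {
  stopifnot(inherits(net, "fbn"))
  cm <- compile_fbn(net)
  if (is.list(state) && !is.null(state$values)) {
    values <- state$values
    counters <- state$counters
  } else {
    values <- state
    counters <- stats::setNames(rep(0L, length(net$genes)), net$genes)
  }
  S <- align_states(matrix(values, nrow = 1L,
                           dimnames = list(NULL, names(values))), net$genes)
  C <- matrix(as.integer(counters[net$genes]), nrow = 1L)
  if (cm$stochastic && !is.null(seed)) set.seed(seed)
  st <- fbn_ensemble_step(cm, S, C)
  list(values = stats::setNames(st$S[1L, ], net$genes),
       counters = stats::setNames(st$C[1L, ], net$genes))
}

#' Simulate a trajectory of the fundamental Boolean model
#'
#' @param net an [fbn()] object.
#' @param initial named 0/1 vector of initial gene values; initial counters
#'   are 0.
#' @param n_steps trajectory length, including the initial state.
#' @param seed optional seed (stochastic networks).
#' @return an integer matrix (genes x n_steps) with gene row names.
#' @examples
#' net <- parse_fbn(paste(
#'   "Multiple Transition Functions for A with decay value = 1:",
#'   "A_1_Inhibitor: A = B (Confidence: 1, TimeStep: 1)",
#'   "Multiple Transition Functions for B with decay value = 1:",
#'   "B_1_Activator: B = A (Confidence: 1, TimeStep: 1)", sep = "\n"))
#' fbn_simulate(net, c(A = 1, B = 0), 3)
#' @export
fbn_simulate <- function(net, initial, n_steps, seed = NULL) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  arr <- fbn_simulate_ensemble(net, matrix(initial, nrow = 1L,
                                           dimnames = list(NULL, names(initial))),
                               n_steps, seed = seed)
  matrix(as.integer(arr[1L, , ]), nrow = length(net$genes),
         dimnames = list(net$genes, NULL))
}

#' Reconstruct a Boolean time series with an FBN
#'
#' For each sample, simulates from that sample's first time-step state for the
#' sample's length, producing a series of identical shape. With a correctly
#' inferred deterministic network the reconstruction reproduces the input.
#'
#' @param net an [fbn()] whose gene universe covers the series' genes.
#' @param series a [boolean_timeseries()].
#' @param seed optional seed (stochastic networks).
#' @return a [boolean_timeseries()] over the series' genes.
#' @export
reconstruct_timeseries <- function(net, series, seed = NULL) {
  stopifnot(inherits(net, "fbn"), inherits(series, "boolean_timeseries"))
  if (!length(series$samples)) stop("empty series", call. = FALSE)
  missing <- setdiff(series$genes, net$genes)
  if (length(missing)) {
    stop(sprintf("network lacks series gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lens <- vapply(series$samples, ncol, 0L)
  inits <- t(vapply(series$samples, function(m) m[, 1L], integer(length(series$genes))))
  colnames(inits) <- series$genes
  if (length(setdiff(net$genes, series$genes))) {
    # genes absent from the series start off
    extra <- setdiff(net$genes, series$genes)
    inits <- cbind(inits, matrix(0L, nrow(inits), length(extra),
                                 dimnames = list(NULL, extra)))
  }
  arr <- fbn_simulate_ensemble(net, inits, max(lens), seed = seed)
  samples <- lapply(seq_along(lens), function(k) {
    m <- matrix(as.integer(arr[k, , seq_len(lens[k])]), nrow = length(net$genes),
                dimnames = list(net$genes, NULL))
    m[series$genes, , drop = FALSE]
  })
  boolean_timeseries(samples, genes = series$genes)
}

#' Infer hidden time steps between two observed states
#'
#' In sparse time series the gap between two observed states may hide
#' intermediate states. Starting from `state_a`, the deterministic FBM is
#' iterated until the generated state equals `state_b`; the states strictly
#' between them are returned.
#'
#' @param net a deterministic [fbn()] (all confidences 1).
#' @param state_a,state_b named 0/1 vectors.
#' @param max_steps maximum number of transitions to try.
#' @return a list of named integer vectors (empty if `state_b` is the
#'   immediate successor of `state_a`), or `NULL` if `state_b` is not reached
#'   within `max_steps`.
#' @export
infer_hidden_steps <- function(net, state_a, state_b, max_steps = 50L) {
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L) {
    stop("max_steps must be >= 1", call. = FALSE)
  }
  cm <- compile_fbn(net)
  if (cm$stochastic) {
    stop("hidden-step inference requires a deterministic network (all confidences 1)",
         call. = FALSE)
  }
  traj <- fbn_simulate(net, state_a, max_steps + 1L)
  target <- as.integer(state_b[net$genes])
  for (s in 2L:(max_steps + 1L)) {
    if (all(traj[, s] == target)) {
      if (s == 2L) return(list())
      return(lapply(2L:(s - 1L), function(j) {
        stats::setNames(traj[, j], net$genes)
      }))
    }
  }
  NULL
}

#' Enumerate attractors of a deterministic FBN
#'
#' Iterates the synchronous FBM update from each initial state over the
#' extended state space (gene values plus decay counters, counters saturated
#' at the decay window -- the value vector alone is non-Markovian when the
#' window exceeds one step) until a repeat, records the cycle projected to
#' gene values, and deduplicates attractors up to rotation. Basin sizes count
#' the initial states reaching each attractor and sum to the number of
#' initial states.
#'
#' @param net a deterministic [fbn()] (all confidences 1).
#' @param initial_states matrix of initial states (rows = states, named
#'   columns); defaults to all `2^n` states.
#' @return an object of class `fbn_attractors`: a list of attractors, each
#'   with `states` (genes x cycle-length integer matrix), `kind`
#'   (`"fixed-point"` or `"cycle"`) and `basin` (count).
#' @export
find_attractors <- function(net, initial_states = NULL) {
  stopifnot(inherits(net, "fbn"))
  cm <- compile_fbn(net)
  if (cm$stochastic) {
    stop("attractors are defined for deterministic networks (all confidences 1)",
         call. = FALSE)
  }
  if (is.null(initial_states)) {
    initial_states <- exhaustive_initial_states(net$genes)
  }
  S <- align_states(initial_states, net$genes)
  n <- nrow(S)
  C <- matrix(0L, n, length(net$genes))
  key_of <- function(S, C) {
    paste(apply(S, 1L, paste, collapse = ""),
          apply(C, 1L, paste, collapse = ","), sep = "|")
  }
  history_keys <- list(key_of(S, C))
  history_vals <- list(S)
  open <- rep(TRUE, n)
  first_rep <- rep(NA_integer_, n)   # index in history where the repeat starts
  rep_step <- rep(NA_integer_, n)    # step at which the repeat was seen
  step <- 1L
  while (any(open)) {
    st <- fbn_ensemble_step(cm, S, C)
    S <- st$S
    C <- st$C
    step <- step + 1L
    keys <- key_of(S, C)
    for (k in which(open)) {
      prev <- match(keys[k], vapply(history_keys, `[`, "", k))
      if (!is.na(prev)) {
        first_rep[k] <- prev
        rep_step[k] <- step
        open[k] <- FALSE
      }
    }
    history_keys[[step]] <- keys
    history_vals[[step]] <- S
    if (step > 2L^(length(net$genes)) * (net$decay + 1L) + 2L) {
      stop("attractor search exceeded the extended state space bound", call. = FALSE)
    }
  }
  attractors <- list()
  seen <- character(0)
  basin <- integer(0)
  for (k in seq_len(n)) {
    cycle_idx <- first_rep[k]:(rep_step[k] - 1L)
    states <- vapply(cycle_idx, function(s) history_vals[[s]][k, ],
                     integer(length(net$genes)))
    states <- matrix(states, nrow = length(net$genes),
                     dimnames = list(net$genes, NULL))
    # canonical rotation: start at the lexicographically smallest state
    skeys <- apply(states, 2L, paste, collapse = "")
    start <- which.min(skeys)
    ord <- c(start:ncol(states), seq_len(start - 1L))
    states <- states[, ord, drop = FALSE]
    ckey <- paste(apply(states, 2L, paste, collapse = ""), collapse = ">")
    at <- match(ckey, seen)
    if (is.na(at)) {
      seen <- c(seen, ckey)
      basin <- c(basin, 1L)
      attractors[[length(attractors) + 1L]] <- list(
        states = states,
        kind = if (ncol(states) == 1L) "fixed-point" else "cycle",
        basin = 1L)
    } else {
      basin[at] <- basin[at] + 1L
      attractors[[at]]$basin <- basin[at]
    }
  }
  structure(attractors, class = "fbn_attractors",
            n_initial_states = n)
}

#' @export
print.fbn_attractors <- function(x, ...) {
  cat(sprintf("%d attractor(s) from %d initial state(s)\n", length(x),
              attr(x, "n_initial_states")))
  for (i in seq_along(x)) {
    a <- x[[i]]
    on_genes <- apply(a$states, 2L, function(v) {
      g <- rownames(a$states)[v == 1L]
      if (length(g)) paste(g, collapse = ",") else "-"
    })
    cat(sprintf("  [%d] %s of length %d, basin %d: %s\n", i, a$kind,
                ncol(a$states), a$basin, paste(on_genes, collapse = " -> ")))
  }
  invisible(x)
}
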