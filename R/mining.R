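#' Mining configuration
#'
#' Thresholds and caps used to extract a fundamental Boolean network from an
#' orchard cube.
#'
#' @param confidence_threshold a candidate's confidence must exceed this
#'   (default 0.7; lower it for noisy data).
#' @param mi_threshold threshold in `[0, 1]` for the mutual-information test
#'   (see [mine_network()]); the default 1 requires fully deterministic
#'   rules, appropriate for noiseless series, and is relaxed for noisy data.
#' @param causality_min minimum conditional causality ratio (default 1).
#' @param max_functions cap `F_n` on the number of functions per (target,
#'   kind), default 5.
#' @param decay decay window attached to the mined network, default 1.
#' @param timestep time step attached to mined functions, default 1.
#' @return a list of class `mining_config`.
#' @export
mining_config <- function(confidence_threshold = 0.7, mi_threshold = 1,
                          causality_min = 1, max_functions = 5L,
                          decay = 1L, timestep = 1L) {
  if (mi_threshold < 0 || mi_threshold > 1) {
    stop("mi_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (max_functions < 1L) stop("max_functions must be >= 1", call. = FALSE)
  structure(list(confidence_threshold = confidence_threshold,
                 mi_threshold = mi_threshold,
                 causality_min = causality_min,
                 max_functions = as.integer(max_functions),
                 decay = as.integer(decay),
                 timestep = as.integer(timestep)),
            class = "mining_config")
}

# parse "A=1&B=0" condition strings back into literal vectors
condition_to_literals <- function(condition) {
  parts <- strsplit(condition, "&", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- vapply(kv, function(p) p[2L] == "1", logical(1))
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}

#' Extract, filter and rank candidate functions from an orchard cube
#'
#' Applies the mining criteria to every cube dimension record:
#' \enumerate{
#'   \item conditional causality ratio at least `causality_min`;
#'   \item mutual-information test at least `mi_threshold`. The test value is
#'     the determinism score `1 - H2(confidence)` (binary entropy of the
#'     rule's conditional outcome distribution): exactly 1 when the condition
#'     determines the outcome without residual uncertainty, as every rule
#'     does on noiseless data, and below 1 in proportion to noise;
#'   \item essentiality: a candidate whose deepest literal can be flipped
#'     without changing the dimension's confidence (exact rational comparison
#'     of counts) is non-essential and discarded together with its sibling --
#'     the shorter prefix carries the same information;
#'   \item confidence strictly above `confidence_threshold`;
#'   \item subsumption: a candidate whose literal set strictly contains a
#'     surviving candidate's set with identical confidence is dropped;
#'   \item stable sort by mutual information (descending), error (ascending),
#'     support (descending) and input size (ascending), lexicographic
#'     condition tie-break; each (target, kind) list is truncated to
#'     `max_functions`.
#' }
#' Dimensions predicting outcome 1 become activation candidates, outcome 0
#' inhibition candidates.
#'
#' @param cube an [build_cube()] result.
#' @param config a [mining_config()].
#' @param cap truncate each (target, kind) list to `max_functions`
#'   (default TRUE).
#' @return a data.frame of surviving candidates with their measures.
#' @export
mine_candidates <- function(cube, config = mining_config(), cap = TRUE) {
  stopifnot(inherits(cube, "orchard_cube"))
  out <- lapply(cube$targets, function(tg) {
    tree <- cube$trees[[tg]]
    nd <- tree$nodes
    if (!nrow(nd)) return(NULL)
    # essentiality on exact counts: equal conditional distribution across the
    # sibling polarity pair (a1/n1 == a0/n0 cross-multiplied); only decidable
    # when both branches carry transitions
    essential <- !(nd$n1 > 0L & nd$n0 > 0L &
                     nd$a1 * nd$n0 == nd$a0 * nd$n1)
    mm <- cube_measures(cube, tg)
    mm$essential <- rep(essential, 4L)
    mm <- mm[mm$matched > 0L & mm$co_occurrence > 0L, , drop = FALSE]
    mm <- mm[mm$essential &
               mm$causality >= config$causality_min &
               (1 - binary_entropy(mm$confidence)) >= config$mi_threshold - 1e-12 &
               mm$confidence > config$confidence_threshold, , drop = FALSE]
    if (!nrow(mm)) return(NULL)
    mm$kind <- ifelse(mm$outcome == 1L, "activation", "inhibition")
    mm$n_literals <- mm$depth
    mm$key <- vapply(mm$condition,
                     function(s) term_key(condition_to_literals(s)), "")
    mm
  })
  cand <- do.call(rbind, out)
  if (is.null(cand) || !nrow(cand)) {
    return(cand)
  }
  # subsumption within (target, kind): shortest first
  kept <- logical(nrow(cand))
  for (grp in split(seq_len(nrow(cand)),
                    paste(cand$target, cand$kind, sep = "\r"))) {
    grp <- grp[order(cand$n_literals[grp], cand$key[grp])]
    kept_lits <- list()
    kept_conf <- numeric(0)
    for (i in grp) {
      lits <- condition_to_literals(cand$condition[i])
      dominated <- FALSE
      for (j in seq_along(kept_lits)) {
        k <- kept_lits[[j]]
        if (length(k) < length(lits) && all(names(k) %in% names(lits)) &&
            all(k == lits[names(k)]) &&
            abs(kept_conf[j] - cand$confidence[i]) < 1e-12) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) {
        kept[i] <- TRUE
        kept_lits[[length(kept_lits) + 1L]] <- lits
        kept_conf <- c(kept_conf, cand$confidence[i])
      }
    }
  }
  cand <- cand[kept, , drop = FALSE]
  # rank
  o <- order(cand$target, cand$kind, -cand$mutual_information, cand$error,
             -cand$support, cand$n_literals, cand$key)
  cand <- cand[o, , drop = FALSE]
  if (cap) {
    keep <- unlist(lapply(split(seq_len(nrow(cand)),
                                paste(cand$target, cand$kind, sep = "\r")),
                          function(idx) utils::head(idx, config$max_functions)))
    cand <- cand[sort(keep), , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Mine a fundamental Boolean network from an orchard cube
#'
#' Assembles an [fbn()] over the cube's gene universe from the candidates
#' surviving [mine_candidates()], attaching each function's confidence and
#' support measured on the training transitions, the configured time step,
#' and the configured network decay window. A target whose next state is
#' constant 1 over all transitions has no essential candidate (every polarity
#' pair is equally predictive), so it receives the pair of self-literal
#' activation rules that keeps it on; a constant-0 target is left rule-less
#' and is governed by decay.
#'
#' @param cube an [build_cube()] result.
#' @param config a [mining_config()].
#' @return a validated [fbn()].
#' @export
mine_network <- function(cube, config = mining_config()) {
  stopifnot(inherits(cube, "orchard_cube"))
  if (!length(cube$trees) ||
      all(vapply(cube$trees, function(tr) nrow(tr$nodes), 0L) == 0L)) {
    stop("empty cube: no nodes to mine", call. = FALSE)
  }
  cand <- mine_candidates(cube, config, cap = TRUE)
  functions <- list()
  if (!is.null(cand) && nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      functions[[length(functions) + 1L]] <- fbn_function(
        target = cand$target[i],
        kind = cand$kind[i],
        inputs = condition_to_literals(cand$condition[i]),
        confidence = cand$confidence[i],
        support = cand$support[i],
        timestep = config$timestep)
    }
  }
  # constant-on targets: keep them on with the self-literal pair
  for (tg in cube$targets) {
    tree <- cube$trees[[tg]]
    if (tree$pos == cube$aleph) {
      has_act <- any(vapply(functions, function(f) {
        f$target == tg && f$kind == "activation"
      }, logical(1)))
      if (!has_act) {
        message(sprintf("target '%s' is constant-on; adding self-literal activators", tg))
        for (pol in c(TRUE, FALSE)) {
          functions[[length(functions) + 1L]] <- fbn_function(
            target = tg, kind = "activation",
            inputs = structure(pol, names = tg),
            confidence = 1,
            support = if (pol) tree$ct1 / cube$aleph else tree$ct0 / cube$aleph,
            timestep = config$timestep)
        }
      }
    }
  }
  net <- fbn(genes = cube$genes, functions = functions, decay = config$decay)
  bad <- validate_network(net)
  if (length(bad)) {
    stop(paste(c("mined network failed validation:", bad), collapse = "\n  "),
         call. = FALSE)
  }
  net
}
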