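## Orchard cube: per-target prefix trees of conditional-gene nodes carrying
## the four-dimension (TT/TF/FT/FF) measure records over a Boolean time
## series' transitions.

# resolve a condition (named logical vector of literals) to row indicators
condition_rows <- function(X, condition, genes) {
  unknown <- setdiff(names(condition), genes)
  if (length(unknown)) {
    stop(sprintf("unknown gene(s) in condition: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  v <- rep(TRUE, nrow(X))
  for (j in seq_along(condition)) {
    v <- v & (X[, match(names(condition)[j], genes)] == as.integer(condition[j]))
  }
  v
}

#' Confidence measure of a candidate regulatory condition
#'
#' The conditional probability that the target gene takes `outcome` at
#' `t + 1` given that the condition (a conjunction of gene literals) held at
#' `t`, counted over all within-sample transitions.
#'
#' @param series a [boolean_timeseries()].
#' @param target target gene name.
#' @param condition named logical vector of literals (`TRUE` = gene on).
#' @param outcome target outcome at `t + 1` (1/TRUE for activation-style,
#'   0/FALSE for inhibition-style).
#' @return a list with `confidence` (0 when no transition matches, flagged via
#'   `matched`), `matched` (transitions where the condition held at `t`) and
#'   `co_occurrence` (of those, transitions where the target took `outcome`).
#' @export
confidence_measure <- function(series, target, condition, outcome) {
  tr <- series_transitions(series)
  if (!target %in% series$genes) {
    stop(sprintf("unknown target gene '%s'", target), call. = FALSE)
  }
  cond <- condition_rows(tr$X0, condition, series$genes)
  y <- tr$X1[, match(target, series$genes)] == as.integer(as.logical(outcome))
  matched <- sum(cond)
  co <- sum(cond & y)
  list(confidence = if (matched > 0L) co / matched else 0,
       matched = matched, co_occurrence = co)
}

#' Counter-confidence measure (reverse-direction conditional probability)
#'
#' The probability that the condition holds at `t + 1` given the target was
#' already in the outcome-consistent state at `t` (on for activation-style
#' candidates, off for inhibition-style). Used as the denominator of the
#' conditional causality test.
#'
#' @inheritParams confidence_measure
#' @param kind `"activation"` (target on at `t`) or `"inhibition"` (target
#'   off at `t`).
#' @return the conditional probability (0 when the denominator is 0).
#' @export
counter_confidence_measure <- function(series, target, condition,
                                       kind = c("activation", "inhibition")) {
  kind <- match.arg(kind)
  tr <- series_transitions(series)
  if (!target %in% series$genes) {
    stop(sprintf("unknown target gene '%s'", target), call. = FALSE)
  }
  cond_t1 <- condition_rows(tr$X1, condition, series$genes)
  y0 <- tr$X0[, match(target, series$genes)] == (if (kind == "activation") 1L else 0L)
  denom <- sum(y0)
  if (denom == 0L) return(0)
  sum(cond_t1 & y0) / denom
}

#' Support measure of a candidate condition
#'
#' The fraction of all \eqn{\aleph} transitions where the condition held at
#' `t` and the target took `outcome` at `t + 1`.
#'
#' @inheritParams confidence_measure
#' @return real in `[0, 1]`.
#' @export
support_measure <- function(series, target, condition, outcome) {
  cm <- confidence_measure(series, target, condition, outcome)
  cm$co_occurrence / transition_count(series)
}

#' Conditional causality test
#'
#' The ratio of the confidence measure to the counter-confidence measure. A
#' value of at least 1 supports the condition-to-target regulatory direction;
#' below 1, the causal hypothesis is rejected. By convention the ratio is
#' `+Inf` when the counter-confidence is 0 but the confidence is positive,
#' and 0 when both are 0.
#'
#' @param confidence,counter_confidence reals in `[0, 1]`.
#' @return the ratio (possibly `Inf`).
#' @export
causality_test <- function(confidence, counter_confidence) {
  if (any(c(confidence, counter_confidence) < 0) ||
      any(c(confidence, counter_confidence) > 1)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(counter_confidence == 0,
         ifelse(confidence > 0, Inf, 0),
         confidence / counter_confidence)
}

#' Shannon entropy of a Boolean sequence (bits)
#'
#' @param x logical or 0/1 vector.
#' @return base-2 entropy with the `0 log 0 = 0` convention.
#' @export
shannon_entropy <- function(x) {
  if (!length(x)) stop("sequence must be non-empty", call. = FALSE)
  p <- mean(as.logical(x))
  binary_entropy(p)
}

binary_entropy <- function(p) {
  h <- function(q) ifelse(q > 0, -q * log2(q), 0)
  h(p) + h(1 - p)
}

#' Mutual information between two Boolean sequences (bits)
#'
#' `M(X, Y) = H(Y) - H(Y|X)`; symmetric and non-negative. The output state of
#' `X` is fully determined by `Y` when `M(X, Y) = H(X)`.
#'
#' @param x,y logical or 0/1 vectors of equal length.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (!length(x)) stop("sequences must be non-empty", call. = FALSE)
  x <- as.logical(x)
  y <- as.logical(y)
  n <- length(x)
  mi_from_counts(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
}

# plug-in MI (bits) from the 2x2 contingency counts
mi_from_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0L) return(0)
  term <- function(nij, ni, nj) {
    if (nij == 0) return(0)
    (nij / n) * log2((nij * n) / (ni * nj))
  }
  term(a, a + b, a + c) + term(b, a + b, b + d) +
    term(c, c + d, a + c) + term(d, c + d, b + d)
}

#' Chi-square screening of candidate conditional genes
#'
#' For each gene, builds the 2x2 contingency table of the gene's state at `t`
#' against the target's state at `t + 1` over all transitions and keeps the
#' gene iff Pearson's chi-square test (without continuity correction) gives
#' `p <= alpha`. Genes with a degenerate table (a zero-variance row or
#' column) are pruned with a warning. The target itself is among the tested
#' genes, so self-regulation remains discoverable.
#'
#' @param series a [boolean_timeseries()].
#' @param target target gene name.
#' @param alpha significance level (default 0.05).
#' @return character vector of retained candidate genes.
#' @export
chi_square_prune <- function(series, target, alpha = 0.05) {
  tr <- series_transitions(series)
  chi_square_prune_tr(tr$X0, tr$X1, series$genes, target, alpha)
}

chi_square_prune_tr <- function(X0, X1, genes, target, alpha) {
  ti <- match(target, genes)
  if (is.na(ti)) stop(sprintf("unknown target gene '%s'", target), call. = FALSE)
  y <- X1[, ti]
  keep <- character(0)
  for (j in seq_along(genes)) {
    x <- X0[, j]
    tab <- matrix(c(sum(x == 0L & y == 0L), sum(x == 0L & y == 1L),
                    sum(x == 1L & y == 0L), sum(x == 1L & y == 1L)),
                  nrow = 2L, byrow = TRUE)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      warning(sprintf("gene '%s' pruned for target '%s': degenerate contingency table",
                      genes[j], target), call. = FALSE)
      next
    }
    p <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
    if (!is.na(p) && p <= alpha) keep <- c(keep, genes[j])
  }
  keep
}

#' Build the orchard cube
#'
#' Constructs one prefix tree per target gene over the series' transitions.
#' Level-1 children are the chi-square survivors; each node fixes one
#' conditional gene beyond its prefix (candidate genes expand in ascending
#' gene order only, so a literal set is computed once, never per permutation)
#' and stores the exact transition counts behind the four TT/TF/FT/FF
#' dimension records. Counting is bottom-up: each node only scans the
#' transition subset matched by its parent. Expansion stops at depth `maxK`;
#' branches with no matched transitions at `t` or `t + 1` are not expanded.
#' Trees are independent, so any subset of targets yields identical nodes to
#' building all targets at once.
#'
#' @param series a [boolean_timeseries()].
#' @param maxK maximum condition depth (number of literals), default 4.
#' @param alpha chi-square screening level, default 0.05.
#' @param targets genes to build trees for (default: all).
#' @param n_jobs parallelism degree for the per-target loop (forked workers
#'   via the parallel package when > 1; results are identical to serial
#'   construction).
#' @return an object of class `orchard_cube`.
#' @export
build_cube <- function(series, maxK = 4L, alpha = 0.05, targets = NULL,
                       n_jobs = 1L) {
  stopifnot(inherits(series, "boolean_timeseries"))
  maxK <- as.integer(maxK)
  if (is.na(maxK) || maxK < 1L) stop("maxK must be >= 1", call. = FALSE)
  if (is.null(targets)) targets <- series$genes
  tr <- series_transitions(series)
  genes <- series$genes
  aleph <- nrow(tr$X0)
  build_target <- function(target) {
    survivors <- suppressWarnings(
      chi_square_prune_tr(tr$X0, tr$X1, genes, target, alpha))
    ti <- match(target, genes)
    y1 <- tr$X1[, ti]
    y0 <- tr$X0[, ti]
    pos <- sum(y1)
    ct1 <- sum(y0)
    ct0 <- aleph - ct1
    surv_idx <- match(survivors, genes)
    rows <- new.env(parent = emptyenv())
    rows$n <- 0L
    rows$lst <- vector("list", 256L)
    push <- function(row) {
      rows$n <- rows$n + 1L
      if (rows$n > length(rows$lst)) {
        rows$lst <- c(rows$lst, vector("list", length(rows$lst)))
      }
      rows$lst[[rows$n]] <- row
    }
    recurse <- function(prefix, start, idx_t, idx_t1, depth) {
      for (jj in start:length(surv_idx)) {
        if (start > length(surv_idx)) break
        gj <- surv_idx[jj]
        x_t <- tr$X0[idx_t, gj]
        i1 <- idx_t[x_t == 1L]
        i0 <- idx_t[x_t == 0L]
        x_t1 <- tr$X1[idx_t1, gj]
        j1 <- idx_t1[x_t1 == 1L]
        j0 <- idx_t1[x_t1 == 0L]
        n1 <- length(i1)
        a1 <- sum(y1[i1])
        n0 <- length(i0)
        a0 <- sum(y1[i0])
        m1a <- sum(y0[j1])
        m1d <- length(j1) - m1a
        m0a <- sum(y0[j0])
        m0d <- length(j0) - m0a
        push(list(gene = genes[gj], depth = depth, prefix = prefix,
                  n1 = n1, a1 = a1, n0 = n0, a0 = a0,
                  m1a = m1a, m1d = m1d, m0a = m0a, m0d = m0d))
        if (depth < maxK && jj < length(surv_idx)) {
          if (n1 > 0L || length(j1) > 0L) {
            recurse(c(prefix, paste0(genes[gj], "=1")), jj + 1L, i1, j1,
                    depth + 1L)
          }
          if (n0 > 0L || length(j0) > 0L) {
            recurse(c(prefix, paste0(genes[gj], "=0")), jj + 1L, i0, j0,
                    depth + 1L)
          }
        }
      }
      invisible(NULL)
    }
    if (length(surv_idx)) {
      recurse(character(0), 1L, seq_len(aleph), seq_len(aleph), 1L)
    }
    node_list <- rows$lst[seq_len(rows$n)]
    nodes <- data.frame(
      gene = vapply(node_list, `[[`, "", "gene"),
      depth = vapply(node_list, `[[`, 0L, "depth"),
      prefix = vapply(node_list, function(r) paste(r$prefix, collapse = "&"), ""),
      n1 = vapply(node_list, `[[`, 0L, "n1"),
      a1 = vapply(node_list, function(r) as.integer(r$a1), 0L),
      n0 = vapply(node_list, `[[`, 0L, "n0"),
      a0 = vapply(node_list, function(r) as.integer(r$a0), 0L),
      m1a = vapply(node_list, function(r) as.integer(r$m1a), 0L),
      m1d = vapply(node_list, function(r) as.integer(r$m1d), 0L),
      m0a = vapply(node_list, function(r) as.integer(r$m0a), 0L),
      m0d = vapply(node_list, function(r) as.integer(r$m0d), 0L),
      stringsAsFactors = FALSE)
    list(target = target, survivors = survivors, pos = pos, ct1 = ct1,
         ct0 = ct0, nodes = nodes)
  }
  if (n_jobs > 1L && .Platform$OS.type == "unix") {
    trees <- parallel::mclapply(targets, build_target, mc.cores = n_jobs)
  } else {
    trees <- lapply(targets, build_target)
  }
  names(trees) <- targets
  structure(list(genes = genes, targets = targets, maxK = maxK, alpha = alpha,
                 aleph = aleph, n_samples = length(series$samples),
                 trees = trees),
            class = "orchard_cube")
}

#' @export
print.orchard_cube <- function(x, ...) {
  n_nodes <- sum(vapply(x$trees, function(tr) nrow(tr$nodes), 0L))
  cat(sprintf("Orchard cube: %d target tree(s), %d node(s), maxK = %d, %d transitions\n",
              length(x$trees), n_nodes, x$maxK, x$aleph))
  invisible(x)
}

#' Derive the four dimension records of every cube node
#'
#' Expands each node's stored transition counts into the TT, TF, FT and FF
#' measure groups: for a node with prefix `P` and conditional gene `g`, TT is
#' the condition `P & g` with target outcome 1 at `t + 1`, TF is `P & !g`
#' with outcome 1, FT is `P & g` with outcome 0, and FF is `P & !g` with
#' outcome 0. Confidence is co-occurrence over matched transitions; support
#' divides by the total transition count; the error measure is the confidence
#' of the paired opposite-outcome dimension (1 - confidence); the causality
#' ratio divides confidence by the counter-confidence; mutual information (in
#' bits) relates the condition indicator at `t` to the target state at
#' `t + 1` over all transitions.
#'
#' @param cube an [build_cube()] result.
#' @param target a target gene (default: all targets, row-bound).
#' @return a data.frame with one row per (node, dimension).
#' @export
cube_measures <- function(cube, target = NULL) {
  stopifnot(inherits(cube, "orchard_cube"))
  targets <- if (is.null(target)) cube$targets else target
  out <- lapply(targets, function(tg) {
    tree <- cube$trees[[tg]]
    if (is.null(tree)) stop(sprintf("no tree for target '%s'", tg), call. = FALSE)
    nd <- tree$nodes
    if (!nrow(nd)) return(NULL)
    aleph <- cube$aleph
    pos <- tree$pos
    dim_rows <- function(label, matched, co, outcome, counter_num, counter_den,
                         polarity) {
      confidence <- ifelse(matched > 0L, co / matched, 0)
      counter <- if (counter_den > 0L) counter_num / counter_den
                 else rep(0, length(counter_num))
      tot_o <- if (outcome == 1L) pos else aleph - pos
      mi <- mapply(function(a, m) {
        mi_from_counts(a, m - a, tot_o - a, aleph - m - tot_o + a)
      }, co, matched)
      data.frame(
        target = tg, dim = label,
        condition = ifelse(nzchar(nd$prefix),
                           paste0(nd$prefix, "&", nd$gene, "=", polarity),
                           paste0(nd$gene, "=", polarity)),
        gene = nd$gene, depth = nd$depth, outcome = outcome,
        matched = matched, co_occurrence = co,
        confidence = confidence, error = 1 - confidence,
        support = co / aleph,
        counter_confidence = counter,
        causality = causality_test(confidence, counter),
        mutual_information = mi,
        zero_matched = matched == 0L,
        stringsAsFactors = FALSE)
    }
    rbind(
      dim_rows("TT", nd$n1, nd$a1, 1L, nd$m1a, tree$ct1, 1L),
      dim_rows("TF", nd$n0, nd$a0, 1L, nd$m0a, tree$ct1, 0L),
      dim_rows("FT", nd$n1, nd$n1 - nd$a1, 0L, nd$m1d, tree$ct0, 1L),
      dim_rows("FF", nd$n0, nd$n0 - nd$a0, 0L, nd$m0d, tree$ct0, 0L))
  })
  do.call(rbind, out)
}

#' Save an orchard cube as JSON lines
#'
#' Line 1 is a header object (schema `orchard-cube/1`: gene universe, maxK,
#' alpha, transition count, sample count, and per-target globals); every
#' following line is one node with its prefix path and exact counts, so the
#' cube can be reloaded and mined without rebuilding.
#'
#' @param cube an `orchard_cube`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_cube <- function(cube, file) {
  stopifnot(inherits(cube, "orchard_cube"))
  con <- file(file, open = "wt")
  on.exit(close(con))
  header <- list(schema = "orchard-cube/1", genes = cube$genes,
                 targets = cube$targets, maxK = cube$maxK, alpha = cube$alpha,
                 aleph = cube$aleph, n_samples = cube$n_samples,
                 globals = lapply(cube$trees, function(tr) {
                   list(survivors = tr$survivors, pos = tr$pos,
                        ct1 = tr$ct1, ct0 = tr$ct0)
                 }))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE), con)
  for (tg in cube$targets) {
    nd <- cube$trees[[tg]]$nodes
    for (i in seq_len(nrow(nd))) {
      writeLines(jsonlite::toJSON(c(list(target = tg), as.list(nd[i, ])),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(file)
}

#' Load an orchard cube written by [write_cube()]
#' @param file path to a cube JSON-lines file.
#' @return an `orchard_cube`.
#' @export
read_cube <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty cube file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[[1L]])
  if (!identical(header$schema, "orchard-cube/1")) {
    stop("unrecognized cube schema", call. = FALSE)
  }
  cols <- c("gene", "depth", "prefix", "n1", "a1", "n0", "a0",
            "m1a", "m1d", "m0a", "m0d")
  empty_nodes <- data.frame(gene = character(0), depth = integer(0),
                            prefix = character(0), n1 = integer(0),
                            a1 = integer(0), n0 = integer(0), a0 = integer(0),
                            m1a = integer(0), m1d = integer(0),
                            m0a = integer(0), m0d = integer(0),
                            stringsAsFactors = FALSE)
  trees <- lapply(header$targets, function(tg) {
    g <- header$globals[[tg]]
    list(target = tg, survivors = as.character(g$survivors), pos = g$pos,
         ct1 = g$ct1, ct0 = g$ct0, nodes = empty_nodes)
  })
  names(trees) <- header$targets
  if (length(lines) > 1L) {
    recs <- lapply(lines[-1L], jsonlite::fromJSON)
    tgts <- vapply(recs, `[[`, "", "target")
    for (tg in unique(tgts)) {
      sub <- recs[tgts == tg]
      trees[[tg]]$nodes <- do.call(rbind, lapply(sub, function(r) {
        as.data.frame(r[cols], stringsAsFactors = FALSE)
      }))
    }
  }
  structure(list(genes = as.character(header$genes),
                 targets = as.character(header$targets),
                 maxK = header$maxK, alpha = header$alpha,
                 aleph = header$aleph, n_samples = header$n_samples,
                 trees = trees),
            class = "orchard_cube")
}
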