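#' Construct a Boolean time-series collection
#'
#' The unit of training and evaluation: a set of samples, each a binary
#' genes-by-time matrix over a shared gene set. The transition count
#' \eqn{\aleph = \sum_i (t_i - 1)} counts the within-sample (t, t+1) pairs;
#' the first time step of each sample contributes no transition.
#'
#' @param samples a list of matrices (rows = genes, columns = time steps,
#'   entries 0/1). Row names must agree across samples; if absent, `genes`
#'   supplies them.
#' @param genes optional character vector of gene names.
#' @return an object of class `boolean_timeseries` with elements `genes` and
#'   `samples`.
#' @export
boolean_timeseries <- function(samples, genes = NULL) {
  if (!is.list(samples) || !length(samples)) {
    stop("samples must be a non-empty list of matrices", call. = FALSE)
  }
  samples <- lapply(samples, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  })
  if (is.null(genes)) genes <- rownames(samples[[1L]])
  if (is.null(genes)) {
    stop("gene names are required (row names or the genes argument)",
         call. = FALSE)
  }
  for (k in seq_along(samples)) {
    m <- samples[[k]]
    if (is.null(rownames(m))) {
      if (nrow(m) != length(genes)) {
        stop(sprintf("sample %d has %d rows but %d genes were given",
                     k, nrow(m), length(genes)), call. = FALSE)
      }
      rownames(m) <- genes
    } else if (!identical(rownames(m), genes)) {
      if (!setequal(rownames(m), genes)) {
        stop(sprintf("sample %d has a different gene set", k), call. = FALSE)
      }
      m <- m[genes, , drop = FALSE]
    }
    bad <- which(!(m %in% c(0L, 1L)) | is.na(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      stop(sprintf("sample %d: non-binary value at gene '%s', time step %d",
                   k, genes[rc[1L]], rc[2L]), call. = FALSE)
    }
    samples[[k]] <- m
  }
  structure(list(genes = genes, samples = samples), class = "boolean_timeseries")
}

#' Total transition count of a Boolean time series
#' @param series a [boolean_timeseries()].
#' @return integer \eqn{\aleph = \sum_i (t_i - 1)}.
#' @export
transition_count <- function(series) {
  stopifnot(inherits(series, "boolean_timeseries"))
  sum(vapply(series$samples, ncol, 0L) - 1L)
}

#' @export
print.boolean_timeseries <- function(x, ...) {
  cat(sprintf("Boolean time series: %d genes, %d sample(s), %d transitions\n",
              length(x$genes), length(x$samples), transition_count(x)))
  invisible(x)
}

# Stack all within-sample transitions: X0[r, ] is the state at t of transition
# r, X1[r, ] the state at t + 1. Columns follow series$genes.
series_transitions <- function(series) {
  g <- length(series$genes)
  x0 <- list()
  x1 <- list()
  for (m in series$samples) {
    tt <- ncol(m)
    if (tt < 2L) next
    tm <- t(m)
    x0[[length(x0) + 1L]] <- tm[seq_len(tt - 1L), , drop = FALSE]
    x1[[length(x1) + 1L]] <- tm[2L:tt, , drop = FALSE]
  }
  if (!length(x0)) stop("series has no transitions (all samples length 1)",
                        call. = FALSE)
  list(X0 = do.call(rbind, x0), X1 = do.call(rbind, x1))
}

#' Write a Boolean time series as tabular text
#'
#' One block per sample: a `# sample <k>` marker line, then one CSV row per
#' gene (`gene,s1,s2,...`), blocks separated by blank lines. Time-step labels
#' are 1-based.
#'
#' @param series a [boolean_timeseries()].
#' @param file output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(series, file, sep = ",") {
  stopifnot(inherits(series, "boolean_timeseries"))
  lines <- character(0)
  for (k in seq_along(series$samples)) {
    m <- series$samples[[k]]
    lines <- c(lines, sprintf("# sample %d", k),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(c(rownames(m)[i], m[i, ]), collapse = sep)
               }, ""),
               "")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a Boolean time series from tabular text
#'
#' Accepts the block layout written by [write_timeseries()] (blocks separated
#' by `# sample` markers and/or blank lines) in a single file, or a vector of
#' file paths with one sample per file.
#'
#' @param file path, or character vector of paths (one sample each).
#' @param sep field separator; auto-detected between comma and tab if `NULL`.
#' @return a [boolean_timeseries()].
#' @export
read_timeseries <- function(file, sep = NULL) {
  read_block <- function(lines, sep, origin) {
    parts <- strsplit(lines, sep, fixed = TRUE)
    genes <- vapply(parts, `[`, "", 1L)
    widths <- lengths(parts) - 1L
    if (length(unique(widths)) != 1L) {
      stop(sprintf("%s: rows have differing numbers of time steps", origin),
           call. = FALSE)
    }
    m <- matrix(NA_integer_, nrow = length(genes), ncol = widths[1L],
                dimnames = list(genes, NULL))
    for (i in seq_along(parts)) {
      v <- trimws(parts[[i]][-1L])
      if (any(!v %in% c("0", "1"))) {
        j <- which(!v %in% c("0", "1"))[1L]
        stop(sprintf("%s: non-binary cell at gene '%s', time step %d ('%s')",
                     origin, genes[i], j, v[j]), call. = FALSE)
      }
      m[i, ] <- as.integer(v)
    }
    m
  }
  all_samples <- list()
  for (path in file) {
    lines <- trimws(readLines(path, warn = FALSE))
    if (is.null(sep)) {
      sep_use <- if (any(grepl("\t", lines, fixed = TRUE))) "\t" else ","
    } else sep_use <- sep
    is_marker <- startsWith(lines, "#") | !nzchar(lines)
    grp <- cumsum(is_marker)
    for (b in split(seq_along(lines)[!is_marker], grp[!is_marker])) {
      all_samples[[length(all_samples) + 1L]] <-
        read_block(lines[b], sep_use, origin = path)
    }
  }
  if (!length(all_samples)) stop("no sample blocks found", call. = FALSE)
  genes <- rownames(all_samples[[1L]])
  boolean_timeseries(all_samples, genes = genes)
}

#' Binarize real-valued expression matrices
#'
#' Thresholds each gene across all samples and time points. `kmeans` splits
#' the gene's values into two clusters (deterministic extreme-value centers;
#' the higher-mean cluster maps to 1); `median` maps values above the gene's
#' median to 1. Genes with constant values map to all 0 with a warning.
#' Already-binary input passes through unchanged.
#'
#' @param samples a list of numeric matrices (rows = genes), or a
#'   [boolean_timeseries()] (returned unchanged).
#' @param method `"kmeans"` (default) or `"median"`.
#' @param genes optional gene names when matrices lack row names.
#' @return a [boolean_timeseries()].
#' @export
binarize_timeseries <- function(samples, method = c("kmeans", "median"),
                                genes = NULL) {
  if (inherits(samples, "boolean_timeseries")) return(samples)
  method <- match.arg(method)
  samples <- lapply(samples, as.matrix)
  if (is.null(genes)) genes <- rownames(samples[[1L]])
  if (is.null(genes)) stop("gene names are required", call. = FALSE)
  vals <- do.call(cbind, samples)
  if (any(!is.finite(vals))) {
    stop("non-finite values cannot be binarized", call. = FALSE)
  }
  if (all(vals %in% c(0, 1))) {
    return(boolean_timeseries(samples, genes = genes))
  }
  thresholds <- numeric(length(genes))
  for (i in seq_along(genes)) {
    x <- vals[i, ]
    if (diff(range(x)) == 0) {
      warning(sprintf("gene '%s' is constant; binarized to all 0", genes[i]),
              call. = FALSE)
      thresholds[i] <- Inf
    } else if (method == "kmeans") {
      km <- stats::kmeans(x, centers = matrix(range(x), ncol = 1L))
      thresholds[i] <- mean(km$centers)
    } else {
      thresholds[i] <- stats::median(x)
    }
  }
  out <- lapply(samples, function(m) {
    b <- (m > thresholds) + 0L
    rownames(b) <- genes
    b
  })
  boolean_timeseries(out, genes = genes)
}

#' All 2^n initial states over a gene set
#'
#' @param genes character vector of gene names (or an integer count).
#' @param cap safety cap on the number of genes (default 20).
#' @return an integer matrix with `2^n` distinct rows in a deterministic
#'   (binary counting) order; columns named by gene.
#' @export
exhaustive_initial_states <- function(genes, cap = 20L) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- paste0("G", seq_len(genes))
  }
  n <- length(genes)
  if (n < 1L) stop("at least one gene is required", call. = FALSE)
  if (n > cap) {
    stop(sprintf("%d genes exceed the exhaustive-enumeration cap of %d", n, cap),
         call. = FALSE)
  }
  m <- all_assignments(genes) + 0L
  storage.mode(m) <- "integer"
  m
}

#' Generate Boolean time series from a network
#'
#' Simulates one sample per initial state under synchronous updating. The
#' network may be an [fbn()] (fundamental Boolean model dynamics, delegating
#' to the simulation engine) or a `boolean_rules` conventional rule set
#' (direct synchronous evaluation of the compressed rules).
#'
#' @param network an [fbn()] or [read_boolnet()] rule set.
#' @param initial_states matrix of initial states (rows = states, columns
#'   named by gene), e.g. from [exhaustive_initial_states()]; a single named
#'   vector is also accepted.
#' @param n_steps number of time steps per sample, including the initial one.
#' @param seed optional seed applied when the network is stochastic
#'   (any confidence < 1).
#' @return a [boolean_timeseries()] with one sample per initial state.
#' @export
generate_timeseries <- function(network, initial_states, n_steps, seed = NULL) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  if (is.null(dim(initial_states))) {
    initial_states <- matrix(initial_states, nrow = 1L,
                             dimnames = list(NULL, names(initial_states)))
  }
  if (inherits(network, "fbn")) {
    arr <- fbn_simulate_ensemble(network, initial_states, n_steps, seed = seed)
  } else if (inherits(network, "boolean_rules")) {
    arr <- rules_simulate_ensemble(network, initial_states, n_steps)
  } else {
    stop("network must be an fbn or a boolean_rules object", call. = FALSE)
  }
  genes <- dimnames(arr)[[2L]]
  samples <- lapply(seq_len(dim(arr)[1L]), function(k) {
    matrix(as.integer(arr[k, , ]), nrow = length(genes),
           dimnames = list(genes, NULL))
  })
  boolean_timeseries(samples, genes = genes)
}

# Synchronous ensemble simulation of a conventional rule set.
# Returns an n_states x genes x n_steps integer array.
rules_simulate_ensemble <- function(rules, initial_states, n_steps) {
  genes <- rules$genes
  S <- align_states(initial_states, genes)
  n <- nrow(S)
  arr <- array(0L, dim = c(n, length(genes), n_steps),
               dimnames = list(NULL, genes, NULL))
  arr[, , 1L] <- S
  if (n_steps > 1L) {
    for (s in 2L:n_steps) {
      env <- lapply(seq_along(genes), function(j) S[, j] == 1L)
      names(env) <- genes
      S <- vapply(genes, function(g) {
        as.integer(rep_len(eval_bool_expr(rules$rules[[g]], env), n))
      }, integer(n))
      S <- matrix(S, nrow = n, dimnames = list(NULL, genes))
      arr[, , s] <- S
    }
  }
  arr
}

align_states <- function(states, genes) {
  states <- as.matrix(states)
  if (is.null(colnames(states))) {
    if (ncol(states) != length(genes)) {
      stop("initial states must name their genes or match the gene count",
           call. = FALSE)
    }
    colnames(states) <- genes
  }
  missing <- setdiff(genes, colnames(states))
  if (length(missing)) {
    stop(sprintf("initial states lack gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- states[, genes, drop = FALSE]
  storage.mode(m) <- "integer"
  if (any(!(m %in% c(0L, 1L)))) stop("initial states must be binary", call. = FALSE)
  m
}
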