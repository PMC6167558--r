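#' Construct a fundamental Boolean function
#'
#' A fundamental Boolean function is an indivisible conjunction of gene
#' literals that, when satisfied at time `t` (and its stochastic confidence
#' gate passes), directly activates or inhibits one target gene at `t + 1`.
#'
#' @param target name of the regulated gene.
#' @param kind `"activation"` or `"inhibition"`.
#' @param inputs a named logical vector: names are the input genes, values are
#'   the required polarity (`TRUE` = gene must be on). Must be non-empty with
#'   no repeated gene.
#' @param confidence conditional probability in `[0, 1]` that the target takes
#'   the function's outcome at `t + 1` given the condition held at `t`.
#' @param support fraction in `[0, 1]` of transitions where condition and
#'   outcome co-occur.
#' @param timestep positive integer update delay; the synchronous engine
#'   honours `timestep = 1` only.
#' @return an object of class `fbn_function`.
#' @export
fbn_function <- function(target, kind = c("activation", "inhibition"), inputs,
                         confidence = 1, support = 1, timestep = 1L) {
  kind <- match.arg(kind)
  if (!is.logical(inputs) || length(inputs) == 0L || is.null(names(inputs)) ||
      any(!nzchar(names(inputs)))) {
    stop("inputs must be a non-empty named logical vector", call. = FALSE)
  }
  if (anyDuplicated(names(inputs))) {
    stop("a gene may appear at most once in a function's inputs", call. = FALSE)
  }
  structure(
    list(target = target, kind = kind, inputs = inputs,
         confidence = as.numeric(confidence), support = as.numeric(support),
         timestep = as.integer(timestep)),
    class = "fbn_function")
}

#' @export
format.fbn_function <- function(x, ...) {
  cond <- paste(ifelse(x$inputs, names(x$inputs), paste0("!", names(x$inputs))),
                collapse = "&")
  sprintf("%s = %s (Confidence: %s, TimeStep: %s)", x$target, cond,
          format(x$confidence), format(x$timestep))
}

#' @export
print.fbn_function <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Construct a fundamental Boolean network
#'
#' An FBN is a gene universe plus, per gene, ordered lists of fundamental
#' activation and inhibition functions, and a network-wide protein decay
#' window.
#'
#' @param genes character vector of unique gene names (case sensitive).
#' @param functions a list of [fbn_function()] objects (any order; they are
#'   grouped by target and kind, preserving relative order).
#' @param decay positive integer protein decay window \eqn{\vartheta}: the
#'   number of steps a gene stays on after the last function effect when no
#'   rule fires.
#' @return an object of class `fbn` with elements `genes`, `activators`
#'   (named list of function lists), `inhibitors`, and `decay`.
#' @seealso [validate_network()], [parse_fbn()], [fbn_simulate()]
#' @export
fbn <- function(genes, functions = list(), decay = 1L) {
  if (anyDuplicated(genes)) stop("gene names must be unique", call. = FALSE)
  decay <- as.integer(decay)
  if (is.na(decay) || decay < 1L) stop("decay window must be >= 1", call. = FALSE)
  activators <- inhibitors <- stats::setNames(
    replicate(length(genes), list(), simplify = FALSE), genes)
  for (f in functions) {
    if (!inherits(f, "fbn_function")) {
      stop("functions must be fbn_function objects", call. = FALSE)
    }
    if (!f$target %in% genes) {
      stop(sprintf("function target '%s' is not in the gene universe", f$target),
           call. = FALSE)
    }
    if (f$kind == "activation") {
      activators[[f$target]] <- c(activators[[f$target]], list(f))
    } else {
      inhibitors[[f$target]] <- c(inhibitors[[f$target]], list(f))
    }
  }
  structure(list(genes = genes, activators = activators,
                 inhibitors = inhibitors, decay = decay),
            class = "fbn")
}

fbn_all_functions <- function(net) {
  c(unlist(net$activators, recursive = FALSE, use.names = FALSE),
    unlist(net$inhibitors, recursive = FALSE, use.names = FALSE))
}

#' Validate an FBN against its structural invariants
#'
#' Checks that every function's target and input genes belong to the gene
#' universe, inputs are non-empty without duplicated genes, confidence and
#' support lie in `[0, 1]`, time steps are positive and the decay window is a
#' positive integer.
#'
#' @param net an [fbn()] object.
#' @return a character vector of violation messages; empty iff the network is
#'   valid.
#' @export
validate_network <- function(net) {
  if (!inherits(net, "fbn")) return("not an fbn object")
  bad <- character(0)
  if (anyDuplicated(net$genes)) bad <- c(bad, "duplicate gene names in universe")
  if (is.na(net$decay) || net$decay < 1L) {
    bad <- c(bad, sprintf("decay window %s is not a positive integer", net$decay))
  }
  for (f in fbn_all_functions(net)) {
    label <- sprintf("%s (%s)", f$target, f$kind)
    if (!f$target %in% net$genes) {
      bad <- c(bad, sprintf("%s: target not in gene universe", label))
    }
    if (length(f$inputs) == 0L) {
      bad <- c(bad, sprintf("%s: empty input set", label))
      next
    }
    unknown <- setdiff(names(f$inputs), net$genes)
    if (length(unknown)) {
      bad <- c(bad, sprintf("%s: unknown input gene(s) %s", label,
                            paste(unknown, collapse = ", ")))
    }
    if (anyDuplicated(names(f$inputs))) {
      bad <- c(bad, sprintf("%s: duplicated input gene", label))
    }
    if (is.na(f$confidence) || f$confidence < 0 || f$confidence > 1) {
      bad <- c(bad, sprintf("%s: confidence %s outside [0, 1]", label,
                            format(f$confidence)))
    }
    if (!is.na(f$support) && (f$support < 0 || f$support > 1)) {
      bad <- c(bad, sprintf("%s: support %s outside [0, 1]", label,
                            format(f$support)))
    }
    if (is.na(f$timestep) || f$timestep < 1L) {
      bad <- c(bad, sprintf("%s: time step must be a positive integer", label))
    }
  }
  bad
}

#' @export
print.fbn <- function(x, ...) {
  cat(serialize_fbn(x))
  invisible(x)
}

#' The mammalian cell-cycle fundamental Boolean network
#'
#' Returns the ten-gene mammalian cell-cycle FBN (CycD, Rb, E2F, CycE, CycA,
#' p27, Cdc20, Cdh1, UbcH10, CycB) shipped with the package: 46 fundamental
#' activation/inhibition functions, all with confidence 1, time step 1 and a
#' one-step decay window. Under synchronous updating it has two attractors --
#' a quiescence fixed point with only Rb, p27 and Cdh1 on, and a seven-state
#' cycle driven by CycD.
#'
#' @return an [fbn()] object.
#' @examples
#' net <- cell_cycle_fbn()
#' length(net$genes)
#' @export
cell_cycle_fbn <- function() {
  path <- system.file("extdata", "cellcycle_fbn.txt", package = "fbmnet",
                      mustWork = TRUE)
  parse_fbn(paste(readLines(path), collapse = "\n"))
}

# literal vector -> "A&!B" display text, preserving input order
literals_text <- function(inputs) {
  paste(ifelse(inputs, names(inputs), paste0("!", names(inputs))), collapse = "&")
}

# canonical sorted key for duplicate / subset tests
literals_key <- function(inputs) term_key(inputs)
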