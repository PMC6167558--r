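#' Read a BoolNet-style "targets, factors" network
#'
#' Parses the plain-text network format used by BoolNet: a header line
#' `targets, factors` followed by one rule per line, `Gene, expression`, with
#' the operators `&`, `|`, `!`, parentheses and constants `0`/`1`.
#' Probabilistic rule syntax (comma-separated probabilities) is rejected.
#'
#' @param text the network as a single string or character vector of lines;
#'   alternatively `file` may name a file to read.
#' @param file optional path to a network file.
#' @return an object of class `boolean_rules`: list with `genes` and `rules`
#'   (a named list of `bool_expr`, one per target gene).
#' @export
read_boolnet <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either text or file must be given", call. = FALSE)
    text <- readLines(file, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (!length(idx)) stop("empty network file", call. = FALSE)
  header <- lines[idx[1L]]
  if (!grepl("^targets\\s*,\\s*factors", header, ignore.case = TRUE)) {
    stop(sprintf("line %d: expected 'targets, factors' header, got '%s'",
                 idx[1L], header), call. = FALSE)
  }
  rules <- list()
  for (i in idx[-1L]) {
    line <- lines[i]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma == -1L) {
      stop(sprintf("line %d: missing comma between target and factors: '%s'",
                   i, line), call. = FALSE)
    }
    target <- trimws(substring(line, 1L, comma - 1L))
    rhs <- trimws(substring(line, comma + 1L))
    if (grepl(",", rhs, fixed = TRUE)) {
      stop(sprintf("line %d: probabilistic rule syntax is not supported", i),
           call. = FALSE)
    }
    if (!nzchar(target) || !nzchar(rhs)) {
      stop(sprintf("line %d: malformed rule '%s'", i, line), call. = FALSE)
    }
    expr <- tryCatch(parse_bool_expr(rhs), error = function(e) {
      stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    rules[[target]] <- expr
  }
  genes <- names(rules)
  for (target in genes) {
    unknown <- setdiff(bool_expr_genes(rules[[target]]), genes)
    if (length(unknown)) {
      stop(sprintf("rule for %s references unknown gene(s): %s",
                   target, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(genes = genes, rules = rules), class = "boolean_rules")
}

#' Serialize a conventional rule set to BoolNet text
#' @param rules a `boolean_rules` object (see [read_boolnet()]).
#' @param file optional path; when given the text is also written there.
#' @return the network text, invisibly when `file` is given.
#' @export
write_boolnet <- function(rules, file = NULL) {
  stopifnot(inherits(rules, "boolean_rules"))
  lines <- c("targets, factors",
             vapply(rules$genes, function(g) {
               paste0(g, ", ", serialize_bool_expr(rules$rules[[g]]))
             }, ""))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(text))
  }
  text
}

#' @export
print.boolean_rules <- function(x, ...) {
  cat(write_boolnet(x))
  invisible(x)
}

#' Parse an FBN from its rule-dialect text
#'
#' The dialect mirrors how fundamental Boolean networks are printed: an
#' optional preamble (`Fundamental Boolean Network with N genes` and a
#' `Genes involved:` list), then per-gene sections
#' `Multiple Transition Functions for <gene> with decay value = <d>:` followed
#' by rule lines of the form
#' `<Gene>_<n>_<Activator|Inhibitor>: <Gene> = <conjunction> (Confidence: <c>, TimeStep: <s>)`.
#'
#' @param text the network text (single string or vector of lines).
#' @return an [fbn()] object; rule order is preserved.
#' @export
parse_fbn <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(gsub("\\*", "", lines))
  lines <- lines[nzchar(lines)]
  involved <- character(0)
  functions <- list()
  decays <- integer(0)
  current <- NULL
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^Fundamental Boolean Network", line)) {
      i <- i + 1L
      next
    }
    if (grepl("^Genes involved:?$", line)) {
      involved <- trimws(unlist(strsplit(lines[i + 1L], ",", fixed = TRUE)))
      i <- i + 2L
      next
    }
    m <- regmatches(line, regexec(
      "^Multiple Transition Functions for ([A-Za-z_][A-Za-z0-9_.]*) with decay value = ([0-9]+):?$",
      line))[[1L]]
    if (length(m)) {
      current <- m[2L]
      d <- as.integer(m[3L])
      if (d < 1L) stop(sprintf("decay value must be >= 1 (gene %s)", current),
                       call. = FALSE)
      decays[current] <- d
      i <- i + 1L
      next
    }
    m <- regmatches(line, regexec(
      "^([A-Za-z_][A-Za-z0-9_.]*)_([0-9]+)_([A-Za-z]+):\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*([^(]+)\\(Confidence:\\s*([0-9.eE+-]+),\\s*TimeStep:\\s*([0-9]+)\\)$",
      line))[[1L]]
    if (!length(m)) {
      stop(sprintf("cannot parse FBN line: '%s'", line), call. = FALSE)
    }
    kind_tok <- m[4L]
    if (!kind_tok %in% c("Activator", "Inhibitor")) {
      stop(sprintf("unknown function kind '%s' in line '%s'", kind_tok, line),
           call. = FALSE)
    }
    target <- m[5L]
    if (!identical(m[2L], target)) {
      stop(sprintf("rule label gene '%s' does not match target '%s'", m[2L], target),
           call. = FALSE)
    }
    cond <- parse_bool_expr(trimws(m[6L]))
    inputs <- conjunction_literals(cond)
    functions[[length(functions) + 1L]] <- fbn_function(
      target = target,
      kind = if (kind_tok == "Activator") "activation" else "inhibition",
      inputs = inputs,
      confidence = as.numeric(m[7L]),
      support = NA_real_,
      timestep = as.integer(m[8L]))
    i <- i + 1L
  }
  genes <- unique(c(involved, names(decays),
                    vapply(functions, function(f) f$target, "")))
  if (!length(genes)) stop("no genes found in FBN text", call. = FALSE)
  if (length(unique(decays)) > 1L) {
    stop("per-gene decay values differ; a single network-wide decay window is supported",
         call. = FALSE)
  }
  decay <- if (length(decays)) decays[[1L]] else 1L
  net <- fbn(genes = genes, functions = functions, decay = decay)
  bad <- validate_network(net)
  if (length(bad)) {
    stop(paste(c("invalid FBN:", bad), collapse = "\n  "), call. = FALSE)
  }
  net
}

# extract the literal vector of a pure conjunction AST; reject anything else
conjunction_literals <- function(expr) {
  lits <- list()
  walk <- function(e) {
    if (e$op == "and") {
      lapply(e$args, walk)
    } else if (e$op == "var") {
      lits[[length(lits) + 1L]] <<- c(e$gene, TRUE)
    } else if (e$op == "not" && e$args[[1L]]$op == "var") {
      lits[[length(lits) + 1L]] <<- c(e$args[[1L]]$gene, FALSE)
    } else {
      stop("fundamental function conditions must be conjunctions of literals",
           call. = FALSE)
    }
    invisible(NULL)
  }
  walk(expr)
  out <- as.logical(vapply(lits, `[`, "", 2L))
  names(out) <- vapply(lits, `[`, "", 1L)
  if (anyDuplicated(names(out))) {
    stop("a gene may appear at most once in a conjunction", call. = FALSE)
  }
  out
}

#' Serialize an FBN to its rule-dialect text
#' @param net an [fbn()] object.
#' @param file optional path to also write the text to.
#' @return the network text.
#' @export
serialize_fbn <- function(net, file = NULL) {
  stopifnot(inherits(net, "fbn"))
  lines <- c(sprintf("Fundamental Boolean Network with %d genes", length(net$genes)),
             "Genes involved:",
             paste(net$genes, collapse = ", "))
  for (g in net$genes) {
    funs <- c(net$activators[[g]], net$inhibitors[[g]])
    if (!length(funs)) next
    lines <- c(lines, sprintf(
      "Multiple Transition Functions for %s with decay value = %d:", g, net$decay))
    for (k in seq_along(funs)) {
      f <- funs[[k]]
      kind_tok <- if (f$kind == "activation") "Activator" else "Inhibitor"
      lines <- c(lines, sprintf(
        "%s_%d_%s: %s = %s (Confidence: %s, TimeStep: %d)",
        g, k, kind_tok, g, literals_text(f$inputs), format(f$confidence),
        f$timestep))
    }
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(lines, file)
  text
}

#' Export an FBN's typed regulatory graph
#'
#' Writes the network as a graph for external viewers: one node per gene, one
#' edge per (input gene, function) pair, typed `activation` or `inhibition`,
#' with the source literal's polarity and the function's confidence as edge
#' attributes.
#'
#' @param net an [fbn()] object.
#' @param file output path.
#' @param format `"dot"` (Graphviz) or `"graphml"`.
#' @return the path, invisibly.
#' @export
export_fbn_graph <- function(net, file, format = c("dot", "graphml")) {
  stopifnot(inherits(net, "fbn"))
  format <- match.arg(format)
  edges <- list()
  for (f in fbn_all_functions(net)) {
    for (j in seq_along(f$inputs)) {
      edges[[length(edges) + 1L]] <- list(
        from = names(f$inputs)[j], to = f$target, kind = f$kind,
        polarity = unname(f$inputs[j]), confidence = f$confidence,
        rule = literals_text(f$inputs))
    }
  }
  if (format == "dot") {
    lines <- c("digraph fbn {",
               sprintf("  \"%s\";", net$genes),
               vapply(edges, function(e) {
                 style <- if (e$kind == "activation") "solid" else "dashed"
                 arrow <- if (e$kind == "activation") "normal" else "tee"
                 sprintf(paste0("  \"%s\" -> \"%s\" [style=%s, arrowhead=%s, ",
                                "kind=\"%s\", polarity=\"%d\", confidence=\"%s\", rule=\"%s\"];"),
                         e$from, e$to, style, arrow, e$kind, as.integer(e$polarity),
                         format(e$confidence), e$rule)
               }, ""),
               "}")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    lines <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <key id=\"kind\" for=\"edge\" attr.name=\"kind\" attr.type=\"string\"/>",
      "  <key id=\"polarity\" for=\"edge\" attr.name=\"polarity\" attr.type=\"int\"/>",
      "  <key id=\"confidence\" for=\"edge\" attr.name=\"confidence\" attr.type=\"double\"/>",
      "  <key id=\"rule\" for=\"edge\" attr.name=\"rule\" attr.type=\"string\"/>",
      "  <graph id=\"fbn\" edgedefault=\"directed\">",
      sprintf("    <node id=\"%s\"/>", net$genes),
      unlist(lapply(edges, function(e) {
        c(sprintf("    <edge source=\"%s\" target=\"%s\">", e$from, e$to),
          sprintf("      <data key=\"kind\">%s</data>", e$kind),
          sprintf("      <data key=\"polarity\">%d</data>", as.integer(e$polarity)),
          sprintf("      <data key=\"confidence\">%s</data>", format(e$confidence)),
          sprintf("      <data key=\"rule\">%s</data>", esc(e$rule)),
          "    </edge>")
      })),
      "  </graph>",
      "</graphml>")
  }
  writeLines(lines, file)
  invisible(file)
}
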