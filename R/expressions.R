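#' @title Boolean expressions in the BoolNet operator dialect
#' @description Parse a Boolean expression over gene names written with the
#'   operators `&` (and), `|` (or), `!` (not), parentheses and the constants
#'   `0`/`1` into an abstract syntax tree.
#'
#' Gene names must start with a letter or underscore and may contain letters,
#' digits, underscores and dots (e.g. `p27`, `UbcH10`). Operator precedence is
#' `!` > `&` > `|`, as in BoolNet network files.
#'
#' @param text a single character string, e.g. `"E2F & !Rb | CycA"`.
#' @return an object of class `bool_expr`: a nested list with elements
#'   `op` (`"var"`, `"const"`, `"not"`, `"and"` or `"or"`), and either
#'   `gene`, `value` or `args`.
#' @examples
#' e <- parse_bool_expr("A & !B | C")
#' serialize_bool_expr(e)
#' @export
parse_bool_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- new.env(parent = emptyenv())
  st$tokens <- bool_tokenize(text)
  st$pos <- 1L
  st$text <- text
  ast <- bparse_or(st)
  tk <- bpeek(st)
  if (!is.null(tk)) {
    stop(sprintf("parse error at position %d: unexpected '%s' in \"%s\"",
                 tk$at, tk$value, text), call. = FALSE)
  }
  class(ast) <- c("bool_expr", class(ast))
  ast
}

bool_tokenize <- function(text) {
  pat <- "^([A-Za-z_][A-Za-z0-9_.]*|[01]|[&|!()])"
  out <- list()
  pos <- 1L
  rest <- text
  repeat {
    ws <- regmatches(rest, regexpr("^\\s*", rest))
    if (nzchar(ws)) {
      pos <- pos + nchar(ws)
      rest <- substring(rest, nchar(ws) + 1L)
    }
    if (!nzchar(rest)) break
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1L) {
      stop(sprintf("parse error at position %d: unexpected character '%s'",
                   pos, substring(rest, 1L, 1L)), call. = FALSE)
    }
    val <- regmatches(rest, m)
    out[[length(out) + 1L]] <- list(value = val, at = pos)
    pos <- pos + nchar(val)
    rest <- substring(rest, nchar(val) + 1L)
  }
  out
}

bpeek <- function(st) {
  if (st$pos > length(st$tokens)) NULL else st$tokens[[st$pos]]
}

bnext <- function(st) {
  tk <- bpeek(st)
  st$pos <- st$pos + 1L
  tk
}

bexpect <- function(st, value) {
  tk <- bnext(st)
  if (is.null(tk) || tk$value != value) {
    at <- if (is.null(tk)) nchar(st$text) + 1L else tk$at
    stop(sprintf("parse error at position %d: expected '%s' in \"%s\"",
                 at, value, st$text), call. = FALSE)
  }
  tk
}

bparse_or <- function(st) {
  args <- list(bparse_and(st))
  while (!is.null(tk <- bpeek(st)) && tk$value == "|") {
    bnext(st)
    args[[length(args) + 1L]] <- bparse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

bparse_and <- function(st) {
  args <- list(bparse_unary(st))
  while (!is.null(tk <- bpeek(st)) && tk$value == "&") {
    bnext(st)
    args[[length(args) + 1L]] <- bparse_unary(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

bparse_unary <- function(st) {
  tk <- bpeek(st)
  if (is.null(tk)) {
    stop(sprintf("parse error at position %d: unexpected end of expression in \"%s\"",
                 nchar(st$text) + 1L, st$text), call. = FALSE)
  }
  if (tk$value == "!") {
    bnext(st)
    return(list(op = "not", args = list(bparse_unary(st))))
  }
  if (tk$value == "(") {
    bnext(st)
    inner <- bparse_or(st)
    bexpect(st, ")")
    return(inner)
  }
  if (tk$value %in% c("0", "1")) {
    bnext(st)
    return(list(op = "const", value = tk$value == "1"))
  }
  if (grepl("^[A-Za-z_]", tk$value)) {
    bnext(st)
    return(list(op = "var", gene = tk$value))
  }
  stop(sprintf("parse error at position %d: unexpected '%s' in \"%s\"",
               tk$at, tk$value, st$text), call. = FALSE)
}

#' Evaluate a Boolean expression
#'
#' @param expr a `bool_expr` (see [parse_bool_expr()]).
#' @param values a named list (or data.frame) mapping every gene referenced by
#'   `expr` to a logical vector; vectors are evaluated elementwise and may have
#'   any common length.
#' @return a logical vector.
#' @export
eval_bool_expr <- function(expr, values) {
  switch(expr$op,
    var = {
      v <- values[[expr$gene]]
      if (is.null(v)) stop(sprintf("unknown gene '%s' in expression", expr$gene),
                           call. = FALSE)
      as.logical(v)
    },
    const = expr$value,
    not = !eval_bool_expr(expr$args[[1L]], values),
    and = Reduce(`&`, lapply(expr$args, eval_bool_expr, values = values)),
    or = Reduce(`|`, lapply(expr$args, eval_bool_expr, values = values)),
    stop("invalid expression node", call. = FALSE)
  )
}

#' Genes referenced by a Boolean expression
#' @param expr a `bool_expr`.
#' @return character vector of gene names in order of first appearance.
#' @export
bool_expr_genes <- function(expr) {
  switch(expr$op,
    var = expr$gene,
    const = character(0),
    unique(unlist(lapply(expr$args, bool_expr_genes)))
  )
}

#' Serialize a Boolean expression back to the BoolNet dialect
#' @param expr a `bool_expr`.
#' @return a single string using `&`, `|`, `!` and minimal parentheses.
#' @export
serialize_bool_expr <- function(expr) {
  ser <- function(e, parent) {
    s <- switch(e$op,
      var = e$gene,
      const = if (e$value) "1" else "0",
      not = paste0("!", ser(e$args[[1L]], "not")),
      and = paste(vapply(e$args, ser, "", parent = "and"), collapse = " & "),
      or = paste(vapply(e$args, ser, "", parent = "or"), collapse = " | ")
    )
    needs_paren <- (e$op == "or" && parent %in% c("and", "not")) ||
      (e$op == "and" && parent == "not")
    if (needs_paren) paste0("(", s, ")") else s
  }
  ser(expr, "top")
}

# All 2^n assignments over `vars` as a logical matrix (one row per assignment,
# first variable toggling slowest -- deterministic enumeration order).
all_assignments <- function(vars) {
  n <- length(vars)
  if (n == 0L) return(matrix(logical(0), nrow = 1L, ncol = 0L))
  g <- expand.grid(rep(list(c(FALSE, TRUE)), n), KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, rev(seq_len(n)), drop = FALSE])
  colnames(g) <- vars
  g
}

# Truth vector of expr over all assignments of `vars`.
expr_truth_table <- function(expr, vars) {
  assign_mat <- all_assignments(vars)
  vals <- lapply(seq_along(vars), function(j) assign_mat[, j])
  names(vals) <- vars
  list(assignments = assign_mat, truth = eval_bool_expr(expr, vals))
}

## ---- Quine-McCluskey style prime implicant computation ---------------------
## Implicants are integer vectors over the variable set: 1 (required on),
## 0 (required off), NA (don't care).

qm_prime_implicants <- function(minterms) {
  if (nrow(minterms) == 0L) return(matrix(integer(0), 0L, ncol(minterms)))
  current <- unique(minterms)
  primes <- list()
  repeat {
    n <- nrow(current)
    combined <- rep(FALSE, n)
    produced <- list()
    if (n > 1L) {
      keys <- apply(current, 1L, function(r) paste(ifelse(is.na(r), "-", r), collapse = ""))
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          a <- current[i, ]
          b <- current[j, ]
          same_na <- identical(is.na(a), is.na(b))
          if (!same_na) next
          diff <- which(!is.na(a) & a != b)
          if (length(diff) == 1L) {
            combined[i] <- TRUE
            combined[j] <- TRUE
            new <- a
            new[diff] <- NA
            produced[[length(produced) + 1L]] <- new
          }
        }
      }
    }
    if (any(!combined)) {
      primes[[length(primes) + 1L]] <- current[!combined, , drop = FALSE]
    }
    if (length(produced) == 0L) break
    current <- unique(do.call(rbind, produced))
  }
  unique(do.call(rbind, primes))
}

implicant_covers <- function(implicant, minterms) {
  keep <- !is.na(implicant)
  if (!any(keep)) return(rep(TRUE, nrow(minterms)))
  apply(minterms[, keep, drop = FALSE], 1L,
        function(r) all(r == implicant[keep]))
}

implicant_term <- function(implicant, vars) {
  keep <- which(!is.na(implicant))
  lit <- as.logical(implicant[keep])
  names(lit) <- vars[keep]
  lit
}

term_key <- function(term) {
  if (length(term) == 0L) return("")
  o <- order(names(term))
  paste(ifelse(term[o], names(term)[o], paste0("!", names(term)[o])), collapse = "&")
}

#' Minimal disjunctive normal form of a Boolean expression
#'
#' Computes the prime implicants of the expression over its referenced genes
#' (Quine-McCluskey iterative combination) and selects a minimal cover
#' (essential primes first, then greedy by residual coverage with a
#' deterministic tie-break on term size and lexicographic term text).
#'
#' @param expr a `bool_expr`, or a string that will be parsed.
#' @param vars optional character vector of variables to build the truth table
#'   over; defaults to the genes referenced by `expr`.
#' @return a list of terms; each term is a named logical vector giving the
#'   required polarity per gene (`TRUE` = gene on). A constant-false
#'   expression yields an empty list; constant-true yields a single
#'   zero-length term.
#' @export
minimal_dnf <- function(expr, vars = NULL) {
  if (is.character(expr)) expr <- parse_bool_expr(expr)
  if (is.null(vars)) vars <- bool_expr_genes(expr)
  if (length(vars) > 12L) {
    stop("minimal_dnf supports at most 12 variables", call. = FALSE)
  }
  tt <- expr_truth_table(expr, vars)
  onset <- tt$assignments[tt$truth, , drop = FALSE]
  if (nrow(onset) == 0L) return(list())
  if (nrow(onset) == nrow(tt$assignments)) {
    return(list(structure(logical(0), names = character(0))))
  }
  storage.mode(onset) <- "integer"
  primes <- qm_prime_implicants(onset)
  cover <- vapply(seq_len(nrow(primes)),
                  function(i) implicant_covers(primes[i, ], onset),
                  logical(nrow(onset)))
  cover <- matrix(cover, nrow = nrow(onset))
  terms <- lapply(seq_len(nrow(primes)), function(i) implicant_term(primes[i, ], vars))
  keys <- vapply(terms, term_key, "")
  sizes <- lengths(terms)

  chosen <- logical(length(terms))
  uncovered <- rep(TRUE, nrow(onset))
  # essential primes
  counts <- rowSums(cover)
  essential_idx <- unique(unlist(lapply(which(counts == 1L), function(m) which(cover[m, ]))))
  chosen[essential_idx] <- TRUE
  if (length(essential_idx)) {
    uncovered <- uncovered & !apply(cover[, essential_idx, drop = FALSE], 1L, any)
  }
  # greedy cover of the rest
  while (any(uncovered)) {
    gain <- colSums(cover & uncovered)
    gain[chosen] <- -1L
    best <- which(gain == max(gain))
    if (length(best) > 1L) {
      best <- best[order(sizes[best], keys[best])][1L]
    }
    chosen[best] <- TRUE
    uncovered <- uncovered & !cover[, best]
  }
  out <- terms[chosen]
  out[order(lengths(out), vapply(out, term_key, ""))]
}

#' Decompose a compressed Boolean rule into fundamental functions
#'
#' A conventional Boolean update rule mixes activating triggers with negated
#' context (absence-of-inhibitor conditions). This decomposition separates the
#' two channels: inhibition functions are the terms of a minimal DNF of
#' `NOT(expr)` (every way the rule is vetoed), and activation functions are
#' the minimal-DNF terms of `expr` with the negated context removed -- each
#' term keeps only its positive literals, because the states excluded by the
#' dropped negative literals are exactly the states some inhibition function
#' fires on, and inhibition dominates activation in the fundamental Boolean
#' model. A term with no positive literal is kept whole. Under the FBM update
#' with all confidences 1 and a one-step decay window, the resulting network
#' computes exactly `expr`.
#'
#' @param expr a `bool_expr` or a string in the BoolNet dialect.
#' @param target name of the regulated gene.
#' @param genes optional gene universe; expressions referencing genes outside
#'   it are rejected. Defaults to the genes in `expr` plus `target`.
#' @return a list with components `activators` and `inhibitors`, each a list
#'   of [fbn_function()] objects (confidence 1, time step 1). Support is the
#'   fraction of all input assignments satisfying the term.
#' @examples
#' d <- decompose_boolean_function(
#'   "E2F & !Rb & !Cdc20 & !(Cdh1 & UbcH10) | CycA & !Rb & !Cdc20 & !(Cdh1 & UbcH10)",
#'   target = "CycA")
#' length(d$activators) + length(d$inhibitors)  # 6
#' @export
decompose_boolean_function <- function(expr, target, genes = NULL) {
  if (is.character(expr)) expr <- parse_bool_expr(expr)
  vars <- bool_expr_genes(expr)
  if (!is.null(genes)) {
    bad <- setdiff(c(vars, target), genes)
    if (length(bad)) {
      stop(sprintf("expression references genes outside the universe: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  inhibitors <- minimal_dnf(list(op = "not", args = list(expr)), vars = vars)
  act_terms <- minimal_dnf(expr, vars = vars)
  # keep the positive trigger of each term; negated context belongs to the
  # inhibition channel
  act_terms <- lapply(act_terms, function(term) {
    pos <- term[term]
    if (length(pos)) pos else term
  })
  act_terms <- dedup_subsume_terms(act_terms)
  inhibitors <- dedup_subsume_terms(inhibitors)
  # a constant expression yields a zero-length term: fundamental functions need
  # non-empty inputs, so encode "always" as the pair of self-literals
  self_pair <- function() {
    list(structure(TRUE, names = target), structure(FALSE, names = target))
  }
  if (any(lengths(act_terms) == 0L)) act_terms <- self_pair()
  if (any(lengths(inhibitors) == 0L)) inhibitors <- self_pair()
  mk <- function(term, kind) {
    fbn_function(target = target, kind = kind, inputs = term,
                 confidence = 1, support = 0.5^length(term), timestep = 1L)
  }
  list(activators = lapply(act_terms, mk, kind = "activation"),
       inhibitors = lapply(inhibitors, mk, kind = "inhibition"))
}

# Drop duplicate terms and terms that are strict supersets of another term,
# then order deterministically by (size, lexicographic key).
dedup_subsume_terms <- function(terms) {
  if (!length(terms)) return(terms)
  keys <- vapply(terms, term_key, "")
  terms <- terms[!duplicated(keys)]
  o <- order(lengths(terms), vapply(terms, term_key, ""))
  terms <- terms[o]
  kept <- list()
  for (term in terms) {
    subsumed <- any(vapply(kept, function(k) {
      all(names(k) %in% names(term)) && all(k == term[names(k)])
    }, logical(1)))
    if (!subsumed) kept[[length(kept) + 1L]] <- term
  }
  kept
}
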