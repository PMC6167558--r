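# Shared fixtures (built in code) and independent counting oracles.

# Two-gene equilibrium network: A activates B, B inhibits A, one-step decay.
two_gene_fbn <- function() {
  parse_fbn(paste(
    "Multiple Transition Functions for A with decay value = 1:",
    "A_1_Inhibitor: A = B (Confidence: 1, TimeStep: 1)",
    "Multiple Transition Functions for B with decay value = 1:",
    "B_1_Activator: B = A (Confidence: 1, TimeStep: 1)",
    sep = "\n"))
}

# Random conventional rule set: per gene, a 1-2 term DNF of 1-3 literals.
random_rules <- function(n_genes, seed) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  rules <- lapply(genes, function(g) {
    n_terms <- sample(1:2, 1)
    terms <- replicate(n_terms, {
      k <- sample(1:min(3, n_genes), 1)
      vars <- sample(genes, k)
      lits <- ifelse(sample(c(TRUE, FALSE), k, replace = TRUE),
                     vars, paste0("!", vars))
      paste(lits, collapse = " & ")
    })
    parse_bool_expr(paste(terms, collapse = " | "))
  })
  names(rules) <- genes
  structure(list(genes = genes, rules = rules), class = "boolean_rules")
}

# Decompose every rule of a conventional set into an FBN.
decomposed_fbn <- function(rules, decay = 1L) {
  funs <- unlist(lapply(rules$genes, function(g) {
    d <- decompose_boolean_function(rules$rules[[g]], g, genes = rules$genes)
    c(d$activators, d$inhibitors)
  }), recursive = FALSE)
  fbn(rules$genes, funs, decay = decay)
}

# Random Boolean time series (not generated by any network).
random_series <- function(n_genes, n_samples, n_steps, seed) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  samples <- replicate(n_samples, {
    matrix(sample(0:1, n_genes * n_steps, replace = TRUE), n_genes,
           dimnames = list(genes, NULL))
  }, simplify = FALSE)
  boolean_timeseries(samples, genes = genes)
}

# Naive per-transition counting oracle, independent of the cube code path:
# explicit double loop over samples and time steps.
oracle_counts <- function(series, target, condition, outcome) {
  matched <- 0L
  co <- 0L
  for (m in series$samples) {
    if (ncol(m) < 2L) next
    for (s in seq_len(ncol(m) - 1L)) {
      sat <- TRUE
      for (g in names(condition)) {
        if (m[g, s] != as.integer(condition[[g]])) { sat <- FALSE; break }
      }
      if (sat) {
        matched <- matched + 1L
        if (m[target, s + 1L] == as.integer(as.logical(outcome))) co <- co + 1L
      }
    }
  }
  list(matched = matched, co = co,
       confidence = if (matched > 0L) co / matched else 0)
}

# Naive counter-confidence oracle: condition at t+1 given target state at t.
oracle_counter <- function(series, target, condition, kind) {
  want <- if (kind == "activation") 1L else 0L
  num <- 0L
  den <- 0L
  for (m in series$samples) {
    if (ncol(m) < 2L) next
    for (s in seq_len(ncol(m) - 1L)) {
      if (m[target, s] == want) {
        den <- den + 1L
        sat <- TRUE
        for (g in names(condition)) {
          if (m[g, s + 1L] != as.integer(condition[[g]])) { sat <- FALSE; break }
        }
        if (sat) num <- num + 1L
      }
    }
  }
  if (den == 0L) 0 else num / den
}

# canonical text of a function's condition: literals sorted by gene name
term_text <- function(f) {
  lit <- f$inputs[order(names(f$inputs))]
  paste(ifelse(lit, names(lit), paste0("!", names(lit))), collapse = "&")
}

sorted_terms <- function(funs) sort(vapply(funs, term_text, ""))
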