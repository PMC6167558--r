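#' Score a reconstructed Boolean time series against its reference
#'
#' State-level rates: each sample's mismatch fraction (unmatched gene-states
#' over genes times time steps) is averaged over samples to give the error
#' rate ER, with AR = 1 - ER. Sample-level rates: PMR is the fraction of
#' samples whose reconstruction matches the reference in every gene at every
#' time step; MMR = 1 - PMR. The state-level rates are symmetric in the two
#' arguments.
#'
#' @param reference,reconstructed [boolean_timeseries()] objects of identical
#'   shape (same genes, same per-sample lengths).
#' @return an object of class `fbn_eval`: list with `ER`, `AR`, `PMR`, `MMR`,
#'   `n_samples` and `mismatches` (per-sample unmatched-state counts).
#' @examples
#' s <- boolean_timeseries(list(matrix(c(1, 0, 0, 1), 2,
#'                                     dimnames = list(c("A", "B"), NULL))))
#' evaluate_reconstruction(s, s)$AR
#' @export
evaluate_reconstruction <- function(reference, reconstructed) {
  stopifnot(inherits(reference, "boolean_timeseries"),
            inherits(reconstructed, "boolean_timeseries"))
  if (!identical(reference$genes, reconstructed$genes)) {
    stop("gene sets differ between reference and reconstruction", call. = FALSE)
  }
  if (length(reference$samples) != length(reconstructed$samples)) {
    stop("sample counts differ", call. = FALSE)
  }
  n <- length(reference$samples)
  mism <- integer(n)
  frac <- numeric(n)
  for (k in seq_len(n)) {
    a <- reference$samples[[k]]
    b <- reconstructed$samples[[k]]
    if (!all(dim(a) == dim(b))) {
      stop(sprintf("sample %d shapes differ (%dx%d vs %dx%d)", k,
                   nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
    }
    mism[k] <- sum(a != b)
    frac[k] <- mism[k] / length(a)
  }
  er <- mean(frac)
  pmr <- mean(mism == 0L)
  structure(list(ER = er, AR = 1 - er, PMR = pmr, MMR = 1 - pmr,
                 n_samples = n, mismatches = mism),
            class = "fbn_eval")
}

#' @export
print.fbn_eval <- function(x, ...) {
  cat(sprintf("Reconstruction over %d sample(s): ER %.4g, AR %.4g%%, PMR %.4g%%, MMR %.4g\n",
              x$n_samples, x$ER, 100 * x$AR, 100 * x$PMR, x$MMR))
  invisible(x)
}
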