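#' Quintile-matched subsampling
#'
#' Matches a pool of observations (e.g. wild-type reversals) to the
#' distribution of a reference sample (e.g. mutant reversals) on one
#' behavioral variable.  Quintile edges come from the reference's empirical
#' 20/40/60/80 percentiles (linear-interpolation definition, boundary values
#' to the lower quintile); pool members are binned by those edges, the
#' smallest per-quintile pool count k is found, and k members are drawn
#' uniformly without replacement from each quintile, yielding a subsample
#' with exactly equal quintile masses under the reference's quintiles.
#'
#' @param reference_values numeric vector (at least 5 values).
#' @param pool_values numeric vector to subsample from.
#' @param seed integer seed.
#' @return an object of class `match_result`: list with `edges` (the break
#'   vector, -Inf/quintile edges/Inf), `k`, `selected` (indices into
#'   `pool_values`), `per_quintile` (list of selected indices per quintile).
#' @export
quintile_match <- function(reference_values, pool_values, seed = 1L) {
  if (length(reference_values) < 5L)
    stop("need at least 5 reference values")
  if (!length(pool_values)) stop("pool must be non-empty")
  edges <- stats::quantile(reference_values, c(0.2, 0.4, 0.6, 0.8),
                           names = FALSE)
  breaks <- c(-Inf, edges, Inf)
  # right-closed bins put boundary values in the lower quintile
  bin <- cut(pool_values, breaks, labels = FALSE, right = TRUE)
  counts <- tabulate(bin, nbins = 5L)
  k <- min(counts)
  if (k == 0L) {
    warning("empty quintile in the pool; empty match returned")
    sel <- integer(0)
    perq <- rep(list(integer(0)), 5L)
  } else {
    set.seed(seed)
    perq <- lapply(1:5, function(q) {
      idx <- which(bin == q)
      idx[sample.int(length(idx), k)]
    })
    sel <- unlist(perq)
  }
  structure(list(edges = breaks, k = k, selected = sel, per_quintile = perq,
                 seed = seed),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> k = %d per quintile (%d selected); reference quintile edges: %s\n",
    x$k, length(x$selected),
    paste(signif(x$edges[2:5], 4), collapse = ", ")))
  invisible(x)
}

#' Normalize a receptor expression table column-wise to its maximum
#'
#' Each receptor's TPM column is divided by the maximum TPM reported in any
#' single neuron for that receptor, giving values from 0 (no expression) to
#' 1 (the maximally expressing neuron).  Idempotent, and invariant to
#' rescaling any column by a positive constant.
#'
#' @param table numeric matrix, neurons x receptors, TPM >= 0.
#' @return matrix of the same shape with values in [0, 1].
#' @export
receptor_normalize <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("table must be a numeric matrix (neurons x receptors)")
  if (any(table < 0)) stop("TPM values must be non-negative")
  mx <- apply(table, 2, max)
  if (any(mx == 0))
    stop("each receptor must have at least one nonzero entry")
  sweep(table, 2, mx, "/")
}

#' Summed normalized expression over a neuron set
#'
#' Per-neuron expression is the sum of normalized values across receptors;
#' the set score is the sum of these over the set.
#'
#' @param normalized output of [receptor_normalize()].
#' @param neuron_set character vector of neuron labels (may be empty).
#' @return scalar score.
#' @export
neuron_set_score <- function(normalized, neuron_set) {
  if (!length(neuron_set)) return(0)
  missing <- setdiff(neuron_set, rownames(normalized))
  if (length(missing))
    stop("unknown neurons: ", paste(missing, collapse = ", "))
  sum(normalized[neuron_set, , drop = FALSE])
}

#' Permutation test for receptor-expression enrichment in a neuron set
#'
#' Compares the observed set score to scores of `n_draws` random neuron
#' sets of the same size (drawn without replacement within a draw).
#' One-sided (enrichment) add-one empirical p:
#' `p = (1 + #\{null >= observed\}) / (n_draws + 1)`, so `p >= 1/(n_draws+1)`
#' always.
#'
#' @param normalized output of [receptor_normalize()].
#' @param neuron_set character vector of neuron labels.
#' @param n_draws number of random sets.
#' @param seed integer seed.
#' @return list with `p`, `observed`, `null` (vector of null scores),
#'   `n_draws`.
#' @export
expression_permutation_test <- function(normalized, neuron_set,
                                        n_draws = 500, seed = 1L) {
  if (n_draws < 1L) stop("n_draws must be at least 1")
  k <- length(neuron_set)
  if (k > nrow(normalized))
    stop("neuron_set larger than the table")
  observed <- neuron_set_score(normalized, neuron_set)
  set.seed(seed)
  per_neuron <- rowSums(normalized)
  null <- vapply(seq_len(n_draws), function(i)
    sum(per_neuron[sample.int(length(per_neuron), k)]), 1)
  list(p = (1 + sum(null >= observed)) / (n_draws + 1),
       observed = observed, null = null, n_draws = n_draws)
}

#' Bootstrap comparison of two classifiers' accuracies
#'
#' Resamples test items with replacement and computes each model's accuracy
#' on every bootstrap replicate; the two-sided empirical p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` (add-one smoothed, capped at 1)
#' for the probability that the accuracy difference is non-zero.
#'
#' @param accuracy_a,accuracy_b either numeric vectors of per-item
#'   correctness (0/1 or fractional) aligned on the same test items, or
#'   functions taking a vector of item indices and returning an accuracy.
#' @param test_items item indices to resample (defaults to all items when
#'   correctness vectors are given).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param labels optional per-item class labels; when given, replicate
#'   accuracies are balanced (mean of per-class means).
#' @return list with `p`, `diff_mean`, `acc_a`, `acc_b`, `diffs`.
#' @export
bootstrap_compare <- function(accuracy_a, accuracy_b, test_items = NULL,
                              n_boot = 1000, seed = 1L, labels = NULL) {
  fa <- .as_accuracy_fn(accuracy_a, labels)
  fb <- .as_accuracy_fn(accuracy_b, labels)
  if (is.null(test_items)) {
    if (is.function(accuracy_a))
      stop("test_items required when accuracies are functions")
    test_items <- seq_along(accuracy_a)
  }
  n <- length(test_items)
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    idx <- test_items[sample.int(n, n, replace = TRUE)]
    fa(idx) - fb(idx)
  }, 1)
  p_le <- (1 + sum(diffs <= 0)) / (n_boot + 1)
  p_ge <- (1 + sum(diffs >= 0)) / (n_boot + 1)
  list(p = min(1, 2 * min(p_le, p_ge)),
       diff_mean = mean(diffs),
       acc_a = fa(test_items), acc_b = fb(test_items), diffs = diffs)
}

.as_accuracy_fn <- function(acc, labels) {
  if (is.function(acc)) return(acc)
  if (!is.numeric(acc)) stop("accuracy must be a vector or a function")
  if (is.null(labels)) {
    function(idx) mean(acc[idx])
  } else {
    function(idx) {
      mean(vapply(split(acc[idx], labels[idx]), mean, 1))
    }
  }
}
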