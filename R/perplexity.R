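#' Log-likelihood of one equivalence class
#'
#' Computes \eqn{\log \sum_{t_i \in \Omega} P(t_i \mid \theta) \, P(\hat f
#' \mid \hat F^q, t_i)}, the log of the approximate per-fragment likelihood
#' shared by all fragments in a class. Accumulation uses a max-shifted
#' log-sum-exp so probabilities down to the smallest normal double do not
#' underflow.
#'
#' @param eqclass An [eqclass()].
#' @param theta A [theta_distribution()].
#' @return The log marginal probability in nats; `-Inf` iff every labelled
#'   transcript has zero probability under `theta` (an impossible class).
#' @export
class_log_likelihood <- function(eqclass, theta) {
  p <- theta$probs
  if (any(eqclass$labels > length(p)))
    stop("class_log_likelihood: label index outside theta's support range")
  lse(log(p[eqclass$labels]) + log(eqclass$weights))
}

# log-sum-exp with a max shift; returns -Inf for an all -Inf input.
lse <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# Per-class log marginals for a whole collection, vectorised.
collection_class_logliks <- function(collection, theta) {
  fl <- flatten_collection(collection)
  if (fl$n_classes == 0L) return(numeric(0))
  lt <- log(theta$probs)[fl$label] + log(fl$weight)
  mx <- tapply_max(lt, fl$cls, fl$n_classes)   # per-class max shift
  shifted <- exp(lt - mx[fl$cls])
  shifted[!is.finite(mx[fl$cls])] <- 0
  sums <- numeric(fl$n_classes)
  agg <- rowsum(shifted, fl$cls)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  out <- mx + log(sums)
  out[!is.finite(mx)] <- -Inf
  out
}

# Group-wise maximum over 1..n groups.
tapply_max <- function(x, g, n) {
  out <- rep(-Inf, n)
  agg <- vapply(split(x, g), max, numeric(1))
  out[as.integer(names(agg))] <- agg
  out
}

#' Perplexity of a validation fragment set under model parameters
#'
#' The inverse geometric mean per-fragment likelihood of the held-out
#' validation set, computed from its equivalence classes:
#' \deqn{PP(\hat F, \theta) = \exp\{-(1/\hat N) \sum_q \hat N^q \log
#' P(\hat f \mid \hat F^q, \theta)\}.}
#' Lower is better; the theoretical minimum of 1 is attained only when
#' every fragment is certain. If any class is impossible under `theta`
#' (every labelled transcript has zero probability) the perplexity is
#' `+Inf` and the impossible-fragment diagnostics report how many fragments
#' and classes were affected — smoothing `theta` first (see
#' [laplace_smooth()], [sgt_smooth()]) is the supported way to obtain a
#' finite, comparable value.
#'
#' @param validation An [eqclass_collection()] of the validation set.
#' @param theta A [theta_distribution()] over the same transcripts.
#' @return An object of class `"perplexity_result"`: a list with
#'   `perplexity`, `log_likelihood_per_fragment` (nats),
#'   `n_validation_fragments`, `n_impossible_fragments`,
#'   `n_impossible_classes` and `smoothing_method`.
#' @export
perplexity <- function(validation, theta) {
  stopifnot(inherits(validation, "eqclass_collection"))
  check_theta_dim(validation, theta)
  N <- validation$total_fragments
  if (N < 1L || length(validation$classes) == 0L)
    stop("perplexity: empty validation set")
  ll <- collection_class_logliks(validation, theta)
  counts <- vapply(validation$classes, `[[`, integer(1), "count")
  imp <- !is.finite(ll)
  mean_ll <- sum(ll[!imp] * counts[!imp]) / N
  if (any(imp)) mean_ll <- -Inf
  perplexity_result(mean_ll, N, sum(counts[imp]), sum(imp), theta$method)
}

perplexity_result <- function(mean_ll, n_fragments, n_impossible_fragments,
                              n_impossible_classes, method) {
  structure(list(perplexity = exp(-mean_ll),
                 log_likelihood_per_fragment = mean_ll,
                 n_validation_fragments = as.integer(n_fragments),
                 n_impossible_fragments = as.integer(n_impossible_fragments),
                 n_impossible_classes = as.integer(n_impossible_classes),
                 smoothing_method = method),
            class = "perplexity_result")
}

#' @export
print.perplexity_result <- function(x, ...) {
  cat(sprintf("Perplexity: %s  (smoothing: %s)\n",
              format(x$perplexity, digits = 6), x$smoothing_method))
  cat(sprintf("  mean log-likelihood/fragment: %s nats over %d fragments\n",
              format(x$log_likelihood_per_fragment, digits = 6),
              x$n_validation_fragments))
  if (x$n_impossible_fragments > 0L)
    cat(sprintf("  impossible: %d fragments in %d classes\n",
                x$n_impossible_fragments, x$n_impossible_classes))
  invisible(x)
}

#' Serialise a perplexity result to JSON
#'
#' @param x A `"perplexity_result"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`). Infinite
#'   perplexities serialise as the string `"Inf"`.
#' @export
perplexity_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "perplexity_result"))
  obj <- unclass(x)
  if (!is.finite(obj$perplexity)) {
    obj$perplexity <- "Inf"
    obj$log_likelihood_per_fragment <- "-Inf"
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Exact fragmentwise perplexity
#'
#' The unapproximated form: each validation fragment carries its own vector
#' of conditional probabilities \eqn{P(\hat f_j \mid t_i)} and the
#' perplexity is the inverse geometric mean of the per-fragment marginals
#' \eqn{\sum_i P(t_i \mid \theta) P(\hat f_j \mid t_i)}. This path is the
#' brute-force reference for the equivalence-class approximation: when the
#' per-fragment rows are exact copies of their class weights the two agree
#' to floating-point accuracy.
#'
#' @param fragment_probs A numeric matrix with one row per fragment and one
#'   column per transcript, entries \eqn{P(\hat f_j \mid t_i)} (zeros for
#'   transcripts a fragment does not map to), or a list of per-fragment
#'   `list(labels=, weights=)` sparse rows.
#' @param theta A [theta_distribution()].
#' @return A `"perplexity_result"` (see [perplexity()]).
#' @export
perplexity_fragmentwise <- function(fragment_probs, theta) {
  p <- theta$probs
  if (is.matrix(fragment_probs)) {
    if (ncol(fragment_probs) != length(p))
      stop("perplexity_fragmentwise: column count must match theta dimension")
    if (nrow(fragment_probs) == 0L) stop("perplexity_fragmentwise: empty input")
    if (any(rowSums(fragment_probs) <= 0))
      stop("perplexity_fragmentwise: fragment with no nonzero conditional probability")
    lp <- log(p)
    ll <- apply(fragment_probs, 1L, function(row) {
      nz <- which(row > 0)
      lse(lp[nz] + log(row[nz]))
    })
  } else if (is.list(fragment_probs)) {
    if (length(fragment_probs) == 0L) stop("perplexity_fragmentwise: empty input")
    lp <- log(p)
    ll <- vapply(fragment_probs, function(fr) {
      lse(lp[fr$labels] + log(fr$weights))
    }, numeric(1))
  } else stop("perplexity_fragmentwise: unsupported input type")
  n <- length(ll)
  imp <- !is.finite(ll)
  mean_ll <- if (any(imp)) -Inf else sum(ll) / n
  perplexity_result(mean_ll, n, sum(imp), NA_integer_, theta$method)
}

#' Count impossible validation fragments and classes
#'
#' A validation class is impossible under `theta` iff every transcript in
#' its label set has zero probability; all its fragments are then
#' impossible. Smoothed (strictly positive) distributions call nothing
#' impossible.
#'
#' @param validation An [eqclass_collection()].
#' @param theta A [theta_distribution()].
#' @return A list with `n_impossible_fragments` and `n_impossible_classes`.
#' @export
count_impossible <- function(validation, theta) {
  stopifnot(inherits(validation, "eqclass_collection"))
  check_theta_dim(validation, theta)
  p <- theta$probs
  imp <- vapply(validation$classes, function(cl) all(p[cl$labels] == 0),
                logical(1))
  counts <- vapply(validation$classes, `[[`, integer(1), "count")
  list(n_impossible_fragments = as.integer(sum(counts[imp])),
       n_impossible_classes = as.integer(sum(imp)))
}
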