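#' Laplacian smoothing of a per-transcript distribution
#'
#' Redistributes a small constant probability mass across the reference:
#' \deqn{\tilde P_\beta(t_i \mid \theta) = (\eta_i + \beta) / (1 + M\beta),}
#' where \eqn{\eta_i = P(t_i \mid \theta)} and M is the reference size. The
#' output sums to 1 analytically and is strictly positive whenever
#' `beta > 0`, so no validation fragment that maps within the reference can
#' be called impossible. Smaller `beta` means a harsher penalty per
#' impossible fragment; the default 1e-8 keeps the penalty large while
#' leaving possible-fragment likelihoods essentially untouched.
#'
#' @param theta A [theta_distribution()].
#' @param beta Non-negative smoothing constant (default `1e-8`).
#' @param M Reference size; defaults to the dimension of `theta`.
#' @return A [theta_distribution()] with `method = "laplace"` (or the input
#'   unchanged when `beta == 0`).
#' @export
laplace_smooth <- function(theta, beta = 1e-8, M = length(theta$probs)) {
  stopifnot(inherits(theta, "theta_distribution"))
  if (beta < 0) stop("laplace_smooth: beta must be >= 0")
  if (M != length(theta$probs))
    stop("laplace_smooth: M must equal the dimension of theta")
  if (beta == 0) return(theta)
  theta_distribution((theta$probs + beta) / (1 + M * beta),
                     method = "laplace", params = list(beta = beta),
                     names = names(theta$probs))
}

#' Round estimated fragment counts to integers
#'
#' Simple Good-Turing smoothing needs integer event frequencies, while
#' abundance estimates are real-valued expected counts; each per-transcript
#' count is rounded to the nearest integer (half-to-even, R's `round`),
#' zeros preserved.
#'
#' @param est An [abundance_estimate()] or a numeric vector of counts.
#' @return Integer vector of rounded counts.
#' @export
round_counts <- function(est) {
  x <- if (inherits(est, "abundance_estimate")) est$NumReads else as.numeric(est)
  if (any(x < 0)) stop("round_counts: negative counts")
  as.integer(round(x))
}

#' Frequencies of frequencies
#'
#' Tallies \eqn{n_r = |\{t_i : c_i = r\}|} for r >= 1 — the number of
#' transcripts with rounded count exactly r — together with the total read
#' count \eqn{n = \sum_r r \, n_r}. Zero counts are excluded from the
#' mapping (they are the unseen events SGT assigns mass to).
#'
#' @param counts Integer vector of per-transcript counts.
#' @return A list of class `"freq_of_freq"` with sorted `r`, `n_r` and
#'   `total_reads`.
#' @export
freq_of_freq <- function(counts) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("freq_of_freq: negative counts")
  pos <- counts[counts > 0L]
  tab <- table(pos)
  r <- as.integer(names(tab))
  structure(list(r = r, n_r = as.integer(tab), total_reads = sum(counts)),
            class = "freq_of_freq")
}

#' Fit the Simple Good-Turing estimator
#'
#' Implements the Gale–Sampson Simple Good-Turing procedure on a
#' frequency-of-frequencies table:
#' \itemize{
#'   \item unseen mass \eqn{P_0 = n_1 / n} (0, with a warning, when no
#'     singletons exist — the caller may prefer Laplacian smoothing then);
#'   \item Z-transform \eqn{Z_r = n_r / \tfrac12 (t - q)} over the gaps to
#'     the neighbouring observed frequencies, then an ordinary least-squares
#'     fit of \eqn{\log Z_r} on \eqn{\log r} (a proper fit needs slope
#'     < -1; otherwise a warning is issued and the fit used regardless);
#'   \item adjusted frequencies \eqn{r^\star = (r+1) S(n_{r+1}) / S(n_r)},
#'     using the raw Turing estimate for small r and switching permanently
#'     to the smoothed log-linear estimate at the first r where the two are
#'     statistically indistinguishable (|difference| within 1.96 standard
#'     deviations) or where \eqn{n_{r+1} = 0};
#'   \item renormalisation so the seen mass sums to \eqn{1 - P_0}.
#' }
#'
#' @param fof A [freq_of_freq()].
#' @return A list of class `"sgt_model"`: `r`, `n_r`, `r_star` (adjusted
#'   frequencies), `p_r` (renormalised probability of one event seen r
#'   times), `P0`, `intercept`, `slope`, `switch_point`, `total_reads`.
#' @export
sgt_fit <- function(fof) {
  stopifnot(inherits(fof, "freq_of_freq"))
  r <- fof$r; n_r <- as.numeric(fof$n_r); n <- fof$total_reads
  if (n < 1L) stop("sgt_fit: no reads")
  m <- length(r)
  if (m < 2L) stop("sgt_fit: need at least 2 distinct frequencies for the fit")
  n1 <- if (1L %in% r) n_r[match(1L, r)] else 0
  P0 <- n1 / n
  if (n1 == 0)
    warning("sgt_fit: no singleton transcripts (n_1 = 0); P0 = 0, ",
            "unseen transcripts keep zero mass")

  # Z-transform: spread each n_r over the gap between neighbouring r.
  q <- c(0L, r[-m])
  t_ <- c(r[-1L], 2L * r[m] - r[m - 1L])
  Z <- n_r / (0.5 * (t_ - q))
  fit <- stats::lm.fit(cbind(1, log(r)), log(Z))
  a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
  if (b >= -1)
    warning(sprintf("sgt_fit: log-linear slope %.3f >= -1; SGT fit is degenerate", b))

  S <- function(rr) exp(a + b * log(rr))
  # n_{r+1} looked up in the observed table (0 when absent)
  n_next <- n_r[match(r + 1L, r)]
  n_next[is.na(n_next)] <- 0

  r_star <- numeric(m)
  switched <- FALSE
  switch_point <- NA_integer_
  for (j in seq_len(m)) {
    x_lgt <- r[j] * (1 + 1 / r[j])^(b + 1)      # (r+1) S(r+1)/S(r)
    if (!switched) {
      if (n_next[j] == 0) {
        switched <- TRUE
        switch_point <- r[j]
      } else {
        x_turing <- (r[j] + 1) * n_next[j] / n_r[j]
        sd_t <- sqrt((r[j] + 1)^2 * (n_next[j] / n_r[j]^2) * (1 + n_next[j] / n_r[j]))
        if (abs(x_turing - x_lgt) <= 1.96 * sd_t) {
          switched <- TRUE
          switch_point <- r[j]
        } else {
          r_star[j] <- x_turing
          next
        }
      }
    }
    r_star[j] <- x_lgt
  }
  if (any(r_star <= 0))
    warning("sgt_fit: non-positive adjusted frequency produced by degenerate fit")

  # renormalise seen probabilities to 1 - P0
  p_unnorm <- r_star / n
  seen_mass <- sum(n_r * p_unnorm)
  p_r <- (1 - P0) * p_unnorm / seen_mass
  structure(list(r = r, n_r = fof$n_r, r_star = r_star, p_r = p_r, P0 = P0,
                 intercept = unname(a), slope = unname(b),
                 switch_point = switch_point, total_reads = n),
            class = "sgt_model")
}

#' @export
print.sgt_model <- function(x, ...) {
  cat(sprintf("Simple Good-Turing model: %d distinct frequencies, %d reads\n",
              length(x$r), x$total_reads))
  cat(sprintf("  P0 = %.4g; log-linear fit: intercept %.3f, slope %.3f; switch at r = %s\n",
              x$P0, x$intercept, x$slope, format(x$switch_point)))
  invisible(x)
}

#' Serialise an SGT model to JSON
#'
#' @param model An `"sgt_model"`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
sgt_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "sgt_model"))
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Good-Turing smoothing of an abundance estimate
#'
#' The adaptive, parameter-free smoothing route: per-transcript expected
#' counts are rounded to integers, a Simple Good-Turing model is fitted to
#' their frequencies of frequencies, and the smoothed distribution is
#' assembled as
#' \itemize{
#'   \item expressed transcripts (rounded count r > 0): probability
#'     proportional to the adjusted frequency over the effective length,
#'     \eqn{r^\star_i / \tilde\ell_i}, normalised to total \eqn{1 - P_0};
#'   \item unexpressed transcripts (rounded count 0): the unseen mass
#'     \eqn{P_0} split proportionally to effective length.
#' }
#' Unlike Laplacian smoothing the redistributed mass shrinks with
#' sequencing depth (\eqn{P_0 = n_1/n}), so deeply sequenced estimates are
#' smoothed less.
#'
#' @param est An [abundance_estimate()].
#' @return A [theta_distribution()] with `method = "sgt"`; its `params`
#'   hold the fitted `"sgt_model"`.
#' @export
sgt_smooth <- function(est) {
  stopifnot(inherits(est, "abundance_estimate"))
  cnt <- round_counts(est)
  if (all(cnt == 0L)) stop("sgt_smooth: no expressed transcripts after rounding")
  model <- sgt_fit(freq_of_freq(cnt))
  el <- est$EffectiveLength
  probs <- numeric(length(cnt))
  expressed <- cnt > 0L
  w <- model$r_star[match(cnt[expressed], model$r)] / el[expressed]
  if (any(!expressed)) {
    probs[expressed] <- (1 - model$P0) * w / sum(w)
    lu <- el[!expressed]
    probs[!expressed] <- model$P0 * lu / sum(lu)
  } else {
    # no unexpressed transcripts: the P0 share is vacuous, seen mass is all
    probs[expressed] <- w / sum(w)
  }
  theta_distribution(probs / sum(probs), method = "sgt",
                     params = list(model = model), names = est$Name)
}
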