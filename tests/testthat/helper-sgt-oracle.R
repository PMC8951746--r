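# Independent reference implementation of the Simple Good-Turing estimator,
# written as a direct, loop-by-loop transcription of the Gale & Sampson
# procedure. Deliberately unvectorised and sharing no code with the package:
# it exists only to cross-check sgt_fit().
#
# Input: integer vectors r (distinct observed frequencies, ascending) and
# n (their frequencies of frequencies). Output mirrors sgt_fit()'s fields.
sgt_oracle <- function(r, n) {
  stopifnot(length(r) == length(n), !is.unsorted(r, strictly = TRUE))
  m <- length(r)
  bign <- 0
  for (j in 1:m) bign <- bign + r[j] * n[j]
  p0 <- if (r[1] == 1) n[1] / bign else 0

  # Z-values: Z_j = n_j / (0.5 * (t - q)), neighbours q (previous r, 0 for
  # the first) and t (next r, 2*r_m - q for the last).
  zval <- numeric(m)
  for (j in 1:m) {
    q <- if (j == 1) 0 else r[j - 1]
    t <- if (j == m) 2 * r[m] - q else r[j + 1]
    zval[j] <- n[j] / (0.5 * (t - q))
  }
  # least-squares fit of log(Z) on log(r), computed from the normal
  # equations directly
  xs <- log(r); ys <- log(zval)
  xbar <- mean(xs); ybar <- mean(ys)
  num <- 0; den <- 0
  for (j in 1:m) {
    num <- num + (xs[j] - xbar) * (ys[j] - ybar)
    den <- den + (xs[j] - xbar)^2
  }
  slope <- num / den
  intercept <- ybar - slope * xbar
  smoothed <- function(rr) exp(intercept + slope * log(rr))

  rstar <- numeric(m)
  use_lgt <- FALSE
  switch_point <- NA
  for (j in 1:m) {
    y <- (r[j] + 1) * smoothed(r[j] + 1) / smoothed(r[j])
    if (!use_lgt) {
      nr1 <- 0
      for (jj in 1:m) if (r[jj] == r[j] + 1) nr1 <- n[jj]
      if (nr1 == 0) {
        use_lgt <- TRUE
        switch_point <- r[j]
      } else {
        x <- (r[j] + 1) * nr1 / n[j]
        sd_turing <- sqrt((r[j] + 1)^2 * (nr1 / n[j]^2) * (1 + nr1 / n[j]))
        if (abs(x - y) <= 1.96 * sd_turing) {
          use_lgt <- TRUE
          switch_point <- r[j]
        } else {
          rstar[j] <- x
        }
      }
    }
    if (use_lgt) rstar[j] <- y
  }

  total <- 0
  for (j in 1:m) total <- total + n[j] * rstar[j] / bign
  p <- numeric(m)
  for (j in 1:m) p[j] <- (1 - p0) * (rstar[j] / bign) / total
  list(P0 = p0, r_star = rstar, p_r = p, slope = slope,
       intercept = intercept, switch_point = switch_point)
}

# random frequency-of-frequencies tables with roughly power-law n_r,
# the shape SGT assumes
random_fof_table <- function(seed, max_r = 30L) {
  set.seed(seed)
  r <- sort(sample(1:max_r, sample(5:15, 1)))
  if (!1L %in% r) r <- sort(c(1L, r[-1]))
  n <- pmax(1L, as.integer(round(300 / r^stats::runif(1, 1.2, 2) *
                                   stats::runif(length(r), 0.6, 1.4))))
  list(r = r, n = n)
}
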