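test_that("laplace smoothing follows the closed form and its identity case", {
  theta <- theta_distribution(c(1, 0))
  expect_identical(laplace_smooth(theta, beta = 0), theta)
  sm <- laplace_smooth(theta, beta = 0.5, M = 2)
  expect_equal(unname(sm$probs), c(0.75, 0.25))  # (1+0.5)/(1+2*0.5)
  expect_equal(sm$method, "laplace")
  expect_error(laplace_smooth(theta, beta = -1), ">= 0")

  # default beta is small and strictly positive
  sm2 <- laplace_smooth(theta)
  expect_equal(sm2$params$beta, 1e-8)
  expect_true(all(sm2$probs > 0))
})

test_that("laplace smoothing preserves ordering and normalisation", {
  set.seed(11)
  for (i in 1:5) {
    p <- stats::rgamma(40, 0.3); p[sample(40, 10)] <- 0; p <- p / sum(p)
    theta <- theta_distribution(p)
    for (beta in c(1e-10, 1e-4, 0.3)) {
      sm <- laplace_smooth(theta, beta)
      expect_equal(sum(sm$probs), 1, tolerance = 1e-12)
      ij <- which(outer(p, p, ">"), arr.ind = TRUE)
      expect_true(all(sm$probs[ij[, 1]] > sm$probs[ij[, 2]]))
    }
  }
})

test_that("count rounding is half-to-even with zeros preserved", {
  expect_equal(round_counts(c(10.4, 0.6, 0.0)), c(10L, 1L, 0L))
  expect_equal(round_counts(c(0.5, 1.5, 2.5)), c(0L, 2L, 2L))
  set.seed(4)
  x <- stats::rgamma(200, 0.5) * 10
  expect_lte(abs(sum(round_counts(x)) - sum(x)), 100)  # <= M/2
})

test_that("frequencies of frequencies tally counts and exclude zeros", {
  fof <- freq_of_freq(c(1L, 1L, 2L, 0L))
  expect_equal(fof$r, c(1L, 2L))
  expect_equal(fof$n_r, c(2L, 1L))
  expect_equal(fof$total_reads, 4L)

  empty <- freq_of_freq(c(0L, 0L))
  expect_length(empty$r, 0)
  expect_equal(empty$total_reads, 0L)
})

test_that("power-law counts give near log-linear frequencies of frequencies", {
  truth <- simulate_truth(2000L, sparsity = 0.4, concentration = 0.2, seed = 42L)
  set.seed(43)
  counts <- as.integer(stats::rmultinom(1, 5e4, truth$theta))
  fof <- freq_of_freq(counts)
  # one observation per transcript (weight n_r): the sparse large-r tail,
  # where most n_r are 0 or 1, is exactly what the SGT Z-transform smooths
  fit <- stats::lm(log(n_r) ~ log(r), data = data.frame(r = fof$r, n_r = fof$n_r),
                   weights = fof$n_r)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("sgt_fit matches the independent Gale-Sampson oracle", {
  for (seed in 1:20) {
    tab <- random_fof_table(seed)
    fof <- structure(list(r = tab$r, n_r = tab$n,
                          total_reads = sum(tab$r * tab$n)),
                     class = "freq_of_freq")
    got <- suppressWarnings(sgt_fit(fof))
    want <- sgt_oracle(tab$r, tab$n)
    expect_equal(got$P0, want$P0, tolerance = 1e-12)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$r_star, want$r_star, tolerance = 1e-9)
    expect_equal(got$p_r, want$p_r, tolerance = 1e-9)
    expect_equal(got$switch_point, as.integer(want$switch_point))
    # mass conservation: P0 plus renormalised seen mass is 1
    expect_equal(got$P0 + sum(got$n_r * got$p_r), 1, tolerance = 1e-9)
  }
})

test_that("sgt_fit computes P0 = n_1/n and flags degenerate inputs", {
  fof <- freq_of_freq(c(1L, 1L, 1L, 2L, 2L, 3L))  # {1:3, 2:2, 3:1}, n = 10
  expect_warning(model <- sgt_fit(fof), "degenerate")
  expect_equal(model$P0, 0.3)

  # no singletons: P0 = 0 with a warning
  fof0 <- freq_of_freq(c(2L, 2L, 3L))
  # warns both about the missing singletons and the shallow two-point fit
  expect_warning(expect_warning(m0 <- sgt_fit(fof0), "n_1"), "degenerate")
  expect_equal(m0$P0, 0)

  expect_error(sgt_fit(freq_of_freq(c(1L, 1L))), "2 distinct")
})

test_that("sgt_smooth assigns length-proportional mass to unexpressed transcripts", {
  set.seed(9)
  counts <- c(stats::rpois(30, 20), sample(1:4, 10, replace = TRUE), 0, 0)
  lens <- c(rep(500, 40), 100, 300)
  est <- abundance_estimate(sprintf("t%d", 1:42), lens, est_counts = counts)
  theta <- suppressWarnings(sgt_smooth(est))
  expect_equal(sum(theta$probs), 1, tolerance = 1e-9)
  expect_true(all(theta$probs > 0))
  P0 <- theta$params$model$P0
  expect_gt(P0, 0)
  # the two unexpressed transcripts split P0 as 100:300
  expect_equal(unname(theta$probs[41] / (theta$probs[41] + theta$probs[42])), 0.25,
               tolerance = 1e-12)
  expect_equal(unname(sum(theta$probs[41:42])), P0, tolerance = 1e-12)
})

test_that("sgt_smooth with no unexpressed transcripts renormalises seen mass to 1", {
  set.seed(10)
  counts <- c(stats::rpois(20, 10) + 1L, sample(1:3, 8, replace = TRUE))
  est <- abundance_estimate(sprintf("t%d", 1:28), rep(1000, 28),
                            est_counts = counts)
  theta <- suppressWarnings(sgt_smooth(est))
  expect_equal(sum(theta$probs), 1, tolerance = 1e-12)
  expect_true(all(theta$probs > 0))

  zero <- abundance_estimate("t1", 100, est_counts = 0.2)
  expect_error(sgt_smooth(zero), "no expressed")
})

test_that("smoothed distributions make every in-reference fragment possible", {
  toy <- toy_trap()
  theta_raw <- estimate_to_theta(toy$all_on_A)
  expect_gt(count_impossible(toy$validation, theta_raw)$n_impossible_fragments, 0)
  theta_lap <- laplace_smooth(theta_raw)
  expect_equal(count_impossible(toy$validation, theta_lap)$n_impossible_fragments, 0L)
  pp <- perplexity(toy$validation, theta_lap)
  expect_true(is.finite(pp$perplexity))
})

test_that("smaller Laplace beta penalises impossible fragments harder", {
  toy <- toy_trap()
  theta_raw <- estimate_to_theta(toy$all_on_A)
  betas <- 10^seq(-12, -2, by = 1)
  pps <- vapply(betas, function(b)
    perplexity(toy$validation, laplace_smooth(theta_raw, b))$perplexity,
    numeric(1))
  expect_true(all(diff(pps) <= 0))  # non-increasing in beta
})

test_that("sgt model JSON dump is readable", {
  fof <- freq_of_freq(c(1L, 1L, 1L, 2L, 2L, 3L))
  model <- suppressWarnings(sgt_fit(fof))
  js <- jsonlite::fromJSON(sgt_to_json(model))
  expect_equal(js$P0, 0.3)
  expect_equal(js$r, c(1, 2, 3))
})
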