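test_that("FASTQ splitting partitions records evenly, deterministically", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq")
  simulate_fastq(10L, fq, seed = 5L)
  man <- split_fastq(fq, k = 5L, seed = 99L, outdir = file.path(dir, "s"))
  expect_equal(man$n_validation, rep(2L, 5))
  for (i in 1:5) {
    val <- read_fastq_lines(man$validation_1[i])
    quo <- read_fastq_lines(man$quantified_1[i])
    expect_equal(length(val) / 4L, 2)
    expect_equal(length(quo) / 4L, 8)
  }
  # determinism: same seed, same assignment
  man2 <- split_fastq(fq, k = 5L, seed = 99L, outdir = file.path(dir, "s2"))
  expect_identical(attr(man, "assignments"), attr(man2, "assignments"))
  # conservation: validation folds together reproduce the input records
  all_names <- sort(unlist(lapply(man$validation_1, function(p) {
    l <- read_fastq_lines(p); l[seq(1, length(l), 4)]
  })))
  expect_equal(all_names, sort(sprintf("@frag_%06d", 1:10)))
})

test_that("paired-end mates are always co-assigned and gz output round-trips", {
  dir <- withr::local_tempdir()
  fq1 <- file.path(dir, "r_1.fastq.gz")
  fq2 <- file.path(dir, "r_2.fastq.gz")
  simulate_fastq(23L, fq1, fq2, seed = 7L)
  man <- split_fastq(fq1, fq2, k = 3L, seed = 11L, outdir = file.path(dir, "s"))
  expect_true(all(grepl("\\.gz$", man$validation_2)))
  for (i in 1:3) {
    n1 <- fastq_names(man$validation_1[i])
    n2 <- fastq_names(man$validation_2[i])
    expect_identical(n1, n2)   # mate co-assignment
  }
  sizes <- man$n_validation
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sum(sizes), 23L)

  # mismatched pairs are rejected
  fq3 <- file.path(dir, "short_2.fastq")
  simulate_fastq(5L, fq3, seed = 8L)
  expect_error(split_fastq(fq1, fq3, k = 2L, seed = 1L,
                           outdir = file.path(dir, "x")),
               "different record counts")
})

test_that("eqclass splitting conserves counts and is seed-deterministic", {
  coll <- eqclass_collection(c("a", "b"),
                             list(eqclass(c(1, 2), c(0.5, 0.5), 10)))
  folds <- split_eqclasses(coll, k = 2L, seed = 3L)
  vt <- sum(vapply(folds, function(f) f$validation$total_fragments, integer(1)))
  expect_equal(vt, 10L)
  for (f in folds)
    expect_equal(f$validation$total_fragments + f$quantified$total_fragments, 10L)

  inst <- random_instance(21L, M = 25L, N = 4000L)
  f1 <- split_eqclasses(inst$collection, k = 5L, seed = 42L)
  f2 <- split_eqclasses(inst$collection, k = 5L, seed = 42L)
  expect_identical(f1[[3]]$validation$classes, f2[[3]]$validation$classes)
  # per-class union of quantified+validation equals the original
  for (i in 1:5) {
    key <- function(cl) paste(cl$labels, collapse = ",")
    orig <- sapply(inst$collection$classes, `[[`, "count")
    names(orig) <- sapply(inst$collection$classes, key)
    vc <- sapply(f1[[i]]$validation$classes, `[[`, "count")
    names(vc) <- sapply(f1[[i]]$validation$classes, key)
    qc <- sapply(f1[[i]]$quantified$classes, `[[`, "count")
    names(qc) <- sapply(f1[[i]]$quantified$classes, key)
    for (kk in names(orig)) {
      expect_equal(sum(vc[kk], na.rm = TRUE) + sum(qc[kk], na.rm = TRUE),
                   unname(orig[kk]))
    }
  }
  expect_error(split_eqclasses(coll, k = 1L, seed = 1L), ">= 2")
})

test_that("validation shares are binomial with mean N/k", {
  coll <- eqclass_collection("a", list(eqclass(1, 1, 200)))
  shares <- vapply(1:200, function(s)
    split_eqclasses(coll, k = 4L, seed = s)[[1]]$validation$total_fragments,
    integer(1))
  # mean within 3 sigma of N/k for Binomial(200, 1/4) averaged over 200 seeds
  se <- sqrt(200 * 0.25 * 0.75 / 200)
  expect_lt(abs(mean(shares) - 50), 3 * se)
})

test_that("necessarily impossible classes are removed by the covered-transcript rule", {
  names <- c("t1", "t2", "t3")
  quantified <- eqclass_collection(names, list(eqclass(c(1, 2), c(0.5, 0.5), 5)))
  validation <- eqclass_collection(names, list(
    eqclass(3, 1, 4),                      # only uncovered t3: removed
    eqclass(c(2, 3), c(0.5, 0.5), 6),      # t2 covered: retained (recoverable)
    eqclass(1, 1, 2)))
  out <- remove_necessarily_impossible(validation, quantified)
  expect_equal(out$removed_fragments, 4L)
  expect_equal(out$removed_classes, 1L)
  expect_equal(out$validation$total_fragments, 8L)

  # full coverage removes nothing
  qfull <- eqclass_collection(names, list(eqclass(c(1, 2, 3), rep(1 / 3, 3), 9)))
  out2 <- remove_necessarily_impossible(validation, qfull)
  expect_equal(out2$removed_classes, 0L)

  # never removes a class some quantified fragment could explain
  for (seed in c(12L, 34L)) {
    inst <- random_instance(seed, M = 12L, N = 400L, sparsity = 0.5)
    folds <- split_eqclasses(inst$collection, k = 2L, seed = seed)
    f <- folds[[1]]
    out <- remove_necessarily_impossible(f$validation, f$quantified)
    covered <- rep(FALSE, 12)
    for (cl in f$quantified$classes) covered[cl$labels] <- TRUE
    for (cl in out$validation$classes)
      expect_true(any(covered[cl$labels]))
    kept_keys <- sapply(out$validation$classes,
                        function(cl) paste(cl$labels, collapse = ","))
    for (cl in f$validation$classes) {
      if (!paste(cl$labels, collapse = ",") %in% kept_keys)
        expect_false(any(covered[cl$labels]))
    }
  }
})

test_that("evaluate_model scores candidates and select_model breaks ties by sparsity", {
  inst <- random_instance(55L, M = 30L, N = 6000L, sparsity = 0.4)
  folds <- split_eqclasses(inst$collection, k = 3L, seed = 9L)
  vals <- lapply(folds, function(f)
    remove_necessarily_impossible(f$validation, f$quantified)$validation)
  cands <- list(
    "0.1" = lapply(folds, function(f)
      em_quantify(f$quantified, prior_size = 0.1, mode = "vbem")),
    "10" = lapply(folds, function(f)
      em_quantify(f$quantified, prior_size = 10, mode = "vbem")))
  scores <- evaluate_model(cands, vals, smooth = "laplace", beta = 1e-8)
  expect_equal(dim(scores$per_fold), c(2L, 3L))
  expect_true(all(is.finite(scores$mean_perplexity)))
  expect_equal(scores$mean_perplexity, rowMeans(scores$per_fold))

  sel <- select_model(scores)
  expect_true(sel %in% c("0.1", "10"))

  # tie-break: synthetic score object with a near-tie
  fake <- structure(list(model_ids = c("m1", "m2", "m3"),
                         per_fold = rbind(c(10, 10), c(9, 9.002), c(9.5, 9.5)),
                         mean_perplexity = c(10, 9.001, 9.5),
                         sparsity = c(5000, 4000, 100),
                         smooth = "sgt", beta = 1e-8),
                    class = "model_scores")
  expect_equal(as.character(select_model(fake)), "m2")
  fake$mean_perplexity <- c(9.000, 9.001, 9.5)
  fake$sparsity <- c(5000, 4000, 100)
  expect_equal(as.character(select_model(fake)), "m2")  # within 0.1%: sparser wins
  fake$mean_perplexity <- c(10, 9, 9.5)
  expect_equal(as.character(select_model(fake)), "m2")  # strict argmin

  single <- fake; single$model_ids <- "only"
  single$mean_perplexity <- 3; single$sparsity <- 1
  single$per_fold <- matrix(3, 1, 2)
  expect_equal(as.character(select_model(single)), "only")
  allinf <- single; allinf$mean_perplexity <- Inf
  expect_error(select_model(allinf), "no admissible")

  expect_error(evaluate_model(cands, vals[1]), ">= 2 folds")
})

test_that("symmetric folds of one candidate score within sampling noise", {
  inst <- random_instance(66L, M = 20L, N = 20000L, sparsity = 0)
  folds <- split_eqclasses(inst$collection, k = 4L, seed = 2L)
  vals <- lapply(folds, function(f)
    remove_necessarily_impossible(f$validation, f$quantified)$validation)
  cand <- list(em = lapply(folds, function(f) em_quantify(f$quantified, mode = "em")))
  scores <- evaluate_model(cand, vals, smooth = "laplace")
  pf <- scores$per_fold[1, ]
  expect_lt((max(pf) - min(pf)) / mean(pf), 0.05)
})
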