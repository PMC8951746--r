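#' Split FASTQ files into K quantify/validate fold pairs
#'
#' Partitions the records of a (single- or paired-end) FASTQ input into K
#' equal-sized validation folds uniformly at random (fold sizes differ by at
#' most one); the quantified set of fold i is everything not in validation
#' fold i. Mates of a pair are always co-assigned. Record content is opaque
#' to the splitter — records are streamed through verbatim — so any
#' well-formed 4-line-per-record FASTQ works, gzipped or plain.
#'
#' @param fastq1 Path to the (first) FASTQ file.
#' @param fastq2 Optional path to the mate file for paired-end input; must
#'   hold the same number of records.
#' @param k Number of folds, >= 2 (default 5).
#' @param seed Integer RNG seed (mandatory, recorded in the manifest).
#' @param outdir Output directory (created if needed).
#' @param prefix File-name prefix for outputs (default `"fold"`).
#' @return Invisibly, a `data.frame` manifest with one row per fold and
#'   columns `fold`, `n_validation`, plus the validation and quantified
#'   file paths; attribute `assignments` holds the fold id of every record
#'   and attribute `seed` the seed.
#' @export
split_fastq <- function(fastq1, fastq2 = NULL, k = 5L, seed, outdir,
                        prefix = "fold") {
  if (k < 2L) stop("split_fastq: k must be >= 2")
  if (missing(seed)) stop("split_fastq: seed is required")
  recs1 <- read_fastq_records(fastq1)
  recs2 <- if (!is.null(fastq2)) read_fastq_records(fastq2) else NULL
  n <- length(recs1)
  if (n == 0L) stop("split_fastq: no records in ", fastq1)
  if (!is.null(recs2) && length(recs2) != n)
    stop("split_fastq: paired files have different record counts (",
         n, " vs ", length(recs2), ")")
  assignments <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gz <- grepl("\\.gz$", fastq1)
  ext <- if (gz) ".fastq.gz" else ".fastq"
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    val <- assignments == i
    v1 <- file.path(outdir, paste0(prefix, i, "_validation_1", ext))
    q1 <- file.path(outdir, paste0(prefix, i, "_quantified_1", ext))
    write_fastq_records(recs1[val], v1)
    write_fastq_records(recs1[!val], q1)
    row <- data.frame(fold = i, n_validation = sum(val),
                      validation_1 = v1, quantified_1 = q1,
                      stringsAsFactors = FALSE)
    if (!is.null(recs2)) {
      v2 <- file.path(outdir, paste0(prefix, i, "_validation_2", ext))
      q2 <- file.path(outdir, paste0(prefix, i, "_quantified_2", ext))
      write_fastq_records(recs2[val], v2)
      write_fastq_records(recs2[!val], q2)
      row$validation_2 <- v2
      row$quantified_2 <- q2
    }
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "assignments") <- assignments
  attr(manifest, "seed") <- seed
  invisible(manifest)
}

# FASTQ records as a character vector, one 4-line record per element.
read_fastq_records <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)   # gz-transparent
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  if (length(lines) == 0L) return(character(0))
  idx <- seq(1L, length(lines), by = 4L)
  if (!all(startsWith(lines[idx], "@")))
    stop("malformed FASTQ (header lines must start with '@'): ", path)
  vapply(idx, function(i) paste(lines[i:(i + 3L)], collapse = "\n"),
         character(1))
}

write_fastq_records <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(records)) writeLines(records, con)
  invisible(path)
}

# Run expr with a local RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split an equivalence-class collection into K fold pairs
#'
#' The sufficient-statistics analogue of [split_fastq()]: each class's
#' \eqn{N^q} fragments are split multinomially (uniform over folds) across
#' the K validation folds, and the quantified collection of fold i holds
#' the complement. Classes left with zero fragments in a sub-collection are
#' dropped; totals are conserved exactly.
#'
#' @param collection An [eqclass_collection()].
#' @param k Number of folds, >= 2 (default 5).
#' @param seed Integer RNG seed (mandatory).
#' @return A list of k elements, each `list(quantified=, validation=)` of
#'   [eqclass_collection()]s; attribute `seed` records the seed.
#' @export
split_eqclasses <- function(collection, k = 5L, seed) {
  stopifnot(inherits(collection, "eqclass_collection"))
  if (k < 2L) stop("split_eqclasses: k must be >= 2")
  if (missing(seed)) stop("split_eqclasses: seed is required")
  classes <- collection$classes
  nC <- length(classes)
  shares <- with_seed(seed, {
    vapply(classes, function(cl)
      as.integer(stats::rmultinom(1L, cl$count, rep(1 / k, k))), integer(k))
  })
  if (nC == 1L) shares <- matrix(shares, nrow = k)
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    val_classes <- list(); quant_classes <- list()
    for (ci in seq_len(nC)) {
      cl <- classes[[ci]]
      nv <- shares[i, ci]
      nq <- cl$count - nv
      if (nv > 0L) {
        clv <- cl; clv$count <- nv
        val_classes[[length(val_classes) + 1L]] <- clv
      }
      if (nq > 0L) {
        clq <- cl; clq$count <- nq
        quant_classes[[length(quant_classes) + 1L]] <- clq
      }
    }
    folds[[i]] <- list(
      quantified = eqclass_collection(collection$transcript_names,
                                      quant_classes, collection$lengths),
      validation = eqclass_collection(collection$transcript_names,
                                      val_classes, collection$lengths))
  }
  attr(folds, "seed") <- seed
  folds
}

#' Remove necessarily impossible validation classes
#'
#' A validation fragment is *necessarily* impossible if it maps only to
#' transcripts to which no fragment in the quantified set maps: no estimate
#' derivable from the quantified set could ever explain it, so penalising
#' estimates for it is meaningless. Such classes are removed before
#' perplexity is computed. A class with even one transcript covered by the
#' quantified set is recoverable (a better estimate could assign it mass)
#' and is retained.
#'
#' @param validation,quantified [eqclass_collection()]s over the same
#'   transcript namespace.
#' @return A list: `validation` (filtered collection), `removed_fragments`,
#'   `removed_classes`.
#' @export
remove_necessarily_impossible <- function(validation, quantified) {
  stopifnot(inherits(validation, "eqclass_collection"),
            inherits(quantified, "eqclass_collection"))
  if (!identical(validation$transcript_names, quantified$transcript_names))
    stop("remove_necessarily_impossible: transcript name sets differ")
  covered <- rep(FALSE, length(validation$transcript_names))
  for (cl in quantified$classes) covered[cl$labels] <- TRUE
  keep <- vapply(validation$classes, function(cl) any(covered[cl$labels]),
                 logical(1))
  removed <- validation$classes[!keep]
  list(validation = eqclass_collection(validation$transcript_names,
                                       validation$classes[keep],
                                       validation$lengths),
       removed_fragments = sum(vapply(removed, `[[`, integer(1), "count"), 0L),
       removed_classes = sum(!keep))
}

#' Score candidate models by per-fold smoothed perplexity
#'
#' Computes the smoothed perplexity of each candidate's per-fold abundance
#' estimate against the matching validation fold and averages over folds.
#' A fold with infinite smoothed perplexity (possible only when SGT yields
#' \eqn{P_0 = 0}) poisons the candidate's mean to `+Inf`: perplexities are
#' only comparable on identical validation sets, so dropping the fold for
#' one candidate but not another would bias the comparison.
#'
#' @param candidates Named list: one element per candidate model, each a
#'   list of k [abundance_estimate()]s (one per fold).
#' @param folds List of k validation [eqclass_collection()]s (already
#'   filtered of necessarily impossible classes).
#' @param smooth `"sgt"` (default) or `"laplace"`.
#' @param beta Laplace smoothing constant (used when `smooth="laplace"`).
#' @param convention Passed to [estimate_to_theta()].
#' @return An object of class `"model_scores"`: list with `model_ids`,
#'   `per_fold` (L x k matrix of perplexities), `mean_perplexity`,
#'   `sparsity` (mean number of transcripts with rounded count > 0),
#'   `smooth`, `beta`.
#' @export
evaluate_model <- function(candidates, folds, smooth = c("sgt", "laplace"),
                           beta = 1e-8, convention = "reads") {
  smooth <- match.arg(smooth)
  k <- length(folds)
  if (k < 2L) stop("evaluate_model: cross-validation requires >= 2 folds")
  L <- length(candidates)
  if (L < 1L) stop("evaluate_model: no candidates")
  ids <- names(candidates)
  if (is.null(ids)) ids <- as.character(seq_len(L))
  per_fold <- matrix(NA_real_, L, k, dimnames = list(ids, NULL))
  sparsity <- numeric(L)
  for (l in seq_len(L)) {
    ests <- candidates[[l]]
    if (length(ests) != k)
      stop("evaluate_model: candidate '", ids[l], "' has ", length(ests),
           " estimates for ", k, " folds")
    sp <- numeric(k)
    for (i in seq_len(k)) {
      est <- ests[[i]]
      theta <- if (smooth == "sgt") sgt_smooth(est)
               else laplace_smooth(estimate_to_theta(est, convention), beta)
      per_fold[l, i] <- perplexity(folds[[i]], theta)$perplexity
      sp[i] <- sum(round_counts(est) > 0L)
    }
    sparsity[l] <- mean(sp)
  }
  structure(list(model_ids = ids, per_fold = per_fold,
                 mean_perplexity = rowMeans(per_fold),
                 sparsity = sparsity, smooth = smooth, beta = beta),
            class = "model_scores")
}

#' @export
print.model_scores <- function(x, ...) {
  df <- data.frame(model = x$model_ids,
                   mean_perplexity = x$mean_perplexity,
                   sparsity = x$sparsity)
  cat(sprintf("Model scores over %d folds (%s smoothing):\n",
              ncol(x$per_fold), x$smooth))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select the best model from cross-validated perplexities
#'
#' Returns the candidate minimising mean perplexity; among candidates whose
#' means are within `tie_tolerance` (relative) of the minimum, the one with
#' the *sparsest* estimates (fewest expressed transcripts) wins. Perplexity
#' tends to prefer smoother-than-ideal estimates, so near-ties are broken
#' in favour of sparsity.
#'
#' @param scores A `"model_scores"` object from [evaluate_model()].
#' @param tie_tolerance Relative tolerance for the near-tie set (default
#'   0.001, i.e. 0.1%).
#' @return The selected model id (character scalar) with attribute `index`.
#' @export
select_model <- function(scores, tie_tolerance = 0.001) {
  stopifnot(inherits(scores, "model_scores"))
  mp <- scores$mean_perplexity
  if (all(!is.finite(mp))) stop("select_model: no admissible model (all means infinite)")
  best <- min(mp[is.finite(mp)])
  tied <- which(is.finite(mp) & mp <= best * (1 + tie_tolerance))
  pick <- tied[which.min(scores$sparsity[tied])]
  structure(scores$model_ids[pick], index = pick)
}

#' Cross-validated perplexity model selection, end to end
#'
#' The full quantify-then-validate protocol on a single fragment set
#' summarised as equivalence classes: split into K folds
#' ([split_eqclasses()]), quantify each fold's quantified set with the
#' built-in quantifier at every candidate prior ([em_quantify()]), remove
#' necessarily impossible validation classes
#' ([remove_necessarily_impossible()]), score the candidates by smoothed
#' perplexity ([evaluate_model()]) and select the winner ([select_model()]).
#'
#' @param collection An [eqclass_collection()] of all fragments.
#' @param priors Numeric vector of VBEM reads-per-transcript prior sizes to
#'   sweep (default `c(0.01, 0.1, 1, 10, 100)`). In `"em"` mode a single
#'   unnamed candidate is fitted instead.
#' @param k Folds (default 5). `seed` is mandatory.
#' @param seed Integer RNG seed for the fold split.
#' @param mode Quantifier mode, `"vbem"` (default) or `"em"`.
#' @param smooth,beta,convention Passed to [evaluate_model()].
#' @param ... Passed to [em_quantify()] (e.g. `max_iters`, `tol`).
#' @return An object of class `"perplexity_cv"`: list with `scores`
#'   (`"model_scores"`), `selected` (model id), `estimates` (candidate ->
#'   per-fold estimates), `folds`, `removed_fragments` (per fold), `k`,
#'   `seed`.
#' @export
perplexity_cv <- function(collection, priors = c(0.01, 0.1, 1, 10, 100),
                          k = 5L, seed, mode = c("vbem", "em"),
                          smooth = c("sgt", "laplace"), beta = 1e-8,
                          convention = "reads", ...) {
  mode <- match.arg(mode)
  smooth <- match.arg(smooth)
  if (missing(seed)) stop("perplexity_cv: seed is required")
  folds <- split_eqclasses(collection, k = k, seed = seed)
  removed <- integer(k)
  val_sets <- vector("list", k)
  for (i in seq_len(k)) {
    filt <- remove_necessarily_impossible(folds[[i]]$validation,
                                          folds[[i]]$quantified)
    val_sets[[i]] <- filt$validation
    removed[i] <- filt$removed_fragments
  }
  ids <- if (mode == "vbem") as.character(priors) else "em"
  candidates <- lapply(seq_along(ids), function(l) {
    lapply(seq_len(k), function(i) {
      if (mode == "vbem")
        em_quantify(folds[[i]]$quantified, prior_size = priors[l],
                    mode = "vbem", ...)
      else em_quantify(folds[[i]]$quantified, mode = "em", ...)
    })
  })
  names(candidates) <- ids
  scores <- evaluate_model(candidates, val_sets, smooth = smooth, beta = beta,
                           convention = convention)
  structure(list(scores = scores, selected = select_model(scores),
                 estimates = candidates, folds = folds,
                 validation_sets = val_sets,
                 removed_fragments = removed, k = k, seed = seed,
                 mode = mode),
            class = "perplexity_cv")
}

#' @export
print.perplexity_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated perplexity (seed %d, %s quantifier, %s smoothing)\n",
              x$k, x$seed, x$mode, x$scores$smooth))
  print(x$scores)
  cat(sprintf("Selected model: %s\n", x$selected))
  if (sum(x$removed_fragments) > 0)
    cat(sprintf("Necessarily impossible fragments removed per fold: %s\n",
                paste(x$removed_fragments, collapse = ", ")))
  invisible(x)
}

#' @export
summary.perplexity_cv <- function(object, ...) {
  df <- data.frame(model = object$scores$model_ids,
                   mean_perplexity = object$scores$mean_perplexity,
                   sparsity = object$scores$sparsity,
                   selected = object$scores$model_ids == as.character(object$selected))
  df
}

#' Plot mean perplexity against the swept hyperparameter
#'
#' Grey points: per-fold perplexities; filled line/points: fold means; the
#' selected model is marked. The x axis is logarithmic when all model ids
#' are positive numbers (the usual prior-size sweep).
#'
#' @param x A `"perplexity_cv"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.perplexity_cv <- function(x, ...) {
  ids <- x$scores$model_ids
  xv <- suppressWarnings(as.numeric(ids))
  numeric_axis <- !anyNA(xv) && all(xv > 0)
  if (!numeric_axis) xv <- seq_along(ids)
  pf <- x$scores$per_fold
  graphics::plot(rep(xv, ncol(pf)), as.vector(pf),
                 log = if (numeric_axis) "x" else "",
                 col = "grey60", pch = 1,
                 xlab = if (numeric_axis) "prior size (reads/transcript)" else "model",
                 ylab = "smoothed perplexity", ...)
  graphics::lines(xv, x$scores$mean_perplexity, col = "red3")
  graphics::points(xv, x$scores$mean_perplexity, col = "red3", pch = 19)
  sel <- attr(x$selected, "index")
  graphics::points(xv[sel], x$scores$mean_perplexity[sel], pch = 8, cex = 1.6)
  invisible(x)
}
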