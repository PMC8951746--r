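#' Simulate a ground-truth transcript abundance distribution
#'
#' Draws a sparse truth: a fixed fraction of transcripts get exactly zero
#' expression and the remainder get Dirichlet-distributed probabilities.
#' Small concentrations give power-law-like abundance profiles whose
#' rounded-count frequencies of frequencies are near log-linear — the
#' regime Good-Turing smoothing assumes. Transcript lengths are drawn
#' uniformly within `length_range`.
#'
#' @param M Number of transcripts (>= 2).
#' @param sparsity Fraction of transcripts with zero truth expression, in
#'   \[0, 1); `round(sparsity * M)` entries are zeroed.
#' @param concentration Dirichlet concentration for the expressed support
#'   (default 0.5, long-tailed).
#' @param length_range Integer bounds for transcript lengths in nucleotides
#'   (default 500–3000).
#' @param seed Integer RNG seed (mandatory; identical seeds give identical
#'   output).
#' @return A list with `theta` (probabilities summing to 1), `lengths`,
#'   and `transcript_names` (`"tx0001"`, ...).
#' @export
simulate_truth <- function(M, sparsity = 0.5, concentration = 0.5,
                           length_range = c(500L, 3000L), seed) {
  if (M < 2L) stop("simulate_truth: M must be >= 2")
  if (sparsity < 0 || sparsity >= 1) stop("simulate_truth: sparsity in [0, 1)")
  if (missing(seed)) stop("simulate_truth: seed is required")
  with_seed(seed, {
    n_zero <- round(sparsity * M)
    zero_idx <- sample.int(M, n_zero)
    g <- stats::rgamma(M - n_zero, shape = concentration, rate = 1)
    # guard against an all-zero gamma draw at tiny concentrations
    if (sum(g) == 0) g[1L] <- 1
    theta <- numeric(M)
    theta[setdiff(seq_len(M), zero_idx)] <- g / sum(g)
    lengths <- sample(length_range[1L]:length_range[2L], M, replace = TRUE)
    list(theta = theta, lengths = lengths,
         transcript_names = sprintf("tx%04d", seq_len(M)))
  })
}

#' Simulate an equivalence-class collection from a known truth
#'
#' Draws N fragment origins from `theta`, attaches a multi-mapping label
#' set to each fragment, and aggregates fragments with identical label
#' sets into equivalence classes. Class weights are proportional to the
#' inverse length of each labelled transcript (shorter transcripts give a
#' fragment a higher conditional probability), renormalised within the
#' class.
#'
#' The ambiguity model assigns each transcript a fixed "sibling pool"
#' (emulating groups of similar isoforms) and builds each fragment's label
#' set as its origin plus decoys from the pool:
#' \describe{
#'   \item{`"siblings"`}{each pool member is included independently with
#'     probability `decoy_prob` (default pool size 3, probability 0.5);}
#'   \item{`"one_of"`}{exactly one pool member is always included,
#'     chosen uniformly — with a pool of 2 this reproduces the classic
#'     three-transcript trap where fragments from A map only to \{A,B\} or
#'     \{A,C\} and nothing maps uniquely;}
#'   \item{`"none"`}{every fragment maps uniquely to its origin.}
#' }
#'
#' @param theta Truth probabilities (length M, summing to 1).
#' @param lengths Transcript lengths (length M).
#' @param N Number of fragments to draw.
#' @param ambiguity List: `type` one of `"siblings"`, `"one_of"`, `"none"`;
#'   `pool_size` (default 3); `decoy_prob` (default 0.5); optional `pools`,
#'   a list of explicit sibling index vectors per transcript.
#' @param seed Integer RNG seed (mandatory).
#' @param transcript_names Optional names (default `"tx0001"`, ...).
#' @return An [eqclass_collection()] with `total_fragments == N` and the
#'   `lengths` field set.
#' @export
simulate_eqclasses <- function(theta, lengths, N,
                               ambiguity = list(type = "siblings"),
                               seed, transcript_names = NULL) {
  M <- length(theta)
  stopifnot(length(lengths) == M, N >= 1)
  if (abs(sum(theta) - 1) > 1e-9) stop("simulate_eqclasses: theta must sum to 1")
  if (missing(seed)) stop("simulate_eqclasses: seed is required")
  type <- ambiguity$type %||% "siblings"
  pool_size <- ambiguity$pool_size %||% 3L
  decoy_prob <- ambiguity$decoy_prob %||% 0.5
  if (is.null(transcript_names)) transcript_names <- sprintf("tx%04d", seq_len(M))

  with_seed(seed, {
    origin_counts <- as.integer(stats::rmultinom(1L, N, theta))
    pools <- ambiguity$pools
    if (is.null(pools) && type != "none") {
      pools <- lapply(seq_len(M), function(i)
        sample(setdiff(seq_len(M), i), min(pool_size, M - 1L)))
    }
    class_tab <- new.env(parent = emptyenv())
    add_class <- function(labels, n) {
      key <- paste(labels, collapse = ",")
      prev <- class_tab[[key]]
      class_tab[[key]] <- if (is.null(prev)) n else prev + n
    }
    for (i in which(origin_counts > 0L)) {
      n_i <- origin_counts[i]
      if (type == "none" || length(pools[[i]]) == 0L) {
        add_class(i, n_i)
      } else if (type == "one_of") {
        pool <- pools[[i]]
        pick <- sample.int(length(pool), n_i, replace = TRUE)
        tab <- tabulate(pick, nbins = length(pool))
        for (j in which(tab > 0L)) add_class(sort(c(i, pool[j])), tab[j])
      } else { # siblings: independent inclusion -> multinomial over patterns
        pool <- pools[[i]]
        P <- length(pool)
        n_pat <- 2L^P
        pat_prob <- vapply(seq_len(n_pat) - 1L, function(b) {
          bits <- bitwAnd(b, 2L^(seq_len(P) - 1L)) > 0L
          prod(ifelse(bits, decoy_prob, 1 - decoy_prob))
        }, numeric(1))
        pat_counts <- as.integer(stats::rmultinom(1L, n_i, pat_prob))
        for (b in which(pat_counts > 0L)) {
          bits <- bitwAnd(b - 1L, 2L^(seq_len(P) - 1L)) > 0L
          add_class(sort(c(i, pool[bits])), pat_counts[b])
        }
      }
    }
    keys <- ls(class_tab)
    classes <- lapply(keys, function(key) {
      labels <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      eqclass(labels, 1 / lengths[labels], class_tab[[key]])
    })
    eqclass_collection(transcript_names, classes, lengths = lengths)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write placeholder FASTQ records for splitter testing
#'
#' Emits N well-formed FASTQ records (random 50-nt sequences, constant
#' quality) whose only meaningful content is the record identity and, for
#' paired output, the shared read names — exactly what the fold splitter
#' consumes. `.gz` paths are written gzip-compressed.
#'
#' @param N Number of fragments.
#' @param path Output path for the (first) mate file.
#' @param path2 Optional second-mate path; when given, mates share names.
#' @param seed Integer RNG seed (mandatory).
#' @param read_length Sequence length (default 50).
#' @return Invisibly, the path(s) written.
#' @export
simulate_fastq <- function(N, path, path2 = NULL, seed, read_length = 50L) {
  if (missing(seed)) stop("simulate_fastq: seed is required")
  with_seed(seed, {
    names <- sprintf("@frag_%06d", seq_len(N))
    qual <- strrep("I", read_length)
    seqs1 <- vapply(seq_len(N), function(i)
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
            collapse = ""), character(1))
    write_fastq_records(paste(names, seqs1, "+", qual, sep = "\n"), path)
    if (!is.null(path2)) {
      seqs2 <- vapply(seq_len(N), function(i)
        paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
              collapse = ""), character(1))
      write_fastq_records(paste(names, seqs2, "+", qual, sep = "\n"), path2)
      return(invisible(c(path, path2)))
    }
    invisible(path)
  })
}
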