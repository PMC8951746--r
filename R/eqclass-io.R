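#' Construct a single equivalence class
#'
#' An equivalence class summarises a set of fragments that map to the same
#' set of transcripts with (approximately) the same conditional mapping
#' probabilities. It is the sufficient statistic of those fragments for the
#' quantification likelihood.
#'
#' @param labels Integer vector of 1-based transcript indices (the label set
#'   \eqn{\Omega}). Must be non-empty with no duplicates; stored sorted
#'   increasing.
#' @param weights Numeric vector of conditional mapping probabilities
#'   \eqn{P(f \mid F^q, t_i)}, one per label, all >= 0. Renormalised to sum
#'   to 1 over the label set.
#' @param count Number of fragments in the class (\eqn{N^q}), a positive
#'   integer.
#' @return A list of class `"eqclass"` with elements `labels`, `weights`,
#'   `count`.
#' @export
eqclass <- function(labels, weights = NULL, count = 1L) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("eqclass: empty label set")
  if (anyDuplicated(labels)) stop("eqclass: duplicate labels")
  if (any(labels < 1L)) stop("eqclass: labels must be >= 1")
  if (is.null(weights)) weights <- rep(1, length(labels))
  weights <- as.numeric(weights)
  if (length(weights) != length(labels))
    stop("eqclass: weights length must equal labels length")
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("eqclass: weights must be finite and >= 0")
  ws <- sum(weights)
  if (ws <= 0) stop("eqclass: weights sum to zero")
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("eqclass: count must be >= 1")
  o <- order(labels)
  structure(list(labels = labels[o], weights = weights[o] / ws, count = count),
            class = "eqclass")
}

#' Construct a collection of equivalence classes
#'
#' Holds the complete sufficient statistics of a fragment set: the reference
#' transcript names, the equivalence classes with their label sets,
#' conditional-probability weights and fragment counts, and the total
#' fragment count.
#'
#' On construction the collection is canonicalised: weights renormalised
#' within each class, labels sorted, and classes with identical
#' (labels, weights) merged by summing counts.
#'
#' @param transcript_names Character vector of transcript identifiers.
#' @param classes List of [eqclass()] objects (or bare lists with the same
#'   fields).
#' @param lengths Optional numeric vector of transcript (effective) lengths,
#'   carried along for downstream quantification output; not required for
#'   likelihood evaluation since length effects live in the class weights.
#' @return A list of class `"eqclass_collection"` with elements
#'   `transcript_names`, `classes`, `total_fragments` and optionally
#'   `lengths`.
#' @export
eqclass_collection <- function(transcript_names, classes = list(), lengths = NULL) {
  transcript_names <- as.character(transcript_names)
  if (anyDuplicated(transcript_names))
    stop("eqclass_collection: duplicate transcript names")
  M <- length(transcript_names)
  classes <- lapply(classes, function(cl) {
    if (!inherits(cl, "eqclass")) cl <- eqclass(cl$labels, cl$weights, cl$count)
    if (any(cl$labels > M))
      stop("eqclass_collection: label index exceeds number of transcripts")
    cl
  })
  classes <- merge_duplicate_classes(classes)
  if (!is.null(lengths)) {
    lengths <- as.numeric(lengths)
    if (length(lengths) != M)
      stop("eqclass_collection: lengths must have one entry per transcript")
  }
  structure(list(transcript_names = transcript_names,
                 classes = classes,
                 total_fragments = sum(vapply(classes, `[[`, integer(1), "count")),
                 lengths = lengths),
            class = "eqclass_collection")
}

# Merge classes whose canonical (labels, weights) coincide, summing counts.
merge_duplicate_classes <- function(classes) {
  if (length(classes) < 2L) return(classes)
  key <- vapply(classes, function(cl) {
    paste(paste(cl$labels, collapse = ","),
          paste(signif(cl$weights, 12), collapse = ","), sep = "|")
  }, character(1))
  if (!anyDuplicated(key)) return(classes)
  idx <- split(seq_along(classes), key)
  out <- lapply(idx, function(ii) {
    cl <- classes[[ii[1L]]]
    cl$count <- sum(vapply(classes[ii], `[[`, integer(1), "count"))
    cl
  })
  unname(out[order(vapply(out, function(cl) cl$labels[1L], integer(1)),
                   vapply(out, function(cl) length(cl$labels), integer(1)))])
}

#' @export
print.eqclass_collection <- function(x, ...) {
  cat(sprintf("Equivalence-class collection: %d transcripts, %d classes, %d fragments\n",
              length(x$transcript_names), length(x$classes), x$total_fragments))
  invisible(x)
}

# Flatten a collection into parallel vectors for vectorised likelihood /
# EM arithmetic: one entry per (class, label) pair.
flatten_collection <- function(collection) {
  classes <- collection$classes
  sizes <- vapply(classes, function(cl) length(cl$labels), integer(1))
  list(label = unlist(lapply(classes, `[[`, "labels"), use.names = FALSE),
       weight = unlist(lapply(classes, `[[`, "weights"), use.names = FALSE),
       cls = rep.int(seq_along(classes), sizes),
       count = vapply(classes, `[[`, integer(1), "count"),
       n_classes = length(classes),
       M = length(collection$transcript_names))
}

#' Read an equivalence-class file
#'
#' Parses the plain-text equivalence-class dialect dumped by salmon-style
#' quantifiers (`--dumpEq`): two integer header lines giving the number of
#' transcripts M and classes C, then M transcript names one per line, then C
#' class lines of the form `k i_1 ... i_k w_1 ... w_k N` where the `i` are
#' 0-based transcript indices, the `w` conditional-probability weights and
#' `N` the fragment count. An older weight-less variant `k i_1 ... i_k N`
#' is also accepted; absent weights are filled proportional to the inverse
#' effective length of each labelled transcript (uniform when
#' `effective_lengths` is not supplied) and renormalised within the class.
#'
#' File indices are 0-based; the returned object uses 1-based R indices.
#' Weights are renormalised to sum to 1 over each label set.
#'
#' @param path Path to the file (gz-transparent).
#' @param effective_lengths Optional numeric vector (length M) used to fill
#'   weights for the weight-less variant.
#' @return An [eqclass_collection()].
#' @export
read_eqclasses <- function(path, effective_lengths = NULL) {
  if (!file.exists(path)) stop("read_eqclasses: file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("read_eqclasses: malformed header (line 1-2)")
  M <- suppressWarnings(as.integer(lines[1L]))
  C <- suppressWarnings(as.integer(lines[2L]))
  if (is.na(M) || is.na(C) || M < 0L || C < 0L)
    stop("read_eqclasses: malformed header (line 1-2)")
  if (length(lines) < 2L + M + C)
    stop("read_eqclasses: truncated file, expected ", 2L + M + C,
         " lines, found ", length(lines))
  names <- lines[seq_len(M) + 2L]
  classes <- vector("list", C)
  for (ci in seq_len(C)) {
    lineno <- 2L + M + ci
    tok <- suppressWarnings(as.numeric(strsplit(trimws(lines[lineno]), "\\s+")[[1L]]))
    if (length(tok) < 3L || anyNA(tok))
      stop("read_eqclasses: malformed class at line ", lineno)
    k <- as.integer(tok[1L])
    if (length(tok) == k + 2L) {          # weight-less variant
      labels0 <- as.integer(tok[1L + seq_len(k)])
      if (is.null(effective_lengths)) {
        weights <- rep(1, k)
      } else {
        weights <- 1 / effective_lengths[labels0 + 1L]
      }
      count <- tok[k + 2L]
    } else if (length(tok) == 2L * k + 2L) {
      labels0 <- as.integer(tok[1L + seq_len(k)])
      weights <- tok[1L + k + seq_len(k)]
      count <- tok[2L * k + 2L]
    } else {
      stop("read_eqclasses: malformed class at line ", lineno,
           " (expected ", k + 2L, " or ", 2L * k + 2L, " fields)")
    }
    if (any(labels0 >= M) || any(labels0 < 0L))
      stop("read_eqclasses: label index out of range at line ", lineno)
    classes[[ci]] <- eqclass(labels0 + 1L, weights, count)
  }
  eqclass_collection(names, classes, lengths = effective_lengths)
}

#' Write an equivalence-class file
#'
#' Emits the same dialect [read_eqclasses()] accepts (0-based indices,
#' weighted class lines); reading the file back yields an identical
#' collection.
#'
#' @param collection An [eqclass_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eqclasses <- function(collection, path) {
  stopifnot(inherits(collection, "eqclass_collection"))
  con <- file(path, "w")
  on.exit(close(con))
  M <- length(collection$transcript_names)
  writeLines(c(as.character(M), as.character(length(collection$classes)),
               collection$transcript_names), con)
  for (cl in collection$classes) {
    writeLines(paste(c(length(cl$labels), cl$labels - 1L,
                       format(cl$weights, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       cl$count), collapse = " "), con)
  }
  invisible(path)
}

#' Construct an abundance-estimate table
#'
#' Per-transcript abundance estimates in the quant.sf layout: name, length,
#' effective length \eqn{\tilde\ell_i}, TPM and estimated fragment count
#' \eqn{c_i}.
#'
#' @param transcript_names Character vector.
#' @param lengths,effective_lengths Numeric vectors of transcript lengths in
#'   nucleotides. Non-positive effective lengths are replaced by the plain
#'   length (with a warning), mirroring the standard handling for
#'   unexpressed transcripts whose effective length some tools set to zero.
#' @param est_counts Estimated fragments per transcript, real-valued, >= 0.
#' @param tpm Transcripts-per-million; computed from counts and effective
#'   lengths when omitted.
#' @return A `data.frame` of class `"abundance_estimate"` with columns
#'   `Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`.
#' @export
abundance_estimate <- function(transcript_names, lengths, effective_lengths = lengths,
                               est_counts, tpm = NULL) {
  n <- length(transcript_names)
  stopifnot(length(lengths) == n, length(effective_lengths) == n,
            length(est_counts) == n)
  est_counts <- as.numeric(est_counts)
  if (any(est_counts < 0)) stop("abundance_estimate: negative counts")
  effective_lengths <- as.numeric(effective_lengths)
  bad <- !is.finite(effective_lengths) | effective_lengths <= 0
  if (any(bad)) {
    warning(sum(bad), " transcript(s) with non-positive effective length; ",
            "using plain length instead")
    effective_lengths[bad] <- as.numeric(lengths)[bad]
  }
  if (any(effective_lengths <= 0))
    stop("abundance_estimate: non-positive length after fallback")
  if (is.null(tpm)) {
    rate <- est_counts / effective_lengths
    tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate
  }
  structure(data.frame(Name = as.character(transcript_names),
                       Length = as.numeric(lengths),
                       EffectiveLength = effective_lengths,
                       TPM = as.numeric(tpm),
                       NumReads = est_counts,
                       stringsAsFactors = FALSE),
            class = c("abundance_estimate", "data.frame"))
}

#' Read a quant.sf-style abundance table
#'
#' Tab-separated with header columns `Name`, `Length`, `EffectiveLength`,
#' `TPM`, `NumReads`. Rows are kept in file order. Transcripts with
#' effective length <= 0 (a convention some tools use for unexpressed
#' transcripts) fall back to the plain length with a warning.
#'
#' @param path Path to the TSV file.
#' @return An [abundance_estimate()].
#' @export
read_quant <- function(path) {
  if (!file.exists(path)) stop("read_quant: file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_quant: missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$NumReads < 0)) stop("read_quant: negative NumReads")
  abundance_estimate(df$Name, df$Length, df$EffectiveLength, df$NumReads,
                     tpm = df$TPM)
}

#' Write a quant.sf-style abundance table
#'
#' @param est An [abundance_estimate()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_quant <- function(est, path) {
  stopifnot(inherits(est, "abundance_estimate"))
  utils::write.table(as.data.frame(est), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert an abundance estimate to multinomial model parameters
#'
#' Produces the per-transcript distribution \eqn{P(t_i \mid \theta)} used in
#' likelihood and perplexity evaluation. The default `"reads"` convention
#' uses the read fraction \eqn{c_i / \sum_j c_j}, leaving all length effects
#' to the conditional class weights so that the per-fragment likelihood
#' factorises into an estimate-only term and a validation-only term. The
#' `"nucleotide"` convention instead weights the molar fraction (TPM) by
#' effective length, probs \eqn{\propto} TPM\eqn{_i \cdot \tilde\ell_i}.
#'
#' @param est An [abundance_estimate()].
#' @param convention `"reads"` (default) or `"nucleotide"`.
#' @return A [theta_distribution()] with `method = "none"`.
#' @export
estimate_to_theta <- function(est, convention = c("reads", "nucleotide")) {
  stopifnot(inherits(est, "abundance_estimate"))
  convention <- match.arg(convention)
  raw <- switch(convention,
                reads = est$NumReads,
                nucleotide = est$TPM * est$EffectiveLength)
  tot <- sum(raw)
  if (tot <= 0) stop("estimate_to_theta: degenerate estimate (all-zero counts)")
  theta_distribution(raw / tot, method = "none",
                     params = list(convention = convention),
                     names = est$Name)
}

#' Construct a per-transcript probability distribution
#'
#' The container for \eqn{P(t_i \mid \theta)} and its smoothed variants.
#'
#' @param probs Numeric vector, non-negative, summing to 1 (checked to
#'   1e-9).
#' @param method Provenance tag: `"none"`, `"laplace"` or `"sgt"`.
#' @param params List of method parameters (e.g. `beta`, or the fitted SGT
#'   model).
#' @param names Optional transcript names.
#' @return A list of class `"theta_distribution"`.
#' @export
theta_distribution <- function(probs, method = c("none", "laplace", "sgt"),
                               params = list(), names = NULL) {
  method <- match.arg(method)
  probs <- as.numeric(probs)
  if (any(probs < 0) || any(!is.finite(probs)))
    stop("theta_distribution: probabilities must be finite and >= 0")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("theta_distribution: probabilities must sum to 1 (got ",
         format(sum(probs)), ")")
  if (!is.null(names)) names(probs) <- names
  structure(list(probs = probs, method = method, params = params),
            class = "theta_distribution")
}

#' @export
print.theta_distribution <- function(x, ...) {
  cat(sprintf("Per-transcript distribution over %d transcripts (smoothing: %s)\n",
              length(x$probs), x$method))
  cat(sprintf("  expressed (p > 0): %d; min positive p: %.3g\n",
              sum(x$probs > 0),
              if (any(x$probs > 0)) min(x$probs[x$probs > 0]) else NA_real_))
  invisible(x)
}

# Check that a theta matches a collection's transcript namespace.
check_theta_dim <- function(collection, theta) {
  if (length(theta$probs) != length(collection$transcript_names))
    stop("dimension mismatch: theta has ", length(theta$probs),
         " transcripts, collection has ", length(collection$transcript_names))
  tn <- names(theta$probs)
  if (!is.null(tn) && !identical(tn, collection$transcript_names))
    stop("transcript name sets of theta and collection differ")
  invisible(TRUE)
}
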