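# Shared fixtures built in code.

# The classic three-transcript multi-mapping trap: every quantified fragment
# from A maps ambiguously to {A,B} or {A,C}; nothing maps uniquely. An
# estimate that piles all mass on A calls a validation class {B,C}
# impossible.
toy_trap <- function() {
  names <- c("A", "B", "C")
  quantified <- eqclass_collection(names, list(
    eqclass(c(1, 2), c(0.5, 0.5), 30),
    eqclass(c(1, 3), c(0.5, 0.5), 30)))
  validation <- eqclass_collection(names, list(
    eqclass(c(1, 2), c(0.5, 0.5), 5),
    eqclass(c(2, 3), c(0.5, 0.5), 7)))
  all_on_A <- abundance_estimate(names, lengths = c(300, 900, 900),
                                 est_counts = c(60, 0, 0))
  list(quantified = quantified, validation = validation, all_on_A = all_on_A)
}

# a small random collection + matching uniform-ish estimate
random_instance <- function(seed, M = 30L, N = 2000L, sparsity = 0.3) {
  truth <- simulate_truth(M, sparsity = sparsity, seed = seed)
  coll <- simulate_eqclasses(truth$theta, truth$lengths, N, seed = seed + 1L,
                             transcript_names = truth$transcript_names)
  list(truth = truth, collection = coll)
}

read_fastq_lines <- function(p) readLines(p)
fastq_names <- function(p) { l <- readLines(p); l[seq(1, length(l), 4)] }

# expand an eqclass collection into one sparse per-fragment row per fragment
# (rows are exact copies of class weights)
expand_fragments <- function(collection) {
  out <- list()
  for (cl in collection$classes)
    for (i in seq_len(cl$count))
      out[[length(out) + 1L]] <- list(labels = cl$labels, weights = cl$weights)
  out
}
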