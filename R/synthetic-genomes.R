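#' Specification for a simulated genome pair with planted homology
#'
#' Describes two genomes descended from a common ancestor: a controlled
#' fraction of the ancestor survives as conserved, alignable segments with a
#' given expected per-site identity; everything else is independent random
#' sequence. The realized segment coordinates and identities (the TruthMap)
#' are the ground truth that HSP discovery and the distance formulas are
#' expected to recover.
#'
#' @param ancestor_length genome length in bases (> 0)
#' @param alignable_fraction fraction of the ancestor retained as conserved
#'   segments, in `[0, 1]`
#' @param within_identity expected per-site identity inside conserved
#'   segments, in `[0, 1]`
#' @param n_segments number of conserved segments
#' @param min_segment minimum segment length (default 100 bases, long enough
#'   that a segment at moderate identity still yields an above-threshold HSP)
#' @param seed optional integer seed
#' @return a `genome_pair_spec` list
#' @export
genome_pair_spec <- function(ancestor_length, alignable_fraction,
                             within_identity, n_segments = 10L,
                             min_segment = 100L, seed = NULL) {
  if (ancestor_length <= 0) stop("ancestor_length must be > 0")
  if (alignable_fraction < 0 || alignable_fraction > 1)
    stop("alignable_fraction must be in [0, 1]")
  if (within_identity < 0 || within_identity > 1)
    stop("within_identity must be in [0, 1]")
  if (alignable_fraction == 0) n_segments <- 0L
  if (n_segments > 0 &&
      alignable_fraction * ancestor_length < n_segments * min_segment)
    stop("infeasible segment packing: alignable_fraction * ancestor_length ",
         "must be >= n_segments * min_segment")
  structure(list(ancestor_length = as.integer(ancestor_length),
                 alignable_fraction = alignable_fraction,
                 within_identity = within_identity,
                 n_segments = as.integer(n_segments),
                 min_segment = as.integer(min_segment),
                 seed = seed),
            class = "genome_pair_spec")
}

# split `total` into `n` non-negative parts uniformly-ish via multinomial
.random_partition <- function(total, n) {
  if (n == 0L) return(integer(0))
  if (total == 0L) return(integer(n))
  drop(rmultinom(1, total, rep(1 / n, n)))
}

#' Simulate a genome pair with planted conserved segments
#'
#' Genome A is the ancestor itself. Conserved segments are copied into
#' genome B with independent per-site substitution at rate
#' `1 - within_identity` (substituted sites become one of the three other
#' bases, Jukes-Cantor style, so `within_identity` is the expected fraction
#' of unchanged sites). Segment positions in B are drawn independently of
#' their positions in A; non-conserved regions of B are i.i.d. uniform
#' random sequence, so background matches are score-limited.
#'
#' @param spec a [genome_pair_spec()]
#' @return list with `genome_a`, `genome_b` ([genome_record()]s) and
#'   `truth`: a BED-like data.frame (0-based half-open) with columns
#'   `a_start`, `a_end`, `b_start`, `b_end`, `identity` (realized per-site
#'   identity of each segment)
#' @examples
#' pair <- simulate_genome_pair(
#'   genome_pair_spec(5000, 0.3, 0.9, n_segments = 3, seed = 1))
#' pair$truth
#' @export
simulate_genome_pair <- function(spec) {
  stopifnot(inherits(spec, "genome_pair_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$ancestor_length
  n <- spec$n_segments

  total_conserved <- as.integer(round(spec$alignable_fraction * L))
  seg_len <- spec$min_segment +
    .random_partition(total_conserved - n * spec$min_segment, n)

  place <- function(lens) {
    gaps <- .random_partition(L - sum(lens), length(lens) + 1L)
    starts <- integer(length(lens))
    pos <- 0L
    for (i in seq_along(lens)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    starts
  }

  a_seq <- sample(BASES, L, replace = TRUE)
  b_seq <- sample(BASES, L, replace = TRUE)
  a_start <- place(seg_len)
  b_start <- place(seg_len)

  identity <- numeric(n)
  for (i in seq_len(n)) {
    seg <- a_seq[(a_start[i] + 1L):(a_start[i] + seg_len[i])]
    mut <- runif(seg_len[i]) > spec$within_identity
    if (any(mut)) {
      seg[mut] <- vapply(seg[mut],
                         function(b) sample(setdiff(BASES, b), 1L), "")
    }
    b_seq[(b_start[i] + 1L):(b_start[i] + seg_len[i])] <- seg
    identity[i] <- 1 - mean(mut)
  }

  truth <- data.frame(a_start = a_start, a_end = a_start + seg_len,
                      b_start = b_start, b_end = b_start + seg_len,
                      identity = identity)
  truth <- truth[order(truth$a_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome_a = genome_record("sim_a", paste(a_seq, collapse = "")),
       genome_b = genome_record("sim_b", paste(b_seq, collapse = "")),
       truth = truth)
}

#' Summarize a TruthMap into realized coverage and identity
#'
#' The sufficient statistics that [compute_distance_formulas()] should
#' recover from the simulated pair: realized alignable coverage
#' (sum of segment lengths / genome length) and length-weighted mean
#' within-segment identity.
#'
#' @param truth the `truth` data.frame from [simulate_genome_pair()]
#' @param genome_length the simulated genome length
#' @return list with `coverage` and `identity`
#' @export
truth_summary <- function(truth, genome_length) {
  if (nrow(truth) == 0L) return(list(coverage = 0, identity = NA_real_))
  lens <- truth$a_end - truth$a_start
  list(coverage = sum(lens) / genome_length,
       identity = sum(lens * truth$identity) / sum(lens))
}

#' Write a TruthMap as BED-like tab-separated intervals
#'
#' @param truth TruthMap data.frame
#' @param path output path
#' @export
write_truth_map <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
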