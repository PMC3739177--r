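# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the alignment oracle is exhaustive enumeration over
# diagonals, and the contrasts oracle is a closed-form GLS computation on
# the Brownian covariance matrix.

# ---- brute-force ungapped local alignment -------------------------------

# all match (+1) / mismatch (-1) runs along one diagonal, as a score vector
.diag_scores <- function(ea, eb, d) {
  # diagonal d: a index i aligns with b index i - d (0-based)
  i0 <- max(0L, d); i1 <- min(length(ea) - 1L, length(eb) - 1L + d)
  if (i0 > i1) return(NULL)
  ai <- ea[(i0 + 1L):(i1 + 1L)]
  bi <- eb[(i0 - d + 1L):(i1 - d + 1L)]
  s <- ifelse(ai < 4L & bi < 4L & ai == bi, 1L, -1L)
  list(offset = i0, scores = s)
}

# best-scoring segment on one score vector (Kadane with traceback)
.best_segment <- function(s) {
  best <- 0L; best_s <- best_e <- 0L
  run <- 0L; run_s <- 1L
  for (i in seq_along(s)) {
    if (run <= 0L) { run <- 0L; run_s <- i }
    run <- run + s[i]
    if (run > best) { best <- run; best_s <- run_s; best_e <- i }
  }
  if (best <= 0L) return(NULL)
  list(score = best, from = best_s, to = best_e)
}

# exhaustive best local ungapped segment between two sequences, both strands
oracle_best_hsp <- function(seq_a, seq_b) {
  ea <- spirotax:::.encode_dna(seq_a)
  best <- NULL
  for (strand in c("+", "-")) {
    sb <- if (strand == "+") seq_b else spirotax:::.revcomp(seq_b)
    eb <- spirotax:::.encode_dna(sb)
    lb <- length(eb)
    for (d in (-(lb - 1L)):(length(ea) - 1L)) {
      ds <- .diag_scores(ea, eb, d)
      if (is.null(ds)) next
      seg <- .best_segment(ds$scores)
      if (is.null(seg)) next
      if (is.null(best) || seg$score > best$score) {
        a_start <- ds$offset + seg$from - 1L
        a_end <- ds$offset + seg$to
        bw_start <- a_start - d; bw_end <- a_end - d
        if (strand == "-") { tmp <- lb - bw_end; bw_end <- lb - bw_start; bw_start <- tmp }
        best <- list(score = seg$score, a_start = a_start, a_end = a_end,
                     b_start = bw_start, b_end = bw_end, strand = strand)
      }
    }
  }
  best
}

# all locally optimal segments >= min_score (recursive Kadane splitting)
.segments_above <- function(s, min_score) {
  seg <- .best_segment(s)
  if (is.null(seg) || seg$score < min_score) return(NULL)
  left <- if (seg$from > 1L) .segments_above(s[1:(seg$from - 1L)], min_score) else NULL
  right <- if (seg$to < length(s)) {
    r <- .segments_above(s[(seg$to + 1L):length(s)], min_score)
    if (!is.null(r)) { r$from <- r$from + seg$to; r$to <- r$to + seg$to }
    r
  } else NULL
  rbind(data.frame(score = seg$score, from = seg$from, to = seg$to),
        left, right)
}

# optimal non-overlapping (on A) segment cover score by exhaustive DP over
# all candidate segments from both strands
oracle_cover_score <- function(seq_a, seq_b, min_score) {
  ea <- spirotax:::.encode_dna(seq_a)
  cand <- NULL
  for (strand in c("+", "-")) {
    sb <- if (strand == "+") seq_b else spirotax:::.revcomp(seq_b)
    eb <- spirotax:::.encode_dna(sb)
    lb <- length(eb)
    for (d in (-(lb - 1L)):(length(ea) - 1L)) {
      ds <- .diag_scores(ea, eb, d)
      if (is.null(ds)) next
      segs <- .segments_above(ds$scores, min_score)
      if (is.null(segs)) next
      cand <- rbind(cand, data.frame(score = segs$score,
                                     a_start = ds$offset + segs$from - 1L,
                                     a_end = ds$offset + segs$to))
    }
  }
  if (is.null(cand)) return(0L)
  # weighted interval scheduling on the A axis
  cand <- cand[order(cand$a_end), ]
  n <- nrow(cand)
  ends <- c(0L, cand$a_end)
  best <- numeric(n + 1L)
  for (i in seq_len(n)) {
    j <- max(which(ends <= cand$a_start[i] + 0L)) # last candidate ending before start
    best[i + 1L] <- max(best[i], best[j] + cand$score[i])
  }
  best[n + 1L]
}

# ---- GLS-whitening oracle for independent contrasts ---------------------

# closed-form contrasts: for each internal node, GLS subtree means computed
# by inverting the Brownian covariance (shared path length) matrices, then
# standardized by the effective variance. Matches Felsenstein's recursion
# without using it.
oracle_contrasts <- function(tree, x) {
  stopifnot(ape::is.binary(tree))
  n_tip <- length(tree$tip.label)
  C <- ape::vcv(tree)
  depth <- ape::node.depth.edgelength(tree)
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under))
  }
  edge_len <- function(node) tree$edge.length[tree$edge[, 2] == node]
  child_stats <- function(node) {
    t_c <- edge_len(node)
    if (node <= n_tip)
      return(list(mean = x[tree$tip.label[node]], u = t_c))
    tl <- tree$tip.label[tips_under(node)]
    Cc <- C[tl, tl, drop = FALSE] - depth[node]
    w <- solve(Cc, rep(1, length(tl)))
    list(mean = sum(w * x[tl]) / sum(w), u = t_c + 1 / sum(w))
  }
  internals <- (n_tip + 1L):(n_tip + tree$Nnode)
  out <- data.frame(node = internals, contrast = NA_real_,
                    variance = NA_real_)
  for (k in seq_along(internals)) {
    ch <- tree$edge[tree$edge[, 1] == internals[k], 2]
    s1 <- child_stats(ch[1]); s2 <- child_stats(ch[2])
    out$variance[k] <- s1$u + s2$u
    out$contrast[k] <- (s1$mean - s2$mean) / sqrt(s1$u + s2$u)
  }
  out
}

# random bifurcating tree with positive branch lengths, for property tests
random_small_tree <- function(n_tip) {
  tr <- ape::rtree(n_tip)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}
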