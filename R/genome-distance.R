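#' Find high-scoring segment pairs (HSPs) between two genomes
#'
#' Ungapped seed-and-extend local alignment in the spirit of blastn: exact
#' word seeds of length `word_size` are extended in both directions under an
#' x-drop rule with +1/-1 match/mismatch scoring, on both strands of genome
#' B. HSPs scoring below `min_score` are dropped, and the surviving set is
#' made non-overlapping on genome A by keeping HSPs greedily in order of
#' decreasing score, so that coverage (distance formula 1) counts no genome-A
#' base twice.
#'
#' Ambiguity characters (N and other IUPAC codes) never seed and always score
#' as mismatches during extension.
#'
#' @param genome_a,genome_b objects from [genome_record()] (or coercible
#'   single sequences)
#' @param word_size exact-match seed length (>= 4; default 11)
#' @param min_score minimum HSP score to report (default 28)
#' @param x_drop extension abandoned once the running score falls this far
#'   below the best score seen (default 20)
#' @param match,mismatch scoring scheme (defaults +1/-1)
#' @return an `hsp_set`: a data.frame with columns `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open on the original sequences),
#'   `strand` ("+" or "-"), `length`, `identities`, `score`; attributes
#'   `len_a`, `len_b` carry the genome lengths.
#' @examples
#' a <- genome_record("a", strrep("ACGTTGCA", 10))
#' find_hsps(a, a, word_size = 8)
#' @export
find_hsps <- function(genome_a, genome_b, word_size = 11L, min_score = 28L,
                      x_drop = 20L, match = 1L, mismatch = -1L) {
  genome_a <- .as_genome(genome_a, "A")
  genome_b <- .as_genome(genome_b, "B")
  if (genome_a$length == 0L || genome_b$length == 0L)
    stop("empty sequence: both genomes must be non-empty")
  if (word_size < 4L) stop("word_size must be >= 4")
  if (word_size > 15L) stop("word_size must be <= 15")

  ea <- .encode_dna(genome_a$seq)
  lb <- genome_b$length

  scan_one <- function(bseq, strand) {
    h <- .hsp_scan(ea, .encode_dna(bseq), as.integer(word_size),
                   as.integer(min_score), as.integer(x_drop),
                   as.integer(match), as.integer(mismatch))
    if (nrow(h) == 0L) return(cbind(h, strand = character(0)))
    if (strand == "-") {
      # map working (reverse-complement) coordinates back to the original B
      bs <- lb - h$b_end
      h$b_end <- lb - h$b_start
      h$b_start <- bs
    }
    h$strand <- strand
    h
  }

  hsps <- rbind(scan_one(genome_b$seq, "+"),
                scan_one(.revcomp(genome_b$seq), "-"))
  hsps <- .filter_overlaps(hsps)
  rownames(hsps) <- NULL
  structure(hsps, len_a = genome_a$length, len_b = genome_b$length,
            class = c("hsp_set", "data.frame"))
}

.as_genome <- function(x, label) {
  if (inherits(x, "genome_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome_record(label, x))
  stop("genome_", tolower(label), " must be a genome_record or a sequence string")
}

# Greedy resolution of genome-A overlaps: keep by descending score (ties by
# position for determinism), discard anything overlapping a kept interval.
.filter_overlaps <- function(hsps) {
  if (nrow(hsps) <= 1L) return(hsps)
  ord <- order(-hsps$score, hsps$a_start, hsps$b_start, hsps$strand)
  hsps <- hsps[ord, ]
  keep <- logical(nrow(hsps))
  starts <- ends <- integer(0)
  for (i in seq_len(nrow(hsps))) {
    s <- hsps$a_start[i]; e <- hsps$a_end[i]
    if (!any(s < ends & e > starts)) {
      keep[i] <- TRUE
      starts <- c(starts, s); ends <- c(ends, e)
    }
  }
  hsps <- hsps[keep, ]
  hsps[order(hsps$a_start), ]
}

#' Genome-to-genome distance components from an HSP set
#'
#' Computes the three components on which digital genome-to-genome comparison
#' is based: `f1`, the fraction of the average genome length covered by HSPs
#' (sum of HSP lengths / mean of the two genome lengths); `f2`, the identity
#' within HSPs (identities / HSP length); and `f3`, the identity over the
#' whole genome (identities / mean length). By construction `f3 = f1 * f2`
#' whenever all three are computed from the same HSP sums.
#'
#' @param hsps an `hsp_set` from [find_hsps()], or any data.frame with
#'   `length` and `identities` columns
#' @param len_a,len_b genome lengths in bases; defaults taken from the
#'   `hsp_set` attributes when present
#' @return a `distance_triple`: list with `f1`, `f2`, `f3` (proportions in
#'   `[0,1]`), `total_length` (the normalizing mean length), `n_hsps`, and
#'   `no_hsps` flag (TRUE when the set was empty, in which case f2 is 0 by
#'   convention and flagged)
#' @examples
#' compute_distance_formulas(
#'   data.frame(length = 100L, identities = 90L), len_a = 1000, len_b = 1000)
#' @export
compute_distance_formulas <- function(hsps, len_a = attr(hsps, "len_a"),
                                      len_b = attr(hsps, "len_b")) {
  if (is.null(len_a) || is.null(len_b))
    stop("len_a and len_b are required when hsps carries no length attributes")
  if (len_a < 0 || len_b < 0) stop("genome lengths must be non-negative")
  mean_len <- (len_a + len_b) / 2
  if (mean_len <= 0) stop("mean genome length must be positive")
  if (nrow(hsps) > 0) {
    bad <- hsps$a_end > len_a | hsps$b_end > len_b |
      hsps$a_start < 0 | hsps$b_start < 0
    if (!is.null(hsps$a_end) && any(bad))
      stop("HSP coordinates exceed the genome lengths")
    if (any(hsps$identities > hsps$length))
      stop("identities exceed HSP length")
  }
  tot_len <- sum(as.numeric(hsps$length))
  tot_id <- sum(as.numeric(hsps$identities))
  no_hsps <- tot_len == 0
  structure(list(f1 = tot_len / mean_len,
                 f2 = if (no_hsps) 0 else tot_id / tot_len,
                 f3 = tot_id / mean_len,
                 total_length = mean_len,
                 n_hsps = nrow(hsps),
                 no_hsps = no_hsps),
            class = "distance_triple")
}

#' @export
print.distance_triple <- function(x, ...) {
  cat(sprintf(paste0("<distance_triple>  f1 (HSP coverage) %.2f%%  ",
                     "f2 (identity in HSPs) %.2f%%  ",
                     "f3 (whole-genome identity) %.2f%%  [%d HSPs]\n"),
              100 * x$f1, 100 * x$f2, 100 * x$f3, x$n_hsps))
  if (x$no_hsps) cat("  (no HSPs: f2 reported as 0 by convention)\n")
  invisible(x)
}

#' Format a distance triple as a report row with two-decimal percentages
#'
#' @param triple a `distance_triple`
#' @param label_a,label_b genome labels for the row
#' @return one-row data.frame with `formula_1`, `formula_2`, `formula_3` in
#'   percent, rounded to two decimals
#' @export
ggd_report_row <- function(triple, label_a = "A", label_b = "B") {
  data.frame(genome_a = label_a, genome_b = label_b,
             formula_1 = round(100 * triple$f1, 2),
             formula_2 = round(100 * triple$f2, 2),
             formula_3 = round(100 * triple$f3, 2),
             n_hsps = triple$n_hsps,
             stringsAsFactors = FALSE)
}

#' Write an HSP table as tab-separated text
#'
#' Coordinates are 0-based half-open, with a strand column for the genome-B
#' interval.
#'
#' @param hsps an `hsp_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hsp_table <- function(hsps, path) {
  write.table(as.data.frame(hsps), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
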