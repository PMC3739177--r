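#' Read a 12-column BLAST tabular hit file into a hit table
#'
#' Accepts `outfmt 6`-compatible files (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Rows are HSPs; they are
#' grouped by subject into hits, each carrying its best bit score, its
#' pooled within-HSP identity (identities summed over HSPs / aligned columns
#' summed over HSPs), and the list of query intervals (converted to 0-based
#' half-open). An optional annotation table supplies per-subject taxon
#' labels and free-text descriptions.
#'
#' @param path BLAST tabular file (no header)
#' @param annot_path optional tab-separated file with columns `subject`,
#'   `taxon`, `description` (header required)
#' @return a `hit_table` data.frame: one row per (query, subject) hit with
#'   `query`, `subject`, `bitscore`, `identity` (percent), `intervals`
#'   (list-column of 2-column matrices), `taxon`, `description`
#' @export
read_hit_table <- function(path, annot_path = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 12L) stop("expected 12 tab-separated columns: ", path)
  names(tab)[1:12] <- cols
  annot <- NULL
  if (!is.null(annot_path)) {
    annot <- read.table(annot_path, sep = "\t", header = TRUE, quote = "",
                        stringsAsFactors = FALSE)
    if (!all(c("subject", "taxon", "description") %in% names(annot)))
      stop("annotation file needs columns subject, taxon, description")
  }
  hit_table(tab, annot)
}

#' Build a hit table from a parsed BLAST tabular data.frame
#'
#' @param tab data.frame with the 12 outfmt-6 columns (see
#'   [read_hit_table()])
#' @param annot optional data.frame with `subject`, `taxon`, `description`
#' @return a `hit_table` (see [read_hit_table()])
#' @export
hit_table <- function(tab, annot = NULL) {
  if (any(tab$bitscore <= 0)) stop("bit scores must be > 0")
  if (any(tab$pident < 0 | tab$pident > 100))
    stop("percent identity must be in [0, 100]")
  key <- paste(tab$qseqid, tab$sseqid, sep = "\r")
  groups <- split(seq_len(nrow(tab)), key)
  groups <- groups[order(vapply(groups, min, 1L))] # stable input order
  rows <- lapply(groups, function(idx) {
    h <- tab[idx, , drop = FALSE]
    ident <- sum(h$pident / 100 * h$length) / sum(h$length) * 100
    iv <- cbind(start = pmin(h$qstart, h$qend) - 1L,
                end = pmax(h$qstart, h$qend))
    list(query = h$qseqid[1], subject = h$sseqid[1],
         bitscore = max(h$bitscore), identity = ident, intervals = iv)
  })
  out <- data.frame(query = vapply(rows, `[[`, "", "query"),
                    subject = vapply(rows, `[[`, "", "subject"),
                    bitscore = vapply(rows, `[[`, 1, "bitscore"),
                    identity = vapply(rows, `[[`, 1, "identity"),
                    stringsAsFactors = FALSE)
  out$intervals <- lapply(rows, `[[`, "intervals")
  if (!is.null(annot)) {
    m <- match(out$subject, annot$subject)
    out$taxon <- annot$taxon[m]
    out$description <- annot$description[m]
  } else {
    out$taxon <- NA_character_
    out$description <- NA_character_
  }
  rownames(out) <- NULL
  structure(out, class = c("hit_table", "data.frame"))
}

# genus = first whitespace-delimited token of the taxon label, quotes stripped
.parse_genus <- function(taxon) {
  g <- sub("^\\s*", "", gsub("[\"']", "", taxon))
  g <- sub("\\s.*$", "", g)
  g[!nzchar(g)] <- NA_character_
  g
}

#' BLAST-score-weighted taxon (genus) frequencies
#'
#' Each hit contributes its bit score to its subject's genus; frequencies
#' are the per-genus score sums normalized by the total score mass, so they
#' sum to 1 and are invariant to uniform rescaling of the scores.
#'
#' @param hits a `hit_table`
#' @return a `weighted_frequency_report`: data.frame with `item`,
#'   `weight`, `frequency`, sorted by decreasing frequency; attributes
#'   `total_weight` and `n_hits`
#' @export
weighted_taxon_frequencies <- function(hits) {
  genus <- .parse_genus(hits$taxon)
  ok <- !is.na(genus)
  if (!any(ok)) stop("no hit has a parseable genus")
  .weight_report(genus[ok], hits$bitscore[ok], sum(ok))
}

#' BLAST-score-weighted stemmed-keyword frequencies
#'
#' Descriptions are lower-cased, tokenized on non-alphabetic runs, filtered
#' (tokens shorter than 3 characters and a fixed English stopword list are
#' dropped) and Porter-stemmed; each distinct stem then contributes the
#' hit's bit score once per hit, regardless of how often it repeats within
#' that description.
#'
#' @param hits a `hit_table`
#' @param stopwords character vector of words to drop (before stemming);
#'   defaults to a built-in English list
#' @return a `weighted_frequency_report` over stems (see
#'   [weighted_taxon_frequencies()])
#' @export
weighted_keyword_frequencies <- function(hits,
                                         stopwords = default_stopwords()) {
  desc <- hits$description
  ok <- !is.na(desc) & nzchar(trimws(desc))
  if (!any(ok)) stop("all hit descriptions are empty")
  items <- character(0); weights <- numeric(0)
  for (i in which(ok)) {
    toks <- .tokenize(desc[i], stopwords)
    stems <- unique(porter_stem(toks))
    if (length(stems)) {
      items <- c(items, stems)
      weights <- c(weights, rep(hits$bitscore[i], length(stems)))
    }
  }
  if (!length(items)) stop("no keywords survive tokenization")
  .weight_report(items, weights, sum(ok))
}

.tokenize <- function(text, stopwords) {
  toks <- strsplit(tolower(text), "[^a-z]+")[[1]]
  toks <- toks[nchar(toks) >= 3L]
  toks[!toks %in% stopwords]
}

.weight_report <- function(items, weights, n_hits) {
  w <- tapply(weights, items, sum)
  out <- data.frame(item = names(w), weight = as.numeric(w),
                    frequency = as.numeric(w) / sum(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$item), ]
  rownames(out) <- NULL
  structure(out, total_weight = sum(w), n_hits = n_hits,
            class = c("weighted_frequency_report", "data.frame"))
}

#' A small fixed English stopword list
#'
#' Function words only; domain terms are never filtered.
#'
#' @return character vector
#' @export
default_stopwords <- function() {
  c("the", "and", "for", "from", "with", "that", "this", "are", "was",
    "were", "has", "have", "had", "its", "their", "not", "but", "all",
    "any", "can", "into", "onto", "out", "over", "under", "between",
    "within", "without", "during", "after", "before", "than", "then",
    "them", "they", "these", "those", "which", "what", "when", "where",
    "who", "whose", "will", "would", "there", "here", "such", "each",
    "other", "also", "been", "being", "both", "more", "most", "some",
    "upon", "via", "per", "non", "two", "one", "three")
}

#' Mean within-HSP identity and mean HSP coverage over hits
#'
#' Per hit, coverage is the length of the union of its query intervals
#' (overlaps merged) divided by the query length; the report gives the
#' unweighted means of identity and coverage across hits.
#'
#' @param hits a `hit_table`
#' @param query_length query sequence length in bases (> 0)
#' @return list with `mean_identity` (percent), `mean_coverage` (percent),
#'   `n_hits`
#' @export
hsp_summary <- function(hits, query_length) {
  if (query_length <= 0) stop("query_length must be > 0")
  cov <- vapply(hits$intervals, function(iv) {
    if (any(iv[, 2] > query_length) || any(iv[, 1] < 0))
      stop("HSP interval exceeds the query length")
    .union_length(iv) / query_length
  }, 1)
  list(mean_identity = mean(hits$identity),
       mean_coverage = 100 * mean(cov),
       n_hits = nrow(hits))
}

.union_length <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0L; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_e) cur_e <- max(cur_e, iv[i, 2])
    else { total <- total + (cur_e - cur_s); cur_s <- iv[i, 1]; cur_e <- iv[i, 2] }
  }
  total + (cur_e - cur_s)
}

#' Pairwise nucleotide difference counts between aligned sequences
#'
#' Counts positions at which two equal-length sequences differ. Positions
#' where either sequence has a gap (`-`) or an ambiguity code (anything
#' outside A/C/G/T) are excluded: they are neither differences nor
#' comparable sites. No alignment is performed; unequal lengths are an
#' error.
#'
#' @param sequences named character vector of aligned sequences (>= 2),
#'   or a path handled by [Biostrings::readDNAStringSet()]
#' @return symmetric integer matrix of mismatch counts with zero diagonal
#' @examples
#' pairwise_differences(c(a = "ACGT", b = "ACGA"))
#' @export
pairwise_differences <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    set <- Biostrings::readDNAStringSet(sequences)
    sequences <- setNames(as.character(set), names(set))
  }
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must have equal length (no alignment is performed)")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(n))
  enc <- lapply(sequences, .encode_dna)
  out <- matrix(0L, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comparable <- enc[[i]] < 4L & enc[[j]] < 4L
    d <- sum(enc[[i]][comparable] != enc[[j]][comparable])
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Write a weighted frequency report as TSV
#'
#' @param report a `weighted_frequency_report`
#' @param path output path
#' @export
write_frequency_report <- function(report, path) {
  df <- as.data.frame(report)
  df$frequency_pct <- round(100 * df$frequency, 1)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
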