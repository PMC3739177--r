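#' G+C content of a genome
#'
#' Counts G and C residues (case-insensitive). The strong-base ambiguity
#' code S (G or C) counts toward the numerator and W (A or T) does not;
#' all other ambiguity codes are excluded from the numerator only — the
#' denominator is always the full sequence length, matching the
#' percent-of-genome-size convention of genome report tables.
#'
#' @param genome a [genome_record()] or sequence string
#' @return list with `gc_bases` (count) and `gc_percent` (proportion in
#'   `[0, 1]`)
#' @examples
#' gc_content("GGCC") # 4, 1.0
#' @export
gc_content <- function(genome) {
  genome <- .as_genome(genome, "A")
  if (genome$length == 0L) stop("empty sequence")
  x <- utf8ToInt(genome$seq)
  gc <- sum(x == 71L | x == 67L | x == 83L) # G, C, S
  list(gc_bases = gc, gc_percent = gc / genome$length)
}

#' Construct a feature table
#'
#' @param type feature class, one of `CDS`, `rRNA`, `tRNA`, `other_RNA`,
#'   `pseudo`
#' @param start,end 0-based half-open interval on the replicon
#' @param strand `+` or `-`
#' @return a `feature_table` data.frame
#' @export
feature_table <- function(type, start, end, strand = "+") {
  valid <- c("CDS", "rRNA", "tRNA", "other_RNA", "pseudo")
  if (!all(type %in% valid))
    stop("feature types must be in: ", paste(valid, collapse = ", "))
  if (any(end <= start)) stop("intervals must satisfy end > start")
  structure(data.frame(type = type, start = as.integer(start),
                       end = as.integer(end),
                       strand = rep_len(strand, length(type)),
                       stringsAsFactors = FALSE),
            class = c("feature_table", "data.frame"))
}

#' Coding density of a genome
#'
#' Length of the strand-merged union of CDS intervals divided by the genome
#' length. RNA genes are not counted as coding; splitting a CDS into
#' abutting pieces does not change the result.
#'
#' @param genome a [genome_record()] (or its length as a number)
#' @param features a [feature_table()]
#' @return proportion in `[0, 1]`
#' @export
coding_density <- function(genome, features) {
  glen <- if (is.numeric(genome)) genome else .as_genome(genome, "A")$length
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(0)
  if (any(cds$end > glen) || any(cds$start < 0))
    stop("CDS interval out of replicon range")
  iv <- cbind(cds$start, cds$end)
  .union_length(iv) / glen
}

#' Gene class breakdown in the style of a genome statistics table
#'
#' Total genes = protein-coding (CDS) + RNA genes; each class is reported
#' as a percentage of that total, rounded to two decimals. Pseudo genes are
#' a disjoint class: their percentage is also relative to total genes but
#' they are not added to it.
#'
#' @param features a [feature_table()], or explicit counts via the named
#'   arguments
#' @param n_cds,n_rna,n_pseudo explicit counts overriding `features`
#' @return data.frame with rows `total_genes`, `protein_coding`,
#'   `rna_genes`, `pseudo_genes` and columns `count`, `percent`
#' @examples
#' gene_class_breakdown(n_cds = 2869, n_rna = 59, n_pseudo = 80)
#' @export
gene_class_breakdown <- function(features = NULL, n_cds = NULL, n_rna = NULL,
                                 n_pseudo = NULL) {
  if (is.null(n_cds)) {
    stopifnot(inherits(features, "feature_table"), nrow(features) >= 1L)
    n_cds <- sum(features$type == "CDS")
    n_rna <- sum(features$type %in% c("rRNA", "tRNA", "other_RNA"))
    n_pseudo <- sum(features$type == "pseudo")
  }
  total <- n_cds + n_rna
  if (total == 0L) stop("no CDS or RNA genes")
  pct <- function(k) round(100 * k / total, 2)
  data.frame(class = c("total_genes", "protein_coding", "rna_genes",
                       "pseudo_genes"),
             count = c(total, n_cds, n_rna, n_pseudo),
             percent = c(100, pct(n_cds), pct(n_rna), pct(n_pseudo)),
             stringsAsFactors = FALSE)
}

#' Full genome statistics report
#'
#' @param genome a [genome_record()]
#' @param features a [feature_table()]
#' @return data.frame with attribute rows: genome size, coding region,
#'   G+C content, and the gene class breakdown, each with value and percent
#' @export
genome_stats_report <- function(genome, features) {
  genome <- .as_genome(genome, "A")
  gc <- gc_content(genome)
  cd <- coding_density(genome, features)
  classes <- gene_class_breakdown(features)
  data.frame(
    attribute = c("Genome size (bp)", "DNA coding region (bp)",
                  "DNA G+C content (bp)", "Total genes",
                  "Protein-coding genes", "RNA genes", "Pseudo genes"),
    value = c(genome$length, round(cd * genome$length), gc$gc_bases,
              classes$count),
    percent = c(100, round(100 * cd, 2), round(100 * gc$gc_percent, 2),
                classes$percent),
    stringsAsFactors = FALSE)
}

#' Read features (and sequence) from a GenBank flat file
#'
#' A minimal parser for the FEATURES and ORIGIN blocks: extracts CDS, rRNA,
#' tRNA, ncRNA/tmRNA/misc_RNA (as `other_RNA`) features, honoring
#' `complement(...)` and flattening `join(...)`/`order(...)` into their
#' constituent intervals; features carrying a `/pseudo` or `/pseudogene`
#' qualifier are classed `pseudo`. Partial-end markers (`<`, `>`) are
#' stripped. Remote references and fuzzy single-base locations are not
#' supported.
#'
#' @param path GenBank flat file
#' @return list with `genome` (a [genome_record()]; sequence empty if no
#'   ORIGIN block) and `features` (a [feature_table()])
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(locus[1], "\\s+")[[1]][2] else "genbank"

  f_start <- grep("^FEATURES", lines)
  o_start <- grep("^ORIGIN", lines)
  end <- grep("^//", lines)
  if (!length(f_start)) stop("no FEATURES block in ", path)

  f_end <- min(c(o_start, end, length(lines) + 1L)[c(o_start, end,
                                                     length(lines) + 1L) > f_start[1]])
  feat_lines <- lines[(f_start[1] + 1L):(f_end - 1L)]

  # a new feature starts with a key at column 6; qualifiers/continuations
  # are indented to column 22
  is_key <- grepl("^ {5}\\S", feat_lines)
  idx <- cumsum(is_key)
  keep <- idx > 0L
  recs <- split(feat_lines[keep], idx[keep])

  types <- character(0); starts <- ends <- integer(0); strands <- character(0)
  for (rec in recs) {
    head_parts <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    key <- head_parts[1]
    cls <- switch(key, CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                  ncRNA = "other_RNA", tmRNA = "other_RNA",
                  misc_RNA = "other_RNA", NULL)
    if (is.null(cls)) next
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s*/", rec)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(rec)
    loc <- paste0(head_parts[-1], collapse = "")
    if (loc_end >= 2L)
      loc <- paste0(loc, paste0(trimws(rec[2:loc_end]), collapse = ""))
    if (any(grepl("^\\s*/pseudo(gene)?\\b|^\\s*/pseudo(gene)?=", rec)))
      cls <- "pseudo"
    parsed <- .parse_location(loc)
    if (is.null(parsed)) next
    types <- c(types, rep(cls, nrow(parsed$iv)))
    starts <- c(starts, parsed$iv[, 1]); ends <- c(ends, parsed$iv[, 2])
    strands <- c(strands, rep(parsed$strand, nrow(parsed$iv)))
  }

  seq <- ""
  if (length(o_start)) {
    o_end <- min(end[end > o_start[1]], length(lines) + 1L)
    body <- lines[(o_start[1] + 1L):(o_end - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }

  feats <- if (length(types)) feature_table(types, starts, ends, strands)
           else structure(data.frame(type = character(0), start = integer(0),
                                     end = integer(0), strand = character(0)),
                          class = c("feature_table", "data.frame"))
  list(genome = genome_record(id, seq), features = feats)
}

# "complement(join(a..b,c..d))" etc. -> 0-based half-open intervals + strand
.parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  while (grepl("^complement\\(", loc)) {
    strand <- if (strand == "+") "-" else "+"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- gsub("^(join|order)\\(|\\)$", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- matrix(NA_integer_, 0, 2)
  for (p in parts) {
    p <- gsub("[<>]", "", p)
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      iv <- rbind(iv, c(ab[1] - 1L, ab[2])) # GenBank is 1-based inclusive
    } else if (grepl("^\\d+$", p)) {
      a <- as.integer(p)
      iv <- rbind(iv, c(a - 1L, a))
    } else {
      return(NULL) # unsupported location form (remote/fuzzy)
    }
  }
  if (nrow(iv) == 0L) return(NULL)
  list(iv = iv, strand = strand)
}

#' Read a plain tab-separated feature table
#'
#' Columns `type`, `start`, `end`, and optionally `strand` (0-based
#' half-open coordinates).
#'
#' @param path TSV path with header
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("type", "start", "end") %in% names(tab)))
    stop("feature table needs columns type, start, end")
  feature_table(tab$type, tab$start, tab$end,
                if ("strand" %in% names(tab)) tab$strand else "+")
}
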