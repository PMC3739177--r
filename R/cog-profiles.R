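#' The 25 single-letter COG functional categories
#'
#' Fixed column order used by every count matrix in the package: J A K L B D
#' Y V T M N Z W U O C G E F H I P Q R S (information storage and
#' processing, cellular processes and signaling, metabolism, poorly
#' characterized).
#'
#' @return character vector of length 25
#' @export
cog_categories <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z", "W",
    "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
}

# split "J;K" / "JK" / "" into single letters
.parse_categories <- function(s) {
  s <- gsub("[;, ]", "", s)
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Count COG category assignments in a gene table
#'
#' A gene carrying k category letters contributes one count to each of the k
#' categories; genes with no assignment are tallied separately as "not in
#' COGs". Unknown category letters are an error naming the offending rows.
#'
#' @param gene_table data.frame with columns `gene_id` and `categories`
#'   (letters concatenated or separated by `;`)
#' @return named integer vector over the 25 categories (in
#'   [cog_categories()] order) with attributes `not_in_cogs` (genes without
#'   assignment), `n_genes`, and `genes_in_cogs`
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   categories = c("J", "J;K", ""))
#' count_categories(tab)
#' @export
count_categories <- function(gene_table) {
  stopifnot(is.data.frame(gene_table), "categories" %in% names(gene_table))
  cats <- cog_categories()
  letters_per_gene <- lapply(gene_table$categories, .parse_categories)
  all_letters <- unlist(letters_per_gene)
  bad <- !all_letters %in% cats
  if (any(bad)) {
    rows <- rep(seq_len(nrow(gene_table)),
                lengths(letters_per_gene))[bad]
    stop("unknown COG category letter(s) '",
         paste(unique(all_letters[bad]), collapse = "', '"),
         "' in row(s) ", paste(unique(rows), collapse = ", "))
  }
  counts <- table(factor(all_letters, levels = cats))
  out <- as.integer(counts)
  names(out) <- cats
  structure(out,
            not_in_cogs = sum(lengths(letters_per_gene) == 0L),
            n_genes = nrow(gene_table),
            genes_in_cogs = sum(lengths(letters_per_gene) > 0L))
}

#' Relative COG category proportions
#'
#' The denominator is the sum of per-category assignment counts over the 25
#' categories — not the number of genes assigned to COGs and not the total
#' gene count. (With multi-category genes these differ; only this convention
#' reproduces published percentage tables where the category column sums
#' above the gene count.) The separate "not in COGs" share, when requested
#' via [not_in_cogs_share()], is instead a fraction of total genes.
#'
#' @param counts named count vector from [count_categories()] (or any
#'   non-negative vector over the 25 categories)
#' @return proportion vector summing to 1
#' @examples
#' relative_proportions(c(J = 3, K = 1)[c("J", "K")] ) # 0.75, 0.25
#' @export
relative_proportions <- function(counts) {
  counts <- .as_category_vector(counts)
  total <- sum(counts)
  if (total <= 0) stop("all-zero count vector: proportions undefined")
  counts / total
}

.as_category_vector <- function(counts) {
  cats <- cog_categories()
  if (is.null(names(counts))) {
    if (length(counts) != 25L)
      stop("unnamed count vectors must have length 25")
    names(counts) <- cats
    return(counts)
  }
  out <- setNames(numeric(25L), cats)
  known <- names(counts) %in% cats
  if (any(!known))
    stop("unknown categories: ", paste(names(counts)[!known], collapse = ", "))
  out[names(counts)] <- counts
  out
}

#' Share of genes not assigned to any COG
#'
#' @param counts count vector from [count_categories()] (needs its
#'   attributes) or explicit `not_in_cogs` / `n_genes`
#' @param not_in_cogs,n_genes explicit tallies overriding the attributes
#' @return proportion of total genes
#' @export
not_in_cogs_share <- function(counts = NULL, not_in_cogs = NULL,
                              n_genes = NULL) {
  if (is.null(not_in_cogs)) not_in_cogs <- attr(counts, "not_in_cogs")
  if (is.null(n_genes)) n_genes <- attr(counts, "n_genes")
  if (is.null(not_in_cogs) || is.null(n_genes))
    stop("need not_in_cogs and n_genes (attributes or arguments)")
  not_in_cogs / n_genes
}

#' Arcsine-square-root transform of a proportion
#'
#' The classical variance-stabilizing transform for proportions:
#' `asin(sqrt(p))`, strictly increasing on `[0, 1]` with range
#' `[0, pi/2]` radians.
#'
#' @param p proportion(s) in `[0, 1]`
#' @return transformed values in radians
#' @export
transform_arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Log transform of absolute counts
#'
#' `log(count + 1)` (natural log), defined at zero and monotone.
#'
#' @param count non-negative count(s)
#' @return log-transformed values
#' @export
transform_log_counts <- function(count) {
  if (any(is.na(count)) || any(count < 0)) stop("counts must be >= 0")
  log(count + 1)
}

#' Assemble a genomes x categories count matrix
#'
#' @param count_list named list of vectors from [count_categories()]
#' @return integer matrix, rows = genomes, columns = the 25 categories in
#'   fixed order
#' @export
cog_count_matrix <- function(count_list) {
  stopifnot(is.list(count_list), !is.null(names(count_list)))
  m <- do.call(rbind, lapply(count_list, .as_category_vector))
  rownames(m) <- names(count_list)
  colnames(m) <- cog_categories()
  m
}

#' Transform a count matrix for heatmap display
#'
#' `arcsine_sqrt` converts each row to proportions (denominator = row sum
#' over the 25 categories) and applies [transform_arcsine_sqrt()]; `log`
#' applies [transform_log_counts()] to the absolute counts.
#'
#' @param m count matrix from [cog_count_matrix()]
#' @param transform `"arcsine_sqrt"` or `"log"`
#' @return numeric matrix with attribute `transform_tag`
#' @export
transform_cog_matrix <- function(m, transform = c("arcsine_sqrt", "log")) {
  transform <- match.arg(transform)
  out <- if (transform == "arcsine_sqrt") {
    t(apply(m, 1, function(r) transform_arcsine_sqrt(relative_proportions(r))))
  } else {
    apply(m, c(1, 2), transform_log_counts)
  }
  dimnames(out) <- dimnames(m)
  attr(out, "transform_tag") <- transform
  out
}

#' Cluster both axes of a transformed COG matrix and render a heatmap
#'
#' Rows (genomes) and columns (categories) are each clustered with Euclidean
#' distance and average linkage (UPGMA); leaf orders come from the
#' dendrograms, so identical rows merge at height zero and the display is
#' deterministic given the matrix.
#'
#' @param m numeric matrix (use [transform_cog_matrix()] first), >= 2 rows
#'   and columns, no missing values
#' @param file optional path; when given, a heatmap is rendered there with
#'   pheatmap (device chosen from the extension: .png, .pdf, or .svg)
#' @return list with `row_hclust`, `col_hclust` (hclust objects),
#'   `row_order`, `col_order` (leaf orders as labels)
#' @export
cluster_heatmap <- function(m, file = NULL) {
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and >= 2 columns")
  if (any(is.na(m))) stop("missing values are not allowed")
  rh <- hclust(dist(m, method = "euclidean"), method = "average")
  ch <- hclust(dist(t(m), method = "euclidean"), method = "average")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    dev <- switch(ext,
                  png = function(f) grDevices::png(f, 1200, 900, res = 150),
                  svg = function(f) grDevices::svg(f, 10, 7.5),
                  pdf = function(f) grDevices::pdf(f, 10, 7.5),
                  stop("unsupported heatmap extension: .", ext))
    dev(file)
    on.exit(grDevices::dev.off(), add = TRUE)
    pheatmap::pheatmap(m, cluster_rows = rh, cluster_cols = ch,
                       main = "COG category profile")
  }
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(m)[rh$order],
       col_order = colnames(m)[ch$order])
}

#' Read a per-genome gene table (gene_id, categories) from TSV
#'
#' @param path tab-separated file with header `gene_id`, `categories`
#' @return data.frame suitable for [count_categories()]
#' @export
read_gene_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE)
  if (!all(c("gene_id", "categories") %in% names(tab)))
    stop("gene table needs 'gene_id' and 'categories' columns: ", path)
  tab$categories[is.na(tab$categories)] <- ""
  tab
}

#' Write a gene table or count/proportion matrix as TSV
#'
#' @param x data.frame or matrix
#' @param path output path
#' @export
write_tsv_matrix <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(label = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
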