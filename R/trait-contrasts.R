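#' Phylogenetically independent contrasts (Felsenstein's method)
#'
#' Post-order pruning recursion on a rooted bifurcating tree: at each
#' internal node joining children i and j with (possibly extended) branch
#' lengths v_i, v_j and values x_i, x_j, the standardized contrast is
#' `(x_i - x_j) / sqrt(v_i + v_j)`, the node's value is the
#' precision-weighted average `(x_i/v_i + x_j/v_j) / (1/v_i + 1/v_j)`, and
#' the branch above the node is extended by `v_i*v_j/(v_i + v_j)`. Under
#' Brownian evolution the n-1 contrasts are i.i.d. normal, which removes the
#' pseudocorrelation that shared ancestry induces between species traits.
#'
#' Polytomies are resolved arbitrarily into bifurcations with zero-length
#' branches, and all zero-length branches are then replaced by a small
#' epsilon (1e-8 times the tree height) to keep the recursion defined.
#'
#' @param tree a rooted [ape::phylo] with branch lengths
#' @param trait named numeric vector of tip values; names must match the
#'   tip labels exactly (an error names any orphans)
#' @return a `contrast_set` data.frame with one row per internal node:
#'   `node` (ape node id), `contrast` (standardized), `variance` (the
#'   expected variance increment v_i + v_j), `node_value` (the ancestral
#'   value estimate)
#' @examples
#' tr <- ape::read.tree(text = "(a:1,b:1);")
#' independent_contrasts(tr, c(a = 3, b = 1)) # contrast 2/sqrt(2)
#' @export
independent_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (is.null(names(trait))) stop("trait vector must be named by tip label")

  orphans <- setdiff(names(trait), tree$tip.label)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(orphans) || length(missing))
    stop("trait/tip label mismatch; ",
         if (length(orphans)) paste0("not in tree: ",
                                     paste(orphans, collapse = ", "), "; "),
         if (length(missing)) paste0("no trait value: ",
                                     paste(missing, collapse = ", ")))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")

  tree <- .resolve_tree(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode

  x <- numeric(n_node)                       # working values
  x[seq_len(n_tip)] <- trait[tree$tip.label]
  v <- numeric(n_node)                       # working (extended) branch lengths
  po <- ape::postorder(tree)
  v[tree$edge[, 2]] <- tree$edge.length      # branch above each node

  children <- split(tree$edge[, 2], tree$edge[, 1])
  contrast <- variance <- value <- numeric(0)
  nodes <- integer(0)
  visits <- integer(n_node)
  for (e in po) {
    node <- tree$edge[e, 1]
    visits[node] <- visits[node] + 1L
    if (visits[node] < 2L) next   # process once both child subtrees are done
    ch <- children[[as.character(node)]]
    stopifnot(length(ch) == 2L)              # guaranteed by .resolve_tree
    vi <- v[ch[1]]; vj <- v[ch[2]]
    nodes <- c(nodes, node)
    contrast <- c(contrast, (x[ch[1]] - x[ch[2]]) / sqrt(vi + vj))
    variance <- c(variance, vi + vj)
    x[node] <- (x[ch[1]] / vi + x[ch[2]] / vj) / (1 / vi + 1 / vj)
    value <- c(value, x[node])
    v[node] <- v[node] + vi * vj / (vi + vj)
  }
  structure(data.frame(node = nodes, contrast = contrast,
                       variance = variance, node_value = value),
            class = c("contrast_set", "data.frame"))
}

# bifurcate polytomies, then lift zero branches to epsilon
.resolve_tree <- function(tree) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (any(tree$edge.length == 0)) {
    height <- max(ape::node.depth.edgelength(tree))
    eps <- 1e-8 * if (height > 0) height else 1
    tree$edge.length[tree$edge.length == 0] <- eps
  }
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  tree
}

#' Correlation of independent contrasts (through the origin)
#'
#' Contrast signs are arbitrary (each depends on which child is subtracted
#' from which), so the correlation is computed through the origin with no
#' centering: `r = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`. Significance uses
#' `t = r * sqrt((n - 1) / (1 - r^2))` on n - 1 degrees of freedom,
#' two-sided.
#'
#' @param cs_x,cs_y contrast vectors (or `contrast_set`s) of equal length
#'   >= 3, computed on the same tree so entries correspond node-by-node
#' @return a `correlation_result`: list with `r`, `p`, `n`, `mode =
#'   "contrasts"`
#' @export
contrast_correlation <- function(cs_x, cs_y) {
  x <- if (inherits(cs_x, "data.frame")) cs_x$contrast else cs_x
  y <- if (inherits(cs_y, "data.frame")) cs_y$contrast else cs_y
  if (length(x) != length(y)) stop("contrast vectors must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 contrasts")
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) stop("all-zero contrasts: correlation undefined")
  r <- sum(x * y) / denom
  p <- .t_pvalue(r, df = n - 1L)
  structure(list(r = r, p = p, n = n, mode = "contrasts"),
            class = "correlation_result")
}

#' Raw (uncorrected) Pearson correlation of two traits
#'
#' Standard centered Pearson correlation across species, ignoring phylogeny;
#' two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. This is the "uncorrected data" panel of a contrasts analysis.
#'
#' @param trait_x,trait_y numeric vectors of equal length >= 3
#' @return a `correlation_result` with `mode = "raw"`
#' @export
raw_correlation <- function(trait_x, trait_y) {
  if (length(trait_x) != length(trait_y)) stop("traits must have equal length")
  n <- length(trait_x)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(trait_x) == 0 || sd(trait_y) == 0)
    stop("zero variance in a trait: correlation undefined")
  r <- cor(trait_x, trait_y)
  p <- .t_pvalue(r, df = n - 2L)
  structure(list(r = r, p = p, n = n, mode = "raw"),
            class = "correlation_result")
}

.t_pvalue <- function(r, df) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(t), df)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> mode=%s  r = %.3f  p = %.3g  (n = %d)\n",
              x$mode, x$r, x$p, x$n))
  invisible(x)
}

#' Two-panel raw-vs-contrasts scatter plot
#'
#' Left: trait y against trait x across species with a least-squares line.
#' Right: the corresponding independent contrasts with a through-origin
#' line. Correlations are annotated above each panel.
#'
#' @param traits data.frame with `label`, `trait_x`, `trait_y`
#' @param tree a rooted [ape::phylo] covering the labels
#' @param file optional output path (.png/.pdf/.svg)
#' @param xlab,ylab axis labels
#' @return list with `raw` and `contrasts` correlation results, invisibly
#' @export
plot_trait_contrasts <- function(traits, tree, file = NULL,
                                 xlab = "trait x", ylab = "trait y") {
  tx <- setNames(traits$trait_x, traits$label)
  ty <- setNames(traits$trait_y, traits$label)
  cx <- independent_contrasts(tree, tx)
  cy <- independent_contrasts(tree, ty)
  raw <- raw_correlation(traits$trait_x, traits$trait_y)
  con <- contrast_correlation(cx, cy)

  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    dev <- switch(ext,
                  png = function(f) grDevices::png(f, 1400, 700, res = 130),
                  svg = function(f) grDevices::svg(f, 11, 5.5),
                  pdf = function(f) grDevices::pdf(f, 11, 5.5),
                  stop("unsupported plot extension: .", ext))
    dev(file)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 3, 1))
    graphics::plot(traits$trait_x, traits$trait_y, pch = 19,
                   xlab = xlab, ylab = ylab,
                   main = sprintf("Uncorrected (r = %.3f, p = %.2g)",
                                  raw$r, raw$p))
    graphics::abline(stats::lm(traits$trait_y ~ traits$trait_x), lty = 2)
    graphics::plot(cx$contrast, cy$contrast, pch = 19,
                   xlab = paste("contrasts,", xlab),
                   ylab = paste("contrasts,", ylab),
                   main = sprintf("Independent contrasts (r = %.3f, p = %.2g)",
                                  con$r, con$p))
    graphics::abline(stats::lm(cy$contrast ~ 0 + cx$contrast), lty = 2)
  }
  invisible(list(raw = raw, contrasts = con))
}
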