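#' Simulate a Yule (pure-birth) tree
#'
#' Constant-rate lineage splitting with exponential waiting times,
#' conditioned on the number of extant taxa: starting from the root split
#' (two lineages), the waiting time while k lineages exist is
#' Exponential(k * birth_rate); after the n-th lineage appears one further
#' waiting period Exponential(n * birth_rate) elapses before the present, so
#' the expected root-to-tip depth is sum(1/(k * birth_rate)) for k = 2..n.
#' The tree is ultrametric and bifurcating with strictly positive branch
#' lengths.
#'
#' @param n_taxa number of tips (>= 2)
#' @param birth_rate speciation rate per lineage per unit time (> 0)
#' @param seed optional integer seed for reproducibility
#' @return an [ape::phylo] rooted ultrametric tree with tip labels
#'   `t1..tn`
#' @examples
#' tr <- simulate_tree(8, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  n <- as.integer(n_taxa)

  # node book-keeping: tips 1..n, internals n+1..2n-1 in order of creation
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)         # 0 for the root
  birth <- numeric(n_nodes)          # time the node's pendant edge began
  split_time <- rep(NA_real_, n_nodes)

  root <- n + 1L
  next_internal <- n + 2L
  # active lineages are provisional ids; they become tips or internals later
  # we track them as indices into a growing table of (parent, birth)
  active <- c(1L, 2L)                # provisional slots
  slot_parent <- c(root, root)
  slot_birth <- c(0, 0)
  t_now <- 0
  k <- 2L
  while (k < n) {
    t_now <- t_now + rexp(1, rate = k * birth_rate)
    i <- if (length(active) == 1L) active else sample(active, 1L)
    # the chosen lineage becomes an internal node
    node <- next_internal; next_internal <- next_internal + 1L
    parent[node] <- slot_parent[i]
    birth[node] <- slot_birth[i]
    split_time[node] <- t_now
    s1 <- length(slot_parent) + 1L; s2 <- s1 + 1L
    slot_parent <- c(slot_parent, node, node)
    slot_birth <- c(slot_birth, t_now, t_now)
    active <- c(setdiff(active, i), s1, s2)
    k <- k + 1L
  }
  t_end <- t_now + rexp(1, rate = n * birth_rate)

  # remaining active slots become the tips, in slot order for determinism
  active <- sort(active)
  for (j in seq_along(active)) {
    tip <- j
    parent[tip] <- slot_parent[active[j]]
    birth[tip] <- slot_birth[active[j]]
    split_time[tip] <- t_end
  }
  parent[root] <- 0L
  birth[root] <- 0 # root split is the time origin; its own time is unused

  child <- seq_len(n_nodes)[-root]
  edge <- cbind(parent[child], child, deparse.level = 0)
  storage.mode(edge) <- "integer"
  edge_len <- split_time[child] - birth[child]
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = n - 1L),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}
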