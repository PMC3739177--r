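#' Specification for synthetic COG gene tables
#'
#' Each group (e.g. a lifestyle: free-living, host-associated, intracellular)
#' has its own probability vector over the 25 COG functional categories.
#' Genes sample their primary category from the group profile; extra
#' assignments per gene are Poisson(`multi_assignment_rate`), reproducing
#' the real-data property that summed category counts exceed the number of
#' genes assigned to COGs. A fraction of genes stays unassigned ("not in
#' COGs").
#'
#' @param group_profiles named list mapping group label to a 25-component
#'   probability vector (ordered as [cog_categories()]); each must sum to 1
#' @param n_genes_range integer interval from which each genome's gene count
#'   is drawn uniformly
#' @param multi_assignment_rate expected extra category assignments per
#'   assigned gene (>= 0)
#' @param unassigned_fraction expected fraction of genes with no COG
#'   assignment (default 0.225, a typical spirochete value)
#' @return a `cog_profile_spec` list
#' @export
cog_profile_spec <- function(group_profiles,
                             n_genes_range = c(2500L, 3500L),
                             multi_assignment_rate = 0.1,
                             unassigned_fraction = 0.225) {
  stopifnot(is.list(group_profiles), length(group_profiles) >= 1,
            !is.null(names(group_profiles)))
  for (g in names(group_profiles)) {
    p <- group_profiles[[g]]
    if (length(p) != 25L) stop("profile for group '", g, "' must have 25 components")
    if (any(p < 0)) stop("profile for group '", g, "' has negative components")
    if (abs(sum(p) - 1) > 1e-9)
      stop("profile for group '", g, "' must sum to 1 (tolerance 1e-9)")
  }
  if (multi_assignment_rate < 0) stop("multi_assignment_rate must be >= 0")
  structure(list(group_profiles = group_profiles,
                 n_genes_range = as.integer(n_genes_range),
                 multi_assignment_rate = multi_assignment_rate,
                 unassigned_fraction = unassigned_fraction),
            class = "cog_profile_spec")
}

#' Simulate a per-genome gene table with COG category assignments
#'
#' @param spec a [cog_profile_spec()]
#' @param group group label; must exist in `spec$group_profiles`
#' @param seed optional integer seed
#' @param n_genes optional fixed gene count (otherwise drawn from
#'   `spec$n_genes_range`)
#' @return data.frame with columns `gene_id` and `categories`
#'   (semicolon-separated single letters, empty string for unassigned genes)
#' @examples
#' prof <- rep(1 / 25, 25)
#' spec <- cog_profile_spec(list(g = prof))
#' head(simulate_cog_table(spec, "g", seed = 1, n_genes = 10))
#' @export
simulate_cog_table <- function(spec, group, seed = NULL, n_genes = NULL) {
  stopifnot(inherits(spec, "cog_profile_spec"))
  if (!group %in% names(spec$group_profiles))
    stop("unknown group: '", group, "'")
  if (!is.null(seed)) set.seed(seed)
  p <- spec$group_profiles[[group]]
  cats <- cog_categories()

  if (is.null(n_genes)) {
    r <- spec$n_genes_range
    n_genes <- if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  }
  assigned <- runif(n_genes) >= spec$unassigned_fraction
  categories <- character(n_genes)
  n_assigned <- sum(assigned)
  if (n_assigned > 0) {
    primary <- sample(cats, n_assigned, replace = TRUE, prob = p)
    extra <- rpois(n_assigned, spec$multi_assignment_rate)
    categories[assigned] <- vapply(seq_len(n_assigned), function(i) {
      cc <- primary[i]
      if (extra[i] > 0)
        cc <- unique(c(cc, sample(cats, extra[i], replace = TRUE, prob = p)))
      paste(cc, collapse = ";")
    }, "")
  }
  data.frame(gene_id = sprintf("%s_%05d", group, seq_len(n_genes)),
             categories = categories, stringsAsFactors = FALSE)
}

#' Draw a Dirichlet-distributed COG profile
#'
#' Convenience generator for planted-group simulations: a 25-component
#' probability vector from Dirichlet(alpha).
#'
#' @param alpha concentration parameters (recycled to length 25)
#' @return probability vector of length 25 summing to 1
#' @export
random_cog_profile <- function(alpha = 1) {
  g <- rgamma(25L, shape = rep_len(alpha, 25L), rate = 1)
  if (sum(g) == 0) g <- rep(1, 25L)
  g / sum(g)
}
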