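# The published spirochete genome's per-category gene counts; the fixed
# 25-letter order is cog_categories().
T4_COUNTS <- c(J = 158, A = 0, K = 156, L = 125, B = 2, D = 33, Y = 0,
               V = 40, T = 228, M = 142, N = 86, Z = 0, W = 0, U = 50,
               O = 91, C = 134, G = 296, E = 188, F = 67, H = 77, I = 60,
               P = 77, Q = 26, R = 293, S = 182)

test_that("count_categories: hand enumeration, multiplicity, bad input", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    categories = c("J", "J;K", ""))
  cc <- count_categories(tab)
  expect_equal(cc[["J"]], 2L)
  expect_equal(cc[["K"]], 1L)
  expect_equal(sum(cc), 3L)
  expect_equal(attr(cc, "not_in_cogs"), 1L)
  expect_equal(attr(cc, "genes_in_cogs"), 2L)

  # concatenated letters parse the same as semicolon-separated
  cc2 <- count_categories(data.frame(gene_id = "g", categories = "JK"))
  expect_equal(cc2[["J"]] + cc2[["K"]], 2L)

  expect_error(
    count_categories(data.frame(gene_id = "g", categories = "JX")),
    "unknown COG category.*X")
})

test_that("relative proportions reproduce the published percentage table", {
  expect_equal(sum(T4_COUNTS), 2511) # summed assignments exceed the 2,270 genes in COGs
  p <- relative_proportions(T4_COUNTS)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  printed <- c(J = 6.3, A = 0.0, K = 6.2, L = 5.0, B = 0.1, D = 1.3,
               Y = 0.0, V = 1.6, T = 9.1, M = 5.7, N = 3.4, Z = 0.0,
               W = 0.0, U = 2.0, O = 3.6, C = 5.3, G = 11.8, E = 7.5,
               F = 2.7, H = 3.1, I = 2.4, P = 3.1, Q = 1.1, R = 11.7,
               S = 7.3)
  computed <- round(100 * p, 1)
  # two printed entries (Q 1.1, S 7.3) disagree with every integer-count
  # denominator by 0.1 -- rounding slips in the source table; all other 23
  # reproduce exactly under the summed-assignments denominator
  mism <- names(printed)[printed != computed[names(printed)]]
  expect_setequal(mism, c("Q", "S"))
  expect_equal(computed[["Q"]], 1.0)
  expect_equal(computed[["S"]], 7.2)

  # the "not in COGs" share instead uses total genes as denominator
  expect_equal(round(100 * not_in_cogs_share(not_in_cogs = 658,
                                             n_genes = 2928), 1), 22.5)
  expect_error(relative_proportions(setNames(rep(0, 25), cog_categories())),
               "all-zero")
})

test_that("transforms: closed forms, bounds, monotonicity", {
  expect_equal(transform_arcsine_sqrt(0), 0)
  expect_equal(transform_arcsine_sqrt(1), pi / 2)
  expect_equal(transform_arcsine_sqrt(0.25), pi / 6)
  expect_error(transform_arcsine_sqrt(1.01), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(transform_arcsine_sqrt(p)) > 0))
  expect_true(all(transform_arcsine_sqrt(p) >= 0 &
                    transform_arcsine_sqrt(p) <= pi / 2))
  # invertible on the range
  expect_equal(sin(transform_arcsine_sqrt(p))^2, p, tolerance = 1e-12)

  expect_equal(transform_log_counts(0), 0)
  expect_equal(transform_log_counts(1), log(2))
  expect_error(transform_log_counts(-1), ">= 0")
  expect_true(all(diff(transform_log_counts(0:50)) > 0))
})

test_that("matrix assembly and transforms keep shape and tags", {
  counts <- list(g1 = T4_COUNTS, g2 = rev(T4_COUNTS))
  m <- cog_count_matrix(counts)
  expect_equal(dim(m), c(2L, 25L))
  expect_equal(colnames(m), cog_categories())
  tm <- transform_cog_matrix(m, "arcsine_sqrt")
  expect_equal(attr(tm, "transform_tag"), "arcsine_sqrt")
  expect_true(all(tm >= 0 & tm <= pi / 2))
  lg <- transform_cog_matrix(m, "log")
  expect_equal(lg[1, "J"], log(159))
})

test_that("cluster_heatmap: zero-distance merge, determinism, permutation", {
  set.seed(43)
  m <- matrix(rnorm(8 * 25), 8, 25,
              dimnames = list(paste0("g", 1:8), cog_categories()))
  m[2, ] <- m[1, ] # two identical rows
  cl <- cluster_heatmap(m)
  expect_equal(cl$row_hclust$height[1], 0) # identical rows merge first
  first_pair <- sort(-cl$row_hclust$merge[1, ])
  expect_equal(first_pair, c(1, 2))

  # permuting input rows: same topology and heights
  perm <- sample(8)
  cl_p <- cluster_heatmap(m[perm, ])
  expect_equal(sort(cl_p$row_hclust$height), sort(cl$row_hclust$height),
               tolerance = 1e-12)
  expect_identical(cl_p$col_order, cl$col_order)

  expect_error(cluster_heatmap(m[1, , drop = FALSE]), ">= 2")
  m_na <- m; m_na[3, 3] <- NA
  expect_error(cluster_heatmap(m_na), "missing")

  # rendering writes a file
  f <- file.path(withr::local_tempdir(), "hm.svg")
  cluster_heatmap(m, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("gene table round-trips through TSV", {
  tab <- data.frame(gene_id = c("a", "b"), categories = c("J;K", ""))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_matrix(tab, f)
  back <- read_gene_table(f)
  expect_equal(count_categories(back), count_categories(tab))
})
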