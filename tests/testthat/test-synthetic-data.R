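test_that("simulate_tree: smallest cases and structural identities", {
  expect_error(simulate_tree(1), "n_taxa")
  expect_error(simulate_tree(5, birth_rate = 0), "birth_rate")

  tr2 <- simulate_tree(2, seed = 5)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tr2$edge.length[1], tr2$edge.length[2]) # ultrametric pair

  tr <- simulate_tree(16, seed = 1)
  expect_equal(length(tr$tip.label), 16L)
  expect_equal(tr$Nnode, 15L)                          # 2n - 1 nodes
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.ultrametric(tr))
  expect_false(anyDuplicated(tr$tip.label) > 0)
  # serializes to valid Newick and round-trips
  rt <- ape::read.tree(text = ape::write.tree(tr))
  expect_equal(sort(rt$tip.label), sort(tr$tip.label))
  expect_true(ape::is.ultrametric(rt))
})

test_that("simulate_tree: mean depth matches the Yule closed form", {
  set.seed(101)
  depths <- replicate(500, max(ape::node.depth.edgelength(simulate_tree(100))))
  expected <- sum(1 / (2:100)) # E[depth] under pure birth, rate 1
  # Monte-Carlo error: sd(depth) = sqrt(sum 1/k^2) ~ 0.8, se ~ 0.036
  expect_lt(abs(mean(depths) - expected), 0.15)
})

test_that("fixed seeds give byte-identical synthetic outputs", {
  expect_identical(ape::write.tree(simulate_tree(12, seed = 7)),
                   ape::write.tree(simulate_tree(12, seed = 7)))
  tr <- simulate_tree(12, seed = 7)
  sp <- trait_sim_spec(rho = 0.5, seed = 9)
  expect_identical(simulate_correlated_traits(tr, sp),
                   simulate_correlated_traits(tr, sp))
  gsp <- genome_pair_spec(5000, 0.3, 0.9, n_segments = 3, seed = 2)
  expect_identical(simulate_genome_pair(gsp), simulate_genome_pair(gsp))
  csp <- cog_profile_spec(list(g = rep(1 / 25, 25)))
  expect_identical(simulate_cog_table(csp, "g", seed = 4),
                   simulate_cog_table(csp, "g", seed = 4))
})

test_that("correlated traits: degenerate and null cases", {
  tr <- simulate_tree(64, seed = 3)
  # rho = 1, equal rates: the two traits are identical processes
  tt <- simulate_correlated_traits(tr, trait_sim_spec(rho = 1, seed = 11))
  cx <- independent_contrasts(tr, setNames(tt$trait_x, tt$label))
  cy <- independent_contrasts(tr, setNames(tt$trait_y, tt$label))
  expect_equal(cx$contrast, cy$contrast, tolerance = 1e-12)
  expect_equal(contrast_correlation(cx, cy)$r, 1, tolerance = 1e-12)

  # rho = 0 at n = 200: one replicate stays inside the null width
  tr0 <- simulate_tree(200, seed = 13)
  t0 <- simulate_correlated_traits(tr0, trait_sim_spec(rho = 0, seed = 17))
  c0x <- independent_contrasts(tr0, setNames(t0$trait_x, t0$label))
  c0y <- independent_contrasts(tr0, setNames(t0$trait_y, t0$label))
  expect_lt(abs(contrast_correlation(c0x, c0y)$r), 0.2)

  expect_error(simulate_correlated_traits(
    structure(list(edge = tr$edge, edge.length = rep(0, nrow(tr$edge)),
                   tip.label = tr$tip.label, Nnode = tr$Nnode),
              class = "phylo"),
    trait_sim_spec()), "branch length")
})

test_that("Brownian increments on disjoint branches are independent", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  set.seed(23)
  inc <- t(replicate(2000, {
    tt <- simulate_correlated_traits(tr, trait_sim_spec(rho = 0))
    tt$trait_x # both tips start at the root value 0
  }))
  expect_lt(abs(cov(inc[, 1], inc[, 2])), 0.1)
  expect_equal(apply(inc, 2, var), c(1, 1), tolerance = 0.15)
})

test_that("genome pair: degenerate fractions", {
  # full conservation, no divergence: identical strings
  pair <- simulate_genome_pair(
    genome_pair_spec(1000, 1, 1, n_segments = 10, seed = 1))
  expect_identical(pair$genome_a$seq, pair$genome_b$seq)

  # nothing alignable: empty TruthMap
  pair0 <- simulate_genome_pair(genome_pair_spec(1000, 0, 0.9, seed = 1))
  expect_equal(nrow(pair0$truth), 0L)

  expect_error(genome_pair_spec(1000, 0.01, 0.9, n_segments = 5),
               "infeasible")
})

test_that("genome pair: TruthMap coverage and identity hit their targets", {
  pair <- simulate_genome_pair(
    genome_pair_spec(50000, 0.30, 0.85, n_segments = 10, seed = 7))
  ts <- truth_summary(pair$truth, 50000)
  expect_lt(abs(ts$coverage - 0.30), 0.02)
  expect_lt(abs(ts$identity - 0.85), 0.02)
  # segments are non-overlapping and inside the genome on both axes
  tr <- pair$truth
  expect_true(all(tr$a_start >= 0 & tr$a_end <= 50000))
  expect_true(all(tr$b_start >= 0 & tr$b_end <= 50000))
  expect_true(all(tr$a_start[-1] >= head(tr$a_end, -1)))
  o <- order(tr$b_start)
  expect_true(all(tr$b_start[o][-1] >= head(tr$b_end[o], -1)))
})

test_that("cog tables: point mass, LLN convergence, multiplicity", {
  point <- c(rep(0, 16), 1, rep(0, 8)) # all mass on G (position 17)
  spec <- cog_profile_spec(list(pm = point, unif = rep(1 / 25, 25)),
                           multi_assignment_rate = 0.1,
                           unassigned_fraction = 0)
  expect_error(simulate_cog_table(spec, "nope"), "unknown group")

  tab <- simulate_cog_table(spec, "pm", seed = 31, n_genes = 500)
  cc <- count_categories(tab)
  expect_equal(sum(cc), cc[["G"]]) # every assignment lands in G

  tab_u <- simulate_cog_table(spec, "unif", seed = 37, n_genes = 10000)
  cc_u <- count_categories(tab_u)
  expect_true(all(abs(relative_proportions(cc_u) - 1 / 25) < 0.02))
  # Poisson(0.1) extra assignments (minus rare duplicate-category collisions)
  ratio <- sum(cc_u) / attr(cc_u, "genes_in_cogs")
  expect_lt(abs(ratio - 1.1), 0.02)

  spec0 <- cog_profile_spec(list(u = rep(1 / 25, 25)),
                            multi_assignment_rate = 0)
  tab0 <- simulate_cog_table(spec0, "u", seed = 41, n_genes = 2000)
  cc0 <- count_categories(tab0)
  expect_lte(sum(cc0), nrow(tab0)) # no multiplicity: assignments <= genes

  expect_error(cog_profile_spec(list(bad = rep(0.1, 25))), "sum to 1")
})
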