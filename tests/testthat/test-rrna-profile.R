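# builds a hit table in code: three subjects, multiple HSP rows for one
make_hits <- function(scores = c(100, 100, 50),
                      descriptions = c("termite gut clone",
                                       "termite hindgut clone",
                                       "hindgut homogenate")) {
  tab <- data.frame(
    qseqid = "q16S", sseqid = c("s1", "s2", "s3"),
    pident = c(99, 98, 97), length = c(100, 200, 150),
    mismatch = 0, gapopen = 0,
    qstart = c(1, 1, 10), qend = c(100, 200, 159),
    sstart = 1, send = 100, evalue = 0, bitscore = scores)
  annot <- data.frame(subject = c("s1", "s2", "s3"),
                      taxon = c("Spirochaeta caldaria",
                                "Spirochaeta africana",
                                "Treponema primitia"),
                      description = descriptions)
  hit_table(tab, annot)
}

test_that("weighted taxon frequencies: hand-computed weights", {
  h <- make_hits()
  rep <- weighted_taxon_frequencies(h)
  expect_equal(rep$frequency[rep$item == "Spirochaeta"], 200 / 250)
  expect_equal(rep$frequency[rep$item == "Treponema"], 50 / 250)
  expect_equal(sum(rep$frequency), 1, tolerance = 1e-9)
  expect_equal(attr(rep, "n_hits"), 3L)

  # single hit: 100%
  one <- make_hits()[1, ]
  expect_equal(weighted_taxon_frequencies(one)$frequency, 1)

  # quoted provisional names parse to the genus
  h2 <- h; h2$taxon <- c("\"Spirochaeta taiwanensis\"", "Treponema sp.",
                         "Treponema primitia")
  r2 <- weighted_taxon_frequencies(h2)
  expect_equal(r2$frequency[r2$item == "Spirochaeta"], 100 / 250)

  h3 <- h; h3$taxon <- NA_character_
  expect_error(weighted_taxon_frequencies(h3), "genus")
})

test_that("weighted keyword frequencies: stems, de-duplication, invariances", {
  h <- make_hits(scores = c(10, 30, 1),
                 descriptions = c("termite gut", "termite hindgut", ""))
  rep <- weighted_keyword_frequencies(h[1:2, ])
  # stems per hit: {termit, gut} at 10, {termit, hindgut} at 30
  expect_equal(rep$frequency[rep$item == "termit"], 40 / 80)
  expect_equal(rep$frequency[rep$item == "hindgut"], 30 / 80)
  expect_equal(rep$frequency[rep$item == "gut"], 10 / 80)

  # a repeated word counts once per hit
  h_rep <- make_hits(descriptions = c("gut gut gut", "gut", "gut"))
  r_rep <- weighted_keyword_frequencies(h_rep)
  expect_equal(r_rep$frequency, 1)

  # identical descriptions: frequencies independent of the score values
  h_a <- make_hits(scores = c(5, 5, 5),
                   descriptions = rep("termite hindgut clone", 3))
  h_b <- make_hits(scores = c(90, 10, 40),
                   descriptions = rep("termite hindgut clone", 3))
  expect_equal(weighted_keyword_frequencies(h_a)$frequency,
               weighted_keyword_frequencies(h_b)$frequency)

  # uniform score rescaling leaves frequencies unchanged
  h1 <- make_hits(scores = c(10, 30, 20))
  h2 <- make_hits(scores = c(10, 30, 20) * 7)
  expect_equal(weighted_keyword_frequencies(h1)$frequency,
               weighted_keyword_frequencies(h2)$frequency)
  expect_equal(weighted_taxon_frequencies(h1)$frequency,
               weighted_taxon_frequencies(h2)$frequency)

  # hit order does not matter
  h_shuf <- h1[c(3, 1, 2), ]
  expect_equal(weighted_keyword_frequencies(h_shuf),
               weighted_keyword_frequencies(h1),
               ignore_attr = TRUE)

  h_empty <- make_hits(descriptions = c("", "", ""))
  expect_error(weighted_keyword_frequencies(h_empty), "empty")
})

test_that("porter stemmer reproduces the published example vectors", {
  input <- c("caresses", "ponies", "ties", "caress", "cats", "feed",
             "agreed", "plastered", "motoring", "sing", "conflated",
             "troubled", "sized", "hopping", "tanned", "falling",
             "hissing", "fizzed", "failing", "filing", "happy", "sky",
             "relational", "conditional", "rational", "digitizer",
             "operator", "generalization", "termite", "hindgut")
  expected <- c("caress", "poni", "ti", "caress", "cat", "feed",
                "agre", "plaster", "motor", "sing", "conflat",
                "troubl", "size", "hop", "tan", "fall",
                "hiss", "fizz", "fail", "file", "happi", "sky",
                "relat", "condit", "ration", "digit",
                "oper", "gener", "termit", "hindgut")
  expect_equal(porter_stem(input), expected)
})

test_that("hsp_summary: means, interval merging, bounds", {
  # full cover at full identity
  tab <- data.frame(qseqid = "q", sseqid = "s", pident = 100, length = 100,
                    mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
                    sstart = 1, send = 100, evalue = 0, bitscore = 200)
  h <- hit_table(tab)
  s <- hsp_summary(h, 100)
  expect_equal(s$mean_identity, 100)
  expect_equal(s$mean_coverage, 100)

  # arithmetic means over hits: coverages 0.9, 0.7; identities 98, 96
  tab2 <- data.frame(qseqid = "q", sseqid = c("s1", "s2"),
                     pident = c(98, 96), length = c(90, 70),
                     mismatch = 0, gapopen = 0,
                     qstart = c(1, 1), qend = c(90, 70),
                     sstart = 1, send = 50, evalue = 0, bitscore = 100)
  s2 <- hsp_summary(hit_table(tab2), 100)
  expect_equal(s2$mean_identity, 97)
  expect_equal(s2$mean_coverage, 80)

  # overlapping HSPs within one hit merge before coverage: [0,60)+[40,100)
  tab3 <- data.frame(qseqid = "q", sseqid = "s", pident = 100,
                     length = c(60, 60), mismatch = 0, gapopen = 0,
                     qstart = c(1, 41), qend = c(60, 100),
                     sstart = 1, send = 60, evalue = 0, bitscore = 100)
  expect_equal(hsp_summary(hit_table(tab3), 100)$mean_coverage, 100)
  # splitting one HSP into abutting pieces leaves coverage unchanged
  tab4 <- tab3; tab4$qstart <- c(1, 61); tab4$qend <- c(60, 100)
  expect_equal(hsp_summary(hit_table(tab4), 100)$mean_coverage, 100)

  expect_error(hsp_summary(hit_table(tab3), 50), "exceeds")
  expect_error(hsp_summary(hit_table(tab3), 0), "query_length")
})

test_that("pairwise_differences: counts, symmetry, ambiguity handling", {
  expect_equal(pairwise_differences(c(a = "ACGT", b = "ACGT"))["a", "b"], 0L)
  expect_equal(pairwise_differences(c(a = "ACGT", b = "ACGA"))["a", "b"], 1L)

  # planted pairwise differences {1, 2, 3}
  s1 <- strrep("A", 50)
  s2 <- paste0("C", strrep("A", 49))                 # 1 diff to s1
  s3 <- paste0("CG", strrep("A", 47), "T")           # d(s1,s3)=3, d(s2,s3)=2
  m <- pairwise_differences(c(x = s1, y = s2, z = s3))
  expect_equal(m["x", "y"], 1L)
  expect_equal(m["y", "z"], 2L)
  expect_equal(m["x", "z"], 3L)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))

  # N and gaps are excluded, not counted as differences
  expect_equal(pairwise_differences(c(a = "ACNT", b = "ACGT"))["a", "b"], 0L)
  expect_equal(pairwise_differences(c(a = "AC-T", b = "ACGT"))["a", "b"], 0L)
  expect_error(pairwise_differences(c(a = "ACGT", b = "ACG")), "equal length")
  expect_error(pairwise_differences(c(a = "ACGT")), "at least 2")
})

test_that("hit files round-trip through the outfmt-6 reader", {
  dir <- withr::local_tempdir()
  hits_path <- file.path(dir, "hits.tsv")
  annot_path <- file.path(dir, "annot.tsv")
  tab <- data.frame(
    qseqid = "q16S", sseqid = c("s1", "s1", "s2"),
    pident = c(99.5, 98, 97), length = c(800, 700, 1500),
    mismatch = c(4, 14, 45), gapopen = 0,
    qstart = c(1, 801, 1), qend = c(800, 1500, 1500),
    sstart = 1, send = 800, evalue = 1e-50,
    bitscore = c(1400, 1200, 2500))
  write.table(tab, hits_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(subject = c("s1", "s2"),
                         taxon = c("Spirochaeta caldaria", "Treponema sp."),
                         description = c("hot spring mat clone",
                                         "termite hindgut clone")),
              annot_path, sep = "\t", quote = FALSE, row.names = FALSE)
  h <- read_hit_table(hits_path, annot_path)
  expect_equal(nrow(h), 2L)                    # two subjects -> two hits
  expect_equal(h$bitscore[h$subject == "s1"], 1400)  # best HSP's bit score
  # pooled identity: (0.995*800 + 0.98*700) / 1500
  expect_equal(h$identity[h$subject == "s1"],
               (0.995 * 800 + 0.98 * 700) / 1500 * 100)
  s <- hsp_summary(h, 1500)
  expect_equal(s$mean_coverage, 100)           # both hits span the query
})
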