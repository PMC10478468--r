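# A small deterministic setup used across the hotspot tests: 10 genes of
# 1 kb each on a 20 kb genome, counts assembled by hand.
toy_matrix <- function(counts, strains = rownames(counts)) {
  genes <- data.frame(
    locus_tag = colnames(counts),
    length = rep(1000L, ncol(counts)),
    start = seq(1L, by = 2000L, length.out = ncol(counts)),
    end = seq(1000L, by = 2000L, length.out = ncol(counts)),
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, genes = genes, strains = strains,
                 total_mutations = sum(counts)),
            class = "gene_mutation_matrix")
}

test_that("the count matrix keeps zero genes and honours effect classes", {
  g <- make_toy_genome(6000, 3, seed = 21)
  tags <- g$features$locus_tag
  ann <- data.frame(
    strain_id = c("A", "A", "B", "B"),
    locus_tag = c(tags[1], tags[1], tags[2], tags[2]),
    effect = c("nonsynonymous", "nonsynonymous", "nonsense", "synonymous"),
    stringsAsFactors = FALSE
  )
  m <- build_matrix(ann, g)
  expect_equal(dim(m$counts), c(2L, 3L))
  expect_equal(m$counts["A", tags[1]], 2L)
  expect_equal(m$counts["B", tags[2]], 1L)  # synonymous excluded
  expect_equal(m$total_mutations, 3L)
  expect_equal(sum(m$counts), m$total_mutations)
  # empty input gives an all-zero matrix over the declared strains
  m0 <- build_matrix(ann[0, ], g, strains = c("A", "B"))
  expect_equal(sum(m0$counts), 0L)
  expect_equal(dim(m0$counts), c(2L, 3L))
})

test_that("hotspot calling applies the inclusive 10% threshold and ranks densely", {
  counts <- matrix(0L, nrow = 20, ncol = 4,
                   dimnames = list(sprintf("s%02d", 1:20),
                                   c("g1", "g2", "g3", "g4")))
  counts[1:5, "g1"] <- 1L     # 25% of strains
  counts[1:2, "g2"] <- 3L     # exactly 10%: kept (boundary inclusive)
  counts[1, "g3"] <- 1L       # 5%: dropped
  counts[3:7, "g4"] <- 1L     # ties g1 on strains, fewer mutations? equal
  m <- toy_matrix(counts)
  hs <- call_hotspots(m, min_fraction = 0.10)
  expect_equal(sort(hs$locus_tag), c("g1", "g2", "g4"))
  expect_false("g3" %in% hs$locus_tag)
  expect_equal(hs$fraction_strains[hs$locus_tag == "g2"], 0.10)
  # dense ranks: g1/g4 tie on 5 strains (rank 1), g2 rank 2
  expect_equal(hs$rank, c(1L, 1L, 2L))
  expect_equal(hs$locus_tag[3], "g2")
  # monotonicity: raising the threshold never adds genes
  for (f in c(0.15, 0.2, 0.5)) {
    expect_true(all(call_hotspots(m, f)$locus_tag %in% hs$locus_tag))
  }
})

test_that("length enrichment reproduces the closed-form expectation", {
  counts <- matrix(0L, nrow = 10, ncol = 10,
                   dimnames = list(sprintf("s%02d", 1:10),
                                   sprintf("g%02d", 1:10)))
  # 100 mutations total, 20 of them in g01: expected 10 under equal lengths
  counts[, "g01"] <- 2L
  for (j in 2:10) counts[1:8, sprintf("g%02d", j)] <- 1L
  counts[9:10, "g02"] <- c(4L, 4L)
  m <- toy_matrix(counts)
  expect_equal(m$total_mutations, 100L)
  enr <- length_enrichment(m)
  expect_equal(enr$expected, rep(10, 10))
  expect_equal(enr$enrichment_fold[enr$locus_tag == "g01"], 2.0)
  # conservation: expected counts sum to the observed total
  expect_equal(sum(enr$expected), m$total_mutations)
  # zero observed -> fold 0
  counts0 <- counts; counts0[, "g03"] <- 0L
  enr0 <- length_enrichment(toy_matrix(counts0))
  expect_equal(enr0$enrichment_fold[enr0$locus_tag == "g03"], 0)
  # zero total is an error
  expect_error(length_enrichment(toy_matrix(counts * 0L)), "zero total")
})

test_that("uniform random placement keeps enrichment folds near one", {
  set.seed(99)
  counts <- matrix(0L, 10, 10,
                   dimnames = list(sprintf("s%02d", 1:10),
                                   sprintf("g%02d", 1:10)))
  hits <- table(factor(sample.int(10, 1000, replace = TRUE), levels = 1:10))
  for (j in 1:10) counts[1, j] <- as.integer(hits[j])
  enr <- length_enrichment(toy_matrix(counts))
  expect_true(all(enr$enrichment_fold > 0.5 & enr$enrichment_fold < 2.0))
})

test_that("co-mutation fractions enumerate shared strains", {
  counts <- matrix(0L, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  counts["s1", ] <- 1L          # both
  counts["s2", "A"] <- 1L       # A only
  counts["s3", "B"] <- 1L       # B only
  m <- toy_matrix(counts)
  expect_equal(co_mutation(m, "A", "B"), 0.5)
  expect_equal(co_mutation(m, "A", "A"), 1.0)
  counts2 <- counts; counts2["s1", "B"] <- 0L
  expect_equal(co_mutation(toy_matrix(counts2), "A", "B"), 0)
  expect_error(co_mutation(toy_matrix(counts * 0L), "A", "B"), "undefined")
  expect_error(co_mutation(m, "A", "Z"), "not in matrix")
})

test_that("candidate ranking follows penalty, then titer, then biomass", {
  counts <- matrix(0L, 3, 6,
                   dimnames = list(c("lean", "loaded", "absent"),
                                   sprintf("h%d", 1:6)))
  counts["lean", "h1"] <- 1L
  counts["loaded", sprintf("h%d", 1:5)] <- 1L
  counts["absent", "h6"] <- 1L
  m <- toy_matrix(counts)
  hs <- data.frame(locus_tag = sprintf("h%d", 1:6))
  screen <- data.frame(strain_id = c("lean", "loaded"),
                       titer_improvement = c(30, 30),
                       biomass_change = c(-5, -5))
  cand <- rank_candidates(m, hs, screen)
  # same titer: the strain with a single hotspot SNP outranks the loaded one
  expect_equal(cand$strain_id[1], "lean")
  expect_equal(cand$abundance_penalty[cand$strain_id == "lean"], 0L)
  expect_true(all(cand$abundance_penalty[cand$strain_id == "loaded"] == 4L))
  # strain missing from the screen ranks last despite zero penalty
  expect_equal(cand$strain_id[nrow(cand)], "absent")
  expect_true(is.na(cand$titer_improvement[nrow(cand)]))

  # equal penalties: +40% beats +15%
  screen2 <- data.frame(strain_id = c("lean", "loaded"),
                        titer_improvement = c(15, 40),
                        biomass_change = c(-5, -5))
  counts2 <- counts; counts2["loaded", sprintf("h%d", 2:5)] <- 0L
  cand2 <- rank_candidates(toy_matrix(counts2), hs, screen2)
  expect_equal(cand2$strain_id[1], "loaded")

  # a single candidate comes back unchanged
  single <- rank_candidates(toy_matrix(counts["lean", "h1", drop = FALSE]),
                            data.frame(locus_tag = "h1"), screen)
  expect_equal(nrow(single), 1L)
})

test_that("pathway attribution is file-driven with empty defaults", {
  td <- withr::local_tempdir()
  map <- file.path(td, "pathways.tsv")
  writeLines(c("locus_tag\tpathway",
               "fasB\tfatty acid synthesis",
               "fasB\tlipid metabolism",
               "pyk1\tglycolysis"), map)
  tags <- attribute_pathways(c("fasB", "unknown"), map)
  expect_equal(tags$fasB, c("fatty acid synthesis", "lipid metabolism"))
  expect_equal(tags$unknown, character(0))
  # empty map: all empty
  writeLines("locus_tag\tpathway", map)
  expect_equal(attribute_pathways("fasB", map)$fasB, character(0))
  expect_error(attribute_pathways("x", data.frame(a = 1)), "malformed")
})

test_that("positional totals order genes by genomic start and conserve counts", {
  counts <- matrix(c(2L, 0L, 1L, 3L, 0L, 1L), nrow = 2)
  dimnames(counts) <- list(c("s1", "s2"), c("gB", "gA", "gC"))
  m <- toy_matrix(counts)
  m$genes$start <- c(5000L, 100L, 9000L)  # gA first on the chromosome
  pt <- positional_totals(m)
  expect_equal(pt$locus_tag, c("gA", "gB", "gC"))
  expect_equal(sum(pt$total), m$total_mutations)
})
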