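test_that("positions map to CDS, promoter window or intergenic space", {
  g <- make_toy_genome(6000, 4, seed = 11)
  f <- g$features
  # inside a CDS body
  inside <- map_to_feature(g, f$start[1] + 5L)
  expect_equal(inside$region, "CDS")
  expect_equal(inside$locus_tag, f$locus_tag[1])
  expect_error(map_to_feature(g, 0L), "out of")
  expect_error(map_to_feature(g, g$length + 1L), "out of")
})

test_that("promoter window arithmetic matches a brute-force oracle", {
  g <- make_toy_genome(8000, 5, seed = 12)
  f <- g$features
  L <- g$length
  # brute-force oracle: enumerate windows directly
  oracle <- function(p) {
    for (i in seq_len(nrow(f))) {
      if (p >= f$start[i] && p <= f$end[i]) return(c("CDS", f$locus_tag[i]))
    }
    best <- NULL
    for (i in seq_len(nrow(f))) {
      d <- if (f$strand[i] == "+") (f$start[i] - p) %% L else (p - f$end[i]) %% L
      if (d >= 1 && d <= 200) {
        if (is.null(best) || d < best$d ||
            (d == best$d && f$locus_tag[i] < best$tag)) {
          best <- list(d = d, tag = f$locus_tag[i])
        }
      }
    }
    if (is.null(best)) c("intergenic", NA) else c("promoter", best$tag)
  }
  set.seed(3)
  pos <- sample.int(L, 400)
  got <- map_to_feature(g, pos)
  want <- t(vapply(pos, oracle, character(2)))
  expect_equal(got$region, unname(want[, 1]))
  expect_equal(got$locus_tag, unname(want[, 2]))
})

test_that("promoter window boundary is exactly 200 bp, on either strand", {
  # single plus-strand CDS far from edges
  g <- codon_genome(rep("GCT", 50), strand = "+", pad = 400)
  s <- g$features$start
  expect_equal(map_to_feature(g, s - 150L)$region, "promoter")
  expect_equal(map_to_feature(g, s - 200L)$region, "promoter")
  expect_equal(map_to_feature(g, s - 201L)$region, "intergenic")
  g2 <- codon_genome(rep("GCT", 50), strand = "-", pad = 400)
  e <- g2$features$end
  expect_equal(map_to_feature(g2, e + 200L)$region, "promoter")
  expect_equal(map_to_feature(g2, e + 201L)$region, "intergenic")
})

test_that("spectrum classes collapse strand-symmetrically with ti/tv labels", {
  expect_equal(classify_spectrum("G", "A"),
               data.frame(spectrum_class = "G:C>A:T", ti_tv = "transition"))
  expect_equal(classify_spectrum("C", "T"),
               data.frame(spectrum_class = "G:C>A:T", ti_tv = "transition"))
  expect_equal(classify_spectrum("G", "T"),
               data.frame(spectrum_class = "G:C>T:A", ti_tv = "transversion"))
  expect_equal(classify_spectrum("A", "G")$ti_tv, "transition")
  expect_equal(classify_spectrum("T", "A")$spectrum_class, "A:T>T:A")
  expect_error(classify_spectrum("N", "A"), "non-ACGT")
  expect_error(classify_spectrum("A", "A"), "differ")
  # the 12 directed substitutions cover exactly the 6 classes, twice each
  bases <- c("A", "C", "G", "T")
  all12 <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  all12 <- all12[all12$ref != all12$alt, ]
  cls <- classify_spectrum(all12$ref, all12$alt)
  expect_equal(sort(unname(table(cls$spectrum_class))), rep(2L, 6L),
               ignore_attr = TRUE)
  expect_equal(sum(cls$ti_tv == "transition"), 4L)
})

test_that("codon-level effects reproduce hand-built expectations", {
  # residue 735 GAC -> GGC must give nonsynonymous D735G
  codons <- rep("GCT", 800)
  codons[734] <- "GAC"  # residue 735 counting the start codon
  g <- codon_genome(codons, strand = "+")
  pos <- g$features$start + 3L * 734L + 1L  # middle base of codon 735
  ann <- classify_coding_effect(
    list(position = pos, ref = "A", alt = "G"), g)
  expect_equal(ann$effect, "nonsynonymous")
  expect_equal(ann$protein_change, "D735G")
  expect_equal(ann$codon_index, 735L)

  # CTG -> CTA: synonymous leucine
  codons2 <- rep("GCT", 10); codons2[5] <- "CTG"
  g2 <- codon_genome(codons2)
  pos2 <- g2$features$start + 3L * 5L + 2L  # third base of codon 6
  ann2 <- classify_coding_effect(list(position = pos2, ref = "G", alt = "A"), g2)
  expect_equal(ann2$effect, "synonymous")

  # TGG -> TGA: nonsense
  codons3 <- rep("GCT", 10); codons3[5] <- "TGG"
  g3 <- codon_genome(codons3)
  pos3 <- g3$features$start + 3L * 5L + 2L
  ann3 <- classify_coding_effect(list(position = pos3, ref = "G", alt = "A"), g3)
  expect_equal(ann3$effect, "nonsense")
  expect_match(ann3$protein_change, "^W6\\*$")
})

test_that("minus-strand CDSs classify on the coding strand", {
  # coding codon GAT at residue 6; genomic strand carries the complement.
  codons <- rep("GCT", 10); codons[5] <- "GAT"
  g <- codon_genome(codons, strand = "-")
  # coding offset of codon 6, base 1 is 15; genomic position = end - 15
  pos <- g$features$end - 15L
  expect_equal(substr(g$sequence, pos, pos), "C")  # complement of coding G
  ann <- classify_coding_effect(list(position = pos, ref = "C", alt = "T"), g)
  expect_equal(ann$effect, "nonsynonymous")
  expect_equal(ann$protein_change, "D6N")  # GAT -> AAT
})

test_that("coding-effect calls agree with whole-CDS retranslation", {
  g <- make_toy_genome(20000, 12, seed = 5)
  snps <- random_cds_snps(g, 200, seed = 6)
  ann <- annotate_variants(snps, g)
  for (i in seq_len(nrow(ann))) {
    want <- oracle_coding_effect(g, ann$position[i], ann$alt[i])
    expect_equal(ann$effect[i], want$effect)
    if (want$effect != "synonymous") {
      expect_equal(ann$protein_change[i], want$protein_change)
    }
  }
})

test_that("origin-wrapping CDSs annotate correctly on both sides of the join", {
  g <- codon_genome(rep("GAC", 40), strand = "+", pad = 30)
  # rotate the genome so the CDS spans the origin
  L <- g$length
  shift <- g$features$start + 60L  # cut inside the CDS
  rotated <- paste0(substr(g$sequence, shift, L), substr(g$sequence, 1, shift - 1L))
  g$sequence <- rotated
  new_start <- L - shift + 1L + g$features$start
  g$features$start <- new_start
  g$features$end <- new_start + g$features$length - 1L
  stopifnot(g$features$end > L)  # wraps
  # codon 30 (GAC), middle base, lies beyond the origin cut
  pos_unwrapped <- g$features$start + 3L * 29L + 1L
  pos <- evohotspot:::wrap_position(pos_unwrapped, L)
  expect_lt(pos, g$features$start)  # really in the wrapped tail
  ann <- classify_coding_effect(list(position = pos, ref = "A", alt = "G"), g)
  expect_equal(ann$effect, "nonsynonymous")
  expect_equal(ann$protein_change, "D30G")
})

test_that("a reference-allele mismatch is an error, not a silent fix", {
  g <- codon_genome(rep("GCT", 10))
  pos <- g$features$start
  wrong <- setdiff(c("A", "C", "G", "T"),
                   substr(g$sequence, pos, pos))[1]
  expect_error(
    annotate_variants(data.frame(strain_id = "s", position = pos, ref = wrong,
                                 alt = "T", kind = "SNP", read_frequency = 1),
                      g),
    "mismatch"
  )
})

test_that("frequency and synonymous filters apply the documented boundaries", {
  v <- data.frame(
    strain_id = "s", position = 1:4, ref = "G", alt = "A", kind = "SNP",
    read_frequency = c(0.49, 0.50, 0.90, 0.95),
    effect = c("nonsynonymous", "nonsynonymous", "synonymous", "promoter"),
    stringsAsFactors = FALSE
  )
  out <- filter_variants(v)
  # 0.49 discarded, 0.50 kept (boundary inclusive), synonymous dropped
  expect_equal(out$position, c(2L, 4L))
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["low_frequency"]), 1L)
  expect_equal(unname(counts["synonymous"]), 1L)
  # empty input passes through
  expect_equal(nrow(filter_variants(v[0, ])), 0L)
  # idempotence
  again <- filter_variants(out)
  expect_equal(again$position, out$position)
})

test_that("mutation load summarises per-strain counts", {
  v <- data.frame(strain_id = rep(c("a", "b"), c(2, 4)), position = 1:6)
  ml <- mutation_load(v)
  expect_equal(ml$mean, 3)
  expect_equal(c(ml$min, ml$max), c(2L, 4L))
  # zero strains: empty summary, no crash
  empty <- mutation_load(v[0, ])
  expect_equal(empty$n_strains, 0L)
  expect_true(is.na(empty$mean))
  # a fixed strain universe keeps zero-count strains
  ml2 <- mutation_load(v, strains = c("a", "b", "c"))
  expect_equal(ml2$min, 0L)
})

test_that("coverage anomalies are maximal runs against the genome median", {
  d <- rep(100, 10000)
  d[4001:5000] <- 0
  calls <- detect_coverage_anomalies(d, strain_id = "s1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "putative_deletion")
  expect_equal(c(calls$start, calls$end), c(4001L, 5000L))
  d2 <- rep(100, 10000)
  d2[2001:3000] <- 200
  dup <- detect_coverage_anomalies(d2)
  expect_equal(dup$kind, "putative_duplication")
  expect_equal(dup$mean_fold, 2.0)
  # uniform depth: no calls; short excursions below min_window: no calls
  expect_equal(nrow(detect_coverage_anomalies(rep(100, 5000))), 0L)
  d3 <- rep(100, 5000); d3[100:300] <- 0
  expect_equal(nrow(detect_coverage_anomalies(d3)), 0L)
  expect_error(detect_coverage_anomalies(rep(0, 1000)), "zero")
})

test_that("spectrum summary fractions sum to one over SNPs", {
  v <- data.frame(spectrum_class = c(rep("G:C>A:T", 8), "A:T>G:C", NA))
  s <- spectrum_summary(v)
  expect_equal(sum(s$count), 9L)
  expect_equal(sum(s$fraction), 1)
  expect_equal(s$fraction[s$class == "G:C>A:T"], 8 / 9)
})
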