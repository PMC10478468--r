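test_that("FASTA + GFF3 reference loads with native 1-based coordinates", {
  td <- withr::local_tempdir()
  seq60 <- paste(rep("ATGGCTGCTGCTGCTGCTGCTGCTGCTTAA", 2), collapse = "")
  writeLines(c(">chr1", seq60), file.path(td, "g.fa"))
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t1\t30\t.\t+\t0\tID=gene1;locus_tag=gene1"
  ), file.path(td, "g.gff"))
  g <- read_reference(file.path(td, "g.fa"), file.path(td, "g.gff"))
  expect_equal(g$length, 60L)
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$features$start, 1L)
  expect_equal(g$features$end, 30L)
  expect_equal(g$features$length, 30L)
  # sequence slice length equals feature length
  expect_equal(nchar(substr(g$sequence, g$features$start, g$features$end)),
               g$features$length)
})

test_that("GenBank flat file round-trips two CDS on opposite strands", {
  td <- withr::local_tempdir()
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  origin <- paste(vapply(seq(1, 600, 60), function(i) {
    chunk <- substr(seq, i, i + 59)
    blocks <- substring(chunk, seq(1, 60, 10), seq(10, 60, 10))
    sprintf("%9d %s", i, paste(tolower(blocks), collapse = " "))
  }, character(1)), collapse = "\n")
  gb <- c(
    "LOCUS       chrgb                600 bp    DNA     circular BCT",
    "DEFINITION  synthetic test chromosome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "     CDS             10..108",
    '                     /locus_tag="GB_0001"',
    '                     /gene="aaa"',
    '                     /product="protein A"',
    "     CDS             complement(201..299)",
    '                     /locus_tag="GB_0002"',
    '                     /product="protein B"',
    "ORIGIN",
    origin,
    "//"
  )
  writeLines(gb, file.path(td, "g.gb"))
  writeLines(c(">chrgb", seq), file.path(td, "g.fa"))
  g <- read_reference(file.path(td, "g.fa"), file.path(td, "g.gb"))
  expect_equal(nrow(g$features), 2L)
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$locus_tag, c("GB_0001", "GB_0002"))
  expect_equal(g$features$gene_name[1], "aaa")
  expect_equal(g$features$length, c(99L, 99L))
  # GenBank ORIGIN alone can also supply the sequence
  g2 <- read_reference(NULL, file.path(td, "g.gb"))
  expect_identical(g2$sequence, g$sequence)
})

test_that("CDS length not divisible by 3 is loaded with a recorded warning", {
  td <- withr::local_tempdir()
  writeLines(c(">chr1", strrep("ACGT", 30)), file.path(td, "g.fa"))
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t5\t35\t.\t+\t0\tID=odd1;locus_tag=odd1"
  ), file.path(td, "g.gff"))
  expect_warning(
    g <- read_reference(file.path(td, "g.fa"), file.path(td, "g.gff")),
    "divisible by 3"
  )
  expect_equal(nrow(g$features), 1L)  # loaded, not dropped
  expect_match(g$warnings, "odd1")
})

test_that("reference loading validates ids, bounds and locus-tag uniqueness", {
  td <- withr::local_tempdir()
  writeLines(c(">chrA", strrep("ACGT", 30)), file.path(td, "g.fa"))
  writeLines(c(
    "##gff-version 3",
    "chrB\ttest\tCDS\t1\t30\t.\t+\t0\tID=g1;locus_tag=g1"
  ), file.path(td, "mismatch.gff"))
  expect_error(read_reference(file.path(td, "g.fa"),
                              file.path(td, "mismatch.gff")), "mismatch")
  writeLines(c(
    "##gff-version 3",
    "chrA\ttest\tCDS\t1\t30\t.\t+\t0\tID=g1;locus_tag=g1",
    "chrA\ttest\tCDS\t40\t69\t.\t+\t0\tID=g2;locus_tag=g1"
  ), file.path(td, "dup.gff"))
  expect_error(read_reference(file.path(td, "g.fa"), file.path(td, "dup.gff")),
               "duplicate locus tags")
  expect_error(read_reference(file.path(td, "missing.fa"),
                              file.path(td, "dup.gff")), "not found")
})

test_that("VCF parsing handles SNPs, InDels, multi-allelics and FREQ formats", {
  td <- withr::local_tempdir()
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="AF">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmut1",
    "chr\t100\t.\tG\tA\t.\tPASS\t.\tGT:FREQ:DP\t1/1:97%:120",
    "chr\t150\t.\tG\tGA\t.\tPASS\t.\tGT:FREQ:DP\t1/1:0.532:80",
    "chr\t200\t.\tC\tT,A\t.\tPASS\t.\tGT:FREQ:DP\t1/1:60%,30%:90",
    "chr\t250\t.\tGTT\tG\t.\tPASS\t.\tGT:FREQ:DP\t1/1:88%:70"
  )
  writeLines(vcf, file.path(td, "m.vcf"))
  v <- read_variants(file.path(td, "m.vcf"))
  expect_equal(nrow(v), 5L)  # multi-allelic site expands to 2 records
  expect_equal(v$strain_id[1], "mut1")
  snp <- v[v$position == 100, ]
  expect_equal(snp$kind, "SNP")
  expect_equal(snp$read_frequency, 0.97)
  expect_equal(snp$depth, 120L)
  expect_equal(v$kind[v$position == 150], "insertion")
  expect_equal(v$kind[v$position == 250], "deletion")
  multi <- v[v$position == 200, ]
  expect_equal(sort(multi$alt), c("A", "T"))
  expect_equal(sort(multi$read_frequency), c(0.30, 0.60))
  # proportion-style frequency normalised identically
  expect_equal(v$read_frequency[v$position == 150], 0.532)
})

test_that("frequency strings normalise to [0,1] and reject impossible values", {
  expect_equal(evohotspot:::normalise_frequency(c("53.2%", "0.532", "53.2")),
               c(0.532, 0.532, 0.532))
  expect_equal(evohotspot:::normalise_frequency("100%"), 1)
  expect_error(evohotspot:::normalise_frequency("150%"), "outside")
})

test_that("mutation table writes a fixed, sorted layout and round-trips", {
  td <- withr::local_tempdir()
  # empty input -> header-only file
  f0 <- file.path(td, "empty.tsv")
  write_mutation_table(data.frame(), f0)
  expect_equal(length(readLines(f0)), 1L)

  ann <- data.frame(
    strain_id = c("s2", "s1", "s1"),
    position = c(50L, 900L, 10L),
    ref = c("G", "C", "T"), alt = c("A", "T", "G"),
    locus_tag = c("g1", NA, "g2"),
    region = c("CDS", "intergenic", "CDS"),
    effect = c("nonsynonymous", "intergenic", "synonymous"),
    protein_change = c("D12G", NA, "L4L"),
    spectrum_class = c("G:C>A:T", "G:C>A:T", "A:T>C:G"),
    read_frequency = c(0.97, 0.55, 0.5),
    stringsAsFactors = FALSE
  )
  f1 <- file.path(td, "tab.tsv")
  written <- write_mutation_table(ann, f1)
  expect_equal(written$strain, c("s1", "s1", "s2"))
  expect_equal(written$position, c(10L, 900L, 50L))
  back <- read_mutation_table(f1)
  expect_equal(back, written, ignore_attr = TRUE)
})

test_that("synthetic VCF output parses back to the emitted records", {
  td <- withr::local_tempdir()
  v <- data.frame(position = c(10L, 400L), ref = c("G", "A"),
                  alt = c("A", "T"), kind = "SNP",
                  read_frequency = c(0.97, 0.5), depth = c(100L, 88L))
  f <- file.path(td, "s.vcf")
  write_variant_vcf(v, f, strain_id = "sX", chrom = "chr1")
  back <- read_variants(f)
  expect_equal(back$strain_id, c("sX", "sX"))
  expect_equal(back$position, v$position)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$read_frequency, v$read_frequency)
  expect_equal(back$depth, v$depth)
})

test_that("depth profiles load from position tables and bedGraph", {
  td <- withr::local_tempdir()
  writeLines(paste(1:10, c(rep(100, 6), rep(5, 4)), sep = "\t"),
             file.path(td, "d.tsv"))
  d <- read_depth_profile(file.path(td, "d.tsv"))
  expect_equal(length(d), 10L)
  expect_equal(as.vector(d[7]), 5)
  writeLines(c("chr\t0\t6\t100", "chr\t6\t10\t5"), file.path(td, "d.bg"))
  d2 <- read_depth_profile(file.path(td, "d.bg"))
  expect_equal(as.vector(d2), as.vector(d))
})
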