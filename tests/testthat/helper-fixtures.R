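# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# A genome hand-assembled from explicit codons, so codon-level expectations
# can be written down directly. `codons` are the sense-strand codons of a
# single CDS (start codon prepended, stop appended); the CDS is embedded in
# random sequence with `pad` bases on each side.
codon_genome <- function(codons, strand = "+", pad = 250L, seed = 42L,
                         topology = "circular") {
  set.seed(seed)
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  cds_len <- nchar(cds)
  left <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                 collapse = "")
  body <- if (strand == "+") cds else evohotspot::revcomp(cds)
  sequence <- paste0(left, body, right)
  start <- pad + 1L
  end <- pad + cds_len
  structure(
    list(id = "codonG", sequence = sequence, length = nchar(sequence),
         topology = topology,
         features = data.frame(
           locus_tag = "CG00001", gene_name = NA_character_,
           start = start, end = end, strand = strand, kind = "CDS",
           product = NA_character_, length = cds_len,
           stringsAsFactors = FALSE),
         warnings = character(0)),
    class = "reference_genome"
  )
}

# Independent whole-CDS-retranslation oracle for coding-effect calls: mutate
# the genomic base, re-extract the full CDS on its coding strand, translate
# both alleles with Biostrings (bacterial code, table 11) and diff the two
# proteins. Completely separate from the package's codon arithmetic.
oracle_coding_effect <- function(genome, position, alt) {
  f <- genome$features
  len <- genome$length
  pos_eff <- ifelse(position < f$start, position + len, position)
  i <- which(f$start <= pos_eff & f$end >= pos_eff)[1]
  stopifnot(!is.na(i))
  extract_cds <- function(sequence) {
    s <- if (f$end[i] <= len) {
      substr(sequence, f$start[i], f$end[i])
    } else {
      paste0(substr(sequence, f$start[i], len),
             substr(sequence, 1L, f$end[i] - len))
    }
    if (f$strand[i] == "-") s <- evohotspot::revcomp(s)
    s
  }
  mutated <- genome$sequence
  substr(mutated, position, position) <- alt
  prot <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       genetic.code = .table11_cache()))
  }
  p_ref <- prot(extract_cds(genome$sequence))
  p_alt <- prot(extract_cds(mutated))
  if (identical(p_ref, p_alt)) {
    return(list(effect = "synonymous"))
  }
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  aa_ref <- substr(p_ref, d, d)
  aa_alt <- substr(p_alt, d, d)
  list(effect = if (aa_alt == "*") "nonsense" else "nonsynonymous",
       protein_change = paste0(aa_ref, d, aa_alt),
       codon_index = d)
}

.table11_cache <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("11")
    code
  }
})

# Draw random SNPs inside CDSs of a genome (positions uniform over all CDS
# bases, alt uniform over the three non-reference bases).
random_cds_snps <- function(genome, n, seed = 1L) {
  set.seed(seed)
  f <- genome$features[genome$features$kind == "CDS", ]
  gene <- sample.int(nrow(f), n, replace = TRUE)
  offset <- vapply(gene, function(i) sample.int(f$length[i], 1L), integer(1))
  pos <- evohotspot:::wrap_position(f$start[gene] + offset - 1L, genome$length)
  ref <- vapply(pos, function(p) substr(genome$sequence, p, p), character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  data.frame(strain_id = "probe", position = pos, ref = ref, alt = alt,
             kind = "SNP", read_frequency = 1, stringsAsFactors = FALSE)
}

# Reverse-complement an entire genome, remapping features and positions:
# position p -> L - p + 1, intervals swap and strands flip.
revcomp_genome <- function(genome) {
  stopifnot(all(genome$features$end <= genome$length))  # unwrapped only
  L <- genome$length
  f <- genome$features
  out <- genome
  out$sequence <- evohotspot::revcomp(genome$sequence)
  f2 <- f
  f2$start <- L - f$end + 1L
  f2$end <- L - f$start + 1L
  f2$strand <- ifelse(f$strand == "+", "-", "+")
  f2 <- f2[order(f2$start), ]
  rownames(f2) <- NULL
  out$features <- f2
  out
}

# The shared large cohort genome: chromosome-scale so that per-gene background
# mutation probabilities are realistically small. Built once per test run.
cohort_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- evohotspot::make_toy_genome(3.2e6, 3000, gc_content = 0.54,
                                            seed = 20260930,
                                            gene_length_range = c(600, 1200))
    }
    cache
  }
})
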