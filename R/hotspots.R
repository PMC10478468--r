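#' Build the strains-by-genes mutation count matrix
#'
#' Aggregates filtered, annotated mutations into a matrix of counts per strain
#' and per gene. By default only nonsynonymous and nonsense CDS mutations are
#' counted -- the quantity the hotspot definition is based on; genes with zero
#' mutations are retained because they enter the enrichment denominators.
#'
#' @param annotations annotated (and typically filtered, see
#'   [filter_variants()]) mutation data frame.
#' @param genome a `reference_genome` supplying the gene universe and lengths.
#' @param effect_classes effects counted (default
#'   `c("nonsynonymous", "nonsense")`; widen to also include `"promoter"` or
#'   `"small_indel"` to count every gene-assigned mutation).
#' @param strains optional full strain set, so strains without retained
#'   mutations keep an all-zero row.
#' @return object of class `gene_mutation_matrix`: list with `counts`
#'   (integer matrix, strains x genes), `genes` (data frame `locus_tag`,
#'   `length`, `start`, `end`), `strains`, `total_mutations`.
#' @export
build_matrix <- function(annotations, genome,
                         effect_classes = c("nonsynonymous", "nonsense"),
                         strains = NULL) {
  a <- as.data.frame(annotations)
  genes <- genome$features[genome$features$kind == "CDS",
                           c("locus_tag", "length", "start", "end"),
                           drop = FALSE]
  rownames(genes) <- NULL
  stopifnot(all(genes$length > 0))
  keep <- !is.na(a$locus_tag) & a$effect %in% effect_classes &
    a$locus_tag %in% genes$locus_tag
  a <- a[keep, , drop = FALSE]
  strain_levels <- strains %||% sort(unique(a$strain_id))
  counts <- table(factor(a$strain_id, levels = strain_levels),
                  factor(a$locus_tag, levels = genes$locus_tag))
  counts <- matrix(as.integer(counts), nrow = length(strain_levels),
                   dimnames = list(strain_levels, genes$locus_tag))
  structure(
    list(counts = counts, genes = genes, strains = strain_levels,
         total_mutations = sum(counts)),
    class = "gene_mutation_matrix"
  )
}

#' @export
print.gene_mutation_matrix <- function(x, ...) {
  cat("gene_mutation_matrix: ", length(x$strains), " strains x ",
      nrow(x$genes), " genes, ", x$total_mutations, " mutations\n", sep = "")
  invisible(x)
}

#' Call hotspot genes
#'
#' A gene is a hotspot when at least `min_fraction` of the strains carry a
#' counted mutation in it (threshold inclusive; 10% of the cohort by default).
#' Hotspots are ranked by the number of mutated strains (descending), ties
#' broken by total mutation count and then locus tag; ranks are dense.
#'
#' @param matrix a `gene_mutation_matrix`.
#' @param min_fraction inclusive strain-fraction threshold (default 0.10).
#' @return data frame `locus_tag`, `n_strains_mutated`, `fraction_strains`,
#'   `n_mutations`, `rank`, `enrichment_fold` (length-based, see
#'   [length_enrichment()]).
#' @export
call_hotspots <- function(matrix, min_fraction = 0.10) {
  stopifnot(inherits(matrix, "gene_mutation_matrix"))
  n_strains <- length(matrix$strains)
  if (n_strains < 1L) stop("matrix has no strains")
  n_mut_strains <- colSums(matrix$counts > 0L)
  n_mut <- colSums(matrix$counts)
  fraction <- n_mut_strains / n_strains
  fold <- if (matrix$total_mutations > 0) {
    length_enrichment(matrix)$enrichment_fold
  } else rep(NA_real_, nrow(matrix$genes))
  df <- data.frame(
    locus_tag = matrix$genes$locus_tag,
    n_strains_mutated = as.integer(n_mut_strains),
    fraction_strains = fraction,
    n_mutations = as.integer(n_mut),
    enrichment_fold = fold,
    stringsAsFactors = FALSE
  )
  df <- df[df$fraction_strains >= min_fraction, , drop = FALSE]
  df <- df[order(-df$n_strains_mutated, -df$n_mutations, df$locus_tag), ,
           drop = FALSE]
  df$rank <- match(-df$n_strains_mutated,
                   sort(unique(-df$n_strains_mutated)))
  rownames(df) <- NULL
  df[, c("locus_tag", "n_strains_mutated", "fraction_strains", "n_mutations",
         "rank", "enrichment_fold")]
}

#' Gene-length mutation enrichment
#'
#' Compares each gene's observed mutation count with the count expected if
#' mutations fell on genes in proportion to sequence length. Under the default
#' background the expected count for gene *g* is
#' `total_mutations * length_g / sum(gene lengths)`, so expected counts sum
#' exactly to the observed total; with `background = "genome"` the denominator
#' is the full chromosome length instead (then part of the total is expected
#' to fall outside genes).
#'
#' @param matrix a `gene_mutation_matrix`.
#' @param background `"genes"` (default) or `"genome"`.
#' @param genome required for `background = "genome"`.
#' @return data frame `locus_tag`, `observed`, `expected`, `enrichment_fold`
#'   (`NA` where the expectation is zero, `0` where nothing was observed).
#' @export
length_enrichment <- function(matrix, background = c("genes", "genome"),
                              genome = NULL) {
  stopifnot(inherits(matrix, "gene_mutation_matrix"))
  background <- match.arg(background)
  total <- matrix$total_mutations
  if (total == 0L) stop("zero total mutations: enrichment undefined")
  denom <- switch(background,
    genes = sum(matrix$genes$length),
    genome = {
      if (is.null(genome)) stop("genome required for background = 'genome'")
      genome$length
    }
  )
  expected <- total * matrix$genes$length / denom
  observed <- as.integer(colSums(matrix$counts))
  fold <- ifelse(expected == 0, NA_real_, observed / expected)
  data.frame(locus_tag = matrix$genes$locus_tag, observed = observed,
             expected = expected, enrichment_fold = fold,
             stringsAsFactors = FALSE)
}

#' Co-mutation fraction of two genes
#'
#' Of the strains mutated in `gene_a`, the fraction also mutated in `gene_b`.
#'
#' @param matrix a `gene_mutation_matrix`.
#' @param gene_a,gene_b locus tags present in the matrix.
#' @return a single fraction in `[0, 1]`.
#' @export
co_mutation <- function(matrix, gene_a, gene_b) {
  stopifnot(inherits(matrix, "gene_mutation_matrix"))
  tags <- matrix$genes$locus_tag
  if (!gene_a %in% tags || !gene_b %in% tags) {
    stop("gene not in matrix: ", setdiff(c(gene_a, gene_b), tags)[1])
  }
  in_a <- matrix$counts[, gene_a] > 0L
  if (!any(in_a)) stop("no strain mutated in ", gene_a, ": fraction undefined")
  mean(matrix$counts[in_a, gene_b] > 0L)
}

#' Rank candidate SNPs by the hotspot selection criteria
#'
#' Scores every (strain, hotspot gene) pair carrying a counted mutation by the
#' two computable selection criteria: (I) *hotspot abundance* -- the number of
#' other hotspot genes mutated in the same strain should be low, because a
#' sparse mutational background makes causality more plausible; and (II)
#' *screen performance* -- high titer improvement with little biomass loss.
#' Ordering is lexicographic: lower `abundance_penalty` first, then higher
#' titer improvement, then the smaller biomass reduction; remaining ties break
#' deterministically on locus tag and strain. A third, expert-judgement
#' criterion is exposed only as a pass-through `user_flag`. Strains absent
#' from `screen_results` keep their candidates with missing performance and
#' rank last.
#'
#' @param matrix a `gene_mutation_matrix`.
#' @param hotspots hotspot table from [call_hotspots()].
#' @param screen_results data frame `strain_id`, `titer_improvement` (percent),
#'   `biomass_change` (percent; negative = reduced biomass).
#' @param annotations optional annotated mutation data frame used to attach
#'   `protein_change` per candidate.
#' @param user_flags optional data frame `strain_id`, `locus_tag`, `user_flag`.
#' @return ordered data frame of candidates.
#' @export
rank_candidates <- function(matrix, hotspots, screen_results = NULL,
                            annotations = NULL, user_flags = NULL) {
  stopifnot(inherits(matrix, "gene_mutation_matrix"))
  hs <- hotspots$locus_tag
  sub <- matrix$counts[, hs, drop = FALSE]
  hit <- which(sub > 0L, arr.ind = TRUE)
  if (length(hit) == 0L) {
    return(data.frame(strain_id = character(0), locus_tag = character(0),
                      protein_change = character(0),
                      abundance_penalty = integer(0),
                      titer_improvement = numeric(0),
                      biomass_change = numeric(0), user_flag = character(0),
                      stringsAsFactors = FALSE))
  }
  per_strain_hs <- rowSums(sub > 0L)
  cand <- data.frame(
    strain_id = rownames(sub)[hit[, 1]],
    locus_tag = colnames(sub)[hit[, 2]],
    abundance_penalty = as.integer(per_strain_hs[hit[, 1]] - 1L),
    stringsAsFactors = FALSE
  )
  cand$protein_change <- NA_character_
  if (!is.null(annotations)) {
    a <- as.data.frame(annotations)
    a <- a[!is.na(a$protein_change) & !is.na(a$locus_tag), , drop = FALSE]
    key <- paste(a$strain_id, a$locus_tag)
    first <- a[!duplicated(key), , drop = FALSE]
    m <- match(paste(cand$strain_id, cand$locus_tag),
               paste(first$strain_id, first$locus_tag))
    cand$protein_change <- first$protein_change[m]
  }
  cand$titer_improvement <- NA_real_
  cand$biomass_change <- NA_real_
  if (!is.null(screen_results)) {
    m <- match(cand$strain_id, screen_results$strain_id)
    cand$titer_improvement <- screen_results$titer_improvement[m]
    if ("biomass_change" %in% names(screen_results)) {
      cand$biomass_change <- screen_results$biomass_change[m]
    }
  }
  cand$user_flag <- NA_character_
  if (!is.null(user_flags)) {
    m <- match(paste(cand$strain_id, cand$locus_tag),
               paste(user_flags$strain_id, user_flags$locus_tag))
    cand$user_flag <- user_flags$user_flag[m]
  }
  ord <- order(is.na(cand$titer_improvement),
               cand$abundance_penalty,
               -ifelse(is.na(cand$titer_improvement), -Inf,
                       cand$titer_improvement),
               -ifelse(is.na(cand$biomass_change), -Inf, cand$biomass_change),
               cand$locus_tag, cand$strain_id)
  cand <- cand[ord, c("strain_id", "locus_tag", "protein_change",
                      "abundance_penalty", "titer_improvement",
                      "biomass_change", "user_flag")]
  rownames(cand) <- NULL
  cand
}

#' Attribute genes to metabolic pathways from an offline map
#'
#' Annotates genes with pathway tags from a two-column TSV (or data frame)
#' mapping `locus_tag` to a pathway identifier, one pair per row -- an offline
#' stand-in for a live pathway-database lookup, so the analysis stays
#' reproducible without network access. Genes absent from the map get an empty
#' tag set.
#'
#' @param genes character vector of locus tags.
#' @param pathway_map TSV path or data frame with columns `locus_tag`,
#'   `pathway`.
#' @return named list mapping each queried gene to a character vector of tags.
#' @export
attribute_pathways <- function(genes, pathway_map) {
  map <- if (is.character(pathway_map)) {
    utils::read.table(pathway_map, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  } else as.data.frame(pathway_map)
  if (ncol(map) < 2L) stop("malformed pathway map: need locus_tag and pathway columns")
  names(map)[1:2] <- c("locus_tag", "pathway")
  out <- lapply(genes, function(g) {
    as.character(map$pathway[map$locus_tag == g])
  })
  names(out) <- genes
  out
}

#' Per-gene mutation totals along the genome
#'
#' Totals per gene ordered by genomic start position -- the mutations-per-gene
#' profile along the chromosome (an origin-spanning gene sits at its unwrapped
#' start).
#'
#' @param matrix a `gene_mutation_matrix`.
#' @return data frame `locus_tag`, `start`, `total` ordered by `start`.
#' @export
positional_totals <- function(matrix) {
  stopifnot(inherits(matrix, "gene_mutation_matrix"))
  df <- data.frame(
    locus_tag = matrix$genes$locus_tag,
    start = matrix$genes$start,
    total = as.integer(colSums(matrix$counts)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$start, df$locus_tag), , drop = FALSE]
  rownames(df) <- NULL
  df
}
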