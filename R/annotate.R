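#' Map genomic positions to genes or promoter windows
#'
#' Assigns each position to one of three regions: `CDS` when it lies inside a
#' coding sequence, `promoter` when it lies within `promoter_window` bases
#' upstream of a CDS start on that CDS's strand (and inside no CDS), otherwise
#' `intergenic`. CDS membership always beats a neighbouring promoter window;
#' a position covered by two promoter windows goes to the CDS whose start is
#' nearer, ties broken towards the lexicographically lower locus tag. No
#' downstream (terminator) window is considered. Circular wrap through the
#' origin is honoured.
#'
#' @param genome a `reference_genome`.
#' @param positions integer vector of 1-based positions.
#' @param promoter_window upstream window size in bp (default 200).
#' @return data frame with columns `position`, `region`, `locus_tag` (`NA`
#'   for intergenic positions) and `feature_index` (row of `genome$features`
#'   for CDS hits).
#' @export
map_to_feature <- function(genome, positions, promoter_window = 200L) {
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > genome$length)) {
    stop("position(s) out of genome range [1, ", genome$length, "]")
  }
  n <- length(positions)
  region <- rep("intergenic", n)
  locus <- rep(NA_character_, n)
  cds_idx <- rep(NA_integer_, n)
  f <- genome$features
  if (nrow(f) == 0L || n == 0L) {
    return(data.frame(position = positions, region = region,
                      locus_tag = locus, feature_index = cds_idx,
                      stringsAsFactors = FALSE))
  }
  circular <- genome$topology == "circular"
  len <- genome$length

  ## split intervals (start in [1, len], end possibly > len when wrapping the
  ## origin) into plain ranges on [1, len], remembering the owning feature
  split_ranges <- function(start, end, owner) {
    wrap <- end > len
    rs <- c(start, rep(1L, sum(wrap)))
    re <- c(ifelse(wrap, len, end), end[wrap] - len)
    ro <- c(owner, owner[wrap])
    keep <- re >= rs
    list(start = as.integer(rs[keep]), end = as.integer(re[keep]),
         owner = ro[keep])
  }

  cds <- split_ranges(f$start, f$end, seq_len(nrow(f)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(positions, width = 1L),
    IRanges::IRanges(cds$start, cds$end)
  )
  if (length(hits)) {
    h <- data.frame(q = S4Vectors::queryHits(hits),
                    owner = cds$owner[S4Vectors::subjectHits(hits)])
    h <- h[order(h$q, f$locus_tag[h$owner]), , drop = FALSE]
    h <- h[!duplicated(h$q), , drop = FALSE]
    region[h$q] <- "CDS"
    locus[h$q] <- f$locus_tag[h$owner]
    cds_idx[h$q] <- h$owner
  }

  ## promoter windows, strand aware; clipped at genome edges when linear
  w <- as.integer(promoter_window)
  plus <- f$strand == "+"
  pstart <- ifelse(plus, f$start - w, f$end + 1L)
  pend <- ifelse(plus, f$start - 1L, f$end + w)
  if (!circular) {
    pstart <- pmax(pstart, 1L)
    pend <- pmin(pend, len)
  } else {
    neg <- pstart < 1L
    pstart[neg] <- pstart[neg] + len
    pend[neg] <- pend[neg] + len
  }
  ok <- pend >= pstart
  prom <- split_ranges(pstart[ok], pend[ok], which(ok))
  open <- which(region == "intergenic")
  if (length(open) && length(prom$start)) {
    ph <- IRanges::findOverlaps(
      IRanges::IRanges(positions[open], width = 1L),
      IRanges::IRanges(prom$start, prom$end)
    )
    if (length(ph)) {
      q <- open[S4Vectors::queryHits(ph)]
      owner <- prom$owner[S4Vectors::subjectHits(ph)]
      ## distance from position to the CDS start on the CDS's strand
      pos_q <- positions[q]
      d_plus <- (f$start[owner] - pos_q) %% len
      d_minus <- (pos_q - f$end[owner]) %% len
      dist <- ifelse(f$strand[owner] == "+", d_plus, d_minus)
      ord <- order(q, dist, f$locus_tag[owner])
      q <- q[ord]; owner <- owner[ord]
      first <- !duplicated(q)
      region[q[first]] <- "promoter"
      locus[q[first]] <- f$locus_tag[owner[first]]
    }
  }

  data.frame(position = positions, region = region, locus_tag = locus,
             feature_index = cds_idx, stringsAsFactors = FALSE)
}

#' Classify the substitution spectrum of single-base changes
#'
#' Collapses the 12 directed single-base substitutions onto the 6
#' strand-symmetric classes conventionally used for mutational spectra
#' (`A:T>G:C`, `G:C>A:T`, `A:T>C:G`, `A:T>T:A`, `G:C>T:A`, `G:C>C:G`) and
#' labels each change as transition (purine-purine or pyrimidine-pyrimidine)
#' or transversion.
#'
#' @param ref_allele,alt_allele character vectors of single bases.
#' @return data frame with columns `spectrum_class` and `ti_tv`.
#' @export
#' @examples
#' classify_spectrum("G", "A")  # G:C>A:T transition
classify_spectrum <- function(ref_allele, alt_allele) {
  ref <- toupper(ref_allele)
  alt <- toupper(alt_allele)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    stop("non-ACGT allele in classify_spectrum()")
  }
  if (any(ref == alt)) stop("ref and alt allele must differ")
  key <- paste0(ref, alt)
  class_map <- c(
    GA = "G:C>A:T", CT = "G:C>A:T",
    GT = "G:C>T:A", CA = "G:C>T:A",
    GC = "G:C>C:G", CG = "G:C>C:G",
    AG = "A:T>G:C", TC = "A:T>G:C",
    AC = "A:T>C:G", TG = "A:T>C:G",
    AT = "A:T>T:A", TA = "A:T>T:A"
  )
  ti <- key %in% c("AG", "GA", "CT", "TC")
  data.frame(
    spectrum_class = unname(class_map[key]),
    ti_tv = ifelse(ti, "transition", "transversion"),
    stringsAsFactors = FALSE
  )
}

#' All six spectrum class labels, in conventional order
#' @export
spectrum_classes <- function() {
  c("A:T>G:C", "G:C>A:T", "A:T>C:G", "A:T>T:A", "G:C>T:A", "G:C>C:G")
}

#' Annotate variants with region, coding effect and spectrum
#'
#' The workhorse of the pipeline: every variant is mapped to a region
#' ([map_to_feature()]); SNPs inside a CDS are classified at the codon level
#' with the bacterial genetic code -- `synonymous` when the residue is
#' unchanged, `nonsense` when a stop codon is introduced, `nonsynonymous`
#' otherwise, with `protein_change` in `"D735G"` notation; minus-strand CDSs
#' are handled by complementing the alleles onto the coding strand. Small
#' InDels inside a CDS are classed `small_indel` (no frameshift sub-typing).
#' SNPs additionally get their strand-symmetric spectrum class.
#'
#' A variant whose reference allele disagrees with the genome sequence at its
#' position raises an error: that always signals a coordinate-convention
#' fault, never data to be silently re-anchored.
#'
#' @param variants data frame as from [read_variants()] (columns `strain_id`,
#'   `position`, `ref`, `alt`, `kind`, `read_frequency`).
#' @param genome a `reference_genome`.
#' @param promoter_window upstream window size in bp (default 200).
#' @return the input with columns `region`, `locus_tag`, `effect`,
#'   `codon_index`, `protein_change`, `spectrum_class`, `ti_tv` appended.
#' @export
annotate_variants <- function(variants, genome, promoter_window = 200L) {
  v <- as.data.frame(variants)
  n <- nrow(v)
  mapped <- map_to_feature(genome, v$position, promoter_window)
  v$region <- mapped$region
  v$locus_tag <- mapped$locus_tag
  v$effect <- ifelse(v$region == "promoter", "promoter", "intergenic")
  v$codon_index <- NA_integer_
  v$protein_change <- NA_character_
  v$spectrum_class <- NA_character_
  v$ti_tv <- NA_character_
  if (n == 0L) return(v)

  is_snp <- v$kind == "SNP"
  if (any(is_snp)) {
    spec <- classify_spectrum(v$ref[is_snp], v$alt[is_snp])
    v$spectrum_class[is_snp] <- spec$spectrum_class
    v$ti_tv[is_snp] <- spec$ti_tv
  }

  in_cds <- !is.na(mapped$feature_index)
  v$effect[in_cds & !is_snp] <- "small_indel"

  ## reference-allele agreement is checked for every SNP, wherever it maps
  if (any(is_snp)) {
    genome_base <- subseq_circular(genome$sequence, v$position[is_snp],
                                   v$position[is_snp])
    bad <- genome_base != toupper(v$ref[is_snp])
    if (any(bad)) {
      i <- which(is_snp)[which(bad)[1]]
      stop("reference allele mismatch at position ", v$position[i], ": VCF '",
           v$ref[i], "' vs genome '", genome_base[which(bad)[1]],
           "' (coordinate-convention fault?)")
    }
  }

  cs <- which(in_cds & is_snp)
  if (length(cs)) {
    fi <- mapped$feature_index[cs]
    f <- genome$features[fi, , drop = FALSE]
    len <- genome$length
    pos <- v$position[cs]
    ## unwrap positions that fall in the wrapped tail of an origin-spanning CDS
    pos_eff <- ifelse(pos < f$start, pos + len, pos)
    plus <- f$strand == "+"
    offset <- ifelse(plus, pos_eff - f$start, f$end - pos_eff)
    ci <- offset %/% 3L + 1L
    slot <- offset %% 3L + 1L
    codon <- character(length(cs))
    if (any(plus)) {
      cstart <- f$start[plus] + 3L * (ci[plus] - 1L)
      codon[plus] <- subseq_circular(genome$sequence, cstart, cstart + 2L,
                                     genome$topology == "circular")
    }
    if (any(!plus)) {
      cend <- f$end[!plus] - 3L * (ci[!plus] - 1L)
      codon[!plus] <- revcomp(subseq_circular(genome$sequence, cend - 2L, cend,
                                              genome$topology == "circular"))
    }
    sub_base <- ifelse(plus, toupper(v$alt[cs]), complement_base(v$alt[cs]))
    alt_codon <- codon
    substr(alt_codon, slot, slot) <- sub_base
    aa_ref <- translate_codons(codon)
    aa_alt <- translate_codons(alt_codon)
    effect <- ifelse(aa_ref == aa_alt, "synonymous",
                     ifelse(aa_alt == "*", "nonsense", "nonsynonymous"))
    v$effect[cs] <- effect
    v$codon_index[cs] <- ci
    v$protein_change[cs] <- paste0(aa_ref, ci, aa_alt)
  }
  v
}

#' Classify the coding effect of a single variant
#'
#' Single-variant convenience wrapper around [annotate_variants()]; the
#' variant must map inside a CDS.
#'
#' @param variant one-row data frame (or list) with `position`, `ref`, `alt`,
#'   `kind` and optionally `strain_id`, `read_frequency`.
#' @param genome a `reference_genome`.
#' @param promoter_window passed through.
#' @return one-row annotated data frame.
#' @export
classify_coding_effect <- function(variant, genome, promoter_window = 200L) {
  v <- as.data.frame(as.list(variant), stringsAsFactors = FALSE)
  if (!"strain_id" %in% names(v)) v$strain_id <- "s"
  if (!"kind" %in% names(v)) {
    v$kind <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "SNP",
                     ifelse(nchar(v$alt) > nchar(v$ref), "insertion", "deletion"))
  }
  if (!"read_frequency" %in% names(v)) v$read_frequency <- NA_real_
  out <- annotate_variants(v, genome, promoter_window)
  if (out$region != "CDS") {
    stop("variant at position ", out$position, " does not map to a CDS (",
         out$region, ")")
  }
  out
}

#' Filter annotated variants by read frequency and synonymy
#'
#' Applies the two comparative-analysis filters: variants with an
#' alternate-allele read frequency below `min_read_frequency` are discarded
#' (the boundary itself is kept: a frequency of exactly 0.50 passes the
#' default filter), and synonymous substitutions are dropped. Input order is
#' preserved; the counts removed by each rule are attached as the
#' `"filter_counts"` attribute.
#'
#' @param variants annotated data frame (needs `read_frequency`; `effect` is
#'   needed only when `drop_synonymous` is `TRUE`).
#' @param min_read_frequency inclusive lower bound (default 0.50).
#' @param drop_synonymous drop `effect == "synonymous"` rows (default `TRUE`).
#' @return filtered data frame.
#' @export
filter_variants <- function(variants, min_read_frequency = 0.50,
                            drop_synonymous = TRUE) {
  v <- as.data.frame(variants)
  n0 <- nrow(v)
  keep_freq <- is.na(v$read_frequency) | v$read_frequency >= min_read_frequency
  n_freq <- sum(!keep_freq)
  v <- v[keep_freq, , drop = FALSE]
  n_syn <- 0L
  if (drop_synonymous && "effect" %in% names(v)) {
    keep_syn <- is.na(v$effect) | v$effect != "synonymous"
    n_syn <- sum(!keep_syn)
    v <- v[keep_syn, , drop = FALSE]
  }
  rownames(v) <- NULL
  attr(v, "filter_counts") <- c(input = n0, low_frequency = n_freq,
                                synonymous = n_syn, retained = nrow(v))
  v
}

#' Per-strain mutation load
#'
#' Counts mutations per strain and summarises the cohort (mean, min, max) --
#' the per-genome mutation-load statistic of a mutagenesis campaign.
#'
#' @param variants data frame with a `strain_id` column (annotated or not).
#' @param strains optional character vector fixing the full strain set, so
#'   strains with zero retained mutations are counted as zeros.
#' @return list with `per_strain` (data frame `strain_id`, `n_mutations`),
#'   `n_strains`, `mean`, `min`, `max`.
#' @export
mutation_load <- function(variants, strains = NULL) {
  v <- as.data.frame(variants)
  lv <- strains %||% sort(unique(v$strain_id))
  counts <- table(factor(v$strain_id, levels = lv))
  per_strain <- data.frame(strain_id = lv, n_mutations = as.integer(counts),
                           stringsAsFactors = FALSE)
  if (length(lv) == 0L) {
    return(list(per_strain = per_strain, n_strains = 0L,
                mean = NA_real_, min = NA_integer_, max = NA_integer_))
  }
  list(per_strain = per_strain, n_strains = length(lv),
       mean = mean(per_strain$n_mutations),
       min = min(per_strain$n_mutations),
       max = max(per_strain$n_mutations))
}

#' Summarise the substitution spectrum
#'
#' Tallies the six strand-symmetric spectrum classes over all SNPs.
#'
#' @param annotations annotated data frame with a `spectrum_class` column.
#' @return data frame `class`, `count`, `fraction` (fractions over all SNPs).
#' @export
spectrum_summary <- function(annotations) {
  cls <- annotations$spectrum_class[!is.na(annotations$spectrum_class)]
  tab <- table(factor(cls, levels = spectrum_classes()))
  data.frame(class = spectrum_classes(), count = as.integer(tab),
             fraction = if (length(cls)) as.numeric(tab) / length(cls) else
               rep(NA_real_, 6L),
             stringsAsFactors = FALSE)
}

#' Flag copy-number anomalies from a read-depth profile
#'
#' Scans a per-base depth profile for maximal runs of at least `min_window`
#' consecutive bases whose depth is at most `low_fold` times the genome-median
#' depth (putative large deletion) or at least `high_fold` times the median
#' (putative duplication) -- the coverage signal large structural events leave
#' in short-read data.
#'
#' @param profile numeric vector of per-base depths (as from
#'   [read_depth_profile()]).
#' @param low_fold,high_fold fold-change thresholds relative to the median.
#' @param min_window minimum run length in bp.
#' @param strain_id label copied into the output.
#' @return data frame `strain_id`, `start`, `end`, `kind`
#'   (`putative_deletion`/`putative_duplication`), `mean_fold`.
#' @export
detect_coverage_anomalies <- function(profile, low_fold = 0.25,
                                      high_fold = 1.75, min_window = 500L,
                                      strain_id = NULL) {
  d <- as.numeric(profile)
  if (length(d) == 0L) stop("empty depth profile")
  med <- stats::median(d)
  if (med == 0) stop("all-zero (or zero-median) depth profile: missing data?")
  state <- ifelse(d <= low_fold * med, -1L, ifelse(d >= high_fold * med, 1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_window
  sid <- strain_id %||% attr(profile, "strain_id") %||% NA_character_
  if (!any(keep)) {
    return(data.frame(strain_id = character(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      mean_fold = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    strain_id = sid,
    start = starts[keep],
    end = ends[keep],
    kind = ifelse(r$values[keep] < 0L, "putative_deletion",
                  "putative_duplication"),
    mean_fold = mapply(function(s, e) mean(d[s:e]) / med,
                       starts[keep], ends[keep]),
    stringsAsFactors = FALSE
  )
}
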