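#' Read a reference genome with gene annotation
#'
#' Loads a single-chromosome reference from FASTA together with its gene
#' features from a GFF3 or GenBank flat file, and validates the two against
#' each other. The result is the coordinate authority for all downstream
#' variant mapping; all coordinates are 1-based inclusive, the convention of
#' GFF3, GenBank and VCF alike.
#'
#' Bacterial chromosomes are circular by default; a feature annotated across
#' the origin (GenBank `join(a..L,1..b)`) is unwrapped internally so that its
#' `end` exceeds the chromosome length.
#'
#' @param fasta_source path to a FASTA file with exactly one record, or `NULL`
#'   to take the sequence from a GenBank file's ORIGIN block.
#' @param annotation_source path to a GFF3 (`.gff`, `.gff3`) or GenBank flat
#'   file (`.gb`, `.gbk`, `.gbff`); format is sniffed when the extension is
#'   ambiguous.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param check_id require the annotation's sequence id to match the FASTA id.
#' @return an object of class `reference_genome`: a list with elements `id`,
#'   `sequence`, `length`, `topology`, `features` (data frame with columns
#'   `locus_tag`, `gene_name`, `start`, `end`, `strand`, `kind`, `product`,
#'   `length`, sorted by `start`) and `warnings` (character; currently records
#'   CDS features whose length is not divisible by 3).
#' @export
read_reference <- function(fasta_source, annotation_source,
                           topology = c("circular", "linear"),
                           check_id = TRUE) {
  topology <- match.arg(topology)

  gb <- NULL
  fmt <- sniff_annotation_format(annotation_source)
  if (fmt == "genbank") gb <- parse_genbank(annotation_source)

  if (!is.null(fasta_source)) {
    if (!file.exists(fasta_source)) stop("FASTA file not found: ", fasta_source)
    dss <- Biostrings::readDNAStringSet(fasta_source)
    if (length(dss) != 1L) {
      stop("expected exactly one FASTA record, found ", length(dss))
    }
    id <- strsplit(names(dss)[1], "\\s+")[[1]][1]
    sequence <- toupper(as.character(dss[[1]]))
  } else if (!is.null(gb) && nzchar(gb$sequence)) {
    id <- gb$id
    sequence <- gb$sequence
  } else {
    stop("no sequence source: supply a FASTA file or a GenBank file with ORIGIN")
  }

  if (fmt == "gff3") {
    feats <- parse_gff3_features(annotation_source)
    ann_id <- attr(feats, "seqid")
  } else {
    feats <- gb$features
    ann_id <- gb$id
  }

  if (check_id && !is.null(ann_id) && length(ann_id) == 1L &&
      !is.na(ann_id) && nzchar(ann_id) && !identical(ann_id, id)) {
    stop("sequence/annotation id mismatch: FASTA '", id, "' vs annotation '",
         ann_id, "'")
  }

  genome_len <- nchar(sequence)
  warnings <- character(0)

  if (nrow(feats) > 0) {
    if (anyDuplicated(feats$locus_tag)) {
      stop("duplicate locus tags in annotation: ",
           paste(unique(feats$locus_tag[duplicated(feats$locus_tag)]),
                 collapse = ", "))
    }
    max_end <- if (topology == "circular") 2L * genome_len else genome_len
    bad <- feats$start < 1L | feats$end > max_end | feats$start > genome_len
    if (any(bad)) {
      stop("feature(s) outside sequence bounds: ",
           paste(feats$locus_tag[bad], collapse = ", "))
    }
    feats$length <- feats$end - feats$start + 1L
    not3 <- feats$kind == "CDS" & feats$length %% 3L != 0L
    if (any(not3)) {
      msg <- paste0("CDS length not divisible by 3: ",
                    paste(feats$locus_tag[not3], collapse = ", "))
      warnings <- c(warnings, msg)
      warning(msg, call. = FALSE)
    }
    feats <- feats[order(feats$start, feats$locus_tag), , drop = FALSE]
    rownames(feats) <- NULL
  }

  structure(
    list(id = id, sequence = sequence, length = genome_len,
         topology = topology, features = feats, warnings = warnings),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome '", x$id, "': ", x$length, " bp (", x$topology, "), ",
      nrow(x$features), " features (",
      sum(x$features$kind == "CDS"), " CDS)\n", sep = "")
  invisible(x)
}

empty_features <- function() {
  data.frame(locus_tag = character(0), gene_name = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             kind = character(0), product = character(0), length = integer(0),
             stringsAsFactors = FALSE)
}

sniff_annotation_format <- function(path) {
  if (is.null(path)) stop("annotation_source is required")
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext %in% c("gb", "gbk", "gbff", "genbank")) return("genbank")
  first <- readLines(path, n = 1L)
  if (grepl("^LOCUS", first)) "genbank" else "gff3"
}

## GFF3 via rtracklayer; keeps CDS features and extracts locus tags.
parse_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  cds <- md[md$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    out <- empty_features()
    attr(out, "seqid") <- unique(as.character(md$seqnames))[1]
    return(out)
  }
  pick <- function(col) {
    if (col %in% names(cds)) as.character(cds[[col]]) else rep(NA_character_, nrow(cds))
  }
  locus <- pick("locus_tag")
  fallback <- pick("ID")
  locus <- ifelse(is.na(locus) | !nzchar(locus), fallback, locus)
  if (anyNA(locus)) stop("GFF3 CDS feature without locus_tag or ID")
  out <- data.frame(
    locus_tag = locus,
    gene_name = pick("gene"),
    start = as.integer(cds$start),
    end = as.integer(cds$end),
    strand = as.character(cds$strand),
    kind = "CDS",
    product = pick("product"),
    length = as.integer(cds$end) - as.integer(cds$start) + 1L,
    stringsAsFactors = FALSE
  )
  if (any(!out$strand %in% c("+", "-"))) {
    stop("GFF3 CDS feature without explicit strand")
  }
  attr(out, "seqid") <- unique(as.character(cds$seqnames))[1]
  out
}

## Minimal GenBank flat-file parser: LOCUS id/length, CDS features with
## locus_tag/gene/product qualifiers, and the ORIGIN sequence block. Location
## forms handled: "a..b", "complement(a..b)", and origin-wrapping
## "join(a..L,1..b)" (optionally inside complement()); partial-end markers
## (< >) are stripped. Anything fancier is rejected loudly.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line) == 0L) stop("not a GenBank flat file: ", path)
  toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
  id <- toks[2]
  seq_len <- suppressWarnings(as.integer(toks[3]))

  feat_start <- grep("^FEATURES", lines)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- feat_end[feat_end > feat_start[1]][1]
  fl <- if (length(feat_start)) lines[(feat_start[1] + 1L):(feat_end - 1L)] else character(0)

  ## split the feature table into records: a new record starts at column 6
  is_key <- grepl("^ {5}\\S", fl)
  rec_id <- cumsum(is_key)
  feats <- empty_features()
  if (any(is_key)) {
    recs <- split(fl, rec_id)
    rows <- lapply(recs, function(r) {
      key <- sub("^ {5}(\\S+).*$", "\\1", r[1])
      loc <- sub("^ {5}\\S+\\s+", "", r[1])
      ## location may continue on following lines until the first qualifier
      qual_at <- grep("^\\s+/", r)
      loc_extra <- if (length(qual_at) && qual_at[1] > 2) r[2:(qual_at[1] - 1)] else character(0)
      if (length(qual_at) == 0 && length(r) > 1) loc_extra <- r[-1]
      loc <- gsub("\\s", "", paste0(loc, paste(loc_extra, collapse = "")))
      qual <- function(name) {
        m <- grep(paste0("^\\s+/", name, "="), r, value = TRUE)
        if (length(m) == 0) return(NA_character_)
        gsub('^[^=]+="?|"$', "", m[1])
      }
      list(key = key, loc = loc, locus_tag = qual("locus_tag"),
           gene = qual("gene"), product = qual("product"))
    })
    rows <- Filter(function(r) r$key == "CDS", rows)
    if (length(rows)) {
      parsed <- lapply(rows, function(r) {
        loc <- gsub("[<>]", "", r$loc)
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        if (grepl("^join\\(", loc)) {
          parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
          ends <- do.call(rbind, lapply(parts, function(p) {
            as.integer(strsplit(p, "\\.\\.")[[1]])
          }))
          if (nrow(ends) == 2L && ends[1, 2] == seq_len && ends[2, 1] == 1L) {
            ## wraps the origin: unwrap past the end
            start <- ends[1, 1]; end <- seq_len + ends[2, 2]
          } else {
            stop("unsupported GenBank join() location: ", r$loc)
          }
        } else {
          se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
          if (length(se) != 2L || anyNA(se)) {
            stop("unsupported GenBank location: ", r$loc)
          }
          start <- se[1]; end <- se[2]
        }
        data.frame(
          locus_tag = r$locus_tag %||% NA_character_,
          gene_name = r$gene, start = start, end = end, strand = strand,
          kind = "CDS", product = r$product, length = end - start + 1L,
          stringsAsFactors = FALSE
        )
      })
      feats <- do.call(rbind, parsed)
      if (anyNA(feats$locus_tag)) stop("GenBank CDS feature without /locus_tag")
      rownames(feats) <- NULL
    }
  }

  sequence <- ""
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at)) {
    end_at <- grep("^//", lines)
    end_at <- end_at[end_at > origin_at[1]][1]
    seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  list(id = id, length = seq_len, sequence = sequence, features = feats)
}

#' Read per-strain variant calls from a VCF file
#'
#' Parses a VCF 4.x file into one record per ALT allele. The alternate-allele
#' read frequency is taken from a configurable FORMAT or INFO key (VarScan
#' writes a FORMAT field `FREQ` holding percent strings such as `"53.2%"`);
#' percent strings and proportions are both accepted and normalised to
#' `[0, 1]`.
#'
#' @param vcf_source path to a VCF file (plain or gzipped).
#' @param strain_id strain identifier; defaults to the single sample name in
#'   the VCF, or the file base name when the VCF carries no sample.
#' @param freq_key name of the FORMAT or INFO field holding the
#'   alternate-allele frequency (default `"FREQ"`; `"AF"` is also tried).
#' @param genome optional `reference_genome`; positions are validated against
#'   its length when supplied.
#' @return data frame with columns `strain_id`, `position` (1-based), `ref`,
#'   `alt`, `kind` (`SNP`/`insertion`/`deletion`), `read_frequency`, `depth`.
#' @export
read_variants <- function(vcf_source, strain_id = NULL, freq_key = "FREQ",
                          genome = NULL) {
  if (!file.exists(vcf_source)) stop("VCF file not found: ", vcf_source)
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(data.frame(strain_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), read_frequency = numeric(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }

  samples <- colnames(v@gt)[-1]
  if (is.null(strain_id)) {
    strain_id <- if (length(samples) == 1L) samples else {
      sub("\\.vcf(\\.gz)?$", "", basename(vcf_source))
    }
  }

  get_field <- function(key) {
    val <- rep(NA_character_, n)
    if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
      gt <- tryCatch(vcfR::extract.gt(v, element = key, as.numeric = FALSE),
                     error = function(e) NULL)
      if (!is.null(gt)) val <- as.character(gt[, 1])
    }
    if (all(is.na(val))) {
      info <- vcfR::extract.info(v, element = key)
      if (!all(is.na(info))) val <- as.character(info)
    }
    val
  }

  freq_raw <- get_field(freq_key)
  if (all(is.na(freq_raw)) && freq_key == "FREQ") freq_raw <- get_field("AF")
  depth_raw <- suppressWarnings(as.integer(get_field("DP")))

  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt_lists <- strsplit(toupper(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_lists)
  if (any(n_alt == 0L) || anyNA(pos)) stop("malformed VCF line(s) in ", vcf_source)

  freq_lists <- strsplit(ifelse(is.na(freq_raw), "", freq_raw), ",", fixed = TRUE)
  idx <- rep(seq_len(n), n_alt)
  alt <- unlist(alt_lists, use.names = FALSE)
  within_idx <- sequence(n_alt)
  freq_chr <- mapply(function(row, k) {
    fl <- freq_lists[[row]]
    if (length(fl) == 0L) NA_character_
    else if (length(fl) >= k) fl[k] else fl[1]
  }, idx, within_idx)

  read_frequency <- normalise_frequency(freq_chr)
  out <- data.frame(
    strain_id = strain_id,
    position = pos[idx],
    ref = ref[idx],
    alt = alt,
    kind = ifelse(nchar(ref[idx]) == 1L & nchar(alt) == 1L, "SNP",
                  ifelse(nchar(alt) > nchar(ref[idx]), "insertion", "deletion")),
    read_frequency = read_frequency,
    depth = depth_raw[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    bad <- out$position < 1L | out$position > genome$length
    if (any(bad)) {
      stop(sum(bad), " variant position(s) outside genome [1, ",
           genome$length, "]")
    }
  }
  out
}

## "53.2%" -> 0.532; "0.532" -> 0.532; "53.2" -> 0.532 (values > 1 are read as
## percentages). Values outside [0,1] after normalisation are an error.
normalise_frequency <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  num <- suppressWarnings(as.numeric(sub("%$", "", x)))
  num[pct] <- num[pct] / 100
  over <- !is.na(num) & !pct & num > 1
  num[over] <- num[over] / 100
  if (any(!is.na(num) & (num < 0 | num > 1))) {
    stop("read frequency outside [0, 1] after normalisation")
  }
  num
}

.MUTATION_TABLE_COLS <- c("strain", "position", "ref", "alt", "locus_tag",
                          "region", "effect", "protein_change",
                          "spectrum_class", "read_frequency")

#' Write an annotated mutation table
#'
#' Serialises annotated mutations as a TSV with a fixed column order
#' (`strain`, `position`, `ref`, `alt`, `locus_tag`, `region`, `effect`,
#' `protein_change`, `spectrum_class`, `read_frequency`) and a bit-stable row
#' order (strain, then position).
#'
#' @param annotations data frame as returned by [annotate_variants()].
#' @param sink output file path or connection.
#' @return invisibly, the data frame actually written.
#' @seealso [read_mutation_table()]
#' @export
write_mutation_table <- function(annotations, sink) {
  df <- as.data.frame(annotations)
  if (nrow(df) == 0L) {
    out <- data.frame(matrix(ncol = length(.MUTATION_TABLE_COLS), nrow = 0))
    names(out) <- .MUTATION_TABLE_COLS
  } else {
    if ("strain_id" %in% names(df) && !"strain" %in% names(df)) {
      df$strain <- df$strain_id
    }
    missing <- setdiff(.MUTATION_TABLE_COLS, names(df))
    for (m in missing) df[[m]] <- NA
    out <- df[order(df$strain, df$position), .MUTATION_TABLE_COLS, drop = FALSE]
  }
  utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(out)
}

#' Read back a mutation table written by [write_mutation_table()]
#'
#' @param source TSV file path.
#' @return data frame with the fixed mutation-table columns.
#' @export
read_mutation_table <- function(source) {
  utils::read.table(source, header = TRUE, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(strain = "character", ref = "character",
                                   alt = "character"))
}

#' Read a per-base read-depth profile
#'
#' Accepts either a two-column TSV (`position`, `depth`) or a four-column
#' bedGraph (`chrom`, `start` 0-based, `end`, `depth`). The profile is
#' expanded to a dense integer vector over `[1, max position]` (or the genome
#' length when a genome is supplied); uncovered positions get depth 0.
#'
#' @param source file path.
#' @param strain_id strain label attached to the profile.
#' @param genome optional `reference_genome` fixing the profile length.
#' @return integer vector of per-base depths with attribute `strain_id`.
#' @export
read_depth_profile <- function(source, strain_id = NULL, genome = NULL) {
  tab <- utils::read.table(source, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (is.character(tab[[1]]) && ncol(tab) >= 4L) {
    start <- as.integer(tab[[2]]) + 1L  # bedGraph is 0-based half-open
    end <- as.integer(tab[[3]])
    depth_val <- as.numeric(tab[[4]])
  } else {
    start <- end <- as.integer(tab[[1]])
    depth_val <- as.numeric(tab[[2]])
  }
  len <- if (!is.null(genome)) genome$length else max(end)
  if (any(end > len)) stop("depth profile extends beyond genome length")
  depth <- integer(len)
  for (i in seq_along(start)) depth[start[i]:end[i]] <- depth_val[i]
  attr(depth, "strain_id") <- strain_id %||% basename(source)
  depth
}

#' Write a reference genome as FASTA and GFF3
#'
#' @param genome a `reference_genome`.
#' @param fasta_path,gff_path output paths (either may be `NULL` to skip).
#' @param line_width FASTA wrap width.
#' @return invisibly, the genome.
#' @export
write_reference <- function(genome, fasta_path = NULL, gff_path = NULL,
                            line_width = 70L) {
  if (!is.null(fasta_path)) {
    seq <- genome$sequence
    starts <- seq(1L, nchar(seq), by = line_width)
    lines <- substring(seq, starts, pmin(starts + line_width - 1L, nchar(seq)))
    writeLines(c(paste0(">", genome$id), lines), fasta_path)
  }
  if (!is.null(gff_path)) {
    f <- genome$features
    header <- c("##gff-version 3",
                paste("##sequence-region", genome$id, 1, genome$length))
    rows <- if (nrow(f) == 0L) character(0) else {
      attrs <- paste0("ID=", f$locus_tag, ";locus_tag=", f$locus_tag,
                      ifelse(is.na(f$gene_name), "",
                             paste0(";gene=", f$gene_name)),
                      ifelse(is.na(f$product), "",
                             paste0(";product=", f$product)))
      paste(genome$id, "evohotspot", f$kind, f$start, f$end, ".", f$strand,
            "0", attrs, sep = "\t")
    }
    writeLines(c(header, rows), gff_path)
  }
  invisible(genome)
}

#' Write variant records as a minimal VCF 4.2 file
#'
#' Emits the dialect produced by VarScan-style callers: one sample column with
#' FORMAT fields `FREQ` (percent string) and `DP`.
#'
#' @param variants data frame with columns `position`, `ref`, `alt`,
#'   `read_frequency` and optionally `depth`.
#' @param path output file path.
#' @param strain_id sample name for the single sample column.
#' @param chrom chromosome name written in the CHROM column.
#' @return invisibly, `path`.
#' @export
write_variant_vcf <- function(variants, path, strain_id = "strain",
                              chrom = "chr") {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="Variant allele frequency">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", strain_id, sep = "\t")
  )
  v <- variants[order(variants$position), , drop = FALSE]
  depth <- if ("depth" %in% names(v) && !all(is.na(v$depth))) v$depth else
    rep(100L, nrow(v))
  rows <- if (nrow(v) == 0L) character(0) else {
    freq <- sprintf("%.2f%%", 100 * v$read_frequency)
    paste(chrom, v$position, ".", v$ref, v$alt, ".", "PASS", ".",
          "GT:FREQ:DP", paste("1/1", freq, depth, sep = ":"), sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
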