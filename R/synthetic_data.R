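#' Generate a toy annotated genome
#'
#' Builds a random chromosome with non-overlapping protein-coding genes:
#' every CDS has a valid start codon, a stop codon, internal codons free of
#' in-frame stops, a length divisible by 3, and a random strand. Intergenic
#' space is random sequence at the requested GC content. The generator is a
#' pure function of its arguments and seed -- two runs with the same seed give
#' byte-identical genomes (and files).
#'
#' @param length chromosome length in bp (must allow `n_genes` genes of at
#'   least 300 bp).
#' @param n_genes number of CDS features (0 gives a gene-free genome).
#' @param gc_content GC fraction of the intergenic background (default 0.54,
#'   a typical high-GC actinobacterial value).
#' @param seed RNG seed.
#' @param gene_length_range min/max CDS length in bp (rounded to codons).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param out_fasta,out_gff optional output paths (see [write_reference()]).
#' @param id sequence identifier.
#' @return a `reference_genome`.
#' @export
make_toy_genome <- function(length, n_genes, gc_content = 0.54, seed = 1,
                            gene_length_range = c(300, 1500),
                            topology = c("circular", "linear"),
                            out_fasta = NULL, out_gff = NULL,
                            id = "toygenome") {
  topology <- match.arg(topology)
  length <- as.integer(length)
  n_genes <- as.integer(n_genes)
  if (n_genes > 0 && length < n_genes * 300L) {
    stop("infeasible packing: need at least ", n_genes * 300L, " bp for ",
         n_genes, " genes")
  }
  set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)

  feats <- empty_features()
  if (n_genes > 0) {
    slot <- length %/% n_genes
    max_len <- min(gene_length_range[2], 3L * ((slot - 30L) %/% 3L))
    min_len <- 3L * (gene_length_range[1] %/% 3L)
    if (max_len < min_len) stop("infeasible packing: genes do not fit")
    codon_choices <- seq.int(min_len %/% 3L, max_len %/% 3L)
    lens <- 3L * codon_choices[sample.int(length(codon_choices), n_genes,
                                          replace = TRUE)]
    ## place each gene at a random offset inside its own slot
    offset <- vapply(seq_len(n_genes), function(i) {
      sample.int(slot - lens[i] - 1L, 1L)
    }, integer(1))
    starts <- (seq_len(n_genes) - 1L) * slot + offset
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    n_codons <- lens %/% 3L
    internal <- sample(.SENSE_CODONS, sum(n_codons - 2L), replace = TRUE)
    stops <- sample(.STOP_CODONS, n_genes, replace = TRUE)
    at <- cumsum(c(0L, utils::head(n_codons - 2L, -1L)))
    for (i in seq_len(n_genes)) {
      cds <- paste0("ATG",
                    paste(internal[(at[i] + 1L):(at[i] + n_codons[i] - 2L)],
                          collapse = ""),
                    stops[i])
      if (strands[i] == "-") cds <- revcomp(cds)
      bases[starts[i]:(starts[i] + lens[i] - 1L)] <-
        strsplit(cds, "", fixed = TRUE)[[1]]
    }
    feats <- data.frame(
      locus_tag = sprintf("TG%05d", seq_len(n_genes)),
      gene_name = NA_character_,
      start = as.integer(starts),
      end = as.integer(starts + lens - 1L),
      strand = strands,
      kind = "CDS",
      product = "hypothetical protein",
      length = as.integer(lens),
      stringsAsFactors = FALSE
    )
  }

  genome <- structure(
    list(id = id, sequence = paste(bases, collapse = ""), length = length,
         topology = topology, features = feats, warnings = character(0)),
    class = "reference_genome"
  )
  write_reference(genome, out_fasta, out_gff)
  genome
}

#' Mutagenesis campaign configuration
#'
#' Study conditions of the simulated chemical-mutagenesis cohort. The defaults
#' emulate an alkylating-mutagen (MNNG-type) campaign: about 180 mutations per
#' genome with a wide, overdispersed spread clamped to 47-470, a strong
#' G:C>A:T transition bias (default share 0.9), and no InDels.
#'
#' @param n_strains number of independently mutagenized strains.
#' @param mean_load mean mutations per genome (negative-binomial mean).
#' @param load_range inclusive clamp on the per-strain mutation count.
#' @param dispersion negative-binomial size parameter (smaller = wider).
#' @param gc_to_at_fraction probability that a SNP is drawn as a G:C>A:T
#'   transition.
#' @param planted_hotspots `NULL` or data frame with columns `locus_tag`,
#'   `prob` (per-strain probability of an extra planted mutation) and
#'   optionally `force_nonsyn` (default `TRUE`).
#' @param decoy_fraction fraction of mutations emitted with read frequency
#'   below 0.5 (mimicking unfixed subpopulations the frequency filter should
#'   discard).
#' @param seed RNG seed.
#' @return list of class `mutagenesis_config`.
#' @export
mutagenesis_config <- function(n_strains = 100, mean_load = 180,
                               load_range = c(47, 470), dispersion = 5,
                               gc_to_at_fraction = 0.9,
                               planted_hotspots = NULL,
                               decoy_fraction = 0.1, seed = 1) {
  stopifnot(load_range[1] <= mean_load, mean_load <= load_range[2],
            gc_to_at_fraction >= 0, gc_to_at_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction < 1)
  if (!is.null(planted_hotspots)) {
    planted_hotspots <- as.data.frame(planted_hotspots)
    stopifnot(all(c("locus_tag", "prob") %in% names(planted_hotspots)),
              all(planted_hotspots$prob >= 0 & planted_hotspots$prob <= 1))
    if (!"force_nonsyn" %in% names(planted_hotspots)) {
      planted_hotspots$force_nonsyn <- TRUE
    }
  }
  structure(
    list(n_strains = n_strains, mean_load = mean_load,
         load_range = load_range, dispersion = dispersion,
         gc_to_at_fraction = gc_to_at_fraction,
         planted_hotspots = planted_hotspots,
         decoy_fraction = decoy_fraction, seed = seed),
    class = "mutagenesis_config"
  )
}

## Propose a nonsynonymous SNP inside a given CDS; returns a one-row list or
## NULL when no proposal succeeds (vanishingly rare for real CDSs).
plant_nonsyn_snp <- function(genome, feature, max_tries = 50L) {
  len <- genome$length
  for (i in seq_len(max_tries)) {
    pos <- feature$start + sample.int(feature$length, 1L) - 1L
    pos_w <- wrap_position(pos, len)
    ref <- subseq_circular(genome$sequence, pos_w, pos_w)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    cand <- data.frame(strain_id = "probe", position = pos_w, ref = ref,
                       alt = alt, kind = "SNP", read_frequency = 1,
                       stringsAsFactors = FALSE)
    ann <- annotate_variants(cand, genome)
    if (identical(ann$locus_tag, feature$locus_tag) &&
        ann$effect %in% c("nonsynonymous", "nonsense")) {
      return(list(position = pos_w, ref = ref, alt = alt))
    }
  }
  NULL
}

#' Simulate a mutagenized strain cohort
#'
#' Draws, for every strain, a mutation count from a negative binomial with the
#' configured mean (clamped to the configured range), places substitutions
#' uniformly along the chromosome, draws each substitution as a G:C>A:T
#' transition with probability `gc_to_at_fraction` (otherwise uniformly over
#' the remaining substitution classes available at the drawn reference base),
#' assigns read frequencies of at least 0.5 to true mutations plus a
#' configurable fraction of sub-0.5 decoys, and finally plants, per configured
#' hotspot gene, an extra nonsynonymous SNP with the given per-strain
#' probability. The returned truth table lists every emitted record with its
#' `planted` flag; optionally one VCF per strain is written.
#'
#' @param genome a `reference_genome` (typically from [make_toy_genome()]).
#' @param config a [mutagenesis_config()].
#' @param out_dir optional directory for per-strain VCF files.
#' @return list with `variants` (data frame: `strain_id`, `position`, `ref`,
#'   `alt`, `kind`, `read_frequency`, `depth`, `planted`, `planted_locus`),
#'   `loads` (per-strain drawn counts), `config`.
#' @export
simulate_mutagenesis <- function(genome, config, out_dir = NULL) {
  stopifnot(inherits(config, "mutagenesis_config"))
  set.seed(config$seed)
  n <- config$n_strains
  strains <- sprintf("S%03d", seq_len(n))

  if (!is.null(config$planted_hotspots)) {
    missing <- setdiff(config$planted_hotspots$locus_tag,
                       genome$features$locus_tag)
    if (length(missing)) {
      stop("planted hotspot locus_tag absent from genome: ",
           paste(missing, collapse = ", "))
    }
  }

  loads <- stats::rnbinom(n, mu = config$mean_load, size = config$dispersion)
  loads <- pmin(pmax(loads, config$load_range[1]), config$load_range[2])

  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  gc_pos <- which(chars %in% c("G", "C"))
  total <- sum(loads)
  strain_of <- rep(strains, loads)

  is_gcat <- stats::runif(total) < config$gc_to_at_fraction
  pos <- integer(total)
  pos[is_gcat] <- sample(gc_pos, sum(is_gcat), replace = TRUE)
  pos[!is_gcat] <- sample.int(genome$length, sum(!is_gcat), replace = TRUE)
  ref <- chars[pos]

  alt <- character(total)
  alt[is_gcat] <- ifelse(ref[is_gcat] == "G", "A", "T")
  if (any(!is_gcat)) {
    ## remaining classes at this base: G/C keep their two transversions, A/T
    ## keep all three substitutions (none is G:C>A:T)
    other <- which(!is_gcat)
    opts <- list(A = c("G", "C", "T"), T = c("C", "G", "A"),
                 G = c("T", "C"), C = c("A", "G"))
    pick <- stats::runif(length(other))
    alt[other] <- vapply(seq_along(other), function(i) {
      o <- opts[[ref[other[i]]]]
      o[ceiling(pick[i] * length(o))]
    }, character(1))
  }

  decoy <- stats::runif(total) < config$decoy_fraction
  freq <- ifelse(decoy, stats::runif(total, 0.05, 0.4999),
                 stats::runif(total, 0.5, 1))

  variants <- data.frame(
    strain_id = strain_of, position = pos, ref = ref, alt = alt,
    kind = "SNP", read_frequency = freq,
    depth = 80L + stats::rpois(total, 40),
    planted = FALSE, planted_locus = NA_character_,
    stringsAsFactors = FALSE
  )
  ## drop duplicate sites within a strain (independent lesions cannot recur)
  variants <- variants[!duplicated(variants[c("strain_id", "position")]), ,
                       drop = FALSE]

  if (!is.null(config$planted_hotspots)) {
    ph <- config$planted_hotspots
    planted_rows <- list()
    for (i in seq_len(nrow(ph))) {
      feature <- genome$features[genome$features$locus_tag == ph$locus_tag[i], ]
      hit <- stats::runif(n) < ph$prob[i]
      for (s in which(hit)) {
        snp <- plant_nonsyn_snp(genome, feature)
        if (is.null(snp)) next
        planted_rows[[length(planted_rows) + 1L]] <- data.frame(
          strain_id = strains[s], position = snp$position, ref = snp$ref,
          alt = snp$alt, kind = "SNP",
          read_frequency = stats::runif(1, 0.6, 1),
          depth = 80L + stats::rpois(1, 40),
          planted = TRUE, planted_locus = ph$locus_tag[i],
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(planted_rows)) {
      variants <- rbind(variants, do.call(rbind, planted_rows))
      variants <- variants[!duplicated(variants[c("strain_id", "position")],
                                       fromLast = TRUE), , drop = FALSE]
    }
  }

  variants <- variants[order(variants$strain_id, variants$position), ,
                       drop = FALSE]
  rownames(variants) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in strains) {
      write_variant_vcf(variants[variants$strain_id == s, , drop = FALSE],
                        file.path(out_dir, paste0(s, ".vcf")),
                        strain_id = s, chrom = genome$id)
    }
    utils::write.table(variants, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(variants = variants, loads = stats::setNames(loads, strains),
       config = config)
}

#' Plate-screen simulation configuration
#'
#' Shape of the simulated microtiter campaign: plates carry a control
#' triplicate plus variants; variant titers are the plate-control level times
#' `(1 + effect)` times multiplicative lognormal noise. A per-plate factor
#' emulates plate-to-plate (humidity-type) variation, which is why decisions
#' are always made against same-plate controls.
#'
#' @param n_variants number of variant strains.
#' @param control_titer_mM,control_titer_sd plate-control titer mean and
#'   between-plate SD (mM).
#' @param control_biomass control final biomass (OD600).
#' @param effects `NULL` (null campaign) or data frame `strain_id`,
#'   `titer_effect`, `biomass_effect` (relative, e.g. 0.2 = +20%).
#' @param plate_size wells per plate.
#' @param n_controls control replicates per plate.
#' @param replicates technical replicates per variant (1 = first-pass,
#'   3 = confirmatory layout).
#' @param noise_cv multiplicative measurement noise CV.
#' @param plate_effect_sd SD of the lognormal per-plate factor.
#' @param seed RNG seed.
#' @return list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_variants = 45, control_titer_mM = 11.5,
                              control_titer_sd = 0.3,
                              control_biomass = 18.4, effects = NULL,
                              plate_size = 48, n_controls = 3,
                              replicates = 3, noise_cv = 0.05,
                              plate_effect_sd = 0.03, seed = 1) {
  stopifnot(control_titer_sd >= 0, plate_size >= n_controls + 1)
  structure(
    list(n_variants = n_variants, control_titer_mM = control_titer_mM,
         control_titer_sd = control_titer_sd,
         control_biomass = control_biomass, effects = effects,
         plate_size = plate_size, n_controls = n_controls,
         replicates = replicates, noise_cv = noise_cv,
         plate_effect_sd = plate_effect_sd, seed = seed),
    class = "screen_sim_config"
  )
}

#' Simulate a plate-screen measurement table
#'
#' @param config a [screen_sim_config()].
#' @return list with `records` (data frame `strain_id`, `plate_id`,
#'   `replicate`, `titer`, `biomass`, `is_control`) and `truth` (per-variant
#'   true effects).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  n_var <- config$n_variants
  variant_ids <- if (n_var > 0) sprintf("V%04d", seq_len(n_var)) else character(0)

  effects <- data.frame(strain_id = variant_ids,
                        titer_effect = numeric(length(variant_ids)),
                        biomass_effect = numeric(length(variant_ids)),
                        stringsAsFactors = FALSE)
  if (!is.null(config$effects)) {
    m <- match(effects$strain_id, config$effects$strain_id)
    hit <- !is.na(m)
    effects$titer_effect[hit] <- config$effects$titer_effect[m[hit]]
    if ("biomass_effect" %in% names(config$effects)) {
      effects$biomass_effect[hit] <- config$effects$biomass_effect[m[hit]]
    }
  }

  per_plate <- config$plate_size - config$n_controls
  plate_of <- if (n_var > 0) (seq_len(n_var) - 1L) %/% per_plate + 1L else integer(0)
  n_plates <- max(plate_of, 1L)

  noisy <- function(mu, n) mu * exp(stats::rnorm(n, 0, config$noise_cv))

  recs <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    plate_id <- sprintf("P%03d", p)
    plate_factor <- exp(stats::rnorm(1, 0, config$plate_effect_sd))
    base_titer <- stats::rnorm(1, config$control_titer_mM,
                               config$control_titer_sd) * plate_factor
    base_biomass <- config$control_biomass * plate_factor
    ctrl <- data.frame(
      strain_id = "control", plate_id = plate_id,
      replicate = seq_len(config$n_controls),
      titer = noisy(base_titer, config$n_controls),
      biomass = noisy(base_biomass, config$n_controls),
      is_control = TRUE, stringsAsFactors = FALSE
    )
    vids <- variant_ids[plate_of == p]
    var <- if (length(vids)) {
      e <- effects[match(vids, effects$strain_id), ]
      do.call(rbind, lapply(seq_along(vids), function(i) {
        data.frame(
          strain_id = vids[i], plate_id = plate_id,
          replicate = seq_len(config$replicates),
          titer = noisy(base_titer * (1 + e$titer_effect[i]),
                        config$replicates),
          biomass = noisy(base_biomass * (1 + e$biomass_effect[i]),
                          config$replicates),
          is_control = FALSE, stringsAsFactors = FALSE
        )
      }))
    } else NULL
    recs[[p]] <- rbind(ctrl, var)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records, truth = effects)
}

#' Simulate noisy batch fermentation time courses
#'
#' Integrates the Monod batch model ([simulate_batch()]) for `n_batches`
#' batches -- optionally with per-batch parameter overrides, e.g. distinct
#' local growth rates over shared global constants -- and applies
#' multiplicative Gaussian noise of the given CV to every observation.
#' Sampling is hourly by default: the short deceleration phase around glucose
#' depletion is what makes the Monod constant identifiable, and coarser grids
#' can miss it entirely.
#'
#' @param params base [monod_params()].
#' @param n_batches number of batches.
#' @param local_overrides optional list (length `n_batches`) of named vectors
#'   overriding parameters per batch.
#' @param init initial state `c(X=, S=, P=)` shared by all batches.
#' @param times sampling grid in hours.
#' @param noise_cv multiplicative noise CV (0 gives exact trajectories).
#' @param seed RNG seed.
#' @param out_dir optional directory for per-batch CSV files.
#' @return list with `batches` (list of data frames), `true_params` (list of
#'   per-batch parameter vectors), `seed`.
#' @export
simulate_fermentation <- function(params, n_batches = 3,
                                  local_overrides = NULL,
                                  init = c(X = 0.25, S = 40, P = 0),
                                  times = seq(0, 48, by = 1),
                                  noise_cv = 0.01, seed = 1,
                                  out_dir = NULL) {
  set.seed(seed)
  true_params <- lapply(seq_len(n_batches), function(b) {
    p <- as.numeric(params)[match(.MONOD_PARAM_NAMES, names(params))]
    names(p) <- .MONOD_PARAM_NAMES
    if (!is.null(local_overrides) && length(local_overrides) >= b &&
        !is.null(local_overrides[[b]])) {
      ov <- local_overrides[[b]]
      p[names(ov)] <- ov
    }
    p
  })
  batches <- lapply(seq_len(n_batches), function(b) {
    clean <- simulate_batch(true_params[[b]], init = init, times = times)
    if (noise_cv > 0) {
      for (col in c("biomass", "glucose", "histidine")) {
        clean[[col]] <- pmax(
          clean[[col]] * (1 + stats::rnorm(nrow(clean), 0, noise_cv)), 0)
      }
    }
    as.data.frame(clean)
  })
  names(batches) <- sprintf("batch%d", seq_len(n_batches))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in seq_len(n_batches)) {
      utils::write.csv(batches[[b]],
                       file.path(out_dir, paste0(names(batches)[b], ".csv")),
                       row.names = FALSE)
    }
  }
  list(batches = batches, true_params = true_params, seed = seed)
}
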