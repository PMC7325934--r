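#' Primer presets
#'
#' Commonly used amplicon primer pairs as IUPAC strings: the 515F/926R pair
#' targeting the 16S rRNA V4-V5 region and the ITS1F/ITS2R pair for the fungal
#' internal transcribed spacer.
#'
#' @param name One of `"515F"`, `"926R"`, `"ITS1F"`, `"ITS2R"`.
#' @return A single IUPAC DNA string.
#' @export
#' @examples
#' primer_preset("515F")
primer_preset <- function(name) {
  presets <- c(
    "515F"  = "GTGYCAGCMGCCGCGGTAA",
    "926R"  = "CCGYCAATTYMTTTRAGTTT",
    "ITS1F" = "CTTGGTCATTTAGAGGAAGTAA",
    "ITS2R" = "GCTGCGTTCTTCATCGATGC"
  )
  if (!name %in% names(presets)) {
    stop("unknown primer preset: ", name, call. = FALSE)
  }
  unname(presets[name])
}

#' Build a synthetic lineage-annotated reference database
#'
#' Generates `n_taxa` random, well-separated reference sequences with
#' QIIME-style seven-rank lineages. A configurable fraction of taxa carry an
#' empty genus and/or species name so that downstream rank-aware taxonomy
#' rules (skipping unnamed ranks) can be exercised. Random sequences of a few
#' hundred bases are far below any clustering identity threshold pairwise, so
#' the taxa are separable by construction; separation is asserted in the test
#' suite with the alignment identity oracle.
#'
#' @param n_taxa Number of reference taxa (at least 2).
#' @param seed Integer seed; the same seed reproduces the database exactly.
#' @param seq_length Length of every reference sequence in bases.
#' @param unnamed_fraction Fraction of taxa whose species name is empty; half
#'   of those additionally have an empty genus.
#' @return A tibble with columns `ref_id`, `lineage` (QIIME-style
#'   `k__...;p__...;...;s__...` string, possibly with empty rank names) and
#'   `sequence`.
#' @export
#' @examples
#' ref <- build_reference(n_taxa = 5, seed = 1)
#' ref$lineage[1]
build_reference <- function(n_taxa, seed, seq_length = 250,
                            unnamed_fraction = 0.2) {
  if (!is.numeric(n_taxa) || n_taxa < 2) {
    stop("n_taxa must be at least 2", call. = FALSE)
  }
  n_taxa <- as.integer(n_taxa)
  stopifnot(seq_length >= 200)
  with_rng(derive_seed(seed, 1L), {
    seqs <- vapply(seq_len(n_taxa), function(i) {
      paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
            collapse = "")
    }, character(1))
    n_unnamed <- floor(unnamed_fraction * n_taxa)
    unnamed <- if (n_unnamed > 0) sample(n_taxa, n_unnamed) else integer(0)
    # half of the unnamed taxa also lack a genus name
    unnamed_genus <- if (length(unnamed) > 1) {
      unnamed[seq_len(floor(length(unnamed) / 2))]
    } else {
      integer(0)
    }
    phyla <- paste0("Phylum", ((seq_len(n_taxa) - 1L) %% 4L) + 1L)
    lineage <- vapply(seq_len(n_taxa), function(i) {
      ranks <- c("Bacteria", phyla[i], paste0("Class", i), paste0("Order", i),
                 paste0("Family", i), paste0("Genus", i), paste0("Species", i))
      if (i %in% unnamed) ranks[7] <- ""
      if (i %in% unnamed_genus) ranks[6:7] <- ""
      paste0(rank_prefixes(), ranks, collapse = ";")
    }, character(1))
    tibble::tibble(
      ref_id = sprintf("REF%03d", seq_len(n_taxa)),
      lineage = lineage,
      sequence = seqs
    )
  })
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic community simulator: the crossed design
#' (contamination level x generation x chamber type), per-sample sequencing
#' depth, the substitution error and chimera rates, the Dirichlet
#' concentration of the abundance model, and per-taxon enrichment effects.
#'
#' The design mirrors an in-situ cultivation study in which diffusion chambers
#' (DC) and microbial traps (MT) are incubated on soils spanning a mercury
#' contamination gradient and transferred over three 20-day generations.
#' Enrichment effects are log-fold-changes that scale up with contamination
#' level (reference 0, low 1/3, medium 2/3, high 1) and generation (G1 1/3,
#' G2 2/3, G3 1), producing the enrichment-across-generations pattern such
#' designs are built to detect.
#'
#' @param n_samples_per_cell Samples per (level, generation, chamber) cell.
#' @param levels,generations,chambers Factor levels of the design.
#' @param reads_per_sample Reads simulated per sample.
#' @param substitution_error_rate Per-base substitution probability.
#' @param chimera_rate Per-read probability of a two-parent crossover.
#' @param concentration Dirichlet concentration; larger values give samples
#'   closer to their expected composition.
#' @param enrichment_effects `NULL` or a data frame with columns `ref_id` and
#'   `lfc` (natural-log fold change at full strength).
#' @param forward_primer,reverse_primer IUPAC primer strings added to every
#'   read (forward at the 5' end, reverse-complemented reverse at the 3' end).
#' @param seed Integer seed; identical configs give bit-identical outputs.
#' @return A list of class `subotu_sim_config`.
#' @export
sim_config <- function(n_samples_per_cell = 1,
                       levels = c("reference", "low", "medium", "high"),
                       generations = c("G1", "G2", "G3"),
                       chambers = c("DC", "MT"),
                       reads_per_sample = 2000,
                       substitution_error_rate = 0.002,
                       chimera_rate = 0.01,
                       concentration = 50,
                       enrichment_effects = NULL,
                       forward_primer = primer_preset("515F"),
                       reverse_primer = primer_preset("926R"),
                       seed = 1L) {
  stopifnot(
    reads_per_sample > 0,
    substitution_error_rate >= 0, substitution_error_rate <= 1,
    chimera_rate >= 0, chimera_rate <= 1,
    concentration > 0,
    n_samples_per_cell >= 1
  )
  structure(
    list(
      n_samples_per_cell = as.integer(n_samples_per_cell),
      levels = levels, generations = generations, chambers = chambers,
      reads_per_sample = as.integer(reads_per_sample),
      substitution_error_rate = substitution_error_rate,
      chimera_rate = chimera_rate,
      concentration = concentration,
      enrichment_effects = enrichment_effects,
      forward_primer = forward_primer,
      reverse_primer = reverse_primer,
      seed = as.integer(seed)
    ),
    class = "subotu_sim_config"
  )
}

level_weight <- function(level, levels) {
  if (length(levels) == 1) return(1)
  (match(level, levels) - 1) / (length(levels) - 1)
}

generation_weight <- function(generation, generations) {
  match(generation, generations) / length(generations)
}

#' Simulate the community design
#'
#' Draws per-sample true taxon relative abundances for the crossed
#' contamination x generation x chamber design. Baseline log-abundances are
#' drawn once per taxon; enrichment effects shift the log-mean of flagged
#' taxa upwards with contamination level and generation, and samples are drawn
#' from a Dirichlet around the resulting expected composition.
#'
#' @param reference Reference tibble from [build_reference()].
#' @param config A [sim_config()].
#' @return A list of class `subotu_truth` with tibbles `samples` (sample_id,
#'   level, generation, chamber, replicate) and `abundances` (sample_id,
#'   ref_id, abundance; abundances sum to 1 per sample).
#' @export
simulate_design <- function(reference, config = sim_config()) {
  stopifnot(inherits(config, "subotu_sim_config"))
  if (nrow(reference) == 0) stop("reference is empty", call. = FALSE)
  eff <- config$enrichment_effects
  if (!is.null(eff)) {
    if (!all(c("ref_id", "lfc") %in% names(eff))) {
      stop("enrichment_effects needs columns ref_id and lfc", call. = FALSE)
    }
    unknown <- setdiff(eff$ref_id, reference$ref_id)
    if (length(unknown) > 0) {
      stop("enrichment_effects references unknown taxa: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  design <- tidyr::expand_grid(
    level = config$levels, generation = config$generations,
    chamber = config$chambers, replicate = seq_len(config$n_samples_per_cell)
  )
  design$sample_id <- sprintf(
    "%s-%s-%s-R%d",
    toupper(substr(design$level, 1, 3)), design$chamber, design$generation,
    design$replicate
  )
  n_taxa <- nrow(reference)
  lfc <- stats::setNames(rep(0, n_taxa), reference$ref_id)
  if (!is.null(eff)) lfc[eff$ref_id] <- eff$lfc

  with_rng(derive_seed(config$seed, 2L), {
    base_log <- stats::rnorm(n_taxa, mean = 0, sd = 1)
    ab <- purrr::pmap_dfr(
      design[, c("sample_id", "level", "generation")],
      function(sample_id, level, generation) {
        w <- level_weight(level, config$levels) *
          generation_weight(generation, config$generations)
        eta <- base_log + w * lfc
        p <- exp(eta - max(eta))
        p <- p / sum(p)
        alpha <- config$concentration * p
        g <- stats::rgamma(n_taxa, shape = alpha, rate = 1)
        # guard against all-zero draws at tiny alpha
        if (sum(g) == 0) g <- p
        tibble::tibble(sample_id = sample_id, ref_id = reference$ref_id,
                       abundance = g / sum(g))
      }
    )
    structure(
      list(samples = tibble::as_tibble(design[, c("sample_id", "level",
                                                  "generation", "chamber",
                                                  "replicate")]),
           abundances = ab),
      class = "subotu_truth"
    )
  })
}

mutate_sequences <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  total <- sum(lens)
  hit <- stats::runif(total) < rate
  offs <- c(0L, cumsum(lens))
  out <- vapply(seq_along(chars), function(i) {
    h <- hit[(offs[i] + 1L):offs[i + 1L]]
    if (any(h)) {
      cur <- chars[[i]]
      idx <- which(h)
      repl <- vapply(cur[idx], function(b) sample(setdiff(bases, b), 1L),
                     character(1))
      cur[idx] <- repl
      paste(cur, collapse = "")
    } else {
      seqs[i]
    }
  }, character(1))
  out
}

#' Generate error-bearing amplicon reads
#'
#' Turns per-sample true abundances into reads: read counts per taxon are
#' multinomial at the configured depth; each read is the forward primer, the
#' source taxon's amplicon, and the reverse-complemented reverse primer; with
#' probability `chimera_rate` the amplicon is instead a single-breakpoint
#' crossover of two distinct taxa present in the same sample (breakpoint
#' uniform over the central 20-80% of the amplicon); substitutions are i.i.d.
#' per base over the whole read. Base qualities are constant (Q40).
#'
#' @param reference Reference tibble from [build_reference()].
#' @param truth A `subotu_truth` from [simulate_design()].
#' @param config The same [sim_config()] used for the design.
#' @return A tibble with one row per read: `sample_id`, `read_id`, `sequence`,
#'   `quality`, `true_ref_id`, `is_chimera`, `parent_a`, `parent_b`.
#' @export
generate_reads <- function(reference, truth, config = sim_config()) {
  stopifnot(inherits(truth, "subotu_truth"))
  ref_seq <- stats::setNames(reference$sequence, reference$ref_id)
  rc_rev <- reverse_complement(config$reverse_primer)
  with_rng(derive_seed(config$seed, 3L), {
    out <- purrr::map_dfr(truth$samples$sample_id, function(sid) {
      ab <- truth$abundances[truth$abundances$sample_id == sid, ]
      counts <- as.vector(stats::rmultinom(1, config$reads_per_sample,
                                           ab$abundance))
      src <- rep(ab$ref_id, counts)
      n <- length(src)
      is_chim <- stats::runif(n) < config$chimera_rate
      present <- ab$ref_id[ab$abundance > 0]
      if (length(present) < 2) is_chim[] <- FALSE
      parent_a <- ifelse(is_chim, src, NA_character_)
      parent_b <- rep(NA_character_, n)
      amplicon <- unname(ref_seq[src])
      for (i in which(is_chim)) {
        others <- setdiff(present, parent_a[i])
        w <- ab$abundance[match(others, ab$ref_id)]
        parent_b[i] <- if (length(others) == 1) others else {
          sample(others, 1, prob = w)
        }
        sa <- ref_seq[[parent_a[i]]]
        sb <- ref_seq[[parent_b[i]]]
        L <- min(nchar(sa), nchar(sb))
        bp <- sample(seq(floor(0.2 * L), ceiling(0.8 * L)), 1)
        amplicon[i] <- paste0(substr(sa, 1, bp), substr(sb, bp + 1, L))
      }
      reads <- paste0(config$forward_primer, amplicon, rc_rev)
      reads <- mutate_sequences(reads, config$substitution_error_rate)
      tibble::tibble(
        sample_id = sid,
        read_id = sprintf("%s_read%05d", sid, seq_len(n)),
        sequence = reads,
        quality = strrep("I", nchar(reads)),
        true_ref_id = ifelse(is_chim, NA_character_, src),
        is_chimera = is_chim,
        parent_a = parent_a,
        parent_b = parent_b
      )
    })
    out
  })
}

#' Write and read simulated reads as FASTQ
#'
#' One uncompressed FASTQ file per sample, named `<sample_id>.fastq`.
#'
#' @param reads Read tibble from [generate_reads()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(reads, reads$sample_id), function(df) {
    path <- file.path(dir, paste0(df$sample_id[1], ".fastq"))
    dna <- Biostrings::DNAStringSet(df$sequence)
    names(dna) <- df$read_id
    qual <- Biostrings::BStringSet(df$quality)
    obj <- Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(qual)
    )
    Biostrings::writeQualityScaledXStringSet(obj, path)
    path
  }, character(1))
  invisible(unname(paths))
}

#' @rdname write_reads_fastq
#' @param files FASTQ file paths; sample ids are taken from file names.
#' @export
read_reads_fastq <- function(files) {
  purrr::map_dfr(files, function(f) {
    # the reader warns that metadata columns are dropped; we do not carry any
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(f))
    suppressWarnings(tibble::tibble(
      sample_id = sub("\\.fastq$", "", basename(f)),
      read_id = names(x),
      sequence = unname(as.character(x)),
      quality = unname(as.character(methods::as(x@quality, "BStringSet")))
    ))
  })
}

#' Write a reference database as FASTA
#'
#' Headers are `ref_id k__...;p__...;...;s__...`.
#'
#' @param reference Reference tibble.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(reference$sequence)
  names(dna) <- paste(reference$ref_id, reference$lineage)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  tibble::tibble(
    ref_id = sub("\\s.*$", "", hdr),
    lineage = sub("^\\S+\\s*", "", hdr),
    sequence = as.character(x)
  )
}

#' Packaged soil geochemistry table
#'
#' The five-site soil geochemistry table bundled with the package: moisture,
#' total carbon/nitrogen/phosphorus, loss on ignition, extractable
#' NH4/NO3/PO4, and total and methyl mercury for two reference-area and three
#' contaminated sampling sites spanning roughly 10-1700 ng/g THg. Values below
#' the analytical detection limit appear as `"b.d."` in the shipped CSV and
#' are parsed to `NA` here (they are excluded pairwise from correlations and
#' imputed at half the variable minimum for clustering).
#'
#' @return A tibble with one row per site and columns `site`, `moisture_pct`,
#'   `tc_g_kg`, `tn_g_kg`, `tp_mg_kg`, `loi_pct`, `nh4_mg_kg`, `no3_mg_kg`,
#'   `po4_mg_kg`, `thg_ng_g`, `mehg_ng_g`.
#' @export
#' @examples
#' geochem_table()
geochem_table <- function() {
  path <- system.file("extdata", "geochem_sites.csv", package = "subotu",
                      mustWork = TRUE)
  readr::read_csv(path, na = "b.d.", show_col_types = FALSE,
                  col_types = readr::cols(
                    site = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
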