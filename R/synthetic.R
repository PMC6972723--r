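#' Configuration for the synthetic gene-panel cohort
#'
#' Describes the simulated world the generator emulates: a five-gene panel
#' sequenced in a 35-individual case cohort (10 with pre-axial longitudinal
#' limb defects, 14 with intercalary transverse defects, 11 other) and a
#' 99-individual reference panel; 145 variants concentrated in UTR/intronic
#' regions with 11 coding ones (3 in CUL4A, 2 in each other gene); 43 of
#' 145 variants rare (MAF < 0.01); per-variant annotation profiles drawn
#' per category; and an optional score-burden enrichment of one case
#' subgroup. All randomness flows from `seed` through named substreams.
#'
#' @param seed Master seed (integer).
#' @param n_pre_axial,n_intercalary,n_other Case subgroup sizes
#'   (defaults 10, 14, 11).
#' @param n_reference Reference-panel size (default 99).
#' @param genes Tibble with `gene`, `n_variants`, `n_coding`; the default
#'   five-gene panel totals 145 variants, 11 coding.
#' @param n_rare Number of variants drawn with MAF < 0.01 (default 43).
#' @param rare_maf_range,common_maf_range MAF ranges for the rare and
#'   common mixture components.
#' @param noncoding_weights Relative placement weights for non-coding
#'   variants over `utr3`, `utr5`, `intronic_flank` (UTR3-heavy default).
#' @param verdict_probs Per-category probabilities of `none`, `possible`,
#'   `strong` verdicts.
#' @param delta Score-burden shift (points) planted into `enriched_group`;
#'   0 gives the null configuration.
#' @param enriched_group Endophenotype receiving the shift.
#' @param flank Intronic panel flank (bp).
#' @param plant_island Plant a CpG-island block in each gene's 3'UTR
#'   (default TRUE).
#' @param island_length Length of the planted island block in bp
#'   (200-600; default 400).
#' @param reference_location_counts Location counts emulating a large
#'   population database, used by the location-distribution comparison. The
#'   default is coding-richer than the cases, as population panels are.
#' @return A list of class `crl4_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_pre_axial = 10L, n_intercalary = 14L, n_other = 11L,
    n_reference = 99L,
    genes = tibble(
      gene = c("CRBN", "CUL4A", "DDB1", "IKZF1", "IKZF3"),
      n_variants = c(45L, 20L, 20L, 40L, 20L),
      n_coding = c(2L, 3L, 2L, 2L, 2L)
    ),
    n_rare = 43L,
    rare_maf_range = c(5e-4, 0.01),
    common_maf_range = c(0.01, 0.3),
    noncoding_weights = c(utr3 = 0.45, utr5 = 0.15, intronic_flank = 0.40),
    verdict_probs = c(none = 0.60, possible = 0.25, strong = 0.15),
    delta = 34,
    enriched_group = "pre_axial_longitudinal",
    flank = 50L,
    plant_island = TRUE,
    island_length = 400L,
    reference_location_counts = tibble(
      location = c("coding", "utr5", "utr3", "intronic_flank"),
      n = c(2100L, 1300L, 4200L, 4400L)
    )) {
  cfg <- list(
    seed = as.integer(seed),
    n_pre_axial = n_pre_axial, n_intercalary = n_intercalary,
    n_other = n_other, n_reference = n_reference,
    genes = genes, n_rare = n_rare,
    rare_maf_range = rare_maf_range, common_maf_range = common_maf_range,
    noncoding_weights = noncoding_weights,
    verdict_probs = verdict_probs,
    delta = delta, enriched_group = enriched_group,
    flank = as.integer(flank),
    plant_island = isTRUE(plant_island),
    island_length = as.integer(island_length),
    reference_location_counts = reference_location_counts
  )
  if (cfg$plant_island && cfg$island_length < 200L) {
    abort("planted islands must be at least 200 bp (the minimum island length)")
  }
  if (cfg$plant_island && cfg$island_length > 600L) {
    abort("planted islands longer than 600 bp do not fit the 3'UTR block")
  }
  n_total <- sum(genes$n_variants)
  if (n_rare > n_total) {
    abort("n_rare cannot exceed the total number of variants")
  }
  if (any(genes$n_coding > genes$n_variants)) {
    abort("n_coding cannot exceed n_variants for a gene")
  }
  if (abs(sum(verdict_probs) - 1) > 1e-8 || any(verdict_probs < 0)) {
    abort("verdict_probs must be non-negative and sum to 1")
  }
  if (delta < 0) abort("delta must be non-negative")
  structure(cfg, class = "crl4_config")
}

# Shared synthetic gene architecture (0-based half-open, + strand).
# Six exons; CDS spans parts of exons 1 and 6 fully covering exons 2-5;
# a long 3'UTR hosting the planted CpG island.
synthetic_gene_layout <- function() {
  list(
    length = 3600L,
    exons = tibble(
      start = c(200L, 800L, 1250L, 1700L, 2150L, 2600L),
      end = c(500L, 950L, 1400L, 1850L, 2300L, 3400L)
    ),
    utr5 = tibble(start = 200L, end = 440L),
    cds = tibble(
      start = c(440L, 800L, 1250L, 1700L, 2150L, 2600L),
      end = c(500L, 950L, 1400L, 1850L, 2300L, 2660L)
    ),
    utr3 = tibble(start = 2660L, end = 3400L),
    island = c(start = 2800L, end = 3200L),
    critical_exon = 4L
  )
}

#' Gene models of the synthetic panel
#'
#' @param config A `crl4_config`.
#' @return Gene-model feature tibble in the [read_gene_models()] schema.
#' @export
synthetic_gene_models <- function(config = synthetic_config()) {
  lay <- synthetic_gene_layout()
  one <- bind_rows(
    mutate(lay$exons, feature = "exon"),
    mutate(lay$cds, feature = "cds"),
    mutate(lay$utr5, feature = "utr5"),
    mutate(lay$utr3, feature = "utr3")
  )
  list_rbind(map(config$genes$gene, function(g) {
    mutate(
      one, gene = g, transcript = paste0("SYN_", g, "_T1"), strand = "+"
    )
  })) |>
    select("gene", "transcript", "strand", "feature", "start", "end")
}

#' First critical exon per synthetic gene
#'
#' Mis-splicing upstream of this exon is treated as removing an essential
#' C-terminal domain (see [apply_modifiers()]).
#'
#' @param config A `crl4_config`.
#' @return Named integer vector.
#' @export
synthetic_critical_exons <- function(config = synthetic_config()) {
  setNames(
    rep(synthetic_gene_layout()$critical_exon, nrow(config$genes)),
    config$genes$gene
  )
}

#' Simulate the panel contig sequences
#'
#' One contig per gene: random background at 40% GC, a deterministic
#' CpG-island block (80% GC, observed/expected CpG = 2.5 in every 200-bp
#' window, so it passes the island criteria by construction) planted in the
#' 3'UTR, and a coding sequence sampled from the packaged human-like codon
#' usage table written across the CDS intervals (ATG start, TAA stop, no
#' internal stops).
#'
#' @param config A `crl4_config`.
#' @return List: `sequences` (named character vector), `truth` (tibble with
#'   the planted island coordinates) and `cds_codons` (tibble of planted
#'   codon counts per gene).
#' @export
simulate_sequences <- function(config = synthetic_config()) {
  lay <- synthetic_gene_layout()
  codon_ref <- human_codon_table()
  sense <- filter(codon_ref, .data$aa != "*")
  with_stream_seed(config$seed, "sequences", {
    seqs <- character(0)
    truth <- list()
    codons_truth <- list()
    for (g in config$genes$gene) {
      n <- lay$length
      base <- sample(
        c("A", "T", "C", "G"), n,
        replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2)
      )
      # vertebrate DNA is CpG-depleted outside islands (obs/exp ~ 0.2);
      # rewrite most background CpG dinucleotides so only planted islands
      # carry CpG density
      cg <- which(base[-n] == "C" & base[-1] == "G")
      drop <- cg[runif(length(cg)) < 0.9]
      base[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
      s <- paste(base, collapse = "")
      island_start <- unname(lay$island["start"])
      island_end <- island_start + config$island_length
      if (config$plant_island) {
        # deterministic CpG island block: "CGCGCGCGTA" repeated gives
        # GC = 0.8 and obs/exp CpG = 2.5 in every window, so the whole
        # block passes the island criteria by construction
        block <- strrep("CGCGCGCGTA", ceiling(config$island_length / 10))
        substr(s, island_start + 1L, island_end) <-
          substr(block, 1, config$island_length)
      }
      # plant the CDS
      cds_len <- sum(lay$cds$end - lay$cds$start)
      n_codons <- cds_len %/% 3L
      # sample codons from the human-like table, but strongly suppress
      # CpG dinucleotides (within codons and across C|G junctions) the way
      # CpG-depleted vertebrate coding sequence does, so that only the
      # planted block can satisfy the island criteria
      body <- character(n_codons - 2L)
      prev <- "ATG"
      for (k in seq_along(body)) {
        repeat {
          cand <- sample(sense$codon, 1, prob = sense$count)
          has_cpg <- grepl("CG", cand, fixed = TRUE) ||
            (endsWith(prev, "C") && startsWith(cand, "G"))
          if (!has_cpg || runif(1) < 0.05) break
        }
        body[k] <- cand
        prev <- cand
      }
      codons <- c("ATG", body, "TAA")
      cds_seq <- paste(codons, collapse = "")
      at <- 1L
      for (i in seq_len(nrow(lay$cds))) {
        w <- lay$cds$end[i] - lay$cds$start[i]
        substr(s, lay$cds$start[i] + 1L, lay$cds$end[i]) <-
          substr(cds_seq, at, at + w - 1L)
        at <- at + w
      }
      seqs[g] <- s
      truth[[g]] <- if (config$plant_island) {
        tibble(gene = g, island_start = island_start,
               island_end = island_end)
      } else {
        tibble(gene = g, island_start = NA_integer_,
               island_end = NA_integer_)
      }
      tab <- table(codons)
      codons_truth[[g]] <- tibble(
        gene = g, codon = names(tab), count = as.integer(tab)
      )
    }
    list(
      sequences = seqs,
      truth = list_rbind(truth),
      cds_codons = list_rbind(codons_truth)
    )
  })
}

#' Human-like genome-scope codon usage table
#'
#' A packaged fixture with approximate human codon frequencies, for
#' genome-scope codon-usage comparisons without any download. Synthetic
#' in the sense of being a rounded, approximate stand-in for a real
#' genome-wide tally.
#'
#' @return Tibble: `codon`, `aa`, `count`.
#' @export
human_codon_table <- function() {
  path <- system.file(
    "extdata", "human_codon_usage_synthetic.tsv", package = "crl4score"
  )
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$aa <- Biostrings::GENETIC_CODE[tab$codon]
  tab
}

#' Simulate a complete synthetic cohort
#'
#' Generates every input the analysis pipeline consumes: the variant
#' catalogue (placed consistently with the gene models and contig
#' sequences), Hardy-Weinberg genotypes for cases and reference panel at
#' each variant's MAF, predictor annotations drawn per category,
#' phenotypes, and a truth table recording every planted parameter. When
#' `delta > 0`, individuals of the enriched endophenotype additionally
#' carry high-score variants (weighted sampling of non-carried variants,
#' proportional to score) until at least `delta` points have been added —
#' the variant catalogue itself is shared across groups.
#'
#' @param config A `crl4_config`.
#' @return List of class `crl4_sim`: `variants`, `genotypes` (long),
#'   `annotations`, `phenotypes`, `gene_models`, `sequences`,
#'   `critical_exons`, `truth` (list: `variants`, `individuals`,
#'   `sequences`, `cds_codons`), `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "crl4_config"))
  lay <- synthetic_gene_layout()
  gene_models <- synthetic_gene_models(config)
  seq_out <- simulate_sequences(config)
  sequences <- seq_out$sequences

  variants <- with_stream_seed(config$seed, "placement", {
    place_variants(config, lay, sequences)
  })
  n_total <- nrow(variants)

  variants <- with_stream_seed(config$seed, "maf", {
    rare_idx <- sample.int(n_total, config$n_rare)
    maf <- runif(
      n_total, config$common_maf_range[1], config$common_maf_range[2]
    )
    maf[rare_idx] <- runif(
      config$n_rare, config$rare_maf_range[1], config$rare_maf_range[2]
    )
    mutate(variants, maf = maf, rare = seq_len(n_total) %in% rare_idx)
  })

  phenotypes <- synthetic_phenotypes(config)

  annotations <- with_stream_seed(config$seed, "annotations", {
    draw_annotations(variants$vid, config$verdict_probs)
  })
  scores <- score_variants(annotations, vids = variants$vid)

  genotypes <- with_stream_seed(config$seed, "genotypes", {
    hwe_genotypes(phenotypes$individual, variants)
  })

  added <- tibble(
    individual = phenotypes$individual, added_score = 0
  )
  if (config$delta > 0) {
    enr <- with_stream_seed(config$seed, "enrichment", {
      enrich_genotypes(
        genotypes, phenotypes, scores, config$delta, config$enriched_group
      )
    })
    genotypes <- enr$genotypes
    added <- enr$added
  }

  truth_variants <- variants |>
    left_join(select(scores, "vid", score_total = "total"), by = "vid")

  structure(
    list(
      variants = select(
        variants, "vid", "chrom", "pos", "ref", "alt", "gene"
      ),
      genotypes = genotypes,
      annotations = annotations,
      phenotypes = phenotypes,
      gene_models = gene_models,
      sequences = sequences,
      critical_exons = synthetic_critical_exons(config),
      truth = list(
        variants = truth_variants,
        individuals = added,
        sequences = seq_out$truth,
        cds_codons = seq_out$cds_codons
      ),
      config = config
    ),
    class = "crl4_sim"
  )
}

#' @export
print.crl4_sim <- function(x, ...) {
  cat(
    "Synthetic cohort: ", nrow(x$variants), " variants across ",
    nrow(x$config$genes), " genes; ",
    sum(x$phenotypes$cohort == "case"), " cases + ",
    sum(x$phenotypes$cohort == "reference"), " reference individuals\n",
    sep = ""
  )
  invisible(x)
}

synthetic_phenotypes <- function(config) {
  n_case <- config$n_pre_axial + config$n_intercalary + config$n_other
  tibble(
    individual = c(
      sprintf("TE%02d", seq_len(n_case)),
      sprintf("REF%02d", seq_len(config$n_reference))
    ),
    cohort = rep(c("case", "reference"), c(n_case, config$n_reference)),
    endophenotype = c(
      rep("pre_axial_longitudinal", config$n_pre_axial),
      rep("intercalary_transverse", config$n_intercalary),
      rep("other", config$n_other),
      rep("none", config$n_reference)
    )
  )
}

# Sample variant positions consistent with the gene models and sequences.
place_variants <- function(config, lay, sequences) {
  flank <- config$flank
  pick_pos <- function(iv, k, taken) {
    pool <- setdiff(unlist(map2(iv$start, iv$end, ~ seq(.x, .y - 1L))), taken)
    sample(pool, k)
  }
  intron_windows <- tibble(
    start = c(lay$exons$start - flank, lay$exons$end),
    end = c(lay$exons$start, lay$exons$end + flank)
  ) |>
    filter(.data$start >= 0) |>
    merge_intervals()
  rows <- list()
  for (i in seq_len(nrow(config$genes))) {
    g <- config$genes$gene[i]
    n_var <- config$genes$n_variants[i]
    n_cod <- config$genes$n_coding[i]
    n_non <- n_var - n_cod
    w <- config$noncoding_weights
    n_u3 <- round(n_non * w[["utr3"]] / sum(w))
    n_u5 <- round(n_non * w[["utr5"]] / sum(w))
    n_in <- n_non - n_u3 - n_u5
    taken <- integer(0)
    p_cod <- pick_pos(lay$cds, n_cod, taken)
    taken <- c(taken, p_cod)
    p_u3 <- pick_pos(lay$utr3, n_u3, taken)
    taken <- c(taken, p_u3)
    p_u5 <- pick_pos(lay$utr5, n_u5, taken)
    taken <- c(taken, p_u5)
    p_in <- pick_pos(intron_windows, n_in, taken)
    p0 <- c(p_cod, p_u3, p_u5, p_in)
    planted <- rep(
      c("coding", "utr3", "utr5", "intronic_flank"),
      c(n_cod, n_u3, n_u5, n_in)
    )
    ord <- order(p0)
    p0 <- p0[ord]
    planted <- planted[ord]
    ref <- substring(sequences[[g]], p0 + 1L, p0 + 1L)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))
    rows[[g]] <- tibble(
      chrom = g, pos = p0 + 1L, ref = unname(ref),
      alt = unname(alt), gene = g, planted_location = planted
    )
  }
  out <- list_rbind(unname(rows))
  # rsID-style identifiers, unique across the catalogue; three variants
  # (one DDB1, two IKZF1) are tagged as novel, mirroring a panel that finds
  # previously unreported sites
  out$vid <- sprintf("rs%06d", sample(100000:999999, nrow(out)))
  novel <- c(
    which(out$gene == "DDB1")[1], which(out$gene == "IKZF1")[1:2]
  )
  out$vid[novel] <- sprintf("novel_%03d", seq_along(novel))
  relocate(out, "vid")
}

draw_annotations <- function(vids, verdict_probs) {
  cats <- rubric_categories()
  n <- length(vids) * length(cats)
  verdicts <- sample(
    names(verdict_probs), n,
    replace = TRUE, prob = verdict_probs
  )
  tidyr::expand_grid(vid = vids, category = cats) |>
    mutate(verdict = verdicts, source = "synthetic_predictor") |>
    filter(.data$verdict != "none")
}

hwe_genotypes <- function(individuals, variants) {
  n_ind <- length(individuals)
  n_var <- nrow(variants)
  dosage <- rbinom(n_ind * n_var, 2L, rep(variants$maf, each = n_ind))
  tibble(
    individual = rep(individuals, times = n_var),
    vid = rep(variants$vid, each = n_ind),
    dosage = as.integer(dosage)
  )
}

# Bias the enriched subgroup toward carrying high-score variants: flip
# non-carried variants to heterozygous, sampled proportionally to score,
# until at least `delta` points have been added per individual.
enrich_genotypes <- function(genotypes, phenotypes, scores, delta,
                             enriched_group) {
  target_ids <- phenotypes$individual[
    phenotypes$endophenotype == enriched_group
  ]
  svec <- setNames(scores$total, scores$vid)
  added <- setNames(rep(0, nrow(phenotypes)), phenotypes$individual)
  g <- genotypes
  key <- paste(g$individual, g$vid)
  idx <- setNames(seq_len(nrow(g)), key)
  for (id in target_ids) {
    rows_id <- which(g$individual == id)
    repeat {
      if (added[id] >= delta) break
      open <- rows_id[!is.na(g$dosage[rows_id]) & g$dosage[rows_id] == 0 &
                        svec[g$vid[rows_id]] > 0]
      if (length(open) == 0) break
      pick <- if (length(open) == 1) {
        open
      } else {
        sample(open, 1, prob = svec[g$vid[open]])
      }
      g$dosage[pick] <- 1L
      added[id] <- added[id] + svec[g$vid[pick]]
    }
  }
  list(
    genotypes = g,
    added = tibble(
      individual = phenotypes$individual,
      added_score = unname(added[phenotypes$individual])
    )
  )
}

#' Redraw Hardy-Weinberg genotypes for an existing synthetic cohort
#'
#' Holds the variant catalogue, MAFs, annotations and scores of a simulated
#' cohort fixed and redraws only the genotypes (and the subgroup enrichment,
#' when the configuration plants one). This is the replication primitive for
#' calibration experiments: each call is one independent realisation of the
#' cohort's genotype layer.
#'
#' @param sim A `crl4_sim`.
#' @param seed Seed for this replicate.
#' @return Long genotype tibble.
#' @export
resample_genotypes <- function(sim, seed) {
  stopifnot(inherits(sim, "crl4_sim"))
  cfg_seed <- as.integer(seed)
  maf_tab <- sim$truth$variants
  g <- with_stream_seed(cfg_seed, "genotypes", {
    hwe_genotypes(sim$phenotypes$individual, maf_tab)
  })
  if (sim$config$delta > 0) {
    scores <- select(sim$truth$variants, "vid", total = "score_total")
    g <- with_stream_seed(cfg_seed, "enrichment", {
      enrich_genotypes(
        g, sim$phenotypes, scores, sim$config$delta,
        sim$config$enriched_group
      )$genotypes
    })
  }
  g
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits: `cohort.vcf`, `annotations.tsv`, `phenotypes.tsv`,
#' `gene_models.tsv`, `sequences.fasta`, `rubric.tsv`,
#' `reference_location_counts.tsv`, and the truth tables
#' (`truth_variants.tsv`, `truth_individuals.tsv`, `truth_sequences.tsv`,
#' `truth_cds_codons.tsv`). Identical configurations produce byte-identical
#' files.
#'
#' @param sim A `crl4_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "crl4_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_vcf(
    sim$variants, sim$genotypes, p("cohort.vcf"),
    contig_lengths = setNames(
      nchar(sim$sequences), names(sim$sequences)
    )
  )
  readr::write_tsv(sim$annotations, p("annotations.tsv"), progress = FALSE)
  readr::write_tsv(sim$phenotypes, p("phenotypes.tsv"), progress = FALSE)
  readr::write_tsv(sim$gene_models, p("gene_models.tsv"), progress = FALSE)
  write_rubric(default_rubric(), p("rubric.tsv"))
  readr::write_tsv(
    tibble(
      gene = names(sim$critical_exons),
      first_critical_exon = unname(sim$critical_exons)
    ),
    p("critical_exons.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    sim$config$reference_location_counts,
    p("reference_location_counts.tsv"),
    progress = FALSE
  )
  writeLines(
    unlist(map2(
      names(sim$sequences), sim$sequences,
      function(nm, s) c(paste0(">", nm), s)
    )),
    p("sequences.fasta")
  )
  readr::write_tsv(
    sim$truth$variants, p("truth_variants.tsv"), progress = FALSE
  )
  readr::write_tsv(
    sim$truth$individuals, p("truth_individuals.tsv"), progress = FALSE
  )
  readr::write_tsv(
    sim$truth$sequences, p("truth_sequences.tsv"), progress = FALSE
  )
  readr::write_tsv(
    sim$truth$cds_codons, p("truth_cds_codons.tsv"), progress = FALSE
  )
  invisible(dir)
}
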