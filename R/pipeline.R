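#' Run the full variant-interpretation pipeline
#'
#' Orchestrates every stage on a directory of input files (the formats
#' [write_cohort()] produces): annotate variant locations, consolidate and
#' score predictor annotations, build the severity heatmap, compute
#' per-individual burden, and run the cohort statistics — case-vs-reference
#' burden t-tests (count and score, overall and per gene), the three-group
#' ANOVA against the reference panel, the location-distribution chi-square
#' against reference counts, and per-variant genotype-endophenotype tests
#' for every heatmap variant. All result tables are written as TSV along
#' with a JSON run manifest (package version, seed, input/output checksums,
#' per-stage row counts). Stages are deterministic given `seed`, so reruns
#' on identical inputs are byte-identical apart from the manifest
#' timestamp.
#'
#' Required inputs in `input_dir`: `cohort.vcf`, `gene_models.tsv`,
#' `annotations.tsv`, `phenotypes.tsv`. Optional: `rubric.tsv` (default
#' rubric otherwise), `sequences.fasta` (enables coding subtypes),
#' `critical_exons.tsv` (enables the splicing promotion modifier),
#' `reference_location_counts.tsv` (enables the distribution comparison).
#'
#' @param input_dir Directory with input files.
#' @param out_dir Output directory (created).
#' @param threshold Heatmap reporting threshold (default 10).
#' @param flank Intronic panel flank in bp (default 50).
#' @param weighting Burden weighting, `"carrier"` (default) or `"dosage"`.
#' @param seed Seed for the (rarely triggered) Monte-Carlo fallback of the
#'   location comparison.
#' @return Invisibly, a list of the in-memory results (`classified`,
#'   `location_counts`, `scores`, `heatmap`, `burden`, `comparisons`,
#'   `anova`, `location_test`, `associations`, `manifest`).
#' @export
run_pipeline <- function(input_dir, out_dir, threshold = 10, flank = 50,
                         weighting = "carrier", seed = 1L) {
  req <- c("cohort.vcf", "gene_models.tsv", "annotations.tsv",
           "phenotypes.tsv")
  paths <- file.path(input_dir, req)
  missing <- req[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0(
      "missing input file(s) in ", input_dir, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  opt <- function(f) {
    p <- file.path(input_dir, f)
    if (file.exists(p)) p else NULL
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))

  vcf <- read_vcf(file.path(input_dir, "cohort.vcf"))
  gene_models <- read_gene_models(file.path(input_dir, "gene_models.tsv"))
  annotations <- read_annotations(file.path(input_dir, "annotations.tsv"))
  phenotypes <- read_phenotypes(file.path(input_dir, "phenotypes.tsv"))
  rubric <- if (!is.null(opt("rubric.tsv"))) {
    read_rubric(opt("rubric.tsv"))
  } else {
    default_rubric()
  }
  sequences <- if (!is.null(opt("sequences.fasta"))) {
    s <- Biostrings::readDNAStringSet(opt("sequences.fasta"))
    setNames(as.character(s), names(s))
  } else {
    NULL
  }
  critical <- if (!is.null(opt("critical_exons.tsv"))) {
    ce <- readr::read_tsv(
      opt("critical_exons.tsv"), show_col_types = FALSE, progress = FALSE
    )
    setNames(as.integer(ce$first_critical_exon), ce$gene)
  } else {
    NULL
  }

  out <- function(f) file.path(out_dir, f)
  counts <- list()

  if (nrow(vcf$variants) == 0) {
    warn("VCF contains no variants; writing empty, schema-valid outputs")
    empty_scores <- score_variants(
      tibble(vid = character(0), category = character(0),
             verdict = character(0)),
      rubric
    )
    readr::write_tsv(
      mutate(vcf$variants, location = character(0),
             coding_subtype = character(0)),
      out("variants_classified.tsv"), progress = FALSE
    )
    readr::write_tsv(empty_scores, out("scores.tsv"), progress = FALSE)
    readr::write_tsv(empty_scores, out("heatmap.tsv"), progress = FALSE)
    readr::write_tsv(
      tibble(individual = character(0), gene = character(0),
             variant_count = integer(0), score_sum = double(0)),
      out("burden.tsv"), progress = FALSE
    )
    manifest <- list(
      tool = "crl4score",
      version = as.character(packageVersion("crl4score")),
      seed = as.integer(seed), threshold = threshold,
      weighting = weighting,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = as.list(tools::md5sum(list.files(input_dir,
                                                full.names = TRUE))),
      outputs = as.list(tools::md5sum(
        list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
      )),
      row_counts = list(variants = 0L)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(manifest = manifest)))
  }

  # --- annotate -------------------------------------------------------
  classified <- classify_location(
    vcf$variants, gene_models, flank = flank, sequences = sequences
  )
  loc_overall <- location_counts(classified)
  loc_by_gene <- location_counts(classified, per_gene = TRUE)
  readr::write_tsv(classified, out("variants_classified.tsv"),
                   progress = FALSE)
  readr::write_tsv(loc_overall, out("location_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(loc_by_gene, out("location_counts_by_gene.tsv"),
                   progress = FALSE)
  counts$variants <- nrow(classified)

  # --- score ----------------------------------------------------------
  consolidated <- consolidate_annotations(annotations, quiet = TRUE)
  if (!is.null(critical)) {
    consolidated <- apply_modifiers(
      consolidated, vcf$variants, gene_models, critical, flank = flank
    )
  }
  scores <- score_variants(consolidated, rubric, vids = vcf$variants$vid)
  heatmap <- build_heatmap(scores, threshold = threshold)
  readr::write_tsv(
    left_join(
      select(classified, "vid", "gene", "location"), scores, by = "vid"
    ),
    out("scores.tsv"),
    progress = FALSE
  )
  write_heatmap(heatmap, out("heatmap.tsv"))
  counts$scored <- nrow(scores)
  counts$heatmap <- nrow(heatmap$matrix)

  # --- genotype heatmaps ---------------------------------------------
  for (g in unique(vcf$variants$gene)) {
    gh <- genotype_heatmap(vcf$genotypes, vcf$variants, g)
    readr::write_tsv(
      gh$matrix, out(paste0("genotypes_", g, ".tsv")), progress = FALSE
    )
  }

  # --- burden ---------------------------------------------------------
  burden <- suppressMessages(individual_burden(
    vcf$genotypes, vcf$variants, scores, weighting = weighting
  ))
  burden_out <- burden |>
    left_join(phenotypes, by = "individual")
  readr::write_tsv(burden_out, out("burden.tsv"), progress = FALSE)
  counts$individuals <- dplyr::n_distinct(burden$individual)

  # --- comparisons ----------------------------------------------------
  comparisons <- bind_rows(
    compare_burden(burden, phenotypes, by = "count", per_gene = TRUE),
    compare_burden(burden, phenotypes, by = "score", per_gene = TRUE)
  )
  anova_res <- tryCatch(
    anova_burden(burden, phenotypes, by = "score"),
    error = function(e) NULL
  )
  if (!is.null(anova_res)) {
    comparisons <- bind_rows(
      comparisons,
      anova_res$result |>
        rename(df = "df1") |>
        select(-"df2")
    )
  }
  location_test <- NULL
  if (!is.null(opt("reference_location_counts.tsv"))) {
    ref_counts <- readr::read_tsv(
      opt("reference_location_counts.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
    sample_counts <- loc_overall |>
      filter(.data$location %in% ref_counts$location) |>
      select("location", "n")
    location_test <- compare_location_distribution(
      sample_counts, ref_counts
    )
    readr::write_tsv(location_test, out("location_comparison.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(comparisons, out("comparisons.tsv"), progress = FALSE)

  # --- per-variant association ---------------------------------------
  associations <- suppressMessages(
    list_rbind(map(
      heatmap$matrix$vid,
      function(v) {
        genotype_phenotype_test(
          v, vcf$genotypes, phenotypes, mode = "carrier"
        )
      }
    ))
  )
  if (nrow(associations) > 0) associations <- select(associations, -"table")
  readr::write_tsv(associations, out("associations.tsv"), progress = FALSE)
  counts$associations <- nrow(associations)

  # --- manifest -------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    tool = "crl4score",
    version = as.character(packageVersion("crl4score")),
    seed = as.integer(seed),
    threshold = threshold,
    weighting = weighting,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(tools::md5sum(
      list.files(input_dir, full.names = TRUE)
    )),
    outputs = as.list(tools::md5sum(outputs)),
    row_counts = counts
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    classified = classified, location_counts = loc_overall,
    scores = scores, heatmap = heatmap, burden = burden,
    comparisons = comparisons, anova = anova_res,
    location_test = location_test, associations = associations,
    manifest = manifest
  ))
}
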