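#' Read variants and genotypes from a VCF
#'
#' Parses a VCF 4.2 file (via `VariantAnnotation::readVcf`) into two tidy
#' tables: a variant catalogue and a long per-individual genotype table of
#' alt-allele dosages. Multi-allelic records are decomposed into one variant
#' per ALT allele (scoring and burden are per-allele); the dosage of each
#' decomposed variant is the number of copies of that specific allele in the
#' genotype. Missing genotypes (`./.`) become `NA`.
#'
#' The panel convention used throughout this package is that each gene is
#' represented on its own contig named after the gene symbol, so `gene` is
#' taken from the CHROM field.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param cohort_ids Optional character vector restricting and ordering the
#'   sample columns; an error is raised if any id is absent from the VCF.
#' @return A list with elements
#'   \describe{
#'     \item{variants}{tibble: `vid`, `chrom`, `pos` (1-based), `ref`,
#'       `alt`, `gene`.}
#'     \item{genotypes}{long tibble: `individual`, `vid`, `dosage`
#'       (0, 1, 2 or NA).}
#'   }
#' @export
read_vcf <- function(path, cohort_ids = NULL) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "panel")),
    error = function(e) {
      abort(paste0("malformed VCF '", path, "': ", conditionMessage(e)))
    }
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) abort("VCF has no GT genotype field")
  samples <- colnames(gt)
  if (!is.null(cohort_ids)) {
    missing <- setdiff(cohort_ids, samples)
    if (length(missing) > 0) {
      abort(paste0(
        "sample(s) absent from VCF: ", paste(missing, collapse = ", ")
      ))
    }
    gt <- gt[, cohort_ids, drop = FALSE]
    samples <- cohort_ids
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- rr$ALT
  ids <- names(rr)

  rows <- vector("list", length(rr))
  geno_rows <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    alts <- as.character(alt_list[[i]])
    alleles <- parse_gt_strings(gt[i, , drop = TRUE])
    for (a in seq_along(alts)) {
      vid <- ids[i]
      if (is.na(vid) || vid == "" || vid == ".") {
        vid <- paste(chrom[i], pos[i], ref[i], alts[a], sep = ":")
      } else if (length(alts) > 1) {
        vid <- paste0(vid, ":", alts[a])
      }
      ch <- chrom[i]
      rows[[length(rows) + 1]] <- tibble(
        vid = vid, chrom = ch, pos = pos[i],
        ref = ref[i], alt = alts[a], gene = ch
      )
      dosage <- colSums(alleles == a)
      dosage[apply(is.na(alleles), 2, any)] <- NA_integer_
      geno_rows[[length(geno_rows) + 1]] <- tibble(
        individual = samples, vid = vid, dosage = as.integer(dosage)
      )
    }
  }
  variants <- list_rbind(purrr::compact(rows))
  if (any(variants$ref == variants$alt)) {
    abort("VCF contains a record whose REF equals its ALT allele")
  }
  list(
    variants = variants,
    genotypes = list_rbind(purrr::compact(geno_rows))
  )
}

# GT strings -> 2 x n matrix of integer allele indices (NA for '.').
parse_gt_strings <- function(gts) {
  parts <- strsplit(gts, "[/|]")
  vapply(parts, function(p) {
    p <- c(p, rep(".", max(0, 2 - length(p))))[1:2]
    suppressWarnings(as.integer(ifelse(p == ".", NA, p)))
  }, integer(2))
}

#' Write variants and genotypes as a VCF 4.2 file
#'
#' Plain-text emitter for the biallelic records this package produces;
#' round-trips exactly through [read_vcf()]. Dosage 0/1/2 maps to genotypes
#' `0/0`, `0/1`, `1/1`; `NA` to `./.`.
#'
#' @param variants Variant tibble (`vid`, `chrom`, `pos`, `ref`, `alt`).
#' @param genotypes Long genotype tibble (`individual`, `vid`, `dosage`).
#' @param path Output file.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, contig_lengths = NULL) {
  assert_cols(variants, c("vid", "chrom", "pos", "ref", "alt"), "variants")
  assert_cols(genotypes, c("individual", "vid", "dosage"), "genotypes")
  samples <- unique(genotypes$individual)
  dmat <- genotypes |>
    tidyr::pivot_wider(names_from = "individual", values_from = "dosage") |>
    arrange(match(.data$vid, variants$vid))
  stopifnot(identical(dmat$vid, variants$vid))
  gt_code <- function(d) {
    dplyr::case_when(
      is.na(d) ~ "./.", d == 0 ~ "0/0", d == 1 ~ "0/1", d == 2 ~ "1/1"
    )
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crl4score",
    if (!is.null(contig_lengths)) {
      paste0(
        "##contig=<ID=", names(contig_lengths),
        ",length=", as.integer(contig_lengths), ">"
      )
    } else {
      paste0("##contig=<ID=", unique(variants$chrom), ">")
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(
      c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", samples),
      collapse = "\t"
    )
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(
      c(
        variants$chrom[i], variants$pos[i], variants$vid[i],
        variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
        gt_code(as.integer(dmat[i, samples]))
      ),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene-model feature table
#'
#' Gene models describe the sequenced panel: for each gene, its exons, CDS
#' and UTR intervals on the gene's own contig, in 0-based half-open
#' coordinates. The panel itself covers all exons and UTRs plus `flank` bp
#' of adjacent intron (default 50 bp).
#'
#' @param path TSV with columns `gene`, `transcript`, `strand`, `feature`
#'   (one of `exon`, `cds`, `utr5`, `utr3`), `start`, `end`.
#' @return Validated tibble of features.
#' @export
read_gene_models <- function(path) {
  gm <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = "c", transcript = "c", strand = "c", feature = "c",
      start = "i", end = "i"
    ),
    progress = FALSE
  )
  validate_gene_models(gm)
}

validate_gene_models <- function(gm) {
  assert_cols(
    gm, c("gene", "transcript", "strand", "feature", "start", "end"),
    "gene models"
  )
  if (!all(gm$feature %in% c("exon", "cds", "utr5", "utr3"))) {
    abort("gene-model feature must be one of exon, cds, utr5, utr3")
  }
  if (!all(gm$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(gm$start < 0 | gm$end <= gm$start)) {
    abort("gene-model intervals must satisfy 0 <= start < end")
  }
  # sub-features must lie inside exons; intervals per (gene, feature)
  # must be disjoint
  by_gene <- split(gm, gm$gene)
  for (g in by_gene) {
    for (feat in unique(g$feature)) {
      iv <- g[g$feature == feat, ] |> arrange(.data$start)
      if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
        abort(paste0(
          "overlapping ", feat, " intervals in gene ", g$gene[1]
        ))
      }
    }
    ex <- g[g$feature == "exon", ]
    sub <- g[g$feature != "exon", ]
    if (nrow(sub) > 0 && nrow(ex) > 0) {
      ok <- map_lgl(seq_len(nrow(sub)), function(i) {
        any(ex$start <= sub$start[i] & sub$end[i] <= ex$end)
      })
      if (!all(ok)) {
        abort(paste0(
          "cds/utr interval outside any exon in gene ", g$gene[1]
        ))
      }
    }
  }
  as_tibble(gm)
}

#' Panel windows for a gene model
#'
#' The targeted intervals: exons widened by `flank` bp of intron on each
#' side, merged. Positions outside these windows were not sequenced and are
#' flagged `out_of_panel` by [classify_location()].
#'
#' @param gene_models Gene-model tibble.
#' @param flank Intronic flank width in bp (default 50).
#' @return Tibble: `gene`, `start`, `end` (0-based half-open, merged).
#' @export
panel_windows <- function(gene_models, flank = 50) {
  gene_models |>
    filter(.data$feature == "exon") |>
    mutate(start = pmax(0L, .data$start - as.integer(flank)),
           end = .data$end + as.integer(flank)) |>
    group_by(.data$gene) |>
    arrange(.data$start, .by_group = TRUE) |>
    group_by(.data$gene) |>
    dplyr::group_modify(~ merge_intervals(.x)) |>
    ungroup() |>
    select("gene", "start", "end")
}

merge_intervals <- function(iv) {
  iv <- arrange(iv, .data$start)
  out_start <- integer(0)
  out_end <- integer(0)
  for (i in seq_len(nrow(iv))) {
    if (length(out_end) > 0 && iv$start[i] <= out_end[length(out_end)]) {
      out_end[length(out_end)] <- max(out_end[length(out_end)], iv$end[i])
    } else {
      out_start <- c(out_start, iv$start[i])
      out_end <- c(out_end, iv$end[i])
    }
  }
  tibble(start = out_start, end = out_end)
}

#' Classify the genomic location of each variant
#'
#' Assigns each variant one of `coding`, `utr5`, `utr3`, `intronic_flank`,
#' or `out_of_panel`, against its gene's model. A position is `coding` when
#' it overlaps a CDS interval, a UTR when it overlaps the respective UTR
#' interval, `intronic_flank` when it falls inside the panel window but in
#' no exon, and `out_of_panel` otherwise (flagged, not fatal — such calls
#' are outside the sequenced design). When `sequences` is supplied, coding
#' SNVs are further subtyped `synonymous` / `missense` / `nonsense` by codon
#' translation (reverse-complemented for minus-strand genes).
#'
#' @param variants Variant tibble (`vid`, `gene`, `pos`, `ref`, `alt`).
#' @param gene_models Gene-model tibble.
#' @param flank Intronic flank width (default 50).
#' @param sequences Optional named character vector (or `DNAStringSet`) of
#'   gene contig sequences, enabling coding subtype calls.
#' @return The variant tibble with columns `location` and `coding_subtype`
#'   (NA outside CDS or without sequence).
#' @export
classify_location <- function(variants, gene_models, flank = 50,
                              sequences = NULL) {
  assert_cols(variants, c("vid", "gene", "pos"), "variants")
  if (!is.null(sequences)) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  windows <- panel_windows(gene_models, flank)
  loc <- character(nrow(variants))
  subtype <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene[i]
    gmg <- filter(gene_models, .data$gene == !!g)
    if (nrow(gmg) == 0) {
      abort(paste0("no gene model for gene ", g))
    }
    p0 <- variants$pos[i] - 1L
    if (p0 < 0) abort("variant position must be >= 1")
    if (!is.null(sequences) && g %in% names(sequences) &&
        p0 >= nchar(sequences[[g]])) {
      abort(paste0(
        "variant ", variants$vid[i], " lies beyond the end of contig ", g
      ))
    }
    w <- filter(windows, .data$gene == !!g)
    inside <- function(feat) {
      iv <- gmg[gmg$feature == feat, ]
      nrow(iv) > 0 && any(iv$start <= p0 & p0 < iv$end)
    }
    if (!any(w$start <= p0 & p0 < w$end)) {
      loc[i] <- "out_of_panel"
    } else if (inside("cds")) {
      loc[i] <- "coding"
      if (!is.null(sequences) && g %in% names(sequences)) {
        subtype[i] <- coding_subtype(
          variants$pos[i], variants$ref[i], variants$alt[i],
          gmg, sequences[[g]]
        )
      }
    } else if (inside("utr5")) {
      loc[i] <- "utr5"
    } else if (inside("utr3")) {
      loc[i] <- "utr3"
    } else {
      loc[i] <- "intronic_flank"
    }
  }
  variants |>
    mutate(location = loc, coding_subtype = subtype)
}

# Synonymous / missense / nonsense call for a coding SNV.
coding_subtype <- function(pos, ref, alt, gmg, seq) {
  if (nchar(ref) != 1 || nchar(alt) != 1) {
    return(NA_character_)
  }
  cds <- gmg |>
    filter(.data$feature == "cds") |>
    arrange(.data$start)
  p0 <- pos - 1L
  seq_ref <- substr(seq, pos, pos)
  if (seq_ref != ref) {
    abort(paste0(
      "reference allele mismatch at ", gmg$gene[1], ":", pos,
      " (sequence has ", seq_ref, ", variant says ", ref, ")"
    ))
  }
  cds_seq <- paste0(
    vapply(seq_len(nrow(cds)), function(i) {
      substr(seq, cds$start[i] + 1L, cds$end[i])
    }, character(1)),
    collapse = ""
  )
  prior <- sum(pmax(0L, pmin(cds$end, p0) - cds$start))
  offset_plus <- prior # 0-based offset on the + strand CDS concatenation
  strand <- gmg$strand[1]
  if (strand == "-") {
    cds_seq <- revcomp(cds_seq)
    offset <- nchar(cds_seq) - 1L - offset_plus
    alt_base <- chartr("ACGT", "TGCA", alt)
  } else {
    offset <- offset_plus
    alt_base <- alt
  }
  codon_i <- offset %/% 3L
  within <- offset %% 3L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "nonsense"
  } else {
    "missense"
  }
}

location_levels <- function() {
  c("coding", "utr5", "utr3", "intronic_flank", "out_of_panel")
}

#' Tally variant locations
#'
#' Counts classified variants per location category, overall or per gene,
#' with percentage shares. Percentages are truncated (not rounded) to one
#' decimal, matching the convention under which 11 coding variants out of
#' 145 are reported as a 7.5% coding share.
#'
#' @param classified Output of [classify_location()].
#' @param per_gene Tally per gene instead of overall.
#' @return Tibble with (`gene`,) `location`, `n`, `pct`.
#' @export
location_counts <- function(classified, per_gene = FALSE) {
  assert_cols(classified, "location", "classified variants")
  levels_present <- location_levels()
  if (!"out_of_panel" %in% classified$location) {
    levels_present <- setdiff(levels_present, "out_of_panel")
  }
  grouping <- if (per_gene) c("gene", "location") else "location"
  base <- if (per_gene) {
    tidyr::expand_grid(
      gene = unique(classified$gene), location = levels_present
    )
  } else {
    tibble(location = levels_present)
  }
  tallied <- classified |>
    count(across(all_of(grouping)), name = "n") |>
    dplyr::right_join(base, by = grouping) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  if (per_gene) {
    tallied <- tallied |>
      group_by(.data$gene) |>
      mutate(pct = trunc1(100 * .data$n / sum(.data$n))) |>
      ungroup() |>
      arrange(.data$gene, match(.data$location, location_levels()))
  } else {
    tallied <- tallied |>
      mutate(pct = trunc1(100 * .data$n / sum(.data$n))) |>
      arrange(match(.data$location, location_levels()))
  }
  tallied
}

#' Read a phenotype table
#'
#' @param path TSV with columns `individual`, `cohort` (`case` or
#'   `reference`) and `endophenotype` (`pre_axial_longitudinal`,
#'   `intercalary_transverse`, `other`, `none`).
#' @return Validated tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  assert_cols(ph, c("individual", "cohort", "endophenotype"), "phenotypes")
  if (anyDuplicated(ph$individual)) {
    abort("each individual must appear exactly once in the phenotype table")
  }
  if (!all(ph$cohort %in% c("case", "reference"))) {
    abort("cohort must be 'case' or 'reference'")
  }
  ok <- c("pre_axial_longitudinal", "intercalary_transverse", "other", "none")
  if (!all(ph$endophenotype %in% ok)) {
    abort(paste0(
      "endophenotype must be one of ", paste(ok, collapse = ", ")
    ))
  }
  as_tibble(ph)
}
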