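#' Read a normalized predictor-annotation table
#'
#' Annotations are the normalized verdicts of external functional predictors
#' (ensemble deleteriousness tools, splice-site tools, PWM scanners, ...),
#' one row per (variant, category, source). Running the predictors themselves
#' is out of scope: their output is ingested here already mapped onto the
#' rubric's categories and verdict levels.
#'
#' @param path TSV with columns `vid`, `category`, `verdict`, `source`.
#' @return Tibble with those columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(ann, c("vid", "category", "verdict"), "annotation table")
  if (!"source" %in% names(ann)) ann$source <- NA_character_
  check_annotation_values(ann)
  as_tibble(ann[c("vid", "category", "verdict", "source")])
}

check_annotation_values <- function(ann) {
  bad_cat <- setdiff(unique(ann$category), rubric_categories())
  if (length(bad_cat) > 0) {
    abort(paste0(
      "unknown annotation category: ", paste(bad_cat, collapse = ", ")
    ))
  }
  bad_v <- setdiff(unique(ann$verdict), verdict_levels())
  if (length(bad_v) > 0) {
    abort(paste0("unknown verdict: ", paste(bad_v, collapse = ", ")))
  }
  invisible(ann)
}

#' Consolidate raw predictor annotations to one verdict per category
#'
#' Several predictors can feed the same evidence category (e.g. two splicing
#' tools). Consolidation keeps, per (variant, category), the single most
#' severe verdict; ties at equal severity keep the first record and note the
#' duplication. Categories with no record at all are simply absent — scoring
#' treats them as `none`.
#'
#' @param annotations Tibble with `vid`, `category`, `verdict` and optionally
#'   `source`.
#' @param quiet Suppress the duplicate-record message.
#' @return Tibble with one row per (vid, category): `vid`, `category`,
#'   `verdict`, `source`.
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   vid = "rs1", category = "splicing",
#'   verdict = c("possible", "strong"), source = c("toolA", "toolB")
#' )
#' consolidate_annotations(raw)
consolidate_annotations <- function(annotations, quiet = FALSE) {
  assert_cols(annotations, c("vid", "category", "verdict"), "annotations")
  if (!"source" %in% names(annotations)) annotations$source <- NA_character_
  check_annotation_values(annotations)
  ranked <- annotations |>
    mutate(.rank = verdict_rank(.data$verdict), .row = row_number())
  ties <- ranked |>
    group_by(.data$vid, .data$category) |>
    filter(sum(.data$.rank == max(.data$.rank)) > 1) |>
    ungroup()
  if (nrow(ties) > 0 && !quiet) {
    inform(paste0(
      nrow(distinct(ties, .data$vid, .data$category)),
      " (vid, category) pair(s) had duplicate records at equal severity;",
      " keeping the first"
    ))
  }
  ranked |>
    group_by(.data$vid, .data$category) |>
    arrange(desc(.data$.rank), .data$.row, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$vid, match(.data$category, rubric_categories())) |>
    select("vid", "category", "verdict", "source")
}

#' Promote splicing verdicts for variants upstream of critical exons
#'
#' Gene-model knowledge modifies predictor verdicts: any splicing alteration
#' in or adjacent to an exon that lies 5' of the first *critical* exon (an
#' exon whose loss removes an essential protein domain, e.g. a C-terminal
#' drug-binding region) is treated as severe, because mis-splicing there can
#' truncate everything downstream. Concretely, a `splicing` verdict of
#' `possible` is promoted to `strong` when the variant falls within an exon,
#' or within `flank` bp of an exon boundary, whose 5'-to-3' index is below
#' the gene's first critical exon. Promotion stays inside the rubric's
#' verdict scale, so the 20-point ceiling is preserved.
#'
#' @param annotations Consolidated annotation tibble.
#' @param variants Variant tibble (`vid`, `gene`, `pos`).
#' @param gene_models Gene-model feature tibble (see [read_gene_models()]).
#' @param critical_exons Named integer vector: first critical exon (1-based,
#'   5'-to-3') per gene. Genes absent from the vector are left untouched.
#' @param flank Intronic window, in bp, around each exon (default 50).
#' @return The annotation tibble with promoted `splicing` verdicts.
#' @export
apply_modifiers <- function(annotations, variants, gene_models,
                            critical_exons, flank = 50) {
  assert_cols(variants, c("vid", "gene", "pos"), "variants")
  spl <- annotations$category == "splicing" &
    annotations$verdict == "possible"
  if (!any(spl)) {
    return(annotations)
  }
  idx <- which(spl)
  vmap <- variants[match(annotations$vid[idx], variants$vid), ]
  promote <- map_lgl(seq_along(idx), function(i) {
    gene <- vmap$gene[i]
    if (is.na(gene) || !gene %in% names(critical_exons)) {
      return(FALSE)
    }
    exons <- exon_table(gene_models, gene)
    if (nrow(exons) == 0) {
      return(FALSE)
    }
    p0 <- vmap$pos[i] - 1L
    hit <- exons$start - flank <= p0 & p0 < exons$end + flank
    any(hit & exons$exon_index < critical_exons[[gene]])
  })
  annotations$verdict[idx[promote]] <- "strong"
  annotations
}

# Exons of one gene with 5'-to-3' indices (strand-aware).
exon_table <- function(gene_models, gene) {
  ex <- gene_models |>
    filter(.data$gene == !!gene, .data$feature == "exon") |>
    arrange(.data$start)
  if (nrow(ex) == 0) {
    return(ex)
  }
  ord <- if (ex$strand[1] == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  ex$exon_index <- ord
  ex
}

#' Score variants under a severity rubric
#'
#' Converts consolidated verdicts into points and sums them per variant.
#' A category with no annotation contributes 0 (the rubric scores predicted
#' effects; absence of a prediction is not missing data). The result is a
#' wide tibble: one row per variant, one column per category, plus `total`.
#'
#' @param annotations Consolidated annotation tibble (`vid`, `category`,
#'   `verdict`).
#' @param rubric Rubric tibble; defaults to [default_rubric()].
#' @param vids Optional character vector of variant ids that must appear in
#'   the output even if they carry no annotation (they score 0).
#' @return Tibble with columns `vid`, one per rubric category, and `total`.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   vid = "rs1", category = c("splicing", "tfbs"),
#'   verdict = c("strong", "possible")
#' )
#' score_variants(ann)$total  # 3
score_variants <- function(annotations, rubric = default_rubric(),
                           vids = NULL) {
  validate_rubric(rubric)
  assert_cols(annotations, c("vid", "category", "verdict"), "annotations")
  check_annotation_values(annotations)
  vids <- union(vids %||% character(), unique(annotations$vid))
  cats <- rubric_categories()
  if (length(vids) == 0) {
    empty <- as_tibble(setNames(
      c(list(character(0)), rep(list(integer(0)), length(cats) + 1)),
      c("vid", cats, "total")
    ))
    return(empty)
  }
  pts <- annotations |>
    inner_join(rubric, by = c("category", "verdict")) |>
    select("vid", "category", "points")
  wide <- tidyr::expand_grid(vid = vids, category = cats) |>
    left_join(pts, by = c("vid", "category")) |>
    mutate(points = dplyr::coalesce(.data$points, 0L)) |>
    tidyr::pivot_wider(names_from = "category", values_from = "points")
  wide$total <- as.integer(rowSums(wide[cats]))
  arrange(wide, .data$vid)
}

#' Build the severity heatmap
#'
#' The reporting artefact of the scoring stage: a variants-by-categories
#' points matrix restricted to variants whose total meets the reporting
#' threshold (default 10, i.e. half the 20-point ceiling), ordered by total
#' descending and then by variant id for determinism. The unfiltered score
#' table is retained in the object.
#'
#' @param scores Wide score tibble from [score_variants()].
#' @param threshold Minimum total for inclusion (default 10).
#' @return An object of class `crl4_heatmap`: a list with elements `matrix`
#'   (the filtered, ordered tibble), `threshold`, and `full` (all scores).
#' @export
build_heatmap <- function(scores, threshold = 10) {
  assert_cols(scores, c("vid", "total"), "scores")
  kept <- scores |>
    filter(.data$total >= threshold) |>
    arrange(desc(.data$total), .data$vid)
  if (nrow(kept) == 0) {
    warn("no variant reaches the heatmap threshold; heatmap is empty")
  }
  structure(
    list(matrix = kept, threshold = threshold, full = scores),
    class = "crl4_heatmap"
  )
}

#' @export
print.crl4_heatmap <- function(x, ...) {
  cat(
    "Severity heatmap: ", nrow(x$matrix), " of ", nrow(x$full),
    " variant(s) with total >= ", x$threshold, "\n",
    sep = ""
  )
  print(x$matrix, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a severity heatmap into long format
#'
#' @param x A `crl4_heatmap`.
#' @param ... Unused.
#' @return Long tibble: `vid`, `category`, `points`, `total`.
#' @export
tidy.crl4_heatmap <- function(x, ...) {
  x$matrix |>
    tidyr::pivot_longer(
      all_of(rubric_categories()),
      names_to = "category", values_to = "points"
    ) |>
    select("vid", "category", "points", "total")
}

#' One-row summary of a severity heatmap
#'
#' @inheritParams tidy.crl4_heatmap
#' @return One-row tibble: threshold, number of variants scored and retained,
#'   and the maximum/mean retained total.
#' @export
glance.crl4_heatmap <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    n_scored = nrow(x$full),
    n_retained = nrow(x$matrix),
    max_total = if (nrow(x$matrix)) max(x$matrix$total) else NA_integer_,
    mean_total = if (nrow(x$matrix)) mean(x$matrix$total) else NA_real_
  )
}

#' Write the heatmap matrix as TSV
#'
#' @param x A `crl4_heatmap`.
#' @param path Output file.
#' @param filtered Write the thresholded matrix (default) or the full one.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(x, path, filtered = TRUE) {
  stopifnot(inherits(x, "crl4_heatmap"))
  tab <- if (filtered) x$matrix else arrange(x$full, desc(.data$total), .data$vid)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
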