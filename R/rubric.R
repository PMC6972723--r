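#' Functional-prediction categories used by the severity rubric
#'
#' The ten categories of in-silico evidence that the scoring rubric
#' aggregates. Each category summarises one family of external predictors:
#' ensemble deleteriousness scores, protein-level effect predictors,
#' splicing-motif tools, polyadenylation-signal tools, transcription-factor
#' binding-site disruption, microRNA binding-site disruption, CpG-island
#' impact, mRNA secondary-structure/stability change, enhancer overlap, and
#' synonymous codon-usage shift.
#'
#' @return Character vector of the ten category names, in canonical order.
#' @export
#' @examples
#' rubric_categories()
rubric_categories <- function() {
  c(
    "ensemble_deleteriousness", "protein_effect", "splicing",
    "polyadenylation", "tfbs", "mirna_binding", "cpg_island",
    "mrna_structure", "enhancer", "codon_usage"
  )
}

#' Verdict levels recognised by the rubric
#'
#' Ordered from least to most severe. `none` means no predictor in the
#' category flagged the variant; `possible` a weak or single-tool call;
#' `strong` a confident or multi-tool call.
#'
#' @return Character vector `c("none", "possible", "strong")`.
#' @export
verdict_levels <- function() c("none", "possible", "strong")

verdict_rank <- function(verdict) {
  match(verdict, verdict_levels())
}

#' Default severity rubric
#'
#' Maps each (category, verdict) pair to a point value. The default awards
#' 0 points for `none`, 1 for `possible` and 2 for `strong` in every one of
#' the ten categories, so the maximum attainable per-variant total is 20 —
#' the ceiling of the published 1–20 score range. Alternative weightings can
#' be supplied as a tibble with the same columns (see [read_rubric()]).
#'
#' @return A tibble with columns `category`, `verdict`, `points`.
#' @export
#' @examples
#' default_rubric()
#' rubric_max_total(default_rubric())
default_rubric <- function() {
  tidyr::expand_grid(
    category = rubric_categories(),
    verdict = verdict_levels()
  ) |>
    mutate(points = c(none = 0L, possible = 1L, strong = 2L)[.data$verdict])
}

#' Validate a rubric table
#'
#' Checks the structural invariants every rubric must satisfy: all ten
#' categories present with all three verdicts, `none` worth 0 points,
#' points non-negative and monotone non-decreasing in verdict severity.
#'
#' @param rubric A rubric tibble (`category`, `verdict`, `points`).
#' @return The rubric, invisibly, if valid; otherwise an error.
#' @export
validate_rubric <- function(rubric) {
  assert_cols(rubric, c("category", "verdict", "points"), "rubric")
  bad_cat <- setdiff(unique(rubric$category), rubric_categories())
  if (length(bad_cat) > 0) {
    abort(paste0("unknown rubric category: ", paste(bad_cat, collapse = ", ")))
  }
  full <- tidyr::expand_grid(
    category = rubric_categories(), verdict = verdict_levels()
  )
  if (nrow(anti_join(full, rubric, by = c("category", "verdict"))) > 0) {
    abort("rubric must define points for every category x verdict pair")
  }
  if (any(rubric$points < 0)) abort("rubric points must be non-negative")
  if (any(rubric$points[rubric$verdict == "none"] != 0)) {
    abort("rubric must award 0 points for verdict 'none'")
  }
  mono <- rubric |>
    mutate(rank = verdict_rank(.data$verdict)) |>
    arrange(.data$category, .data$rank) |>
    group_by(.data$category) |>
    summarise(ok = !is.unsorted(.data$points), .groups = "drop")
  if (!all(mono$ok)) {
    abort("rubric points must be monotone non-decreasing in verdict severity")
  }
  invisible(rubric)
}

#' Maximum total score attainable under a rubric
#'
#' The sum over categories of the per-category maximum point value — the
#' score a variant would receive if every evidence category returned its most
#' severe verdict. Equals 20 for the default rubric.
#'
#' @param rubric A rubric tibble; defaults to [default_rubric()].
#' @return Integer scalar.
#' @export
rubric_max_total <- function(rubric = default_rubric()) {
  validate_rubric(rubric)
  rubric |>
    group_by(.data$category) |>
    summarise(mx = max(.data$points), .groups = "drop") |>
    pull("mx") |>
    sum() |>
    as.integer()
}

#' Read / write a rubric as tab-separated text
#'
#' @param path Path to a TSV with columns `category`, `verdict`, `points`.
#' @return `read_rubric()` returns a validated rubric tibble;
#'   `write_rubric()` returns `path` invisibly.
#' @export
read_rubric <- function(path) {
  rubric <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rubric$points <- as.integer(rubric$points)
  validate_rubric(rubric)
  rubric
}

#' @rdname read_rubric
#' @param rubric A rubric tibble.
#' @export
write_rubric <- function(rubric, path) {
  validate_rubric(rubric)
  readr::write_tsv(rubric, path, progress = FALSE)
  invisible(path)
}
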