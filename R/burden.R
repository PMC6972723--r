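#' Per-individual variant burden
#'
#' Aggregates, for every individual, the number of carried variants and the
#' sum of their severity scores, per gene. Two weightings are supported:
#' `carrier` (the default) counts each carried variant once regardless of
#' zygosity — matching a genotype-presence reading of the burden — while
#' `dosage` multiplies by the alt-allele count, so homozygotes contribute
#' twice. Missing genotypes are excluded from that individual's sums.
#' Variants without a score contribute to counts with score 0 (noted).
#'
#' @param genotypes Long genotype tibble (`individual`, `vid`, `dosage`).
#' @param variants Variant tibble (`vid`, `gene`).
#' @param scores Score tibble (`vid`, `total`), e.g. from
#'   [score_variants()]. May be `NULL` for count-only burden.
#' @param weighting `"carrier"` or `"dosage"`.
#' @return Tibble: `individual`, `gene`, `variant_count`, `score_sum`, one
#'   row per individual x gene.
#' @export
individual_burden <- function(genotypes, variants, scores = NULL,
                              weighting = c("carrier", "dosage")) {
  weighting <- match.arg(weighting)
  assert_cols(genotypes, c("individual", "vid", "dosage"), "genotypes")
  assert_cols(variants, c("vid", "gene"), "variants")
  inds <- unique(genotypes$individual)
  vids <- variants$vid
  m <- matrix(
    NA_integer_, length(inds), length(vids),
    dimnames = list(inds, vids)
  )
  keep <- genotypes$vid %in% vids
  m[cbind(
    match(genotypes$individual[keep], inds),
    match(genotypes$vid[keep], vids)
  )] <- genotypes$dosage[keep]
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    inform(paste0(
      n_missing, " missing genotype(s) excluded from burden sums"
    ))
  }
  w <- if (weighting == "carrier") {
    (!is.na(m) & m >= 1) * 1
  } else {
    mm <- m
    mm[is.na(mm)] <- 0L
    mm
  }
  s <- if (is.null(scores)) {
    setNames(rep(0, length(vids)), vids)
  } else {
    assert_cols(scores, c("vid", "total"), "scores")
    sv <- setNames(scores$total[match(vids, scores$vid)], vids)
    if (anyNA(sv)) {
      inform(paste0(
        sum(is.na(sv)),
        " variant(s) without a score contribute count only (score 0)"
      ))
      sv[is.na(sv)] <- 0
    }
    sv
  }
  genes <- split(vids, variants$gene[match(vids, variants$vid)])
  rows <- imap(genes, function(gv, gene) {
    wg <- w[, gv, drop = FALSE]
    tibble(
      individual = inds,
      gene = gene,
      variant_count = as.integer(rowSums(wg)),
      score_sum = as.numeric(wg %*% s[gv])
    )
  })
  list_rbind(unname(rows)) |>
    arrange(.data$individual, .data$gene)
}

#' Total burden per individual across all genes
#'
#' @param profiles Output of [individual_burden()].
#' @return Tibble: `individual`, `variant_count`, `score_sum`.
#' @export
total_burden <- function(profiles) {
  profiles |>
    group_by(.data$individual) |>
    summarise(
      variant_count = sum(.data$variant_count),
      score_sum = sum(.data$score_sum),
      .groups = "drop"
    )
}

burden_values <- function(profiles, by, gene = NULL) {
  col <- if (by == "score") "score_sum" else "variant_count"
  tab <- if (is.null(gene)) {
    total_burden(profiles)
  } else {
    filter(profiles, .data$gene == !!gene)
  }
  setNames(tab[[col]], tab$individual)
}

two_sample_t <- function(x, y, welch = FALSE) {
  res <- tryCatch(
    t.test(x, y, var.equal = !welch),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # degenerate variance: both groups constant
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      list(statistic = 0, parameter = length(x) + length(y) - 2,
           p.value = 1)
    } else {
      inform("zero within-group variance with unequal means; p set to 0")
      list(statistic = sign(mean(x) - mean(y)) * Inf,
           parameter = length(x) + length(y) - 2, p.value = 0)
    }
  } else {
    list(statistic = unname(res$statistic),
         parameter = unname(res$parameter), p.value = res$p.value)
  }
}

#' Compare burden between two groups
#'
#' Two-sided independent two-sample t-test of per-individual burden (variant
#' count or score sum) between two groups, overall and optionally per gene.
#' The default is the pooled-variance Student's t (equal variances assumed);
#' `welch = TRUE` switches to Welch's t. No multiple-testing correction is
#' applied by default — nominal p-values are reported — but
#' `adjust = "BH"` adds a Benjamini-Hochberg column across the returned
#' rows.
#'
#' @param profiles Output of [individual_burden()].
#' @param phenotypes Phenotype tibble (`individual`, plus the grouping
#'   column).
#' @param by Burden measure: `"score"` (default) or `"count"`.
#' @param group_col Column of `phenotypes` defining groups (default
#'   `"cohort"`).
#' @param groups Length-2 character vector of group levels to compare;
#'   default the first two levels present, with `c("case", "reference")`
#'   preferred when `group_col` is `"cohort"`.
#' @param per_gene Also test each gene separately.
#' @param welch Use Welch's t instead of the pooled-variance test.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble of comparisons: `gene` (`"overall"` or a gene symbol),
#'   `test`, `by`, `group1`, `group2`, `n1`, `n2`, `mean1`, `mean2`,
#'   `mean_diff`, `statistic`, `df`, `p_value` (and `p_adjusted`).
#' @export
compare_burden <- function(profiles, phenotypes, by = c("score", "count"),
                           group_col = "cohort", groups = NULL,
                           per_gene = FALSE, welch = FALSE,
                           adjust = c("none", "BH")) {
  by <- match.arg(by)
  adjust <- match.arg(adjust)
  assert_cols(phenotypes, c("individual", group_col), "phenotypes")
  if (is.null(groups)) {
    lv <- unique(phenotypes[[group_col]])
    groups <- if (group_col == "cohort" &&
                  all(c("case", "reference") %in% lv)) {
      c("case", "reference")
    } else {
      lv[1:2]
    }
  }
  if (length(groups) != 2) abort("compare_burden needs exactly two groups")
  ids <- map(groups, function(g) {
    phenotypes$individual[phenotypes[[group_col]] == g]
  })
  if (any(lengths(ids) < 2)) {
    abort("both groups need at least two individuals")
  }
  scopes <- c(
    list(NULL),
    if (per_gene) as.list(sort(unique(profiles$gene)))
  )
  rows <- map(scopes, function(g) {
    v <- burden_values(profiles, by, g)
    x <- v[names(v) %in% ids[[1]]]
    y <- v[names(v) %in% ids[[2]]]
    tt <- two_sample_t(x, y, welch)
    tibble(
      gene = g %||% "overall",
      test = if (welch) "welch_t" else "t_test", by = by,
      group1 = groups[1], group2 = groups[2],
      n1 = length(x), n2 = length(y),
      mean1 = mean(x), mean2 = mean(y),
      mean_diff = mean(x) - mean(y),
      statistic = tt$statistic, df = tt$parameter, p_value = tt$p.value
    )
  })
  out <- list_rbind(rows)
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_value, "BH")
  out
}

#' One-way ANOVA of burden across three or more groups
#'
#' Tests whether mean burden differs across groups — typically the two
#' case endophenotype subgroups against the reference panel. Individuals
#' whose group label is not in `groups` are excluded. Uses the classical
#' equal-variance one-way ANOVA.
#'
#' @inheritParams compare_burden
#' @param groups Character vector (length >= 3) of group labels. The
#'   default compares the two limb-defect endophenotypes with the reference
#'   panel; labels are taken from `endophenotype` for case individuals and
#'   `"reference"` for panel individuals.
#' @param gene Restrict to one gene (default: overall burden).
#' @return Object of class `crl4_anova`: list with `result` (one-row
#'   tibble: `test`, `by`, `gene`, `statistic`, `df1`, `df2`, `p_value`)
#'   and `group_summary` (per-group `n`, `mean`, `sd`).
#' @export
anova_burden <- function(profiles, phenotypes, by = c("score", "count"),
                         groups = c("pre_axial_longitudinal",
                                    "intercalary_transverse", "reference"),
                         gene = NULL) {
  by <- match.arg(by)
  assert_cols(
    phenotypes, c("individual", "cohort", "endophenotype"), "phenotypes"
  )
  if (length(groups) < 3) abort("anova_burden needs at least three groups")
  labels <- if_else(
    phenotypes$cohort == "reference", "reference", phenotypes$endophenotype
  )
  v <- burden_values(profiles, by, gene)
  df <- tibble(
    individual = phenotypes$individual, group = labels
  ) |>
    filter(.data$group %in% groups) |>
    mutate(value = unname(v[.data$individual]))
  counts <- count(df, .data$group)
  missing_groups <- setdiff(groups, counts$group)
  if (length(missing_groups) > 0 || any(counts$n < 2)) {
    abort("every ANOVA group needs at least two individuals")
  }
  fit <- oneway.test(value ~ group, data = df, var.equal = TRUE)
  structure(
    list(
      result = tibble(
        test = "anova", by = by, gene = gene %||% "overall",
        statistic = unname(fit$statistic),
        df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
        p_value = fit$p.value
      ),
      group_summary = df |>
        group_by(.data$group) |>
        summarise(
          n = n(), mean = mean(.data$value), sd = stats::sd(.data$value),
          .groups = "drop"
        ) |>
        arrange(match(.data$group, groups))
    ),
    class = "crl4_anova"
  )
}

#' @export
print.crl4_anova <- function(x, ...) {
  r <- x$result
  cat(
    "One-way ANOVA of ", r$by, " burden (", r$gene, "): F(",
    r$df1, ", ", round(r$df2, 1), ") = ", signif(r$statistic, 4),
    ", p = ", signif(r$p_value, 3), "\n",
    sep = ""
  )
  print(x$group_summary)
  invisible(x)
}

#' @export
tidy.crl4_anova <- function(x, ...) x$group_summary

#' @export
glance.crl4_anova <- function(x, ...) x$result

#' Compare a variant-location distribution with a reference panel
#'
#' Pearson chi-square test of homogeneity on the 2 x k table of location
#' counts (sample vs reference). When any expected cell count falls below
#' 1 the asymptotic test is unreliable; a Monte-Carlo p-value (conditional
#' on the margins) is then reported alongside, with a warning.
#'
#' @param sample_counts,reference_counts Tibbles with columns `location`
#'   and `n` over the same category set.
#' @param mc_replicates Monte-Carlo replicates for the fallback p-value.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `mc_p_value` (NA unless the fallback triggered).
#' @export
compare_location_distribution <- function(sample_counts, reference_counts,
                                          mc_replicates = 10000) {
  assert_cols(sample_counts, c("location", "n"), "sample counts")
  assert_cols(reference_counts, c("location", "n"), "reference counts")
  cats <- sample_counts$location
  if (!setequal(cats, reference_counts$location)) {
    abort("sample and reference must share the same location categories")
  }
  tab <- rbind(
    sample = sample_counts$n[match(cats, sample_counts$location)],
    reference = reference_counts$n[match(cats, reference_counts$location)]
  )
  colnames(tab) <- cats
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  mc_p <- NA_real_
  if (any(res$expected < 1)) {
    warn("expected cell count < 1; reporting a Monte-Carlo p-value as well")
    mc_p <- suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = mc_replicates)$p.value
    )
  }
  tibble(
    test = "chisq", statistic = unname(res$statistic),
    df = unname(res$parameter), p_value = res$p.value, mc_p_value = mc_p
  )
}

#' Genotype-endophenotype association for one variant
#'
#' Builds the contingency table of carrier status (`carrier` mode: 2 x 2,
#' carrier vs non-carrier) or full genotype (`genotype` mode: 2 x 3,
#' dosage 0/1/2) against two endophenotype groups, and tests it with the
#' Pearson chi-square (no continuity correction). For 2 x 2 tables the
#' Fisher exact p-value is reported alongside. Monomorphic variants (or
#' degenerate tables with an all-zero row/column margin) are skipped with a
#' notice.
#'
#' @param vid Variant id.
#' @param genotypes Long genotype tibble.
#' @param phenotypes Phenotype tibble.
#' @param mode `"carrier"` or `"genotype"`.
#' @param groups Length-2 vector of endophenotype levels to contrast.
#' @return Tibble with zero rows (skipped) or one row: `vid`, `mode`,
#'   `test`, `statistic`, `df`, `p_value`, `fisher_p`, `odds_ratio`
#'   (2 x 2 only), plus the table cell counts in list-column `table`.
#' @export
genotype_phenotype_test <- function(vid, genotypes, phenotypes,
                                    mode = c("carrier", "genotype"),
                                    groups = c("pre_axial_longitudinal",
                                               "intercalary_transverse")) {
  mode <- match.arg(mode)
  if (length(groups) != 2) abort("exactly two endophenotype groups required")
  g <- genotypes |>
    filter(.data$vid == !!vid) |>
    inner_join(phenotypes, by = "individual") |>
    filter(.data$endophenotype %in% groups, !is.na(.data$dosage))
  if (nrow(g) == 0) {
    inform(paste0("variant ", vid, " has no genotypes in the two groups"))
    return(empty_assoc())
  }
  tab <- if (mode == "carrier") {
    table(
      factor(g$endophenotype, levels = groups),
      factor(if_else(g$dosage >= 1, "carrier", "non_carrier"),
             levels = c("carrier", "non_carrier"))
    )
  } else {
    table(
      factor(g$endophenotype, levels = groups),
      factor(g$dosage, levels = 0:2)
    )
  }
  if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) {
    inform(paste0(
      "variant ", vid, " is monomorphic or degenerate in the two groups; ",
      "test skipped"
    ))
    return(empty_assoc())
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  is_2x2 <- all(dim(tab) == c(2, 2))
  fish <- if (is_2x2) fisher.test(tab) else NULL
  tibble(
    vid = vid, mode = mode, test = "chisq",
    statistic = unname(chi$statistic), df = unname(chi$parameter),
    p_value = chi$p.value,
    fisher_p = if (is_2x2) fish$p.value else NA_real_,
    odds_ratio = if (is_2x2) unname(fish$estimate) else NA_real_,
    table = list(tab)
  )
}

empty_assoc <- function() {
  tibble(
    vid = character(0), mode = character(0), test = character(0),
    statistic = double(0), df = double(0), p_value = double(0),
    fisher_p = double(0), odds_ratio = double(0), table = list()
  )
}

#' Flag rare variants by minor allele frequency
#'
#' A variant is rare when its minor allele frequency is strictly below
#' `maf_threshold` (default 0.01). Variants without a frequency are flagged
#' `NA` (unknown).
#'
#' @param variants Variant tibble (`vid`).
#' @param freqs Tibble (`vid`, `maf`) of reference-panel or external allele
#'   frequencies. Values above 0.5 are folded to the minor allele.
#' @param maf_threshold Rarity threshold, strict inequality.
#' @return `variants` with columns `maf` and `rare` appended.
#' @export
rarity_flags <- function(variants, freqs, maf_threshold = 0.01) {
  assert_cols(freqs, c("vid", "maf"), "frequency table")
  variants |>
    left_join(select(freqs, "vid", "maf"), by = "vid") |>
    mutate(
      maf = pmin(.data$maf, 1 - .data$maf),
      rare = .data$maf < maf_threshold
    )
}

#' Summarise the rare-variant fraction
#'
#' @param flagged Output of [rarity_flags()].
#' @return One-row tibble: `n_rare`, `n_known`, `n_unknown`, `fraction`,
#'   `pct` (truncated to one decimal).
#' @export
rarity_summary <- function(flagged) {
  known <- flagged$rare[!is.na(flagged$rare)]
  tibble(
    n_rare = sum(known), n_known = length(known),
    n_unknown = sum(is.na(flagged$rare)),
    fraction = sum(known) / length(known),
    pct = trunc1(100 * sum(known) / length(known))
  )
}

#' Genotype heatmap for one gene
#'
#' The per-gene genotype presentation: a variants-by-individuals categorical
#' matrix (`Ref/Ref`, `Ref/Alt`, `Alt/Alt`, `NA` for missing) plus the
#' per-individual count of carried variants.
#'
#' @param genotypes Long genotype tibble.
#' @param variants Variant tibble (`vid`, `gene`).
#' @param gene Gene symbol.
#' @return List with `matrix` (wide tibble, first column `vid`) and
#'   `counts` (`individual`, `n_variants`).
#' @export
genotype_heatmap <- function(genotypes, variants, gene) {
  vids <- variants$vid[variants$gene == gene]
  if (length(vids) == 0) abort(paste0("no variants for gene ", gene))
  g <- genotypes |>
    filter(.data$vid %in% vids) |>
    mutate(
      genotype = dplyr::case_when(
        is.na(.data$dosage) ~ NA_character_,
        .data$dosage == 0 ~ "Ref/Ref",
        .data$dosage == 1 ~ "Ref/Alt",
        .data$dosage == 2 ~ "Alt/Alt"
      )
    )
  wide <- g |>
    select("vid", "individual", "genotype") |>
    tidyr::pivot_wider(names_from = "individual",
                       values_from = "genotype") |>
    arrange(match(.data$vid, vids))
  counts <- g |>
    group_by(.data$individual) |>
    summarise(
      n_variants = sum(.data$dosage >= 1, na.rm = TRUE), .groups = "drop"
    )
  list(matrix = wide, counts = counts)
}
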