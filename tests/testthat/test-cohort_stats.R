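make_burden_fixture <- function() {
  variants <- tibble::tibble(
    vid = c("v1", "v2", "v3"),
    gene = c("CRBN", "CRBN", "CUL4A")
  )
  scores <- tibble::tibble(vid = c("v1", "v2", "v3"),
                           total = c(5L, 10L, 20L))
  genotypes <- tibble::tibble(
    individual = rep(c("i_ref", "i_carrier"), each = 3),
    vid = rep(c("v1", "v2", "v3"), 2),
    dosage = c(0L, 0L, 0L, 1L, 2L, 0L)
  )
  list(variants = variants, scores = scores, genotypes = genotypes)
}

test_that("burden weightings: carrier counts once, dosage by copies", {
  f <- make_burden_fixture()
  carrier <- individual_burden(f$genotypes, f$variants, f$scores, "carrier")
  tc <- total_burden(carrier)
  expect_equal(tc$variant_count[tc$individual == "i_ref"], 0)
  expect_equal(tc$score_sum[tc$individual == "i_ref"], 0)
  expect_equal(tc$variant_count[tc$individual == "i_carrier"], 2)
  expect_equal(tc$score_sum[tc$individual == "i_carrier"], 15)

  dosage <- individual_burden(f$genotypes, f$variants, f$scores, "dosage")
  td <- total_burden(dosage)
  expect_equal(td$variant_count[td$individual == "i_carrier"], 3)
  expect_equal(td$score_sum[td$individual == "i_carrier"], 25)
})

test_that("missing genotypes are excluded with a note", {
  f <- make_burden_fixture()
  f$genotypes$dosage[4] <- NA # i_carrier x v1
  expect_message(
    b <- individual_burden(f$genotypes, f$variants, f$scores),
    "missing genotype"
  )
  tb <- total_burden(b)
  expect_equal(tb$score_sum[tb$individual == "i_carrier"], 10)
})

test_that("unscored variants contribute count only", {
  f <- make_burden_fixture()
  expect_message(
    b <- individual_burden(f$genotypes, f$variants, f$scores[1:2, ]),
    "without a score"
  )
  g3 <- make_burden_fixture()$genotypes
  g3$dosage[6] <- 1L # i_carrier now carries v3 too
  expect_message(
    b2 <- individual_burden(g3, f$variants, f$scores[1:2, ]),
    "without a score"
  )
  tb2 <- total_burden(b2)
  expect_equal(tb2$variant_count[tb2$individual == "i_carrier"], 3)
  expect_equal(tb2$score_sum[tb2$individual == "i_carrier"], 15)
})

test_that("overall burden is additive over genes", {
  set.seed(9)
  sim <- simulate_cohort(synthetic_config(seed = 5, delta = 0))
  scores <- dplyr::select(sim$truth$variants, vid, total = score_total)
  b <- individual_burden(sim$genotypes, sim$variants, scores)
  tb <- total_burden(b)
  by_hand <- tapply(b$score_sum, b$individual, sum)
  expect_equal(tb$score_sum, as.vector(by_hand[tb$individual]),
               ignore_attr = TRUE)
})

test_that("t-test matches the closed-form pooled-variance formula", {
  profiles <- tibble::tibble(
    individual = sprintf("p%d", 1:6), gene = "G",
    variant_count = 0L, score_sum = c(1, 2, 3, 4, 5, 6)
  )
  phen <- tibble::tibble(
    individual = sprintf("p%d", 1:6),
    cohort = rep(c("case", "reference"), each = 3),
    endophenotype = "none"
  )
  cmp <- compare_burden(profiles, phen, by = "score")
  # closed form: means 2 and 5, pooled s^2 = 1, t = -3 / sqrt(2/3)
  t_hand <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(t_hand, df = 4)
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  expect_equal(cmp$mean_diff, -3)
})

test_that("identical groups give t = 0, p = 1", {
  profiles <- tibble::tibble(
    individual = sprintf("p%d", 1:6), gene = "G",
    variant_count = 0L, score_sum = rep(c(1, 2, 3), 2)
  )
  phen <- tibble::tibble(
    individual = sprintf("p%d", 1:6),
    cohort = rep(c("case", "reference"), 3),
    endophenotype = "none"
  )
  cmp <- compare_burden(profiles, phen)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  # fully constant data: degenerate-variance branch
  profiles$score_sum <- 7
  cmp2 <- compare_burden(profiles, phen)
  expect_equal(cmp2$statistic, 0)
  expect_equal(cmp2$p_value, 1)
})

test_that("per-gene comparisons and BH adjustment are reported", {
  sim <- simulate_cohort(synthetic_config(seed = 3, delta = 0))
  scores <- dplyr::select(sim$truth$variants, vid, total = score_total)
  b <- individual_burden(sim$genotypes, sim$variants, scores)
  cmp <- compare_burden(b, sim$phenotypes, per_gene = TRUE, adjust = "BH")
  expect_setequal(
    cmp$gene, c("overall", sim$config$genes$gene)
  )
  expect_true(all(cmp$p_adjusted >= cmp$p_value - 1e-12))
  welch <- compare_burden(b, sim$phenotypes, welch = TRUE)
  expect_identical(welch$test, "welch_t")
})

test_that("one-way ANOVA matches hand computation on a textbook case", {
  profiles <- tibble::tibble(
    individual = sprintf("p%d", 1:9), gene = "G",
    variant_count = 0L,
    score_sum = c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  )
  phen <- tibble::tibble(
    individual = sprintf("p%d", 1:9),
    cohort = rep(c("case", "case", "reference"), each = 3),
    endophenotype = rep(
      c("pre_axial_longitudinal", "intercalary_transverse", "none"),
      each = 3
    )
  )
  res <- anova_burden(profiles, phen, by = "score")
  # SSB = 3*((2-3)^2 + (3-3)^2 + (4-3)^2) = 6, MSB = 3
  # SSW = 3 groups x var 1 x 2 df = 6, MSW = 1 -> F = 3
  expect_equal(glance(res)$statistic, 3, tolerance = 1e-12)
  expect_equal(glance(res)$df1, 2)
  expect_equal(glance(res)$df2, 6)
  expect_equal(glance(res)$p_value, 1 - pf(3, 2, 6), tolerance = 1e-12)
  expect_equal(nrow(tidy(res)), 3)

  # three identical groups: F = 0, p = 1
  profiles$score_sum <- rep(c(1, 2, 3), 3)
  res0 <- anova_burden(profiles, phen, by = "score")
  expect_equal(glance(res0)$statistic, 0)
  expect_equal(glance(res0)$p_value, 1)
})

test_that("ANOVA errors when a group is empty or too small", {
  profiles <- tibble::tibble(
    individual = sprintf("p%d", 1:4), gene = "G",
    variant_count = 0L, score_sum = 1:4
  )
  phen <- tibble::tibble(
    individual = sprintf("p%d", 1:4),
    cohort = c("case", "case", "reference", "reference"),
    endophenotype = c("pre_axial_longitudinal", "pre_axial_longitudinal",
                      "none", "none")
  )
  expect_error(anova_burden(profiles, phen), "at least two")
})

test_that("location-distribution chi-square matches the closed form", {
  s <- tibble::tibble(location = c("a", "b"), n = c(10L, 90L))
  r <- tibble::tibble(location = c("a", "b"), n = c(50L, 50L))
  res <- compare_location_distribution(s, r)
  hand <- oracle_pearson_chisq(rbind(c(10, 90), c(50, 50)))
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(res$df, 1)

  # identical distributions: statistic 0, p 1
  same <- compare_location_distribution(s, s)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # k = 4 independent-oracle check
  s4 <- tibble::tibble(location = letters[1:4], n = c(11L, 20L, 60L, 54L))
  r4 <- tibble::tibble(location = letters[1:4], n = c(210L, 130L, 420L, 440L))
  res4 <- compare_location_distribution(s4, r4)
  hand4 <- oracle_pearson_chisq(rbind(s4$n, r4$n))
  expect_equal(res4$statistic, hand4, tolerance = 1e-12)
  expect_equal(res4$df, 3)
  expect_error(
    compare_location_distribution(
      s4, dplyr::mutate(r4, location = letters[3:6])
    ),
    "same location categories"
  )
})

test_that("carrier association reproduces the 6/10 vs 1/14 contrast", {
  f <- make_assoc_fixture()
  res <- genotype_phenotype_test("rs_x", f$genotypes, f$phenotypes)
  tab <- res$table[[1]]
  expect_equal(as.vector(tab), c(6, 1, 4, 13))
  hand_chi <- oracle_pearson_chisq(matrix(c(6, 1, 4, 13), 2))
  expect_equal(res$statistic, hand_chi, tolerance = 1e-12)
  expect_equal(hand_chi, 7.8886, tolerance = 1e-4)
  hand_fisher <- oracle_fisher_2x2(matrix(c(6, 1, 4, 13), 2))
  expect_equal(res$fisher_p, hand_fisher, tolerance = 1e-10)
  expect_lt(res$p_value, 0.01)
})

test_that("genotype-mode association uses the dosage table", {
  f <- make_assoc_fixture()
  res <- genotype_phenotype_test("rs_x", f$genotypes, f$phenotypes,
                                 mode = "genotype")
  expect_equal(dim(res$table[[1]]), c(2L, 3L))
  expect_true(is.na(res$fisher_p))
})

test_that("degenerate association tables are skipped with a notice", {
  f <- make_assoc_fixture()
  f$genotypes$dosage <- 1L # everyone a carrier
  expect_message(
    res <- genotype_phenotype_test("rs_x", f$genotypes, f$phenotypes),
    "monomorphic|degenerate"
  )
  expect_equal(nrow(res), 0)
})

test_that("balanced tables give chi-square 0", {
  f <- make_assoc_fixture(pre_carriers_het = 5, pre_carriers_hom = 0,
                          pre_total = 10, int_carriers_het = 7,
                          int_total = 14)
  res <- genotype_phenotype_test("rs_x", f$genotypes, f$phenotypes)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("Fisher exact equals exhaustive enumeration on random tables", {
  set.seed(13)
  for (i in 1:10) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(
      fisher.test(tab)$p.value, oracle_fisher_2x2(tab), tolerance = 1e-10
    )
  }
})

test_that("rarity uses a strict MAF threshold", {
  variants <- tibble::tibble(vid = c("a", "b", "c", "d"))
  freqs <- tibble::tibble(vid = c("a", "b", "c"),
                          maf = c(0.009, 0.01, 0.995))
  fl <- rarity_flags(variants, freqs)
  expect_identical(fl$rare, c(TRUE, FALSE, TRUE, NA))
  expect_equal(fl$maf[3], 0.005) # folded to the minor allele
  sm <- rarity_summary(fl)
  expect_equal(sm$n_rare, 2)
  expect_equal(sm$n_unknown, 1)
})

test_that("the synthetic catalogue plants 43 of 145 rare variants", {
  sim <- simulate_cohort(synthetic_config(seed = 2))
  fl <- rarity_flags(
    sim$variants, dplyr::select(sim$truth$variants, vid, maf)
  )
  sm <- rarity_summary(fl)
  expect_equal(sm$n_rare, 43)
  expect_equal(sm$n_known, 145)
  expect_equal(sm$fraction, 43 / 145, tolerance = 1e-12)
})

test_that("genotype heatmap maps dosages and counts carried variants", {
  f <- make_burden_fixture()
  gh <- genotype_heatmap(f$genotypes, f$variants, "CRBN")
  expect_identical(gh$matrix$vid, c("v1", "v2"))
  expect_identical(gh$matrix$i_carrier, c("Ref/Alt", "Alt/Alt"))
  expect_identical(gh$matrix$i_ref, c("Ref/Ref", "Ref/Ref"))
  expect_identical(
    gh$counts$n_variants[gh$counts$individual == "i_carrier"], 2L
  )
  # byte-stable TSV across reruns
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(gh$matrix, p1)
  readr::write_tsv(genotype_heatmap(f$genotypes, f$variants, "CRBN")$matrix,
                   p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
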