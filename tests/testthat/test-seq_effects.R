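# ---- CpG islands -----------------------------------------------------

test_that("AT-only sequence has no islands; pure CpG repeat is one", {
  expect_equal(nrow(find_cpg_islands(strrep("AT", 500))), 0)
  isl <- find_cpg_islands(strrep("CG", 150))
  expect_equal(nrow(isl), 1)
  expect_identical(c(isl$start, isl$end), c(0L, 300L))
  expect_equal(isl$gc_fraction, 1.0)
  expect_equal(isl$obs_exp_cpg, 2.0)
})

test_that("sequences shorter than the window yield no islands", {
  expect_equal(nrow(find_cpg_islands(strrep("CG", 90))), 0)
})

test_that("N breaks islands", {
  s <- paste0(strrep("CG", 100), "N", strrep("CG", 100))
  isl <- find_cpg_islands(s)
  expect_true(all(isl$end <= 200 | isl$start >= 201))
})

test_that("detector matches the exhaustive window-enumeration oracle", {
  set.seed(101)
  for (i in 1:20) {
    s <- random_dna(2000, gc = runif(1, 0.45, 0.7))
    got <- find_cpg_islands(s)
    want <- oracle_cpg_islands(s)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
  }
})

test_that("variant impact on islands: none / disrupted / created", {
  # far from any island: substitution changes nothing
  desert <- strrep("AT", 400)
  d <- cpg_island_delta(desert, 101, "A", "G")
  expect_identical(d$verdict, "none")
  expect_identical(d$size_change, 0L)

  # borderline island: GC exactly 0.50; one C->A drops it below threshold
  borderline <- paste0(strrep("AT", 200), strrep("CGAT", 50),
                       strrep("AT", 200))
  stopifnot(nrow(find_cpg_islands(borderline)) == 1)
  dis <- cpg_island_delta(borderline, 401, "C", "A")
  expect_identical(dis$verdict, "disrupted")
  expect_lt(dis$size_change, 0)

  # the reverse substitution on the disrupted sequence creates the island
  broken <- borderline
  substr(broken, 401, 401) <- "A"
  cre <- cpg_island_delta(broken, 401, "A", "C")
  expect_identical(cre$verdict, "created")
  expect_gt(cre$size_change, 0)
})

test_that("delta is none whenever ref and alt island sets are identical", {
  set.seed(55)
  for (i in 1:10) {
    s <- random_dna(600, gc = 0.5)
    pos <- sample(300, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    alt_seq <- s
    substr(alt_seq, pos, pos) <- alt
    same <- identical(find_cpg_islands(s), find_cpg_islands(alt_seq))
    if (same) {
      expect_identical(cpg_island_delta(s, pos, ref, alt)$verdict, "none")
    }
  }
})

test_that("ref mismatch is an error", {
  expect_error(cpg_island_delta(strrep("AT", 200), 1, "C", "G"),
               "mismatch")
})

# ---- codon usage -----------------------------------------------------

test_that("codon table computes within-family frequencies", {
  tab <- codon_usage_table("ATGGGAGGAGGGTAA")
  gly <- tab[tab$aa == "G", ]
  expect_equal(gly$rel_freq[gly$codon == "GGA"], 2 / 3)
  expect_equal(gly$rel_freq[gly$codon == "GGG"], 1 / 3)
  expect_equal(tab$rel_freq[tab$codon == "ATG"], 1) # single-codon family
  expect_false(any(tab$aa == "*"))
  fam_sums <- tapply(tab$rel_freq, tab$aa, sum)
  expect_true(all(abs(fam_sums[!is.na(fam_sums)] - 1) < 1e-12))
})

test_that("codon table warnings and errors fire", {
  expect_error(codon_usage_table(character(0)), "non-empty")
  expect_warning(codon_usage_table("ATGGGATAAGGGTAA"), "internal stop")
  expect_warning(codon_usage_table("GGGAAATAA"), "start with ATG")
  expect_warning(codon_usage_table("ATGAAACCC"), "stop codon")
})

test_that("tables over a concatenation equal the sum of per-CDS tables", {
  set.seed(3)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  make_cds <- function(n) {
    paste(c("ATG", sample(sense, n, TRUE), "TAA"), collapse = "")
  }
  a <- make_cds(30)
  b <- make_cds(45)
  both <- codon_usage_table(c(a, b))
  ta <- codon_usage_table(a)
  tb <- codon_usage_table(b)
  # rows are ordered by within-family count, so join by codon
  merged <- dplyr::inner_join(ta, tb, by = "codon") |>
    dplyr::inner_join(both, by = "codon")
  expect_identical(merged$count, merged$count.x + merged$count.y)
})

test_that("synonymous shift verdicts follow family ranks in each scope", {
  gene_tab <- tibble::tibble(
    codon = c("GGA", "GGG", "GGC", "GGT"), aa = "G",
    count = c(5L, 10L, 1L, 1L)
  )
  genome_tab <- dplyr::mutate(gene_tab, count = c(10L, 5L, 1L, 1L))
  out <- synonymous_codon_shift("GGA", "GGG", gene_tab, genome_tab)
  expect_identical(out$verdict, c("to_most_frequent", "to_less_frequent"))
  # both scopes to the top codon
  out2 <- synonymous_codon_shift("GGC", "GGG", gene_tab, gene_tab)
  expect_identical(unique(out2$verdict), "to_most_frequent")
  # tie -> unchanged rank
  out3 <- synonymous_codon_shift("GGC", "GGT", gene_tab, genome_tab)
  expect_identical(unique(out3$verdict), "unchanged_rank")
  expect_error(
    synonymous_codon_shift("GGA", "GCA", gene_tab, genome_tab),
    "not synonymous"
  )
})

# ---- PWM motif disruption --------------------------------------------

test_that("log-odds scores match hand arithmetic on a toy PWM", {
  counts <- rbind(
    A = c(8, 0, 0, 2),
    C = c(0, 8, 0, 2),
    G = c(0, 0, 8, 2),
    T = c(2, 2, 2, 4)
  )
  pwm <- new_pwm(counts, id = "TOY")
  # independent hand computation of the log-odds matrix
  pc <- 0.8
  bg <- 0.25
  manual <- matrix(0, 4, 4)
  for (j in 1:4) {
    col <- counts[, j]
    p <- (col + pc * bg) / (sum(col) + pc)
    p <- p / sum(p)
    manual[, j] <- log2(p / bg)
  }
  seq <- "AAACGTAAAA"
  # best window on the forward strand containing position 4 ("ACGT"
  # starting at 3) scored by hand
  hand_score <- function(window) {
    idx <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
    sum(manual[cbind(idx, 1:4)])
  }
  windows <- sapply(1:4, function(s) substr(seq, s, s + 3))
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x))
  )
  best_ref <- max(sapply(c(windows, sapply(windows, rc)), hand_score))
  res <- pwm_motif_break(seq, 4, "C", "A", pwm, score_threshold = 0)
  expect_equal(res$ref_score, best_ref, tolerance = 1e-12)
})

test_that("palindromic motifs score identically on both strands", {
  counts <- rbind(
    A = c(10, 0, 0, 10),
    C = c(0, 10, 0, 0),
    G = c(0, 0, 10, 0),
    T = c(10, 0, 0, 10)
  ) # consensus (A/T) C G (A/T): reverse complement identical
  pwm <- new_pwm(counts)
  lo <- crl4score:::pwm_log_odds(pwm)
  s <- "TTACGATT"
  fwd <- crl4score:::score_windows(s, lo, 4)
  rev <- crl4score:::score_windows(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    lo, 4
  )
  expect_equal(max(fwd), max(rev), tolerance = 1e-12)
})

test_that("motif break verdicts respond to the score change", {
  counts <- rbind(
    A = c(20, 0, 0, 0),
    C = c(0, 20, 0, 0),
    G = c(0, 0, 20, 0),
    T = c(0, 0, 0, 20)
  )
  pwm <- new_pwm(counts) # strong ACGT consensus
  s <- "TTTTACGTTTTT"
  hit <- pwm_motif_break(s, 6, "C", "A", pwm)
  expect_identical(hit$verdict, "broken")
  expect_lt(hit$delta, 0)
  # flat motif: no window reaches threshold on ref or alt, delta is 0
  flat <- new_pwm(matrix(5, 4, 4))
  none <- pwm_motif_break("TTTTTTTTTTTT", 6, "T", "A", flat,
                          score_threshold = 1)
  expect_identical(none$verdict, "unchanged")
  expect_equal(none$delta, 0)
})

test_that("JASPAR tab matrices parse in both layouts", {
  p1 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TOY",
    "A  [ 4 19  0 ]",
    "C  [16  0  1 ]",
    "G  [ 0  1 19 ]",
    "T  [ 0  0  0 ]"
  ), p1)
  pwm1 <- read_jaspar_pwm(p1)
  expect_identical(pwm1$id, "MA0001.1")
  expect_equal(ncol(pwm1$counts), 3)
  expect_equal(unname(pwm1$counts["A", 2]), 19)
  p2 <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c("4 19 0", "16 0 1", "0 1 19", "0 0 0"), p2)
  expect_equal(read_jaspar_pwm(p2)$counts, pwm1$counts,
               ignore_attr = TRUE)
})

# ---- bisulfite -------------------------------------------------------

test_that("bisulfite conversion follows the methylation states", {
  s <- "ACGTCCGAC" # CpG cytosines at positions 2 and 6
  expect_identical(cpg_positions(s), c(2L, 6L))
  all_un <- bisulfite_convert(s, c(FALSE, FALSE))
  expect_identical(all_un, "ATGTTTGAT") # every C reads T
  all_me <- bisulfite_convert(s, c(TRUE, TRUE))
  expect_identical(all_me, "ACGTTCGAT") # CpG Cs retained, rest converted
  calls <- call_methylation(s, all_me)
  expect_identical(calls$status, c("methylated", "methylated"))
  calls_un <- call_methylation(s, all_un)
  expect_identical(calls_un$status, c("unmethylated", "unmethylated"))
})

test_that("mismatched input is rejected or uninformative", {
  expect_error(bisulfite_convert("ACGT", c(TRUE, TRUE)), "cover")
  expect_error(call_methylation("ACGT", "ACG"), "equal length")
  odd <- call_methylation("ACGT", "AGGT") # G where C/T expected
  expect_identical(odd$status, "uninformative")
})

test_that("calling inverts conversion exactly on random fixtures", {
  set.seed(202)
  for (i in 1:100) {
    s <- random_dna(300, gc = runif(1, 0.3, 0.7))
    sites <- cpg_positions(s)
    states <- sample(c(TRUE, FALSE), length(sites), replace = TRUE)
    conv <- bisulfite_convert(s, states)
    calls <- call_methylation(s, conv)
    expect_identical(calls$pos, sites)
    expect_identical(calls$status == "methylated", states)
  }
})

# ---- NG86 dN/dS ------------------------------------------------------

test_that("identical sequences give zero distances, undefined omega", {
  r <- ng86_dnds("ATGGGGTTTTAA", "ATGGGGTTTTAA")
  expect_equal(r$Nd + r$Sd, 0)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_false(r$omega_defined)
})

test_that("a single synonymous difference gives omega = 0", {
  r <- ng86_dnds("ATGGGGTTTCCCAAA", "ATGGGATTTCCCAAA")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)
  expect_true(r$omega_defined)
  expect_equal(r$omega, 0)
})

test_that("TTT vs TTA matches the per-position enumeration oracle", {
  r <- ng86_dnds("TTT", "TTA")
  expect_equal(r$Nd, 1)
  expect_equal(r$Sd, 0)
  expect_equal(r$S, 0.5)
  expect_equal(r$N, 2.5)
  expect_equal(r$N + r$S, 3)
})

test_that("site counts equal enumeration of all single-base mutations", {
  # independent oracle: translate every possible single-base mutation
  oracle_syn_sites <- function(codon) {
    tr <- function(x) {
      as.character(Biostrings::translate(Biostrings::DNAString(x),
                                         no.init.codon = TRUE))
    }
    aa <- tr(codon)
    tot <- 0
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(codon, p, p)) next
        mut <- codon
        substr(mut, p, p) <- b
        maa <- tr(mut)
        if (maa == aa) tot <- tot + 1 / 3
      }
    }
    tot
  }
  set.seed(8)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (codon in sample(sense, 12)) {
    r <- ng86_dnds(codon, codon)
    expect_equal(r$S, oracle_syn_sites(codon), tolerance = 1e-12,
                 label = codon)
  }
})

test_that("omega separates purifying from neutral evolution", {
  set.seed(77)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anc <- paste(sample(sense, 2000, replace = TRUE), collapse = "")
  mutate_seq <- function(s, rate, syn_only) {
    b <- strsplit(s, "")[[1]]
    for (i in seq_along(b)) {
      if (runif(1) > rate) next
      cand <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
      if (syn_only) {
        ci <- (i - 1) %/% 3
        codon <- paste(b[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
        mut <- codon
        substr(mut, (i - 1) %% 3 + 1, (i - 1) %% 3 + 1) <- cand
        if (Biostrings::GENETIC_CODE[[mut]] !=
            Biostrings::GENETIC_CODE[[codon]]) {
          next
        }
      }
      b[i] <- cand
    }
    paste(b, collapse = "")
  }
  neutral <- ng86_dnds(anc, mutate_seq(anc, 0.04, syn_only = FALSE))
  purifying <- ng86_dnds(anc, mutate_seq(anc, 0.04, syn_only = TRUE))
  expect_true(neutral$omega_defined)
  expect_gt(neutral$omega, 0.6)
  expect_lt(neutral$omega, 1.6)
  expect_true(purifying$omega_defined)
  expect_lt(purifying$omega, 0.1)
})

test_that("ng86 rejects malformed alignments", {
  expect_error(ng86_dnds("ATG", "ATGGGG"), "equal length")
  expect_error(ng86_dnds("ATGG", "ATGC"), "divisible")
  expect_error(ng86_dnds("AT-", "ATG"), "gap-free")
})
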