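# Small hand-built gene model on a 150-bp contig "G1" (+ strand).
# exon1 10-40 (utr5 10-22, cds 22-40), exon2 60-90 (all cds),
# exon3 110-140 (cds 110-122, utr3 122-140). CDS = 60 bp = 20 codons.
tiny_gene_model <- function(gene = "G1", strand = "+") {
  tibble::tibble(
    gene = gene,
    transcript = paste0(gene, "_T1"),
    strand = strand,
    feature = c("exon", "exon", "exon", "utr5", "cds", "cds", "cds", "utr3"),
    start = c(10L, 60L, 110L, 10L, 22L, 60L, 110L, 122L),
    end = c(40L, 90L, 140L, 22L, 40L, 90L, 122L, 140L)
  )
}

# Contig for tiny_gene_model with a known CDS planted across the cds
# intervals; everything else is A so codon arithmetic is easy to hand-check.
tiny_contig <- function(cds_codons) {
  stopifnot(sum(nchar(cds_codons)) == 60)
  s <- strrep("A", 150)
  cds_seq <- paste(cds_codons, collapse = "")
  substr(s, 23, 40) <- substr(cds_seq, 1, 18)
  substr(s, 61, 90) <- substr(cds_seq, 19, 48)
  substr(s, 111, 122) <- substr(cds_seq, 49, 60)
  s
}

default_tiny_codons <- function() {
  c(
    "ATG", "GGG", "TTT", "CCC", "AAA", "GAT", "CAT", "TGT", "CGT", "GCT",
    "ATT", "GTT", "ACT", "TCT", "AGT", "CTT", "TAT", "AAT", "GGA", "TAA"
  )
}

# Random verdict profile over all ten categories.
random_profile <- function(vid) {
  tibble::tibble(
    vid = vid,
    category = rubric_categories(),
    verdict = sample(verdict_levels(), 10, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
  )
}

# Independent O(n^2)-style CpG island oracle: enumerate every window of
# exactly min_length, test the criteria directly on the substring, merge
# qualifying windows.
oracle_cpg_islands <- function(seq, min_length = 200, gc_min = 0.5,
                               oe_min = 0.6) {
  n <- nchar(seq)
  qual <- logical(0)
  starts <- integer(0)
  if (n >= min_length) {
    for (s in 1:(n - min_length + 1)) {
      w <- substr(seq, s, s + min_length - 1)
      ch <- strsplit(w, "")[[1]]
      if (any(!ch %in% c("A", "C", "G", "T"))) next
      nc <- sum(ch == "C")
      ng <- sum(ch == "G")
      ncg <- 0
      for (i in 1:(min_length - 1)) {
        if (ch[i] == "C" && ch[i + 1] == "G") ncg <- ncg + 1
      }
      gc <- (nc + ng) / min_length
      oe <- if (nc * ng > 0) ncg * min_length / (nc * ng) else 0
      if (gc >= gc_min && oe >= oe_min) starts <- c(starts, s)
    }
  }
  if (length(starts) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  # merge overlapping windows (0-based half-open)
  s0 <- starts - 1L
  e0 <- s0 + as.integer(min_length)
  out_s <- s0[1]
  out_e <- e0[1]
  if (length(s0) > 1) {
    for (i in 2:length(s0)) {
      if (s0[i] <= out_e[length(out_e)]) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], e0[i])
      } else {
        out_s <- c(out_s, s0[i])
        out_e <- c(out_e, e0[i])
      }
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# Exhaustive Fisher exact p for a 2x2 table with fixed margins.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  p_table <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  a_obs <- tab[1, 1]
  p_obs <- p_table(a_obs)
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_range, p_table, double(1))[
    vapply(a_range, p_table, double(1)) <= p_obs * (1 + 1e-7)
  ])
}

# Closed-form Pearson chi-square on an r x k count table (no correction).
oracle_pearson_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

random_dna <- function(n, gc = 0.5) {
  paste(
    sample(c("A", "T", "C", "G"), n, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""
  )
}

make_assoc_fixture <- function(pre_carriers_het = 2, pre_carriers_hom = 4,
                               pre_total = 10, int_carriers_het = 1,
                               int_total = 14) {
  n <- pre_total + int_total
  dos <- c(
    rep(1L, pre_carriers_het), rep(2L, pre_carriers_hom),
    rep(0L, pre_total - pre_carriers_het - pre_carriers_hom),
    rep(1L, int_carriers_het), rep(0L, int_total - int_carriers_het)
  )
  list(
    genotypes = tibble::tibble(
      individual = sprintf("t%02d", 1:n), vid = "rs_x", dosage = dos
    ),
    phenotypes = tibble::tibble(
      individual = sprintf("t%02d", 1:n),
      cohort = "case",
      endophenotype = rep(
        c("pre_axial_longitudinal", "intercalary_transverse"),
        c(pre_total, int_total)
      )
    )
  )
}

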