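#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' A purifying-selection screen for a pair of aligned coding sequences.
#' Synonymous (S) and nonsynonymous (N) site counts are obtained per codon as
#' the fraction of the three possible changes at each position that preserve
#' the encoded amino acid, averaged over the two sequences; mutations to stop
#' codons count as nonsynonymous, so N + S always equals the number of
#' compared nucleotide sites. Observed differences (Sd, Nd) are classified by
#' averaging over all substitution orders with equal weight when codons
#' differ at more than one position. Proportions pS = Sd/S and pN = Nd/N are
#' Jukes-Cantor corrected, d = -3/4 ln(1 - 4p/3), and omega = dN/dS.
#'
#' This is deliberately a simple counting method (no transition/transversion
#' bias, no codon-frequency model): a stand-in screen where a full
#' maximum-likelihood codon model would otherwise be used. omega < 1
#' indicates purifying selection.
#'
#' @param cds_a,cds_b Equal-length, gap-free aligned CDS strings with length
#'   divisible by 3.
#' @return One-row tibble: `n_codons`, `N`, `S`, `Nd`, `Sd`, `pN`, `pS`,
#'   `dN`, `dS`, `omega`, `omega_defined` (FALSE when dS = 0 or a
#'   correction is undefined because p >= 3/4).
#' @export
#' @examples
#' ng86_dnds("TTT", "TTA") # one nonsynonymous difference
ng86_dnds <- function(cds_a, cds_b) {
  cds_a <- toupper(as.character(cds_a))
  cds_b <- toupper(as.character(cds_b))
  if (nchar(cds_a) != nchar(cds_b)) {
    abort("aligned CDS must have equal length")
  }
  if (nchar(cds_a) %% 3 != 0) {
    abort("aligned CDS length must be divisible by 3")
  }
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE)) {
    abort("aligned CDS must be gap-free")
  }
  n_codons <- nchar(cds_a) %/% 3
  split_codons <- function(s) {
    substring(s, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)

  S <- (sum(vapply(ca, syn_sites, double(1))) +
          sum(vapply(cb, syn_sites, double(1)))) / 2
  N <- 3 * n_codons - S

  diffs <- map(seq_len(n_codons), function(i) codon_path_diffs(ca[i], cb[i]))
  Sd <- sum(map_dbl(diffs, "syn"))
  Nd <- sum(map_dbl(diffs, "nonsyn"))

  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) {
      return(NA_real_)
    }
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  omega_defined <- !is.na(dS) && !is.na(dN) && dS > 0
  omega <- if (omega_defined) dN / dS else NA_real_
  tibble(
    n_codons = n_codons, N = N, S = S, Nd = Nd, Sd = Sd,
    pN = pN, pS = pS, dN = dN, dS = dS,
    omega = omega, omega_defined = omega_defined
  )
}

# Fraction-of-synonymous-changes site count for one codon: for each of the
# three positions, the share of the three alternative bases that encode the
# same amino acid (changes to stop codons are nonsynonymous).
syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  if (!codon %in% names(code)) {
    abort(paste0("invalid codon: ", codon))
  }
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous difference counts over all equal-weight
# substitution pathways between two codons.
codon_path_diffs <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  if (k == 0) {
    return(list(syn = 0, nonsyn = 0))
  }
  perms <- all_permutations(pos)
  syn_tot <- 0
  non_tot <- 0
  for (ord in perms) {
    cur <- codon_a
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (code[[nxt]] == code[[cur]]) {
        syn_tot <- syn_tot + 1
      } else {
        non_tot <- non_tot + 1
      }
      cur <- nxt
    }
  }
  n_paths <- length(perms)
  list(syn = syn_tot / n_paths, nonsyn = non_tot / n_paths)
}

all_permutations <- function(x) {
  if (length(x) <= 1) {
    return(list(x))
  }
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}
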