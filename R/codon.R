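#' Build a codon-usage table
#'
#' Counts codons over one or more coding sequences and computes each codon's
#' relative frequency within its synonymous family (codons encoding the same
#' amino acid). Stop codons are counted during validation but excluded from
#' the table, since they form no synonymous-choice family for translation.
#'
#' @param cds Character vector (or `DNAStringSet`) of CDS sequences. Each
#'   should have length divisible by 3, start with `ATG` and end with a stop
#'   codon; deviations produce warnings, not errors. Codons following an
#'   internal stop are still counted, but the internal stop itself is
#'   excluded with a warning.
#' @param scope Label for the table: `"gene"` or `"genome"`.
#' @return Tibble: `codon`, `aa`, `count`, `rel_freq` (within-family,
#'   summing to 1 per family with any counts), `scope`. All 61 sense codons
#'   are present, zero counts included; `rel_freq` is `NA` for families with
#'   zero total.
#' @export
#' @examples
#' codon_usage_table("ATGGGAGGAGGGTAA")
codon_usage_table <- function(cds, scope = c("gene", "genome")) {
  scope <- match.arg(scope)
  cds <- toupper(as.character(cds))
  if (length(cds) == 0 || all(nchar(cds) == 0)) {
    abort("codon_usage_table requires at least one non-empty CDS")
  }
  code <- Biostrings::GENETIC_CODE
  stops <- names(code)[code == "*"]
  counts <- setNames(integer(length(code)), names(code))
  for (s in cds) {
    if (nchar(s) %% 3 != 0) {
      warn("CDS length not divisible by 3; trailing bases ignored")
    }
    n_codons <- nchar(s) %/% 3
    if (n_codons == 0) next
    codons <- substring(s, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
    if (codons[1] != "ATG") warn("CDS does not start with ATG")
    if (!codons[n_codons] %in% stops) {
      warn("CDS does not end with a stop codon")
    }
    if (any(codons[-n_codons] %in% stops)) {
      warn("internal stop codon(s) excluded from the usage table")
    }
    known <- codons[codons %in% names(code)]
    tab <- table(known)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  tibble(
    codon = names(code), aa = unname(code), count = unname(counts)
  ) |>
    filter(.data$aa != "*") |>
    group_by(.data$aa) |>
    mutate(
      rel_freq = if (sum(.data$count) > 0) {
        .data$count / sum(.data$count)
      } else {
        NA_real_
      }
    ) |>
    ungroup() |>
    mutate(scope = scope) |>
    arrange(.data$aa, desc(.data$count), .data$codon)
}

#' Extract the reference and alternate codon of a coding SNV
#'
#' Maps a genomic single-base substitution onto its codon in the gene's CDS,
#' reverse-complementing for minus-strand genes.
#'
#' @param pos 1-based genomic position on the gene's contig.
#' @param ref,alt Single-base alleles (genomic strand).
#' @param gene_model Feature tibble for one gene (rows of the gene-model
#'   table with a `cds` feature).
#' @param seq The gene's contig sequence.
#' @return List with `ref_codon`, `alt_codon`, `codon_index` (1-based) and
#'   `position_in_codon` (1-3, on the coding strand).
#' @export
variant_codons <- function(pos, ref, alt, gene_model, seq) {
  seq <- toupper(as.character(seq))
  cds <- gene_model |>
    filter(.data$feature == "cds") |>
    arrange(.data$start)
  if (nrow(cds) == 0) abort("gene model has no CDS intervals")
  p0 <- pos - 1L
  if (!any(cds$start <= p0 & p0 < cds$end)) {
    abort("variant does not fall inside a CDS interval")
  }
  seq_ref <- substr(seq, pos, pos)
  if (seq_ref != toupper(ref)) {
    abort(paste0(
      "reference allele mismatch at position ", pos, ": sequence has ",
      seq_ref, ", variant says ", ref
    ))
  }
  cds_seq <- paste0(
    vapply(seq_len(nrow(cds)), function(i) {
      substr(seq, cds$start[i] + 1L, cds$end[i])
    }, character(1)),
    collapse = ""
  )
  offset_plus <- sum(pmax(0L, pmin(cds$end, p0) - cds$start))
  if (gene_model$strand[1] == "-") {
    cds_seq <- revcomp(cds_seq)
    offset <- nchar(cds_seq) - 1L - offset_plus
    alt_base <- chartr("ACGT", "TGCA", toupper(alt))
  } else {
    offset <- offset_plus
    alt_base <- toupper(alt)
  }
  codon_i <- offset %/% 3L
  within <- offset %% 3L
  ref_codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- alt_base
  list(
    ref_codon = ref_codon, alt_codon = alt_codon,
    codon_index = codon_i + 1L, position_in_codon = within + 1L
  )
}

#' Codon-usage shift of a synonymous variant
#'
#' For a synonymous substitution, compares the alternate codon's rank within
#' its synonymous family against the reference codon's rank, in a
#' gene-scope and a genome-scope usage table. Rank 1 is the family's most
#' frequent codon. Verdicts per scope: `to_most_frequent` when the change
#' moves to a higher-ranked (more frequent) codon, `to_less_frequent` when
#' it moves to a lower-ranked one, `unchanged_rank` when the two codons tie.
#' A variant can shift toward the preferred codon at gene scope yet toward a
#' rare codon genome-wide (or vice versa), which is why both scopes are
#' reported.
#'
#' @param ref_codon,alt_codon Synonymous codon pair (same amino acid).
#' @param gene_table,genome_table Codon-usage tables from
#'   [codon_usage_table()] (or any tibble with `codon`, `aa`, `count`).
#' @return Tibble with one row per scope: `scope`, `ref_codon`, `alt_codon`,
#'   `ref_rank`, `alt_rank`, `verdict`.
#' @export
synonymous_codon_shift <- function(ref_codon, alt_codon, gene_table,
                                   genome_table) {
  ref_codon <- toupper(ref_codon)
  alt_codon <- toupper(alt_codon)
  code <- Biostrings::GENETIC_CODE
  if (!ref_codon %in% names(code) || !alt_codon %in% names(code)) {
    abort("codons must be valid DNA triplets")
  }
  if (code[[ref_codon]] != code[[alt_codon]]) {
    abort(paste0(
      "variant is not synonymous: ", ref_codon, " (", code[[ref_codon]],
      ") vs ", alt_codon, " (", code[[alt_codon]], ")"
    ))
  }
  one_scope <- function(tab, scope) {
    fam <- tab |>
      filter(.data$aa == code[[ref_codon]]) |>
      mutate(rank = dplyr::min_rank(desc(.data$count)))
    rr <- fam$rank[fam$codon == ref_codon]
    ra <- fam$rank[fam$codon == alt_codon]
    if (length(rr) == 0 || length(ra) == 0) {
      abort(paste0("codon family incomplete in ", scope, " table"))
    }
    tibble(
      scope = scope, ref_codon = ref_codon, alt_codon = alt_codon,
      ref_rank = rr, alt_rank = ra,
      verdict = dplyr::case_when(
        ra == rr ~ "unchanged_rank",
        ra < rr ~ "to_most_frequent",
        TRUE ~ "to_less_frequent"
      )
    )
  }
  bind_rows(
    one_scope(gene_table, "gene"),
    one_scope(genome_table, "genome")
  )
}
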