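#' CpG cytosine positions of a sequence
#'
#' @param seq DNA string.
#' @return Integer vector of 1-based positions of the C in each CpG
#'   dinucleotide.
#' @export
cpg_positions <- function(seq) {
  seq <- toupper(as.character(seq))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < 2) {
    return(integer(0))
  }
  which(b[-n] == "C" & b[-1] == "G")
}

#' Simulate bisulfite conversion of a sequence
#'
#' Bisulfite treatment deaminates unmethylated cytosine to uracil (read as
#' thymine after sequencing) while 5-methylcytosine resists conversion. The
#' simulator converts every non-CpG C to T, converts unmethylated CpG Cs to
#' T, and retains methylated CpG Cs. An optional conversion-failure rate
#' leaves a fraction of unmethylated Cs unconverted, emulating incomplete
#' treatment (default 0: complete conversion).
#'
#' @param seq Original DNA string.
#' @param methylated Logical vector (or integer positions) marking which
#'   CpG cytosines are methylated. A logical vector must have one entry per
#'   CpG site of `seq`, in order.
#' @param failure_rate Probability that an unmethylated C escapes
#'   conversion; draws use the current RNG state.
#' @return The converted sequence (character scalar).
#' @export
bisulfite_convert <- function(seq, methylated, failure_rate = 0) {
  seq <- toupper(as.character(seq))
  sites <- cpg_positions(seq)
  if (is.logical(methylated)) {
    if (length(methylated) != length(sites)) {
      abort(paste0(
        "methylation states must cover all ", length(sites),
        " CpG cytosines"
      ))
    }
    meth_pos <- sites[methylated]
  } else {
    meth_pos <- as.integer(methylated)
    if (!all(meth_pos %in% sites)) {
      abort("methylated positions must be CpG cytosines of the sequence")
    }
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_c <- b == "C"
  convert <- is_c
  convert[meth_pos] <- FALSE
  if (failure_rate > 0) {
    fails <- runif(length(b)) < failure_rate
    convert <- convert & !fails
  }
  b[convert] <- "T"
  paste(b, collapse = "")
}

#' Call CpG methylation from an original/bisulfite-converted sequence pair
#'
#' Inverts the bisulfite mapping at each CpG cytosine of the original
#' sequence: a retained `C` in the converted read means `methylated`, a `T`
#' means `unmethylated`, anything else is `uninformative` (e.g. a sequencing
#' mismatch).
#'
#' @param original The untreated sequence.
#' @param converted The bisulfite-converted read of the same region.
#' @return Tibble: `pos` (1-based C position of each CpG), `status`
#'   (`methylated`, `unmethylated`, `uninformative`).
#' @export
#' @examples
#' s <- "ACGTCGAC"
#' conv <- bisulfite_convert(s, c(TRUE, FALSE))
#' call_methylation(s, conv)
call_methylation <- function(original, converted) {
  original <- toupper(as.character(original))
  converted <- toupper(as.character(converted))
  if (nchar(original) != nchar(converted)) {
    abort("original and converted sequences must have equal length")
  }
  sites <- cpg_positions(original)
  obs <- substring(converted, sites, sites)
  tibble(
    pos = sites,
    status = dplyr::case_when(
      obs == "C" ~ "methylated",
      obs == "T" ~ "unmethylated",
      TRUE ~ "uninformative"
    )
  )
}
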