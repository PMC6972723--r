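#' Read a position weight matrix in JASPAR tab format
#'
#' Accepts the common JASPAR text layouts: an optional `>ID name` header
#' followed by four rows of counts, either bracketed (`A  [ 4 19 0 ]`) or
#' bare (`4 19 0`), in A, C, G, T order.
#'
#' @param path Path to the matrix file.
#' @return A `crl4_pwm` object: list with `id`, `name`, and `counts`
#'   (4 x L numeric matrix, rows A/C/G/T).
#' @export
read_jaspar_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- name <- NA_character_
  if (startsWith(lines[1], ">")) {
    hdr <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) hdr[2] else NA_character_
    lines <- lines[-1]
  }
  if (length(lines) < 4) abort("JASPAR matrix needs four base rows")
  rows <- map(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    abort("JASPAR matrix rows have unequal lengths")
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  new_pwm(counts, id = id, name = name)
}

#' Construct a PWM from a count (or probability) matrix
#'
#' @param counts 4 x L numeric matrix with rows A, C, G, T.
#' @param id,name Optional identifiers.
#' @return A `crl4_pwm` object.
#' @export
new_pwm <- function(counts, id = NA_character_, name = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("PWM needs 4 rows (A, C, G, T)")
  if (any(counts < 0) || any(colSums(counts) <= 0)) {
    abort("PWM columns must contain non-negative counts with positive sums")
  }
  rownames(counts) <- c("A", "C", "G", "T")
  structure(
    list(id = id, name = name, counts = counts),
    class = "crl4_pwm"
  )
}

#' @export
print.crl4_pwm <- function(x, ...) {
  cat("PWM", x$id %||% "", x$name %||% "", "- length",
      ncol(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

# Per-position log2 odds against background, after pseudocount smoothing.
pwm_log_odds <- function(pwm, pseudocount = 0.8,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  counts <- pwm$counts
  probs <- apply(counts, 2, function(col) {
    p <- (col + pseudocount * background) / (sum(col) + pseudocount)
    p / sum(p)
  })
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    abort("PWM column probabilities do not sum to 1 after pseudocounts")
  }
  log2(probs / background)
}

score_windows <- function(seq, lo, L) {
  n <- nchar(seq)
  starts <- seq_len(max(0L, n - L + 1L))
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  vapply(starts, function(s) {
    cols <- idx[s:(s + L - 1L)]
    if (anyNA(cols)) {
      return(-Inf)
    }
    sum(lo[cbind(cols, seq_len(L))])
  }, double(1))
}

#' Score the disruption of a PWM motif by a variant
#'
#' motifbreakR-style log-odds comparison: every window of the motif's length
#' that covers the variant position is scored on both strands of the
#' reference and of the alt-substituted sequence; the best window score per
#' allele is kept. Verdicts, from the score change `delta = alt - ref`:
#' `broken` when the reference (but not the alt) sequence reaches
#' `score_threshold`; `weakened` / `strengthened` when `|delta|` is at
#' least `delta_bits`; `unchanged` otherwise.
#'
#' @param seq Reference sequence containing the motif context.
#' @param pos 1-based variant position in `seq`.
#' @param ref,alt Single-base alleles.
#' @param pwm A `crl4_pwm`.
#' @param score_threshold Log-odds score a bona fide site must reach.
#'   Default: 80% of the motif's maximum attainable score (conservative).
#' @param delta_bits Minimum |delta| (bits) to call weakening or
#'   strengthening; default 1.
#' @param pseudocount,background Passed to the log-odds transformation.
#' @return One-row tibble: `ref_score`, `alt_score`, `delta`, `verdict`,
#'   `score_threshold`.
#' @export
pwm_motif_break <- function(seq, pos, ref, alt, pwm, score_threshold = NULL,
                            delta_bits = 1, pseudocount = 0.8,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  stopifnot(inherits(pwm, "crl4_pwm"))
  seq <- toupper(as.character(seq))
  if (nchar(ref) != 1 || nchar(alt) != 1) {
    abort("pwm_motif_break handles single-base substitutions only")
  }
  if (substr(seq, pos, pos) != toupper(ref)) {
    abort("reference allele mismatch with the supplied sequence")
  }
  lo <- pwm_log_odds(pwm, pseudocount, background)
  L <- ncol(lo)
  if (is.null(score_threshold)) {
    score_threshold <- 0.8 * sum(apply(lo, 2, max))
  }
  alt_seq <- seq
  substr(alt_seq, pos, pos) <- toupper(alt)

  best_score <- function(s) {
    # restrict to windows covering the variant, on both strands
    lo_start <- max(1L, pos - L + 1L)
    hi_start <- min(nchar(s) - L + 1L, pos)
    if (hi_start < lo_start) {
      abort("sequence too short for a motif window covering the variant")
    }
    region <- substr(s, lo_start, hi_start + L - 1L)
    fwd <- score_windows(region, lo, L)
    rev <- score_windows(revcomp(region), lo, L)
    max(c(fwd, rev))
  }
  ref_score <- best_score(seq)
  alt_score <- best_score(alt_seq)
  delta <- alt_score - ref_score
  verdict <- if (ref_score >= score_threshold &&
                 alt_score < score_threshold) {
    "broken"
  } else if (delta <= -delta_bits) {
    "weakened"
  } else if (delta >= delta_bits) {
    "strengthened"
  } else {
    "unchanged"
  }
  tibble(
    ref_score = ref_score, alt_score = alt_score, delta = delta,
    verdict = verdict, score_threshold = score_threshold
  )
}
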