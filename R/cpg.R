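#' Detect CpG islands by sliding-window criteria
#'
#' Classic CpG-island definition (Gardiner-Garden & Frommer): a region of at
#' least `min_length` bp with GC content of at least `gc_min` and an
#' observed/expected CpG ratio of at least `oe_min`, where for a window of
#' length L, expected CpG = (#C x #G) / L. The detector slides a window of
#' exactly `min_length` bp in steps of 1, marks qualifying windows (windows
#' containing `N` never qualify), and merges overlapping qualifying windows
#' into maximal islands. Island-level GC and obs/exp are recomputed over the
#' merged interval.
#'
#' @param seq A DNA string over `A,C,G,T,N` (character scalar or
#'   `DNAString`).
#' @param min_length Minimum island (and window) length, default 200 bp.
#' @param gc_min Minimum GC fraction, default 0.5.
#' @param oe_min Minimum observed/expected CpG ratio, default 0.6.
#' @return Tibble of islands: `start`, `end` (0-based half-open), `length`,
#'   `gc_fraction`, `obs_exp_cpg`. Zero rows when no window qualifies or
#'   the sequence is shorter than `min_length`.
#' @export
#' @examples
#' find_cpg_islands(strrep("CG", 150)) # one 300-bp island, obs/exp = 2
find_cpg_islands <- function(seq, min_length = 200, gc_min = 0.5,
                             oe_min = 0.6) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  L <- as.integer(min_length)
  empty <- tibble(
    start = integer(0), end = integer(0), length = integer(0),
    gc_fraction = double(0), obs_exp_cpg = double(0)
  )
  if (n < L) {
    return(empty)
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_c <- b == "C"
  is_g <- b == "G"
  is_n <- !(b %in% c("A", "C", "G", "T"))
  is_cg <- c(is_c[-n] & is_g[-1], FALSE) # CpG starting at each position
  cum <- function(x) c(0, cumsum(x))
  cC <- cum(is_c)
  cG <- cum(is_g)
  cN <- cum(is_n)
  cCG <- cum(is_cg)
  starts <- seq_len(n - L + 1L) # 1-based window starts
  nc <- cC[starts + L] - cC[starts]
  ng <- cG[starts + L] - cG[starts]
  nn <- cN[starts + L] - cN[starts]
  ncg <- cCG[starts + L - 1L] - cCG[starts] # CpGs fully inside window
  gc <- (nc + ng) / L
  oe <- ifelse(nc * ng > 0, ncg * L / (nc * ng), 0)
  ok <- nn == 0 & gc >= gc_min & oe >= oe_min
  if (!any(ok)) {
    return(empty)
  }
  # merge overlapping qualifying windows (0-based half-open)
  w0 <- starts[ok] - 1L
  runs <- merge_intervals(tibble(start = w0, end = w0 + L))
  stats <- pmap(runs, function(start, end) {
    len <- end - start
    nc <- cC[end + 1L] - cC[start + 1L]
    ng <- cG[end + 1L] - cG[start + 1L]
    ncg <- cCG[end] - cCG[start + 1L]
    tibble(
      start = start, end = end, length = len,
      gc_fraction = (nc + ng) / len,
      obs_exp_cpg = if (nc * ng > 0) ncg * len / (nc * ng) else 0
    )
  })
  list_rbind(stats)
}

#' Effect of a single-nucleotide variant on CpG islands
#'
#' Re-runs the island detector on the reference and on the alt-substituted
#' sequence and compares islands in the variant's neighbourhood (the variant
#' position widened by `min_length` on each side). Verdicts: `created`
#' (no overlapping island before, one after), `disrupted` (island lost),
#' `enlarged` / `shrunk` (total overlapping island length changed), `none`.
#'
#' @param seq Reference DNA string.
#' @param pos 1-based variant position in `seq`.
#' @param ref,alt Single-base reference and alternate alleles.
#' @inheritParams find_cpg_islands
#' @return One-row tibble: `verdict`, `size_change` (alt minus ref island
#'   bp in the neighbourhood), `ref_island_bp`, `alt_island_bp`.
#' @export
cpg_island_delta <- function(seq, pos, ref, alt, min_length = 200,
                             gc_min = 0.5, oe_min = 0.6) {
  seq <- toupper(as.character(seq))
  if (nchar(ref) != 1 || nchar(alt) != 1) {
    abort("cpg_island_delta handles single-base substitutions only")
  }
  if (pos < 1 || pos > nchar(seq)) {
    abort("variant position outside the sequence")
  }
  if (substr(seq, pos, pos) != toupper(ref)) {
    abort(paste0(
      "reference allele mismatch at position ", pos, ": sequence has ",
      substr(seq, pos, pos), ", variant says ", ref
    ))
  }
  alt_seq <- seq
  substr(alt_seq, pos, pos) <- toupper(alt)
  lo <- pos - 1L - min_length
  hi <- pos - 1L + min_length # neighbourhood, 0-based half-open-ish
  overlap_bp <- function(islands) {
    if (nrow(islands) == 0) {
      return(0L)
    }
    keep <- islands$end > lo & islands$start < hi
    sum(islands$length[keep])
  }
  ref_bp <- overlap_bp(find_cpg_islands(seq, min_length, gc_min, oe_min))
  alt_bp <- overlap_bp(find_cpg_islands(alt_seq, min_length, gc_min, oe_min))
  verdict <- if (ref_bp == 0 && alt_bp == 0) {
    "none"
  } else if (ref_bp == 0) {
    "created"
  } else if (alt_bp == 0) {
    "disrupted"
  } else if (alt_bp > ref_bp) {
    "enlarged"
  } else if (alt_bp < ref_bp) {
    "shrunk"
  } else {
    "none"
  }
  tibble(
    verdict = verdict, size_change = alt_bp - ref_bp,
    ref_island_bp = ref_bp, alt_island_bp = alt_bp
  )
}
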