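#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols distinct rename count
#'   n across all_of any_of desc if_else row_number slice pull relocate
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap
#'   list_rbind
#' @importFrom stats t.test chisq.test fisher.test oneway.test setNames
#'   rbinom runif p.adjust pt pf
#' @importFrom utils head packageVersion
NULL

# Derive a reproducible substream seed from a master seed.  Streams are named
# so modules (genotypes, annotations, sequences, ...) can be regenerated
# independently without sharing RNG state.  Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  offsets <- c(
    maf = 11L, genotypes = 23L, annotations = 37L, sequences = 53L,
    enrichment = 71L, phenotypes = 89L, placement = 101L
  )
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown RNG stream: ", stream))
  }
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stream]]
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

# Truncate (not round) to one decimal place; used for reporting percentage
# shares the way the source tooling printed them (11/145 -> 7.5, not 7.6).
trunc1 <- function(x) trunc(x * 10) / 10

# Complement / reverse complement for plain character DNA.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
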