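# Shared low-level helpers: sequence handling, genotype codes, seeded RNG.

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")
IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

DNA_BASES <- c("A", "C", "G", "T")

# Scoped RNG: every generator draws from a stream derived from (seed, tag) so
# that stages are individually reproducible and insensitive to call order.
with_seed <- function(seed, tag, code) {
  # fold the tag into a 31-bit stream id
  tagnum <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  derived <- (as.numeric(seed) * 7919 + tagnum) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(derived))
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a nucleotide string
#'
#' @param x A character vector of DNA sequences (ACGTN).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-nucleotide characters (allowed: %s)",
      what, if (allow_n) "ACGTN" else "ACGT"
    ))
  }
  invisible(x)
}

translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n == 0) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1, n)),
    no.init.codon = TRUE
  ))
}

# Substitute a fraction of positions with a different base, deterministically
# under the current RNG state.
mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  paste(chars, collapse = "")
}

# Majority-vote consensus over equal-anchored character fragments.
# `align` = "left": fragments share their first column (e.g. clips that start
# at a breakpoint); "right": fragments share their last column.
consensus_sequence <- function(frags, align = c("left", "right")) {
  align <- match.arg(align)
  if (length(frags) == 0) return("")
  width <- max(nchar(frags))
  mat <- vapply(frags, function(f) {
    chars <- strsplit(f, "")[[1]]
    pad <- rep(NA_character_, width - length(chars))
    if (align == "left") c(chars, pad) else c(pad, chars)
  }, character(width))
  if (width == 1) mat <- matrix(mat, nrow = 1)
  cons <- apply(mat, 1, function(col) {
    col <- col[!is.na(col)]
    tab <- sort(table(col), decreasing = TRUE)
    # deterministic tie-break: alphabetical among maxima
    winners <- names(tab)[tab == tab[1]]
    sort(winners)[1]
  })
  paste(cons, collapse = "")
}

interval_length <- function(start, end) end - start + 1

#' Length of a 1-based inclusive genomic interval
#'
#' Coordinates follow the 1-based inclusive convention used throughout the
#' package, so a region `chr:60042581-62111666` has
#' `62111666 - 60042581 + 1` bases.
#'
#' @param regions Data frame with `start` and `end` columns (1-based inclusive).
#' @return Input tibble with a `length_bp` column appended.
#' @export
region_length <- function(regions) {
  as_tibble(regions) |> mutate(length_bp = interval_length(.data$start, .data$end))
}
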