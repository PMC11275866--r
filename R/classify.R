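# Repeat-library classification: affine-gap global alignment and the
# pairwise percent-identity matrix used to assign an inserted sequence to
# its source repeat family.

#' Default alignment scoring for repeat classification
#'
#' Match +2, mismatch -3, gap open -5, gap extend -2 (a gap of length k
#' costs open + k * extend). `N` scores 0 against everything.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A list understood by [global_align()].
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2) {
  mat <- matrix(mismatch, 5, 5, dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(mat) <- match
  mat["N", ] <- 0
  mat[, "N"] <- 0
  list(
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend, matrix = mat
  )
}

#' Global alignment with percent identity
#'
#' Needleman-Wunsch global alignment with affine gap penalties (delegated to
#' [Biostrings::pairwiseAlignment()]). Percent identity is computed from the
#' aligned strings as `100 * matched columns / aligned columns`, where
#' columns belonging to a terminal gap run (in either sequence) are excluded
#' from the denominator, so a full-length element embedded in a longer
#' sequence scores by its aligned core.
#'
#' @param seq_a,seq_b Nucleotide strings (ACGTN).
#' @param scoring Scoring scheme from [align_scoring()].
#' @return Tibble with `score`, `identity` (percent), `aligned_a`,
#'   `aligned_b`, `columns`, `matches`.
#' @export
global_align <- function(seq_a, seq_b, scoring = align_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  check_dna(c(seq_a, seq_b), "alignment input")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- a == "-" | b == "-"
  n <- length(a)
  # terminal gap runs: leading/trailing columns where either row is gapped
  lead <- if (gap[1]) seq_len(rle(gap)$lengths[1]) else integer()
  trail <- if (gap[n]) (n - rle(rev(gap))$lengths[1] + 1):n else integer()
  core <- setdiff(seq_len(n), c(lead, trail))
  matches <- sum(a[core] == b[core] & a[core] != "-")
  tibble(
    score = Biostrings::score(aln),
    identity = 100 * matches / length(core),
    aligned_a = paste(a, collapse = ""),
    aligned_b = paste(b, collapse = ""),
    columns = length(core),
    matches = matches
  )
}

#' Percent-identity matrix of a query against a repeat library
#'
#' Aligns every pair among `{query} + library` and returns the symmetric
#' percent-identity matrix together with the library best hit (maximal
#' identity to the query; ties broken lexicographically by name and
#' reported).
#'
#' @param query Tibble with `name` and `seq` (single row), or a plain string
#'   (named "query").
#' @param library Repeat library tibble (`name`, `seq`), e.g. from
#'   [read_fasta()].
#' @param scoring Scoring scheme from [align_scoring()].
#' @return An `identity_matrix` object: the numeric matrix with dimnames,
#'   plus `best_hit`, `best_identity` and `ties` attributes.
#' @export
identity_matrix <- function(query, library, scoring = align_scoring()) {
  if (is.character(query)) query <- tibble(name = "query", seq = query)
  if (nrow(library) == 0) abort("repeat library is empty")
  if (anyDuplicated(c(query$name, library$name))) abort("duplicate sequence names")
  entries <- bind_rows(query[, c("name", "seq")], library[, c("name", "seq")])
  n <- nrow(entries)
  m <- matrix(100, n, n, dimnames = list(entries$name, entries$name))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- global_align(entries$seq[i], entries$seq[j], scoring)$identity
      m[i, j] <- id
      m[j, i] <- id
    }
  }
  qids <- m[1, -1]
  best <- max(qids)
  winners <- sort(names(qids)[qids == best])
  structure(
    m,
    class = c("identity_matrix", "matrix", "array"),
    best_hit = winners[1],
    best_identity = unname(best),
    ties = winners,
    query = entries$name[1]
  )
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf(
    "<identity_matrix> %d sequences; best hit for '%s': %s (%.1f%%)%s\n",
    nrow(x), attr(x, "query"), attr(x, "best_hit"), attr(x, "best_identity"),
    if (length(attr(x, "ties")) > 1) sprintf(" [tied: %s]", paste(attr(x, "ties"), collapse = ", ")) else ""
  ))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Tidy an identity matrix into long pair form
#'
#' @param x An `identity_matrix`.
#' @param ... Unused.
#' @return Tibble with `name_a`, `name_b`, `identity`.
#' @export
#' @exportS3Method generics::tidy
tidy.identity_matrix <- function(x, ...) {
  as_tibble(as.data.frame(as.table(unclass(x)))) |>
    setNames(c("name_a", "name_b", "identity")) |>
    mutate(across(c("name_a", "name_b"), as.character))
}

#' Write an identity matrix as labelled TSV
#'
#' @param x An `identity_matrix`.
#' @param path Output path.
#' @export
write_identity_tsv <- function(x, path) {
  df <- as.data.frame(round(unclass(x), 3))
  readr::write_tsv(bind_cols(tibble(name = rownames(x)), df), path)
  invisible(path)
}

#' Heatmap of a percent-identity matrix
#'
#' @param object An `identity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.identity_matrix <- function(object, ...) {
  df <- tidy(object)
  lv <- rownames(object)
  ggplot2::ggplot(
    df |> mutate(
      name_a = factor(.data$name_a, levels = lv),
      name_b = factor(.data$name_b, levels = rev(lv))
    ),
    ggplot2::aes(.data$name_a, .data$name_b, fill = .data$identity)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$identity)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8", limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
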