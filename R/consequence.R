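# Coding-consequence prediction for insertions: genomic<->CDS mapping,
# translation of the mutant reading frame, premature-stop bookkeeping and
# isoform specificity.

#' Build a transcript model
#'
#' A transcript model holds the exon table of a gene and the exon composition
#' of each isoform. Exons are genomic 1-based inclusive intervals; the CDS is
#' taken to be the full exon span (the synthetic gene carries no UTRs, a
#' documented simplification). An exon flagged `alt_spliced` is present in
#' some isoforms and skipped in others, the situation that makes an exonic
#' variant isoform-specific.
#'
#' @param gene_id Gene identifier.
#' @param accession Protein/transcript accession used in variant designations.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"` (coding strand).
#' @param exons Tibble with `exon_id`, `start`, `end`, `alt_spliced`.
#' @param isoforms Named list mapping isoform id to an integer vector of
#'   `exon_id`s (in genomic order).
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(gene_id, accession, chrom, strand, exons, isoforms) {
  exons <- as_tibble(exons) |> arrange(.data$start)
  if (any(exons$end < exons$start)) abort("exon end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons overlap")
  }
  for (iso in names(isoforms)) {
    len <- sum(interval_length(
      exons$start[exons$exon_id %in% isoforms[[iso]]],
      exons$end[exons$exon_id %in% isoforms[[iso]]]
    ))
    if (len %% 3 != 0) {
      abort(sprintf("CDS length of isoform '%s' (%d) is not divisible by 3", iso, len))
    }
  }
  structure(
    list(
      gene_id = gene_id, accession = accession, chrom = chrom,
      strand = strand, exons = exons, isoforms = isoforms
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s) on %s strand %s: %d exons, isoforms: %s\n",
    x$gene_id, x$accession, x$chrom, x$strand, nrow(x$exons),
    paste(sprintf("%s (%d exons)", names(x$isoforms), lengths(x$isoforms)), collapse = ", ")
  ))
  invisible(x)
}

iso_exons <- function(model, isoform) {
  ex <- model$exons |> filter(.data$exon_id %in% model$isoforms[[isoform]])
  if (model$strand == "-") ex <- ex |> arrange(desc(.data$start))
  ex
}

#' Map a genomic position to CDS and codon coordinates
#'
#' CDS positions count coding bases 5'->3' on the coding strand; the codon
#' index is `ceiling(cds/3)`. Positions that fall in an intron, outside the
#' gene, or inside an exon the isoform skips raise an error naming the
#' category.
#'
#' @param model A [transcript_model()].
#' @param isoform Isoform id.
#' @param gpos Genomic position (1-based).
#' @return Tibble with `cds_pos`, `codon`, `exon_id`.
#' @export
map_genomic_to_cds <- function(model, isoform, gpos) {
  if (!isoform %in% names(model$isoforms)) abort(sprintf("unknown isoform '%s'", isoform))
  span <- range(model$exons$start, model$exons$end)
  if (gpos < span[1] || gpos > span[2]) abort("position is outside the gene span")
  all_hit <- model$exons |> filter(.data$start <= gpos, .data$end >= gpos)
  ex <- iso_exons(model, isoform)
  hit <- ex |> filter(.data$start <= gpos, .data$end >= gpos)
  if (nrow(hit) == 0) {
    if (nrow(all_hit) > 0) {
      abort(sprintf(
        "position %d is not in isoform '%s' (exon %d is skipped)",
        gpos, isoform, all_hit$exon_id[1]
      ))
    }
    abort(sprintf("position %d is intronic in isoform '%s'", gpos, isoform))
  }
  idx <- which(ex$exon_id == hit$exon_id[1])
  before <- if (idx > 1) sum(interval_length(ex$start[seq_len(idx - 1)], ex$end[seq_len(idx - 1)])) else 0L
  offset <- if (model$strand == "+") gpos - hit$start[1] + 1L else hit$end[1] - gpos + 1L
  cds <- before + offset
  tibble(cds_pos = as.integer(cds), codon = as.integer(ceiling(cds / 3)), exon_id = hit$exon_id[1])
}

#' Map a CDS position back to the genome
#'
#' Inverse of [map_genomic_to_cds()].
#'
#' @inheritParams map_genomic_to_cds
#' @param cds_pos CDS coordinate (1-based).
#' @return Genomic position (integer).
#' @export
map_cds_to_genomic <- function(model, isoform, cds_pos) {
  ex <- iso_exons(model, isoform)
  lens <- interval_length(ex$start, ex$end)
  ends <- cumsum(lens)
  if (cds_pos < 1 || cds_pos > ends[length(ends)]) abort("CDS position out of range")
  i <- which(ends >= cds_pos)[1]
  offset <- cds_pos - (if (i > 1) ends[i - 1] else 0L)
  as.integer(if (model$strand == "+") ex$start[i] + offset - 1L else ex$end[i] - offset + 1L)
}

cds_sequence <- function(model, isoform, genome_seq) {
  ex <- iso_exons(model, isoform)
  parts <- substring(genome_seq, ex$start, ex$end)
  if (model$strand == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

#' Predict the coding consequence of an insertion, per isoform
#'
#' Splices the inserted sequence into the coding sequence immediately after
#' genomic base `site` (on the plus strand of the genome), translates the
#' mutant reading frame from the first affected codon and reports, per
#' isoform: frame status, the first altered protein position, the number of
#' aberrant residues up to (and excluding) the first stop, the premature-stop
#' codon index, the wild-type residue count from the insertion point to the
#' end of the host exon, and the exon extension (aberrant minus wild-type
#' tail). Isoforms that skip the host exon are reported `affected = FALSE`.
#'
#' Counting rules: codons consisting entirely of inserted bases are aberrant
#' by definition; the codon mixing reference and inserted bases counts as
#' aberrant only if its translation differs from the wild-type residue. If no
#' stop is reached before the end of the mutant CDS the call is flagged
#' `stop_lost` with `stop_protein_position = NA`.
#'
#' @param model A [transcript_model()].
#' @param genome_seq Reference sequence of the model's contig (single string).
#' @param site Genomic position of the last reference base before the
#'   insertion point.
#' @param insert Inserted sequence, reference-strand orientation (ACGT).
#' @return Tibble with one row per isoform.
#' @export
predict_insertion_consequence <- function(model, genome_seq, site, insert) {
  check_dna(insert, "inserted sequence", allow_n = FALSE)
  span <- range(model$exons$start, model$exons$end)
  if (site < span[1] || site > span[2]) abort("insertion site is outside the gene span")
  rows <- map(names(model$isoforms), function(iso) {
    base <- tibble(
      isoform = iso, affected = FALSE, in_frame = nchar(insert) %% 3 == 0,
      cds_insertion_position = NA_integer_, protein_start_position = NA_integer_,
      aberrant_aa_count = NA_integer_, stop_protein_position = NA_integer_,
      wildtype_tail_aa = NA_integer_, exon_extension_aa = NA_integer_,
      stop_lost = FALSE
    )
    hit <- tryCatch(map_genomic_to_cds(model, iso, site), error = function(e) NULL)
    if (is.null(hit)) return(base)
    # insertion point in CDS coordinates: after base k on the coding strand
    k <- if (model$strand == "+") hit$cds_pos else {
      map_genomic_to_cds(model, iso, site + 1L)$cds_pos
    }
    ins_cds <- if (model$strand == "+") insert else revcomp(insert)
    wt <- cds_sequence(model, iso, genome_seq)
    mut <- paste0(substr(wt, 1, k), ins_cds, substr(wt, k + 1, nchar(wt)))
    wt_prot <- translate_dna(wt)
    mut_prot <- translate_dna(mut)
    c0 <- as.integer(ceiling((k + 1) / 3)) # first codon containing inserted bases
    mixed <- k %% 3 != 0
    start <- c0
    if (mixed && substr(mut_prot, c0, c0) == substr(wt_prot, c0, c0)) {
      start <- c0 + 1L
    }
    stops <- which(strsplit(mut_prot, "")[[1]] == "*")
    stop_idx <- stops[stops >= start][1]
    stop_lost <- is.na(stop_idx)
    aberrant <- if (stop_lost) nchar(mut_prot) - start + 1L else stop_idx - start
    # wild-type residues from the first altered position to the end of the
    # exon hosting the insertion
    ex <- iso_exons(model, iso)
    idx <- which(ex$exon_id == hit$exon_id)
    exon_end_cds <- sum(interval_length(ex$start[seq_len(idx)], ex$end[seq_len(idx)]))
    last_codon <- as.integer(floor(exon_end_cds / 3))
    tail_aa <- max(0L, last_codon - start + 1L)
    base |> mutate(
      affected = TRUE,
      cds_insertion_position = as.integer(k),
      protein_start_position = as.integer(start),
      aberrant_aa_count = as.integer(aberrant),
      stop_protein_position = if (stop_lost) NA_integer_ else as.integer(stop_idx),
      wildtype_tail_aa = tail_aa,
      exon_extension_aa = as.integer(aberrant - tail_aa),
      stop_lost = stop_lost
    )
  })
  out <- bind_rows(rows)
  ok <- !is.na(out$stop_protein_position)
  stopifnot(all(out$stop_protein_position[ok] ==
                  out$protein_start_position[ok] + out$aberrant_aa_count[ok]))
  out
}

#' Render an insertion designation string
#'
#' Formats an insertion as `"<accession> c.<pos>_ins<length> p.<start>"`,
#' the style used for published canine retinal-disease insertions (not
#' strict HGVS). `pos` is the CDS coordinate of the last reference base
#' before the insertion. An unknown insert length (for example, a partial
#' soft-clip consensus) renders as `ins?` with a warning.
#'
#' @param accession Reference accession string.
#' @param cds_pos CDS coordinate of the insertion point.
#' @param insert_length Inserted length in bp, or `NA` when unknown.
#' @param protein_start First altered protein position (optional).
#' @return A single designation string.
#' @export
name_variant <- function(accession, cds_pos, insert_length, protein_start = NULL) {
  len <- if (is.na(insert_length)) {
    warn("insert length unknown (partial consensus); rendering 'ins?'")
    "?"
  } else {
    as.character(as.integer(insert_length))
  }
  out <- sprintf("%s c.%d_ins%s", accession, as.integer(cds_pos), len)
  if (!is.null(protein_start) && !is.na(protein_start)) {
    out <- sprintf("%s p.%d", out, as.integer(protein_start))
  }
  out
}
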