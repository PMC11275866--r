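# Reference simulator: mini-contigs, a 7-exon gene with an alternatively
# spliced internal exon, a SINE-like repeat library, and the planted element.

# Per-exon CDS lengths (bp). Chosen so the "long" isoform encodes 716
# residues (2151 nt with stop), the skipped exon 4 encodes 56 residues, and
# the "short" isoform therefore encodes 660 residues -- the isoform pair the
# consequence module is designed around. Exons 1-4 accumulate 1758 coding
# bases, so the default insertion point (10 wild-type residues before the
# exon 4 boundary) sits after CDS base 1728, codon boundary 576|577.
EXON_CDS_LEN <- c(450L, 570L, 570L, 168L, 150L, 150L, 93L)
ALT_SPLICED_EXON <- 4L
WILDTYPE_TAIL_TARGET <- 10L
GENE_START <- 3000L
INTRON_LEN <- 300L

sense_codons <- function() {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

# Replace in-frame stop codons with sense codons; force a stop at codon
# `stop_at` (if given). Frame = codon boundaries of the element itself.
frame_force <- function(seq, stop_at = NA) {
  n3 <- nchar(seq) %/% 3
  codons <- substring(seq, 3 * seq_len(n3) - 2, 3 * seq_len(n3))
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  codons[is_stop] <- paste0(substr(codons[is_stop], 1, 2), "C")
  if (!is.na(stop_at)) codons[stop_at] <- "TAA"
  paste0(paste(codons, collapse = ""), substr(seq, 3 * n3 + 1, nchar(seq)))
}

#' Simulate a mini-reference: contigs, gene model, repeat library, element
#'
#' Generates, deterministically from `config$seed`:
#' * one contig per chromosome (`contig_length_bp` of random sequence), each
#'   representing a sequenced focal window at a recorded offset on a nominal
#'   Mb-scale chromosome;
#' * a 7-exon plus-strand gene on the first contig whose internal exon 4 is
#'   alternatively spliced, giving a long isoform (716 aa) that contains it
#'   and a short isoform (660 aa) that skips it;
#' * a repeat library of four poly-A-tailed SINE-like consensuses with ~25%
#'   mutual divergence;
#' * the planted element: the first library consensus mutated at
#'   `element_divergence`, with its poly-A tail restored and, for in-frame
#'   lengths, its reading frame engineered so that translation from the
#'   insertion point yields 49 aberrant residues followed by a stop.
#'
#' The insertion point is placed at a codon boundary 10 wild-type residues
#' before the end of the alternatively spliced exon, with a
#' `tsd_length_bp` target-site duplication immediately 5' of it.
#'
#' @param config A [sim_config()].
#' @return A `sim_reference` list: `contigs` (tibble `name`,
#'   `chrom_length`, `window_offset`, `seq`), `repeats` (tibble), `model`
#'   (a [transcript_model()]), and `truth` (planted insertion ground truth).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_span <- sum(EXON_CDS_LEN) + (length(EXON_CDS_LEN) - 1) * INTRON_LEN
  if (GENE_START + gene_span - 1 > config$contig_length_bp - 1000) {
    abort(sprintf(
      "gene model (%d bp starting at %d) does not fit on a %d bp contig",
      gene_span, GENE_START, config$contig_length_bp
    ))
  }
  with_seed(config$seed, "reference", {
    contigs <- tibble(
      name = sprintf("chr%d", seq_len(config$n_chromosomes)),
      chrom_length = as.integer(config$chromosome_length_bp),
      window_offset = as.integer(config$chromosome_length_bp %/% 2 -
                                   config$contig_length_bp %/% 2),
      seq = vapply(seq_len(config$n_chromosomes), function(i) random_dna(config$contig_length_bp), "")
    )

    # exon layout on contig 1
    starts <- GENE_START + cumsum(c(0L, head(EXON_CDS_LEN, -1) + INTRON_LEN))
    exons <- tibble(
      exon_id = seq_along(EXON_CDS_LEN),
      start = as.integer(starts),
      end = as.integer(starts + EXON_CDS_LEN - 1L),
      alt_spliced = seq_along(EXON_CDS_LEN) == ALT_SPLICED_EXON
    )
    model <- transcript_model(
      gene_id = "GENE1", accession = "XP_SYN000001.1", chrom = contigs$name[1],
      strand = "+", exons = exons,
      isoforms = list(
        long = seq_along(EXON_CDS_LEN),
        short = setdiff(seq_along(EXON_CDS_LEN), ALT_SPLICED_EXON)
      )
    )

    # embed a stop-free CDS into contig 1 at the exon positions
    n_codons <- sum(EXON_CDS_LEN) %/% 3
    cds <- paste(c("ATG", sample(sense_codons(), n_codons - 2, replace = TRUE), "TAA"), collapse = "")
    chr1 <- strsplit(contigs$seq[1], "")[[1]]
    cds_chars <- strsplit(cds, "")[[1]]
    offset <- 0L
    for (i in seq_len(nrow(exons))) {
      len <- EXON_CDS_LEN[i]
      chr1[exons$start[i]:exons$end[i]] <- cds_chars[(offset + 1):(offset + len)]
      offset <- offset + len
    }
    contigs$seq[1] <- paste(chr1, collapse = "")

    # repeat library: poly-A tailed SINE-like consensuses
    L <- as.integer(config$insertion_length_bp)
    tail_len <- as.integer(config$polyA_tail_bp)
    body <- random_dna(L - tail_len)
    tail <- strrep("A", tail_len)
    lib <- tibble(
      name = c("SINEC_A", "SINEC_B", "SINEC_C", "MIR_A"),
      seq = c(
        paste0(body, tail),
        paste0(mutate_sequence(body, 0.25), tail),
        paste0(mutate_sequence(body, 0.25), tail),
        paste0(mutate_sequence(body, 0.35), tail)
      )
    )

    # planted element: mutated copy of the first consensus
    element <- mutate_sequence(lib$seq[1], config$element_divergence)
    element <- paste0(substr(element, 1, L - tail_len), tail)
    if (L %% 3 == 0) {
      # premature stop at element codon 50 (or as late as the body allows)
      stop_at <- min(50L, (L - tail_len) %/% 3)
      element <- frame_force(element, stop_at = stop_at)
    }

    # insertion point: codon boundary, 10 wild-type residues before the end
    # of the alternatively spliced exon
    k <- sum(EXON_CDS_LEN[seq_len(ALT_SPLICED_EXON)]) - 3L * WILDTYPE_TAIL_TARGET
    g <- map_cds_to_genomic(model, "long", k)
    s <- g - as.integer(config$tsd_length_bp) + 1L
    tsd <- substr(contigs$seq[1], s, g)

    truth <- list(
      insertion_contig = contigs$name[1],
      bp_left = as.integer(s),
      bp_right = as.integer(g),
      tsd_sequence = tsd,
      inserted_sequence = element,
      source_repeat = lib$name[1],
      cds_insertion_position = as.integer(k),
      insertion_site_genomic = as.integer(contigs$window_offset[1] + g)
    )
    structure(
      list(contigs = contigs, repeats = lib, model = model, truth = truth),
      class = "sim_reference"
    )
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf(
    "<sim_reference> %d contigs (%d bp each), gene %s (%d exons), %d repeat consensuses; planted %d bp element at %s:%d-%d (TSD %d bp)\n",
    nrow(x$contigs), nchar(x$contigs$seq[1]), x$model$gene_id, nrow(x$model$exons),
    nrow(x$repeats), nchar(x$truth$inserted_sequence), x$truth$insertion_contig,
    x$truth$bp_left, x$truth$bp_right, nchar(x$truth$tsd_sequence)
  ))
  invisible(x)
}

# Donor (insertion-carrying) sequence of the focal contig: the element plus
# a duplicated target site, as retrotransposition leaves it.
donor_sequence <- function(reference) {
  tr <- reference$truth
  ref <- reference$contigs$seq[reference$contigs$name == tr$insertion_contig]
  paste0(
    substr(ref, 1, tr$bp_right),
    tr$inserted_sequence,
    tr$tsd_sequence,
    substr(ref, tr$bp_right + 1, nchar(ref))
  )
}
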