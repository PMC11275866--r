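# Fragment-length genotyping: in-silico PCR over allele templates,
# genotype calls from observed fragment sizes, and cohort segregation
# analysis under a full-penetrance recessive model.

#' Define a fragment-length genotyping assay
#'
#' An allele-specific PCR assay: a common (optionally tailed) reverse
#' primer paired with a wild-type forward primer and/or an
#' insertion-anchored forward primer. The tail is a non-binding 5'
#' extension (for example a fluorophore tail) that adds its length to every
#' product of the tailed primer.
#'
#' @param forward_wt Wild-type forward primer (ACGT, >= 15 bp), or NA.
#' @param forward_ins Insertion-specific forward primer, or NA.
#' @param reverse Reverse primer (given 5'->3' on the opposite strand, i.e.
#'   its reverse complement appears in the template).
#' @param tail_bp Tail length added to products of the reverse primer.
#' @return A `primer_assay` object.
#' @export
primer_assay <- function(forward_wt = NA, forward_ins = NA, reverse, tail_bp = 0) {
  primers <- c(forward_wt = forward_wt, forward_ins = forward_ins, reverse = reverse)
  for (nm in names(primers)) {
    p <- primers[[nm]]
    if (is.na(p)) next
    check_dna(p, sprintf("primer %s", nm), allow_n = FALSE)
    if (nchar(p) < 15) abort(sprintf("primer %s is shorter than 15 bp", nm))
  }
  if (is.na(forward_wt) && is.na(forward_ins)) abort("at least one forward primer required")
  structure(
    list(forward_wt = forward_wt, forward_ins = forward_ins,
         reverse = reverse, tail_bp = as.integer(tail_bp)),
    class = "primer_assay"
  )
}

find_sites <- function(template, primer) {
  if (nchar(primer) > nchar(template)) return(integer())
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(template))
  Biostrings::start(m)
}

#' Predict PCR fragment lengths per allele template
#'
#' For each template, each forward primer is located on the plus strand and
#' the reverse primer's reverse complement downstream of it; the fragment
#' length is the 5'-to-5' distance (forward primer start to the reverse
#' primer's 5' end, inclusive) plus the tail length. A primer with no
#' binding site on a template yields no product from that primer (that is
#' the allele-discriminating mechanism); a primer with multiple binding
#' sites on one template is a design error and raises.
#'
#' @param templates Named character vector of allele templates (for example
#'   `c(wt = ..., ins = ...)`).
#' @param assay A [primer_assay()].
#' @return Tibble: `allele`, `primer` (`forward_wt` / `forward_ins`),
#'   `fragment_bp` (NA when no product).
#' @export
insilico_pcr <- function(templates, assay) {
  stopifnot(inherits(assay, "primer_assay"))
  rows <- list()
  for (allele in names(templates)) {
    tmpl <- templates[[allele]]
    rev_sites <- find_sites(tmpl, revcomp(assay$reverse))
    if (length(rev_sites) > 1) {
      abort(sprintf("primer 'reverse' has %d binding sites on allele '%s'",
                    length(rev_sites), allele))
    }
    rev_end <- if (length(rev_sites) == 1) rev_sites + nchar(assay$reverse) - 1L else NA_integer_
    for (fp in c("forward_wt", "forward_ins")) {
      primer <- assay[[fp]]
      if (is.na(primer)) next
      f_sites <- find_sites(tmpl, primer)
      f_sites <- f_sites[is.na(rev_end) | f_sites < rev_end]
      if (length(f_sites) > 1) {
        abort(sprintf("primer '%s' has %d binding sites on allele '%s'",
                      fp, length(f_sites), allele))
      }
      frag <- if (length(f_sites) == 1 && !is.na(rev_end) && rev_end > f_sites) {
        rev_end - f_sites + 1L + assay$tail_bp
      } else {
        NA_integer_
      }
      rows[[length(rows) + 1]] <- tibble(allele = allele, primer = fp, fragment_bp = frag)
    }
  }
  bind_rows(rows)
}

#' Call a genotype from observed fragment lengths
#'
#' Matches observed sizes against the expected wild-type and insertion
#' fragment lengths within `tolerance_bp`: both present is het, insertion
#' only hom_ins, wild-type only hom_wt, neither nocall. Expectations closer
#' together than twice the tolerance are a configuration error.
#'
#' @param observed Numeric vector of observed fragment lengths (possibly
#'   empty).
#' @param expected_wt,expected_ins Expected sizes (bp).
#' @param tolerance_bp Matching tolerance (default 1).
#' @return One of `"hom_wt"`, `"het"`, `"hom_ins"`, `"nocall"`.
#' @export
genotype_from_fragments <- function(observed, expected_wt, expected_ins,
                                    tolerance_bp = 1) {
  if (abs(expected_wt - expected_ins) <= 2 * tolerance_bp) {
    abort("expected fragment sizes are not separable at this tolerance")
  }
  wt <- any(abs(observed - expected_wt) <= tolerance_bp)
  ins <- any(abs(observed - expected_ins) <= tolerance_bp)
  if (wt && ins) "het" else if (ins) "hom_ins" else if (wt) "hom_wt" else "nocall"
}

#' Simulate capillary fragment observations for a cohort
#'
#' Emits per-sample observed fragment sizes from true insertion genotypes,
#' with uniform +/- `sizing_error_bp` measurement error.
#'
#' @param genotypes Tibble with `sample_id` and `insertion_genotype`
#'   (hom_ref / het / hom_alt).
#' @param expected_wt,expected_ins Assay fragment sizes (bp).
#' @param sizing_error_bp Maximal absolute sizing error (default 1).
#' @return Tibble with `sample_id` and `fragments` (list-column of numeric).
#' @export
simulate_fragments <- function(genotypes, expected_wt, expected_ins,
                               sizing_error_bp = 1) {
  jitter1 <- function() sample(seq(-sizing_error_bp, sizing_error_bp), 1)
  genotypes |>
    mutate(fragments = map(.data$insertion_genotype, function(g) {
      sizes <- switch(g,
        hom_ref = expected_wt,
        het = c(expected_wt, expected_ins),
        hom_alt = expected_ins,
        numeric()
      )
      sizes + vapply(seq_along(sizes), function(i) jitter1(), numeric(1))
    })) |>
    select("sample_id", "fragments")
}

#' Cohort segregation analysis under a full-penetrance recessive model
#'
#' Cross-tabulates phenotype against assay genotype, lists discordant
#' samples (affected samples not homozygous for the insertion, and clear
#' samples that are), and reports the insertion allele frequency
#' `(2 hom_ins + het) / (2 called)` and the observed penetrance (affected
#' fraction among hom_ins).
#'
#' @param cohort Tibble with `sample_id`, `phenotype` (affected / clear /
#'   unknown) and `genotype` (hom_ins / het / hom_wt / nocall).
#' @return A `segregation_report` object; see [tidy.segregation_report()]
#'   and [glance.segregation_report()].
#' @export
segregation_report <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!any(cohort$phenotype == "affected")) {
    abort("segregation analysis needs at least one affected sample")
  }
  called <- cohort |> filter(.data$genotype != "nocall")
  if (nrow(called) == 0) abort("every sample is nocall; nothing to analyse")
  counts <- called |>
    count(.data$phenotype, .data$genotype) |>
    tidyr::complete(
      phenotype = unique(cohort$phenotype),
      genotype = c("hom_ins", "het", "hom_wt"),
      fill = list(n = 0L)
    )
  discordant <- called |>
    filter((.data$phenotype == "affected" & .data$genotype != "hom_ins") |
             (.data$phenotype == "clear" & .data$genotype == "hom_ins"))
  n_ins <- sum(called$genotype == "hom_ins")
  n_het <- sum(called$genotype == "het")
  af <- (2 * n_ins + n_het) / (2 * nrow(called))
  penetrance <- if (n_ins > 0) {
    sum(called$genotype == "hom_ins" & called$phenotype == "affected") / n_ins
  } else {
    NA_real_
  }
  structure(
    list(
      contingency = counts,
      discordant = discordant,
      allele_frequency = af,
      penetrance = penetrance,
      n_called = nrow(called),
      n_nocall = sum(cohort$genotype == "nocall")
    ),
    class = "segregation_report"
  )
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf(
    "<segregation_report> %d called samples; insertion allele frequency %.3f; %d discordant; observed penetrance %s\n",
    x$n_called, x$allele_frequency, nrow(x$discordant),
    if (is.na(x$penetrance)) "NA" else sprintf("%.2f", x$penetrance)
  ))
  print(tidy(x))
  invisible(x)
}

#' Contingency table of a segregation report
#'
#' One row per phenotype, one column per genotype plus a total -- the
#' familiar case/control segregation layout.
#'
#' @param x A `segregation_report`.
#' @param ... Unused.
#' @return Tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.segregation_report <- function(x, ...) {
  x$contingency |>
    pivot_wider(names_from = "genotype", values_from = "n", values_fill = 0L) |>
    select("phenotype", any_of(c("hom_ins", "het", "hom_wt"))) |>
    mutate(total = rowSums(across(-"phenotype")))
}

#' @rdname tidy.segregation_report
#' @export
#' @exportS3Method generics::glance
glance.segregation_report <- function(x, ...) {
  tibble(
    allele_frequency = x$allele_frequency,
    n_discordant = nrow(x$discordant),
    penetrance = x$penetrance,
    n_called = x$n_called,
    n_nocall = x$n_nocall
  )
}

#' Design an allele-specific fragment assay around a called insertion
#'
#' Builds a [primer_assay()] from the reference and element sequences: the
#' wild-type forward primer spans the insertion junction (so it is
#' disrupted on the insertion allele), the insertion forward primer is
#' anchored in the element, and a tailed reverse primer sits in the shared
#' downstream flank.
#'
#' @param ref_seq Reference contig sequence.
#' @param bp_right Last reference base before the inserted material.
#' @param element Inserted element sequence.
#' @param tsd Target-site duplication sequence.
#' @param primer_bp Primer length (default 20).
#' @param tail_bp Reverse-primer tail length (default 16).
#' @param offset_bp Distance from the junction to the reverse primer
#'   (default 60).
#' @return List with `assay` (a [primer_assay()]) and `templates` (named
#'   alleles `wt`, `ins`) and the `expected` fragment tibble.
#' @export
design_insertion_assay <- function(ref_seq, bp_right, element, tsd,
                                   primer_bp = 20, tail_bp = 16, offset_bp = 60) {
  win <- 400L
  wt <- str_sub(ref_seq, max(1, bp_right - win), bp_right + win)
  j <- bp_right - max(1, bp_right - win) + 1L # junction position inside wt window
  ins <- paste0(str_sub(wt, 1, j), element, tsd, str_sub(wt, j + 1))
  # the wild-type forward primer must span the whole duplicated target site
  # (plus flanks) or both insertion-allele junctions would reconstruct it
  span <- max(primer_bp, nchar(tsd) + 10L)
  fwd_wt <- str_sub(wt, j - span + 6L, j + 5L)
  fwd_ins <- str_sub(element, nchar(element) - 90L, nchar(element) - 91L + primer_bp)
  rev_bind <- str_sub(wt, j + offset_bp + 1, j + offset_bp + primer_bp)
  assay <- primer_assay(
    forward_wt = fwd_wt, forward_ins = fwd_ins,
    reverse = revcomp(rev_bind), tail_bp = tail_bp
  )
  templates <- c(wt = wt, ins = ins)
  expected <- insilico_pcr(templates, assay)
  list(assay = assay, templates = templates, expected = expected)
}
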