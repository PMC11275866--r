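# Recessive-model variant filtering: known-variant exclusion screen,
# case/control recessive filter, population-panel frequency filter, and
# critical-region restriction, with a stage-count report.

impact_rank <- function(x) match(x, IMPACT_LEVELS)

variant_calls <- function(variants, samples) {
  # per-variant named genotype vectors for a sample subset
  lapply(variants$genotypes, function(g) {
    setNames(g$call, g$sample_id)[samples]
  })
}

#' Screen cases against a panel of known disease variants
#'
#' A case "tests clear" of a panel variant when it is not homozygous for
#' the alternate allele at that site. Panel variants without a matching
#' record in the genotype data are reported as untyped (and therefore not
#' clear), never silently passed.
#'
#' @param variants Variant tibble with a `genotypes` list-column (see
#'   [read_vcf()]).
#' @param panel Exclusion panel tibble: `chrom`, `pos`, `ref`, `alt`,
#'   `disease`.
#' @param cases Character vector of case sample ids.
#' @return Tibble with one row per panel variant: `disease`, `status`
#'   (`"clear"`, `"hit"`, `"untyped"`) and `hit_samples` (list-column).
#' @export
screen_known_variants <- function(variants, panel, cases) {
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) {
    return(tibble(chrom = character(), pos = integer(), disease = character(),
                  status = character(), hit_samples = list()))
  }
  if (anyDuplicated(panel[c("chrom", "pos", "ref", "alt")])) {
    abort("exclusion panel has duplicate variant keys")
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  vkey <- key(variants)
  rows <- map(seq_len(nrow(panel)), function(i) {
    j <- match(key(panel[i, ]), vkey)
    if (is.na(j)) {
      return(tibble(chrom = panel$chrom[i], pos = panel$pos[i],
                    disease = panel$disease[i], status = "untyped",
                    hit_samples = list(character())))
    }
    calls <- variant_calls(variants[j, ], cases)[[1]]
    hits <- names(calls)[!is.na(calls) & calls == "hom_alt"]
    tibble(chrom = panel$chrom[i], pos = panel$pos[i],
           disease = panel$disease[i],
           status = if (length(hits) > 0) "hit" else "clear",
           hit_samples = list(hits))
  })
  bind_rows(rows)
}

new_filter_report <- function(stages) {
  stopifnot(all(diff(stages$n) <= 0))
  structure(list(stages = stages), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stages)
  invisible(x)
}

#' Stage counts of a variant filter report
#'
#' @param x A `filter_report`.
#' @param ... Unused.
#' @return Tibble with `stage` and `n` (monotonically non-increasing).
#' @export
#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) x$stages

#' @rdname tidy.filter_report
#' @export
#' @exportS3Method generics::glance
glance.filter_report <- function(x, ...) {
  tibble(
    n_input = x$stages$n[1],
    n_surviving = x$stages$n[nrow(x$stages)],
    n_stages = nrow(x$stages)
  )
}

filter_report <- function(variants) attr(variants, "filter_report")

#' Recessive-model case/control filter
#'
#' Keeps variants where every case is homozygous for the alternate allele
#' (a missing case call disqualifies), no control is homozygous alternate
#' (missing control calls are ignored), and the predicted impact reaches
#' `impact_min` on the MODIFIER < LOW < MODERATE < HIGH ladder.
#'
#' @param variants Variant tibble.
#' @param cases,controls Disjoint character vectors of sample ids.
#' @param impact_min Minimal impact level (default `"HIGH"`).
#' @return Surviving variants with a `filter_report` attribute.
#' @export
recessive_filter <- function(variants, cases, controls, impact_min = "HIGH") {
  if (length(cases) == 0) abort("recessive filter needs at least one case")
  overlap <- intersect(cases, controls)
  if (length(overlap) > 0) {
    abort(sprintf("samples in both case and control lists: %s",
                  paste(overlap, collapse = ", ")))
  }
  if (!impact_min %in% IMPACT_LEVELS) abort("unknown impact level")
  case_calls <- variant_calls(variants, cases)
  ctrl_calls <- variant_calls(variants, controls)
  keep_case <- map_lgl(case_calls, function(x) all(!is.na(x) & x == "hom_alt"))
  keep_ctrl <- map_lgl(ctrl_calls, function(x) !any(!is.na(x) & x == "hom_alt"))
  keep_imp <- impact_rank(variants$impact) >= impact_rank(impact_min)
  keep_imp[is.na(keep_imp)] <- FALSE
  stages <- tibble(
    stage = c("input", "case_hom_alt", "control_not_hom_alt", "impact"),
    n = c(
      nrow(variants),
      sum(keep_case),
      sum(keep_case & keep_ctrl),
      sum(keep_case & keep_ctrl & keep_imp)
    )
  )
  out <- variants[keep_case & keep_ctrl & keep_imp, ]
  attr(out, "filter_report") <- new_filter_report(stages)
  out
}

#' Population-panel frequency filter
#'
#' Removes variants that are common in an external population panel:
#' alternate-allele frequency above `af_max`, or (when `hom_disqualifies`)
#' any panel individual homozygous alternate. Variants absent from the
#' panel -- the private-variant case -- are retained and flagged in the
#' `panel_status` column.
#'
#' @param variants Variant tibble with `panel_af` and `panel_nhom` columns
#'   (parsed from the `PANEL_AF` / `PANEL_NHOM` INFO keys).
#' @param af_max Maximal panel allele frequency (default 0.05).
#' @param hom_disqualifies Whether one panel hom-alt individual removes the
#'   variant (default TRUE).
#' @return Surviving variants with a `panel_status` column
#'   (`"panel-absent"` or `"panel-rare"`).
#' @export
panel_frequency_filter <- function(variants, af_max = 0.05, hom_disqualifies = TRUE) {
  absent <- is.na(variants$panel_af)
  common <- !absent & (variants$panel_af > af_max |
                         (hom_disqualifies & !is.na(variants$panel_nhom) & variants$panel_nhom > 0))
  out <- variants[!common, ]
  out$panel_status <- ifelse(is.na(out$panel_af), "panel-absent", "panel-rare")
  out
}

#' Restrict variants to a critical region
#'
#' Keeps variants whose position lies in `[start, end]` (1-based inclusive)
#' of the region's chromosome.
#'
#' @param variants Variant tibble.
#' @param region One-row tibble with `chrom`, `start`, `end`.
#' @return Filtered variant tibble.
#' @export
restrict_to_region <- function(variants, region) {
  stopifnot(nrow(region) == 1)
  variants |>
    filter(.data$chrom == region$chrom, .data$pos >= region$start,
           .data$pos <= region$end)
}

#' Run the full variant-filter cascade
#'
#' Region restriction, recessive case/control filter, then the
#' population-panel filter, with a combined stage report.
#'
#' @inheritParams recessive_filter
#' @inheritParams panel_frequency_filter
#' @param region Optional critical region (skipped when NULL).
#' @return Surviving variants with a combined `filter_report` attribute.
#' @export
filter_variants <- function(variants, cases, controls, region = NULL,
                            impact_min = "HIGH", af_max = 0.05,
                            hom_disqualifies = TRUE) {
  stages <- tibble(stage = "input", n = nrow(variants))
  if (!is.null(region)) {
    variants <- restrict_to_region(variants, region)
    stages <- bind_rows(stages, tibble(stage = "critical_region", n = nrow(variants)))
  }
  variants <- recessive_filter(variants, cases, controls, impact_min)
  stages <- bind_rows(stages, tidy(filter_report(variants))[-1, ])
  variants <- panel_frequency_filter(variants, af_max, hom_disqualifies)
  stages <- bind_rows(stages, tibble(stage = "population_panel", n = nrow(variants)))
  attr(variants, "filter_report") <- new_filter_report(stages)
  variants
}
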