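# Homozygosity mapping: marker QC, PLINK-style sliding-window ROH
# detection, case-intersection / control-exclusion critical regions, and
# heterozygous-call refinement.

#' PLINK-style ROH scan parameters
#'
#' The published scan used a viewer's "default parameters"; these are the
#' corresponding explicit constants, with `min_markers` scaled to
#' desk-scale marker densities (~1 marker / 25 kb) so that a ~2 Mb run is
#' detectable on a sparse synthetic panel.
#'
#' @param window_snps Sliding-window width in markers.
#' @param het_allow Heterozygous calls tolerated per window.
#' @param missing_allow Missing calls tolerated per window.
#' @param hit_threshold Minimal fraction of homozygous windows covering a
#'   marker for it to be ROH-eligible.
#' @param min_markers Minimal markers per reported run.
#' @param min_length_bp Minimal run length.
#' @param gap_max_bp Maximal gap between consecutive markers in a run.
#' @param density_max_kb Maximal kb per marker within a run.
#' @return Named list of parameters.
#' @export
roh_params <- function(window_snps = 50, het_allow = 1, missing_allow = 5,
                       hit_threshold = 0.05, min_markers = 25,
                       min_length_bp = 1e6, gap_max_bp = 1e6,
                       density_max_kb = 50) {
  as.list(environment())
}

#' Marker quality control: MAF and missingness filters
#'
#' Removes markers with minor-allele frequency below `maf_min` (computed
#' over all non-missing calls of all samples, counting hom_alt as two
#' alternate alleles and het as one) or with a missing-call fraction above
#' `missing_max`.
#'
#' @param geno Long genotype tibble (`sample_id`, `phenotype`, `chrom`,
#'   `pos`, `marker_id`, `call`).
#' @param maf_min Minimum minor-allele frequency (markers strictly below are
#'   removed; default 0.05).
#' @param missing_max Maximum missing fraction (markers strictly above are
#'   removed; default 0.10).
#' @return Filtered genotype tibble with a `qc_report` attribute (class
#'   `qc_report`; see [glance.qc_report()]).
#' @export
qc_filter <- function(geno, maf_min = 0.05, missing_max = 0.10) {
  if (dplyr::n_distinct(geno$sample_id) < 2) abort("QC needs at least 2 samples")
  stats <- geno |>
    summarise(
      n = n(),
      n_missing = sum(.data$call == "missing"),
      alt = sum((.data$call == "hom_alt") * 2L + (.data$call == "het")),
      called = sum(.data$call != "missing"),
      .by = "marker_id"
    ) |>
    mutate(
      miss_frac = .data$n_missing / .data$n,
      af = ifelse(.data$called > 0, .data$alt / (2 * .data$called), 0),
      maf = pmin(.data$af, 1 - .data$af),
      fail_maf = .data$maf < maf_min,
      fail_miss = .data$miss_frac > missing_max
    )
  keep <- stats$marker_id[!stats$fail_maf & !stats$fail_miss]
  report <- structure(
    list(
      markers_total = nrow(stats),
      markers_removed_maf = sum(stats$fail_maf),
      markers_removed_missing = sum(stats$fail_miss & !stats$fail_maf),
      markers_kept = length(keep),
      maf_min = maf_min, missing_max = missing_max
    ),
    class = "qc_report"
  )
  if (length(keep) == 0) {
    abort(sprintf(
      "no markers left after QC: %d failed MAF < %g, %d failed missing > %g",
      report$markers_removed_maf, maf_min,
      sum(stats$fail_miss), missing_max
    ))
  }
  out <- geno |> filter(.data$marker_id %in% keep)
  attr(out, "qc_report") <- report
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d markers: removed %d (MAF < %g), %d (missing > %g); kept %d\n",
    x$markers_total, x$markers_removed_maf, x$maf_min,
    x$markers_removed_missing, x$missing_max, x$markers_kept
  ))
  invisible(x)
}

#' One-row summary of a QC report
#'
#' @param x A `qc_report` (or a genotype tibble carrying one as attribute).
#' @param ... Unused.
#' @return One-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  as_tibble(x[c("markers_total", "markers_removed_maf",
                "markers_removed_missing", "markers_kept",
                "maf_min", "missing_max")])
}

#' Retrieve the QC report attached by [qc_filter()]
#'
#' @param geno A genotype tibble returned by [qc_filter()].
#' @return The `qc_report` object.
#' @export
qc_report <- function(geno) attr(geno, "qc_report")

# marker eligibility by the sliding-window rule, vectorised with cumsums
roh_eligible <- function(call, params) {
  n <- length(call)
  w <- params$window_snps
  if (n < w) return(NULL)
  het <- as.integer(call == "het")
  mis <- as.integer(call == "missing")
  wsum <- function(x) {
    cs <- c(0L, cumsum(x))
    cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  }
  hom_win <- as.integer(wsum(het) <= params$het_allow & wsum(mis) <= params$missing_allow)
  nw <- n - w + 1L
  # windows covering marker j: indices max(1, j-w+1) .. min(j, nw)
  cs <- c(0L, cumsum(hom_win))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  hits <- cs[hi + 1L] - cs[lo]
  cover <- hi - lo + 1L
  hits / cover >= params$hit_threshold
}

empty_roh_tbl <- function() {
  tibble(start = integer(), end = integer(),
         n_markers = integer(), n_het = integer())
}

roh_runs_from_eligible <- function(pos, call, eligible, params) {
  # maximal index-consecutive eligible runs, additionally split at bp gaps
  # exceeding gap_max_bp, then filtered on size criteria
  out <- list(empty_roh_tbl())
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    gaps <- diff(pos[idx])
    brk <- which(gaps > params$gap_max_bp)
    pieces <- Map(c, c(1, brk + 1), c(brk, length(idx)))
    for (p in pieces) {
      sub <- idx[p[1]:p[2]]
      len <- pos[sub[length(sub)]] - pos[sub[1]] + 1L
      nm <- length(sub)
      if (nm >= params$min_markers && len >= params$min_length_bp &&
          len / nm <= params$density_max_kb * 1000) {
        out[[length(out) + 1]] <- tibble(
          start = pos[sub[1]], end = pos[sub[length(sub)]],
          n_markers = nm, n_het = sum(call[sub] == "het")
        )
      }
    }
  }
  bind_rows(out)
}

#' Detect runs of homozygosity per sample
#'
#' PLINK-style scan: a window of `window_snps` markers slides one marker at
#' a time; a window is homozygous when it holds at most `het_allow`
#' heterozygous and `missing_allow` missing calls; a marker is ROH-eligible
#' when the fraction of homozygous windows covering it reaches
#' `hit_threshold`; maximal runs of eligible markers are reported when they
#' satisfy `min_markers`, `min_length_bp`, marker gaps at most `gap_max_bp`
#' and density at least one marker per `density_max_kb`.
#'
#' @param geno Long genotype tibble (QC-filtered).
#' @param params [roh_params()].
#' @param samples Samples to scan (default: all).
#' @return A `roh_segments` tibble: `sample_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_markers`, `n_het`.
#' @export
detect_roh <- function(geno, params = roh_params(), samples = NULL) {
  if (!is.null(samples)) geno <- geno |> filter(.data$sample_id %in% samples)
  skipped <- character()
  out <- geno |>
    arrange(.data$sample_id, .data$chrom, .data$pos) |>
    group_by(.data$sample_id, .data$chrom) |>
    group_modify(function(d, key) {
      eligible <- roh_eligible(d$call, params)
      if (is.null(eligible)) {
        skipped <<- c(skipped, sprintf("%s/%s", key$sample_id, key$chrom))
        return(empty_roh_tbl())
      }
      roh_runs_from_eligible(d$pos, d$call, eligible, params)
    }) |>
    ungroup()
  if (length(skipped) > 0) {
    warn(sprintf(
      "skipped %d sample/chromosome pairs with fewer markers than window_snps (%s%s)",
      length(skipped), paste(head(skipped, 3), collapse = ", "),
      if (length(skipped) > 3) ", ..." else ""
    ))
  }
  structure(out, class = c("roh_segments", class(out)))
}

#' Plot ROH segments per sample
#'
#' @param object A `roh_segments` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.roh_segments <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$sample_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   yend = .data$sample_id),
      linewidth = 3, colour = "#2c7fb8"
    ) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

control_fully_hom <- function(geno, chrom, start, end, control_ids) {
  # TRUE per control: no het call at interval markers (missing ignored)
  sub <- geno |>
    filter(.data$chrom == !!chrom, .data$pos >= start, .data$pos <= end,
           .data$sample_id %in% control_ids)
  sub |>
    summarise(fully_hom = !any(.data$call == "het"), .by = "sample_id")
}

#' Intersect case ROHs and exclude control-homozygous intervals
#'
#' Per chromosome, intersects the ROH segments of every case; a resulting
#' interval is discarded when any control (samples with phenotype
#' `"control"` or `"unknown"`; unknowns are flagged) is fully homozygous --
#' no heterozygous call, missing calls ignored -- across the interval's
#' markers. Remaining intervals are returned sorted by length, longest
#' first.
#'
#' @param roh A `roh_segments` tibble (cases only are used).
#' @param geno Long genotype tibble (for phenotypes and control calls).
#' @return A `critical_region` tibble: `chrom`, `start`, `end`,
#'   `length_bp`, `n_markers`, `cases` (list-column of supporting case
#'   ids), `boundary_markers` (list-column).
#' @export
shared_critical_region <- function(roh, geno) {
  phen <- geno |> distinct(.data$sample_id, .data$phenotype)
  cases <- phen$sample_id[phen$phenotype == "case"]
  controls <- phen$sample_id[phen$phenotype %in% c("control", "unknown")]
  if (any(phen$phenotype == "unknown")) {
    inform("samples of unknown status are treated as controls for the exclusion step")
  }
  if (length(cases) == 0) abort("no case samples in the cohort")
  case_roh <- roh |> filter(.data$sample_id %in% cases)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    length_bp = integer(), n_markers = integer(),
    cases = list(), boundary_markers = list()
  )
  if (any(!cases %in% case_roh$sample_id)) {
    return(structure(empty, class = c("critical_region", class(empty))))
  }
  out <- list()
  for (ch in unique(case_roh$chrom)) {
    per_case <- lapply(cases, function(cs) {
      seg <- case_roh |> filter(.data$chrom == ch, .data$sample_id == cs)
      if (nrow(seg) == 0) return(IRanges::IRanges())
      IRanges::reduce(IRanges::IRanges(start = seg$start, end = seg$end))
    })
    inter <- Reduce(IRanges::intersect, per_case)
    if (length(inter) == 0) next
    for (i in seq_along(inter)) {
      st <- IRanges::start(inter)[i]
      en <- IRanges::end(inter)[i]
      ctl <- control_fully_hom(geno, ch, st, en, controls)
      if (nrow(ctl) > 0 && any(ctl$fully_hom)) next
      mk <- geno |>
        distinct(.data$chrom, .data$pos, .data$marker_id) |>
        filter(.data$chrom == ch, .data$pos >= st, .data$pos <= en) |>
        arrange(.data$pos)
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start = st, end = en,
        length_bp = en - st + 1L, n_markers = nrow(mk),
        cases = list(cases),
        boundary_markers = list(c(head(mk$marker_id, 1), tail(mk$marker_id, 1)))
      )
    }
  }
  res <- bind_rows(empty, bind_rows(out)) |> arrange(desc(.data$length_bp))
  structure(res, class = c("critical_region", class(res)))
}

#' Refine a critical region using case heterozygous calls
#'
#' Trims the region to the longest sub-interval whose markers carry no
#' heterozygous call in any case: the new boundaries are the outermost
#' case-homozygous markers flanked by the nearest case het calls. A case
#' het interior to the region splits it; the longest piece is returned and
#' the alternates are reported via a message and the `alternates`
#' attribute. Missing calls do not terminate a run.
#'
#' @param region A one-row `critical_region` (or tibble with `chrom`,
#'   `start`, `end`).
#' @param geno Long genotype tibble.
#' @return The refined `critical_region` tibble.
#' @export
refine_by_het_calls <- function(region, geno) {
  stopifnot(nrow(region) == 1)
  phen <- geno |> distinct(.data$sample_id, .data$phenotype)
  cases <- phen$sample_id[phen$phenotype == "case"]
  mk <- geno |>
    filter(.data$chrom == region$chrom, .data$pos >= region$start,
           .data$pos <= region$end, .data$sample_id %in% cases) |>
    summarise(any_het = any(.data$call == "het"), .by = c("pos", "marker_id")) |>
    arrange(.data$pos)
  if (nrow(mk) == 0 || !any(mk$any_het)) {
    return(region)
  }
  bad <- which(mk$any_het)
  bounds <- c(0L, bad, nrow(mk) + 1L)
  pieces <- tibble(
    from = head(bounds, -1) + 1L,
    to = tail(bounds, -1) - 1L
  ) |>
    filter(.data$to >= .data$from) |>
    mutate(
      start = mk$pos[.data$from],
      end = mk$pos[.data$to],
      length_bp = .data$end - .data$start + 1L,
      n_markers = .data$to - .data$from + 1L
    ) |>
    arrange(desc(.data$length_bp))
  if (nrow(pieces) == 0) {
    abort("every marker in the region carries a case het call; nothing to refine to")
  }
  if (nrow(pieces) > 1) {
    inform(sprintf(
      "case het calls split the region into %d candidates; returning the longest (%d bp)",
      nrow(pieces), pieces$length_bp[1]
    ))
  }
  out <- region |>
    mutate(
      start = pieces$start[1], end = pieces$end[1],
      length_bp = pieces$length_bp[1]
    )
  if ("n_markers" %in% names(out)) out$n_markers <- pieces$n_markers[1]
  if ("boundary_markers" %in% names(out)) {
    out$boundary_markers <- list(c(mk$marker_id[pieces$from[1]], mk$marker_id[pieces$to[1]]))
  }
  attr(out, "alternates") <- if (nrow(pieces) > 1) pieces[-1, c("start", "end", "length_bp")] else NULL
  out
}
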