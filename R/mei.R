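# Mobile-element-insertion calling from alignment signatures: localized
# depth elevation over the duplicated target site, clustered terminal
# soft-clips carrying element sequence and a poly-A tail, and discordant
# repeat-mapped mates. Breakpoints are 1-based inclusive; bp_left is the
# first base of the target-site duplication, bp_right its last.

#' Default thresholds for the insertion caller
#'
#' The published analysis made these judgements by eye in a genome viewer;
#' here they are explicit, logged numbers.
#'
#' @param elevation_factor Depth must reach this multiple of the median
#'   regional depth to count as elevated.
#' @param tsd_max_bp Maximal target-site-duplication length.
#' @param min_clip Minimal terminal soft-clip length considered (bp).
#' @param min_support Minimal reads per clip cluster, and minimal informative
#'   reads for a genotype call.
#' @param cluster_tol_bp Breakpoint tolerance when grouping clips.
#' @param het_min,hom_min Clipped-read fraction cutoffs: below `het_min` is
#'   hom_ref, at or above `hom_min` is hom_alt, between is het.
#' @param merge_min_overlap,merge_min_identity Overlap-merge rule for the two
#'   clip consensuses.
#' @param max_insert Insert size beyond which a same-contig pair counts as
#'   discordant.
#' @return A named list of thresholds.
#' @export
mei_params <- function(elevation_factor = 1.3, tsd_max_bp = 50, min_clip = 20,
                       min_support = 3, cluster_tol_bp = 2,
                       het_min = 0.2, hom_min = 0.8,
                       merge_min_overlap = 15, merge_min_identity = 0.9,
                       max_insert = 1000) {
  as.list(environment())
}

region_tbl <- function(contig, start, end) {
  tibble(chrom = contig, start = as.integer(start), end = as.integer(end))
}

aligned_spans <- function(aln) {
  # reference intervals covered by aligned (M/=/X) bases, one row per M run
  tk <- cigar_tokens(aln$cigar)
  refc <- tk$len * (tk$op %in% c("M", "D", "N", "=", "X"))
  cum_after <- cumsum(refc)
  off <- cum_after - refc # ref consumed before this token, global running
  first <- !duplicated(tk$idx)
  base <- off[first][match(tk$idx, tk$idx[first])]
  rel <- off - base
  keep <- tk$op %in% c("M", "=", "X")
  tibble(
    row = tk$idx[keep],
    start = aln$pos[tk$idx[keep]] + rel[keep],
    end = aln$pos[tk$idx[keep]] + rel[keep] + tk$len[keep] - 1L
  )
}

#' Per-base aligned depth and elevated intervals over a region
#'
#' Depth counts aligned (non-clipped) bases only, so soft-clipped tails do
#' not contribute. Elevated intervals are maximal runs where depth is at
#' least `elevation_factor` times the median depth of the region, kept only
#' if no longer than `tsd_max_bp` -- the width scale of a target-site
#' duplication.
#'
#' @param aln Alignment tibble (one sample or several; all records count).
#' @param region Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param params [mei_params()].
#' @return A `depth_profile` object: tibble (`chrom`, `pos`, `depth`) with
#'   attributes `elevated` (tibble of intervals with `mean_depth`) and
#'   `median_depth`.
#' @export
depth_profile <- function(aln, region, params = mei_params()) {
  region <- as_tibble(region)
  if (nrow(region) == 0 || region$end < region$start) {
    out <- tibble(chrom = character(), pos = integer(), depth = integer())
    attr(out, "elevated") <- region_tbl(character(), integer(), integer())
    attr(out, "median_depth") <- NA_real_
    class(out) <- c("depth_profile", class(out))
    return(out)
  }
  sub <- aln |> filter(.data$rname == region$chrom)
  spans <- if (nrow(sub) > 0) aligned_spans(sub) else NULL
  width <- region$end - region$start + 1L
  cov <- integer(width)
  if (!is.null(spans) && nrow(spans) > 0) {
    ir <- IRanges::IRanges(start = spans$start, end = spans$end)
    ir <- IRanges::restrict(ir, start = region$start, end = region$end)
    ir <- ir[IRanges::width(ir) > 0]
    covr <- IRanges::coverage(IRanges::shift(ir, 1L - region$start), width = width)
    cov <- as.integer(covr)
  }
  out <- tibble(chrom = region$chrom, pos = seq(region$start, region$end), depth = cov)
  med <- median(cov)
  thr <- params$elevation_factor * med
  hot <- cov >= thr & med > 0
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths <= params$tsd_max_bp
  elevated <- tibble(
    chrom = region$chrom,
    start = region$start + starts[keep] - 1L,
    end = region$start + ends[keep] - 1L
  ) |>
    mutate(mean_depth = map_dbl(seq_len(n()), function(i) {
      mean(cov[(starts[keep][i]):(ends[keep][i])])
    }))
  attr(out, "elevated") <- elevated
  attr(out, "median_depth") <- med
  class(out) <- c("depth_profile", class(out))
  out
}

#' Plot a depth profile with elevated intervals highlighted
#'
#' @param object A `depth_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.depth_profile <- function(object, ...) {
  elev <- attr(object, "elevated")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$pos, .data$depth)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_hline(yintercept = attr(object, "median_depth"),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = sprintf("position on %s", object$chrom[1]), y = "aligned depth") +
    ggplot2::theme_minimal()
  if (nrow(elev) > 0) {
    p <- p + ggplot2::geom_rect(
      data = elev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = Inf),
      fill = "#d7301f", alpha = 0.2
    )
  }
  p
}

#' Cluster terminal soft-clips at putative breakpoints
#'
#' Reads with a terminal soft-clip of at least `min_clip` bases are grouped
#' by clip side and position (within `cluster_tol_bp`). For a trailing clip
#' the breakpoint is the last aligned base and the clipped sequence extends
#' right of it (`side = "clip_right_of"`); for a leading clip the breakpoint
#' is the first aligned base (`side = "clip_left_of"`). The cluster
#' consensus is a column-wise majority over the clipped fragments, anchored
#' at the breakpoint (left-aligned for right-extending clips, right-aligned
#' for left-extending ones). Clusters below `min_support` are dropped.
#'
#' @inheritParams depth_profile
#' @return Tibble: `chrom`, `breakpoint`, `side`, `support`, `consensus`,
#'   plus `reads` (list-column of row indices into `aln`).
#' @export
cluster_soft_clips <- function(aln, region, params = mei_params()) {
  region <- as_tibble(region)
  sub_idx <- which(aln$rname == region$chrom)
  sub <- aln[sub_idx, ]
  lead <- leading_clip(sub$cigar)
  trail <- trailing_clip(sub$cigar)
  refw <- cigar_ref_width(sub$cigar)
  clips <- bind_rows(
    tibble(
      idx = sub_idx, bp = sub$pos, side = "clip_left_of", cliplen = lead,
      frag = str_sub(sub$seq, 1, lead)
    ) |> filter(lead >= params$min_clip),
    tibble(
      idx = sub_idx, bp = sub$pos + refw - 1L, side = "clip_right_of", cliplen = trail,
      frag = str_sub(sub$seq, -trail)
    ) |> filter(trail >= params$min_clip)
  ) |>
    filter(.data$bp >= region$start, .data$bp <= region$end)
  if (nrow(clips) == 0) {
    return(tibble(chrom = character(), breakpoint = integer(), side = character(),
                  support = integer(), consensus = character(), reads = list()))
  }
  clips |>
    arrange(.data$side, .data$bp) |>
    mutate(cluster = cumsum(c(1L, (diff(.data$bp) > params$cluster_tol_bp) |
                                (.data$side[-1] != .data$side[-n()]))), .by = NULL) |>
    summarise(
      chrom = region$chrom,
      breakpoint = as.integer(round(median(.data$bp))),
      side = .data$side[1],
      support = n(),
      consensus = consensus_sequence(
        .data$frag,
        align = if (.data$side[1] == "clip_right_of") "left" else "right"
      ),
      reads = list(.data$idx),
      .by = "cluster"
    ) |>
    filter(.data$support >= params$min_support) |>
    select(-"cluster") |>
    arrange(.data$breakpoint)
}

#' Detect a terminal poly-A (or leading poly-T) tract
#'
#' Scans both ends of a sequence for the longest terminal window of length
#' at least `min_run` whose adenine fraction (or thymine fraction at the 5'
#' end, the reverse-complement signature) is at least `purity`.
#'
#' @param sequence Nucleotide string.
#' @param min_run Minimal run length (default 10).
#' @param purity Minimal A (or T) fraction in the window (default 0.8).
#' @return Tibble with `polyA_length` (0 when absent) and `orientation`
#'   (`"forward"` for a 3' A-tail, `"reverse"` for a 5' T-head, `NA` when
#'   absent).
#' @export
detect_polyA <- function(sequence, min_run = 10, purity = 0.8) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  best_run <- function(x) {
    # longest k with mean(x[1:k]) >= purity, k >= min_run, and the window's
    # inner edge on the target base (so flanking sequence is not annexed)
    if (n < min_run) return(0L)
    frac <- cumsum(x) / seq_len(n)
    k <- which(frac >= purity & x)
    k <- k[k >= min_run]
    if (length(k) == 0) 0L else max(k)
  }
  a_tail <- best_run(rev(chars) == "A")
  t_head <- best_run(chars == "T")
  if (a_tail == 0 && t_head == 0) {
    return(tibble(polyA_length = 0L, orientation = NA_character_))
  }
  if (a_tail >= t_head) {
    tibble(polyA_length = as.integer(a_tail), orientation = "forward")
  } else {
    tibble(polyA_length = as.integer(t_head), orientation = "reverse")
  }
}

#' Count discordant reads over a region
#'
#' A region-overlapping record is discordant when its mate maps to a
#' different contig, is unmapped, or lies further than `max_insert` away on
#' the same contig.
#'
#' @inheritParams depth_profile
#' @return Integer count (0 with a warning for unpaired data).
#' @export
count_discordant <- function(aln, region, params = mei_params()) {
  region <- as_tibble(region)
  sub <- aln |>
    filter(.data$rname == region$chrom, .data$pos <= region$end,
           .data$pos + cigar_ref_width(.data$cigar) - 1L >= region$start)
  if (nrow(sub) == 0) return(0L)
  paired <- bitwAnd(sub$flag, 1L) > 0
  if (!any(paired)) {
    warn("no paired records in region; discordant count is 0")
    return(0L)
  }
  sub <- sub[paired, ]
  mate_unmapped <- bitwAnd(sub$flag, 8L) > 0
  diff_contig <- sub$rnext != "=" & sub$rnext != sub$rname
  too_far <- sub$rnext == "=" & abs(sub$pnext - sub$pos) > params$max_insert
  sum(mate_unmapped | diff_contig | too_far)
}

# overlap-merge the element-prefix and element-suffix consensuses
merge_consensus <- function(prefix, suffix, params) {
  p <- nchar(prefix); q <- nchar(suffix)
  if (min(p, q) < params$merge_min_overlap) {
    return(list(consensus = paste0(prefix, suffix), merged = FALSE))
  }
  for (o in seq(min(p, q), params$merge_min_overlap)) {
    a <- strsplit(str_sub(prefix, p - o + 1, p), "")[[1]]
    b <- strsplit(str_sub(suffix, 1, o), "")[[1]]
    if (mean(a == b) >= params$merge_min_identity) {
      return(list(
        consensus = paste0(prefix, str_sub(suffix, o + 1, q)),
        merged = TRUE
      ))
    }
  }
  list(consensus = paste0(prefix, suffix), merged = FALSE)
}

genotype_sample <- function(aln, idx, bp_left, bp_right, params) {
  sub <- aln[idx, ]
  informative <- sub$mapq > 0
  sub <- sub[informative, ]
  if (nrow(sub) == 0) {
    return(tibble(n_clip = 0L, n_span = 0L, genotype = "nocall"))
  }
  lead <- leading_clip(sub$cigar)
  trail <- trailing_clip(sub$cigar)
  refw <- cigar_ref_width(sub$cigar)
  endp <- sub$pos + refw - 1L
  tol <- params$cluster_tol_bp
  clip <- (lead >= params$min_clip & abs(sub$pos - bp_left) <= tol) |
    (trail >= params$min_clip & abs(endp - bp_right) <= tol)
  span <- lead < params$min_clip & trail < params$min_clip &
    sub$pos <= bp_left - 1L & endp >= bp_right + 1L
  n_clip <- sum(clip); n_span <- sum(span)
  r <- if (n_clip + n_span == 0) NA_real_ else n_clip / (n_clip + n_span)
  genotype <- if (n_clip + n_span < params$min_support) "nocall"
  else if (r >= params$hom_min) "hom_alt"
  else if (r >= params$het_min) "het"
  else "hom_ref"
  tibble(n_clip = as.integer(n_clip), n_span = as.integer(n_span), genotype = genotype)
}

#' Call mobile-element insertions in a region and genotype each sample
#'
#' Combines the three evidence channels: a call requires a left-extending
#' and a right-extending clip cluster whose breakpoints delimit a
#' target-site duplication of at most `tsd_max_bp`, plus poly-A evidence in
#' at least one cluster consensus. The insert consensus is the
#' overlap-merge of the two clipped consensuses (at least
#' `merge_min_overlap` bp at `merge_min_identity`); if they do not overlap
#' the concatenation is reported as partial with unknown insert length --
#' the caller never fabricates a full element length. Per-sample genotypes
#' come from the clipped fraction r = clipped / (clipped + spanning) among
#' mapping-quality > 0 reads: r >= `hom_min` hom_alt, r >= `het_min` het,
#' else hom_ref; fewer than `min_support` informative reads gives nocall.
#' An unpaired cluster is emitted as a low-confidence one-sided call.
#'
#' @param aln Alignment tibble with a `sample_id` column (multi-sample).
#' @param ref_seq Reference sequence of the region's contig (single string),
#'   used to extract the TSD.
#' @param region Tibble `chrom`, `start`, `end`.
#' @param params [mei_params()].
#' @return A `mei_calls` tibble: breakpoints, `tsd_sequence`,
#'   `insert_consensus`, `insert_length_estimate` (NA when unknown),
#'   `polyA_length`, evidence counts, `one_sided`, and a `genotypes`
#'   list-column (`sample_id`, `genotype`, `n_clip`, `n_span`).
#' @export
call_mei <- function(aln, ref_seq, region, params = mei_params()) {
  clusters <- cluster_soft_clips(aln, region, params)
  prof <- depth_profile(aln, region, params)
  elevated <- attr(prof, "elevated")
  med <- attr(prof, "median_depth")
  disc <- count_discordant(aln, region, params)
  samples <- unique(aln$sample_id %||% "sample")

  empty <- tibble(
    chrom = character(), bp_left = integer(), bp_right = integer(),
    tsd_sequence = character(), insert_consensus = character(),
    insert_length_estimate = integer(), polyA_length = integer(),
    polyA_orientation = character(), split_support = integer(),
    discordant_support = integer(), depth_ratio = double(),
    one_sided = logical(), genotypes = list()
  )
  if (nrow(clusters) == 0) {
    return(structure(empty, class = c("mei_calls", class(empty))))
  }

  lefts <- clusters |> filter(.data$side == "clip_left_of")
  rights <- clusters |> filter(.data$side == "clip_right_of")
  pairs <- tidyr::expand_grid(l = seq_len(nrow(lefts)), r = seq_len(nrow(rights)))
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      mutate(
        bp_left = lefts$breakpoint[.data$l],
        bp_right = rights$breakpoint[.data$r],
        tsd_len = .data$bp_right - .data$bp_left + 1L
      ) |>
      filter(.data$tsd_len >= 1, .data$tsd_len <= params$tsd_max_bp)
  }
  used <- c()
  calls <- list()
  for (i in seq_len(nrow(pairs))) {
    lc <- lefts[pairs$l[i], ]
    rc <- rights[pairs$r[i], ]
    prefix <- rc$consensus # right-extending clips carry the element 5' end
    suffix <- lc$consensus # left-extending clips carry the element 3' end
    pa <- bind_rows(detect_polyA(prefix), detect_polyA(suffix)) |>
      arrange(desc(.data$polyA_length)) |> head(1)
    if (pa$polyA_length == 0) next
    merged <- merge_consensus(prefix, suffix, params)
    idx <- c(lc$reads[[1]], rc$reads[[1]])
    gts <- bind_rows(lapply(samples, function(sid) {
      sel <- which(aln$sample_id == sid)
      genotype_sample(aln, sel, pairs$bp_left[i], pairs$bp_right[i], params) |>
        mutate(sample_id = sid, .before = 1)
    }))
    tsd_depth <- prof$depth[prof$pos >= pairs$bp_left[i] & prof$pos <= pairs$bp_right[i]]
    calls[[length(calls) + 1]] <- tibble(
      chrom = region$chrom,
      bp_left = pairs$bp_left[i], bp_right = pairs$bp_right[i],
      tsd_sequence = str_sub(ref_seq, pairs$bp_left[i], pairs$bp_right[i]),
      insert_consensus = merged$consensus,
      insert_length_estimate = if (merged$merged) nchar(merged$consensus) else NA_integer_,
      polyA_length = pa$polyA_length,
      polyA_orientation = pa$orientation,
      split_support = lc$support + rc$support,
      discordant_support = as.integer(disc),
      depth_ratio = if (med > 0) mean(tsd_depth) / med else NA_real_,
      one_sided = FALSE,
      genotypes = list(gts)
    )
    used <- c(used, paste0("L", pairs$l[i]), paste0("R", pairs$r[i]))
  }
  # unpaired clusters -> one-sided low-confidence calls
  singles <- bind_rows(
    lefts |> mutate(tag = paste0("L", seq_len(n()))),
    rights |> mutate(tag = paste0("R", seq_len(n())))
  ) |> filter(!.data$tag %in% used)
  for (i in seq_len(nrow(singles))) {
    sc <- singles[i, ]
    pa <- detect_polyA(sc$consensus)
    calls[[length(calls) + 1]] <- tibble(
      chrom = region$chrom,
      bp_left = if (sc$side == "clip_left_of") sc$breakpoint else NA_integer_,
      bp_right = if (sc$side == "clip_right_of") sc$breakpoint else NA_integer_,
      tsd_sequence = NA_character_,
      insert_consensus = sc$consensus,
      insert_length_estimate = NA_integer_,
      polyA_length = pa$polyA_length,
      polyA_orientation = pa$orientation,
      split_support = sc$support,
      discordant_support = as.integer(disc),
      depth_ratio = NA_real_,
      one_sided = TRUE,
      genotypes = list(tibble(sample_id = samples, genotype = "nocall",
                              n_clip = NA_integer_, n_span = NA_integer_))
    )
  }
  out <- bind_rows(empty, bind_rows(calls))
  # TSD consistency is a hard invariant of the breakpoint convention
  ok <- !out$one_sided
  stopifnot(all(nchar(out$tsd_sequence[ok]) == out$bp_right[ok] - out$bp_left[ok] + 1L))
  elev_attr <- elevated
  attr(out, "elevated") <- elev_attr
  structure(out, class = c("mei_calls", class(out)))
}

#' Tidy insertion calls into one row per sample
#'
#' @param x A `mei_calls` tibble.
#' @param ... Unused.
#' @return Tibble with call coordinates joined to per-sample genotypes.
#' @export
#' @exportS3Method generics::tidy
tidy.mei_calls <- function(x, ...) {
  as_tibble(x) |>
    select("chrom", "bp_left", "bp_right", "genotypes") |>
    unnest("genotypes")
}

#' Export insertion calls as VCF with symbolic ALT
#'
#' POS is the anchor base before the target-site duplication
#' (`bp_left - 1`), ALT is `<INS:ME:SINE>`; INFO carries `TSD`, `POLYA` and
#' `SVLEN` (omitted when the insert length is unknown); per-sample `GT`.
#'
#' @param calls A `mei_calls` tibble.
#' @param ref_seq Reference sequence of the contig (for the anchor base).
#' @param path Output path.
#' @param contigs Optional contig tibble (`name`, `length`).
#' @export
write_mei_vcf <- function(calls, ref_seq, path, contigs = NULL) {
  calls <- calls |> filter(!.data$one_sided)
  samples <- if (nrow(calls) > 0) calls$genotypes[[1]]$sample_id else character()
  meta <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=INS:ME:SINE,Description=\"SINE mobile element insertion\">",
    "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication\">",
    "##INFO=<ID=POLYA,Number=1,Type=Integer,Description=\"Poly-A tract length in insert consensus\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insert length estimate\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(contigs)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>", contigs$name, as.integer(contigs$length)))
  }
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples), collapse = "\t")
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", nocall = "./.")
  body <- map_chr(seq_len(nrow(calls)), function(i) {
    pos <- calls$bp_left[i] - 1L
    info <- sprintf("TSD=%s;POLYA=%d", calls$tsd_sequence[i], calls$polyA_length[i])
    if (!is.na(calls$insert_length_estimate[i])) {
      info <- sprintf("%s;SVLEN=%d", info, calls$insert_length_estimate[i])
    }
    gts <- paste(gt_code[calls$genotypes[[i]]$genotype], collapse = "\t")
    paste(calls$chrom[i], pos, sprintf("MEI_%d", i), str_sub(ref_seq, pos, pos),
          "<INS:ME:SINE>", ".", "PASS", info, "GT", gts, sep = "\t")
  })
  readr::write_lines(c(meta, hdr, body), path)
  invisible(path)
}
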