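# Read simulator: paired-end alignments over the focal contig, emitted
# pre-aligned to the insertion-free reference so that the insertion allele
# leaves its diagnostic signatures (soft-clip clusters at the breakpoints,
# doubled depth over the duplicated target site, discordant repeat-mapped
# mates) without an aligner dependency.

MIN_ANCHOR_BP <- 20L

#' Simulate aligned paired-end reads for a set of samples
#'
#' Draws fragments (normal insert-size model) from the wild-type or donor
#' allele of the focal contig according to each sample's insertion genotype,
#' and writes each read as an alignment against the insertion-free
#' reference:
#' * reads crossing a breakpoint with at least 20 bp of reference anchor are
#'   emitted soft-clipped, the clip carrying element sequence;
#' * reads whose reference anchor is too short (including reads wholly
#'   inside the element) are emitted on a different contig with mapping
#'   quality 0, mimicking multi-copy repeat mapping, which makes their mates
#'   discordant;
#' * of the remaining breakpoint-crossing pairs, a `discordant_frac`
#'   fraction has its clipped read re-assigned the same way.
#'
#' Because the donor carries two copies of the target site, reads from both
#' copies pile onto the single reference copy, which doubles depth over the
#' TSD interval. Coordinates are 1-based, CIGARs valid, and records
#' round-trip unchanged through [write_sam()] / [read_sam()].
#'
#' @param config A [sim_config()].
#' @param reference A [simulate_reference()] result.
#' @param sample_genotypes Tibble (`sample_id`, `insertion_genotype` in
#'   hom_ref/het/hom_alt). Defaults to two probands, one obligate carrier
#'   and one clear control drawn from `truth`.
#' @param truth Ground truth from [simulate_genotype_cohort()] (only needed
#'   to derive the default `sample_genotypes`).
#' @param tiled When TRUE, fragments are placed on a regular grid with a
#'   fixed insert size instead of being sampled, giving flat coverage --
#'   the fully noiseless setting in which depth signatures are exact.
#' @return Alignment tibble (SAM columns + `sample_id`), with attributes
#'   `sq` (contig header tibble) and `read_stats` (per-sample pair counts
#'   used by the discordant-mate oracle: `n_pairs`, `n_forced`,
#'   `n_coin_eligible`).
#' @export
simulate_reads <- function(config, reference, sample_genotypes = NULL, truth = NULL,
                           tiled = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "sim_reference"))
  if (is.null(sample_genotypes)) {
    if (is.null(truth)) abort("supply sample_genotypes or truth")
    sample_genotypes <- default_wgs_samples(truth)
  }
  bad <- setdiff(sample_genotypes$insertion_genotype, c("hom_ref", "het", "hom_alt"))
  if (length(bad) > 0) abort(sprintf("unknown insertion genotype: %s", bad[1]))

  tr <- reference$truth
  focal <- tr$insertion_contig
  ref_seq <- reference$contigs$seq[reference$contigs$name == focal]
  don_seq <- donor_sequence(reference)
  rl <- as.integer(config$read_length_bp)
  g <- tr$bp_right
  s <- tr$bp_left
  el_tot <- nchar(tr$inserted_sequence) + nchar(tr$tsd_sequence)
  contig_len <- nchar(ref_seq)
  n_pairs <- as.integer(round(contig_len * config$mean_depth / (2 * rl)))
  others <- setdiff(reference$contigs$name, focal)
  if (length(others) == 0) abort("need >= 2 contigs so repeat-mapped mates have a destination")

  # classify one read interval [a, b] on the donor against the reference
  classify_donor <- function(a, b) {
    n <- length(a)
    type <- character(n)
    pos <- integer(n)
    cigar <- character(n)
    ref_end <- b <= g
    post <- a > g + nchar(tr$inserted_sequence)
    type[ref_end] <- "ref"
    pos[ref_end] <- a[ref_end]
    type[post] <- "ref"
    pos[post] <- a[post] - el_tot
    cigar[ref_end | post] <- sprintf("%dM", rl)
    cross1 <- a <= g & b > g
    anch1 <- g - a + 1L
    ok1 <- cross1 & anch1 >= MIN_ANCHOR_BP
    type[ok1] <- "clip_right"
    pos[ok1] <- a[ok1]
    cigar[ok1] <- sprintf("%dM%dS", anch1[ok1], rl - anch1[ok1])
    cross2 <- a > g & a <= g + nchar(tr$inserted_sequence) & b > g + nchar(tr$inserted_sequence)
    anch2 <- b - g - nchar(tr$inserted_sequence)
    ok2 <- cross2 & anch2 >= MIN_ANCHOR_BP
    type[ok2] <- "clip_left"
    pos[ok2] <- s
    cigar[ok2] <- sprintf("%dS%dM", rl - anch2[ok2], anch2[ok2])
    type[type == ""] <- "ambig"
    tibble(type = type, pos = pos, cigar = cigar)
  }

  with_seed(config$seed, "reads", {
    per_sample <- lapply(seq_len(nrow(sample_genotypes)), function(si) {
      sid <- sample_genotypes$sample_id[si]
      gt <- sample_genotypes$insertion_genotype[si]
      frag <- if (tiled) {
        rep(as.integer(config$fragment_mean_bp), n_pairs)
      } else {
        pmin(pmax(as.integer(round(rnorm(n_pairs, config$fragment_mean_bp,
                                         config$fragment_sd_bp))),
                  2L * rl), 3L * as.integer(config$fragment_mean_bp))
      }
      from_donor <- switch(gt,
        hom_ref = rep(FALSE, n_pairs),
        hom_alt = rep(TRUE, n_pairs),
        het = if (tiled) seq_len(n_pairs) %% 2L == 0L else runif(n_pairs) < 0.5
      )
      allele_len <- ifelse(from_donor, contig_len + el_tot, contig_len)
      start <- if (tiled) {
        as.integer(round(seq(1L, allele_len[1] - frag[1], length.out = n_pairs)))
      } else {
        as.integer(floor(runif(n_pairs) * (allele_len - frag))) + 1L
      }
      a1 <- start; b1 <- start + rl - 1L
      a2 <- start + frag - rl; b2 <- start + frag - 1L

      cl1 <- classify_donor(a1, b1)
      cl2 <- classify_donor(a2, b2)
      # wild-type fragments map trivially
      cl1$type[!from_donor] <- "ref"; cl1$pos[!from_donor] <- a1[!from_donor]
      cl2$type[!from_donor] <- "ref"; cl2$pos[!from_donor] <- a2[!from_donor]
      cl1$cigar[!from_donor] <- sprintf("%dM", rl)
      cl2$cigar[!from_donor] <- sprintf("%dM", rl)

      moved1 <- cl1$type == "ambig"
      moved2 <- cl2$type == "ambig"
      n_forced <- sum((moved1 | moved2) & !(moved1 & moved2))
      eligible <- !moved1 & !moved2 &
        (cl1$type %in% c("clip_right", "clip_left") | cl2$type %in% c("clip_right", "clip_left"))
      coin <- eligible & runif(n_pairs) < config$discordant_frac
      # the coin moves the clipped read of the pair
      move_r1 <- coin & cl1$type %in% c("clip_right", "clip_left")
      move_r2 <- coin & !move_r1 & cl2$type %in% c("clip_right", "clip_left")
      moved1 <- moved1 | move_r1
      moved2 <- moved2 | move_r2

      place_moved <- function(n) {
        tibble(
          rname = sample(others, n, replace = TRUE),
          pos = as.integer(floor(runif(n) * (contig_len - rl))) + 1L
        )
      }
      mk_read <- function(cl, moved, a, first) {
        rname <- rep(focal, n_pairs)
        pos <- cl$pos
        cigar <- cl$cigar
        mapq <- rep(60L, n_pairs)
        if (any(moved)) {
          dest <- place_moved(sum(moved))
          rname[moved] <- dest$rname
          pos[moved] <- dest$pos
          cigar[moved] <- sprintf("%dM", rl)
          mapq[moved] <- 0L
        }
        seq <- substring(ifelse(from_donor, don_seq, ref_seq), a, a + rl - 1L)
        tibble(rname = rname, pos = pos, cigar = cigar, mapq = mapq,
               seq = seq, first = first)
      }
      r1 <- mk_read(cl1, moved1, a1, TRUE)
      r2 <- mk_read(cl2, moved2, a2, FALSE)

      same_contig <- r1$rname == r2$rname
      flag1 <- 1L + 64L + 32L + ifelse(same_contig, 2L, 0L)
      flag2 <- 1L + 128L + 16L + ifelse(same_contig, 2L, 0L)
      qname <- sprintf("%s_p%06d", sid, seq_len(n_pairs))
      tl <- ifelse(same_contig, frag, 0L)
      reads <- bind_rows(
        r1 |> mutate(qname = qname, flag = flag1,
                     rnext = ifelse(same_contig, "=", r2$rname),
                     pnext = r2$pos, tlen = as.integer(tl)),
        r2 |> mutate(qname = qname, flag = flag2,
                     rnext = ifelse(same_contig, "=", r1$rname),
                     pnext = r1$pos, tlen = as.integer(-tl))
      ) |>
        mutate(qual = "*", sample_id = sid) |>
        select("qname", "flag", "rname", "pos", "mapq", "cigar",
               "rnext", "pnext", "tlen", "seq", "qual", "sample_id")
      if (config$error_rate > 0) {
        reads$seq <- vapply(reads$seq, mutate_sequence, "", rate = config$error_rate)
      }
      list(
        reads = reads,
        stats = tibble(sample_id = sid, n_pairs = n_pairs, n_forced = n_forced,
                       n_coin_eligible = sum(eligible))
      )
    })
    out <- bind_rows(lapply(per_sample, `[[`, "reads")) |>
      arrange(.data$rname, .data$pos, .data$qname)
    attr(out, "sq") <- tibble(name = reference$contigs$name,
                              length = nchar(reference$contigs$seq))
    attr(out, "read_stats") <- bind_rows(lapply(per_sample, `[[`, "stats"))
    out
  })
}
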