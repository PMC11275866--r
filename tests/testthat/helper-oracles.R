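# Independent oracles used across the suite. These deliberately re-derive
# results by a different route from the package implementation.

# ---- brute-force ROH enumerator -------------------------------------------
# Eligibility by explicit per-window loops; runs by testing every
# sub-interval against the criteria directly and keeping maximal ones.
oracle_roh <- function(pos, call, params) {
  n <- length(call)
  w <- params$window_snps
  if (n < w) return(tibble::tibble(start = integer(), end = integer(),
                                   n_markers = integer(), n_het = integer()))
  nw <- n - w + 1
  hom_win <- logical(nw)
  for (i in seq_len(nw)) {
    win <- call[i:(i + w - 1)]
    hom_win[i] <- sum(win == "het") <= params$het_allow &&
      sum(win == "missing") <= params$missing_allow
  }
  eligible <- logical(n)
  for (j in seq_len(n)) {
    cover <- max(1, j - w + 1):min(j, nw)
    eligible[j] <- mean(hom_win[cover]) >= params$hit_threshold
  }
  # every sub-interval: core-valid = all eligible and gaps within bound
  core <- function(i, j) {
    all(eligible[i:j]) &&
      (i == j || all(diff(pos[i:j]) <= params$gap_max_bp))
  }
  out <- list(tibble::tibble(start = integer(), end = integer(),
                             n_markers = integer(), n_het = integer()))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!core(i, j)) next
      maximal <- (i == 1 || !core(i - 1, j)) && (j == n || !core(i, j + 1))
      if (!maximal) next
      len <- pos[j] - pos[i] + 1
      nm <- j - i + 1
      if (nm >= params$min_markers && len >= params$min_length_bp &&
          len / nm <= params$density_max_kb * 1000) {
        out[[length(out) + 1]] <- tibble::tibble(
          start = pos[i], end = pos[j], n_markers = nm,
          n_het = sum(call[i:j] == "het")
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# single-sample genotype tibble for the ROH scanners
single_sample_geno <- function(pos, call, sample_id = "s1", phenotype = "case",
                               chrom = "chr1") {
  tibble::tibble(
    sample_id = sample_id, phenotype = phenotype, chrom = chrom,
    pos = as.integer(pos), marker_id = sprintf("%s_%d", chrom, pos), call = call
  )
}

# ---- recursive affine-gap aligner (memoised Gotoh recursion) --------------
# Independent of Biostrings: best global alignment score with gap cost
# open + k * extend, plus the maximal match count among optimal alignments
# is not tracked -- score equality is the contract under test.
oracle_affine_score <- function(a, b, match = 2, mismatch = -3,
                                gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  # state: in_gap = 0 none, 1 gap in b (consuming a), 2 gap in a
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > n && j > m) {
      0
    } else {
      best <- -Inf
      if (i <= n && j <= m) {
        sub <- if (av[i] == bv[j]) match else mismatch
        best <- max(best, sub + rec(i + 1, j + 1, 0L))
      }
      if (i <= n) { # a[i] against gap
        cost <- gap_extend + if (state == 1L) 0 else gap_open
        best <- max(best, -cost + rec(i + 1, j, 1L))
      }
      if (j <= m) { # gap against b[j]
        cost <- gap_extend + if (state == 2L) 0 else gap_open
        best <- max(best, -cost + rec(i, j + 1, 2L))
      }
      best
    }
    memo[[key]] <- res
    res
  }
  rec(1L, 1L, 0L)
}

# ---- misc -----------------------------------------------------------------
random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mutate_dna_str <- function(seq, k) {
  # exactly k substitutions at distinct positions
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(chars, collapse = "")
}

# a small two-isoform transcript model on a given strand for mapping tests
toy_model <- function(strand = "+") {
  exons <- tibble::tibble(
    exon_id = 1:5,
    start = c(101L, 301L, 501L, 701L, 901L),
    end = c(160L, 390L, 590L, 790L, 1000L), # lengths 60, 90, 90, 90, 100
    alt_spliced = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  # total 430 -- pad exon 5 to make both isoform CDS lengths multiples of 3
  exons$end[5] <- 998L # lengths 60+90+90+90+98 = 428 ... adjust below
  exons$end[5] <- 1000L
  exons$end[1] <- 162L # 62+90+90+90+100 = 432 (/3); short 342 (/3)
  transcript_model(
    gene_id = "toy", accession = "ACC_1", chrom = "ctg", strand = strand,
    exons = exons,
    isoforms = list(long = 1:5, short = c(1:3, 5L))
  )
}
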