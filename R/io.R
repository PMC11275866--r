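# Standard-format I/O: FASTA (Biostrings), SAM text, VCF 4.2, PED/MAP, BED,
# transcript-model JSON. All readers return tibbles (or light list objects);
# all coordinates are 1-based inclusive except BED export (0-based half-open).

#' Read / write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] returning a tibble
#' with `name` and `seq` columns, the container used for reference contigs
#' and repeat libraries throughout the package.
#'
#' @param path File path.
#' @param x For `write_fasta()`, a data frame with `name` and `seq` columns.
#' @return `read_fasta()`: tibble with columns `name`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(name = names(ss), seq = as.character(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$seq, x$name))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

SAM_COLS <- c(
  "qname", "flag", "rname", "pos", "mapq", "cigar",
  "rnext", "pnext", "tlen", "seq", "qual"
)

#' Read / write SAM alignment text
#'
#' Plain-text SAM is the alignment contract for the insertion caller. The
#' reader keeps the `@SQ` header (as an attribute) and returns one row per
#' record; an optional `sample_id` labels all records from one file so that
#' multi-sample evidence can live in one tibble.
#'
#' @param path SAM file path.
#' @param sample_id Optional sample label attached as a column.
#' @return Tibble with the 11 mandatory SAM columns (`pos`, `flag`, `mapq`,
#'   `pnext`, `tlen` as integers) and attribute `sq` (tibble `name`, `length`).
#' @export
read_sam <- function(path, sample_id = NULL) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_tbl <- tibble(
    name = sub(".*SN:([^\t]+).*", "\\1", sq),
    length = as.integer(sub(".*LN:([0-9]+).*", "\\1", sq))
  )
  if (length(rec) == 0) {
    out <- tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character()
    )
  } else {
    fields <- str_split(rec, "\t")
    short <- which(lengths(fields) < 11)
    if (length(short) > 0) {
      abort(sprintf("malformed SAM record at data line %d of %s", short[1], path))
    }
    mat <- t(vapply(fields, function(f) f[1:11], character(11)))
    out <- as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE), SAM_COLS))
    out <- out |> mutate(across(c("flag", "pos", "mapq", "pnext", "tlen"), as.integer))
  }
  if (!is.null(sample_id)) out$sample_id <- sample_id
  attr(out, "sq") <- sq_tbl
  out
}

#' @rdname read_sam
#' @param aln Alignment tibble as produced by [simulate_reads()] or
#'   [read_sam()]; needs an `sq` attribute or `sq` argument for the header.
#' @param sq Tibble with contig `name` and `length` for `@SQ` lines.
#' @export
write_sam <- function(aln, path, sq = attr(aln, "sq")) {
  if (is.null(sq)) abort("write_sam() needs @SQ contig info (sq argument or attribute)")
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", sq$name, as.integer(sq$length))
  )
  aln <- aln |> arrange(.data$rname, .data$pos, .data$qname)
  body <- if (nrow(aln) == 0) character() else {
    do.call(paste, c(lapply(SAM_COLS, function(cl) as.character(aln[[cl]])), sep = "\t"))
  }
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

# --- CIGAR arithmetic -------------------------------------------------------

# flat token table for a vector of CIGAR strings: one row per operation
cigar_tokens <- function(cigar) {
  toks <- stringr::str_extract_all(cigar, "[0-9]+[MIDNSHP=X]")
  n <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  tibble(
    idx = rep(seq_along(cigar), n),
    len = as.integer(sub("[MIDNSHP=X]$", "", flat)),
    op = str_sub(flat, -1)
  )
}

cigar_op_sum <- function(cigar, ops) {
  tk <- cigar_tokens(cigar)
  w <- tk$len * (tk$op %in% ops)
  out <- integer(length(cigar))
  s <- rowsum(w, tk$idx)
  out[as.integer(rownames(s))] <- as.integer(s)
  out
}

cigar_ref_width <- function(cigar) cigar_op_sum(cigar, c("M", "D", "N", "=", "X"))

cigar_query_width <- function(cigar) cigar_op_sum(cigar, c("M", "I", "S", "=", "X"))

leading_clip <- function(cigar) {
  as.integer(ifelse(grepl("^[0-9]+S", cigar), sub("^([0-9]+)S.*", "\\1", cigar), 0L))
}

trailing_clip <- function(cigar) {
  as.integer(ifelse(grepl("[0-9]+S$", cigar), sub(".*?([0-9]+)S$", "\\1", cigar), 0L))
}

# --- VCF --------------------------------------------------------------------

gt_to_call <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("\\|", "/", gt)
  dplyr::case_when(
    gt %in% c("0/0") ~ "hom_ref",
    gt %in% c("0/1", "1/0") ~ "het",
    gt %in% c("1/1") ~ "hom_alt",
    TRUE ~ "missing"
  )
}

call_to_gt <- function(call) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[call]
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Read an annotated VCF into a variant tibble
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into the tabular variant
#' representation used by the filtering stages: one row per record with an
#' `impact` column taken from the `IMPACT` INFO key, optional population-panel
#' summary columns (`panel_af` from `PANEL_AF`, `panel_nhom` from
#' `PANEL_NHOM`), and per-sample genotype calls in a `genotypes` list-column
#' of tibbles (`sample_id`, `call`).
#'
#' A light line-level validation pass runs first so that malformed files fail
#' with the offending line number rather than an opaque parser error.
#'
#' @param path VCF file path.
#' @return Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `impact`,
#'   `panel_af`, `panel_nhom`, `genotypes`.
#' @export
read_vcf <- function(path) {
  lines <- readr::read_lines(path)
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1) {
    abort(sprintf("invalid VCF %s: missing #CHROM header line", path))
  }
  body <- seq_along(lines) > hdr_idx & nzchar(lines)
  nfield <- str_count(lines, "\t") + 1
  nhdr <- str_count(lines[hdr_idx], "\t") + 1
  bad <- which(body & nfield != nhdr)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid VCF %s: line %d has %d fields, expected %d",
      path, bad[1], nfield[bad[1]], nhdr
    ))
  }
  badpos <- which(body)[is.na(suppressWarnings(
    as.integer(map_chr(str_split(lines[body], "\t"), 2))
  ))]
  if (length(badpos) > 0) {
    abort(sprintf("invalid VCF %s: non-numeric POS at line %d", path, badpos[1]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- v@fix[, "INFO"]
  samples <- colnames(v@gt)[-1]
  gt_raw <- vcfR::extract.gt(v, element = "GT", return.alleles = FALSE)
  genotypes <- lapply(seq_len(nrow(fix)), function(i) {
    tibble(sample_id = samples, call = gt_to_call(gt_raw[i, ]))
  })
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    impact = info_field(info, "IMPACT"),
    panel_af = suppressWarnings(as.numeric(info_field(info, "PANEL_AF"))),
    panel_nhom = suppressWarnings(as.integer(info_field(info, "PANEL_NHOM"))),
    genotypes = genotypes
  )
}

#' Write a variant tibble as VCF 4.2
#'
#' Inverse of [read_vcf()]: emits `IMPACT`, `PANEL_AF`, `PANEL_NHOM` INFO
#' keys (the panel keys only where non-missing) and a `GT` FORMAT column per
#' sample.
#'
#' @param variants Variant tibble (see [read_vcf()] for the contract).
#' @param path Output path.
#' @param contigs Optional tibble (`name`, `length`) for `##contig` lines.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  samples <- if (nrow(variants) > 0) variants$genotypes[[1]]$sample_id else character()
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted functional impact\">",
    "##INFO=<ID=PANEL_AF,Number=1,Type=Float,Description=\"Population panel alternate allele frequency\">",
    "##INFO=<ID=PANEL_NHOM,Number=1,Type=Integer,Description=\"Population panel hom-alt sample count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(contigs)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>", contigs$name, as.integer(contigs$length)))
  }
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples), collapse = "\t")
  body <- if (nrow(variants) == 0) character() else {
    info <- sprintf("IMPACT=%s", variants$impact)
    if ("panel_af" %in% names(variants)) {
      has <- !is.na(variants$panel_af)
      info[has] <- sprintf("%s;PANEL_AF=%s;PANEL_NHOM=%d",
                           info[has], format(variants$panel_af[has], trim = TRUE),
                           as.integer(variants$panel_nhom[has]))
    }
    gt <- vapply(variants$genotypes, function(g) paste(call_to_gt(g$call), collapse = "\t"), "")
    paste(variants$chrom, variants$pos, variants$id %||% ".", variants$ref,
          variants$alt, ".", "PASS", info, "GT", gt, sep = "\t")
  }
  readr::write_lines(c(meta, hdr, body), path)
  invisible(path)
}

# --- PED/MAP ----------------------------------------------------------------

#' Read / write a genotype cohort as a PED/MAP pair
#'
#' The long genotype tibble (`sample_id`, `phenotype`, `chrom`, `pos`,
#' `marker_id`, `call`) maps onto PLINK text PED/MAP: MAP carries the marker
#' order, PED one row per sample with two allele columns per marker (`0 0`
#' for missing). Alleles are written as A (reference) and B (alternate);
#' phenotype is coded 2 = case, 1 = control, 0 = unknown.
#'
#' @param geno Genotype tibble.
#' @param prefix Path prefix; `.ped` and `.map` are appended.
#' @return `read_pedmap()` returns the genotype tibble.
#' @export
write_pedmap <- function(geno, prefix) {
  markers <- geno |> distinct(.data$chrom, .data$pos, .data$marker_id) |> arrange(.data$chrom, .data$pos)
  readr::write_tsv(
    tibble(chrom = markers$chrom, marker_id = markers$marker_id, cm = 0, pos = markers$pos),
    paste0(prefix, ".map"), col_names = FALSE
  )
  allele_str <- c(hom_ref = "A A", het = "A B", hom_alt = "B B", missing = "0 0")
  wide <- geno |>
    mutate(marker_id = factor(.data$marker_id, levels = markers$marker_id)) |>
    arrange(.data$sample_id, .data$marker_id) |>
    summarise(gt = paste(allele_str[.data$call], collapse = " "),
              phenotype = .data$phenotype[1], .by = "sample_id")
  pheno_code <- c(case = 2, control = 1, unknown = 0)
  lines <- sprintf("FAM1 %s 0 0 0 %d %s", wide$sample_id, pheno_code[wide$phenotype], wide$gt)
  readr::write_lines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_pedmap
#' @export
read_pedmap <- function(prefix) {
  map <- readr::read_tsv(paste0(prefix, ".map"),
    col_names = c("chrom", "marker_id", "cm", "pos"),
    col_types = "ccin", progress = FALSE
  )
  ped <- str_split(readr::read_lines(paste0(prefix, ".ped")), "[ \t]+")
  pheno_code <- c("2" = "case", "1" = "control", "0" = "unknown")
  rows <- map(ped, function(f) {
    al <- matrix(f[-(1:6)], ncol = 2, byrow = TRUE)
    call <- dplyr::case_when(
      al[, 1] == "0" | al[, 2] == "0" ~ "missing",
      al[, 1] == al[, 2] & al[, 1] == "A" ~ "hom_ref",
      al[, 1] == al[, 2] ~ "hom_alt",
      TRUE ~ "het"
    )
    tibble(
      sample_id = f[2], phenotype = unname(pheno_code[f[6]]),
      chrom = map$chrom, pos = as.integer(map$pos),
      marker_id = map$marker_id, call = call
    )
  })
  bind_rows(rows)
}

# --- BED --------------------------------------------------------------------

#' Export 1-based inclusive intervals as BED
#'
#' Converts the package's 1-based inclusive `start`/`end` columns to BED's
#' 0-based half-open convention.
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally a name column.
#' @param path Output path.
#' @param name_col Column used for the BED name field (optional).
#' @export
write_bed <- function(x, path, name_col = NULL) {
  nm <- if (!is.null(name_col)) as.character(x[[name_col]]) else "."
  readr::write_lines(sprintf("%s\t%d\t%d\t%s", x$chrom, x$start - 1L, as.integer(x$end), nm), path)
  invisible(path)
}

# --- transcript model JSON --------------------------------------------------

#' Read / write a transcript model as JSON
#'
#' Serialises the exon table, isoform composition, strand and accession of a
#' [transcript_model()].
#'
#' @param model A `transcript_model` object.
#' @param path JSON path.
#' @export
write_transcript_json <- function(model, path) {
  jsonlite::write_json(
    list(
      gene_id = model$gene_id, accession = model$accession,
      chrom = model$chrom, strand = model$strand,
      exons = model$exons,
      isoforms = model$isoforms
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_transcript_json
#' @export
read_transcript_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transcript_model(
    gene_id = x$gene_id, accession = x$accession, chrom = x$chrom,
    strand = x$strand, exons = as_tibble(x$exons),
    isoforms = lapply(x$isoforms, as.integer)
  )
}
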