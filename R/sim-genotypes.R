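# Genotype-cohort simulator: an array-scale marker panel with a shared
# homozygous-by-descent interval in cases, background heterozygosity in
# controls, low-MAF fodder markers and injected missingness.

#' Simulate a SNP-array genotype cohort with a planted shared ROH
#'
#' Places `markers_per_chromosome` markers uniformly at random on each
#' nominal chromosome and draws genotypes so that:
#' * every case is homozygous for one shared haplotype across a
#'   `roh_length_bp` interval centred on the planted insertion site;
#' * controls carry heterozygous calls inside that interval at
#'   `background_het_rate`;
#' * a `low_maf_frac` minority of markers has minor-allele frequency < 5%
#'   (quality-control fodder);
#' * every call is independently set missing at `genotyping_missing_rate`.
#'
#' The ground truth (ROH interval, per-sample insertion genotypes with the
#' first two controls as obligate heterozygous carriers) is attached as the
#' `truth` attribute.
#'
#' @param config A [sim_config()].
#' @param reference A [simulate_reference()] result (fixes the insertion
#'   site the ROH must contain).
#' @return A long genotype tibble (`sample_id`, `phenotype`, `chrom`, `pos`,
#'   `marker_id`, `call`) with attribute `truth`.
#' @export
simulate_genotype_cohort <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "sim_reference"))
  if (config$roh_length_bp > config$chromosome_length_bp) {
    abort("roh_length_bp exceeds the chromosome length")
  }
  with_seed(config$seed, "genotypes", {
    ins_pos <- reference$truth$insertion_site_genomic
    roh_start <- max(1L, as.integer(ins_pos - config$roh_length_bp %/% 2))
    roh_end <- as.integer(roh_start + config$roh_length_bp - 1L)
    if (roh_end > config$chromosome_length_bp) {
      abort("planted ROH does not fit on the chromosome")
    }
    focal <- reference$truth$insertion_contig

    markers <- bind_rows(lapply(reference$contigs$name, function(ch) {
      pos <- sort(sample.int(as.integer(config$chromosome_length_bp),
                             config$markers_per_chromosome))
      tibble(chrom = ch, pos = pos)
    })) |>
      mutate(
        marker_id = sprintf("%s_%d", .data$chrom, .data$pos),
        low_maf = runif(n()) < config$low_maf_frac,
        in_roh = .data$chrom == focal & .data$pos >= roh_start & .data$pos <= roh_end,
        shared_call = ifelse(runif(n()) < 0.6, "hom_alt", "hom_ref")
      )

    samples <- tibble(
      sample_id = c(case_ids(config), control_ids(config)),
      phenotype = rep(c("case", "control"), c(config$n_cases, config$n_controls))
    )

    grid <- tidyr::expand_grid(samples, markers)
    u <- runif(nrow(grid))
    call <- ifelse(
      grid$low_maf,
      ifelse(u < 0.02, "het", "hom_ref"),
      dplyr::case_when(
        u < config$background_het_rate ~ "het",
        u < config$background_het_rate + 0.15 ~ "hom_alt",
        TRUE ~ "hom_ref"
      )
    )
    in_case_roh <- grid$phenotype == "case" & grid$in_roh
    call[in_case_roh] <- grid$shared_call[in_case_roh]
    call[runif(nrow(grid)) < config$genotyping_missing_rate] <- "missing"

    geno <- grid |>
      mutate(call = call) |>
      select("sample_id", "phenotype", "chrom", "pos", "marker_id", "call") |>
      arrange(.data$sample_id, .data$chrom, .data$pos)

    carriers <- c(
      rep(TRUE, min(2L, config$n_controls)),
      runif(max(0L, config$n_controls - 2L)) < config$carrier_rate
    )
    truth <- list(
      roh_interval = tibble(chrom = focal, start = roh_start, end = roh_end),
      insertion_site_genomic = ins_pos,
      sample_genotypes = bind_rows(
        tibble(sample_id = case_ids(config), phenotype = "case",
               insertion_genotype = "hom_alt"),
        tibble(sample_id = control_ids(config), phenotype = "control",
               insertion_genotype = ifelse(carriers, "het", "hom_ref"))
      )
    )
    attr(geno, "truth") <- truth
    geno
  })
}

# Default WGS sub-cohort: two probands, one obligate carrier, one clear
# control (the samples a sequencing budget would actually cover).
default_wgs_samples <- function(truth) {
  sg <- truth$sample_genotypes
  cases <- sg |> filter(.data$phenotype == "case") |> head(2)
  het <- sg |> filter(.data$phenotype == "control", .data$insertion_genotype == "het") |> head(1)
  ref <- sg |> filter(.data$phenotype == "control", .data$insertion_genotype == "hom_ref") |> head(1)
  bind_rows(cases, het, ref) |> select("sample_id", "insertion_genotype")
}
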