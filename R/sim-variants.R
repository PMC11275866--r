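# Variant-table simulator: one planted recessive high-impact candidate
# inside the shared ROH among decoys that each violate exactly one filter
# criterion, plus a typed known-disease exclusion panel.

random_snv_alleles <- function(n) {
  ref <- sample(DNA_BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1), "")
  tibble(ref = ref, alt = unname(alt))
}

#' Simulate an annotated variant table with a planted recessive candidate
#'
#' Emits, in the tabular VCF representation of [read_vcf()]:
#' * one planted HIGH-impact variant inside the central half of the shared
#'   case ROH: homozygous alternate in every case, heterozygous or
#'   reference in every control, absent from the population panel and from
#'   the exclusion panel;
#' * 55 decoys, each violating exactly one criterion of the cascade: a
#'   wrong (het or missing) genotype in one case, a hom-alt control,
#'   common in the population panel, sub-HIGH impact, or positioned
#'   outside the critical region;
#' * 81 known-disease panel sites, typed non-hom-alt in the cases, so the
#'   exclusion screen runs on real records.
#'
#' @param config A [sim_config()].
#' @param geno Genotype cohort from [simulate_genotype_cohort()] (supplies
#'   samples, phenotypes and the planted ROH).
#' @param reference A [simulate_reference()] result.
#' @return Variant tibble with attributes `planted` (one-row tibble) and
#'   `exclusion_panel` (tibble `chrom`, `pos`, `ref`, `alt`, `disease`).
#' @export
simulate_variant_table <- function(config, geno, reference) {
  truth <- attr(geno, "truth")
  if (is.null(truth)) abort("geno must carry the simulation ground truth")
  samples <- geno |> distinct(.data$sample_id, .data$phenotype)
  cases <- samples$sample_id[samples$phenotype == "case"]
  controls <- samples$sample_id[samples$phenotype == "control"]
  roh <- truth$roh_interval
  core_lo <- roh$start + (roh$end - roh$start) %/% 4
  core_hi <- roh$end - (roh$end - roh$start) %/% 4
  all_ids <- samples$sample_id

  with_seed(config$seed, "variants", {
    gt_clean <- function() {
      # all cases hom_alt; controls het or hom_ref
      tibble(
        sample_id = all_ids,
        call = ifelse(all_ids %in% cases, "hom_alt",
                      ifelse(runif(length(all_ids)) < 0.3, "het", "hom_ref"))
      )
    }
    n_decoy <- c(wrong_case = 15L, ctrl_hom = 15L, panel_common = 10L,
                 low_impact = 10L, outside_region = 5L)
    classes <- c("planted", rep(names(n_decoy), n_decoy), rep("panel_site", 81L))
    n <- length(classes)
    inside <- classes %in% c("planted", "wrong_case", "ctrl_hom", "panel_common", "low_impact")
    pos <- integer(n)
    chrom <- character(n)
    pos[inside] <- sort(sample(seq(core_lo, core_hi), sum(inside)))
    chrom[inside] <- roh$chrom
    other_chrom <- setdiff(reference$contigs$name, roh$chrom)
    out_idx <- which(classes == "outside_region")
    chrom[out_idx] <- sample(other_chrom, length(out_idx), replace = TRUE)
    pos[out_idx] <- sample.int(as.integer(config$chromosome_length_bp), length(out_idx))
    pan_idx <- which(classes == "panel_site")
    chrom[pan_idx] <- sample(reference$contigs$name, length(pan_idx), replace = TRUE)
    pos[pan_idx] <- sample.int(as.integer(config$chromosome_length_bp), length(pan_idx))

    alleles <- random_snv_alleles(n)
    rows <- lapply(seq_len(n), function(i) {
      cls <- classes[i]
      g <- gt_clean()
      impact <- "HIGH"
      panel_af <- NA_real_
      panel_nhom <- NA_integer_
      if (cls == "wrong_case") {
        g$call[g$sample_id == sample(cases, 1)] <-
          if (runif(1) < 0.5) "het" else "missing"
      } else if (cls == "ctrl_hom") {
        g$call[g$sample_id == sample(controls, 1)] <- "hom_alt"
      } else if (cls == "panel_common") {
        if (runif(1) < 0.5) {
          panel_af <- round(runif(1, 0.06, 0.4), 3)
          panel_nhom <- 0L
        } else {
          panel_af <- round(runif(1, 0.005, 0.05), 3)
          panel_nhom <- sample(1:5, 1)
        }
      } else if (cls == "low_impact") {
        impact <- sample(c("MODERATE", "LOW", "MODIFIER"), 1)
      } else if (cls == "panel_site") {
        impact <- sample(c("MODERATE", "LOW"), 1)
        panel_af <- round(runif(1, 0.1, 0.5), 3)
        panel_nhom <- sample(0:10, 1)
        g$call <- ifelse(runif(nrow(g)) < 0.2, "het", "hom_ref")
      }
      if (cls %in% c("planted", "wrong_case", "ctrl_hom", "low_impact", "outside_region")) {
        # rare-or-absent in the population panel (violates nothing there)
        if (runif(1) < 0.5 && cls != "planted") {
          panel_af <- round(runif(1, 0.001, 0.04), 3)
          panel_nhom <- 0L
        }
      }
      tibble(
        chrom = chrom[i], pos = pos[i],
        id = sprintf("var_%04d", i),
        ref = alleles$ref[i], alt = alleles$alt[i],
        impact = impact, panel_af = panel_af, panel_nhom = panel_nhom,
        class = cls, genotypes = list(g)
      )
    })
    variants <- bind_rows(rows) |> arrange(.data$chrom, .data$pos)
    planted <- variants |> filter(.data$class == "planted") |>
      select("chrom", "pos", "id", "ref", "alt")
    panel <- variants |>
      filter(.data$class == "panel_site") |>
      transmute(.data$chrom, .data$pos, .data$ref, .data$alt,
                disease = sprintf("IED_%03d", seq_len(81)))
    variants <- variants |> select(-"class")
    attr(variants, "planted") <- planted
    attr(variants, "exclusion_panel") <- panel
    variants
  })
}

#' Run all four generators in one call
#'
#' Convenience wrapper returning every synthetic input the pipeline
#' consumes, plus the combined ground truth.
#'
#' @param config A [sim_config()].
#' @return List: `reference`, `geno`, `alignments`, `variants`, `panel`,
#'   `truth` (merged ground truth: insertion, ROH interval, per-sample
#'   genotypes, planted variant).
#' @export
simulate_all <- function(config) {
  reference <- simulate_reference(config)
  geno <- simulate_genotype_cohort(config, reference)
  gt <- attr(geno, "truth")
  alignments <- simulate_reads(config, reference, truth = gt)
  variants <- simulate_variant_table(config, geno, reference)
  truth <- c(
    reference$truth,
    gt[c("roh_interval", "sample_genotypes")],
    list(planted_variant = attr(variants, "planted"))
  )
  list(
    reference = reference, geno = geno, alignments = alignments,
    variants = variants, panel = attr(variants, "exclusion_panel"),
    truth = truth
  )
}
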