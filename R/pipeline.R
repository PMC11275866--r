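# End-to-end orchestration: validated YAML configuration, stage execution
# over standard-format files, a checksum manifest, and the final candidate
# report.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(
      simulate = TRUE, screen = TRUE, roh = TRUE, filter = TRUE,
      mei = TRUE, classify = TRUE, consequence = TRUE, genotype = TRUE
    ),
    inputs = list(
      reference_fasta = NULL, repeats_fasta = NULL, transcript_json = NULL,
      genotypes_prefix = NULL, variants_vcf = NULL, panel_tsv = NULL,
      alignments = NULL, contig_map_tsv = NULL, truth_json = NULL
    ),
    region = NULL,
    sim = list(),
    qc = list(maf_min = 0.05, missing_max = 0.10),
    roh = roh_params(),
    filter = list(impact_min = "HIGH", af_max = 0.05, hom_disqualifies = TRUE),
    mei = mei_params(),
    align = list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2),
    assay = list(tolerance_bp = 1, tail_bp = 16, sizing_error_bp = 1)
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a plain list, fills documented defaults, and
#' checks the schema: unknown keys (at any level) are rejected, thresholds
#' must have the right type and sign, and referenced input paths must
#' exist when the simulate stage is off. All problems are collected and
#' reported together, not first-fail.
#'
#' @param config YAML file path or named list.
#' @return A validated `pipeline_config` list; on failure, a character
#'   vector of all error messages with class `config_errors`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      return(structure(sprintf("config file not found: %s", config),
                       class = "config_errors"))
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  defaults <- default_pipeline_config()
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errs <- c(errs, sprintf("unknown config key: %s", unknown))
  }
  for (blk in c("stages", "inputs", "qc", "roh", "filter", "mei", "align", "assay", "sim")) {
    sub <- config[[blk]]
    if (is.null(sub)) next
    if (!is.list(sub)) {
      errs <- c(errs, sprintf("'%s' must be a mapping", blk))
      next
    }
    known <- names(defaults[[blk]])
    if (blk == "sim") known <- names(formals(sim_config))
    bad <- setdiff(names(sub), known)
    if (length(bad) > 0) errs <- c(errs, sprintf("unknown key '%s.%s'", blk, bad))
  }
  merged <- modifyList(defaults, config[intersect(names(config), names(defaults))])
  num_pos <- list(
    c("qc", "maf_min"), c("qc", "missing_max"),
    c("roh", "window_snps"), c("roh", "het_allow"), c("roh", "missing_allow"),
    c("roh", "hit_threshold"), c("roh", "min_markers"), c("roh", "min_length_bp"),
    c("roh", "gap_max_bp"), c("roh", "density_max_kb"),
    c("filter", "af_max"),
    c("mei", "elevation_factor"), c("mei", "tsd_max_bp"), c("mei", "min_clip"),
    c("mei", "min_support"), c("mei", "het_min"), c("mei", "hom_min"),
    c("assay", "tolerance_bp"), c("assay", "tail_bp")
  )
  for (p in num_pos) {
    v <- merged[[p[1]]][[p[2]]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      errs <- c(errs, sprintf("'%s.%s' must be a non-negative number", p[1], p[2]))
    }
  }
  if (!is.numeric(merged$seed) || length(merged$seed) != 1) {
    errs <- c(errs, "'seed' must be a single integer")
  }
  if (!is.null(merged$region)) {
    need <- c("chrom", "start", "end")
    miss <- setdiff(need, names(merged$region))
    if (length(miss) > 0) {
      errs <- c(errs, sprintf("'region' is missing key: %s", miss))
    } else if (merged$region$end < merged$region$start) {
      errs <- c(errs, "'region' end is before start")
    }
  }
  if (!isTRUE(merged$stages$simulate)) {
    needed <- c("genotypes_prefix", "variants_vcf", "reference_fasta")
    for (k in needed) {
      v <- merged$inputs[[k]]
      if (is.null(v)) {
        errs <- c(errs, sprintf("'inputs.%s' is required when simulate is off", k))
      } else if (k == "genotypes_prefix") {
        if (!file.exists(paste0(v, ".ped"))) {
          errs <- c(errs, sprintf("input file not found: %s.ped", v))
        }
      } else if (!file.exists(v)) {
        errs <- c(errs, sprintf("input file not found: %s", v))
      }
    }
  }
  if (length(errs) > 0) {
    return(structure(errs, class = "config_errors"))
  }
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = "pipeline_config")
}

#' @export
print.config_errors <- function(x, ...) {
  cat("invalid pipeline configuration:\n")
  cat(paste0("  - ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

stage_fail <- function(stage, file, parent) {
  abort(
    sprintf("pipeline halted at stage '%s' on input %s: %s",
            stage, file %||% "<memory>", conditionMessage(parent)),
    class = "pipeline_stage_error"
  )
}

#' Run the discovery pipeline end to end
#'
#' Executes, in order: synthetic-data generation (optional), the
#' known-variant exclusion screen, genotype QC + ROH mapping + critical
#' region refinement, region-restricted recessive variant filtering, the
#' mobile-element-insertion scan, repeat classification of the insert
#' consensus, consequence prediction, and fragment-assay segregation
#' analysis. Every stage reads the previous stage's standard-format file
#' from `out_dir`, so each is independently re-runnable; a stage failure
#' halts the run naming the stage and the offending input. A manifest with
#' config hash, per-file checksums and stage timings is written alongside
#' the outputs.
#'
#' @param config A `pipeline_config` (from [validate_pipeline_config()]),
#'   a YAML path, or a plain list.
#' @return Invisibly, a list with `manifest`, `report` (final candidate
#'   tibble) and the per-stage result objects.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(config)
    if (inherits(config, "config_errors")) {
      abort(c("invalid pipeline configuration", unclass(config)))
    }
  }
  out_dir <- config$out_dir %||% abort("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  manifest <- list(
    tool = as.character(packageVersion("sinescout")),
    config_hash = unname(tools::md5sum(textConnection_write(config, pth("config_echo.yaml")))),
    stages = list(), warnings = character()
  )
  timings <- list()
  results <- list()
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(code)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- config$inputs
  # ---- simulate -----------------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    sim <- t_stage("simulate", {
      cfg <- do.call(sim_config, modifyList(list(seed = config$seed), config$sim))
      s <- simulate_all(cfg)
      write_fasta(s$reference$contigs[, c("name", "seq")], pth("reference.fa"))
      write_fasta(s$reference$repeats, pth("repeats.fa"))
      write_transcript_json(s$reference$model, pth("transcript.json"))
      readr::write_tsv(
        s$reference$contigs |> select("name", "chrom_length", "window_offset"),
        pth("contig_map.tsv")
      )
      write_pedmap(s$geno, pth("cohort"))
      write_vcf(s$variants, pth("variants.vcf"))
      readr::write_tsv(s$panel, pth("exclusion_panel.tsv"))
      for (sid in unique(s$alignments$sample_id)) {
        write_sam(s$alignments |> filter(.data$sample_id == sid),
                  pth(sprintf("%s.sam", sid)))
      }
      jsonlite::write_json(
        s$truth[c("insertion_contig", "bp_left", "bp_right", "tsd_sequence",
                  "inserted_sequence", "source_repeat", "cds_insertion_position",
                  "insertion_site_genomic")],
        pth("truth.json"), auto_unbox = TRUE, digits = NA
      )
      s
    })
    inputs <- list(
      reference_fasta = pth("reference.fa"), repeats_fasta = pth("repeats.fa"),
      transcript_json = pth("transcript.json"), genotypes_prefix = pth("cohort"),
      variants_vcf = pth("variants.vcf"), panel_tsv = pth("exclusion_panel.tsv"),
      alignments = pth(sprintf("%s.sam", unique(sim$alignments$sample_id))),
      contig_map_tsv = pth("contig_map.tsv")
    )
    results$sim <- sim
  }

  geno <- tryCatch(read_pedmap(inputs$genotypes_prefix),
                   error = function(e) stage_fail("roh", inputs$genotypes_prefix, e))
  variants <- tryCatch(read_vcf(inputs$variants_vcf),
                       error = function(e) stage_fail("filter", inputs$variants_vcf, e))
  phen <- geno |> distinct(.data$sample_id, .data$phenotype)
  cases <- phen$sample_id[phen$phenotype == "case"]
  controls <- phen$sample_id[phen$phenotype != "case"]

  # ---- known-variant screen ----------------------------------------------
  if (isTRUE(config$stages$screen) && !is.null(inputs$panel_tsv)) {
    screen <- t_stage("screen", {
      panel <- readr::read_tsv(inputs$panel_tsv, show_col_types = FALSE, progress = FALSE)
      out <- screen_known_variants(variants, panel, cases)
      readr::write_tsv(out |> select(-"hit_samples"), pth("screen_report.tsv"))
      out
    })
    if (any(screen$status == "hit")) {
      hits <- screen |> filter(.data$status == "hit")
      abort(sprintf(
        "pipeline halted at stage 'screen': case(s) homozygous for known disease variant(s): %s",
        paste(hits$disease, collapse = ", ")
      ))
    }
    if (any(screen$status == "untyped")) {
      manifest$warnings <- c(manifest$warnings, sprintf(
        "%d exclusion-panel variants untyped in the cohort", sum(screen$status == "untyped")
      ))
    }
    results$screen <- screen
  }

  # ---- QC + ROH + critical region ----------------------------------------
  if (isTRUE(config$stages$roh)) {
    region <- t_stage("roh", {
      genoqc <- tryCatch(
        qc_filter(geno, config$qc$maf_min, config$qc$missing_max),
        error = function(e) stage_fail("roh", inputs$genotypes_prefix, e)
      )
      segs <- detect_roh(genoqc, do.call(roh_params, config$roh), samples = cases)
      readr::write_tsv(segs, pth("roh_segments.tsv"))
      write_bed(segs |> mutate(name = .data$sample_id), pth("roh_segments.bed"),
                name_col = "name")
      regions <- shared_critical_region(segs, genoqc)
      if (nrow(regions) == 0) {
        abort("pipeline halted at stage 'roh': no shared case ROH absent in controls")
      }
      refined <- refine_by_het_calls(regions[1, ], genoqc)
      readr::write_tsv(refined |> select(-"cases", -"boundary_markers"),
                       pth("critical_region.tsv"))
      write_bed(refined, pth("critical_region.bed"))
      results$qc <- qc_report(genoqc)
      results$roh_segments <- segs
      refined
    })
  } else {
    if (is.null(config$region)) {
      abort("pipeline halted at stage 'roh': stage disabled and no manual region supplied")
    }
    region <- as_tibble(config$region[c("chrom", "start", "end")])
  }
  results$region <- region

  # ---- recessive variant filter ------------------------------------------
  if (isTRUE(config$stages$filter)) {
    survivors <- t_stage("filter", {
      out <- filter_variants(
        variants, cases, controls, region = region,
        impact_min = config$filter$impact_min, af_max = config$filter$af_max,
        hom_disqualifies = config$filter$hom_disqualifies
      )
      readr::write_tsv(out |> select(-"genotypes"), pth("variant_survivors.tsv"))
      jsonlite::write_json(tidy(filter_report(out)), pth("filter_report.json"),
                           digits = NA)
      out
    })
    results$variants <- survivors
  }

  # ---- MEI scan -----------------------------------------------------------
  calls <- NULL
  if (isTRUE(config$stages$mei)) {
    calls <- t_stage("mei", {
      ref <- tryCatch(read_fasta(inputs$reference_fasta),
                      error = function(e) stage_fail("mei", inputs$reference_fasta, e))
      cmap <- readr::read_tsv(inputs$contig_map_tsv, show_col_types = FALSE, progress = FALSE)
      aln <- bind_rows(lapply(inputs$alignments, function(f) {
        read_sam(f, sample_id = sub("\\.sam$", "", basename(f)))
      }))
      # project the (chromosome-scale) critical region onto the sequenced
      # focal window of its contig
      cm <- cmap |> filter(.data$name == region$chrom)
      if (nrow(cm) == 0) abort(sprintf("no contig window for %s", region$chrom))
      ctg_len <- nchar(ref$seq[ref$name == region$chrom])
      scan <- region_tbl(
        region$chrom,
        max(1L, region$start - cm$window_offset),
        min(ctg_len, region$end - cm$window_offset)
      )
      if (scan$end < scan$start) {
        abort("pipeline halted at stage 'mei': critical region does not overlap the sequenced window")
      }
      params <- do.call(mei_params, config$mei)
      out <- call_mei(aln, ref$seq[ref$name == region$chrom], scan, params)
      write_mei_vcf(out, ref$seq[ref$name == region$chrom], pth("mei_calls.vcf"),
                    contigs = tibble(name = ref$name, length = nchar(ref$seq)))
      conf <- out |> filter(!.data$one_sided)
      if (nrow(conf) > 0) {
        write_bed(conf |> mutate(start = .data$bp_left, end = .data$bp_right,
                                 name = "TSD"),
                  pth("tsd_intervals.bed"), name_col = "name")
      }
      attr(out, "window_offset") <- cm$window_offset
      out
    })
    results$mei <- calls
  }

  # ---- repeat classification ---------------------------------------------
  best <- NULL
  if (isTRUE(config$stages$classify) && !is.null(calls) && nrow(calls |> filter(!.data$one_sided)) > 0) {
    best <- t_stage("classify", {
      lib <- read_fasta(inputs$repeats_fasta)
      conf <- calls |> filter(!.data$one_sided)
      im <- identity_matrix(
        tibble(name = "insert_consensus", seq = conf$insert_consensus[1]),
        lib, do.call(align_scoring, config$align)
      )
      write_identity_tsv(im, pth("identity_matrix.tsv"))
      im
    })
    results$identity <- best
  }

  # ---- consequence --------------------------------------------------------
  consequence <- NULL
  if (isTRUE(config$stages$consequence) && !is.null(calls) && nrow(calls |> filter(!.data$one_sided)) > 0) {
    consequence <- t_stage("consequence", {
      model <- tryCatch(read_transcript_json(inputs$transcript_json),
                        error = function(e) stage_fail("consequence", inputs$transcript_json, e))
      ref <- read_fasta(inputs$reference_fasta)
      conf <- calls |> filter(!.data$one_sided)
      # the element begins after bp_right; translation stops inside it, so
      # the trailing duplicated target site is immaterial
      insert <- conf$insert_consensus[1]
      cons <- predict_insertion_consequence(
        model, ref$seq[ref$name == model$chrom], conf$bp_right[1], insert
      )
      readr::write_tsv(cons, pth("consequence.tsv"))
      aff <- cons |> filter(.data$affected)
      if (nrow(aff) > 0) {
        desig <- name_variant(model$accession, aff$cds_insertion_position[1],
                              conf$insert_length_estimate[1],
                              aff$protein_start_position[1])
        readr::write_lines(desig, pth("designation.txt"))
        attr(cons, "designation") <- desig
      }
      cons
    })
    results$consequence <- consequence
  }

  # ---- assay genotyping + segregation ------------------------------------
  if (isTRUE(config$stages$genotype) && !is.null(calls) &&
      nrow(calls |> filter(!.data$one_sided)) > 0 && !is.null(results$sim)) {
    seg <- t_stage("genotype", {
      s <- results$sim
      tr <- s$truth
      ref_seq <- s$reference$contigs$seq[s$reference$contigs$name == tr$insertion_contig]
      asy <- design_insertion_assay(ref_seq, tr$bp_right, tr$inserted_sequence,
                                    tr$tsd_sequence, tail_bp = config$assay$tail_bp)
      exp_wt <- asy$expected$fragment_bp[asy$expected$allele == "wt" &
                                           asy$expected$primer == "forward_wt"]
      exp_ins <- asy$expected$fragment_bp[asy$expected$allele == "ins" &
                                            asy$expected$primer == "forward_ins"]
      frags <- with_seed(config$seed, "fragments", {
        simulate_fragments(tr$sample_genotypes, exp_wt, exp_ins,
                           sizing_error_bp = config$assay$sizing_error_bp)
      })
      gmap <- c(hom_ref = "hom_wt", het = "het", hom_alt = "hom_ins")
      cohort <- tr$sample_genotypes |>
        left_join(frags, by = "sample_id") |>
        mutate(
          genotype = map_chr(.data$fragments, genotype_from_fragments,
                             expected_wt = exp_wt, expected_ins = exp_ins,
                             tolerance_bp = config$assay$tolerance_bp),
          phenotype = ifelse(.data$phenotype == "case", "affected", "clear")
        )
      readr::write_tsv(cohort |> select("sample_id", "phenotype", "genotype"),
                       pth("assay_genotypes.tsv"))
      rep <- segregation_report(cohort)
      readr::write_tsv(tidy(rep), pth("segregation_table.tsv"))
      rep
    })
    results$segregation <- seg
  }

  # ---- final report -------------------------------------------------------
  conf <- if (!is.null(calls)) calls |> filter(!.data$one_sided) else tibble()
  report <- tibble(
    chrom = region$chrom,
    region_start = region$start, region_end = region$end,
    region_length_bp = region$end - region$start + 1,
    n_candidate_insertions = nrow(conf),
    n_surviving_variants = if (!is.null(results$variants)) nrow(results$variants) else NA_integer_
  )
  if (nrow(conf) > 0) {
    off <- attr(calls, "window_offset") %||% 0L
    aff <- if (!is.null(consequence)) consequence |> filter(.data$affected) else tibble()
    report <- report |> mutate(
      bp_left = conf$bp_left[1], bp_right = conf$bp_right[1],
      bp_left_genomic = conf$bp_left[1] + off,
      bp_right_genomic = conf$bp_right[1] + off,
      tsd = conf$tsd_sequence[1],
      insert_length = conf$insert_length_estimate[1],
      polyA_length = conf$polyA_length[1],
      best_hit = if (!is.null(best)) attr(best, "best_hit") else NA_character_,
      best_identity = if (!is.null(best)) attr(best, "best_identity") else NA_real_,
      stop_protein_position = if (nrow(aff) > 0) aff$stop_protein_position[1] else NA_integer_,
      aberrant_aa = if (nrow(aff) > 0) aff$aberrant_aa_count[1] else NA_integer_,
      exon_extension_aa = if (nrow(aff) > 0) aff$exon_extension_aa[1] else NA_integer_,
      designation = if (!is.null(consequence)) attr(consequence, "designation") %||% NA_character_ else NA_character_
    )
  }
  jsonlite::write_json(report, pth("final_report.json"), auto_unbox = FALSE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$stages <- timings
  manifest$checksums <- as.list(tools::md5sum(sort(files)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(list(manifest = manifest, report = report), results))
}

# serialise the config for hashing / provenance
textConnection_write <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  path
}
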