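# Simulation configuration: the study conditions every generator draws from.

#' Simulation configuration
#'
#' Bundles the parameters shared by the four generators ([simulate_reference()],
#' [simulate_genotype_cohort()], [simulate_reads()],
#' [simulate_variant_table()]). The defaults reproduce the study conditions
#' the pipeline is designed for: a four-case / 22-control SNP-array mapping
#' cohort, a shared ~2 Mb homozygous-by-descent interval, a homozygous 210 bp
#' poly-A-tailed exonic insertion with a 15 bp target-site duplication, and
#' 150 bp paired-end reads at ~30x depth.
#'
#' Each simulated chromosome has a nominal Mb-scale length
#' (`chromosome_length_bp`), on which array markers are placed at ~1 marker
#' per 25 kb, and a small sequence window (`contig_length_bp`, "the contig")
#' that carries the gene, the insertion and the reads; the window's offset on
#' the chromosome is recorded so contig coordinates map back to chromosome
#' coordinates.
#'
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @param n_cases,n_controls Cohort sizes.
#' @param n_chromosomes Number of simulated chromosomes (>= 2 so discordant
#'   mates have somewhere to go).
#' @param chromosome_length_bp Nominal chromosome length for marker placement.
#' @param markers_per_chromosome Array markers per chromosome.
#' @param contig_length_bp Length of the sequenced focal window per chromosome.
#' @param roh_length_bp Length of the shared case ROH.
#' @param insertion_length_bp Length of the inserted element (default 210).
#' @param tsd_length_bp Target-site duplication length (default 15).
#' @param read_length_bp Read length (default 150).
#' @param mean_depth Fold coverage (default 30).
#' @param fragment_mean_bp,fragment_sd_bp Insert-size model.
#' @param polyA_tail_bp Poly-A tail length at the element 3' end.
#' @param background_het_rate Per-marker heterozygosity outside planted
#'   structure (and for controls inside the ROH).
#' @param genotyping_missing_rate Per-call missing probability.
#' @param element_divergence Substitution rate between the planted element
#'   and its source repeat consensus (default 0.03, i.e. ~97% identity).
#' @param discordant_frac Fraction of placeable insertion-crossing pairs
#'   re-assigned to a different contig, mimicking multi-copy repeat mapping.
#' @param error_rate Read substitution-error rate (default 0: the alignment
#'   signature, not the error model, is the object of study).
#' @param carrier_rate Probability that a non-obligate control carries one
#'   insertion allele; the first two controls are always heterozygous
#'   obligate carriers (parents of affected dogs under a recessive model).
#' @param low_maf_frac Fraction of markers given minor-allele frequency < 5%
#'   (quality-control fodder).
#' @return A validated `sim_config` object (a named list).
#' @export
sim_config <- function(seed = 1,
                       n_cases = 4,
                       n_controls = 22,
                       n_chromosomes = 3,
                       chromosome_length_bp = 10e6,
                       markers_per_chromosome = 400,
                       contig_length_bp = 20000,
                       roh_length_bp = 2e6,
                       insertion_length_bp = 210,
                       tsd_length_bp = 15,
                       read_length_bp = 150,
                       mean_depth = 30,
                       fragment_mean_bp = 400,
                       fragment_sd_bp = 50,
                       polyA_tail_bp = 16,
                       background_het_rate = 0.2,
                       genotyping_missing_rate = 0.02,
                       element_divergence = 0.03,
                       discordant_frac = 0.3,
                       error_rate = 0,
                       carrier_rate = 0.2,
                       low_maf_frac = 0.08) {
  cfg <- as.list(environment())
  counts <- c(
    "n_cases", "n_controls", "n_chromosomes", "markers_per_chromosome",
    "contig_length_bp", "roh_length_bp", "insertion_length_bp",
    "tsd_length_bp", "read_length_bp", "polyA_tail_bp"
  )
  probs <- c(
    "background_het_rate", "genotyping_missing_rate", "element_divergence",
    "discordant_frac", "error_rate", "carrier_rate", "low_maf_frac"
  )
  errs <- character()
  for (f in counts) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
    errs <- c(errs, sprintf("%s must be a count >= 1", f))
  }
  for (f in probs) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
    errs <- c(errs, sprintf("%s must be a probability in [0, 1]", f))
  }
  if (cfg$insertion_length_bp < cfg$polyA_tail_bp) {
    errs <- c(errs, "insertion_length_bp must be >= polyA_tail_bp")
  }
  if (cfg$mean_depth <= 0) errs <- c(errs, "mean_depth must be positive")
  if (cfg$roh_length_bp >= cfg$chromosome_length_bp) {
    errs <- c(errs, "roh_length_bp must be smaller than chromosome_length_bp")
  }
  if (length(errs) > 0) abort(c("invalid simulation config:", errs))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d: %d cases / %d controls, %d chromosomes, %d bp insertion (TSD %d bp), %dx %d bp reads\n",
    x$seed, x$n_cases, x$n_controls, x$n_chromosomes,
    x$insertion_length_bp, x$tsd_length_bp, x$mean_depth, x$read_length_bp
  ))
  invisible(x)
}

case_ids <- function(config) sprintf("case_%02d", seq_len(config$n_cases))
control_ids <- function(config) sprintf("ctrl_%02d", seq_len(config$n_controls))
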