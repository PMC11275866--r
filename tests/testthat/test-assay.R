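# In-silico PCR, fragment-length genotyping and segregation analysis.

# templates engineered so the 5'-to-5' distances give the published assay
# sizes: 248 (Sanger wild-type product), and 266/250 for the tailed
# wild-type/insertion fragment pair
make_sanger_template <- function() {
  set.seed(301)
  t <- random_dna_str(400)
  fwd <- substr(t, 51, 70)
  rev_bind <- substr(t, 279, 298) # 5' end at 298: 298 - 51 + 1 = 248
  list(template = t, assay = primer_assay(forward_wt = fwd, reverse = revcomp(rev_bind)))
}

make_aflp_templates <- function(tail_bp = 16) {
  set.seed(302)
  shared <- random_dna_str(120)
  fwd_wt <- random_dna_str(20)
  fwd_ins <- random_dna_str(20)
  # wild-type: fwd_wt ... rev 5' end 250 bases downstream (250 + 16 = 266)
  wt <- paste0(random_dna_str(30), fwd_wt, random_dna_str(210), shared)
  # insertion: fwd_ins ... rev 5' end 234 bases downstream (234 + 16 = 250)
  ins <- paste0(random_dna_str(30), fwd_ins, random_dna_str(194), shared)
  # rev binds shared[1..20]: 5' end at 280 on wt (span 250) and 264 on ins
  # (span 234), from the forward 5' at position 31 on both
  rev_bind <- substr(shared, 1, 20)
  list(
    templates = c(wt = wt, ins = ins),
    assay = primer_assay(forward_wt = fwd_wt, forward_ins = fwd_ins,
                         reverse = revcomp(rev_bind), tail_bp = tail_bp)
  )
}

test_that("a 248 bp wild-type product is predicted from primer geometry", {
  s <- make_sanger_template()
  res <- insilico_pcr(c(wt = s$template), s$assay)
  expect_equal(res$fragment_bp[res$primer == "forward_wt"], 248L)
})

test_that("allele-specific primers give no product on the other allele", {
  a <- make_aflp_templates()
  res <- insilico_pcr(a$templates, a$assay)
  expect_true(is.na(res$fragment_bp[res$allele == "wt" & res$primer == "forward_ins"]))
  expect_true(is.na(res$fragment_bp[res$allele == "ins" & res$primer == "forward_wt"]))
})

test_that("the tailed assay reproduces the 266/250 fragment pair and tails are additive", {
  a <- make_aflp_templates(tail_bp = 16)
  res <- insilico_pcr(a$templates, a$assay)
  expect_equal(res$fragment_bp[res$allele == "wt" & res$primer == "forward_wt"], 266L)
  expect_equal(res$fragment_bp[res$allele == "ins" & res$primer == "forward_ins"], 250L)
  a0 <- make_aflp_templates(tail_bp = 0)
  res0 <- insilico_pcr(a0$templates, a0$assay)
  expect_equal(res$fragment_bp[!is.na(res$fragment_bp)],
               res0$fragment_bp[!is.na(res0$fragment_bp)] + 16L)
})

test_that("multiple binding sites raise an error naming the primer", {
  set.seed(303)
  core <- random_dna_str(200)
  fwd <- substr(core, 11, 30)
  tmpl <- paste0(core, core) # every site duplicated
  assay <- primer_assay(forward_wt = fwd, reverse = revcomp(substr(core, 151, 170)))
  expect_error(insilico_pcr(c(wt = tmpl), assay), "reverse")
})

test_that("fragment sizes call genotypes with tolerance", {
  expect_equal(genotype_from_fragments(266, 266, 250), "hom_wt")
  expect_equal(genotype_from_fragments(250, 266, 250), "hom_ins")
  expect_equal(genotype_from_fragments(c(250, 266), 266, 250), "het")
  expect_equal(genotype_from_fragments(numeric(), 266, 250), "nocall")
  expect_equal(genotype_from_fragments(251, 266, 250, tolerance_bp = 1), "hom_ins")
  expect_error(genotype_from_fragments(250, 250, 251), "not separable")
})

test_that("the published cohort table segregates perfectly under the recessive model", {
  cohort <- tibble::tibble(
    sample_id = sprintf("d%02d", 1:26),
    phenotype = rep(c("affected", "clear"), c(6, 20)),
    genotype = c(rep("hom_ins", 6), rep("het", 6), rep("hom_wt", 14))
  )
  rep <- segregation_report(cohort)
  expect_equal(nrow(rep$discordant), 0)
  expect_equal(rep$allele_frequency, (2 * 6 + 6) / (2 * 26))
  expect_equal(rep$penetrance, 1)
  tab <- tidy(rep)
  expect_equal(tab$total[tab$phenotype == "affected"], 6)
  expect_equal(tab$total[tab$phenotype == "clear"], 20)
})

test_that("an affected het sample is reported discordant", {
  cohort <- tibble::tibble(
    sample_id = c("a1", "a2", "c1"),
    phenotype = c("affected", "affected", "clear"),
    genotype = c("hom_ins", "het", "hom_wt")
  )
  rep <- segregation_report(cohort)
  expect_equal(nrow(rep$discordant), 1)
  expect_equal(rep$discordant$sample_id, "a2")
})

test_that("allele frequency is a closed form invariant to sample order", {
  cohort <- tibble::tibble(
    sample_id = "only", phenotype = "affected", genotype = "hom_ins"
  )
  expect_equal(segregation_report(cohort)$allele_frequency, 1)
  set.seed(9)
  cohort2 <- tibble::tibble(
    sample_id = sprintf("s%d", 1:20),
    phenotype = rep(c("affected", "clear"), c(4, 16)),
    genotype = c(rep("hom_ins", 4), sample(c(rep("het", 5), rep("hom_wt", 11))))
  )
  r1 <- segregation_report(cohort2)
  r2 <- segregation_report(cohort2[sample(nrow(cohort2)), ])
  expect_equal(r1$allele_frequency, r2$allele_frequency)
  expect_equal(r1$allele_frequency, (2 * 4 + 5) / 40)
})

test_that("degenerate cohorts raise", {
  expect_error(segregation_report(tibble::tibble(
    sample_id = "c", phenotype = "clear", genotype = "hom_wt"
  )), "affected")
  expect_error(segregation_report(tibble::tibble(
    sample_id = "a", phenotype = "affected", genotype = "nocall"
  )), "nocall")
})

test_that("genotypes called from simulated fragments match ground truth end to end", {
  cfg <- sim_config(seed = 21)
  ref <- simulate_reference(cfg)
  geno <- simulate_genotype_cohort(cfg, ref)
  tr <- attr(geno, "truth")
  asy <- design_insertion_assay(
    ref$contigs$seq[1], ref$truth$bp_right,
    ref$truth$inserted_sequence, ref$truth$tsd_sequence
  )
  exp_wt <- asy$expected$fragment_bp[asy$expected$allele == "wt" & asy$expected$primer == "forward_wt"]
  exp_ins <- asy$expected$fragment_bp[asy$expected$allele == "ins" & asy$expected$primer == "forward_ins"]
  expect_false(is.na(exp_wt))
  expect_false(is.na(exp_ins))
  # the wild-type junction primer must not amplify the insertion allele
  expect_true(is.na(asy$expected$fragment_bp[asy$expected$allele == "ins" &
                                               asy$expected$primer == "forward_wt"]))
  set.seed(22)
  frags <- simulate_fragments(tr$sample_genotypes, exp_wt, exp_ins, sizing_error_bp = 1)
  called <- vapply(frags$fragments, genotype_from_fragments,
                   character(1), expected_wt = exp_wt, expected_ins = exp_ins,
                   tolerance_bp = 1)
  gmap <- c(hom_ref = "hom_wt", het = "het", hom_alt = "hom_ins")
  expect_equal(unname(called), unname(gmap[tr$sample_genotypes$insertion_genotype]))
})
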