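# Known-variant screen, recessive filter, panel filter, region restriction.

make_variants <- function(rows) {
  # rows: list of list(chrom, pos, impact, calls = named chr, panel_af, panel_nhom)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(
      chrom = r$chrom %||% "chr1", pos = r$pos %||% (1000L * i),
      id = sprintf("v%d", i), ref = "A", alt = "T",
      impact = r$impact %||% "HIGH",
      panel_af = r$panel_af %||% NA_real_,
      panel_nhom = r$panel_nhom %||% NA_integer_,
      genotypes = list(tibble::tibble(sample_id = names(r$calls), call = unname(r$calls)))
    )
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cases clear of all panel variants pass the screen", {
  v <- make_variants(list(
    list(calls = c(p1 = "hom_ref", p2 = "het")),
    list(calls = c(p1 = "hom_ref", p2 = "hom_ref"))
  ))
  panel <- tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L), ref = "A",
                          alt = "T", disease = c("d1", "d2"))
  out <- screen_known_variants(v, panel, cases = c("p1", "p2"))
  expect_equal(out$status, c("clear", "clear"))
})

test_that("a hom-alt case flags the disease and untyped sites are reported", {
  v <- make_variants(list(list(calls = c(p1 = "hom_alt", p2 = "het"))))
  panel <- tibble::tibble(chrom = "chr1", pos = c(1000L, 9999L), ref = "A",
                          alt = "T", disease = c("d1", "d_untyped"))
  out <- screen_known_variants(v, panel, cases = c("p1", "p2"))
  expect_equal(out$status, c("hit", "untyped"))
  expect_equal(out$hit_samples[[1]], "p1")
})

test_that("an empty panel passes vacuously", {
  v <- make_variants(list(list(calls = c(p1 = "hom_ref"))))
  out <- screen_known_variants(v, tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), disease = character()
  ), cases = "p1")
  expect_equal(nrow(out), 0)
})

test_that("the recessive filter applies all three rules", {
  cases <- c("p1", "p2"); controls <- c("c1", "c2")
  v <- make_variants(list(
    list(calls = c(p1 = "hom_alt", p2 = "hom_alt", c1 = "het", c2 = "hom_ref")), # survives
    list(calls = c(p1 = "het", p2 = "hom_alt", c1 = "het", c2 = "hom_ref")), # case het
    list(calls = c(p1 = "hom_alt", p2 = "missing", c1 = "het", c2 = "hom_ref")), # case missing
    list(calls = c(p1 = "hom_alt", p2 = "hom_alt", c1 = "hom_alt", c2 = "hom_ref")), # control hom
    list(impact = "MODERATE", calls = c(p1 = "hom_alt", p2 = "hom_alt", c1 = "het", c2 = "hom_ref")), # low impact
    list(calls = c(p1 = "hom_alt", p2 = "hom_alt", c1 = "missing", c2 = "missing")) # missing controls ignored
  ))
  out <- recessive_filter(v, cases, controls)
  expect_setequal(out$id, c("v1", "v6"))
  rep <- tidy(filter_report(out))
  expect_equal(rep$n, c(6, 4, 3, 2))
  expect_true(all(diff(rep$n) <= 0))
})

test_that("overlapping case/control lists are rejected", {
  v <- make_variants(list(list(calls = c(p1 = "hom_alt"))))
  expect_error(recessive_filter(v, "p1", "p1"), "both case and control")
  expect_error(recessive_filter(v, character(), "p1"), "at least one case")
})

test_that("the recessive filter is invariant to sample and variant order", {
  set.seed(61)
  cases <- c("p1", "p2"); controls <- c("c1", "c2", "c3")
  rows <- lapply(1:30, function(i) {
    list(calls = setNames(
      sample(c("hom_ref", "het", "hom_alt", "missing"), 5, replace = TRUE),
      c(cases, controls)
    ))
  })
  v <- make_variants(rows)
  a <- recessive_filter(v, cases, controls)
  shuffled <- v[sample(nrow(v)), ]
  shuffled$genotypes <- lapply(shuffled$genotypes, function(g) g[sample(nrow(g)), ])
  b <- recessive_filter(shuffled, rev(cases), rev(controls))
  expect_setequal(a$id, b$id)
})

test_that("panel frequency rules remove common variants and flag private ones", {
  v <- make_variants(list(
    list(panel_af = 0.20, panel_nhom = 0L), # common by AF
    list(panel_af = 0.01, panel_nhom = 1L), # disqualified by a hom-alt carrier
    list(panel_af = 0.01, panel_nhom = 0L), # rare: kept
    list() # absent: kept, flagged private
  ))
  out <- panel_frequency_filter(v)
  expect_setequal(out$id, c("v3", "v4"))
  expect_equal(out$panel_status[out$id == "v4"], "panel-absent")
  # disabled filter is the identity
  all_kept <- panel_frequency_filter(v, af_max = 1, hom_disqualifies = FALSE)
  expect_equal(nrow(all_kept), 4)
})

test_that("region restriction is inclusive of its boundaries", {
  v <- make_variants(list(
    list(pos = 100L), list(pos = 500L), list(pos = 501L),
    list(chrom = "chr2", pos = 200L)
  ))
  region <- tibble::tibble(chrom = "chr1", start = 100L, end = 500L)
  out <- restrict_to_region(v, region)
  expect_setequal(out$id, c("v1", "v2"))
  empty <- restrict_to_region(v, tibble::tibble(chrom = "chr3", start = 1L, end = 10L))
  expect_equal(nrow(empty), 0)
})

test_that("only the planted variant survives the cascade across seeds", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed)
    ref <- simulate_reference(cfg)
    geno <- simulate_genotype_cohort(cfg, ref)
    v <- simulate_variant_table(cfg, geno, ref)
    planted <- attr(v, "planted")
    tr <- attr(geno, "truth")
    cases <- unique(geno$sample_id[geno$phenotype == "case"])
    controls <- unique(geno$sample_id[geno$phenotype == "control"])
    out <- filter_variants(v, cases, controls, region = tr$roh_interval)
    expect_equal(out$id, planted$id, info = sprintf("seed %d", seed))
    rep <- tidy(filter_report(out))
    expect_true(all(diff(rep$n) <= 0))
  }
})

test_that("decoys violate exactly one criterion each", {
  cfg <- sim_config(seed = 9)
  ref <- simulate_reference(cfg)
  geno <- simulate_genotype_cohort(cfg, ref)
  v <- simulate_variant_table(cfg, geno, ref)
  tr <- attr(geno, "truth")
  cases <- unique(geno$sample_id[geno$phenotype == "case"])
  controls <- unique(geno$sample_id[geno$phenotype == "control"])
  # without region restriction, the outside-region decoys also survive
  out <- filter_variants(v, cases, controls, region = NULL)
  expect_gt(nrow(out), 1)
  # with it, the planted variant is alone (the filter oracle: exhaustive check)
  out2 <- filter_variants(v, cases, controls, region = tr$roh_interval)
  expect_equal(nrow(out2), 1)
})
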