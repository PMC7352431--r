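ped_small <- small_pedigree(c("case", "case", "control"))

test_that("quality gate uses strict thresholds and the caller pass flag", {
  cfg <- filter_config()
  expect_true(quality_filter(make_variant(ped_small, qual = 50), cfg))
  # strict ">" boundaries
  expect_false(quality_filter(make_variant(ped_small, qual = 20), cfg))
  expect_true(quality_filter(make_variant(ped_small, qual = 20.01), cfg))
  dp <- setNames(as.list(c(30L, 30L, 5L, 30L, 30L)),
                 paste0("dp_", ped_small$id))
  expect_false(quality_filter(do.call(make_variant,
                                      c(list(ped_small), dp)), cfg))
  # caller filter flag dominates high scores
  expect_false(quality_filter(make_variant(ped_small, filter_pass = FALSE),
                              cfg))
  # no usable depth fails
  nodp <- setNames(as.list(rep(NA_integer_, 5)), paste0("dp_", ped_small$id))
  expect_false(quality_filter(do.call(make_variant,
                                      c(list(ped_small), nodp)), cfg))
})

test_that("rarity gate removes common variants, keeps novel and boundary ones", {
  cfg <- filter_config()
  expect_true(rarity_filter(make_variant(ped_small, maf_1kg = 5e-4,
                                         maf_exac_nontcga = 5e-4), cfg))
  expect_false(rarity_filter(make_variant(ped_small,
                                          maf_exac_nontcga = 0.002), cfg))
  # exactly 0.1% is retained (removal is strict ">")
  expect_true(rarity_filter(make_variant(ped_small, maf_1kg = 0.001,
                                         maf_exac_nontcga = 0.001), cfg))
  # novel variant: both sources missing
  expect_true(rarity_filter(make_variant(ped_small), cfg))
})

test_that("CADD and conservation gates follow the stated boundary semantics", {
  cfg <- filter_config()
  expect_true(cadd_filter(make_variant(ped_small, cadd_phred = 23.1), cfg))
  expect_false(cadd_filter(make_variant(ped_small, cadd_phred = 10), cfg))
  expect_false(cadd_filter(make_variant(ped_small,
                                        cadd_phred = NA_real_), cfg))
  expect_true(cadd_filter(make_variant(ped_small, cadd_phred = NA_real_),
                          filter_config(cadd_missing_fails = FALSE)))

  expect_true(conservation_filter(
    make_variant(ped_small, gerp = 4.1, phastcons = 0.9, phylop = 5.2), cfg))
  # PhyloP boundary is inclusive, GERP and PhastCons strict
  expect_true(conservation_filter(
    make_variant(ped_small, phylop = 3.0), cfg))
  expect_false(conservation_filter(
    make_variant(ped_small, gerp = 2.0), cfg))
  expect_false(conservation_filter(
    make_variant(ped_small, phastcons = 0.3), cfg))
  # individually missing scores are skipped, all-missing fails
  expect_true(conservation_filter(
    make_variant(ped_small, gerp = NA_real_, phastcons = NA_real_), cfg))
  expect_false(conservation_filter(
    make_variant(ped_small, gerp = NA_real_, phastcons = NA_real_,
                 phylop = NA_real_), cfg))
})

test_that("consensus vote counts available calls with a minimum denominator", {
  cfg <- filter_config()
  calls <- function(d, t, m = 10 - d - t) {
    setNames(c(rep("D", d), rep("T", t), rep(NA_character_, m)),
             predictor_tools())
  }
  v6 <- deleteriousness_vote(calls(6, 4), cfg)
  expect_true(v6$pass) # 6/10 meets "at least 60%"
  expect_equal(v6$n_deleterious, 6L)
  expect_equal(v6$n_available, 10L)
  expect_false(deleteriousness_vote(calls(5, 5), cfg)$pass)
  # missing calls shrink the denominator: 3/5 = 60%
  v3 <- deleteriousness_vote(calls(3, 2), cfg)
  expect_true(v3$pass)
  expect_equal(v3$n_available, 5L)
  # below the minimum of evaluable calls the vote fails
  expect_false(deleteriousness_vote(calls(4, 0), cfg)$pass)
  expect_error(deleteriousness_vote(c(a = "D")), "named by the 10 tools")
})

test_that("rescue is scoped to the deleteriousness stages only", {
  cfg <- filter_config(rescue_genes = "POT1")
  ped <- ped_small
  good_seg <- make_variant(ped, gene = "POT1", cadd_phred = 3) # fails CADD
  rep <- run_cascade(good_seg, ped, cfg)
  expect_equal(nrow(rep$candidates), 1L)
  expect_true(rep$candidates$rescued)
  expect_equal(rep$trail$cadd, "rescued")

  # rescue never bypasses segregation
  bad_gt <- setNames(as.list(c(0L, 0L, 0L, 0L, 1L)),
                     paste0("gt_", ped$id)) # control carries
  bad_seg <- do.call(make_variant,
                     c(list(ped, gene = "POT1", cadd_phred = 3), bad_gt))
  expect_equal(nrow(run_cascade(bad_seg, ped, cfg)$candidates), 0L)

  # non-rescue gene failing the vote is removed
  tolerated <- setNames(as.list(rep("T", 10)), predictor_tools())
  lost <- do.call(make_variant, c(list(ped, gene = "OTHER"), tolerated))
  expect_equal(nrow(run_cascade(lost, ped, cfg)$candidates), 0L)
  # synonymous variants are not rescue-eligible
  expect_false(rescue_check(make_variant(ped, gene = "POT1",
                                         consequence = "synonymous"), cfg))
})

test_that("run_cascade produces a consistent funnel report", {
  ped <- ped_small
  vt <- bind_variants(
    make_variant(ped, id = "keep"),
    make_variant(ped, id = "common", maf_1kg = 0.05),
    make_variant(ped, id = "lowqual", qual = 5),
    make_variant(ped, id = "weak", cadd_phred = 2),
    make_variant(ped, id = "syn", consequence = "synonymous")
  )
  rep <- run_cascade(vt, ped)
  expect_equal(rep$n_input, 5L)
  expect_equal(rep$candidates$id, "keep")
  # funnel monotonicity
  expect_true(all(diff(rep$stages$n_surviving) <= 0))
  expect_true(all(rep$stages$n_input >= rep$stages$n_surviving))
  # dead variants are not re-evaluated
  expect_equal(rep$trail$rarity[rep$trail$id == "lowqual"], "not-applicable")

  # degenerate inputs
  empty <- vt[0, ]
  class(empty) <- c("variant_table", "data.frame")
  rep0 <- run_cascade(empty, ped)
  expect_equal(rep0$stages$n_surviving, rep(0L, 6))
  expect_equal(nrow(rep0$candidates), 0L)
  all_common <- bind_variants(
    make_variant(ped, id = "c1", maf_1kg = 0.05),
    make_variant(ped, id = "c2", maf_exac_nontcga = 0.05))
  expect_equal(nrow(run_cascade(all_common, ped)$candidates), 0L)
})

test_that("cascade equals brute-force predicate reapplication", {
  st <- simulate_study(sim_config(seed = 21, n_background = 99))
  vt <- st$variants
  ped <- st$pedigree
  cfg <- filter_config()
  rep <- run_cascade(vt, ped, cfg)
  dose <- vt_dosage(vt)
  expected_alive <- quality_filter(vt, cfg) & rarity_filter(vt, cfg) &
    varfunnel:::segregation_pass_matrix(dose, ped) &
    (rescue_check(vt, cfg) |
       (cadd_filter(vt, cfg) & conservation_filter(vt, cfg) &
          varfunnel:::vote_filter(vt, cfg)))
  expect_setequal(rep$candidates$id, vt$id[expected_alive])
})

test_that("final candidate set is invariant to stage order", {
  st <- simulate_study(sim_config(seed = 22, n_background = 60))
  base <- run_cascade(st$variants, st$pedigree)
  orders <- list(
    c("vote", "conservation", "cadd", "segregation", "rarity", "quality"),
    c("rarity", "quality", "cadd", "segregation", "vote", "conservation")
  )
  for (ord in orders) {
    rep <- run_cascade(st$variants, st$pedigree,
                       filter_config(stage_order = ord))
    expect_setequal(rep$candidates$id, base$candidates$id)
  }
})

test_that("filter config validates and round-trips through JSON", {
  expect_error(filter_config(consensus_fraction = 0), "consensus_fraction")
  expect_error(filter_config(cadd_min = Inf), "finite")
  expect_error(filter_config(stage_order = c("quality")), "permutation")
  cfg <- filter_config(maf_max = 0.005, rescue_genes = c("TP53", "POT1"))
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  back <- read_filter_config(tf)
  expect_equal(config_hash(back), config_hash(cfg))
})
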