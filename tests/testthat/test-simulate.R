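test_that("family template matches the stated composition", {
  ped <- simulate_family(sim_config())
  expect_equal(nrow(ped), 11L)
  expect_equal(sum(ped$sample_available), 9L)
  genotyped <- ped[ped$sample_available, ]
  expect_equal(sum(genotyped$role == "case"), 4L)
  expect_equal(sum(genotyped$role == "carrier"), 3L)
  expect_equal(sum(genotyped$role == "control"), 2L)
  # matches the packaged PED transcription
  expect_equal(as.data.frame(ped)[c("father", "mother", "role",
                                    "sample_available")],
               as.data.frame(family_template())[c("father", "mother", "role",
                                                  "sample_available")])

  # founders only
  ped0 <- simulate_family(sim_config(n_children = 0,
                                     sample_unavailable = "I-2"))
  expect_equal(nrow(ped0), 2L)
  # custom roles
  ped2 <- simulate_family(sim_config(
    n_children = 2,
    role_assignment = c(`II-1` = "case", `II-2` = "control"),
    sample_unavailable = "I-2"))
  expect_equal(ped2$role[ped2$id == "II-1"], "case")
})

test_that("planted variant satisfies every gate and all role constraints", {
  cfg <- sim_config(seed = 33)
  ped <- simulate_family(cfg)
  v <- plant_causal_variant(ped, cfg)
  cfgf <- filter_config()
  expect_true(quality_filter(v, cfgf))
  expect_true(rarity_filter(v, cfgf))
  expect_true(cadd_filter(v, cfgf))
  expect_true(conservation_filter(v, cfgf))
  calls <- setNames(unlist(as.data.frame(v)[predictor_tools()]),
                    predictor_tools())
  expect_true(deleteriousness_vote(calls, cfgf)$pass)
  gv <- setNames(as.integer(v[paste0("gt_", vt_members(v))]), vt_members(v))
  dec <- classify_segregation(gv, ped)
  expect_true(dec$pass)
  expect_equal(dec$n_case_carriers, 4L)
  expect_equal(dec$n_control_carriers, 0L)
  # dosage 1 in all genotyped cases, 0 in all controls
  expect_true(all(gv[ped$id[ped$role == "case" & ped$sample_available]] == 1L))
  expect_true(all(gv[ped$id[ped$role == "control"]] == 0L))
  # the cascade on the planted variant alone yields exactly one candidate
  expect_equal(run_cascade(v, ped, cfgf)$candidates$id, "planted")
})

test_that("unsatisfiable role constraints are rejected", {
  cfg <- sim_config(n_children = 2,
                    role_assignment = c(`II-1` = "case", `II-2` = "case"),
                    sample_unavailable = character())
  ped <- simulate_family(cfg)
  ped$role[ped$id == "I-2"] <- "control" # genotyped wild-type father
  expect_error(plant_causal_variant(ped, cfg), "unsatisfiable")
})

test_that("generation is deterministic and substream-stable", {
  cfg <- sim_config(seed = 17, n_background = 30)
  ped <- simulate_family(cfg)
  a <- simulate_background(ped, cfg)
  b <- simulate_background(ped, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(as.data.frame(plant_causal_variant(ped, cfg)),
                   as.data.frame(plant_causal_variant(ped, cfg)))
  # growing n_background must not change earlier variants
  bigger <- simulate_background(ped, sim_config(seed = 17,
                                                n_background = 45))
  expect_identical(as.data.frame(bigger)[1:30, ], as.data.frame(a))
  # a different seed changes the data
  other <- simulate_background(ped, sim_config(seed = 18,
                                               n_background = 30))
  expect_false(identical(as.data.frame(other), as.data.frame(a)))
  # n = 0 gives a well-formed empty table
  none <- simulate_background(ped, sim_config(n_background = 0))
  expect_equal(nrow(none), 0L)
})

test_that("background genotypes are Mendelian and phenotype-independent", {
  cfg <- sim_config(seed = 29, n_background = 400)
  ped <- simulate_family(cfg)
  vt <- simulate_background(ped, cfg)
  members <- vt_members(vt)
  viol <- 0L
  for (i in seq_len(50)) {
    gv <- setNames(as.integer(vt[i, paste0("gt_", members)]), members)
    viol <- viol + nrow(mendelian_consistency(gv, ped))
  }
  expect_equal(viol, 0L)
})

test_that("null segregation pass rate matches the closed form", {
  cfg <- sim_config(seed = 41, n_background = 10000)
  ped <- simulate_family(cfg)
  vt <- simulate_background(ped, cfg)
  emp <- mean(varfunnel:::segregation_pass_matrix(vt_dosage(vt), ped))
  p <- sum(vapply(seq_along(cfg$af_values), function(k) {
    cfg$af_weights[k] * segregation_pass_prob(ped, cfg$af_values[k])
  }, numeric(1)))
  se <- sqrt(p * (1 - p) / cfg$n_background)
  expect_lt(abs(emp - p), 3 * se)
})

test_that("simulate_study writes deterministic, reloadable outputs", {
  cfg <- sim_config(seed = 55, n_background = 20)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  st1 <- simulate_study(cfg, dir = d1)
  st2 <- simulate_study(cfg, dir = d2)
  for (f in c("family.ped", "variants.tsv", "sim_manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  expect_equal(st1$variants$id[nrow(st1$variants)], "planted")
  back <- read_variant_table(file.path(d1, "variants.tsv"), st1$pedigree)
  vt <- st1$variants
  rownames(vt) <- NULL
  expect_identical(as.data.frame(back), as.data.frame(vt))
})
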