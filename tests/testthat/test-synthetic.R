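test_that("default config yields the published group sizes", {
  cfg <- cohort_config(seed = 42L)
  sim <- generate_cohort(cfg)
  expect_identical(nrow(sim$cohort), 185L)
  expect_identical(sum(sim$cohort$group == "DKD"), 50L)
  expect_identical(sum(sim$cohort$group == "DM"), 65L)
  expect_identical(sum(sim$cohort$group == "HC"), 70L)
  expect_identical(length(sim$samples), 185L)
  expect_false(anyDuplicated(sim$cohort$subject_id) > 0)
})

test_that("generation is deterministic given the config", {
  cfg <- tiny_config(seed = 5L)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$samples, s2$samples)
})

test_that("invalid configs are rejected", {
  expect_error(cohort_config(group_sizes = c(HC = 1L, DM = 5L, DKD = 5L)),
               class = "morphnet_config_error")
  expect_error(cohort_config(effect_grades = c(HC = 0, DM = 0.5, DKD = 0.2)),
               class = "morphnet_config_error")
  expect_error(cohort_config(effect_grades = c(HC = -0.1, DM = 0, DKD = 0)),
               class = "morphnet_config_error")
  expect_error(cohort_config(affected_rois = c(1L, 95L)),
               class = "morphnet_config_error")
})

test_that("DKD kidney-function marginals match the configured values", {
  # 4 x 50 = 200 simulated DKD subjects across independent seeds
  vals <- do.call(rbind, lapply(1:4, function(k) {
    cfg <- cohort_config(seed = 1000L + k)
    co <- generate_cohort(cfg)$cohort
    co[co$group == "DKD", c("eGFR", "Scr")]
  }))
  expect_identical(nrow(vals), 200L)
  expect_lt(abs(mean(vals$eGFR) - 56.14), 2 * 13.54 / sqrt(200))
  expect_lt(abs(mean(vals$Scr) - 216.54), 2 * 31.52 / sqrt(200))
})

test_that("per-group clinical marginals track clinical_params", {
  cfg <- cohort_config(group_sizes = c(HC = 120L, DM = 120L, DKD = 120L),
                       n_rois = 4L, voxels_per_roi = c(10L, 20L),
                       affected_rois = 1L, seed = 77L)
  co <- generate_cohort(cfg)$cohort
  pars <- default_clinical_params()
  for (v in c("age", "MMSE", "NCTA")) {
    for (g in c("HC", "DM", "DKD")) {
      ms <- pars[[v]][[g]]
      x <- co[co$group == g, v]
      expect_lt(abs(mean(x) - ms[1]), 3.5 * ms[2] / sqrt(120))
      expect_lt(abs(sd(x) - ms[2]), 0.2 * ms[2] + 0.05)
    }
  }
  # gender frequency
  expect_lt(abs(mean(co$gender[co$group == "HC"]) - 48 / 70), 0.15)
})

test_that("eGFR and Scr are anti-correlated through the latent severity", {
  cfg <- cohort_config(group_sizes = c(HC = 80L, DM = 80L, DKD = 80L),
                       n_rois = 4L, voxels_per_roi = c(10L, 20L),
                       affected_rois = 1L, seed = 13L)
  co <- generate_cohort(cfg)$cohort
  within_r <- sapply(split(co, co$group), function(d) cor(d$eGFR, d$Scr))
  expect_true(all(within_r < -0.1))
  # severity drives the coupling
  dkd <- co[co$group == "DKD", ]
  expect_lt(cor(dkd$severity, dkd$eGFR), -0.3)
  expect_gt(cor(dkd$severity, dkd$Scr), 0.3)
})

test_that("affected-pair similarity decreases monotonically HC -> DM -> DKD", {
  cfg <- cohort_config(group_sizes = c(HC = 30L, DM = 30L, DKD = 30L),
                       n_rois = 10L, voxels_per_roi = c(150L, 300L),
                       affected_rois = c(2L, 5L, 8L),
                       effect_grades = c(HC = 0, DM = 0.25, DKD = 0.5),
                       seed = 21L)
  sim <- generate_cohort(cfg)
  aff <- cfg$affected_rois
  pair_mean <- vapply(sim$samples, function(s) {
    m <- build_network(s)
    # pairs involving an affected ROI
    mean(m[aff, -aff])
  }, numeric(1))
  by_group <- tapply(pair_mean, sim$cohort$group, mean)
  expect_gt(by_group[["HC"]], by_group[["DM"]])
  expect_gt(by_group[["DM"]], by_group[["DKD"]])
})

test_that("roi vectors respect the configured voxel range and positivity", {
  sim <- generate_cohort(tiny_config(seed = 3L))
  lens <- unlist(lapply(sim$samples, function(s) lengths(s$samples)))
  expect_true(all(lens >= 60 & lens <= 120))
  expect_true(all(unlist(lapply(sim$samples, function(s) {
    vapply(s$samples, function(v) all(v > 0), TRUE)
  }))))
})
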