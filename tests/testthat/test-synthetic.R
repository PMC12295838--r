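test_that("generation is seed-deterministic and respects forced configs", {
  cfg <- synthetic_config(n = 200)
  c1 <- generate_cohort(cfg, seed = 99)
  c2 <- generate_cohort(cfg, seed = 99)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_equal(nrow(c1), 200)
  expect_equal(attr(c1, "provenance"), "SYNTHETIC")
  # class 4 -> certainty under the default gradient
  cls4 <- c1$aida_class == 4
  expect_true(all(binary_outcome(c1)[cls4] == "CESAREAN"))
  # all-green color model -> all class 0
  cfg0 <- synthetic_config(
    n = 50,
    stratum_weights = c(CLASSIC = 0, NEAR = 0, TRANSITIONAL = 1, OTHER = 0),
    color_model = list(TRANSITIONAL = c("GREEN|GREEN|GREEN|GREEN" = 1)))
  c0 <- generate_cohort(cfg0, seed = 1)
  expect_true(all(c0$aida_class == 0))
})

test_that("synthetic raw values are color-consistent under the thresholds", {
  cfg <- synthetic_config(n = 300)
  co <- generate_cohort(cfg, seed = 4)
  rec <- profile_to_class(data.frame(aop = co$aop, hsd = co$hsd,
                                     mla = co$mla_deg, ad = co$ad),
                          cfg$thresholds)
  for (col in c("aida_mla", "aida_aop", "aida_spd", "aida_ad"))
    expect_equal(as.character(rec[[col]]), as.character(co[[col]]))
  expect_equal(rec$aida_class, co$aida_class)
  # generating stratum agrees with the stratum recomputed from the angle
  expect_equal(as.character(mla_stratum(co$mla_deg)), co$gen_stratum)
  # both sides are emitted
  expect_true(any(co$mla_deg > 180) && any(co$mla_deg < 180))
})

test_that("fitting a config from the fixture recovers its empirical structure", {
  f <- aida_fixture()
  cfg <- fit_synthetic_config(f)
  expect_equal(unname(cfg$stratum_weights[c("CLASSIC", "NEAR", "TRANSITIONAL")]),
               c(29, 9, 28) / 66)
  expect_equal(cfg$cd_prob[5], 1)            # class 4: all cesarean
  expect_equal(cfg$cd_prob[4], 29 / 32)
  expect_true(all(diff(cfg$cd_prob) >= 0))   # monotone gradient
  # pattern frequencies sum to one per stratum
  for (s in names(cfg$color_model))
    expect_equal(sum(cfg$color_model[[s]]), 1)
})

test_that("generate-then-refit recovers class rates within 3 binomial SE", {
  cfg <- synthetic_config(n = 10000)
  co <- generate_cohort(cfg, seed = 123)
  cls <- co$aida_class
  ces <- binary_outcome(co) == "CESAREAN"
  for (k in 0:4) {
    nk <- sum(cls == k)
    if (nk == 0) next
    p <- cfg$cd_prob[k + 1]
    se <- sqrt(p * (1 - p) / nk)
    expect_lte(abs(mean(ces[cls == k]) - p), max(3 * se, 1e-12),
               label = paste("class", k))
  }
  refit <- fit_synthetic_config(co)
  expect_equal(unname(refit$stratum_weights[c("CLASSIC", "NEAR", "TRANSITIONAL")]),
               unname(cfg$stratum_weights[c("CLASSIC", "NEAR", "TRANSITIONAL")]),
               tolerance = 0.05)
})

test_that("latent correlation propagates to the raw measurements", {
  lc <- diag(4)
  lc[2, 3] <- lc[3, 2] <- 0.7   # aop-hsd
  cfg <- synthetic_config(n = 4000, latent_correlation = lc)
  co <- generate_cohort(cfg, seed = 31)
  # within a fixed color cell the band map is monotone, so strong latent
  # correlation survives as positive observed correlation
  cell <- co$aida_aop == "RED" & co$aida_spd == "RED"
  r <- pearson_cor(co$aop[cell], co$hsd[cell])
  expect_gt(r$r, 0.4)
  expect_lt(r$p, 0.001)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n = 10, stratum_weights =
    c(CLASSIC = 0.5, NEAR = 0.2, TRANSITIONAL = 0.1, OTHER = 0.2)),
    "OTHER")
  expect_error(synthetic_config(n = 10, cd_prob = c(0.1, 0.5, 2, 0.9, 1)),
               "cd_prob")
  # MLA color with no support inside the stratum band
  cfg <- synthetic_config(
    n = 5,
    stratum_weights = c(CLASSIC = 1, NEAR = 0, TRANSITIONAL = 0, OTHER = 0),
    color_model = list(CLASSIC = c("GREEN|RED|RED|RED" = 1)))
  expect_error(generate_cohort(cfg, seed = 1), "no support")
})

test_that("the full pipeline runs end to end on synthetic output", {
  co <- generate_cohort(synthetic_config(n = 120), seed = 6)
  expect_equal(nrow(validate_cohort(co)), 0)
  expect_s3_class(stratified_cd_rates(co), "data.frame")
  expect_s3_class(class_cd_rates(co), "data.frame")
  expect_equal(sum(class_stratum_table(co)), 120)
  expect_s3_class(color_distribution(co), "data.frame")
  vaginal_profile(co)
  res <- multi_seed_evaluate(co, backends = "rf", seeds = c(1, 0),
                             encoding = "raw")
  expect_equal(nrow(res$per_seed), 2)
  expect_true(all(is.finite(res$per_seed$accuracy)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(nrow(read_cohort(path)), 120)
})
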