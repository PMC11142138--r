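test_that("monotherapy generator follows the median-effect equation", {
  cfg <- noiseless_cfg()
  # fa = 0.5 at D = Dm by definition of the median-effect dose
  p <- gen_monotherapy_plate(drug_params(1, 1, "d"), c(0.5, 1, 2), cfg)
  expect_equal(p$signal[2, 1], 0.5)
  # zero-dose limit: viability -> 1
  p2 <- gen_monotherapy_plate(drug_params(2, 1, "d"), c(1e-8, 1, 2), cfg)
  expect_equal(p2$signal[1, 1], 1, tolerance = 1e-6)
  # direct evaluation of the median-effect equation as oracle
  doses <- c(0.25, 0.5, 1, 2, 4)
  p3 <- gen_monotherapy_plate(drug_params(1, 1, "d"), doses, cfg)
  expect_equal(1 - p3$signal[, 1], c(0.2, 1/3, 0.5, 2/3, 0.8))
  expect_error(gen_monotherapy_plate(drug_params(1, 1, "d"), c(-1, 1, 2), cfg),
               "positive")
})

test_that("generators are deterministic and use independent streams", {
  cfg <- sim_config(seed = 42, noise_model = "multiplicative_gaussian",
                    noise_sd = 0.05)
  a <- gen_monotherapy_plate(drug_params(1, 1, "d"), c(0.5, 1, 2), cfg)
  b <- gen_monotherapy_plate(drug_params(1, 1, "d"), c(0.5, 1, 2), cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # interleaving an unrelated generator call does not shift the stream
  invisible(gen_survival_cohort(10, cfg = cfg))
  c3 <- gen_monotherapy_plate(drug_params(1, 1, "d"), c(0.5, 1, 2), cfg)
  expect_identical(a$signal, c3$signal)
  # different drug labels get different noise draws
  d <- gen_monotherapy_plate(drug_params(1, 1, "other"), c(0.5, 1, 2), cfg)
  expect_false(identical(a$signal, d$signal))
})

test_that("combination generator honors ratio, CI profile, and skips
           unreachable points", {
  cfg <- noiseless_cfg()
  pa <- drug_params(1.5, 2, "A"); pb <- drug_params(0.8, 0.7, "B")
  s <- gen_combination_series(pa, pb, ratio = 2,
                              ci_profile = function(fa) 0.5, cfg = cfg)
  expect_equal(s$points$doseA / s$points$doseB, rep(2, 5))
  # dose identity: dA/DxA + dB/DxB = 0.5 by construction
  DxA <- pa$Dm * (s$points$fa_true / (1 - s$points$fa_true))^(1 / pa$m)
  DxB <- pb$Dm * (s$points$fa_true / (1 - s$points$fa_true))^(1 / pb$m)
  expect_equal(s$points$doseA / DxA + s$points$doseB / DxB, rep(0.5, 5),
               tolerance = 1e-12)
  expect_error(gen_combination_series(pa, pb, ratio = -1, cfg = cfg), "ratio")
  expect_error(gen_combination_series(pa, pb, n_points = 2, cfg = cfg),
               "n_points")
})

test_that("pan-cancer generator plants effects and annotates samples", {
  ds <- gen_pancancer_expression(n_types = 2, n_tumor = 40, n_normal = c(40, 2),
                                 effects = matrix(c(1, 0), 1, 2),
                                 sd_log2 = 0.5, cfg = sim_config(5))
  ann <- ds$annotations
  expect_setequal(unique(ann$cancer_type), c("CT01", "CT02"))
  expect_true(all(c("tumor", "normal") %in% ann$tissue))
  expect_true(all(ds$expr > 0))
  # planted +1 log2 shift detected in the eligible type
  r <- diff_expr_one_sided(ds, "gene0001", "CT01")
  expect_lt(r$p_up, 0.05)
  # the 2-normal type trips the eligibility filter
  expect_error(diff_expr_one_sided(ds, "gene0001", "CT02"), "ineligible")
  expect_error(gen_pancancer_expression(1, -5, 3, cfg = sim_config(1)),
               "non-negative")
})

test_that("survival generator recovers beta and the censoring rate", {
  betas <- vapply(1:20, function(s) {
    d <- gen_survival_cohort(500, beta = 0.5, censor_rate = 0.3,
                             cfg = sim_config(s))
    unname(coef(survival::coxph(survival::Surv(time, event) ~ expression,
                                data = d)))
  }, numeric(1))
  expect_lt(abs(median(betas) - 0.5), 0.15)
  d0 <- gen_survival_cohort(4000, beta = 0, censor_rate = 0.3,
                            cfg = sim_config(9))
  expect_equal(mean(d0$event), 0.7, tolerance = 0.05)
  expect_error(gen_survival_cohort(10, censor_rate = 1), "censor_rate")
})

test_that("knockdown generator reproduces prescribed folds exactly", {
  fc <- matrix(c(-1, -2, 0, 0.5), 2, 2)
  kd <- gen_knockdown_screen(c("gA", "gB"), ic50_fold = c(0.4, 1.5),
                             expr_fc = fc, cfg = sim_config(3))
  expect_equal(nrow(kd), 4)  # two treatments per gene: two terms in the sum
  got_fc <- log2(kd$expr_treated) - log2(kd$expr_control)
  expect_equal(got_fc, as.vector(fc), tolerance = 1e-12)
  expect_equal(unique(kd$ic50_kd / kd$ic50_control), c(0.4, 1.5))
  expect_error(gen_knockdown_screen("g", ic50_fold = 0), "ic50_fold")
})

test_that("tumor volume follows the caliper formula", {
  expect_equal(tumor_volume(6, 5), 25 * pi)
  expect_lt(tumor_volume(1e-4, 1e-4), 1e-10)
  # doubling width quadruples volume at fixed length
  expect_equal(tumor_volume(7, 4) / tumor_volume(7, 2), 4)
  expect_error(tumor_volume(0, 1), "positive")
  expect_warning(tumor_volume(2, 5), "longer axis")
})

test_that("geneset annotation generator records the expected set", {
  g <- gen_geneset_annotations(n_genes = 30, n_extra = 6,
                               cfg = sim_config(2))
  gs <- build_brcaness_set(g$annotations, g$extra_list)
  expect_identical(gs$members, g$expected_set)
})
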