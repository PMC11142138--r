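test_that("min-max normalization orients by direction and flags degeneracy", {
  expect_equal(normalize_feature(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_feature(c(2, 4, 6), "lower"), c(1, 0.5, 0))
  expect_warning(out <- normalize_feature(c(5, 5, 5)), "degenerate")
  expect_equal(out, c(0.5, 0.5, 0.5))
  expect_error(normalize_feature(c(NA, NA, 1)), "2 finite")
})

test_that("priority score is a convex combination with sensible extremes", {
  ft <- data.frame(candidate = c("best", "mid", "worst"),
                   ci = c(0.3, 0.8, 1.2),          # lower is good
                   efficacy = c(0.9, 0.5, 0.1),
                   dependency = c(-1.5, -0.5, 0),  # more negative is good
                   dysregulation = c(3, 2, 1),
                   alteration = c(0.4, 0.2, 0.1))
  ps <- priority_score(ft)
  expect_equal(ps$candidate, c("best", "mid", "worst"))
  expect_equal(ps$score[1], 1)   # best in all five features
  expect_equal(ps$score[3], 0)
  expect_true(all(ps$score >= 0 & ps$score <= 1))
  # degenerate weighting reduces to the CI feature alone
  ps_ci <- priority_score(ft, weights = c(1, 0, 0, 0, 0))
  expect_equal(ps_ci$score, sort(normalize_feature(ft$ci, "lower"),
                                 decreasing = TRUE))
  # row-order invariance
  ps_rev <- priority_score(ft[3:1, ])
  expect_equal(ps_rev$score, ps$score)
  expect_equal(ps_rev$candidate, ps$candidate)
})

test_that("priority score renormalizes over missing features and is
           monotone in any single feature", {
  ft <- data.frame(candidate = c("a", "b", "c"),
                   ci = c(0.5, 0.7, NA),
                   efficacy = c(0.2, 0.8, 0.5),
                   dependency = c(-1, 0, -0.5),
                   dysregulation = c(1, 2, 3),
                   alteration = c(0.1, 0.3, 0.2))
  ps <- priority_score(ft)
  expect_false(ps$complete[ps$candidate == "c"])
  expect_true(all(ps$score >= 0 & ps$score <= 1))
  # improving one feature (with positive weight) never lowers the score
  ft2 <- ft
  ft2$efficacy[1] <- 0.9  # was 0.2; higher-is-good
  s1 <- priority_score(ft)
  s2 <- priority_score(ft2)
  expect_gte(s2$score[s2$candidate == "a"], s1$score[s1$candidate == "a"])
})

test_that("impact score applies the four printed formulas literally", {
  # 3-gene table with hand-computable values
  screen <- data.frame(
    gene = rep(c("A", "B", "C"), 2),
    treatment = rep(c("t1", "t2"), each = 3),
    ic50_kd = rep(c(2.5, 5, 10), 2), ic50_control = 5,
    expr_treated = c(5, 10, 10, 5, 10, 10),
    expr_control = c(10, 10, 10, 10, 20, 10))
  out <- impact_score(screen)
  # FIC50 {0.5, 1, 2}: min-max gives (1 - 0.5)/(2 - 0.5) = 1/3 for gene B
  expect_equal(out$fic50_scaled[match(c("A", "B", "C"), out$gene)],
               c(0, 1/3, 1))
  # gene A: sum Fexpt = -2, F' = 0 -> score 0; B: -1 * 1/3; C: 0
  expect_equal(out$score[match("A", out$gene)], 0)
  expect_equal(out$score[match("B", out$gene)], -1/3)
  expect_equal(out$score[match("C", out$gene)], 0)
  # literal formula ranks the F'=0 strongly-repressed gene at the top
  # (tied with the neutral gene, broken lexicographically)
  expect_lt(match("A", out$gene), match("B", out$gene))
  # sum over treatments has exactly the provided terms
  expect_equal(out$sum_fexpt[match("A", out$gene)], -2)
})

test_that("impact score matches a brute-force oracle on random tables", {
  for (s in 1:200) {
    screen <- random_knockdown_screen(sample(3:12, 1), seed = s)
    got <- impact_score(screen)
    want <- impact_score_oracle(screen)
    idx <- match(want$gene, got$gene)
    expect_equal(got$score[idx], want$score, tolerance = 1e-12)
    expect_equal(got$fic50_scaled[idx], want$fic50_scaled, tolerance = 1e-12)
    expect_true(all(got$fic50_scaled >= 0 & got$fic50_scaled <= 1))
  }
})

test_that("impact score is invariant to a common IC50 rescaling", {
  screen <- random_knockdown_screen(8, seed = 99)
  base <- impact_score(screen)
  scaled <- screen
  scaled$ic50_kd <- scaled$ic50_kd * 37
  scaled$ic50_control <- scaled$ic50_control * 37
  out <- impact_score(scaled)
  expect_equal(out$score, base$score, tolerance = 1e-12)
  expect_equal(out$fic50, base$fic50, tolerance = 1e-12)
  # rescaling only the control shifts FIC50 but min-max absorbs the shift
  ctrl <- screen; ctrl$ic50_control <- ctrl$ic50_control * 2
  out2 <- impact_score(ctrl)
  expect_equal(out2$fic50, base$fic50 / 2, tolerance = 1e-12)
  expect_equal(out2$fic50_scaled, base$fic50_scaled, tolerance = 1e-12)
})

test_that("impact score errors on degenerate or invalid input", {
  kd <- gen_knockdown_screen(c("a", "b"), ic50_fold = 1, expr_fc = -1,
                             cfg = sim_config(1))
  expect_error(impact_score(kd), "degenerate")
  bad <- random_knockdown_screen(3, 1)
  bad$expr_treated[1] <- -1
  expect_error(impact_score(bad), "positive")
})

test_that("magnitude mode rewards joint sensitization and repression", {
  screen <- data.frame(
    gene = c("sens", "neut"), treatment = "t1",
    ic50_kd = c(1, 10), ic50_control = 5,
    expr_treated = c(2.5, 10), expr_control = c(10, 10))
  out <- impact_score(screen, mode = "magnitude")
  expect_identical(attr(out, "mode"), "magnitude")
  expect_identical(out$gene[1], "sens")
  expect_equal(out$score[1], 2)  # (1 - 0) * |-2|
})

test_that("ranking is a stable descending sort with lexicographic ties", {
  o <- rank_candidates(c(x = 0.9, y = 0.9, z = 0.1), c("x", "y", "z"))
  expect_equal(o, c(1, 2, 3))
  o2 <- rank_candidates(c(0.9, 0.9, 0.1), c("y", "x", "z"))
  expect_equal(o2, c(2, 1, 3))
  expect_equal(rank_candidates(5), 1L)
  expect_error(rank_candidates(c(1, NA)), "finite")
})
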