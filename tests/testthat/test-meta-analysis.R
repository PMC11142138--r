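test_that("sample dedup applies type > portion > plate priority", {
  # rule (1) outranks rule (2)
  b <- data.frame(participant = "P1",
                  sample_type_code = c("01", "02"),
                  portion = c(1, 9), plate = "A100",
                  sample_id = c("s1", "s2"))
  expect_identical(select_unique_samples(b)$sample_id, "s1")
  # higher portion wins within a type
  b$sample_type_code <- "01"
  expect_identical(select_unique_samples(b)$sample_id, "s2")
  # higher plate wins at equal type and portion
  b$portion <- 1; b$plate <- c("A497", "A498")
  expect_identical(select_unique_samples(b)$sample_id, "s2")
  # unknown code excluded with warning
  b2 <- data.frame(participant = "P1", sample_type_code = c("01", "99"),
                   portion = 1, plate = "A1", sample_id = c("s1", "s2"))
  expect_warning(sel <- select_unique_samples(b2), "unknown")
  expect_identical(sel$sample_id, "s1")
})

test_that("dedup agrees with a brute-force tournament oracle", {
  for (s in 1:25) {
    g <- gen_tcga_like_barcodes(40, max_extra = 3, cfg = sim_config(s))
    sel <- select_unique_samples(g$barcodes)
    oracle <- dedup_oracle(g$barcodes)
    expect_identical(sel$sample_id[match(names(oracle), sel$participant)],
                     unname(oracle))
    # the generator's own recorded expectation matches too
    expect_identical(unname(g$expected), unname(oracle))
  }
})

test_that("barcode strings parse to the fields the rules need", {
  p <- parse_barcode("TCGA-AB-1234-01A-21-A123")
  expect_identical(p$participant, "TCGA-AB-1234")
  expect_identical(p$sample_type_code, "01")
  expect_equal(p$portion, 21L)
  expect_identical(p$plate, "A123")
  expect_error(parse_barcode("garbage"), "unparseable")
})

test_that("one-sided differential tests behave at the null and under shift", {
  ds0 <- gen_pancancer_expression(1, n_tumor = 30, n_normal = 30,
                                  effects = 0, n_genes = 1,
                                  cfg = sim_config(4))
  r <- diff_expr_one_sided(ds0, "gene0001", "CT01")
  expect_gt(r$p_up, 0.01); expect_gt(r$p_down, 0.01)
  # pooled-variance variant: p_up + p_down = 1 exactly
  rp <- diff_expr_one_sided(ds0, "gene0001", "CT01", var_equal = TRUE)
  expect_equal(rp$p_up + rp$p_down, 1, tolerance = 1e-12)
  # planted +1 log2 shift at n = 50/50: strong up-regulation signal
  hits <- vapply(1:20, function(s) {
    ds <- gen_pancancer_expression(1, 50, 50, effects = 1, n_genes = 1,
                                   sd_log2 = 1, cfg = sim_config(s))
    diff_expr_one_sided(ds, "gene0001", "CT01")$p_up < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Fisher combination matches the chi-square oracle", {
  expect_equal(fisher_combine(0.01)$meta_p, 0.01, tolerance = 1e-12)
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$X2, -4 * log(0.05), tolerance = 1e-9)
  expect_equal(fc$meta_p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(fc$meta_p - 0.0175), 1e-4)
  all1 <- fisher_combine(c(1, 1, 1))
  expect_equal(all1$X2, 0)
  expect_equal(all1$meta_p, 1)
  expect_warning(fisher_combine(c(0, 0.5)), "floored")
  expect_error(fisher_combine(numeric(0)), "at least one")
  # exchangeable and monotone
  ps <- c(0.01, 0.2, 0.7)
  expect_equal(fisher_combine(ps)$meta_p, fisher_combine(rev(ps))$meta_p)
  expect_gt(fisher_combine(c(0.05, 0.2))$meta_p,
            fisher_combine(c(0.01, 0.2))$meta_p)
})

test_that("direction selection reports signed normal quantiles", {
  up <- meta_direction(1e-6, 0.4)
  expect_identical(up$direction, "up")
  expect_equal(up$meta_z, qnorm(1 - 1e-6), tolerance = 1e-6)
  expect_equal(up$meta_z, 4.75, tolerance = 0.01)
  dn <- meta_direction(0.4, 1e-6)
  expect_identical(dn$direction, "down")
  expect_equal(dn$meta_z, -up$meta_z)
  tie <- meta_direction(0.3, 0.3)
  expect_identical(tie$direction, "none")
  expect_equal(tie$meta_z, 0)
  # no overflow at extreme significance
  expect_true(is.finite(meta_direction(1e-120, 0.5)$meta_z))
})

test_that("pan-cancer meta-analysis excludes ineligible types and
           detects planted effects", {
  effects <- matrix(0, 2, 3)
  effects[1, 1:2] <- 1.5  # gene0001 up in the two eligible types
  ds <- gen_pancancer_expression(n_types = 3, n_tumor = 25,
                                 n_normal = c(25, 25, 2),
                                 effects = effects, sd_log2 = 1,
                                 cfg = sim_config(6))
  mr <- meta_expression(ds)
  expect_identical(attr(mr, "excluded_types"), "CT03")
  expect_equal(unique(mr$k), 2)
  expect_identical(mr$direction[mr$gene == "gene0001"], "up")
  expect_lt(mr$meta_p[mr$gene == "gene0001"], 0.001)
  expect_gt(mr$meta_z[mr$gene == "gene0001"], 3)
})

test_that("signature scoring and correlation ranking behave as declared", {
  cfg <- sim_config(8)
  ds <- gen_pancancer_expression(1, n_tumor = 100, n_normal = 3,
                                 effects = 0, n_genes = 30, sd_log2 = 1,
                                 cfg = cfg)
  expr <- ds$expr
  # singleton set: the score is that gene's standardized value
  s1 <- signature_score(expr, "gene0001")
  lx <- log2(expr["gene0001", ] + 1)
  expect_equal(unname(s1), unname((lx - mean(lx)) / sd(lx)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant matrix: all scores 0
  flat <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(signature_score(flat, paste0("g", 1:3))), rep(0, 4),
               ignore_attr = TRUE)
  expect_error(signature_score(expr, "absent"), "no gene-set member")
  # a jointly up-shifted set separates the shifted samples (AUC > 0.9)
  set.seed(1)
  n <- 200
  shifted <- rep(c(TRUE, FALSE), each = n / 2)
  mat <- matrix(2^rnorm(20 * n, 4), 20, n,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%03d", 1:n)))
  mat[1:10, shifted] <- mat[1:10, shifted] * 2  # +1 SD on the log2 scale
  sc <- signature_score(mat, sprintf("g%02d", 1:10))
  ranks <- rank(sc)
  auc <- (sum(ranks[shifted]) - sum(seq_len(n / 2))) / (n / 2)^2
  expect_gt(auc, 0.9)
})

test_that("correlation ranks map p-values linearly onto [0, 1]", {
  set.seed(2)
  n <- 120
  g <- rexp(n, 0.1)
  scores <- cbind(strong = log2(g + 1) + rnorm(n, 0, 0.2),
                  weak = log2(g + 1) + rnorm(n, 0, 3),
                  none = rnorm(n))
  cr <- correlation_rank(g, scores)
  expect_equal(cr$rank01[cr$signature == "strong"], 1)
  expect_setequal(cr$rank01, c(1, 0.5, 0))
  expect_error(correlation_rank(g, scores[, 1, drop = FALSE]), "at least 2")
})
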