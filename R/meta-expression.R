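# Pan-cancer differential-expression meta-analysis: per-cancer one-sided
# t-tests combined by Fisher's method, direction chosen by the smaller
# meta-p, signed meta-z.

#' One-sided differential-expression tests for one gene in one cancer type
#'
#' Two one-sided two-sample t-tests (Welch by default) on
#' `log2(expression + 1)` of tumor versus normal samples: `p_up` tests
#' up-regulation in tumors, `p_down` tests down-regulation. With the
#' pooled-variance variant the identity `p_up + p_down = 1` is exact; with
#' Welch it holds up to the degrees-of-freedom approximation.
#'
#' @param dataset List with `expr` (genes x samples) and `annotations`
#'   (columns `sample`, `cancer_type`, `tissue`), as from
#'   [gen_pancancer_expression()].
#' @param gene Gene (row) identifier.
#' @param cancer_type Cancer-type label.
#' @param min_normal Minimum number of normal adjacent samples for the type
#'   to be eligible (default 3).
#' @param var_equal Pooled-variance t-test instead of Welch (default FALSE).
#' @param pseudocount Added before the log2 transform (default 1).
#' @return List with `p_up`, `p_down`, `t`, `n_tumor`, `n_normal`.
#' @export
diff_expr_one_sided <- function(dataset, gene, cancer_type,
                                min_normal = 3L, var_equal = FALSE,
                                pseudocount = 1) {
  ann <- dataset$annotations
  sel <- ann$cancer_type == cancer_type
  tum <- ann$sample[sel & ann$tissue == "tumor"]
  nor <- ann$sample[sel & ann$tissue == "normal"]
  if (length(nor) < min_normal)
    stop("cancer type ", cancer_type, " has fewer than ", min_normal,
         " normal adjacent samples and is ineligible")
  x <- log2(dataset$expr[gene, tum] + pseudocount)
  y <- log2(dataset$expr[gene, nor] + pseudocount)
  up <- stats::t.test(x, y, alternative = "greater", var.equal = var_equal)
  dn <- stats::t.test(x, y, alternative = "less", var.equal = var_equal)
  list(p_up = up$p.value, p_down = dn$p.value,
       t = unname(up$statistic),
       n_tumor = length(tum), n_normal = length(nor))
}

#' Fisher's combined probability test
#'
#' `X2 = -2 * sum(log(p))`, referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom. For a single study the
#' combined p equals the input p.
#'
#' @param ps P-values in (0, 1]. Zeros are floored at `p_floor` with a
#'   warning.
#' @param p_floor Floor applied to zero p-values (default 1e-300).
#' @return List with `X2`, `df`, `meta_p`.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05))  # X2 = 11.98, meta_p ~ 0.0175
fisher_combine <- function(ps, p_floor = 1e-300) {
  if (length(ps) < 1) stop("at least one p-value is required")
  if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
    stop("p-values must lie in [0, 1]")
  if (any(ps == 0)) {
    warning("p-value(s) of 0 floored at ", p_floor)
    ps[ps == 0] <- p_floor
  }
  X2 <- -2 * sum(log(ps))
  df <- 2L * length(ps)
  list(X2 = X2, df = df,
       meta_p = stats::pchisq(X2, df = df, lower.tail = FALSE))
}

#' Choose the reported direction and signed meta-z
#'
#' The direction with the more significant meta-p is reported;
#' `meta_z = qnorm(1 - meta_p)` signed positive for up-regulation (or risky
#' survival effect) and negative for down-regulation (protective). An exact
#' tie yields direction `"none"` with `meta_z = 0`.
#'
#' @param meta_p_up,meta_p_down Meta-p values for the two directions,
#'   computed on the same cancer-type set.
#' @return List with `direction` (`"up"`, `"down"` or `"none"`), `meta_p`
#'   (the chosen one) and `meta_z` (signed).
#' @export
meta_direction <- function(meta_p_up, meta_p_down) {
  if (meta_p_up == meta_p_down)
    return(list(direction = "none", meta_p = meta_p_up, meta_z = 0))
  up <- meta_p_up < meta_p_down
  p <- if (up) meta_p_up else meta_p_down
  z <- stats::qnorm(p, lower.tail = FALSE)
  list(direction = if (up) "up" else "down", meta_p = p,
       meta_z = if (up) z else -z)
}

#' Pan-cancer differential-expression meta-analysis
#'
#' For every gene: per-cancer one-sided t-tests (only cancer types with at
#' least `min_normal` normal adjacent samples are eligible; ineligible types
#' are recorded and excluded), Fisher combination of each direction's
#' p-values across eligible types, and the more significant direction
#' reported with a signed meta-z.
#'
#' @inheritParams diff_expr_one_sided
#' @param genes Genes to test (default: all rows).
#' @return data.frame with one row per gene: `gene`, `k` (types combined),
#'   `X2_up`, `meta_p_up`, `X2_down`, `meta_p_down`, `direction`, `meta_p`,
#'   `meta_z`. Excluded types are attached as attribute
#'   `"excluded_types"`.
#' @export
meta_expression <- function(dataset, genes = rownames(dataset$expr),
                            min_normal = 3L, var_equal = FALSE,
                            pseudocount = 1) {
  ann <- dataset$annotations
  counts <- table(ann$cancer_type[ann$tissue == "normal"])
  types <- names(counts)[counts >= min_normal]
  excluded <- setdiff(unique(ann$cancer_type), types)
  if (length(types) == 0) stop("no eligible cancer types")
  rows <- lapply(genes, function(g) {
    per <- lapply(types, function(ty)
      diff_expr_one_sided(dataset, g, ty, min_normal = min_normal,
                          var_equal = var_equal, pseudocount = pseudocount))
    up <- fisher_combine(vapply(per, `[[`, numeric(1), "p_up"))
    dn <- fisher_combine(vapply(per, `[[`, numeric(1), "p_down"))
    dir <- meta_direction(up$meta_p, dn$meta_p)
    data.frame(gene = g, k = length(types), X2_up = up$X2,
               meta_p_up = up$meta_p, X2_down = dn$X2,
               meta_p_down = dn$meta_p, direction = dir$direction,
               meta_p = dir$meta_p, meta_z = dir$meta_z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_types") <- excluded
  out
}

#' Per-sample signature score
#'
#' Mean of per-gene standardized log2 expression over the set members
#' present in the matrix (a declared stand-in for heavier single-sample
#' enrichment scoring; the choice is echoed in the attributes). Missing set
#' members are reported.
#'
#' @param expr Expression matrix (genes x samples, FPKM-like).
#' @param gene_set Character vector of member genes.
#' @param pseudocount Added before the log2 transform.
#' @return Named numeric vector of per-sample scores; attribute `"missing"`
#'   lists set members absent from the matrix.
#' @export
signature_score <- function(expr, gene_set, pseudocount = 1) {
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0)
    stop("no gene-set member present in the expression matrix")
  missing <- setdiff(gene_set, present)
  lx <- log2(expr[present, , drop = FALSE] + pseudocount)
  z <- t(apply(lx, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  out <- colMeans(z)
  names(out) <- colnames(expr)
  attr(out, "missing") <- missing
  attr(out, "method") <- "mean standardized log2 expression"
  out
}

#' Rank signatures 0 to 1 by correlation significance
#'
#' Correlates one gene's expression with each signature's per-sample score
#' (Pearson on log2 expression by default) and maps the signatures'
#' p-values to [0, 1], 1 for the most significant signature and 0 for the
#' least: `rank_i = (n - position_i) / (n - 1)` with positions ordered by
#' ascending p.
#'
#' @param gene_expr Numeric vector: the gene's expression across samples.
#' @param scores Matrix or data.frame of signature scores
#'   (samples x signatures), or a named list of score vectors.
#' @param method Correlation method passed to [stats::cor.test()].
#' @param log_transform Log2(x+1)-transform `gene_expr` first (default TRUE).
#' @return data.frame: `signature`, `cor`, `p`, `rank01`, sorted by
#'   descending `rank01`.
#' @export
correlation_rank <- function(gene_expr, scores, method = "pearson",
                             log_transform = TRUE) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- do.call(cbind, scores)
  scores <- as.matrix(scores)
  n <- ncol(scores)
  if (n < 2) stop("ranking requires at least 2 signatures")
  g <- if (log_transform) log2(gene_expr + 1) else gene_expr
  tests <- lapply(seq_len(n), function(j)
    stats::cor.test(g, scores[, j], method = method))
  p <- vapply(tests, `[[`, numeric(1), "p.value")
  est <- vapply(tests, `[[`, numeric(1), "estimate")
  position <- rank(p, ties.method = "first")
  out <- data.frame(signature = colnames(scores), cor = est, p = p,
                    rank01 = (n - position) / (n - 1),
                    stringsAsFactors = FALSE)
  out[order(-out$rank01), ]
}
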