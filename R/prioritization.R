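# Candidate scoring: the five-feature weighted priority score for drug
# combinations and the formula-defined impact score for knockdown screens.

#' Min-max normalize a feature onto [0, 1]
#'
#' The minimum maps to 0 and the maximum to 1 after orienting by direction:
#' with `direction = "lower"` (lower raw value is "good") the orientation is
#' flipped so that "good" always maps toward 1. A constant feature is
#' degenerate and maps to 0.5 everywhere with a warning.
#'
#' @param values Numeric vector (>= 2 finite values; NAs preserved).
#' @param direction `"higher"` (higher-is-good, default) or `"lower"`.
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' normalize_feature(c(2, 4, 6))               # 0, 0.5, 1
#' normalize_feature(c(2, 4, 6), "lower")      # 1, 0.5, 0
normalize_feature <- function(values, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  fin <- is.finite(values)
  if (sum(fin) < 2)
    stop("min-max normalization needs at least 2 finite values")
  lo <- min(values[fin]); hi <- max(values[fin])
  if (hi == lo) {
    warning("constant feature: min-max scaling is degenerate, returning 0.5")
    out <- ifelse(fin, 0.5, NA_real_)
    return(out)
  }
  out <- (values - lo) / (hi - lo)
  if (direction == "lower") out <- 1 - out
  out
}

#' Five-feature weighted priority score
#'
#' Each candidate combination is scored on five features — summarized CI,
#' single-agent efficacy, cancer-dependency effect, expression
#' dysregulation, and genomic alteration — each min-max normalized with its
#' "good" direction mapped toward 1, then combined as
#' `score = sum(w_i * f_i)` with weights renormalized to 1. Candidates with
#' some missing features are scored on the renormalized remaining weights
#' and flagged; candidates missing all features are excluded.
#'
#' @param features data.frame with column `candidate` and the five feature
#'   columns `ci`, `efficacy`, `dependency`, `dysregulation`, `alteration`
#'   (NA = missing).
#' @param weights Five non-negative weights summing to a positive number
#'   (default equal, 0.2 each), named or in feature-column order.
#' @param directions Named orientation per feature; defaults: `ci` lower-is-
#'   good, `dependency` lower(-more-negative)-is-good, others higher-is-good.
#' @return A data.frame sorted by descending score: candidate, the five
#'   normalized features, `score`, `complete` (no missing feature), `rank`.
#' @export
priority_score <- function(features,
                           weights = c(ci = 0.2, efficacy = 0.2,
                                       dependency = 0.2, dysregulation = 0.2,
                                       alteration = 0.2),
                           directions = c(ci = "lower", efficacy = "higher",
                                          dependency = "lower",
                                          dysregulation = "higher",
                                          alteration = "higher")) {
  feat_cols <- c("ci", "efficacy", "dependency", "dysregulation", "alteration")
  stopifnot(all(c("candidate", feat_cols) %in% names(features)))
  if (anyDuplicated(features$candidate))
    stop("one row per candidate required")
  if (is.null(names(weights))) names(weights) <- feat_cols
  weights <- weights[feat_cols]
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and sum to a positive number")
  weights <- weights / sum(weights)
  norm <- sapply(feat_cols, function(f)
    normalize_feature(features[[f]], directions[[f]]))
  norm <- matrix(norm, nrow = nrow(features),
                 dimnames = list(features$candidate, feat_cols))
  present <- !is.na(norm)
  if (any(rowSums(present) == 0)) {
    drop <- rownames(norm)[rowSums(present) == 0]
    message("excluding candidate(s) with all features missing: ",
            paste(drop, collapse = ", "))
    keep <- rowSums(present) > 0
    norm <- norm[keep, , drop = FALSE]; present <- present[keep, , drop = FALSE]
    features <- features[keep, , drop = FALSE]
  }
  w <- matrix(weights, nrow = nrow(norm), ncol = 5, byrow = TRUE)
  w[!present] <- 0
  w <- w / rowSums(w)
  score <- rowSums(norm * w, na.rm = TRUE)
  out <- data.frame(candidate = features$candidate, norm, score = score,
                    complete = rowSums(present) == 5L,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[rank_candidates(out$score, out$candidate), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Impact score for a knockdown screen
#'
#' Applies, literally, the four formulas defining the score: per-treatment
#' expression fold change `Fexpt_g = log2(expt_g) - log2(expC_g)`; IC50
#' fold change `FIC50_g = IC50k_g / IC50C`; min-max scaling
#' `F'_g = (F_g - Fmin) / (Fmax - Fmin)`; and
#' `Score_g = F'_g * sum(Fexpt_g)` with the sum over the provided
#' treatments.
#'
#' Sign convention: with the literal product, the most-sensitizing gene
#' (F' = 0) scores exactly 0, which is the maximum whenever all expression
#' sums are negative. The alternative `"magnitude"` mode scores
#' `(1 - F') * |sum(Fexpt)|` so that strong sensitization *and* strong
#' repression jointly produce large scores. The mode used is echoed in the
#' output attributes.
#'
#' @param screen data.frame as produced by [gen_knockdown_screen()]: one row
#'   per gene x treatment with columns `gene`, `treatment`, `ic50_kd`,
#'   `ic50_control`, `expr_treated`, `expr_control`.
#' @param mode `"literal"` (the printed formula, default) or `"magnitude"`.
#' @return data.frame, one row per gene, sorted by descending score:
#'   `gene`, `sum_fexpt`, `fic50`, `fic50_scaled`, `score`, `rank`; the
#'   per-treatment `Fexpt` values are attached as attribute `"fexpt"`.
#' @export
impact_score <- function(screen, mode = c("literal", "magnitude")) {
  mode <- match.arg(mode)
  need <- c("gene", "treatment", "ic50_kd", "ic50_control",
            "expr_treated", "expr_control")
  stopifnot(all(need %in% names(screen)))
  if (any(screen$ic50_kd <= 0) || any(screen$ic50_control <= 0) ||
      any(screen$expr_treated <= 0) || any(screen$expr_control <= 0))
    stop("IC50 and expression values must be positive")
  screen$fexpt <- log2(screen$expr_treated) - log2(screen$expr_control)
  sum_fexpt <- tapply(screen$fexpt, screen$gene, sum)
  per_gene <- unique(screen[c("gene", "ic50_kd", "ic50_control")])
  if (anyDuplicated(per_gene$gene))
    stop("inconsistent IC50 values across treatments for the same gene")
  genes <- per_gene$gene
  if (length(genes) < 2)
    stop("min-max scaling needs at least 2 genes")
  fic50 <- per_gene$ic50_kd / per_gene$ic50_control
  if (max(fic50) == min(fic50))
    stop("degenerate min-max scaling: all IC50 fold changes are equal")
  fic50_scaled <- (fic50 - min(fic50)) / (max(fic50) - min(fic50))
  sf <- unname(sum_fexpt[genes])
  score <- switch(mode,
                  literal = fic50_scaled * sf,
                  magnitude = (1 - fic50_scaled) * abs(sf))
  out <- data.frame(gene = genes, sum_fexpt = sf, fic50 = fic50,
                    fic50_scaled = fic50_scaled, score = score,
                    stringsAsFactors = FALSE)
  out <- out[rank_candidates(out$score, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "fexpt") <- screen[c("gene", "treatment", "fexpt")]
  out
}

#' Stable descending ranking with deterministic tie-break
#'
#' @param scores Finite numeric scores.
#' @param ids Candidate identifiers used to break ties (lexicographic).
#' @return An ordering permutation (use to index the original rows).
#' @export
rank_candidates <- function(scores, ids = seq_along(scores)) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  order(-scores, as.character(ids))
}
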