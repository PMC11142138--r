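# Combination-index analysis for constant-ratio two-drug series
# (Chou-Talalay, mutually exclusive form).

#' Combination-index profile for a constant-ratio series
#'
#' For each combination point with observed effect `fa`,
#' `CI(fa) = dA/DxA(fa) + dB/DxB(fa)`, where `dA`, `dB` are the actual
#' component doses at that point and `Dx` comes from each single agent's
#' median-effect fit via [dose_for_effect()]. This is the mutually exclusive
#' Chou-Talalay form; the nonexclusive form adds a cross term
#' `(dA dB)/(DxA DxB)` and is available behind `form = "nonexclusive"`.
#'
#' @param series A `combination_series` (see [gen_combination_series()]), or
#'   a data.frame with columns `doseA`, `doseB` and either `fa` or
#'   `viability`.
#' @param fitA,fitB Successful [fit_median_effect()] results for the two
#'   single agents.
#' @param form `"exclusive"` (default) or `"nonexclusive"`.
#' @param clamp Clamp bound applied to observed fa before inversion.
#' @param r_warn Warn when either single-agent fit has `r` below this
#'   (default 0.90).
#' @return An object of class `fa_ci_profile`: data.frame `profile`
#'   (`fa`, `ci`, `doseA`, `doseB`), `summary_median`, `summary_mean`,
#'   `classification` (of the median).
#' @export
combination_index <- function(series, fitA, fitB,
                              form = c("exclusive", "nonexclusive"),
                              clamp = 1e-3, r_warn = 0.90) {
  form <- match.arg(form)
  stopifnot(inherits(fitA, "median_effect_fit"),
            inherits(fitB, "median_effect_fit"))
  if (!fitA$ok || !fitB$ok)
    stop("combination index refused: failed single-agent fit (",
         paste(c(fitA$failure, fitB$failure), collapse = "; "), ")")
  if (fitA$r < r_warn || fitB$r < r_warn)
    warning("single-agent fit quality below r = ", r_warn,
            " (rA = ", signif(fitA$r, 3), ", rB = ", signif(fitB$r, 3), ")")
  pts <- if (inherits(series, "combination_series")) series$points else series
  fa <- if ("fa" %in% names(pts)) pts$fa else 1 - pts$viability
  fa <- pmin(pmax(fa, clamp), 1 - clamp)
  DxA <- dose_for_effect(fitA, fa)
  DxB <- dose_for_effect(fitB, fa)
  ci <- pts$doseA / DxA + pts$doseB / DxB
  if (form == "nonexclusive")
    ci <- ci + (pts$doseA * pts$doseB) / (DxA * DxB)
  keep <- is.finite(ci)
  if (any(!keep))
    warning("dropped ", sum(!keep), " point(s) with unreachable Dx")
  prof <- data.frame(fa = fa[keep], ci = ci[keep],
                     doseA = pts$doseA[keep], doseB = pts$doseB[keep])
  if (nrow(prof) == 0) stop("no retainable combination points")
  structure(list(
    drugA = if (inherits(series, "combination_series")) series$drugA else NA,
    drugB = if (inherits(series, "combination_series")) series$drugB else NA,
    line = if (inherits(series, "combination_series")) series$line else NA,
    form = form,
    profile = prof,
    summary_median = stats::median(prof$ci),
    summary_mean = mean(prof$ci),
    classification = classify_ci(stats::median(prof$ci))),
    class = "fa_ci_profile")
}

#' @export
print.fa_ci_profile <- function(x, ...) {
  cat(sprintf("Fa-CI profile %s + %s [%s]: median CI %.3f (%s), mean %.3f, %d points\n",
              x$drugA, x$drugB, x$line, x$summary_median, x$classification,
              x$summary_mean, nrow(x$profile)))
  invisible(x)
}

#' Summarize a CI profile
#'
#' The median over the tested Fa points drives hit calling; the arithmetic
#' mean is the alternative used for heatmap-style summaries. Both are
#' always stored on the profile; this accessor returns the requested one.
#'
#' @param profile A [combination_index()] result.
#' @param method `"median"` (default) or `"mean"`.
#' @return A scalar CI summary.
#' @export
summarize_ci <- function(profile, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "fa_ci_profile"))
  if (nrow(profile$profile) < 1) stop("empty CI profile")
  if (method == "median") profile$summary_median else profile$summary_mean
}

#' Classify a combination-index value
#'
#' Synergism for CI < 0.83, additive effect for CI in the closed interval
#' [0.83, 1.2], antagonism for CI > 1.2.
#'
#' @param ci Positive CI value(s).
#' @param synergy_max,antagonism_min Class boundaries (defaults 0.83, 1.2).
#' @return Character vector in `{"synergism", "additive", "antagonism"}`.
#' @export
#' @examples
#' classify_ci(c(0.5, 0.83, 1.0, 1.3))
classify_ci <- function(ci, synergy_max = 0.83, antagonism_min = 1.2) {
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("CI values must be positive and finite")
  ifelse(ci < synergy_max, "synergism",
         ifelse(ci > antagonism_min, "antagonism", "additive"))
}

#' Roll up a combination screen
#'
#' From per-(line, pair) CI summaries, calls per-line synergistic hit sets
#' (median CI strictly below `threshold`) and the set shared across all
#' lines.
#'
#' @param results data.frame with columns `line`, `pair`, `ci` (summarized
#'   CI, median by convention). Duplicate (line, pair) rows are rejected.
#' @param threshold Hit-calling threshold on the summarized CI
#'   (default 0.83, strict `<`).
#' @return An object of class `screen_result`: `hits` (named list of per-line
#'   hit character vectors), `shared` (intersection), `counts`, and the
#'   input table with classifications.
#' @export
screen_rollup <- function(results, threshold = 0.83) {
  stopifnot(all(c("line", "pair", "ci") %in% names(results)))
  if (anyDuplicated(results[c("line", "pair")]))
    stop("duplicate (line, pair) entries in screen results")
  results$classification <- classify_ci(results$ci,
                                        synergy_max = threshold)
  lines <- unique(results$line)
  hits <- lapply(stats::setNames(lines, lines), function(ln)
    sort(results$pair[results$line == ln & results$ci < threshold]))
  shared <- if (length(hits)) sort(Reduce(intersect, hits)) else character()
  structure(list(hits = hits, shared = shared,
                 counts = c(vapply(hits, length, integer(1)),
                            shared = length(shared)),
                 threshold = threshold, table = results),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Combination screen rollup (median CI <", x$threshold, "):\n")
  for (ln in names(x$hits))
    cat("  ", ln, ":", length(x$hits[[ln]]), "synergistic hit(s)\n")
  cat("  shared:", length(x$shared), "\n")
  invisible(x)
}
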