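# Median-effect dose-response analysis: raw viability -> fraction affected
# -> log-linearized fit of fa/(1-fa) = (D/Dm)^m.

#' Viability plate container
#'
#' Raw absorbance-like signal for one drug in one condition: a dose vector,
#' a per-dose by per-replicate signal matrix, and untreated control
#' replicates.
#'
#' @param drug,condition Identifiers.
#' @param doses Positive dose vector (>= 3 distinct doses).
#' @param signal Numeric matrix, `length(doses)` rows, one column per
#'   replicate; all values >= 0.
#' @param control_signal Untreated control replicates (>= 1 value).
#' @param truth Optional list of ground-truth parameters (simulations only).
#' @return An object of class `viability_plate`.
#' @export
viability_plate <- function(drug, condition, doses, signal, control_signal,
                            truth = NULL) {
  signal <- as.matrix(signal)
  if (length(unique(doses[doses > 0])) < 3)
    stop("a plate needs at least 3 distinct positive doses")
  if (nrow(signal) != length(doses))
    stop("`signal` must have one row per dose")
  if (any(signal < 0) || any(control_signal < 0))
    stop("signals must be >= 0")
  if (length(control_signal) < 1)
    stop("at least one control replicate is required")
  structure(list(drug = drug, condition = condition, doses = doses,
                 signal = signal, control_signal = control_signal,
                 truth = truth),
            class = "viability_plate")
}

#' @export
print.viability_plate <- function(x, ...) {
  cat("Viability plate:", x$drug, "in", x$condition, "-",
      length(x$doses), "doses x", ncol(x$signal), "replicates\n")
  invisible(x)
}

#' Fraction affected per dose
#'
#' `fa(D) = 1 - mean(signal at D) / mean(control)`. Replicates are averaged
#' before log-linearization (one Fa per dose). Values outside (0, 1) are
#' flagged: fa <= 0 (signal at or above control, e.g. growth stimulation)
#' is excluded by default; fa values are clamped into
#' `[clamp, 1 - clamp]` for downstream log-linearization, with the clamp
#' recorded.
#'
#' @param plate A [viability_plate()].
#' @param clamp Clamping bound for fa (default 1e-3).
#' @param exclude_negative Drop doses with fa <= 0 (default TRUE).
#' @return data.frame with columns `dose`, `fa_raw`, `fa`, `clamped`,
#'   `excluded`.
#' @export
compute_fa <- function(plate, clamp = 1e-3, exclude_negative = TRUE) {
  stopifnot(inherits(plate, "viability_plate"))
  ctrl <- mean(plate$control_signal)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("mean control signal must be > 0")
  fa_raw <- 1 - rowMeans(plate$signal) / ctrl
  fa <- pmin(pmax(fa_raw, clamp), 1 - clamp)
  clamped <- fa != fa_raw
  excluded <- exclude_negative & (fa_raw <= 0)
  if (any(clamped & !excluded))
    warning(sum(clamped & !excluded), " fa value(s) clamped to [",
            clamp, ", ", 1 - clamp, "]")
  data.frame(dose = plate$doses, fa_raw = fa_raw, fa = fa,
             clamped = clamped, excluded = excluded)
}

#' Fit the median-effect model
#'
#' Ordinary least squares of `log10(fa / (1 - fa))` on `log10(D)`:
#' the slope is `m` and `Dm = 10^(-intercept / m)`. The linear correlation
#' `r` of the fit is reported as the fit-quality statistic.
#'
#' @param doses Positive dose vector.
#' @param fa Fraction affected per dose, strictly inside (0, 1).
#' @param excluded Optional logical vector of points to drop (as produced by
#'   [compute_fa()]).
#' @return An object of class `median_effect_fit` with elements `m`, `Dm`,
#'   `r`, `n_points`, `excluded`, `ok` and a `failure` message when the fit
#'   is refused or non-monotone.
#' @export
#' @examples
#' fit <- fit_median_effect(c(0.25, 0.5, 1, 2, 4),
#'                          c(0.2, 1/3, 0.5, 2/3, 0.8))
#' c(fit$m, fit$Dm)
fit_median_effect <- function(doses, fa, excluded = NULL) {
  if (inherits(doses, "viability_plate")) {
    tab <- compute_fa(doses)
    return(fit_median_effect(tab$dose, tab$fa, tab$excluded))
  }
  if (is.null(excluded)) excluded <- rep(FALSE, length(doses))
  keep <- !excluded & is.finite(fa) & fa > 0 & fa < 1 & doses > 0
  if (sum(keep) < 3)
    stop("median-effect fit refused: fewer than 3 usable (dose, fa) points")
  x <- log10(doses[keep])
  y <- log10(fa[keep] / (1 - fa[keep]))
  co <- stats::coef(stats::lm(y ~ x))
  m <- unname(co[2]); b <- unname(co[1])
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  fit <- structure(list(m = m, Dm = if (m > 0) 10^(-b / m) else NA_real_,
                        r = r, n_points = sum(keep),
                        excluded = which(!keep), ok = m > 0,
                        failure = if (m > 0) NULL else "non-monotone"),
                   class = "median_effect_fit")
  fit
}

#' @export
print.median_effect_fit <- function(x, digits = 4, ...) {
  if (x$ok)
    cat(sprintf("Median-effect fit: m = %.*g, Dm = %.*g, r = %.*g (%d points)\n",
                digits, x$m, digits, x$Dm, digits, x$r, x$n_points))
  else
    cat("Median-effect fit FAILED:", x$failure, "\n")
  invisible(x)
}

#' Dose producing a given effect level
#'
#' Inverts the median-effect relation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit A successful [fit_median_effect()] result.
#' @param fa Effect level strictly inside (0, 1).
#' @return Dose(s) in the fit's concentration unit. Overflow (fa near 1 with
#'   shallow slopes) is reported as `Inf`, never silently capped.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (!fit$ok) stop("cannot invert a failed median-effect fit: ", fit$failure)
  if (any(fa <= 0) || any(fa >= 1))
    stop("`fa` must be strictly inside (0, 1); the dose is undefined at 0/1")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' IC50 from a median-effect fit
#'
#' Under the median-effect model the half-maximal dose is `Dm` itself
#' (identically `dose_for_effect(fit, 0.5)`).
#'
#' @param fit A successful [fit_median_effect()] result.
#' @return The IC50 concentration.
#' @export
ic50 <- function(fit) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (!fit$ok) stop("cannot report IC50 of a failed fit: ", fit$failure)
  fit$Dm
}
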