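# Pan-cancer survival meta-analysis: per-cancer Cox proportional-hazards
# z-statistics, one-sided p-values for risky/protective arms, Fisher
# combination of each arm, reported direction with signed meta-z.

#' Survival meta-analysis across cancer types
#'
#' Per cancer type, fits `Surv(time, event) ~ expression` by Cox
#' proportional-hazards regression and obtains the Wald z for the
#' expression covariate. The one-sided p for a risky effect (higher
#' expression, shorter survival; z > 0) is `P(Z > z)` and for a protective
#' effect `P(Z < z)`. Each arm is Fisher-combined across types and the more
#' significant arm is reported with a signed meta-z (positive = risky).
#'
#' @param tables Named list of per-cancer-type data.frames with columns
#'   `time`, `event`, `expression`.
#' @param min_events Minimum number of events for a type to be included
#'   (default 10); types below this, or with non-convergent fits, are
#'   dropped and recorded.
#' @return List with `per_type` (data.frame: type, n, events, beta, z,
#'   p_risky, p_protective), `meta_p_risky`, `meta_p_protective`,
#'   `direction` (`"risky"`, `"protective"` or `"none"`), `meta_p`,
#'   `meta_z`, `dropped`.
#' @export
survival_meta <- function(tables, min_events = 10L) {
  if (is.data.frame(tables)) tables <- list(cohort = tables)
  if (is.null(names(tables)))
    names(tables) <- sprintf("type%d", seq_along(tables))
  per <- list(); dropped <- character()
  for (ty in names(tables)) {
    d <- tables[[ty]]
    stopifnot(all(c("time", "event", "expression") %in% names(d)))
    if (sum(d$event) < min_events) {
      dropped <- c(dropped, ty)
      next
    }
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ expression, data = d),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit))) {
      dropped <- c(dropped, ty)
      next
    }
    s <- summary(fit)$coefficients
    z <- s[1, "z"]
    per[[ty]] <- data.frame(
      type = ty, n = nrow(d), events = sum(d$event),
      beta = s[1, "coef"], z = z,
      p_risky = stats::pnorm(z, lower.tail = FALSE),
      p_protective = stats::pnorm(z),
      stringsAsFactors = FALSE)
  }
  if (length(per) == 0) stop("no cancer type yielded a usable Cox fit")
  per_type <- do.call(rbind, per)
  rownames(per_type) <- NULL
  risky <- fisher_combine(per_type$p_risky)
  prot <- fisher_combine(per_type$p_protective)
  dir <- meta_direction(risky$meta_p, prot$meta_p)
  list(per_type = per_type,
       meta_p_risky = risky$meta_p, meta_p_protective = prot$meta_p,
       direction = switch(dir$direction, up = "risky", down = "protective",
                          none = "none"),
       meta_p = dir$meta_p, meta_z = dir$meta_z,
       dropped = dropped)
}
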