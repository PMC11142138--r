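# Pipeline driver: declarative config, simulation bundles, screen reports.
# The exported cmd_* functions are the command-style entry points; they are
# plain R functions so they compose in scripts and tests.

#' Pipeline configuration
#'
#' A single declarative configuration for the whole pipeline. Every
#' threshold is echoed into output metadata; unknown keys are rejected so
#' typos fail fast.
#'
#' @param ... Overrides of the defaults: `seed`, `noise_model`, `noise_sd`,
#'   `replicates`, `ci_synergy_max` (0.83), `ci_antagonism_min` (1.2),
#'   `ci_summary` ("median"), `priority_weights` (equal), `impact_mode`
#'   ("literal"), `lfc_threshold` (0.585), `fdr_threshold` (0.05),
#'   `detect_threshold` (1), `min_normal` (3), `min_events` (10).
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L, noise_model = "none", noise_sd = 0.05, replicates = 3L,
    ci_synergy_max = 0.83, ci_antagonism_min = 1.2, ci_summary = "median",
    priority_weights = c(ci = 0.2, efficacy = 0.2, dependency = 0.2,
                         dysregulation = 0.2, alteration = 0.2),
    impact_mode = "literal", lfc_threshold = 0.585, fdr_threshold = 0.05,
    detect_threshold = 1, min_normal = 3L, min_events = 10L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "pipeline_config")
}

as_sim_config <- function(cfg) {
  sim_config(seed = cfg$seed, noise_model = cfg$noise_model,
             noise_sd = cfg$noise_sd, replicates = cfg$replicates)
}

#' Simulate a full fixture bundle on disk
#'
#' Writes monotherapy plates, a combination screen, a pan-cancer expression
#' dataset, survival cohorts, a knockdown-screen table, gene-set annotation
#' tables, and a ground-truth JSON sidecar, plus a manifest. All files are
#' re-readable by the package's readers, and identical seeds give identical
#' files.
#'
#' @param config A [pipeline_config()].
#' @param outdir Writable output directory (created if absent).
#' @return Invisibly, the manifest (named vector of file paths).
#' @export
cmd_simulate <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0)
    stop("output directory is not writable: ", outdir)
  scfg <- as_sim_config(config)
  manifest <- character()

  screen <- synthetic_combination_screen(n_partners = 8L,
                                         hits = list(line1 = 1:3,
                                                     line2 = 2:4),
                                         cfg = scfg)
  for (ln in names(screen$plates))
    for (drug in names(screen$plates[[ln]])) {
      f <- file.path(outdir, sprintf("plate_%s_%s.csv", ln, drug))
      write_plate_csv(screen$plates[[ln]][[drug]], f)
      manifest[basename(f)] <- f
    }
  combos <- do.call(rbind, lapply(names(screen$series), function(k) {
    s <- screen$series[[k]]
    cbind(data.frame(line = s$line, drugA = s$drugA, drugB = s$drugB,
                     ratio = s$ratio), s$points)
  }))
  f <- file.path(outdir, "combination_series.csv")
  utils::write.csv(combos, f, row.names = FALSE)
  manifest["combination_series.csv"] <- f

  expr <- gen_pancancer_expression(n_types = 3, n_tumor = 20, n_normal = 5,
                                   effects = 0, n_genes = 50, cfg = scfg)
  f <- file.path(outdir, "expression.tsv")
  utils::write.table(expr$expr, f, sep = "\t", quote = FALSE)
  manifest["expression.tsv"] <- f
  f <- file.path(outdir, "expression_annotations.tsv")
  utils::write.table(expr$annotations, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest["expression_annotations.tsv"] <- f

  surv <- gen_survival_cohort(200, beta = 0.5, cfg = scfg)
  f <- file.path(outdir, "survival.tsv")
  utils::write.table(surv, f, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest["survival.tsv"] <- f

  kd <- gen_knockdown_screen(sprintf("cand%02d", 1:10),
                             ic50_fold = seq(0.4, 1.3, length.out = 10),
                             expr_fc = -1, cfg = scfg)
  f <- file.path(outdir, "knockdown_screen.csv")
  utils::write.csv(kd, f, row.names = FALSE)
  manifest["knockdown_screen.csv"] <- f

  cat <- synthetic_brcaness_catalog()
  f <- file.path(outdir, "brcaness_annotations.csv")
  utils::write.csv(cat$annotations, f, row.names = FALSE)
  manifest["brcaness_annotations.csv"] <- f
  f <- file.path(outdir, "brcaness_sensitivity.gmt")
  write_gmt(list(sensitivity = cat$sensitivity_list), f)
  manifest["brcaness_sensitivity.gmt"] <- f

  truth <- list(config = unclass(config),
                screen_hits = screen$hits,
                knockdown_ic50_fold = seq(0.4, 1.3, length.out = 10),
                brcaness_counts = cat[c("n_hrfa", "n_sensitivity", "n_union")])
  f <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest["ground_truth.json"] <- f

  f <- file.path(outdir, "MANIFEST")
  writeLines(sort(names(manifest)), f)
  manifest["MANIFEST"] <- f
  invisible(manifest)
}

#' Run the combination-screen stage
#'
#' Fits every single agent's median-effect model, computes a CI profile per
#' (line, partner) series, and rolls the screen up into per-line and shared
#' synergistic hit sets. Pairs whose fits are refused are reported as
#' unevaluable and the run continues.
#'
#' @param plates Nested named list: per line, per drug, a
#'   [viability_plate()] (as in [synthetic_combination_screen()]).
#' @param series Named list of `combination_series` (names "line/partner").
#' @param config A [pipeline_config()].
#' @return List with `rollup` (a [screen_rollup()] result), `profiles`,
#'   `unevaluable` (character), and the config echo.
#' @export
cmd_screen <- function(plates, series, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  fits <- lapply(plates, function(by_drug)
    lapply(by_drug, function(p)
      tryCatch(fit_median_effect(p), error = function(e) e)))
  rows <- list(); profiles <- list(); uneval <- character()
  for (key in names(series)) {
    s <- series[[key]]
    ln <- s$line
    fa_fit <- fits[[ln]][[s$drugA]]
    fb_fit <- fits[[ln]][[s$drugB]]
    prof <- tryCatch({
      if (inherits(fa_fit, "error")) stop(conditionMessage(fa_fit))
      if (inherits(fb_fit, "error")) stop(conditionMessage(fb_fit))
      combination_index(s, fa_fit, fb_fit)
    }, error = function(e) e)
    if (inherits(prof, "error")) {
      uneval <- c(uneval, key)
      next
    }
    profiles[[key]] <- prof
    rows[[key]] <- data.frame(
      line = ln, pair = paste(s$drugA, s$drugB, sep = "+"),
      partner = s$drugB,
      ci = summarize_ci(prof, config$ci_summary),
      ci_mean = prof$summary_mean,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("empty combination table: empty screen report")
    return(list(rollup = NULL, profiles = profiles, unevaluable = uneval,
                config = unclass(config)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$pair <- tab$partner  # hit identity is the partner inhibitor
  list(rollup = screen_rollup(tab[c("line", "pair", "ci")],
                              threshold = config$ci_synergy_max),
       profiles = profiles, unevaluable = uneval,
       config = unclass(config))
}

#' Assemble a machine-readable pipeline report
#'
#' Collects stage outputs into one JSON-serializable list with the config
#' echo, package version and seeds, and optionally writes it to disk.
#'
#' @param stages Named list of stage outputs (e.g. `screen = cmd_screen(...)`,
#'   `meta = meta_expression(...)` results).
#' @param config A [pipeline_config()].
#' @param path Optional JSON output path.
#' @return The report list, invisibly when `path` is given.
#' @export
cmd_report <- function(stages, config = pipeline_config(), path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(
    package = "epicombi",
    version = as.character(utils::packageVersion("epicombi")),
    config = unclass(config),
    stages = lapply(stages, function(s) {
      if (!is.null(s$rollup)) {
        list(hits = s$rollup$hits, shared = s$rollup$shared,
             counts = as.list(s$rollup$counts),
             unevaluable = s$unevaluable)
      } else s
    }))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}
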