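# Readers/writers for the tidy plate CSVs, GMT gene sets, and TSV/JSON
# exports shared by the pipeline stages.

#' Write / read a viability plate as tidy CSV
#'
#' Tidy long format with a header row: columns `drug`, `condition`, `dose`,
#' `replicate`, `signal`; control wells carry `dose = 0`.
#'
#' @param plate A [viability_plate()].
#' @param path Output CSV path.
#' @return `write_plate_csv` returns `path` invisibly; `read_plate_csv`
#'   returns a `viability_plate`.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "viability_plate"))
  reps <- ncol(plate$signal)
  long <- rbind(
    data.frame(drug = plate$drug, condition = plate$condition,
               dose = rep(plate$doses, each = reps),
               replicate = rep(seq_len(reps), length(plate$doses)),
               signal = as.vector(t(plate$signal))),
    data.frame(drug = plate$drug, condition = plate$condition, dose = 0,
               replicate = seq_along(plate$control_signal),
               signal = plate$control_signal))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "condition", "dose", "replicate", "signal")
  if (!all(need %in% names(d)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  ctrl <- d$signal[d$dose == 0]
  trt <- d[d$dose > 0, ]
  doses <- sort(unique(trt$dose))
  reps <- max(trt$replicate)
  sig <- matrix(NA_real_, length(doses), reps)
  for (i in seq_len(nrow(trt)))
    sig[match(trt$dose[i], doses), trt$replicate[i]] <- trt$signal[i]
  viability_plate(drug = d$drug[1], condition = d$condition[1],
                  doses = doses, signal = sig, control_signal = ctrl)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors (or a single `gene_set`).
#' @param path GMT file path.
#' @param descriptions Optional per-set description column (defaults to the
#'   set name).
#' @return `write_gmt` returns `path` invisibly; `read_gmt` returns a named
#'   list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set"))
    sets <- stats::setNames(list(sets$members), sets$name)
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Export a median-effect fit as a one-row TSV / JSON-ready list
#'
#' @param fit A [fit_median_effect()] result.
#' @param path Optional TSV path; when NULL only the list is returned.
#' @return List of the fit's fields (invisibly writes TSV when `path`
#'   given).
#' @export
export_fit <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "median_effect_fit"))
  row <- data.frame(m = fit$m, Dm = fit$Dm, r = fit$r,
                    n_points = fit$n_points, ok = fit$ok,
                    failure = if (is.null(fit$failure)) "" else fit$failure)
  if (!is.null(path))
    utils::write.table(row, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(as.list(row))
}
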