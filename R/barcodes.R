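# Sample deduplication for barcode-style cohorts.

#' Parse TCGA-like barcode strings
#'
#' Accepts dashed (or dotted) barcodes of the form
#' `PROJECT-SITE-PARTICIPANT-01A-21-A123` (or longer): the participant is
#' the first three fields joined, the sample-type code is the leading two
#' digits of the fourth field, the portion is the numeric part of the fifth
#' field, and the plate is the sixth field. Only the depth the selection
#' rules need is parsed; full barcode semantics are not reproduced.
#'
#' @param x Character vector of barcode strings.
#' @return data.frame with columns `barcode`, `participant`,
#'   `sample_type_code`, `portion`, `plate`.
#' @export
#' @examples
#' parse_barcode("TCGA-AB-1234-01A-21-A123")
parse_barcode <- function(x) {
  parts <- strsplit(gsub("\\.", "-", x), "-", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 4
  if (any(bad))
    stop("unparseable barcode(s): ", paste(x[bad], collapse = ", "))
  data.frame(
    barcode = x,
    participant = vapply(parts, function(p) paste(p[1:3], collapse = "-"),
                         character(1)),
    sample_type_code = vapply(parts, function(p) substr(p[4], 1, 2),
                              character(1)),
    portion = vapply(parts, function(p)
      if (length(p) >= 5) as.integer(gsub("\\D", "", p[5])) else 1L,
      integer(1)),
    plate = vapply(parts, function(p)
      if (length(p) >= 6) p[6] else "", character(1)),
    stringsAsFactors = FALSE)
}

#' Select one sample per participant
#'
#' Deduplication follows a lexicographic priority: (1) tumor sample type,
#' primary (01) > recurrent (02) > metastatic (06); (2) higher portion
#' number; (3) higher plate identifier (ordered string comparison, as plate
#' identifiers sort lexicographically). Samples with an unknown sample-type
#' code are excluded with a warning.
#'
#' @param barcodes data.frame with columns `participant`,
#'   `sample_type_code`, `portion`, `plate` (e.g. from [parse_barcode()] or
#'   [gen_tcga_like_barcodes()]), or a character vector of barcode strings.
#' @return The selected rows (one per participant), ordered by participant.
#' @export
select_unique_samples <- function(barcodes) {
  if (is.character(barcodes)) barcodes <- parse_barcode(barcodes)
  stopifnot(all(c("participant", "sample_type_code", "portion", "plate")
                %in% names(barcodes)))
  codes <- c("01", "02", "06")
  known <- barcodes$sample_type_code %in% codes
  if (any(!known)) {
    warning("excluding ", sum(!known),
            " sample(s) with unknown sample-type code: ",
            paste(unique(barcodes$sample_type_code[!known]), collapse = ", "))
    barcodes <- barcodes[known, , drop = FALSE]
  }
  if (nrow(barcodes) == 0) return(barcodes)
  type_rank <- match(barcodes$sample_type_code, codes)
  o <- order(barcodes$participant, type_rank, -barcodes$portion,
             -xtfrm(barcodes$plate))
  sel <- barcodes[o, , drop = FALSE]
  sel <- sel[!duplicated(sel$participant), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}
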