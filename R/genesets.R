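# Gene-set construction, over-representation testing, and
# expression-fraction summaries.

#' Build the BRCAness gene set
#'
#' Two arms are combined: (i) homologous-recombination / Fanconi-anemia
#' pathway genes annotated by at least two of three databases, and (ii) a
#' curated PARP-inhibitor-sensitivity gene list. The result is their union,
#' with per-gene provenance retained.
#'
#' @param hrfa_annotations data.frame with columns `gene` and exactly three
#'   logical membership columns (one per database).
#' @param sensitivity_list Character vector of sensitivity-arm genes.
#' @return An object of class `gene_set`: `name`, `members` (unique, sorted),
#'   and `provenance` (data.frame: gene, hrfa, sensitivity, n_databases).
#' @export
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g3"),
#'                   db1 = c(TRUE, TRUE, TRUE),
#'                   db2 = c(TRUE, FALSE, TRUE),
#'                   db3 = c(FALSE, FALSE, TRUE))
#' build_brcaness_set(ann, "g4")$members  # g1 g3 g4
build_brcaness_set <- function(hrfa_annotations, sensitivity_list = character()) {
  stopifnot("gene" %in% names(hrfa_annotations))
  dbs <- setdiff(names(hrfa_annotations), "gene")
  if (length(dbs) != 3)
    stop("the HR/FA annotation universe must have exactly 3 databases, got ",
         length(dbs))
  memb <- as.matrix(hrfa_annotations[dbs])
  storage.mode(memb) <- "logical"
  n_db <- rowSums(memb)
  hrfa <- unique(hrfa_annotations$gene[n_db >= 2])
  members <- sort(union(hrfa, unique(sensitivity_list)))
  prov <- data.frame(
    gene = members,
    hrfa = members %in% hrfa,
    sensitivity = members %in% sensitivity_list,
    n_databases = unname(n_db[match(members, hrfa_annotations$gene)]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(name = "BRCAness", members = members, provenance = prov,
                 n_hrfa = length(hrfa),
                 n_sensitivity = length(unique(sensitivity_list))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set", x$name, "-", length(x$members), "members (",
      x$n_hrfa, "HR/FA,", x$n_sensitivity, "sensitivity )\n")
  invisible(x)
}

#' Over-representation test (Fisher's exact, with BH correction)
#'
#' One-sided enrichment of a hit list in a gene set against a background,
#' by the hypergeometric 2x2 exact test; when several sets are tested,
#' Benjamini-Hochberg q-values are computed across them via
#' [adjust_bh()] / [stats::p.adjust()].
#'
#' @param hit_list Character vector, must be a subset of `background`.
#' @param gene_set Character vector (or `gene_set` object); intersected with
#'   the background before testing.
#' @param background Character vector: the gene universe.
#' @return data.frame with `overlap`, `set_size`, `hits`, `background`,
#'   `odds_ratio`, `p`.
#' @export
overrepresentation_test <- function(hit_list, gene_set, background) {
  if (inherits(gene_set, "gene_set")) gene_set <- gene_set$members
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  if (!all(hit_list %in% background))
    stop("`hit_list` must be a subset of `background`")
  hit_list <- unique(hit_list)
  set_in_bg <- intersect(unique(gene_set), background)
  a <- length(intersect(hit_list, set_in_bg))
  b <- length(setdiff(hit_list, set_in_bg))
  cc <- length(setdiff(set_in_bg, hit_list))
  d <- length(background) - a - b - cc
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                           alternative = "greater")
  data.frame(overlap = a, set_size = length(set_in_bg),
             hits = length(hit_list), background = length(background),
             odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin, named wrapper over `p.adjust(method = "BH")` so the multiple-
#' testing scope used by each analysis is explicit in the outputs.
#'
#' @param p Numeric p-values.
#' @return q-values of the same length (monotone in p, never below p).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Detectable-gene stratified up-regulation proportions
#'
#' Restricts to reliably detectable genes (baseline expression above
#' `threshold`, RPKM-like units), splits them into an annotated stratum
#' (e.g. immune-related genes) versus the rest, compares the fraction
#' up-regulated in each stratum, and tests the 2x2 association by Fisher's
#' exact test.
#'
#' @param baseline_expr Named numeric vector: per-gene baseline expression.
#' @param up_calls Character vector of genes called up-regulated.
#' @param annotated_set Character vector: the annotated stratum (e.g.
#'   immune-related genes).
#' @param threshold Detectability threshold (default 1, strict `>`).
#' @return List with `table` (2x2 counts), `prop_annotated`,
#'   `prop_other` (fractions up-regulated), and `p`.
#' @export
detectable_and_proportions <- function(baseline_expr, up_calls,
                                       annotated_set, threshold = 1) {
  detectable <- names(baseline_expr)[baseline_expr > threshold]
  if (length(detectable) == 0)
    stop("no detectable genes at threshold ", threshold)
  in_set <- detectable %in% annotated_set
  up <- detectable %in% up_calls
  if (all(in_set) || !any(in_set)) stop("empty stratum")
  tab <- table(stratum = factor(in_set, c(TRUE, FALSE),
                                c("annotated", "other")),
               up = factor(up, c(TRUE, FALSE), c("up", "not_up")))
  list(table = tab,
       prop_annotated = tab["annotated", "up"] / sum(tab["annotated", ]),
       prop_other = tab["other", "up"] / sum(tab["other", ]),
       p = stats::fisher.test(tab)$p.value)
}

#' Fraction of genes down-regulated by a treatment
#'
#' Per-gene Welch t-tests between treated and control replicate matrices on
#' log2(x+1), BH-corrected; genes pass with `log2FC <= -lfc_threshold` and
#' `q < fdr_threshold`. A fold-change-only mode (no replicates) applies the
#' log2FC threshold alone and must be requested explicitly.
#'
#' @param treated,control Matrices (genes x replicates) on the expression
#'   scale, or single-column matrices/vectors in fold-change-only mode.
#' @param lfc_threshold Magnitude of the down-regulation log2
#'   fold-change cutoff (default 0.585, i.e. 1.5-fold).
#' @param fdr_threshold BH q cutoff (default 0.05).
#' @param fc_only Skip testing and threshold on fold change alone.
#' @return List with `fraction` (of tested genes), `genes` (those passing),
#'   `table` (per-gene log2fc, p, q).
#' @export
downregulated_fraction <- function(treated, control, lfc_threshold = 0.585,
                                   fdr_threshold = 0.05, fc_only = FALSE) {
  treated <- as.matrix(treated); control <- as.matrix(control)
  stopifnot(nrow(treated) == nrow(control))
  genes <- rownames(treated)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(nrow(treated)))
  lt <- log2(treated + 1); lc <- log2(control + 1)
  log2fc <- rowMeans(lt) - rowMeans(lc)
  if (fc_only) {
    pass <- log2fc <= -lfc_threshold
    tab <- data.frame(gene = genes, log2fc = log2fc, p = NA_real_,
                      q = NA_real_, stringsAsFactors = FALSE)
  } else {
    if (ncol(treated) < 2 || ncol(control) < 2)
      stop("per-gene testing needs >= 2 replicates per arm; ",
           "use `fc_only = TRUE` for fold-change-only calling")
    p <- vapply(seq_len(nrow(treated)), function(i)
      stats::t.test(lt[i, ], lc[i, ])$p.value, numeric(1))
    q <- adjust_bh(p)
    pass <- log2fc <= -lfc_threshold & q < fdr_threshold
    tab <- data.frame(gene = genes, log2fc = log2fc, p = p, q = q,
                      stringsAsFactors = FALSE)
  }
  list(fraction = mean(pass), genes = genes[pass], table = tab)
}
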