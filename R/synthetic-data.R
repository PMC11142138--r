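# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, so downstream stages have closed-loop tests.

#' True median-effect parameters for a simulated drug
#'
#' @param m Median-effect slope (sigmoidicity), must be > 0.
#' @param Dm Median-effect dose (the dose producing 50% effect; same unit as
#'   the doses it will be used with, e.g. uM), must be > 0.
#' @param label Drug identifier.
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(m, Dm, label = "drug") {
  if (!is.numeric(m) || m <= 0) stop("`m` must be > 0")
  if (!is.numeric(Dm) || Dm <= 0) stop("`Dm` must be > 0")
  structure(list(m = m, Dm = Dm, label = as.character(label)),
            class = "drug_params")
}

# fraction affected under the median-effect model
median_effect_fa <- function(D, m, Dm) {
  r <- (D / Dm)^m
  r / (1 + r)
}

#' Simulate a monotherapy viability plate
#'
#' Viability at dose D is `1 - fa(D)` with
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)` (the median-effect equation); untreated
#' control wells are included at viability 1 before noise.
#'
#' @param params A [drug_params()] object.
#' @param doses Positive dose vector (>= 3 distinct doses recommended).
#' @param cfg A [sim_config()].
#' @param condition Condition/cell-line identifier.
#' @return A `viability_plate` object (see [viability_plate()]).
#' @export
#' @examples
#' p <- gen_monotherapy_plate(drug_params(1, 1, "drugA"),
#'                            doses = c(0.25, 0.5, 1, 2, 4),
#'                            cfg = sim_config(seed = 1))
gen_monotherapy_plate <- function(params, doses, cfg = sim_config(),
                                  condition = "line1") {
  stopifnot(inherits(params, "drug_params"), inherits(cfg, "sim_config"))
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("all doses must be positive and finite")
  with_seed(stream_seed(cfg$seed, paste0("monotherapy/", params$label, "/",
                                         condition)), {
    fa <- median_effect_fa(doses, params$m, params$Dm)
    v <- 1 - fa
    signal <- matrix(rep(v, each = cfg$replicates),
                     nrow = length(doses), ncol = cfg$replicates,
                     byrow = TRUE)
    signal[] <- apply_noise(as.vector(signal), cfg)
    control <- apply_noise(rep(1, cfg$replicates), cfg)
    viability_plate(drug = params$label, condition = condition,
                    doses = doses, signal = signal, control_signal = control,
                    truth = list(m = params$m, Dm = params$Dm))
  })
}

#' Simulate a constant-ratio two-drug combination series
#'
#' For each target effect level `fa` on a grid, component doses `(dA, dB)`
#' are constructed so that `dA/DxA(fa) + dB/DxB(fa) = ci_profile(fa)` with
#' `dA = ratio * dB`, where `Dx` is the single-agent dose producing `fa`
#' under each drug's median-effect model. The returned viability is
#' `1 - fa` plus noise; ground-truth CI is stored alongside.
#'
#' @param paramsA,paramsB [drug_params()] for the two drugs.
#' @param ratio Dose of drug A per unit dose of drug B (> 0).
#' @param ci_profile Function mapping fa in (0,1) to a positive target CI;
#'   defaults to Loewe additivity (CI = 1).
#' @param n_points Number of effect levels (>= 3; default 5).
#' @param fa_range Range of the equally spaced fa grid (default 0.2-0.8,
#'   the informative range of a 5-point constant-ratio design).
#' @param cfg A [sim_config()].
#' @param line Cell-line identifier.
#' @return A `combination_series` object: data.frame `points` with columns
#'   `doseA`, `doseB`, `viability`, `fa_true`, `ci_true`, plus identifiers.
#' @export
gen_combination_series <- function(paramsA, paramsB, ratio = 1,
                                   ci_profile = function(fa) 1,
                                   n_points = 5L, fa_range = c(0.2, 0.8),
                                   cfg = sim_config(), line = "line1") {
  stopifnot(inherits(paramsA, "drug_params"), inherits(paramsB, "drug_params"))
  if (ratio <= 0) stop("`ratio` must be > 0")
  if (n_points < 3) stop("`n_points` must be >= 3")
  fa <- seq(fa_range[1], fa_range[2], length.out = n_points)
  ci <- vapply(fa, ci_profile, numeric(1))
  if (any(ci <= 0)) stop("`ci_profile` must be positive on (0,1)")
  DxA <- paramsA$Dm * (fa / (1 - fa))^(1 / paramsA$m)
  DxB <- paramsB$Dm * (fa / (1 - fa))^(1 / paramsB$m)
  ok <- is.finite(DxA) & is.finite(DxB)
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " effect level(s) with unreachable Dx")
    fa <- fa[ok]; ci <- ci[ok]; DxA <- DxA[ok]; DxB <- DxB[ok]
  }
  dB <- ci / (ratio / DxA + 1 / DxB)
  dA <- ratio * dB
  with_seed(stream_seed(cfg$seed, paste0("combination/", paramsA$label, "+",
                                         paramsB$label, "/", line)), {
    viability <- apply_noise(1 - fa, cfg)
    structure(list(
      drugA = paramsA$label, drugB = paramsB$label, ratio = ratio,
      line = line,
      points = data.frame(doseA = dA, doseB = dB, viability = viability,
                          fa_true = fa, ci_true = ci)),
      class = "combination_series")
  })
}

#' Simulate a pan-cancer tumor/normal expression dataset
#'
#' Log-normal expression on an FPKM-like scale: per-gene baseline log2 means
#' are drawn once, tumor samples are shifted by the specified per-gene,
#' per-type log2 effects, and sample annotations carry cancer type, tissue
#' class and a synthetic barcode.
#'
#' @param n_types Number of cancer types (>= 1).
#' @param n_tumor,n_normal Samples per type; scalars are recycled. Types with
#'   fewer than 3 normals are generated (to exercise downstream eligibility
#'   filtering) but flagged.
#' @param effects Per-gene-per-type log2 tumor shift: a matrix
#'   (genes x types), a vector per gene (recycled across types), or a scalar.
#' @param n_genes Number of genes (used when `effects` does not imply it).
#' @param sd_log2 Within-group SD on the log2 scale.
#' @param cfg A [sim_config()].
#' @return List with `expr` (genes x samples FPKM-like matrix), `annotations`
#'   (data.frame: sample, cancer_type, tissue, barcode) and `effects`.
#' @export
gen_pancancer_expression <- function(n_types, n_tumor, n_normal,
                                     effects = 0, n_genes = NULL,
                                     sd_log2 = 1, cfg = sim_config()) {
  if (n_types < 1) stop("`n_types` must be >= 1")
  n_tumor <- rep_len(n_tumor, n_types)
  n_normal <- rep_len(n_normal, n_types)
  if (any(n_tumor < 0) || any(n_normal < 0))
    stop("sample counts must be non-negative")
  if (is.matrix(effects)) {
    if (ncol(effects) != n_types) stop("`effects` must have n_types columns")
    n_genes <- nrow(effects)
  } else {
    if (is.null(n_genes)) n_genes <- length(effects)
    effects <- matrix(rep_len(effects, n_genes * n_types),
                      nrow = n_genes, ncol = n_types)
  }
  genes <- sprintf("gene%04d", seq_len(n_genes))
  rownames(effects) <- genes
  with_seed(stream_seed(cfg$seed, "pancancer_expression"), {
    base_mu <- stats::runif(n_genes, 2, 6)  # log2 FPKM baselines
    cols <- list(); ann <- list()
    for (ty in seq_len(n_types)) {
      type_name <- sprintf("CT%02d", ty)
      for (cls in c("tumor", "normal")) {
        n <- if (cls == "tumor") n_tumor[ty] else n_normal[ty]
        if (n == 0) next
        shift <- if (cls == "tumor") effects[, ty] else 0
        x <- matrix(stats::rnorm(n_genes * n, mean = base_mu + shift,
                                 sd = sd_log2),
                    nrow = n_genes, ncol = n)
        ids <- sprintf("%s-%s-%03d", type_name,
                       if (cls == "tumor") "T" else "N", seq_len(n))
        code <- if (cls == "tumor") "01" else "11"
        bar <- sprintf("SYN-%s-%04d-%sA-01-A%03d", type_name,
                       seq_len(n) + if (cls == "tumor") 0L else 5000L,
                       code, ty)
        cols[[length(cols) + 1L]] <- structure(2^x, dimnames = list(genes, ids))
        ann[[length(ann) + 1L]] <- data.frame(
          sample = ids, cancer_type = type_name, tissue = cls, barcode = bar,
          stringsAsFactors = FALSE)
      }
    }
    list(expr = do.call(cbind, cols),
         annotations = do.call(rbind, ann),
         effects = effects)
  })
}

#' Simulate a survival cohort with expression-dependent hazard
#'
#' Event times follow an exponential baseline hazard scaled by
#' `exp(beta * expression)` (proportional hazards); censoring is independent
#' and tuned to the requested rate.
#'
#' @param n Cohort size.
#' @param beta Log-hazard per unit of the (standard-normal) expression
#'   covariate.
#' @param censor_rate Expected fraction censored, in `[0, 1)`.
#' @param base_hazard Baseline exponential rate.
#' @param cfg A [sim_config()].
#' @param stream Extra stream label so multiple cohorts from one seed are
#'   independent.
#' @return data.frame with columns `sample`, `time`, `event`, `expression`.
#' @export
gen_survival_cohort <- function(n, beta = 0, censor_rate = 0.3,
                                base_hazard = 0.1, cfg = sim_config(),
                                stream = "cohort1") {
  if (censor_rate < 0 || censor_rate >= 1)
    stop("`censor_rate` must be in [0, 1)")
  with_seed(stream_seed(cfg$seed, paste0("survival/", stream)), {
    expr <- stats::rnorm(n)
    rate <- base_hazard * exp(beta * expr)
    t_event <- stats::rexp(n, rate)
    if (censor_rate > 0) {
      # exponential censoring with rate chosen so that for beta = 0 the
      # marginal censored fraction is close to censor_rate
      c_rate <- base_hazard * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, c_rate)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    data.frame(sample = sprintf("s%04d", seq_len(n)),
               time = time, event = event, expression = expr,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a knockdown (siRNA) screen table
#'
#' Produces, per gene, a control IC50, a knockdown IC50 equal to
#' `control * fold`, and per-treatment/control expression pairs whose log2
#' ratios equal the prescribed fold changes exactly.
#'
#' @param genes Character vector of gene identifiers.
#' @param ic50_fold Per-gene IC50 ratio (knockdown / control), > 0; recycled.
#' @param expr_fc Per-gene per-treatment log2 fold changes: a matrix
#'   (genes x treatments) or a vector recycled per gene across treatments.
#' @param n_treatments Number of treatments when `expr_fc` is not a matrix.
#' @param ic50_control Control-arm IC50 (single value).
#' @param cfg A [sim_config()].
#' @return A data.frame usable by [impact_score()]: one row per
#'   gene x treatment, columns `gene`, `treatment`, `ic50_kd`, `ic50_control`,
#'   `expr_treated`, `expr_control`.
#' @export
gen_knockdown_screen <- function(genes, ic50_fold = 1, expr_fc = 0,
                                 n_treatments = 2L, ic50_control = 5,
                                 cfg = sim_config()) {
  ng <- length(genes)
  ic50_fold <- rep_len(ic50_fold, ng)
  if (any(ic50_fold <= 0)) stop("`ic50_fold` must be > 0")
  if (is.matrix(expr_fc)) {
    n_treatments <- ncol(expr_fc)
    stopifnot(nrow(expr_fc) == ng)
  } else {
    expr_fc <- matrix(rep_len(expr_fc, ng * n_treatments),
                      nrow = ng, ncol = n_treatments)
  }
  with_seed(stream_seed(cfg$seed, "knockdown_screen"), {
    expr_control <- matrix(stats::runif(ng * n_treatments, 5, 50),
                           nrow = ng)
    out <- data.frame(
      gene = rep(genes, times = n_treatments),
      treatment = rep(sprintf("treatment%d", seq_len(n_treatments)),
                      each = ng),
      ic50_kd = rep(ic50_control * ic50_fold, times = n_treatments),
      ic50_control = ic50_control,
      expr_control = as.vector(expr_control),
      stringsAsFactors = FALSE)
    out$expr_treated <- out$expr_control * 2^as.vector(expr_fc)
    out[c("gene", "treatment", "ic50_kd", "ic50_control",
          "expr_treated", "expr_control")]
  })
}

#' Simulate annotated barcode cohorts with known dedup winners
#'
#' Each participant receives one or more tumor samples whose sample-type
#' codes, portion numbers and plate identifiers exercise the deduplication
#' rules (primary 01 > recurrent 02 > metastatic 06; then higher portion;
#' then higher plate). The expected winner per participant is recorded for
#' oracle testing.
#'
#' @param n_participants Number of participants.
#' @param max_extra Maximum number of extra (duplicate) samples per
#'   participant.
#' @param cfg A [sim_config()].
#' @return List with `barcodes` (data.frame: participant, sample_type_code,
#'   portion, plate, sample_id) and `expected` (participant -> expected
#'   winning sample_id).
#' @export
gen_tcga_like_barcodes <- function(n_participants, max_extra = 2L,
                                   cfg = sim_config()) {
  codes <- c("01", "02", "06")
  with_seed(stream_seed(cfg$seed, "barcodes"), {
    rows <- list()
    for (i in seq_len(n_participants)) {
      n_samp <- 1L + stats::rbinom(1, max_extra, 0.5)
      rows[[i]] <- data.frame(
        participant = sprintf("P%04d", i),
        sample_type_code = sample(codes, n_samp, replace = TRUE),
        portion = sample(1:9, n_samp, replace = TRUE),
        plate = sprintf("A%03d", sample(100:999, n_samp)),
        stringsAsFactors = FALSE)
    }
    barcodes <- do.call(rbind, rows)
    barcodes$sample_id <- sprintf("samp%05d", seq_len(nrow(barcodes)))
    expected <- vapply(split(barcodes, barcodes$participant), function(d) {
      # independent ordering route used to freeze the expected winner
      rank_type <- match(d$sample_type_code, codes)
      o <- order(rank_type, -d$portion,
                 -xtfrm(d$plate), d$sample_id)
      d$sample_id[o[1]]
    }, character(1))
    list(barcodes = barcodes, expected = expected)
  })
}

#' Simulate gene-set database annotations
#'
#' Builds an annotation table (gene x database membership over exactly three
#' databases) plus an extra sensitivity gene list, with the expected output
#' of the >=2-of-3 + union construction recorded.
#'
#' @param n_genes Number of annotated genes.
#' @param p_member Per-database membership probability.
#' @param n_extra Number of genes in the extra (sensitivity) list; drawn
#'   partly from annotated genes and partly novel.
#' @param cfg A [sim_config()].
#' @return List with `annotations` (data.frame gene, db1, db2, db3 logical),
#'   `extra_list` (character) and `expected_set` (character).
#' @export
gen_geneset_annotations <- function(n_genes = 50, p_member = 0.5,
                                    n_extra = 10, cfg = sim_config()) {
  with_seed(stream_seed(cfg$seed, "geneset_annotations"), {
    genes <- sprintf("g%03d", seq_len(n_genes))
    memb <- matrix(stats::runif(n_genes * 3) < p_member, ncol = 3,
                   dimnames = list(genes, c("db1", "db2", "db3")))
    extra <- unique(c(
      sample(genes, min(n_extra %/% 2, n_genes)),
      sprintf("x%03d", seq_len(n_extra - n_extra %/% 2))))
    hrfa <- genes[rowSums(memb) >= 2]
    ann <- data.frame(gene = genes, db1 = memb[, 1], db2 = memb[, 2],
                      db3 = memb[, 3], stringsAsFactors = FALSE)
    list(annotations = ann, extra_list = extra,
         expected_set = sort(union(hrfa, extra)))
  })
}

#' Xenograft tumor volume from caliper measurements
#'
#' `volume = (1/6) * pi * length * width^2` in cubic millimetres.
#'
#' @param length,width Caliper measurements in mm; `length` should be the
#'   longer axis (a warning, not an error, is raised otherwise).
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumor_volume(6, 5)  # 25 * pi
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("tumor dimensions must be positive")
  if (any(length < width))
    warning("`length` < `width`: check that length is the longer axis")
  (1 / 6) * pi * length * width^2
}

#' Synthetic reconstruction of the BRCAness gene catalog structure
#'
#' The curated catalog this emulates combines (i) homologous-recombination /
#' Fanconi-anemia pathway genes annotated by at least two of three
#' databases (73 genes) with (ii) a 223-gene PARP-inhibitor-sensitivity
#' list, for a union of 247 genes. The real annotations are not
#' redistributable, so this function plants a synthetic catalog with the
#' same marginal structure (73 multi-database HR/FA genes, 223 sensitivity
#' genes, 49 genes in both arms); [build_brcaness_set()] then recomputes the
#' set from these inputs.
#'
#' @param n_single_db Number of decoy genes annotated by only one database
#'   (excluded by the >=2-of-3 rule).
#' @return List with `annotations` (gene x db1/db2/db3), `sensitivity_list`,
#'   and the planted counts.
#' @export
synthetic_brcaness_catalog <- function(n_single_db = 40L) {
  hrfa <- sprintf("HRFA%03d", 1:73)
  # cycle membership patterns over the three 2-of-3 pairs and the triple
  pat <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
              c(FALSE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
  memb <- t(vapply(seq_along(hrfa),
                   function(i) pat[[(i - 1L) %% 4L + 1L]], logical(3)))
  decoys <- sprintf("DECOY%03d", seq_len(n_single_db))
  dmemb <- t(vapply(seq_len(n_single_db), function(i) {
    v <- c(FALSE, FALSE, FALSE); v[(i - 1L) %% 3L + 1L] <- TRUE; v
  }, logical(3)))
  ann <- data.frame(gene = c(hrfa, decoys),
                    db1 = c(memb[, 1], dmemb[, 1]),
                    db2 = c(memb[, 2], dmemb[, 2]),
                    db3 = c(memb[, 3], dmemb[, 3]),
                    stringsAsFactors = FALSE)
  sensitivity <- c(hrfa[1:49], sprintf("SENS%03d", 1:174))
  list(annotations = ann, sensitivity_list = sensitivity,
       n_hrfa = 73L, n_sensitivity = 223L, n_union = 247L)
}

#' Synthetic planted-truth combination screen
#'
#' Simulates a full anchor-drug x panel combination screen: per line, each
#' partner inhibitor gets a noiseless (or noisy) constant-ratio series whose
#' ground-truth CI profile is flat at `ci_hit` for planted synergists and
#' `ci_null` otherwise, together with single-agent plates for every drug.
#'
#' @param n_partners Panel size.
#' @param hits Named list: per line, integer indices of planted synergists.
#' @param ci_hit,ci_null Flat ground-truth CI for hits / non-hits.
#' @param cfg A [sim_config()].
#' @param anchor Anchor-drug label.
#' @return List with `plates` (named list of [viability_plate] per
#'   line/drug), `series` (list of combination_series), `hits` (the plan).
#' @export
synthetic_combination_screen <- function(n_partners = 20L,
                                         hits = list(line1 = 1:6,
                                                     line2 = c(1:3, 7:9)),
                                         ci_hit = 0.5, ci_null = 1.0,
                                         cfg = sim_config(),
                                         anchor = "anchor") {
  lines <- names(hits)
  partners <- sprintf("epi%02d", seq_len(n_partners))
  doses <- c(0.25, 0.5, 1, 2, 4)
  with_seed(stream_seed(cfg$seed, "combo_screen_params"), {
    # per-drug true parameters, shared across lines for simplicity
    par_anchor <- drug_params(m = 1.2, Dm = 1, label = anchor)
    par_partner <- lapply(seq_len(n_partners), function(i)
      drug_params(m = stats::runif(1, 0.8, 2), Dm = stats::runif(1, 0.5, 2),
                  label = partners[i]))
  })
  plates <- list(); series <- list()
  for (ln in lines) {
    plates[[ln]] <- c(
      stats::setNames(list(gen_monotherapy_plate(
        par_anchor, doses * par_anchor$Dm, cfg, condition = ln)), anchor),
      stats::setNames(lapply(par_partner, function(p)
        gen_monotherapy_plate(p, doses * p$Dm, cfg, condition = ln)),
        partners))
    for (i in seq_len(n_partners)) {
      ci <- if (i %in% hits[[ln]]) ci_hit else ci_null
      key <- paste(ln, partners[i], sep = "/")
      series[[key]] <- gen_combination_series(
        par_anchor, par_partner[[i]], ratio = 1,
        ci_profile = local({ ci0 <- ci; function(fa) ci0 }),
        cfg = cfg, line = ln)
    }
  }
  list(plates = plates, series = series, hits = hits,
       anchor = anchor, partners = partners)
}
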