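# Shared fixtures and independent oracle routines used across test files.
# Oracles are deliberately coded by a different route than the package
# implementation they check.

noiseless_cfg <- function(seed = 1L) sim_config(seed = seed, noise_model = "none")

five_dose_plate <- function(m, Dm, label = "drug", seed = 1L,
                            fa_grid = c(0.2, 1/3, 0.5, 2/3, 0.8)) {
  # doses chosen so the true fa values land on fa_grid exactly
  doses <- Dm * (fa_grid / (1 - fa_grid))^(1 / m)
  gen_monotherapy_plate(drug_params(m, Dm, label), doses,
                        noiseless_cfg(seed))
}

# Brute-force impact-score oracle: a literal, loop-based transcription of
# the four defining formulas.
impact_score_oracle <- function(screen) {
  genes <- unique(screen$gene)
  fexpt_sum <- numeric(length(genes))
  fic50 <- numeric(length(genes))
  for (i in seq_along(genes)) {
    rows <- screen[screen$gene == genes[i], ]
    s <- 0
    for (j in seq_len(nrow(rows)))
      s <- s + (log2(rows$expr_treated[j]) - log2(rows$expr_control[j]))
    fexpt_sum[i] <- s
    fic50[i] <- rows$ic50_kd[1] / rows$ic50_control[1]
  }
  fmin <- min(fic50); fmax <- max(fic50)
  fprime <- (fic50 - fmin) / (fmax - fmin)
  data.frame(gene = genes, sum_fexpt = fexpt_sum,
             fic50_scaled = fprime, score = fprime * fexpt_sum,
             stringsAsFactors = FALSE)
}

# Brute-force dedup oracle: for each participant, find the sample that wins
# every pairwise comparison (tournament), instead of sorting.
dedup_oracle <- function(barcodes) {
  beats <- function(a, b) {
    ra <- match(a$sample_type_code, c("01", "02", "06"))
    rb <- match(b$sample_type_code, c("01", "02", "06"))
    if (ra != rb) return(ra < rb)
    if (a$portion != b$portion) return(a$portion > b$portion)
    if (a$plate != b$plate) return(a$plate > b$plate)
    a$sample_id < b$sample_id
  }
  vapply(split(barcodes, barcodes$participant), function(d) {
    best <- 1L
    if (nrow(d) > 1) for (i in 2:nrow(d))
      if (beats(d[i, ], d[best, ])) best <- i
    d$sample_id[best]
  }, character(1))
}

random_knockdown_screen <- function(n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  data.frame(
    gene = rep(genes, 2),
    treatment = rep(c("t1", "t2"), each = n_genes),
    ic50_kd = rep(runif(n_genes, 0.5, 20), 2),
    ic50_control = 5,
    expr_treated = runif(2 * n_genes, 1, 100),
    expr_control = runif(2 * n_genes, 1, 100),
    stringsAsFactors = FALSE)
}
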