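# Seeded generator of a full synthetic multi-omics experiment (RNA, RPF,
# protein, tracer, qPCR, dose-response) with known per-gene ground truth.

GENE_CLASSES <- c("regulon_core", "tm_specific", "th_specific",
                  "translational_only", "turnover_only", "ridd_like_down",
                  "null")

#' Generator parameters for the synthetic experiment
#'
#' Defaults emulate the staged two-inducer design the package targets:
#' two ER-stress agents (tunicamycin, TM; thapsigargin, TH) plus DMSO-style
#' controls, RNA-seq and ribosome profiling at 2 and 6 h, shotgun proteomics
#' at 6/16/24 h, ~10,000 protein-coding genes with a planted co-induced
#' regulon of 267 genes, treatment-specific responders, a global ~34%
#' translational downshift in treated ribosome-profiling libraries
#' (factor 0.66), and delayed protein kinetics (effect scale 0.25/0.75/1.0
#' at 6/16/24 h).
#'
#' @param n_genes total genes (>= 100).
#' @param n_regulon_core,n_tm_specific,n_th_specific,n_translational_only,n_turnover_only,n_ridd_like_down
#'   planted class sizes; remaining genes are null.
#' @param reps named replicate counts for TM / TH / control groups (TM uses 2
#'   technical-style replicates, TH and control 3 biological-style replicates).
#' @param effect_mean,effect_sd mean and SD of planted log2 fold-change
#'   magnitudes (log2 units).
#' @param baseline_meanlog,baseline_sdlog,baseline_min log-normal parameters
#'   (natural log) and lower floor of per-gene baseline mean counts.
#' @param alpha_median,alpha_sdlog log-normal NB dispersion distribution
#'   (Var = mu + alpha * mu^2).
#' @param libsize_fold_range library size factors are drawn log-uniform over
#'   this fold range (e.g. 2 = a two-fold spread).
#' @param loading_sdlog spread (natural log) of the per-gene ribosome loading
#'   factor linking RPF to RNA means.
#' @param rpf_downshift multiplicative global translation downshift applied to
#'   treated RPF libraries (0.66 = a 34% reduction).
#' @param protein_kinetics named effect scaling of planted protein effects at
#'   6, 16 and 24 h.
#' @param protein_baseline_meanlog2,protein_baseline_sdlog2 log2-scale
#'   baseline distribution of protein intensities.
#' @param protein_sdlog2 replicate noise SD of log2 protein intensities.
#' @param protein_missing_rate completely-at-random missingness of intensities.
#' @param replicate_var_inflation multiplies replicate noise in TM groups
#'   (1 = identical variance in both agents).
#' @param pool_fold_changes planted treated/control fold-changes of free
#'   amino-acid pools (defaults: serine 2.98, proline 2.78, glycine 4.34).
#' @param mito_share_control,mito_share_treated planted mitochondrial share of
#'   labeled dTTP synthesis per condition.
#' @param serine_labeled_frac,glycine_labeled_frac_control,glycine_labeled_frac_treated
#'   planted labeled fractions of the serine and glycine pools.
#' @param dttp_labeled_frac planted labeled (M+2 plus M+3) fraction of dTTP.
#' @param tracer_noise_cv multiplicative CV of tracer peak areas.
#' @param tracer_reps tracer replicates per condition.
#' @param nadp_ratio_control,nadp_ratio_treated planted NADP+/NADPH ratios.
#' @param nadp_reps,nadp_noise_cv NADP assay replicates and noise.
#' @param qpcr_true_ratio planted target induction (treated/control input).
#' @param qpcr_efficiency,qpcr_ct0_target,qpcr_ct0_ref primer efficiency in
#'   (1, 2.2] and baseline Ct of target and reference at control input.
#' @param qpcr_noise_sd,qpcr_reps Ct replicate noise SD and replicates.
#' @param ic50_control,ic50_treated planted IC50s (uM) of the two conditions.
#' @param hill,top,bottom remaining 4PL parameters of the viability curve.
#' @param doses dose series (uM).
#' @param viability_noise_sd additive viability noise (percentage points).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       n_regulon_core = 267L,
                       n_tm_specific = 150L,
                       n_th_specific = 150L,
                       n_translational_only = 100L,
                       n_turnover_only = 100L,
                       n_ridd_like_down = 50L,
                       reps = c(TM = 2L, TH = 3L, control = 3L),
                       effect_mean = 1.5, effect_sd = 0.5,
                       baseline_meanlog = log(250), baseline_sdlog = 1.0,
                       baseline_min = 5,
                       alpha_median = 0.05, alpha_sdlog = 0.35,
                       libsize_fold_range = 2,
                       loading_sdlog = 0.25,
                       rpf_downshift = 0.66,
                       protein_kinetics = c(`6` = 0.25, `16` = 0.75, `24` = 1),
                       protein_baseline_meanlog2 = 20,
                       protein_baseline_sdlog2 = 2,
                       protein_sdlog2 = 0.3,
                       protein_missing_rate = 0.05,
                       replicate_var_inflation = 1,
                       pool_fold_changes = c(serine = 2.98, proline = 2.78,
                                             glycine = 4.34),
                       mito_share_control = 0.35,
                       mito_share_treated = 0.7,
                       serine_labeled_frac = 0.5,
                       glycine_labeled_frac_control = 0.2,
                       glycine_labeled_frac_treated = 0.45,
                       dttp_labeled_frac = 0.4,
                       tracer_noise_cv = 0.05,
                       tracer_reps = 3L,
                       nadp_ratio_control = 1.0,
                       nadp_ratio_treated = 0.6,
                       nadp_reps = 4L,
                       nadp_noise_cv = 0.1,
                       qpcr_true_ratio = 8,
                       qpcr_efficiency = 2,
                       qpcr_ct0_target = 24,
                       qpcr_ct0_ref = 18,
                       qpcr_noise_sd = 0.1,
                       qpcr_reps = 3L,
                       ic50_control = 0.01,
                       ic50_treated = 100,
                       hill = 1, top = 100, bottom = 0,
                       doses = 10^seq(-4, 4),
                       viability_noise_sd = 2) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 100L) stop("n_genes must be >= 100")
  n_planted <- n_regulon_core + n_tm_specific + n_th_specific +
    n_translational_only + n_turnover_only + n_ridd_like_down
  if (n_planted > cfg$n_genes) stop("planted class sizes exceed n_genes")
  if (any(reps < 2L)) stop("replicate counts must be >= 2")
  if (!all(c("TM", "TH", "control") %in% names(reps)))
    stop("reps must name TM, TH and control")
  if (alpha_median <= 0 || baseline_meanlog <= 0)
    stop("dispersion and baseline parameters must be positive")
  if (rpf_downshift <= 0) stop("rpf_downshift must be positive")
  if (mito_share_control < 0 || mito_share_control > 1 ||
      mito_share_treated < 0 || mito_share_treated > 1)
    stop("mito_share must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# Independent per-matrix RNG streams: a stable polynomial hash of
# (seed, stream name), kept below 2^31 so it is a valid set.seed() input.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 69069 + h + 1) %% 2147483629)
}

#' Sample a negative-binomial count matrix
#'
#' Counts are drawn with `Var = mu + alpha * mu^2` (dispersion `alpha` per
#' gene/row). Used internally by [simulate_experiment()] and directly
#' testable for its marginal moments.
#'
#' @param mu matrix of means (genes x samples).
#' @param alpha per-gene dispersion vector (> 0).
#' @return an integer-valued matrix with the dimnames of `mu`.
#' @export
sim_nb_counts <- function(mu, alpha) {
  stopifnot(is.matrix(mu), length(alpha) == nrow(mu))
  if (any(alpha <= 0)) stop("dispersion must be positive")
  if (any(mu < 0)) stop("means must be non-negative")
  n <- length(mu)
  counts <- stats::rnbinom(n, mu = as.vector(mu),
                           size = rep(1 / alpha, times = ncol(mu)))
  matrix(as.numeric(counts), nrow = nrow(mu), dimnames = dimnames(mu))
}

make_sheet <- function(cfg) {
  rows <- list()
  add <- function(layer, tps) {
    for (agent in c("TM", "TH", "control")) {
      n <- cfg$reps[[agent]]
      for (tp in tps) {
        for (r in seq_len(n)) {
          rows[[length(rows) + 1L]] <<- data.frame(
            sample_id = sprintf("%s_%s_%gh_r%d", layer, agent, tp, r),
            agent = agent, timepoint_h = tp, replicate = r, layer = layer,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  add("rna", c(2, 6))
  add("rpf", c(2, 6))
  add("protein", c(6, 16, 24))
  validate_sample_sheet(do.call(rbind, rows))
}

make_truth <- function(cfg, seed) {
  set.seed(stream_seed(seed, "truth"))
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  klass <- rep("null", n)
  idx <- 0L
  take <- function(k) {
    out <- idx + seq_len(k)
    idx <<- idx + k
    out
  }
  klass[take(cfg$n_regulon_core)] <- "regulon_core"
  klass[take(cfg$n_tm_specific)] <- "tm_specific"
  klass[take(cfg$n_th_specific)] <- "th_specific"
  klass[take(cfg$n_translational_only)] <- "translational_only"
  klass[take(cfg$n_turnover_only)] <- "turnover_only"
  klass[take(cfg$n_ridd_like_down)] <- "ridd_like_down"

  eff <- function(k) stats::rnorm(k, cfg$effect_mean, cfg$effect_sd)
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)

  tr <- data.frame(gene_id = gene_id, klass = klass,
                   rna_TM = 0, rna_TH = 0,
                   rls_TM = 0, rls_TH = 0,
                   protein_TM = 0, protein_TH = 0,
                   stringsAsFactors = FALSE)
  i <- klass == "regulon_core"        # same positive effect in both agents
  e <- eff(sum(i))
  tr$rna_TM[i] <- e; tr$rna_TH[i] <- e
  tr$protein_TM[i] <- e; tr$protein_TH[i] <- e
  i <- klass == "tm_specific"
  e <- rsign(sum(i)) * eff(sum(i))
  tr$rna_TM[i] <- e; tr$protein_TM[i] <- e
  i <- klass == "th_specific"
  e <- rsign(sum(i)) * eff(sum(i))
  tr$rna_TH[i] <- e; tr$protein_TH[i] <- e
  i <- klass == "translational_only"  # loading change only, both agents
  e <- abs(eff(sum(i)))
  tr$rls_TM[i] <- e; tr$rls_TH[i] <- e
  i <- klass == "turnover_only"       # protein abundance only
  e <- abs(eff(sum(i)))
  tr$protein_TM[i] <- e; tr$protein_TH[i] <- e
  i <- klass == "ridd_like_down"      # decayed mRNAs, both agents
  e <- -abs(eff(sum(i)))
  tr$rna_TM[i] <- e; tr$rna_TH[i] <- e
  tr$protein_TM[i] <- e; tr$protein_TH[i] <- e
  tr
}

#' Simulate a full synthetic multi-omics experiment
#'
#' Generates RNA-seq and ribosome-profiling count matrices (negative binomial
#' around baseline x library size x planted fold-change, with the RPF mean
#' tied to the RNA mean through a per-gene loading factor, the global
#' translational downshift in treated libraries and any planted loading
#' shift), delayed-kinetics log-normal protein intensities, a sample sheet,
#' the ground-truth table, tracer isotopologue profiles, amino-acid pool and
#' NADP assay tables, a qPCR Ct table and dose-response curves. Identical
#' (config, seed) pairs give byte-identical output; each component uses an
#' independent RNG stream hashed from the root seed.
#'
#' @param config a [sim_config()].
#' @param seed root integer seed.
#' @return a list of class `synthetic_experiment` with elements `rna`, `rpf`,
#'   `protein` (matrices), `sheet`, `truth`, `true_size_factors`, `tracer`,
#'   `pools`, `nadp`, `qpcr`, `dose_response`, `config`, `seed`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sheet <- make_sheet(cfg)
  truth <- make_truth(cfg, seed)
  n <- cfg$n_genes

  set.seed(stream_seed(seed, "genes"))
  baseline <- pmax(stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog),
                   cfg$baseline_min)
  alpha <- stats::rlnorm(n, log(cfg$alpha_median), cfg$alpha_sdlog)
  loading <- stats::rlnorm(n, 0, cfg$loading_sdlog)

  set.seed(stream_seed(seed, "libsizes"))
  all_ids <- sheet$sample_id
  half <- log(cfg$libsize_fold_range) / 2
  sf_true <- exp(stats::runif(length(all_ids), -half, half))
  names(sf_true) <- all_ids

  planted_log2fc <- function(layer, agent, tp) {
    # per-gene planted log2 fold-change of the mean for a treated group
    if (agent == "control") return(rep(0, n))
    rna_fc <- truth[[paste0("rna_", agent)]]
    if (layer == "rna") return(rna_fc)
    if (layer == "rpf") return(rna_fc + truth[[paste0("rls_", agent)]])
    scale <- cfg$protein_kinetics[[as.character(tp)]]
    truth[[paste0("protein_", agent)]] * scale
  }

  count_layer <- function(layer) {
    sub <- sheet[sheet$layer == layer, , drop = FALSE]
    mu <- matrix(0, n, nrow(sub),
                 dimnames = list(truth$gene_id, sub$sample_id))
    for (j in seq_len(nrow(sub))) {
      m <- baseline * sf_true[sub$sample_id[j]] *
        2^planted_log2fc(layer, sub$agent[j], sub$timepoint_h[j])
      if (layer == "rpf") {
        m <- m * loading
        if (sub$agent[j] != "control") m <- m * cfg$rpf_downshift
      }
      mu[, j] <- m
    }
    set.seed(stream_seed(seed, layer))
    new_count_matrix(sim_nb_counts(mu, alpha), layer)
  }
  rna <- count_layer("rna")
  rpf <- count_layer("rpf")

  # protein: log2-normal intensities, delayed kinetics, MCAR missingness
  subp <- sheet[sheet$layer == "protein", , drop = FALSE]
  set.seed(stream_seed(seed, "protein"))
  base2 <- stats::rnorm(n, cfg$protein_baseline_meanlog2,
                        cfg$protein_baseline_sdlog2)
  pint <- matrix(NA_real_, n, nrow(subp),
                 dimnames = list(truth$gene_id, subp$sample_id))
  for (j in seq_len(nrow(subp))) {
    infl <- if (subp$agent[j] == "TM") sqrt(cfg$replicate_var_inflation) else 1
    lg2 <- base2 +
      planted_log2fc("protein", subp$agent[j], subp$timepoint_h[j]) +
      stats::rnorm(n, 0, cfg$protein_sdlog2 * infl)
    pint[, j] <- 2^lg2
  }
  if (cfg$protein_missing_rate > 0) {
    drop <- stats::runif(length(pint)) < cfg$protein_missing_rate
    pint[drop] <- NA_real_
  }
  protein <- new_intensity_matrix(pint)

  tracer <- rbind(
    simulate_tracer(cfg$mito_share_control, cfg$tracer_noise_cv,
                    n_reps = cfg$tracer_reps,
                    seed = stream_seed(seed, "tracer_control"),
                    serine_labeled_frac = cfg$serine_labeled_frac,
                    glycine_labeled_frac = cfg$glycine_labeled_frac_control,
                    dttp_labeled_frac = cfg$dttp_labeled_frac,
                    condition = "control"),
    simulate_tracer(cfg$mito_share_treated, cfg$tracer_noise_cv,
                    n_reps = cfg$tracer_reps,
                    seed = stream_seed(seed, "tracer_treated"),
                    serine_labeled_frac = cfg$serine_labeled_frac,
                    glycine_labeled_frac = cfg$glycine_labeled_frac_treated,
                    dttp_labeled_frac = cfg$dttp_labeled_frac,
                    condition = "TM"))

  # free amino-acid pools (internal-standard-quantified amounts, nmol)
  set.seed(stream_seed(seed, "pools"))
  pools <- do.call(rbind, lapply(names(cfg$pool_fold_changes), function(a) {
    fc <- cfg$pool_fold_changes[[a]]
    data.frame(
      analyte = a,
      condition = rep(c("control", "TM"), each = cfg$tracer_reps),
      replicate = rep(seq_len(cfg$tracer_reps), 2L),
      amount_nmol = c(10 * lnorm_noise(cfg$tracer_reps, cfg$tracer_noise_cv),
                      10 * fc * lnorm_noise(cfg$tracer_reps,
                                            cfg$tracer_noise_cv)),
      stringsAsFactors = FALSE)
  }))

  set.seed(stream_seed(seed, "nadp"))
  nadph <- 1000 * lnorm_noise(2L * cfg$nadp_reps, cfg$nadp_noise_cv)
  ratio <- rep(c(cfg$nadp_ratio_control, cfg$nadp_ratio_treated),
               each = cfg$nadp_reps)
  nadp <- data.frame(
    condition = rep(c("control", "TM"), each = cfg$nadp_reps),
    replicate = rep(seq_len(cfg$nadp_reps), 2L),
    nadp_signal = nadph * ratio *
      lnorm_noise(2L * cfg$nadp_reps, cfg$nadp_noise_cv),
    nadph_signal = nadph,
    stringsAsFactors = FALSE)

  assays <- simulate_assays(cfg, seed = stream_seed(seed, "assays"))

  structure(list(rna = rna, rpf = rpf, protein = protein, sheet = sheet,
                 truth = truth, true_size_factors = sf_true,
                 baseline = stats::setNames(baseline, truth$gene_id),
                 dispersion = stats::setNames(alpha, truth$gene_id),
                 tracer = tracer, pools = pools, nadp = nadp,
                 qpcr = assays$qpcr, dose_response = assays$dose_response,
                 config = cfg, seed = as.integer(seed)),
            class = "synthetic_experiment")
}

# multiplicative log-normal noise with unit mean and given CV
lnorm_noise <- function(k, cv) {
  if (cv <= 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, -sdlog^2 / 2, sdlog)
}

#' Simulate isotopologue profiles from a heavy-serine labeling experiment
#'
#' Emulates tracing with a \[1,2,3-13C; 2,3,3-2H; 2-15N\]serine tracer:
#' labeled serine appears as M+7, SHMT-derived glycine as M+4, and labeled
#' dTTP as M+3 when the one-carbon unit was produced in the cytosol or M+2
#' when it passed through the mitochondrial arm, so the expected M+2 share
#' of labeled dTTP equals `mito_share`.
#'
#' @param mito_share mitochondrial fraction of labeled dTTP synthesis, in
#'   \[0, 1\].
#' @param noise_cv multiplicative coefficient of variation of peak areas.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @param serine_labeled_frac,glycine_labeled_frac,dttp_labeled_frac labeled
#'   fractions of each pool.
#' @param condition condition label attached to the rows.
#' @param total_area expected summed peak area per analyte.
#' @return data frame with columns `analyte`, `mass_shift`, `condition`,
#'   `replicate`, `intensity`.
#' @export
simulate_tracer <- function(mito_share, noise_cv = 0.05, n_reps = 3L,
                            seed = 1L, serine_labeled_frac = 0.5,
                            glycine_labeled_frac = 0.3,
                            dttp_labeled_frac = 0.4,
                            condition = "treated", total_area = 1e6) {
  if (mito_share < 0 || mito_share > 1) stop("mito_share must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  set.seed(seed)
  profiles <- list(
    serine = c(`0` = 1 - serine_labeled_frac, `7` = serine_labeled_frac),
    glycine = c(`0` = 1 - glycine_labeled_frac, `4` = glycine_labeled_frac),
    dTTP = c(`0` = 1 - dttp_labeled_frac,
             `2` = dttp_labeled_frac * mito_share,
             `3` = dttp_labeled_frac * (1 - mito_share)))
  rows <- list()
  for (a in names(profiles)) {
    pr <- profiles[[a]]
    for (r in seq_len(n_reps)) {
      inten <- total_area * pr * lnorm_noise(length(pr), noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, mass_shift = as.integer(names(pr)),
        condition = condition, replicate = r, intensity = unname(inten),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate qPCR Ct and dose-response viability tables
#'
#' Ct values follow `Ct = Ct0 - log_E(relative input)` for the configured
#' primer efficiency, with an invariant reference gene (GAPDH-like) and a
#' target induced by the planted ratio; viabilities follow a four-parameter
#' logistic dose-response with the planted condition-specific IC50s.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `qpcr` (sample, condition, replicate, gene, ct,
#'   efficiency) and `dose_response` (compound, condition, replicate, dose,
#'   viability_percent).
#' @export
simulate_assays <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  e <- cfg$qpcr_efficiency
  if (e <= 1 || e > 2.2) stop("primer efficiency must lie in (1, 2.2]")
  set.seed(seed)
  conds <- rep(c("control", "TM"), each = cfg$qpcr_reps)
  reps <- rep(seq_len(cfg$qpcr_reps), 2L)
  input_ratio <- ifelse(conds == "TM", cfg$qpcr_true_ratio, 1)
  qpcr <- rbind(
    data.frame(sample = paste0(conds, "_r", reps), condition = conds,
               replicate = reps, gene = "target",
               ct = cfg$qpcr_ct0_target - log(input_ratio, base = e) +
                 stats::rnorm(length(conds), 0, cfg$qpcr_noise_sd),
               efficiency = e, stringsAsFactors = FALSE),
    data.frame(sample = paste0(conds, "_r", reps), condition = conds,
               replicate = reps, gene = "reference",
               ct = cfg$qpcr_ct0_ref +
                 stats::rnorm(length(conds), 0, cfg$qpcr_noise_sd),
               efficiency = e, stringsAsFactors = FALSE))

  dr <- do.call(rbind, lapply(c("control", "TM"), function(cond) {
    ic50 <- if (cond == "TM") cfg$ic50_treated else cfg$ic50_control
    do.call(rbind, lapply(seq_len(cfg$tracer_reps), function(r) {
      v <- cfg$bottom + (cfg$top - cfg$bottom) /
        (1 + (cfg$doses / ic50)^cfg$hill) +
        stats::rnorm(length(cfg$doses), 0, cfg$viability_noise_sd)
      data.frame(compound = "antifolate", condition = cond, replicate = r,
                 dose = cfg$doses, viability_percent = v,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(qpcr = qpcr, dose_response = dr)
}

#' Write a synthetic experiment bundle as TSV files
#'
#' Writes the count/intensity matrices, sample sheet, ground-truth table,
#' true size factors and the assay tables into a directory in the package's
#' TSV formats, ready for [run_all()].
#'
#' @param exp a `synthetic_experiment`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(exp$rna, file.path(dir, "rna.tsv"))
  write_count_matrix(exp$rpf, file.path(dir, "rpf.tsv"))
  write_intensity_matrix(exp$protein, file.path(dir, "protein.tsv"))
  write_sample_sheet(exp$sheet, file.path(dir, "sheet.tsv"))
  write_table(exp$truth, file.path(dir, "truth.tsv"))
  write_table(data.frame(sample_id = names(exp$true_size_factors),
                         size_factor = unname(exp$true_size_factors),
                         stringsAsFactors = FALSE),
              file.path(dir, "true_size_factors.tsv"), digits = 10L)
  write_table(exp$tracer, file.path(dir, "tracer.tsv"))
  write_table(exp$pools, file.path(dir, "pools.tsv"))
  write_table(exp$nadp, file.path(dir, "nadp.tsv"))
  write_table(exp$qpcr, file.path(dir, "qpcr.tsv"))
  write_table(exp$dose_response, file.path(dir, "dose_response.tsv"))
  invisible(dir)
}
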