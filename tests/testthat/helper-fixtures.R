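# Shared fixtures and independent oracle implementations.

toy_counts <- function(mat, layer = "rna",
                       genes = sprintf("g%03d", seq_len(nrow(mat))),
                       samples = sprintf("s%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(genes, samples)
  stressregulon:::new_count_matrix(mat, layer)
}

toy_intensities <- function(mat,
                            genes = sprintf("p%03d", seq_len(nrow(mat))),
                            samples = sprintf("s%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(genes, samples)
  stressregulon:::new_intensity_matrix(mat)
}

# minimal sheet for one contrast: n_t treated + n_c control samples of one
# layer at one timepoint, sample ids s1..s(n_t+n_c)
contrast_sheet <- function(n_t, n_c, agent = "TM", tp = 6, layer = "rna") {
  df <- data.frame(
    sample_id = sprintf("s%d", seq_len(n_t + n_c)),
    agent = c(rep(agent, n_t), rep("control", n_c)),
    timepoint_h = tp,
    replicate = c(seq_len(n_t), seq_len(n_c)),
    layer = layer, stringsAsFactors = FALSE)
  stressregulon:::validate_sample_sheet(df)
}

# synthetic contrast result assembled by hand (df column optional)
make_contrast <- function(log2fc, p, se = rep(0.3, length(log2fc)),
                          layer = "rna", agent = "TM", tp = 6, df = NULL,
                          genes = sprintf("g%03d", seq_along(log2fc))) {
  res <- data.frame(gene_id = genes, base_mean = 100, log2fc = log2fc,
                    se = se, stat = log2fc / se, p = p,
                    padj = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  if (!is.null(df)) res$df <- df
  structure(res, class = c("contrast_result", "data.frame"),
            agent = agent, timepoint_h = tp, layer = layer)
}

make_calls <- function(genes, direction, layer, agent, tp = 6) {
  structure(data.frame(gene_id = genes, layer = layer, agent = agent,
                       timepoint_h = tp, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("layer_call", "data.frame"))
}

# scaled-down generator configurations
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 600L, n_regulon_core = 30L, n_tm_specific = 15L,
         n_th_specific = 15L, n_translational_only = 10L,
         n_turnover_only = 10L, n_ridd_like_down = 5L),
    list(...))
  do.call(sim_config, args)
}

null_cfg <- function(reps = c(TM = 3L, TH = 3L, control = 3L), ...) {
  sim_config(n_regulon_core = 0L, n_tm_specific = 0L, n_th_specific = 0L,
             n_translational_only = 0L, n_turnover_only = 0L,
             n_ridd_like_down = 0L, reps = reps, ...)
}

# Independent oracle: direct loop evaluation of the NB Wald formulas
# (median-of-ratios normalization is taken as given via sf; MoM dispersion,
# delta-method SE, normal tail, BH).
oracle_nb_wald <- function(counts, t_idx, c_idx, sf, pseudocount = 0.5,
                           floor = 1e-8) {
  out <- NULL
  for (g in rownames(counts)) {
    norm <- counts[g, ] / sf
    xt <- norm[t_idx]; xc <- norm[c_idx]
    n_t <- length(xt); n_c <- length(xc)
    if (sum(counts[g, c(t_idx, c_idx)]) == 0) next
    mt <- sum(xt) / n_t
    mc <- sum(xc) / n_c
    vt <- sum((xt - mt)^2) / (n_t - 1)
    vc <- sum((xc - mc)^2) / (n_c - 1)
    s2 <- (vt * (n_t - 1) + vc * (n_c - 1)) / (n_t + n_c - 2)
    mbar <- sum(c(xt, xc)) / (n_t + n_c)
    alpha <- max((s2 - mbar) / mbar^2, floor)
    if (mt == 0 || mc == 0) {
      l2 <- log2((mt + pseudocount) / (mc + pseudocount))
    } else {
      l2 <- log2(mt / mc)
    }
    vln <- function(m, n) {
      m <- max(m, pseudocount)
      (m / n + alpha * m^2 / n) / (m^2 * log(2)^2)
    }
    se <- sqrt(vln(mt, n_t) + vln(mc, n_c))
    stat <- l2 / se
    p <- 2 * pnorm(-abs(stat))
    out <- rbind(out, data.frame(gene_id = g, log2fc = l2, se = se,
                                 stat = stat, p = p,
                                 stringsAsFactors = FALSE))
  }
  out$padj <- p.adjust(out$p, "BH")
  out
}

# full in-memory call + regulon pass over a simulated experiment
regulon_from_experiment <- function(ex, cfg = analysis_config()) {
  calls <- list()
  for (layer in c("rna", "rpf")) {
    for (agent in c("TM", "TH")) {
      for (tp in c(2, 6)) {
        r <- nb_wald_contrast(ex[[layer]], ex$sheet, agent = agent,
                              timepoint = tp, cfg = cfg)
        calls[[paste(layer, agent, tp)]] <- call_regulated(r, cfg)
      }
    }
  }
  for (agent in c("TM", "TH")) {
    for (tp in c(6, 16, 24)) {
      r <- protein_contrast(ex$protein, ex$sheet, agent = agent,
                            timepoint = tp)
      calls[[paste("protein", agent, tp)]] <-
        call_regulated_proteins(r, cfg)$calls
    }
  }
  build_regulon(calls, cfg)
}

member_metrics <- function(reg, truth) {
  member <- reg$records$gene_id[grepl("^member", reg$records$status)]
  core <- truth$gene_id[truth$klass == "regulon_core"]
  pos <- truth$gene_id[truth$klass %in% c("regulon_core",
                                          "translational_only")]
  c(sensitivity = length(intersect(member, core)) / max(length(core), 1),
    fdr = length(setdiff(member, pos)) / max(length(member), 1),
    n_members = length(member))
}

# Independent oracle: pooled-variance two-sample t on log2 intensities
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(stat = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}
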