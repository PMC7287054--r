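# Count-based differential expression: median-of-ratios size factors,
# method-of-moments dispersion, NB Wald contrast (optionally with
# empirical-Bayes moderation of the per-gene overdispersion) and the
# dual quantile + p-value regulated-gene gate.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio count / per-gene geometric mean, where the reference set is the
#' genes with no zero count across samples. Scaling one sample's counts by a
#' constant scales its factor by exactly that constant.
#'
#' @param m a `count_matrix`.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene with all-positive counts; filter low-count genes or add a pseudocount before estimating size factors")
  logg <- rowMeans(log(counts[ref, , drop = FALSE]))
  apply(counts[ref, , drop = FALSE], 2, function(cj) {
    stats::median(cj / exp(logg))
  })
}

group_moments <- function(norm, idx) {
  x <- norm[, idx, drop = FALSE]
  n <- length(idx)
  mean <- rowMeans(x)
  var <- rowSums((x - mean)^2) / (n - 1)
  list(mean = mean, var = var, n = n)
}

#' Method-of-moments NB dispersion
#'
#' Per gene, within-group sample variances of the normalized counts are
#' pooled across groups (degrees-of-freedom weighted) and the dispersion is
#' `alpha = max((s2 - m) / m^2, floor)` where `m` is the pooled mean.
#' Genes with zero mean everywhere get the floor and are flagged untestable.
#'
#' @param m a `count_matrix`.
#' @param groups character/factor of group labels, one per sample (each group
#'   needs >= 2 samples).
#' @param sf size factors (defaults to [estimate_size_factors()]).
#' @param floor dispersion floor.
#' @return named per-gene dispersion vector with attribute `untestable`
#'   (gene ids with zero mean in all groups).
#' @export
estimate_dispersion <- function(m, groups, sf = NULL, floor = 1e-8) {
  stopifnot(inherits(m, "count_matrix"))
  groups <- as.character(groups)
  if (length(groups) != ncol(m$counts))
    stop("groups must have one label per sample")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (is.null(sf)) sf <- estimate_size_factors(m)
  norm <- sweep(m$counts, 2, sf, "/")
  lev <- unique(groups)
  s2 <- 0
  df <- 0
  for (g in lev) {
    mom <- group_moments(norm, which(groups == g))
    s2 <- s2 + mom$var * (mom$n - 1L)
    df <- df + (mom$n - 1L)
  }
  s2 <- s2 / df
  mbar <- rowMeans(norm)
  alpha <- ifelse(mbar > 0, pmax((s2 - mbar) / mbar^2, floor), floor)
  names(alpha) <- rownames(m$counts)
  attr(alpha, "untestable") <- rownames(m$counts)[mbar == 0]
  alpha
}

#' Negative-binomial Wald contrast (treated vs time-matched control)
#'
#' The log2 fold-change is the log2 ratio of normalized group means (a
#' pseudocount enters only when a group mean is zero). Its standard error is
#' the delta-method variance `Var(log2 mhat) = (m/n + alpha m^2/n)/(m^2 ln^2 2)`
#' per group, summed over the two groups; `stat = log2fc / se`; p-values are
#' two-sided with BH adjustment within the contrast.
#'
#' With `moderate = TRUE` (default) the per-gene overdispersion (squared
#' coefficient of variation of the normalized counts) is stabilized by
#' empirical-Bayes pooling toward a global prior ([limma::squeezeVar]) and
#' the statistic is referred to a t distribution with residual + prior
#' degrees of freedom, which keeps the test calibrated at 2-3 replicates.
#' With `moderate = FALSE` the per-gene method-of-moments dispersion
#' (`disp`, or [estimate_dispersion()] on the contrast samples) is plugged in
#' unchanged and the tail is normal.
#'
#' @param m a `count_matrix`.
#' @param sheet a `sample_sheet` covering the matrix's samples.
#' @param sf size factors for the matrix's samples (defaults to
#'   median-of-ratios on the full matrix). Pass known library factors, e.g.
#'   the generator's true factors, to preserve global shifts that
#'   within-layer normalization would absorb.
#' @param disp optional per-gene dispersion (used when `moderate = FALSE`).
#' @param agent `"TM"` or `"TH"`.
#' @param timepoint timepoint in hours.
#' @param cfg an [analysis_config()].
#' @param moderate moderate the variance estimates (see Details).
#' @return data frame of class `contrast_result` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `p`, `padj`, `df`, `n_treated`,
#'   `n_control`; attributes `excluded` (all-zero genes), `agent`,
#'   `timepoint_h`, `layer`.
#' @export
nb_wald_contrast <- function(m, sheet, sf = NULL, disp = NULL,
                             agent, timepoint, cfg = analysis_config(),
                             moderate = TRUE) {
  stopifnot(inherits(m, "count_matrix"), inherits(sheet, "sample_sheet"))
  agent <- match.arg(agent, c("TM", "TH"))
  ids <- colnames(m$counts)
  sub <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  if (anyNA(sub$sample_id)) stop("sample sheet does not cover all samples")
  if (any(sub$layer != m$layer)) stop("sheet layer disagrees with the matrix")
  t_idx <- which(sub$agent == agent & sub$timepoint_h == timepoint)
  c_idx <- which(sub$agent == "control" & sub$timepoint_h == timepoint)
  if (length(t_idx) < 2L || length(c_idx) < 2L)
    stop(sprintf("contrast %s vs control at %g h needs >= 2 samples per group",
                 agent, timepoint))
  if (is.null(sf)) sf <- estimate_size_factors(m)
  if (is.null(names(sf))) names(sf) <- ids
  norm <- sweep(m$counts, 2, sf[ids], "/")

  keep <- rowSums(m$counts[, c(t_idx, c_idx), drop = FALSE]) > 0
  excluded <- rownames(norm)[!keep]
  norm <- norm[keep, , drop = FALSE]

  mt <- group_moments(norm, t_idx)
  mc <- group_moments(norm, c_idx)
  n_t <- mt$n
  n_c <- mc$n
  df_res <- n_t + n_c - 2L
  pc <- cfg$pseudocount
  zero <- mt$mean == 0 | mc$mean == 0
  log2fc <- ifelse(zero,
                   log2((mt$mean + pc) / (mc$mean + pc)),
                   log2(mt$mean / mc$mean))
  mbar <- (mt$mean * n_t + mc$mean * n_c) / (n_t + n_c)
  s2 <- (mt$var * (n_t - 1L) + mc$var * (n_c - 1L)) / df_res
  ln2sq <- log(2)^2

  if (moderate) {
    phi_hat <- pmax(s2 / pmax(mbar, pc)^2, 0)
    sq <- limma::squeezeVar(phi_hat, df = df_res)
    alpha <- pmax(sq$var.post - 1 / pmax(mbar, pc), cfg$dispersion_floor)
    df_total <- df_res + sq$df.prior
    if (!is.finite(df_total)) df_total <- Inf
  } else {
    if (is.null(disp)) {
      alpha <- ifelse(mbar > 0, pmax((s2 - mbar) / mbar^2,
                                     cfg$dispersion_floor),
                      cfg$dispersion_floor)
    } else {
      alpha <- unname(disp[rownames(norm)])
      if (anyNA(alpha)) stop("disp does not cover all tested genes")
    }
    df_total <- Inf
  }
  gvar <- function(gm, n) (1 / pmax(gm, pc) + alpha) / (n * ln2sq)
  se <- sqrt(gvar(mt$mean, n_t) + gvar(mc$mean, n_c))
  stat <- log2fc / se
  p <- if (is.finite(df_total)) 2 * stats::pt(-abs(stat), df = df_total)
       else 2 * stats::pnorm(-abs(stat))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(gene_id = rownames(norm),
                    base_mean = rowMeans(norm[, c(t_idx, c_idx),
                                              drop = FALSE]),
                    log2fc = log2fc, se = se, stat = stat, p = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    df = if (is.finite(df_total)) rep(df_total, length(p))
                         else rep(Inf, length(p)),
                    n_treated = n_t, n_control = n_c,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("contrast_result", "data.frame"),
            excluded = excluded, agent = agent, timepoint_h = timepoint,
            layer = m$layer)
}

quantile_gate <- function(log2fc, p_gate, cfg) {
  if (length(log2fc) < 20L)
    stop("quantile gates need >= 20 tested genes")
  direction <- rep("ns", length(log2fc))
  if (diff(range(log2fc)) < 1e-12) {
    warning("degenerate log2 fold-change distribution; no calls made")
    return(list(direction = direction,
                q_low = unname(stats::quantile(log2fc, cfg$q_low, type = 7)),
                q_high = unname(stats::quantile(log2fc, cfg$q_high, type = 7))))
  }
  qs <- stats::quantile(log2fc, c(cfg$q_low, cfg$q_high), type = 7,
                        names = FALSE)
  direction[log2fc >= qs[2] & p_gate] <- "up"
  direction[log2fc <= qs[1] & p_gate] <- "down"
  list(direction = direction, q_low = qs[1], q_high = qs[2])
}

#' Call regulated genes with the dual quantile + p-value gate
#'
#' A gene is called up if its log2 fold-change is at or above the type-7
#' `q_high` quantile of all tested genes of the contrast AND its p-value
#' (BH-adjusted when `cfg$use_fdr`) is below `p_max`; down symmetrically at
#' the `q_low` quantile; otherwise ns.
#'
#' @param r a `contrast_result` (or `loading_result`).
#' @param cfg an [analysis_config()].
#' @return data frame of class `layer_call` with columns `gene_id`, `layer`,
#'   `agent`, `timepoint_h`, `direction`; attribute `thresholds`.
#' @export
call_regulated <- function(r, cfg = analysis_config()) {
  fc_col <- if ("rls_log2_change" %in% names(r)) "rls_log2_change" else "log2fc"
  pvec <- if (cfg$use_fdr) r$padj else r$p
  g <- quantile_gate(r[[fc_col]], pvec < cfg$p_max, cfg)
  layer <- attr(r, "layer")
  res <- data.frame(gene_id = r$gene_id,
                    layer = if (is.null(layer)) NA_character_ else layer,
                    agent = attr(r, "agent"),
                    timepoint_h = attr(r, "timepoint_h"),
                    direction = g$direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("layer_call", "data.frame"),
            thresholds = list(q_low = g$q_low, q_high = g$q_high,
                              p_max = cfg$p_max, use_fdr = cfg$use_fdr))
}
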