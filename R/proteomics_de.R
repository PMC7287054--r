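# Protein-level differential abundance: two-sided equal-variance t-test on
# log2 intensities plus the median +/- k*SD regulation cutoff.

#' Protein differential abundance contrast
#'
#' Intensities are log2-transformed; the log2 fold-change is the difference
#' of group means of log2 intensities, tested with a two-sided equal-variance
#' (pooled) Student t-test. Missing values are excluded pairwise, never
#' imputed: a protein needs at least `min_present` present values in each
#' group to be tested, and proteins with zero variance in both groups are
#' flagged untestable.
#'
#' @param m an `intensity_matrix`.
#' @param sheet a `sample_sheet` covering the matrix's samples.
#' @param agent `"TM"` or `"TH"`.
#' @param timepoint timepoint in hours.
#' @param min_present minimum present intensities per group.
#' @param exclude optional gene ids to drop before testing (e.g. proteins
#'   failing an upstream unique-peptide identification filter).
#' @return data frame of class `contrast_result` with columns `gene_id`,
#'   `base_mean` (mean log2 intensity), `log2fc`, `se`, `stat`, `p`, `padj`,
#'   `df`, `n_treated`, `n_control`; attributes `excluded` (presence filter),
#'   `untestable` (zero variance), `agent`, `timepoint_h`, `layer`.
#' @export
protein_contrast <- function(m, sheet, agent, timepoint, min_present = 2L,
                             exclude = character()) {
  stopifnot(inherits(m, "intensity_matrix"), inherits(sheet, "sample_sheet"))
  agent <- match.arg(agent, c("TM", "TH"))
  ids <- colnames(m$intensities)
  sub <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  if (anyNA(sub$sample_id)) stop("sample sheet does not cover all samples")
  t_idx <- which(sub$agent == agent & sub$timepoint_h == timepoint)
  c_idx <- which(sub$agent == "control" & sub$timepoint_h == timepoint)
  if (length(t_idx) < 2L || length(c_idx) < 2L)
    stop(sprintf("contrast %s vs control at %g h needs >= 2 samples per group",
                 agent, timepoint))
  x <- log2(m$intensities)
  x[is.infinite(x)] <- NA  # zero intensity carries no quantitative signal
  if (length(exclude)) x <- x[!(rownames(x) %in% exclude), , drop = FALSE]

  xt <- x[, t_idx, drop = FALSE]
  xc <- x[, c_idx, drop = FALSE]
  nt <- rowSums(!is.na(xt))
  nc <- rowSums(!is.na(xc))
  testable <- nt >= min_present & nc >= min_present
  excluded_ids <- rownames(x)[!testable]
  xt <- xt[testable, , drop = FALSE]
  xc <- xc[testable, , drop = FALSE]
  nt <- nt[testable]
  nc <- nc[testable]

  mt <- rowMeans(xt, na.rm = TRUE)
  mc <- rowMeans(xc, na.rm = TRUE)
  vt <- rowSums((xt - mt)^2, na.rm = TRUE) / (nt - 1L)
  vc <- rowSums((xc - mc)^2, na.rm = TRUE) / (nc - 1L)
  df <- nt + nc - 2L
  sp2 <- (vt * (nt - 1L) + vc * (nc - 1L)) / df
  se <- sqrt(sp2 * (1 / nt + 1 / nc))
  untestable <- sp2 == 0
  log2fc <- mt - mc
  stat <- ifelse(untestable, NA_real_, log2fc / se)
  p <- 2 * stats::pt(-abs(stat), df = df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  keep <- !untestable
  res <- data.frame(gene_id = rownames(xt)[keep],
                    base_mean = ((mt + mc) / 2)[keep],
                    log2fc = log2fc[keep], se = se[keep], stat = stat[keep],
                    p = p[keep],
                    padj = stats::p.adjust(p[keep], method = "BH"),
                    df = df[keep], n_treated = nt[keep], n_control = nc[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("contrast_result", "data.frame"),
            excluded = excluded_ids,
            untestable = rownames(xt)[untestable],
            agent = agent, timepoint_h = timepoint, layer = "protein")
}

#' Call regulated proteins with the median +/- k*SD cutoff
#'
#' The regulation cutoff is the median of the log2 fold-changes of the
#' tested proteins of this contrast plus/minus `cfg$protein_sd_mult` times
#' their standard deviation; a protein is called up if its log2 fold-change
#' exceeds the upper cutoff AND its p-value is below `p_max` (down
#' symmetrically below the lower cutoff).
#'
#' @param r a protein `contrast_result` (>= 20 tested proteins).
#' @param cfg an [analysis_config()].
#' @return list with `calls` (a `layer_call` data frame) and `cutoff`
#'   (class `proteomics_cutoff`: `median_log2fc`, `sd_log2fc`, `low`, `high`,
#'   `k`, `n_tested`).
#' @export
call_regulated_proteins <- function(r, cfg = analysis_config()) {
  stopifnot(inherits(r, "contrast_result"))
  if (nrow(r) < 20L) stop("protein cutoff needs >= 20 tested proteins")
  med <- stats::median(r$log2fc)
  sdv <- stats::sd(r$log2fc)
  k <- cfg$protein_sd_mult
  low <- med - k * sdv
  high <- med + k * sdv
  pvec <- if (cfg$use_fdr) r$padj else r$p
  direction <- rep("ns", nrow(r))
  if (sdv == 0) {
    warning("degenerate log2 fold-change SD of 0; no proteins called")
  } else {
    direction[r$log2fc > high & pvec < cfg$p_max] <- "up"
    direction[r$log2fc < low & pvec < cfg$p_max] <- "down"
  }
  calls <- structure(
    data.frame(gene_id = r$gene_id, layer = "protein",
               agent = attr(r, "agent"), timepoint_h = attr(r, "timepoint_h"),
               direction = direction, row.names = NULL,
               stringsAsFactors = FALSE),
    class = c("layer_call", "data.frame"),
    thresholds = list(low = low, high = high, p_max = cfg$p_max,
                      use_fdr = cfg$use_fdr))
  cutoff <- structure(list(median_log2fc = med, sd_log2fc = sdv,
                           low = low, high = high, k = k, n_tested = nrow(r)),
                      class = "proteomics_cutoff")
  list(calls = calls, cutoff = cutoff)
}

#' @export
print.proteomics_cutoff <- function(x, ...) {
  cat(sprintf(
    "proteomics cutoff: median %.3f +/- %.1f * SD %.3f -> [%.3f, %.3f] (%d tested)\n",
    x$median_log2fc, x$k, x$sd_log2fc, x$low, x$high, x$n_tested))
  invisible(x)
}
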