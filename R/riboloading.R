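# Ribosome loading scores: differential translation as the difference of the
# RPF and RNA contrasts of the same agent/timepoint.

#' Differential ribosome loading from paired RNA/RPF contrasts
#'
#' The ribosome loading score (RLS) of a gene is its RPF abundance
#' normalized by RNA abundance; its log2 change under treatment is therefore
#' exactly `log2fc_rpf - log2fc_rna`. Because RNA and RPF libraries come
#' from separate samples, the two layer estimates are independent and the
#' variance of the difference is the sum `se_rpf^2 + se_rna^2`. The
#' statistic `change / se` is referred to a t distribution with
#' Welch-Satterthwaite degrees of freedom combined from the two contrasts
#' (a normal tail when both are infinite-df); BH adjustment and the same
#' quantile + significance gates as [call_regulated()] give the call.
#'
#' @param rna,rpf `contrast_result`s for the same agent and timepoint
#'   (layers rna and rpf).
#' @param cfg an [analysis_config()].
#' @return data frame of class `loading_result` with columns `gene_id`,
#'   `rls_log2_change`, `se`, `stat`, `p`, `padj`, `call`; attributes
#'   `excluded` (genes present in only one layer), `agent`, `timepoint_h`,
#'   `layer = "rls"`.
#' @export
delta_rls <- function(rna, rpf, cfg = analysis_config()) {
  stopifnot(inherits(rna, "contrast_result"), inherits(rpf, "contrast_result"))
  if (!identical(attr(rna, "agent"), attr(rpf, "agent")) ||
      !identical(attr(rna, "timepoint_h"), attr(rpf, "timepoint_h")))
    stop("RNA and RPF contrasts must share agent and timepoint")
  if (identical(attr(rna, "layer"), "rpf") || identical(attr(rpf, "layer"), "rna"))
    stop("arguments look swapped: pass the RNA contrast first")
  common <- intersect(rna$gene_id, rpf$gene_id)
  excluded <- setdiff(union(rna$gene_id, rpf$gene_id), common)
  a <- rna[match(common, rna$gene_id), , drop = FALSE]
  b <- rpf[match(common, rpf$gene_id), , drop = FALSE]
  change <- b$log2fc - a$log2fc
  se <- sqrt(a$se^2 + b$se^2)
  stat <- change / se
  df_a <- if ("df" %in% names(a)) a$df else rep(Inf, nrow(a))
  df_b <- if ("df" %in% names(b)) b$df else rep(Inf, nrow(b))
  denom <- ifelse(is.finite(df_a), a$se^4 / df_a, 0) +
    ifelse(is.finite(df_b), b$se^4 / df_b, 0)
  df_ws <- ifelse(denom > 0, se^4 / denom, Inf)
  p <- ifelse(is.finite(df_ws),
              2 * stats::pt(-abs(stat), df = df_ws),
              2 * stats::pnorm(-abs(stat)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(gene_id = common, rls_log2_change = change, se = se,
                    stat = stat, p = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    df = df_ws, row.names = NULL, stringsAsFactors = FALSE)
  res <- structure(res, class = c("loading_result", "contrast_result",
                                  "data.frame"),
                   excluded = excluded, agent = attr(rna, "agent"),
                   timepoint_h = attr(rna, "timepoint_h"), layer = "rls")
  calls <- call_regulated(res, cfg)
  res$call <- calls$direction
  attr(res, "thresholds") <- attr(calls, "thresholds")
  res
}

#' Global translational shift summary
#'
#' Summarizes a set of loading results by the median log2 RLS change and the
#' fraction of genes with a negative change; under a global translational
#' downshift the median recovers the log2 of the downshift factor when
#' library scaling is known (see the methods vignette on normalization).
#'
#' @param results a `loading_result` (>= 100 genes).
#' @return list with `median_rls_log2_change`, `fraction_negative`, `n`.
#' @export
global_loading_shift <- function(results) {
  stopifnot(inherits(results, "loading_result"))
  if (nrow(results) < 100L)
    stop("global loading summary needs >= 100 genes")
  list(median_rls_log2_change = stats::median(results$rls_log2_change),
       fraction_negative = mean(results$rls_log2_change < 0),
       n = nrow(results))
}
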