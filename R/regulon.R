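# Two-treatment co-regulation filtering and the cross-layer decision tree
# defining regulon membership.

REGULON_STATUSES <- c("member_sensu_stricto", "member_translational",
                      "excluded_rna_only", "excluded_turnover",
                      "not_regulated")

#' Genes co-regulated under both treatments
#'
#' Returns the genes called in the given direction under BOTH agents for the
#' same layer and timepoint. Genes regulated in only one treatment, or
#' inversely regulated between the two, are dropped. Symmetric in its two
#' arguments.
#'
#' @param tm,th `layer_call` data frames for the two agents (same layer and
#'   timepoint).
#' @param direction `"up"` or `"down"`.
#' @return sorted character vector of gene ids.
#' @export
coregulated <- function(tm, th, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(tm, "layer_call"), inherits(th, "layer_call"))
  for (col in c("layer", "timepoint_h")) {
    if (!identical(sort(unique(tm[[col]])), sort(unique(th[[col]]))))
      stop("call sets disagree on ", col)
  }
  a <- tm$gene_id[tm$direction == direction]
  b <- th$gene_id[th$direction == direction]
  sort(intersect(a, b))
}

#' Classify one gene from its co-regulation evidence
#'
#' Applies the cross-layer decision tree for the up direction: RNA induction
#' corroborated by increased synthesis (RPF) or protein abundance makes a
#' regulon member sensu stricto; RPF induction without RNA induction is a
#' translationally induced member (excluded when
#' `cfg$strict_sensu_stricto`); RNA induction alone is excluded (no evidence
#' of increased synthesis); protein induction alone most likely reflects
#' altered turnover and is excluded; otherwise the gene is not regulated.
#' Protein evidence corroborates RNA evidence from any earlier-or-equal
#' timepoint.
#'
#' @param evidence data frame with columns `layer`, `timepoint_h`,
#'   `direction` listing the co-regulated (both-agents) calls of one gene.
#' @param cfg an [analysis_config()].
#' @return list with `status`, `evidence` (semicolon-joined codes) and
#'   `timepoints_supporting`.
#' @export
classify_gene <- function(evidence, cfg = analysis_config()) {
  if (nrow(evidence)) {
    key <- paste(evidence$layer, evidence$timepoint_h)
    ndir <- tapply(evidence$direction, key, function(d) length(unique(d)))
    if (any(ndir > 1L))
      stop("conflicting duplicate evidence rows for ",
           names(ndir)[ndir > 1L][1L])
    evidence <- evidence[!duplicated(key), , drop = FALSE]
  }
  up <- evidence[evidence$direction == "up", , drop = FALSE]
  rna_tp <- up$timepoint_h[up$layer == "rna"]
  rpf_up <- any(up$layer == "rpf")
  prot_tp <- up$timepoint_h[up$layer == "protein"]
  rna_up <- length(rna_tp) > 0L
  prot_up <- length(prot_tp) > 0L
  prot_corroborates <- rna_up && prot_up &&
    any(outer(rna_tp, prot_tp, "<="))
  status <-
    if (rna_up && (rpf_up || prot_corroborates)) "member_sensu_stricto"
    else if (rpf_up && !rna_up && !cfg$strict_sensu_stricto) "member_translational"
    else if (rna_up) "excluded_rna_only"
    else if (prot_up && !rpf_up) "excluded_turnover"
    else "not_regulated"
  codes <- if (nrow(up))
    paste(sprintf("%s@%gh:%s", up$layer, up$timepoint_h, up$direction),
          collapse = ";") else ""
  list(status = status, evidence = codes,
       timepoints_supporting = sort(unique(up$timepoint_h)))
}

#' Build the regulon table from per-layer call sets
#'
#' For every layer and timepoint, genes co-induced under both agents are
#' collected ([coregulated()]); the per-gene evidence is aggregated across
#' timepoints and classified ([classify_gene()]), with membership granted if
#' the decision tree fires at any matched timepoint. Down co-regulation is
#' reported separately (a RIDD-adjacent readout) and never feeds membership.
#'
#' @param calls list of `layer_call` data frames covering both agents for at
#'   least one layer/timepoint each.
#' @param cfg an [analysis_config()].
#' @return list of class `regulon_result` with `records` (gene_id, status,
#'   evidence, timepoints_supporting), `summary` (status counts),
#'   `coregulated_up` and `coregulated_down` (per layer/timepoint gene sets).
#' @export
build_regulon <- function(calls, cfg = analysis_config()) {
  stopifnot(is.list(calls), length(calls) > 0L)
  tab <- do.call(rbind, lapply(calls, as.data.frame))
  tab <- tab[tab$layer != "rls", , drop = FALSE]
  layers <- unique(tab$layer)
  universes <- lapply(layers, function(l) unique(tab$gene_id[tab$layer == l]))
  if (length(layers) > 1L && length(Reduce(intersect, universes)) == 0L)
    stop("no overlapping gene universe across layers")
  universe <- sort(unique(tab$gene_id))

  combos <- unique(tab[, c("layer", "timepoint_h")])
  ev_rows <- list()
  co_up <- list()
  co_down <- list()
  for (i in seq_len(nrow(combos))) {
    l <- combos$layer[i]
    tp <- combos$timepoint_h[i]
    slice <- function(agent) {
      s <- tab[tab$layer == l & tab$timepoint_h == tp & tab$agent == agent, ,
               drop = FALSE]
      structure(s, class = c("layer_call", "data.frame"))
    }
    tm <- slice("TM")
    th <- slice("TH")
    if (!nrow(tm) || !nrow(th)) next  # need both agents for co-regulation
    key <- sprintf("%s@%gh", l, tp)
    for (dir in c("up", "down")) {
      genes <- coregulated(tm, th, dir)
      if (dir == "up") co_up[[key]] <- genes else co_down[[key]] <- genes
      if (length(genes))
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          gene_id = genes, layer = l, timepoint_h = tp, direction = dir,
          stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows)
    else data.frame(gene_id = character(), layer = character(),
                    timepoint_h = numeric(), direction = character(),
                    stringsAsFactors = FALSE)

  flagged <- unique(evidence$gene_id[evidence$direction == "up"])
  records <- data.frame(gene_id = universe, status = "not_regulated",
                        evidence = "", timepoints_supporting = "",
                        stringsAsFactors = FALSE)
  idx <- match(flagged, records$gene_id)
  for (j in seq_along(flagged)) {
    ev <- evidence[evidence$gene_id == flagged[j], , drop = FALSE]
    cl <- classify_gene(ev, cfg)
    records$status[idx[j]] <- cl$status
    records$evidence[idx[j]] <- cl$evidence
    records$timepoints_supporting[idx[j]] <-
      paste(cl$timepoints_supporting, collapse = ",")
  }
  counts <- table(factor(records$status, levels = REGULON_STATUSES))
  structure(list(records = records,
                 summary = as.list(counts),
                 coregulated_up = co_up, coregulated_down = co_down),
            class = "regulon_result")
}

#' @export
print.regulon_result <- function(x, ...) {
  cat("regulon result:\n")
  for (s in names(x$summary)) cat(sprintf("  %-22s %d\n", s, x$summary[[s]]))
  invisible(x)
}
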