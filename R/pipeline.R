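# Orchestration: run every stage over a directory of TSV inputs, write all
# stage tables, the regulon, JSON summaries and a reproducibility manifest.

contrast_schema <- c("gene_id", "base_mean", "log2fc", "se", "stat", "p",
                     "padj", "df", "n_treated", "n_control", "call")
rls_schema <- c("gene_id", "rls_log2_change", "se", "stat", "p", "padj",
                "df", "call")

stage_summary <- function(stage, calls) {
  tb <- table(factor(calls$direction, levels = c("up", "down", "ns")))
  list(stage = stage, n_tested = nrow(calls),
       n_up = unname(tb[["up"]]), n_down = unname(tb[["down"]]))
}

#' Run the full multi-omics regulon pipeline over a directory of inputs
#'
#' Expects `rna.tsv`, `rpf.tsv`, `protein.tsv` and `sheet.tsv` in
#' `input_dir` (the formats written by [write_experiment()]). Per agent and
#' timepoint it computes NB Wald contrasts for RNA and RPF, ribosome loading
#' scores, protein contrasts with the median +/- k*SD cutoff, then the
#' two-treatment co-regulation filter and the regulon decision tree. All
#' stage tables are written as deterministic TSV, plus `regulon.tsv`, a JSON
#' run summary and a reproducibility manifest (config echo, input digests,
#' seed, per-stage call counts; no timestamps, so reruns are byte-identical).
#'
#' @param input_dir directory of input TSVs.
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param size_factors optional named size-factor vector covering the count
#'   samples (e.g. known library factors); defaults to per-layer
#'   median-of-ratios estimation.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(input_dir, config = analysis_config(), out_dir,
                    size_factors = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  inputs <- file.path(input_dir, c("rna.tsv", "rpf.tsv", "protein.tsv",
                                   "sheet.tsv"))
  names(inputs) <- basename(inputs)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(names(missing_in), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  open_run_log(file.path(out_dir, "run.log"))
  on.exit(open_run_log(NULL))
  log_stage("run_all", "config ", config_echo(config), " seed ", config$seed)

  sheet <- read_sample_sheet(inputs[["sheet.tsv"]])
  mats <- list(rna = read_count_matrix(inputs[["rna.tsv"]], "rna"),
               rpf = read_count_matrix(inputs[["rpf.tsv"]], "rpf"))
  protein <- read_intensity_matrix(inputs[["protein.tsv"]])
  for (l in names(mats))
    log_stage("core_io", l, " matrix ", nrow(mats[[l]]$counts), " x ",
              ncol(mats[[l]]$counts))
  log_stage("core_io", "protein matrix ", nrow(protein$intensities), " x ",
            ncol(protein$intensities))

  stage_stats <- list()
  all_calls <- list()
  contrasts <- list()

  run_stage <- function(fun, stage, ...) {
    tryCatch(fun(...), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  for (layer in c("rna", "rpf")) {
    m <- mats[[layer]]
    sub <- sheet[sheet$layer == layer, , drop = FALSE]
    sf <- if (is.null(size_factors)) estimate_size_factors(m)
          else size_factors[colnames(m$counts)]
    tps <- sort(unique(sub$timepoint_h[sub$agent != "control"]))
    for (agent in c("TM", "TH")) {
      for (tp in tps) {
        stage <- sprintf("de %s %s %gh", layer, agent, tp)
        n_t <- sum(sub$agent == agent & sub$timepoint_h == tp)
        n_c <- sum(sub$agent == "control" & sub$timepoint_h == tp)
        if (n_t < 2L || n_c < 2L) {
          log_stage("diffexpr", stage, " skipped: missing controls")
          warning(sprintf("skipping %s: fewer than 2 treated or control samples",
                          stage))
          next
        }
        res <- run_stage(nb_wald_contrast, stage, m = m, sheet = sheet,
                         sf = sf, agent = agent, timepoint = tp, cfg = config)
        calls <- run_stage(call_regulated, stage, r = res, cfg = config)
        key <- sprintf("%s_%s_%gh", layer, agent, tp)
        contrasts[[key]] <- res
        all_calls[[key]] <- calls
        out <- cbind(as.data.frame(res), call = calls$direction)
        write_table(out, file.path(out_dir, paste0("contrast_", key, ".tsv")),
                    schema = contrast_schema)
        st <- stage_summary(stage, calls)
        stage_stats[[length(stage_stats) + 1L]] <- st
        log_stage("diffexpr", stage, ": tested ", st$n_tested, ", up ",
                  st$n_up, ", down ", st$n_down)
      }
    }
  }

  rna_keys <- grep("^rna_", names(contrasts), value = TRUE)
  for (rk in rna_keys) {
    pk <- sub("^rna_", "rpf_", rk)
    if (is.null(contrasts[[pk]])) next
    stage <- sub("^rna_", "rls ", rk)
    rls <- run_stage(delta_rls, stage, rna = contrasts[[rk]],
                     rpf = contrasts[[pk]], cfg = config)
    key <- sub("^rna_", "rls_", rk)
    all_calls[[key]] <- structure(
      data.frame(gene_id = rls$gene_id, layer = "rls",
                 agent = attr(rls, "agent"),
                 timepoint_h = attr(rls, "timepoint_h"),
                 direction = rls$call, stringsAsFactors = FALSE),
      class = c("layer_call", "data.frame"))
    write_table(as.data.frame(rls),
                file.path(out_dir, paste0("contrast_", key, ".tsv")),
                schema = rls_schema)
    st <- stage_summary(stage, all_calls[[key]])
    stage_stats[[length(stage_stats) + 1L]] <- st
    log_stage("riboloading", stage, ": tested ", st$n_tested, ", up ",
              st$n_up, ", down ", st$n_down)
  }

  subp <- sheet[sheet$layer == "protein", , drop = FALSE]
  ptps <- sort(unique(subp$timepoint_h[subp$agent != "control"]))
  for (agent in c("TM", "TH")) {
    for (tp in ptps) {
      stage <- sprintf("prot %s %gh", agent, tp)
      n_t <- sum(subp$agent == agent & subp$timepoint_h == tp)
      n_c <- sum(subp$agent == "control" & subp$timepoint_h == tp)
      if (n_t < 2L || n_c < 2L) {
        log_stage("proteomics_de", stage, " skipped: missing controls")
        warning(sprintf("skipping %s: fewer than 2 treated or control samples",
                        stage))
        next
      }
      res <- run_stage(protein_contrast, stage, m = protein, sheet = sheet,
                       agent = agent, timepoint = tp)
      called <- run_stage(call_regulated_proteins, stage, r = res,
                          cfg = config)
      key <- sprintf("protein_%s_%gh", agent, tp)
      all_calls[[key]] <- called$calls
      out <- cbind(as.data.frame(res), call = called$calls$direction)
      write_table(out, file.path(out_dir, paste0("contrast_", key, ".tsv")),
                  schema = contrast_schema)
      st <- stage_summary(stage, called$calls)
      st$cutoff <- called$cutoff[c("median_log2fc", "sd_log2fc", "low", "high")]
      stage_stats[[length(stage_stats) + 1L]] <- st
      log_stage("proteomics_de", stage, ": tested ", st$n_tested, ", up ",
                st$n_up, ", down ", st$n_down,
                sprintf(", cutoff [%.4g, %.4g]", called$cutoff$low,
                        called$cutoff$high))
    }
  }

  reg <- run_stage(build_regulon, "regulon", calls = all_calls, cfg = config)
  write_table(reg$records, file.path(out_dir, "regulon.tsv"),
              schema = c("gene_id", "status", "evidence",
                         "timepoints_supporting"))
  log_stage("regulon", paste(names(reg$summary), unlist(reg$summary),
                             sep = "=", collapse = " "))

  summary_json <- list(stages = stage_stats, regulon = reg$summary)
  jsonlite::write_json(summary_json, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    artifact = "stressregulon",
    version = as.character(utils::packageVersion("stressregulon")),
    seed = config$seed,
    config = unclass(config),
    inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                             names(inputs)),
    stages = lapply(stage_stats, function(s)
      s[c("stage", "n_tested", "n_up", "n_down")]),
    regulon = reg$summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
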