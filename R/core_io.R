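#' @keywords internal
"_PACKAGE"

AGENTS <- c("TM", "TH", "control")
LAYERS <- c("rna", "rpf", "protein")
TIMEPOINTS <- c(2, 6, 16, 24)

#' Analysis configuration
#'
#' Bundles the thresholds used across the pipeline: the significance gate,
#' the fold-change quantile gates used for regulated-gene calling, the
#' proteomics median +/- k*SD cutoff multiplier, the pseudocount used when a
#' group mean is zero, and the dispersion floor.
#'
#' @param p_max significance threshold on p (or BH-adjusted p when
#'   `use_fdr = TRUE`); the regulated-gene gate is `p < p_max`.
#' @param q_low,q_high quantile gates on the log2 fold-change distribution of
#'   tested genes (down / up, type-7 quantiles, inclusive comparisons).
#' @param use_fdr gate on BH-adjusted p instead of raw p.
#' @param protein_sd_mult multiplier k of the proteomics median +/- k*SD cutoff.
#' @param pseudocount added inside the log-ratio when a group mean is zero.
#' @param dispersion_floor lower bound for dispersion estimates.
#' @param strict_sensu_stricto if `TRUE`, genes with translation-only evidence
#'   (RPF up without RNA up) are not admitted as regulon members.
#' @param seed integer seed echoed into run manifests.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(p_max = 0.05, q_low = 0.05, q_high = 0.95,
                            use_fdr = FALSE, protein_sd_mult = 2.0,
                            pseudocount = 0.5, dispersion_floor = 1e-8,
                            strict_sensu_stricto = FALSE, seed = 1L) {
  stopifnot(is.numeric(p_max), length(p_max) == 1L)
  if (!(p_max > 0 && p_max < 1)) stop("p_max must be in (0, 1)")
  if (!(q_low > 0 && q_low < q_high && q_high < 1))
    stop("quantile gates must satisfy 0 < q_low < q_high < 1")
  if (!(protein_sd_mult > 0)) stop("protein_sd_mult must be > 0")
  if (!(pseudocount > 0)) stop("pseudocount must be > 0")
  if (!(dispersion_floor > 0)) stop("dispersion_floor must be > 0")
  structure(list(p_max = p_max, q_low = q_low, q_high = q_high,
                 use_fdr = isTRUE(use_fdr),
                 protein_sd_mult = protein_sd_mult,
                 pseudocount = pseudocount,
                 dispersion_floor = dispersion_floor,
                 strict_sensu_stricto = isTRUE(strict_sensu_stricto),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys take the [analysis_config()]
#' defaults.
#' @param path path to a JSON object with `analysis_config` keys.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, raw)
}

new_count_matrix <- function(counts, layer) {
  layer <- match.arg(layer, c("rna", "rpf"))
  if (!is.matrix(counts)) stop("counts must be a matrix")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (ncol(counts) < 2L) stop("a count matrix needs at least 2 samples")
  if (anyNA(counts)) stop("counts must not contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("negative or non-integer count for gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, layer = layer), class = "count_matrix")
}

new_intensity_matrix <- function(intensities) {
  if (!is.matrix(intensities)) stop("intensities must be a matrix")
  gene_ids <- rownames(intensities)
  sample_ids <- colnames(intensities)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("intensities must have gene row names and sample column names")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (ncol(intensities) < 2L) stop("an intensity matrix needs at least 2 samples")
  neg <- which(!is.na(intensities) & intensities < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative intensity for gene '%s', sample '%s'",
                 gene_ids[neg[1L, 1L]], sample_ids[neg[1L, 2L]]))
  }
  structure(list(intensities = intensities, layer = "protein"),
            class = "intensity_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d genes x %d samples\n",
              x$layer, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix [protein]: %d genes x %d samples (%.1f%% missing)\n",
              nrow(x$intensities), ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Read a gene x sample count matrix from TSV
#'
#' The first column holds opaque gene identifiers; remaining columns are
#' non-negative integer counts, one per sample. Column order is preserved.
#'
#' @param path TSV file with a header row.
#' @param layer `"rna"` or `"rpf"`.
#' @return a validated `count_matrix`.
#' @export
read_count_matrix <- function(path, layer) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("count matrix needs a gene column and >= 2 samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count columns must be numeric")
  rownames(m) <- as.character(df[[1L]])
  new_count_matrix(m, layer)
}

#' Read a gene x sample protein intensity matrix from TSV
#'
#' Empty fields encode missing values (not-quantified proteins), which are
#' distinct from zero abundance.
#'
#' @inheritParams read_count_matrix
#' @return a validated `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("intensity matrix needs a gene column and >= 2 samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("intensity columns must be numeric")
  rownames(m) <- as.character(df[[1L]])
  new_intensity_matrix(m)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "agent", "timepoint_h", "replicate", "layer")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$agent <- as.character(df$agent)
  df$layer <- as.character(df$layer)
  df$timepoint_h <- as.numeric(df$timepoint_h)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_agent <- setdiff(unique(df$agent), AGENTS)
  if (length(bad_agent))
    stop("unknown agent(s): ", paste(bad_agent, collapse = ", "))
  bad_layer <- setdiff(unique(df$layer), LAYERS)
  if (length(bad_layer))
    stop("unknown layer(s): ", paste(bad_layer, collapse = ", "))
  bad_tp <- setdiff(unique(df$timepoint_h), TIMEPOINTS)
  if (length(bad_tp))
    stop("unknown timepoint_h value(s): ", paste(bad_tp, collapse = ", "))
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  key <- paste(df$agent, df$timepoint_h, df$replicate, df$layer)
  if (anyDuplicated(key))
    stop("duplicate design key (agent, timepoint_h, replicate, layer): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  # every treated group must be contrastable against >=2 time-matched controls
  treated <- df[df$agent != "control", , drop = FALSE]
  if (nrow(treated)) {
    grp <- unique(treated[, c("agent", "timepoint_h", "layer")])
    for (i in seq_len(nrow(grp))) {
      nt <- sum(treated$agent == grp$agent[i] &
                  treated$timepoint_h == grp$timepoint_h[i] &
                  treated$layer == grp$layer[i])
      nc <- sum(df$agent == "control" &
                  df$timepoint_h == grp$timepoint_h[i] &
                  df$layer == grp$layer[i])
      if (nt < 2L || nc < 2L)
        stop(sprintf(
          "contrast %s vs control at %g h (%s) needs >= 2 treated and >= 2 control samples (found %d/%d)",
          grp$agent[i], grp$timepoint_h[i], grp$layer[i], nt, nc))
    }
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read and validate a sample sheet
#'
#' Columns: `sample_id`, `agent` (TM/TH/control), `timepoint_h` (2/6/16/24),
#' `replicate`, `layer` (rna/rpf/protein). The design key
#' (agent, timepoint_h, replicate, layer) must be unique and every treated
#' group must have at least two treated and two time-matched control samples.
#'
#' @param path TSV file with a header row.
#' @return a `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

format_table_cols <- function(df, digits = 6L) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.double(x)) {
      out <- formatC(x, digits = digits, format = "g")
      out[is.na(x)] <- ""
      df[[nm]] <- out
    } else if (is.numeric(x)) {
      out <- as.character(x)
      out[is.na(x)] <- ""
      df[[nm]] <- out
    } else {
      x <- as.character(x)
      x[is.na(x)] <- ""
      df[[nm]] <- x
    }
  }
  df
}

#' Write a record table as deterministic TSV
#'
#' Records are written with a header, floats rendered with a fixed number of
#' significant digits, missing values as empty fields, and rows ordered
#' lexicographically by `gene_id` when that column is present, so repeated
#' writes of the same records are byte-identical.
#'
#' @param records a data frame.
#' @param path output file.
#' @param schema character vector of required column names, in order.
#' @param digits significant digits for floating-point columns.
#' @return invisibly, the path.
#' @export
write_table <- function(records, path, schema = names(records), digits = 6L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!identical(names(records), as.character(schema))) {
    if (!setequal(names(records), schema))
      stop("records do not match schema; expected columns: ",
           paste(schema, collapse = ", "))
    records <- records[, as.character(schema), drop = FALSE]
  }
  if ("gene_id" %in% names(records) && nrow(records)) {
    records <- records[order(records$gene_id, method = "radix"), , drop = FALSE]
  }
  records <- format_table_cols(records, digits = digits)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(schema, collapse = "\t"), con)
  if (nrow(records)) {
    lines <- do.call(paste, c(unname(as.list(records)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a count matrix as TSV
#' @param m a `count_matrix`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(gene_id = rownames(m$counts),
                   m$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seqatail(df)) df[[j]] <- as.integer(round(df[[j]]))
  write_table(df, path, schema = names(df))
}

seqatail <- function(df) setdiff(seq_along(df), 1L)

#' Write a protein intensity matrix as TSV (missing values as empty fields)
#' @param m an `intensity_matrix`.
#' @param path output file.
#' @param digits significant digits for intensities.
#' @return invisibly, the path.
#' @export
write_intensity_matrix <- function(m, path, digits = 8L) {
  stopifnot(inherits(m, "intensity_matrix"))
  df <- data.frame(gene_id = rownames(m$intensities),
                   m$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path, schema = names(df), digits = digits)
}

#' Write a sample sheet as TSV
#' @param sheet a `sample_sheet`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  df <- as.data.frame(sheet)
  df <- df[order(df$layer, df$agent, df$timepoint_h, df$replicate,
                 method = "radix"), ]
  write_table(df, path,
              schema = c("sample_id", "agent", "timepoint_h", "replicate",
                         "layer"))
}

# Plain-text stage logging: every stage appends config, shapes, seed and
# call counts when a log path has been opened with open_run_log().
the_log <- new.env(parent = emptyenv())

#' Open (or disable) the plain-text run log
#' @param path log file path, or `NULL` to disable logging.
#' @return invisibly, the previous path.
#' @export
open_run_log <- function(path) {
  old <- the_log$path
  the_log$path <- path
  if (!is.null(path) && !file.exists(path)) file.create(path)
  invisible(old)
}

log_stage <- function(stage, ...) {
  if (is.null(the_log$path)) return(invisible(NULL))
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  cat(msg, "\n", sep = "", file = the_log$path, append = TRUE)
  invisible(NULL)
}

config_echo <- function(cfg) {
  paste(vapply(names(unclass(cfg)), function(k)
    paste0(k, "=", format(cfg[[k]])), character(1)), collapse = " ")
}
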