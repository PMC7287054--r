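test_that("co-regulation keeps shared-direction genes only", {
  tm <- make_calls(c("a", "b", "c", "d"), c("up", "up", "down", "ns"),
                   "rna", "TM")
  th <- make_calls(c("a", "b", "c", "d"), c("up", "down", "down", "up"),
                   "rna", "TH")
  expect_identical(coregulated(tm, th, "up"), "a")        # up in both
  expect_identical(coregulated(tm, th, "down"), "c")
  # inversely regulated (b) and single-treatment (d) genes are dropped
  expect_false("b" %in% coregulated(tm, th, "up"))
  expect_false("d" %in% coregulated(tm, th, "up"))
  # symmetric, and a subset of each argument's calls
  expect_identical(coregulated(tm, th, "up"), coregulated(th, tm, "up"))
  expect_true(all(coregulated(tm, th, "up") %in%
                    tm$gene_id[tm$direction == "up"]))

  th2 <- make_calls("a", "up", "rna", "TH", tp = 2)
  expect_error(coregulated(tm, th2, "up"), "timepoint")
})

test_that("the decision tree classifies each evidence pattern", {
  ev <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(layer = r[[1]], timepoint_h = as.numeric(r[[2]]),
                 direction = r[[3]], stringsAsFactors = FALSE)))
  }
  cfg <- analysis_config()
  # RNA induction corroborated by synthesis evidence
  expect_identical(
    classify_gene(ev(list("rna", 6, "up"), list("rpf", 6, "up")), cfg)$status,
    "member_sensu_stricto")
  # protein abundance at a later timepoint corroborates earlier RNA
  expect_identical(
    classify_gene(ev(list("rna", 2, "up"), list("protein", 16, "up")),
                  cfg)$status,
    "member_sensu_stricto")
  expect_identical(classify_gene(ev(list("rna", 6, "up")), cfg)$status,
                   "excluded_rna_only")
  expect_identical(classify_gene(ev(list("protein", 24, "up")), cfg)$status,
                   "excluded_turnover")
  expect_identical(classify_gene(ev(list("rpf", 6, "up")), cfg)$status,
                   "member_translational")
  strict <- analysis_config(strict_sensu_stricto = TRUE)
  expect_identical(classify_gene(ev(list("rpf", 6, "up")), strict)$status,
                   "not_regulated")
  expect_identical(
    classify_gene(ev(list("rna", 2, "up"))[0, ], cfg)$status,
    "not_regulated")
  cl <- classify_gene(ev(list("rna", 2, "up"), list("rpf", 6, "up")), cfg)
  expect_identical(cl$evidence, "rna@2h:up;rpf@6h:up")
  expect_identical(cl$timepoints_supporting, c(2, 6))
  expect_error(
    classify_gene(ev(list("rna", 2, "up"), list("rna", 2, "down")), cfg),
    "conflicting")
})

test_that("build_regulon aggregates evidence across layers and timepoints", {
  genes <- c("core1", "core2", "rnaonly", "turnover", "transl", "none")
  mk <- function(layer, agent, tp, up) {
    make_calls(genes, ifelse(genes %in% up, "up", "ns"), layer, agent, tp)
  }
  calls <- list(
    mk("rna", "TM", 6, c("core1", "core2", "rnaonly")),
    mk("rna", "TH", 6, c("core1", "core2", "rnaonly")),
    mk("rpf", "TM", 6, c("core1", "transl")),
    mk("rpf", "TH", 6, c("core1", "transl")),
    mk("protein", "TM", 24, c("core2", "turnover")),
    mk("protein", "TH", 24, c("core2", "turnover")))
  reg <- build_regulon(calls, analysis_config())
  status <- setNames(reg$records$status, reg$records$gene_id)
  expect_identical(unname(status["core1"]), "member_sensu_stricto")
  expect_identical(unname(status["core2"]), "member_sensu_stricto")
  expect_identical(unname(status["rnaonly"]), "excluded_rna_only")
  expect_identical(unname(status["turnover"]), "excluded_turnover")
  expect_identical(unname(status["transl"]), "member_translational")
  expect_identical(unname(status["none"]), "not_regulated")
  expect_identical(reg$summary$member_sensu_stricto, 2L)
  expect_identical(reg$coregulated_up[["rna@6h"]], c("core1", "core2",
                                                     "rnaonly"))

  none <- list(mk("rna", "TM", 6, character()), mk("rna", "TH", 6, character()))
  reg0 <- build_regulon(none, analysis_config())
  expect_true(all(reg0$records$status == "not_regulated"))

  disjoint <- list(mk("rna", "TM", 6, character()),
                   make_calls("other", "ns", "protein", "TM", 24))
  expect_error(build_regulon(disjoint, analysis_config()), "overlapping")
})

test_that("down co-regulation is reported but never grants membership", {
  genes <- paste0("g", 1:5)
  dn <- function(agent, layer) make_calls(genes, c("down", "down", "ns", "ns",
                                                   "ns"), layer, agent, 6)
  reg <- build_regulon(list(dn("TM", "rna"), dn("TH", "rna"),
                            dn("TM", "rpf"), dn("TH", "rpf")),
                       analysis_config())
  expect_identical(reg$coregulated_down[["rna@6h"]], c("g1", "g2"))
  expect_true(all(reg$records$status == "not_regulated"))
})

test_that("loosening the gates never shrinks the member set", {
  ex <- simulate_experiment(small_cfg(n_genes = 800L), seed = 29L)
  members <- function(cfg) {
    calls <- list()
    for (layer in c("rna", "rpf")) {
      for (agent in c("TM", "TH")) {
        r <- nb_wald_contrast(ex[[layer]], ex$sheet, agent = agent,
                              timepoint = 6, cfg = cfg)
        calls[[paste(layer, agent)]] <- call_regulated(r, cfg)
      }
    }
    reg <- build_regulon(calls, cfg)
    reg$records$gene_id[grepl("^member", reg$records$status)]
  }
  tight <- members(analysis_config())
  loose <- members(analysis_config(p_max = 0.2, q_low = 0.2, q_high = 0.8))
  expect_true(all(tight %in% loose))
  expect_gt(length(tight), 0L)
})
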