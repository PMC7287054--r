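test_that("identical config and seed give byte-identical experiments", {
  a <- simulate_experiment(small_cfg(), seed = 7L)
  b <- simulate_experiment(small_cfg(), seed = 7L)
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$rpf$counts, b$rpf$counts)
  expect_identical(a$protein$intensities, b$protein$intensities)
  expect_identical(a$tracer, b$tracer)
  expect_identical(a$qpcr, b$qpcr)
  c <- simulate_experiment(small_cfg(), seed = 8L)
  expect_false(identical(a$rna$counts, c$rna$counts))
  # layers use independent streams: the RNA stream is not reused for RPF
  expect_false(identical(unname(a$rna$counts[, 1]), unname(a$rpf$counts[, 1])))
})

test_that("negative-binomial sampler matches configured moments", {
  n_reps <- 1000L
  mu <- matrix(rep(c(5, 20, 50, 100, 250, 500, 1000, 2000, 40, 8),
                   times = n_reps), 10L, n_reps)
  rownames(mu) <- sprintf("g%02d", 1:10)
  colnames(mu) <- sprintf("r%04d", seq_len(n_reps))
  alpha <- rep(0.1, 10)
  set.seed(99)
  x <- sim_nb_counts(mu, alpha)
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  se_mean <- sqrt((mu[, 1] + alpha * mu[, 1]^2) / n_reps)
  expect_true(all(abs(m - mu[, 1]) < 4 * se_mean))
  expect_equal(v, mu[, 1] + alpha * mu[, 1]^2, tolerance = 0.3)
  expect_error(sim_nb_counts(mu, rep(0, 10)), "positive")
})

test_that("ground truth respects class constraints", {
  ex <- simulate_experiment(small_cfg(), seed = 3L)
  tr <- ex$truth
  nulls <- tr[tr$klass == "null", ]
  expect_true(all(nulls[, c("rna_TM", "rna_TH", "rls_TM", "rls_TH",
                            "protein_TM", "protein_TH")] == 0))
  core <- tr[tr$klass == "regulon_core", ]
  expect_true(all(sign(core$rna_TM) == sign(core$rna_TH)))
  expect_true(all(tr$rls_TM[tr$klass == "translational_only"] > 0))
  expect_true(all(tr$rna_TM[tr$klass == "ridd_like_down"] < 0))
  expect_setequal(unique(tr$klass),
                  c("regulon_core", "tm_specific", "th_specific",
                    "translational_only", "turnover_only", "ridd_like_down",
                    "null"))
})

test_that("a dominant planted effect yields the largest estimated log2fc", {
  cfg <- sim_config(n_genes = 300L, n_regulon_core = 1L, n_tm_specific = 0L,
                    n_th_specific = 0L, n_translational_only = 0L,
                    n_turnover_only = 0L, n_ridd_like_down = 0L,
                    effect_mean = 5, effect_sd = 1e-9,
                    baseline_meanlog = log(2000), baseline_sdlog = 0.2,
                    alpha_median = 1e-4, alpha_sdlog = 1e-9)
  ex <- simulate_experiment(cfg, seed = 2L)
  r <- nb_wald_contrast(ex$rna, ex$sheet, agent = "TM", timepoint = 6)
  expect_identical(r$gene_id[which.max(r$log2fc)], "g00001")
  expect_gt(max(r$log2fc), 4)
})

test_that("generator rejects invalid parameters", {
  expect_error(sim_config(n_genes = 50L), ">= 100")
  expect_error(sim_config(reps = c(TM = 1L, TH = 3L, control = 3L)), ">= 2")
  expect_error(sim_config(alpha_median = -1), "positive")
  expect_error(sim_config(mito_share_treated = 1.5), "\\[0, 1\\]")
  expect_error(simulate_tracer(-0.1), "\\[0, 1\\]")
})

test_that("tracer profiles encode the planted mitochondrial share", {
  pure <- simulate_tracer(1, noise_cv = 0, n_reps = 1, seed = 1)
  d <- pure[pure$analyte == "dTTP", ]
  expect_identical(d$intensity[d$mass_shift == 3], 0)
  even <- simulate_tracer(0.5, noise_cv = 0, n_reps = 1, seed = 1)
  d <- even[even$analyte == "dTTP", ]
  expect_equal(d$intensity[d$mass_shift == 2], d$intensity[d$mass_shift == 3])

  # recovery within 3 SE, with the SE propagated from the stated CV:
  # se(f) = f(1-f) * sqrt(2) * cv / sqrt(n)
  tr <- simulate_tracer(0.7, noise_cv = 0.05, n_reps = 3, seed = 42)
  d <- tr[tr$analyte == "dTTP", ]
  fr <- vapply(split(d, d$replicate), function(rep)
    mitochondrial_dttp_fraction(rep$intensity, rep$mass_shift), numeric(1))
  se <- 0.7 * 0.3 * sqrt(2) * 0.05 / sqrt(3)
  expect_lt(abs(mean(fr) - 0.7), 3 * se)
})

test_that("assay simulator reproduces the planted qPCR arithmetic", {
  cfg <- sim_config(qpcr_true_ratio = 8, qpcr_noise_sd = 0)
  a <- simulate_assays(cfg, seed = 1L)
  q <- a$qpcr
  ct <- function(gene, cond) mean(q$ct[q$gene == gene & q$condition == cond])
  # 8-fold input with E = 2 advances the target by exactly 3 cycles
  expect_equal(ct("target", "control") - ct("target", "TM"), 3)
  expect_equal(ct("reference", "control") - ct("reference", "TM"), 0)
  ratio <- pfaffl_ratio(ct("target", "control"), ct("target", "TM"),
                        ct("reference", "control"), ct("reference", "TM"))
  expect_equal(ratio, 8)

  flat <- simulate_assays(sim_config(qpcr_true_ratio = 1, qpcr_noise_sd = 0),
                          seed = 1L)
  qf <- flat$qpcr
  ctf <- function(gene, cond) mean(qf$ct[qf$gene == gene & qf$condition == cond])
  expect_equal(pfaffl_ratio(ctf("target", "control"), ctf("target", "TM"),
                            ctf("reference", "control"), ctf("reference", "TM")),
               1)
  expect_error(simulate_assays(sim_config(qpcr_efficiency = 2.5), seed = 1),
               "efficiency")
})

test_that("noiseless dose-response data refit to the planted IC50", {
  cfg <- sim_config(viability_noise_sd = 0, ic50_control = 1)
  a <- simulate_assays(cfg, seed = 1L)
  d <- a$dose_response[a$dose_response$condition == "control" &
                         a$dose_response$replicate == 1, ]
  fit <- fit_4pl_ic50(d$dose, d$viability_percent)
  expect_false(fit$no_fit)
  expect_lt(abs(fit$ic50 - 1) / 1, 0.01)
})

test_that("the experiment bundle writes a consistent TSV directory", {
  ex <- simulate_experiment(small_cfg(), seed = 12L)
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_true(all(file.exists(file.path(dir,
    c("rna.tsv", "rpf.tsv", "protein.tsv", "sheet.tsv", "truth.tsv",
      "tracer.tsv", "pools.tsv", "nadp.tsv", "qpcr.tsv",
      "dose_response.tsv", "true_size_factors.tsv")))))
  sheet <- read_sample_sheet(file.path(dir, "sheet.tsv"))
  rna <- read_count_matrix(file.path(dir, "rna.tsv"), "rna")
  expect_setequal(colnames(rna$counts),
                  sheet$sample_id[sheet$layer == "rna"])
  expect_identical(sort(rownames(rna$counts)), sort(ex$truth$gene_id))
})
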