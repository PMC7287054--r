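test_that("size factors obey symmetry, equivariance and the hand toy", {
  m <- toy_counts(matrix(c(5, 10, 20, 40), 4, 3), "rna")
  expect_equal(unname(estimate_size_factors(m)), rep(1, 3))

  set.seed(1)
  x <- matrix(rnbinom(30, mu = 40, size = 5) + 1, 10, 3)
  m2 <- toy_counts(cbind(x, x[, 1] * 2), "rna",
                   samples = c("a", "b", "c", "a2x"))
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf["a2x"]), unname(sf["a"]) * 2)

  # 4 genes x 3 samples, ratios enumerable by hand: geometric means
  # (4, 2, 8, 16) give per-sample ratios of exactly 0.5, 1 and 2
  toy <- toy_counts(matrix(c(2, 1, 4, 8,
                             4, 2, 8, 16,
                             8, 4, 16, 32), 4, 3), "rna")
  expect_equal(unname(estimate_size_factors(toy)), c(0.5, 1, 2))

  all_zero_somewhere <- toy_counts(rbind(c(0, 1, 2), c(1, 0, 2), c(1, 2, 0)),
                                   "rna")
  expect_error(estimate_size_factors(all_zero_somewhere), "all-positive")
})

test_that("method-of-moments dispersion floors and recovers", {
  # equal counts everywhere: s2 = 0 <= mean, so alpha hits the floor
  m <- toy_counts(matrix(10, 1, 6), "rna")
  a <- estimate_dispersion(m, groups = rep(c("t", "c"), each = 3))
  expect_equal(unname(a[1]), 1e-8)

  set.seed(21)
  pois <- toy_counts(matrix(rpois(60, 20), 10, 6), "rna")
  a <- estimate_dispersion(pois, groups = rep(c("t", "c"), each = 3),
                           sf = rep(1, 6))
  expect_true(all(a >= 1e-8))

  # NB simulation at alpha = 0.1, 200 replicate samples: the per-gene MoM
  # median lands close to the truth
  mu <- matrix(100, 60, 200)
  dimnames(mu) <- list(sprintf("g%02d", 1:60), sprintf("s%03d", 1:200))
  set.seed(5)
  counts <- sim_nb_counts(mu, rep(0.1, 60))
  m200 <- toy_counts(counts, "rna", genes = rownames(mu),
                     samples = colnames(mu))
  a <- estimate_dispersion(m200, groups = rep("g1", 200), sf = rep(1, 200))
  expect_gt(median(a), 0.08)
  expect_lt(median(a), 0.12)
})

test_that("identical treated and control groups give null statistics", {
  set.seed(2)
  x <- matrix(rnbinom(30, mu = 50, size = 5), 10, 3)
  m <- toy_counts(cbind(x, x), "rna", samples = sprintf("s%d", 1:6))
  sheet <- contrast_sheet(3, 3)
  r <- nb_wald_contrast(m, sheet, sf = rep(1, 6), agent = "TM", timepoint = 6)
  expect_equal(r$log2fc, rep(0, nrow(r)))
  expect_equal(r$stat, rep(0, nrow(r)))
  expect_equal(r$p, rep(1, nrow(r)))
})

test_that("log2fc approaches the true ratio for large clean counts", {
  base <- c(1e4, 2e4, 5e4, 1e5, 25, 3e4, 800, 1200, 6e4, 9e4)
  m <- toy_counts(cbind(matrix(base * 4, 10, 3), matrix(base, 10, 3)), "rna",
                  samples = sprintf("s%d", 1:6))
  sheet <- contrast_sheet(3, 3)
  disp <- setNames(rep(1e-8, 10), rownames(m$counts))
  r <- nb_wald_contrast(m, sheet, sf = rep(1, 6), disp = disp,
                        agent = "TM", timepoint = 6, moderate = FALSE)
  expect_equal(r$log2fc, rep(2, 10), tolerance = 1e-9)
})

test_that("Wald statistics match an independent direct evaluation", {
  set.seed(17)
  mu <- matrix(rep(c(20, 60, 150, 400, 1000, 35, 80, 220, 550, 90), 6), 10, 6)
  dimnames(mu) <- list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6))
  counts <- sim_nb_counts(mu, rep(0.05, 10))
  counts[1, 1:3] <- counts[1, 1:3] * 3        # one regulated gene
  counts[2, ] <- c(0, 0, 0, 5, 6, 7)          # a zero-mean group
  m <- toy_counts(counts, "rna", genes = rownames(mu), samples = colnames(mu))
  sheet <- contrast_sheet(3, 3)
  sf <- estimate_size_factors(m)
  r <- nb_wald_contrast(m, sheet, sf = sf, agent = "TM", timepoint = 6,
                        moderate = FALSE)
  o <- oracle_nb_wald(counts, 1:3, 4:6, sf)
  expect_equal(nrow(r), nrow(o))
  for (col in c("log2fc", "se", "stat", "p", "padj")) {
    expect_equal(r[[col]], o[[col]], tolerance = 1e-8,
                 label = paste("column", col))
  }
})

test_that("moderation preserves estimates and improves calibration", {
  ex <- simulate_experiment(null_cfg(n_genes = 2000L), seed = 31L)
  r_mod <- nb_wald_contrast(ex$rna, ex$sheet, agent = "TM", timepoint = 6)
  r_raw <- nb_wald_contrast(ex$rna, ex$sheet, agent = "TM", timepoint = 6,
                            moderate = FALSE)
  expect_equal(r_mod$log2fc, r_raw$log2fc)  # moderation touches only the SE
  expect_lt(mean(r_mod$p < 0.05), 0.08)
  expect_gt(mean(r_raw$p < 0.05), mean(r_mod$p < 0.05))
})

test_that("the dual gate selects exactly the genes past the type-7 quantiles", {
  fc <- (1:100) / 10
  r <- make_contrast(fc, p = rep(0.01, 100))
  calls <- call_regulated(r, analysis_config())
  # direct enumeration: type-7 Q(0.95) of 1..100/10 is 9.505, Q(0.05) is
  # 0.595, so exactly genes 96..100 are at/above and 1..5 at/below
  expect_identical(calls$gene_id[calls$direction == "up"],
                   sprintf("g%03d", 96:100))
  expect_identical(calls$gene_id[calls$direction == "down"],
                   sprintf("g%03d", 1:5))
  th <- attr(calls, "thresholds")
  expect_equal(th$q_high, 9.505)
  expect_equal(th$q_low, 0.595)
})

test_that("the p-value gate vetoes even the largest fold-change", {
  p <- rep(0.01, 100)
  p[100] <- 0.5
  calls <- call_regulated(make_contrast((1:100) / 10, p), analysis_config())
  expect_identical(calls$direction[calls$gene_id == "g100"], "ns")
  expect_identical(calls$gene_id[calls$direction == "up"],
                   sprintf("g%03d", 96:99))
})

test_that("degenerate and undersized inputs are handled", {
  r <- make_contrast(rep(0, 50), p = rep(0.001, 50))
  expect_warning(calls <- call_regulated(r, analysis_config()), "degenerate")
  expect_true(all(calls$direction == "ns"))
  expect_error(call_regulated(make_contrast(1:10, rep(0.01, 10))), ">= 20")
})

test_that("calls are monotone in the gates and BH dominates raw p", {
  set.seed(9)
  for (i in 1:3) {
    fc <- rnorm(200, 0, 1)
    p <- runif(200)^2
    r <- make_contrast(fc, p)
    base <- call_regulated(r, analysis_config())
    wider <- call_regulated(r, analysis_config(p_max = 0.2, q_low = 0.15,
                                               q_high = 0.85))
    called <- function(cl) cl$gene_id[cl$direction != "ns"]
    expect_true(all(called(base) %in% called(wider)))

    fdr <- call_regulated(r, analysis_config(use_fdr = TRUE))
    expect_true(all(r$padj >= r$p))
    expect_lte(length(called(fdr)), length(called(base)))
  }
})
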