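test_that("standard curves recover doubling chemistry and invert cleanly", {
  # slope -1/log10(2) = -3.3219 Ct per decade for a perfectly efficient assay
  copies <- c(1e6, 1e5, 1e4)
  ct <- 20 + (6 - log10(copies)) / log10(2)
  curve <- fit_standard_curve(copies, ct)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-12)

  # ct at the intercept means one copy
  expect_equal(ct_to_copies(curve$intercept, curve), 1.0, tolerance = 1e-9)
  # hand case: slope -3.3219, intercept 40, ct 30 -> 2^10 copies
  c2 <- curve; c2$slope <- -3.3219; c2$intercept <- 40
  expect_equal(ct_to_copies(30, c2), 1024, tolerance = 1)
  # round trip
  for (copies in 10^seq(0, 7, by = 0.5))
    expect_equal(ct_to_copies(predict_ct(copies, curve), curve), copies,
                 tolerance = 1e-9 * copies)
})

test_that("jittered standard curves match the closed-form OLS solution", {
  set.seed(77)
  for (i in 1:5) {
    lg <- log10(10^(2:7))
    ct <- 38 - 3.3 * lg + rnorm(6, 0, 0.3)
    curve <- fit_standard_curve(10^(2:7), ct)
    slope_ref <- sum((lg - mean(lg)) * (ct - mean(ct))) /
      sum((lg - mean(lg))^2)
    intercept_ref <- mean(ct) - slope_ref * mean(lg)
    expect_equal(curve$slope, slope_ref, tolerance = 1e-10)
    expect_equal(curve$intercept, intercept_ref, tolerance = 1e-10)
  }
  expect_error(fit_standard_curve(c(1e2, 1e3), c(30, 27)), "at least 3")
  expect_error(fit_standard_curve(c(0, 1e3, 1e4), c(30, 27, 24)),
               "strictly positive")
  expect_warning(fit_standard_curve(10^(2:4), c(20, 23, 26)),
                 "non-negative")
})

test_that("splicing index is the short-isoform proportion", {
  expect_equal(splicing_index(300, 100), 0.75)
  expect_equal(splicing_index(0, 50), 0.0)
  expect_true(is.na(splicing_index(0, 0)))
  expect_error(splicing_index(-1, 5), "non-negative")
  # complementarity: short and long views sum to one
  s <- c(10, 250, 3.5); l <- c(90, 50, 0)
  expect_equal(splicing_index(s, l) + splicing_index(l, s), rep(1, 3))
  # a per-sample reference scalar cancels
  expect_equal(splicing_index(300 * 7.3, 100 * 7.3), 0.75,
               tolerance = 1e-12)
})

test_that("group comparison reproduces the closed-form Welch test", {
  tab <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("tumor", "normal"), each = 3),
    short_copies = c(0.8, 0.9, 0.85, 0.2, 0.3, 0.25) * 1000,
    long_copies = c(0.2, 0.1, 0.15, 0.8, 0.7, 0.75) * 1000,
    stringsAsFactors = FALSE)
  res <- compare_groups(tab)
  ref <- welch_reference(c(0.8, 0.9, 0.85), c(0.2, 0.3, 0.25))
  expect_equal(res$t_statistic, ref$t, tolerance = 1e-10)
  expect_equal(res$df, ref$df, tolerance = 1e-10)
  expect_equal(res$p_value, ref$p, tolerance = 1e-10)
  expect_equal(res$mean_tumor, 0.85)

  # identical groups: t = 0, p = 1
  same <- tab
  same$short_copies <- rep(c(800, 900, 850), 2)
  same$long_copies <- rep(c(200, 100, 150), 2)
  res0 <- compare_groups(same)
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # swapping labels negates t, keeps p
  swapped <- tab
  swapped$group <- rev(tab$group)
  res_sw <- compare_groups(swapped)
  expect_equal(res_sw$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
})

test_that("undefined indices are excluded and scarce groups are errors", {
  tab <- data.frame(
    sample_id = sprintf("s%d", 1:7),
    group = c(rep("tumor", 4), rep("normal", 3)),
    short_copies = c(80, 90, 85, 0, 20, 30, 25),
    long_copies = c(20, 10, 15, 0, 80, 70, 75),
    stringsAsFactors = FALSE)
  expect_message(res <- compare_groups(tab), "excluding 1")
  expect_equal(res$n_tumor, 3L)
  expect_true(is.na(res$indices[["s4"]]))

  small <- tab[c(1, 5, 6, 7), ]
  expect_error(suppressMessages(compare_groups(small)), ">= 2 samples")
  bad <- tab; bad$reference_copies <- c(rep(1e6, 6), 0)
  expect_error(compare_groups(bad), "strictly positive")
})

test_that("reference-gene scaling cancels in the group comparison", {
  cfg <- sim_config(seed = 31)
  truth <- structure(list(splice = list(), de_genes = character(0)),
                     class = "ground_truth")
  qp <- simulate_qpcr(cfg, truth)
  tab <- qp$quant
  res0 <- compare_groups(tab)
  scaled <- tab
  scaled$short_copies <- scaled$short_copies / scaled$reference_copies
  scaled$long_copies <- scaled$long_copies / scaled$reference_copies
  res1 <- compare_groups(scaled)
  expect_equal(res1$t_statistic, res0$t_statistic, tolerance = 1e-10)
  expect_equal(res1$p_value, res0$p_value, tolerance = 1e-10)
})

test_that("multi-gene validation tables round-trip and match per-gene runs", {
  cfg <- sim_config(seed = 8, qpcr_n_assays = 3, n_genes = 30,
                    n_tumors = 5, n_normals = 4, n_splice_genes = 5,
                    n_de_genes = 0)
  ann <- simulate_annotation(cfg)
  sim <- simulate_expression(cfg, ann)
  qp <- simulate_qpcr(cfg, sim$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(qp$quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- read_quant(path)
  res <- validate_all_genes(tab)
  expect_equal(nrow(res), 3L)
  for (g in res$gene) {
    single <- compare_groups(tab[tab$gene == g, ])
    expect_equal(res$p_value[res$gene == g], single$p_value,
                 tolerance = 1e-12)
  }
})
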