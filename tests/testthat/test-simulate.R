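test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 25, n_tumors = 6, n_normals = 4,
                    n_splice_genes = 4, n_de_genes = 4, seed = 17)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  s1 <- simulate_expression(cfg, a1)
  s2 <- simulate_expression(cfg, a2)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  q1 <- simulate_qpcr(cfg, s1$truth)
  q2 <- simulate_qpcr(cfg, s2$truth)
  expect_identical(q1, q2)
  # and the caller's RNG stream is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_annotation(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("annotation geometry respects the configured ranges", {
  cfg <- sim_config(n_genes = 10, exons_per_gene = c(3, 5),
                    probesets_per_exon = c(1, 2), n_splice_genes = 0,
                    n_de_genes = 0, seed = 4)
  ann <- simulate_annotation(cfg)
  counts <- table(ann$gene_id)
  expect_true(all(counts >= 3 & counts <= 10))
  exons <- tapply(ann$exon_id, ann$gene_id, function(e) length(unique(e)))
  expect_true(all(exons >= 3 & exons <= 5))
  expect_setequal(unique(ann$strand), c("+", "-"))
  # probesets never overlap within a chromosome
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(diff(sub$start) >= 25))
  }
  # construction guarantees the >=3 probeset filter keeps everything
  expect_equal(nrow(suppressMessages(filter_min_probesets(ann, 3))),
               nrow(ann))
})

test_that("spiked events propagate exactly through a noise-free chain", {
  cfg <- sim_config(n_genes = 12, n_tumors = 6, n_normals = 4,
                    baseline_sd_between_probesets = 0, noise_sd = 0,
                    n_splice_genes = 3, splice_delta = 2.0,
                    splice_exon_fraction = 0.5, splice_tumor_fraction = 1,
                    n_de_genes = 3, de_delta = 4.0, seed = 2)
  ann <- simulate_annotation(cfg)
  sim <- simulate_expression(cfg, ann)
  tab <- score_pipeline(sim$matrix, ann)
  spiked <- names(sim$truth$splice)
  for (i in seq_len(nrow(tab))) {
    scores <- unlist(tab[i, sprintf("T%03d", 1:6)])
    if (tab$gene_id[i] %in% spiked) {
      expect_identical(unname(scores), rep(2.0, 6))
    } else {
      expect_identical(unname(scores), rep(0.0, 6))
    }
  }
  # DE-only genes score zero despite a 4-unit whole-gene shift
  expect_true(all(tab$mean_mmes[tab$gene_id %in% sim$truth$de_genes] == 0))
  # affected tumors recorded exactly
  for (ev in sim$truth$splice)
    expect_setequal(ev$tumor_ids, sprintf("T%03d", 1:6))
})

test_that("noise-free, spike-free data scores zero everywhere", {
  cfg <- sim_config(n_genes = 8, n_tumors = 4, n_normals = 3,
                    noise_sd = 0, baseline_sd_between_probesets = 0,
                    n_splice_genes = 0, n_de_genes = 0, seed = 6)
  ann <- simulate_annotation(cfg)
  sim <- simulate_expression(cfg, ann)
  tab <- score_pipeline(sim$matrix, ann)
  expect_true(all(tab$mean_mmes == 0))
})

test_that("ground truth is well-formed and round-trips through TSV", {
  cfg <- sim_config(n_genes = 40, n_tumors = 10, n_normals = 5,
                    n_splice_genes = 6, n_de_genes = 6,
                    splice_tumor_fraction = 0.4, seed = 19)
  ann <- simulate_annotation(cfg)
  sim <- simulate_expression(cfg, ann)
  truth <- sim$truth
  expect_length(intersect(names(truth$splice), truth$de_genes), 0)
  tumors <- sprintf("T%03d", 1:10)
  models <- build_gene_models(ann)
  for (ev in truth$splice) {
    expect_true(all(ev$tumor_ids %in% tumors))
    expect_gte(length(ev$tumor_ids), 1)
    model <- models[[ev$gene_id]]
    # affected block is contiguous at the 5' or 3' end of the transcript
    pos <- match(ev$exon_ids, model$exons)
    expect_false(anyNA(pos))
    expect_equal(pos, seq(min(pos), max(pos)))
    expect_true(min(pos) == 1 || max(pos) == length(model$exons))
    expect_lt(length(pos), length(model$exons))
  }
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, p1, p2)
  back <- read_truth(p1, p2)
  expect_identical(back$de_genes, truth$de_genes)
  expect_identical(back$splice, truth$splice)
})

test_that("recovery metrics count recall and rank enrichment correctly", {
  truth <- structure(list(
    splice = list(g1 = list(gene_id = "g1"), g4 = list(gene_id = "g4")),
    de_genes = character(0)), class = "ground_truth")
  # spikes at ranks 1 and 4 of six genes, k = 3 -> recall 0.5
  ranked <- c("g1", "g2", "g3", "g4", "g5", "g6")
  m <- recovery_metrics(ranked, truth, k = 3)
  expect_equal(m$recall_at_k, 0.5)
  # AUC by hand: g1 beats 4 negatives, g4 beats 2 -> 6/8
  expect_equal(m$auc_splice, 6 / 8)
  # perfect recovery
  m <- recovery_metrics(c("g1", "g4", "g2", "g3", "g5", "g6"), truth, k = 2)
  expect_equal(m$recall_at_k, 1.0)
  expect_equal(m$auc_splice, 1.0)
  expect_error(recovery_metrics(c("g1", "g2"), truth, 1), "absent")

  # random ranking is unenriched on average
  set.seed(14)
  aucs <- replicate(200, {
    ids <- sample(sprintf("g%02d", 1:40))
    tr <- structure(list(
      splice = stats::setNames(
        lapply(sprintf("g%02d", 1:8), function(g) list(gene_id = g)),
        sprintf("g%02d", 1:8)),
      de_genes = character(0)), class = "ground_truth")
    recovery_metrics(ids, tr, 5)$auc_splice
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("null qPCR proportions give well-calibrated p-values", {
  truth <- structure(list(splice = list(), de_genes = character(0)),
                     class = "ground_truth")
  ps <- vapply(1:40, function(seed) {
    cfg <- sim_config(seed = 500 + seed, qpcr_tumor_prop = 0.5,
                      qpcr_normal_prop = 0.5)
    qp <- simulate_qpcr(cfg, truth)
    compare_groups(qp$quant)$p_value
  }, numeric(1))
  # roughly uniform: no mass collapse at either end
  expect_gt(mean(ps > 0.1), 0.5)
  expect_lt(mean(ps < 0.05), 0.25)

  # strong separation with realistic proportions is reliably detected
  cfg <- sim_config(seed = 9, qpcr_tumor_prop = 0.8, qpcr_normal_prop = 0.3)
  qp <- simulate_qpcr(cfg, truth)
  expect_lt(compare_groups(qp$quant)$p_value, 0.001)
})
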