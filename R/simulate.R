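#' Simulation configuration
#'
#' Builds the configuration for the synthetic exon-array cohort. The
#' defaults emulate the discovery study conditions: 44 tumors versus 25
#' normal samples of log2 probeset intensities around a baseline of 6.0
#' log2 units, Gaussian measurement noise, a set of genes carrying an
#' isoform-switch event (a contiguous 5' or 3' exon block shifted by
#' `splice_delta` in a fraction of tumors) and a disjoint set of whole-gene
#' differential-expression confounders shifted by `de_delta` in all tumors.
#' The qPCR stage emulates the validation cohort of 47 tumors and 19
#' normals with group-specific short-isoform proportions.
#'
#' One seed drives everything; sub-streams are split deterministically
#' (annotation uses `seed`, expression `seed + 1`, qPCR `seed + 2`) so each
#' stage can be regenerated independently.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param probesets_per_exon integer range of probesets per exon.
#' @param n_tumors,n_normals discovery cohort sizes.
#' @param baseline_mean mean baseline log2 intensity.
#' @param baseline_sd_between_probesets SD of per-probeset baselines (log2).
#' @param noise_sd per-measurement Gaussian noise SD (log2).
#' @param n_splice_genes number of genes given a splice-switch event.
#' @param splice_delta log2 shift applied to the affected exon block.
#' @param splice_exon_fraction fraction of a gene's exons in the block.
#' @param splice_tumor_fraction per-tumor probability of carrying the event.
#' @param n_de_genes number of whole-gene differential-expression genes.
#' @param de_delta log2 whole-gene shift in tumors.
#' @param qpcr_n_tumors,qpcr_n_normals validation cohort sizes.
#' @param qpcr_tumor_prop,qpcr_normal_prop short-isoform proportion per group.
#' @param qpcr_total_copies typical total isoform copies per sample.
#' @param qpcr_noise_sd log-normal sdlog of simulated copy numbers.
#' @param qpcr_n_assays number of spiked genes carried into the qPCR stage.
#' @param curve_slope,curve_intercept standard-curve parameters (Ct per
#'   log10 copies; Ct at one copy).
#' @param qpcr_ct_sd Gaussian Ct noise of the dilution standards.
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       exons_per_gene = c(3, 8),
                       probesets_per_exon = c(1, 4),
                       n_tumors = 44, n_normals = 25,
                       baseline_mean = 6.0,
                       baseline_sd_between_probesets = 1.0,
                       noise_sd = 0.25,
                       n_splice_genes = 50,
                       splice_delta = 1.5,
                       splice_exon_fraction = 0.5,
                       splice_tumor_fraction = 0.5,
                       n_de_genes = 50,
                       de_delta = 1.5,
                       qpcr_n_tumors = 47, qpcr_n_normals = 19,
                       qpcr_tumor_prop = 0.8, qpcr_normal_prop = 0.3,
                       qpcr_total_copies = 1e5,
                       qpcr_noise_sd = 0.35,
                       qpcr_n_assays = 1,
                       curve_slope = -1 / log10(2),
                       curve_intercept = 40,
                       qpcr_ct_sd = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, n_tumors >= 1, n_normals >= 1,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 1,
            exons_per_gene[1] <= exons_per_gene[2],
            length(probesets_per_exon) == 2, probesets_per_exon[1] >= 1,
            probesets_per_exon[1] <= probesets_per_exon[2],
            noise_sd >= 0, n_splice_genes >= 0, n_de_genes >= 0,
            n_splice_genes + n_de_genes <= n_genes,
            splice_tumor_fraction > 0, splice_tumor_fraction <= 1,
            splice_exon_fraction > 0, splice_exon_fraction <= 1,
            qpcr_tumor_prop >= 0, qpcr_tumor_prop <= 1,
            qpcr_normal_prop >= 0, qpcr_normal_prop <= 1,
            abs(seed) < .Machine$integer.max)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds a mapping whose keys mirror [sim_config()] arguments;
#' unknown keys are an error, absent keys take the defaults.
#'
#' @param path config file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(sim_config)))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

# Run code under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a probeset annotation
#'
#' Generates `n_genes` genes with exon and probeset counts drawn uniformly
#' from the configured ranges, non-overlapping coordinates on autosomes and
#' mixed strands. Deterministic given the config seed.
#'
#' @param config a `sim_config`.
#' @return a `probeset_annotation`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rows <- vector("list", config$n_genes)
    cursor <- stats::setNames(rep(1000L, 22), paste0("chr", 1:22))
    for (g in seq_len(config$n_genes)) {
      gene_id <- sprintf("G%04d", g)
      n_exons <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      strand <- sample(c("+", "-"), 1)
      chrom <- sample(names(cursor), 1)
      pos <- cursor[[chrom]]
      exon_rows <- vector("list", n_exons)
      for (e in seq_len(n_exons)) {
        exon_id <- sprintf("%s.E%02d", gene_id, e)
        n_ps <- sample(
          config$probesets_per_exon[1]:config$probesets_per_exon[2], 1)
        starts <- pos + seq_len(n_ps) * 60L - 60L
        exon_rows[[e]] <- data.frame(
          probeset_id = sprintf("%s.P%d", exon_id, seq_len(n_ps)),
          gene_id = gene_id, exon_id = exon_id, chrom = chrom,
          start = starts, end = starts + 25L, strand = strand,
          stringsAsFactors = FALSE)
        pos <- pos + n_ps * 60L + 200L
      }
      gene <- do.call(rbind, exon_rows)
      # transcript order: genomic order on '+', reversed on '-'
      ord <- order(gene$start, decreasing = (strand == "-"))
      gene$order_index <- NA_integer_
      gene$order_index[ord] <- seq_len(nrow(gene)) - 1L
      cursor[[chrom]] <- pos + 5000L
      rows[[g]] <- gene
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    validate_annotation(ann)
  })
}

#' Simulate the discovery expression matrix with recorded ground truth
#'
#' Each probeset gets a baseline drawn around `baseline_mean`; every
#' measurement adds Gaussian noise of SD `noise_sd`. Differential-expression
#' confounder genes add `de_delta` to all probesets in all tumors.
#' Splice-switch genes add `splice_delta` to a contiguous block of exons at
#' a random (5' or 3') end of the transcript — mirroring alternative
#' first/last-exon usage — in a per-gene random subset of tumors drawn at
#' rate `splice_tumor_fraction` (at least one tumor). Splice and DE gene
#' sets are disjoint; only genes with at least two exons receive splice
#' events. Deterministic given the config seed.
#'
#' @param config a `sim_config`.
#' @param annotation a `probeset_annotation`, typically from
#'   [simulate_annotation()].
#' @return a list with `matrix` (an `expr_matrix`) and `truth` (class
#'   `ground_truth`: `splice`, a list of per-gene events with `gene_id`,
#'   `exon_ids`, `tumor_ids`, `delta`; and `de_genes`, a character vector).
#' @export
simulate_expression <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    probesets <- annotation$probeset_id
    tumors <- sprintf("T%03d", seq_len(config$n_tumors))
    normals <- sprintf("N%03d", seq_len(config$n_normals))
    samples <- c(tumors, normals)
    groups <- stats::setNames(
      rep(c("tumor", "normal"), c(length(tumors), length(normals))), samples)

    baseline <- stats::rnorm(length(probesets), config$baseline_mean,
                             config$baseline_sd_between_probesets)
    values <- baseline + matrix(
      stats::rnorm(length(probesets) * length(samples), 0, config$noise_sd),
      nrow = length(probesets))
    dimnames(values) <- list(probesets, samples)

    models <- build_gene_models(annotation)
    genes <- vapply(models, function(m) m$gene_id, "")
    multi_exon <- genes[vapply(models, function(m) length(m$exons) > 1,
                               NA)]
    if (config$n_splice_genes > length(multi_exon))
      stop("not enough multi-exon genes for n_splice_genes")
    splice_genes <- sort(sample(multi_exon, config$n_splice_genes))
    de_genes <- sort(sample(setdiff(genes, splice_genes), config$n_de_genes))

    for (g in de_genes) {
      ps <- gene_probesets(models[[g]])
      values[ps, tumors] <- values[ps, tumors] + config$de_delta
    }

    splice <- vector("list", length(splice_genes))
    names(splice) <- splice_genes
    for (g in splice_genes) {
      model <- models[[g]]
      n_exons <- length(model$exons)
      block_len <- min(n_exons - 1L,
                       max(1L, round(config$splice_exon_fraction * n_exons)))
      from_5prime <- sample(c(TRUE, FALSE), 1)
      block <- if (from_5prime) model$exons[seq_len(block_len)]
               else model$exons[(n_exons - block_len + 1L):n_exons]
      hit <- tumors[stats::runif(length(tumors)) < config$splice_tumor_fraction]
      if (length(hit) == 0) hit <- sample(tumors, 1)
      ps <- unlist(model$probesets_by_exon[block], use.names = FALSE)
      values[ps, hit] <- values[ps, hit] + config$splice_delta
      splice[[g]] <- list(gene_id = g, exon_ids = block, tumor_ids = hit,
                          delta = config$splice_delta)
    }
    truth <- structure(list(splice = splice, de_genes = de_genes),
                       class = "ground_truth")
    list(matrix = expr_matrix(values, groups), truth = truth)
  })
}

#' Simulate the validation-stage qPCR tables
#'
#' Emulates the validation design: `qpcr_n_tumors` tumors and
#' `qpcr_n_normals` normals assayed for up to `qpcr_n_assays` genes (taken
#' from the spiked splice genes in `truth`, or a synthetic assay gene when
#' none exist). Per sample, total isoform copies are drawn log-normally
#' around `qpcr_total_copies` and split into short/long channels around the
#' group's short-isoform proportion, with independent log-normal noise per
#' channel; 18S reference copies are drawn log-normally around 1e6. A
#' 10-fold dilution standard series (1e2..1e7 copies) is generated per assay
#' from the configured curve with Gaussian Ct noise. Deterministic given the
#' config seed.
#'
#' @param config a `sim_config`.
#' @param truth a `ground_truth` (may contain zero splice events).
#' @return a list with `quant` (data.frame: `sample_id`, `group`, `gene`,
#'   `short_copies`, `long_copies`, `reference_copies`) and `standards`
#'   (data.frame: `gene`, `copies`, `ct`).
#' @export
simulate_qpcr <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  with_seed(config$seed + 2L, {
    assay_genes <- names(truth$splice)
    if (length(assay_genes) == 0) assay_genes <- "ASSAY1"
    assay_genes <- assay_genes[seq_len(min(config$qpcr_n_assays,
                                           length(assay_genes)))]
    samples <- c(sprintf("VT%03d", seq_len(config$qpcr_n_tumors)),
                 sprintf("VN%03d", seq_len(config$qpcr_n_normals)))
    group <- rep(c("tumor", "normal"),
                 c(config$qpcr_n_tumors, config$qpcr_n_normals))
    prop <- ifelse(group == "tumor", config$qpcr_tumor_prop,
                   config$qpcr_normal_prop)
    quant <- do.call(rbind, lapply(assay_genes, function(g) {
      total <- stats::rlnorm(length(samples), log(config$qpcr_total_copies),
                             config$qpcr_noise_sd)
      short <- ifelse(prop > 0,
                      stats::rlnorm(length(samples), log(pmax(total * prop,
                                                              1e-12)),
                                    config$qpcr_noise_sd), 0)
      long <- ifelse(prop < 1,
                     stats::rlnorm(length(samples),
                                   log(pmax(total * (1 - prop), 1e-12)),
                                   config$qpcr_noise_sd), 0)
      data.frame(sample_id = samples, group = group, gene = g,
                 short_copies = short, long_copies = long,
                 reference_copies = stats::rlnorm(length(samples), log(1e6),
                                                  config$qpcr_noise_sd),
                 stringsAsFactors = FALSE)
    }))
    standards <- do.call(rbind, lapply(assay_genes, function(g) {
      copies <- 10^(2:7)
      data.frame(gene = g, copies = copies,
                 ct = config$curve_intercept +
                   config$curve_slope * log10(copies) +
                   stats::rnorm(length(copies), 0, config$qpcr_ct_sd),
                 stringsAsFactors = FALSE)
    }))
    rownames(quant) <- rownames(standards) <- NULL
    list(quant = quant, standards = standards)
  })
}

#' Recovery metrics of a rank list against the simulation truth
#'
#' Quantifies how well the rank list recovers the spiked splice genes (the
#' analog of what manual screening of the ranked list achieves):
#' `recall_at_k` is the fraction of spiked splice genes among the top `k`
#' ranks, and `auc_splice` / `auc_de` are rank-sum enrichment AUCs
#' (0.5 = no enrichment). `auc_splice` compares spiked genes against all
#' other genes (DE confounders included — they are exactly the negatives a
#' splice detector must not rank highly); `auc_de` compares DE-only genes
#' against the unspiked background only, so that splice genes, which
#' legitimately dominate the top ranks, do not mechanically depress it.
#'
#' @param rank_list an `mmes_table` or a character vector of gene ids in
#'   rank order (best first).
#' @param truth a `ground_truth`; every truth gene must appear in the list.
#' @param k rank cutoff for recall.
#' @return a list with `recall_at_k`, `auc_splice`, `auc_de` (the AUCs are
#'   `NA` when the corresponding gene set is empty).
#' @export
recovery_metrics <- function(rank_list, truth, k = 100) {
  stopifnot(inherits(truth, "ground_truth"), k >= 1)
  ids <- if (inherits(rank_list, "mmes_table")) rank_list$gene_id
         else as.character(rank_list)
  splice_genes <- names(truth$splice)
  absent <- setdiff(c(splice_genes, truth$de_genes), ids)
  if (length(absent) > 0)
    stop("truth gene(s) absent from rank list: ",
         paste(absent, collapse = ", "))
  top <- ids[seq_len(min(k, length(ids)))]
  recall <- if (length(splice_genes) == 0) NA_real_
            else mean(splice_genes %in% top)
  list(recall_at_k = recall,
       auc_splice = rank_auc(ids, splice_genes),
       auc_de = rank_auc(setdiff(ids, splice_genes), truth$de_genes))
}

# P(random member of `positives` outranks a random non-member), from rank
# positions (1 = best, no ties). Equivalent to the Wilcoxon rank-sum AUC.
rank_auc <- function(ids, positives) {
  if (length(positives) == 0 || length(positives) == length(ids))
    return(NA_real_)
  pos <- which(ids %in% positives)
  n1 <- length(pos)
  n0 <- length(ids) - n1
  worse_negatives <- vapply(pos, function(r) {
    (length(ids) - r) - sum(pos > r)
  }, numeric(1))
  sum(worse_negatives) / (n1 * n0)
}

#' Write the ground truth to JSON-like TSV files
#'
#' Two tables: one row per spiked gene/exon/tumor triple expansion is
#' avoided — events are stored as one row per gene with `;`-joined exon and
#' tumor lists — plus the DE-only gene list.
#'
#' @param truth a `ground_truth`.
#' @param path output TSV path for splice events.
#' @param de_path output TSV path for DE-only genes.
#' @export
write_truth <- function(truth, path, de_path) {
  ev <- do.call(rbind, lapply(truth$splice, function(e) {
    data.frame(gene_id = e$gene_id,
               exon_ids = paste(e$exon_ids, collapse = ";"),
               tumor_ids = paste(e$tumor_ids, collapse = ";"),
               delta = e$delta, stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(gene_id = character(0), exon_ids = character(0),
                     tumor_ids = character(0), delta = numeric(0))
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = truth$de_genes), de_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth pair written by [write_truth()]
#' @param path splice-events TSV path.
#' @param de_path DE-only gene list TSV path.
#' @return a `ground_truth`.
#' @export
read_truth <- function(path, de_path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(delta = "numeric"))
  splice <- lapply(seq_len(nrow(ev)), function(i) {
    list(gene_id = ev$gene_id[i],
         exon_ids = strsplit(ev$exon_ids[i], ";", fixed = TRUE)[[1]],
         tumor_ids = strsplit(ev$tumor_ids[i], ";", fixed = TRUE)[[1]],
         delta = ev$delta[i])
  })
  names(splice) <- ev$gene_id
  de <- utils::read.delim(de_path, stringsAsFactors = FALSE)
  structure(list(splice = splice, de_genes = as.character(de$gene_id)),
            class = "ground_truth")
}
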