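#' Cohort-level screening plot data for one gene
#'
#' Assembles the quantities behind the cohort gene plot used in visual
#' screening: for every probeset of the gene (5' to 3'), the difference
#' between the tumor-cohort mean and the normal-cohort mean; a floored
#' horizontal baseline (the grand mean of the raw log2 signal over the
#' gene's probesets across all samples, rounded down to the nearest whole
#' number — a cosmetic reference only, never used in scoring); and the
#' deviation histogram counts: how many tumors lie more than one normal-
#' cohort standard deviation above (`count_above`) or below (`count_below`)
#' the normal mean of that probeset. The SD is the per-probeset sample SD of
#' the normal cohort (n-1 denominator); the threshold comparisons are strict.
#'
#' @param x an `expr_matrix`.
#' @param ann a `probeset_annotation` covering the gene.
#' @param gene_id gene to plot.
#' @return an object of class `cohort_plot_data` with elements `gene_id`,
#'   `probeset_id`, `exon_id`, `tracing`, `baseline`, `count_above`,
#'   `count_below`, `n_tumors`.
#' @export
build_cohort_plot <- function(x, ann, gene_id) {
  stopifnot(inherits(x, "expr_matrix"))
  ord <- gene_probeset_order(ann, gene_id)
  missing <- setdiff(ord$probeset_id, rownames(x$values))
  if (length(missing) > 0)
    stop("probeset(s) of gene ", gene_id, " absent from matrix: ",
         paste(missing, collapse = ", "))
  normals <- sample_ids(x, "normal")
  tumors <- sample_ids(x, "tumor")
  if (length(normals) < 2)
    stop("need >= 2 normal samples for a deviation SD")
  m <- x$values[ord$probeset_id, , drop = FALSE]
  mn <- rowMeans(m[, normals, drop = FALSE])
  sdn <- apply(m[, normals, drop = FALSE], 1, stats::sd)
  mt <- rowMeans(m[, tumors, drop = FALSE])
  tum <- m[, tumors, drop = FALSE]
  count_above <- rowSums(tum > mn + sdn)
  count_below <- rowSums(tum < mn - sdn)
  structure(list(
    gene_id = gene_id,
    probeset_id = ord$probeset_id,
    exon_id = ord$exon_id,
    tracing = unname(mt - mn),
    baseline = floor(mean(m)),
    count_above = unname(count_above),
    count_below = unname(count_below),
    n_tumors = length(tumors)
  ), class = "cohort_plot_data")
}

#' Per-tumor screening plot data for one gene
#'
#' Extracts one tumor's normalized probeset values (log2, zero = normal-
#' cohort mean) for a gene, in 5' to 3' probeset order with the exon track,
#' for the individual-tumor plots used to spot splicing events confined to a
#' subset of tumors.
#'
#' @param norm a `norm_tumor_matrix`.
#' @param ann a `probeset_annotation` covering the gene.
#' @param gene_id gene to plot.
#' @param tumor_id tumor sample id.
#' @return an object of class `tumor_plot_data` with elements `gene_id`,
#'   `tumor_id`, `probeset_id`, `exon_id`, `values`.
#' @export
build_tumor_plot <- function(norm, ann, gene_id, tumor_id) {
  if (!tumor_id %in% colnames(norm)) stop("unknown tumor: ", tumor_id)
  ord <- gene_probeset_order(ann, gene_id)
  missing <- setdiff(ord$probeset_id, rownames(norm))
  if (length(missing) > 0)
    stop("probeset(s) of gene ", gene_id, " absent from matrix: ",
         paste(missing, collapse = ", "))
  structure(list(
    gene_id = gene_id,
    tumor_id = tumor_id,
    probeset_id = ord$probeset_id,
    exon_id = ord$exon_id,
    values = unname(norm[ord$probeset_id, tumor_id])
  ), class = "tumor_plot_data")
}

# 5'->3' probeset order of one gene (exon order, then order_index within).
gene_probeset_order <- function(ann, gene_id) {
  g <- ann[ann$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("gene not present in annotation: ", gene_id)
  model <- build_gene_models(g)[[1]]
  ps <- gene_probesets(model)
  data.frame(probeset_id = ps,
             exon_id = g$exon_id[match(ps, g$probeset_id)],
             stringsAsFactors = FALSE)
}

#' Render a screening plot to an image file
#'
#' Draws the gene plot for either cohort-level or per-tumor plot data:
#' probesets along the horizontal axis 5' (left) to 3' (right), signal
#' relative to normal (0) on the vertical axis (log2), an exon track above
#' the signal panel, and — for cohort data — a signed deviation histogram
#' below it (tumors beyond +1 SD as upward bars, beyond -1 SD downward).
#'
#' @param data a `cohort_plot_data` or `tumor_plot_data`.
#' @param out_path output file path.
#' @param format `"png"` or `"pdf"`.
#' @return the output path, invisibly.
#' @export
render_gene_plot <- function(data, out_path, format = c("png", "pdf")) {
  format <- match.arg(format)
  dir <- dirname(out_path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (format == "png") grDevices::png(out_path, width = 900, height = 600)
  else grDevices::pdf(out_path, width = 9, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (inherits(data, "cohort_plot_data")) draw_cohort_plot(data)
  else if (inherits(data, "tumor_plot_data")) draw_tumor_plot(data)
  else stop("unsupported plot data class")
  invisible(out_path)
}

draw_exon_track <- function(exon_id) {
  n <- length(exon_id)
  runs <- rle(exon_id)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(0, 1), axes = FALSE,
                 xlab = "", ylab = "", xaxs = "i")
  shade <- rep(c("grey75", "grey90"), length.out = length(runs$values))
  graphics::rect(starts - 0.4, 0.2, ends + 0.4, 0.8, col = shade,
                 border = "grey40")
  graphics::text((starts + ends) / 2, 0.5, runs$values, cex = 0.6)
  graphics::mtext("exons", side = 2, las = 1, cex = 0.6, line = 0.2)
}

draw_cohort_plot <- function(data) {
  n <- length(data$probeset_id)
  graphics::layout(matrix(1:3, ncol = 1), heights = c(1, 3, 2))
  op <- graphics::par(mar = c(0.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  draw_exon_track(data$exon_id)
  graphics::title(main = paste0(data$gene_id, " - cohort"), line = 0.5)
  graphics::par(mar = c(0.5, 4, 0.5, 1))
  ylim <- range(c(data$tracing, 0))
  graphics::plot(seq_len(n), data$tracing, type = "o", pch = 16,
                 xlim = c(0.5, n + 0.5), ylim = ylim, xaxs = "i",
                 xlab = "", ylab = "tumor - normal mean (log2)", xaxt = "n")
  graphics::abline(h = 0, col = "grey50")
  graphics::par(mar = c(4, 4, 0.5, 1))
  ylim <- c(-1, 1) * max(c(data$count_above, data$count_below, 1))
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = ylim, xaxs = "i",
                 xlab = "probeset (5' to 3')",
                 ylab = "tumors beyond +/-1 SD")
  graphics::rect(seq_len(n) - 0.35, 0, seq_len(n) + 0.35, data$count_above,
                 col = "firebrick")
  graphics::rect(seq_len(n) - 0.35, 0, seq_len(n) + 0.35, -data$count_below,
                 col = "steelblue")
  graphics::abline(h = 0)
  graphics::axis(1, at = seq_len(n), labels = data$probeset_id, las = 2,
                 cex.axis = 0.6)
}

draw_tumor_plot <- function(data) {
  n <- length(data$probeset_id)
  graphics::layout(matrix(1:2, ncol = 1), heights = c(1, 4))
  op <- graphics::par(mar = c(0.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  draw_exon_track(data$exon_id)
  graphics::title(main = paste0(data$gene_id, " - tumor ", data$tumor_id),
                  line = 0.5)
  graphics::par(mar = c(4, 4, 0.5, 1))
  ylim <- range(c(data$values, 0))
  graphics::plot(seq_len(n), data$values, type = "o", pch = 16,
                 xlim = c(0.5, n + 0.5), ylim = ylim, xaxs = "i",
                 xlab = "probeset (5' to 3')",
                 ylab = "signal relative to normal (log2)", xaxt = "n")
  graphics::abline(h = 0, col = "grey50")
  graphics::axis(1, at = seq_len(n), labels = data$probeset_id, las = 2,
                 cex.axis = 0.6)
}

#' Render the screening bundle for a gene list
#'
#' For every gene in `genes`, writes one cohort plot and one plot per tumor
#' into `out_dir`. Unknown genes are skipped with a warning.
#'
#' @param x an `expr_matrix`.
#' @param ann a `probeset_annotation`.
#' @param genes character vector of gene ids.
#' @param out_dir output directory (created if absent).
#' @param format `"png"` or `"pdf"`.
#' @param per_tumor also render the individual tumor plots (default TRUE).
#' @return character vector of files written, invisibly.
#' @export
render_screening_bundle <- function(x, ann, genes, out_dir,
                                    format = c("png", "pdf"),
                                    per_tumor = TRUE) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  norm <- normalize_to_normal_mean(x)
  written <- character(0)
  for (g in genes) {
    if (!g %in% ann$gene_id) {
      warning("gene not in annotation, skipped: ", g)
      next
    }
    f <- file.path(out_dir, paste0(g, "_cohort.", format))
    render_gene_plot(build_cohort_plot(x, ann, g), f, format)
    written <- c(written, f)
    if (per_tumor) {
      for (t in colnames(norm)) {
        f <- file.path(out_dir, paste0(g, "_", t, ".", format))
        render_gene_plot(build_tumor_plot(norm, ann, g, t), f, format)
        written <- c(written, f)
      }
    }
  }
  invisible(written)
}
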