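#' Max-min exon score of one gene in one tumor
#'
#' The score is the range of the gene's exon-level normalized signals in that
#' tumor: the maximum `Exon_et` minus the minimum. It is zero when all exons
#' of the gene move together (including a uniform whole-gene expression
#' change) and grows when an exon subset departs from the rest of the gene,
#' the signature of a candidate splicing event. Always non-negative; a
#' single-exon gene scores 0.
#'
#' @param exon_signals an `exon_signal_matrix`.
#' @param gene_id gene to score.
#' @param tumor_id tumor sample id.
#' @return the score, in log2 units.
#' @export
mmes_per_tumor <- function(exon_signals, gene_id, tumor_id) {
  idx <- which(exon_signals$exon_gene$gene_id == gene_id)
  if (length(idx) == 0) stop("gene not present in exon signals: ", gene_id)
  if (!tumor_id %in% colnames(exon_signals$values))
    stop("unknown tumor: ", tumor_id)
  v <- exon_signals$values[idx, tumor_id]
  max(v) - min(v)
}

#' Score and rank all genes
#'
#' Computes one max-min exon score per gene per tumor, the per-gene mean
#' score over all tumors, and a rank (1 = highest mean score). Ties in mean
#' score are broken by ascending `gene_id` so output is deterministic. Genes
#' in `models` with no exon rows in `exon_signals` are excluded with a
#' logged count rather than scored zero.
#'
#' @param exon_signals an `exon_signal_matrix`.
#' @param models a `gene_models` list.
#' @return a data.frame of class `mmes_table` with columns `rank`, `gene_id`,
#'   `mean_mmes`, then one score column per tumor, ordered by rank.
#' @export
mmes_score_all <- function(exon_signals, models) {
  tumors <- colnames(exon_signals$values)
  gene_rows <- split(seq_len(nrow(exon_signals$values)),
                     exon_signals$exon_gene$gene_id)
  wanted <- vapply(models, function(m) m$gene_id, "")
  absent <- setdiff(wanted, names(gene_rows))
  if (length(absent) > 0)
    message("mmes_score_all: excluding ", length(absent),
            " gene(s) with no exon signals")
  gene_rows <- gene_rows[intersect(wanted, names(gene_rows))]
  if (length(gene_rows) == 0) stop("no genes to score")
  scores <- t(vapply(gene_rows, function(idx) {
    m <- exon_signals$values[idx, , drop = FALSE]
    apply(m, 2, max) - apply(m, 2, min)
  }, numeric(length(tumors))))
  colnames(scores) <- tumors
  mean_mmes <- rowMeans(scores)
  ord <- order(-mean_mmes, names(gene_rows))
  out <- data.frame(rank = seq_along(ord), gene_id = names(gene_rows)[ord],
                    mean_mmes = unname(mean_mmes[ord]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores[ord, , drop = FALSE],
                                  check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("mmes_table", "data.frame")
  out
}

#' Top-ranked candidate genes
#'
#' Returns the first `min(n, n_genes)` gene ids of the rank list, in rank
#' order. The default of 900 is the screening depth used for manual plot
#' review.
#'
#' @param table an `mmes_table`.
#' @param n how many genes to keep (>= 1).
#' @return character vector of gene ids.
#' @export
select_top <- function(table, n = 900) {
  stopifnot(is.numeric(n), n >= 1)
  table$gene_id[seq_len(min(n, nrow(table)))]
}

#' Write a rank list to TSV
#'
#' Columns: `rank`, `gene_id`, `mean_mmes`, then one column per tumor score,
#' in the deterministic order produced by [mmes_score_all()].
#'
#' @param table an `mmes_table`.
#' @param path output path.
#' @export
write_rank_list <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
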