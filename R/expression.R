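#' Construct an expression matrix object
#'
#' Bundles a log2 probeset-by-sample intensity matrix with tumor/normal group
#' labels. The matrix is the post-RMA input to the pipeline: rows are
#' probesets, columns are samples, values are log2 intensities with no
#' missing or non-finite entries.
#'
#' @param values numeric matrix with probeset rownames and sample colnames.
#' @param groups named character vector mapping every sample id to `"tumor"`
#'   or `"normal"`.
#' @return an object of class `expr_matrix` with elements `values` and
#'   `groups` (reordered to match the matrix columns).
#' @export
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probeset rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicated probeset ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite value at probeset ", rownames(values)[bad[1, 1]],
         ", sample ", colnames(values)[bad[1, 2]])
  unlabeled <- setdiff(colnames(values), names(groups))
  if (length(unlabeled) > 0)
    stop("sample(s) without group label: ", paste(unlabeled, collapse = ", "))
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  if (sum(groups == "tumor") < 1 || sum(groups == "normal") < 1)
    stop("need at least one tumor and one normal sample")
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "probesets x", ncol(x$values),
      "samples (", sum(x$groups == "tumor"), "tumor /",
      sum(x$groups == "normal"), "normal )\n")
  invisible(x)
}

#' Sample ids of one group
#' @param x an `expr_matrix`.
#' @param group `"tumor"` or `"normal"`.
#' @export
sample_ids <- function(x, group) names(x$groups)[x$groups == group]

#' Read an expression matrix and its sample labels
#'
#' The expression TSV has probeset ids in the first column and one numeric
#' column per sample; the labels TSV has two columns, `sample_id` and `group`
#' (`tumor` or `normal`). Missing or non-numeric cells are a hard error
#' naming the offending cell.
#'
#' @param path expression TSV path.
#' @param labels either a path to the two-column labels TSV or a named
#'   character vector of group labels.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, labels) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    ltab <- utils::read.delim(labels, stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(ltab[[2]]), as.character(ltab[[1]]))
  }
  expr_matrix(values, labels)
}

#' Write an expression matrix and labels to TSV
#'
#' @param x an `expr_matrix`.
#' @param path expression TSV path.
#' @param labels_path optional labels TSV path.
#' @export
write_expression <- function(x, path, labels_path = NULL) {
  tab <- data.frame(probeset_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    ltab <- data.frame(sample_id = names(x$groups), group = unname(x$groups))
    utils::write.table(ltab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Normalize tumor signals to the normal-cohort probeset means
#'
#' The first scoring step: every probeset signal in each individual tumor is
#' re-expressed relative to the mean signal of the same probeset across the
#' normal samples. On the log2 scale this is a subtraction, so the stored
#' value is a log2 fold-change versus the normal mean; a tumor probeset equal
#' to the normal mean maps to 0. Only tumor columns are retained.
#'
#' @param x an `expr_matrix` with at least one normal sample.
#' @return a probeset-by-tumor numeric matrix of class `norm_tumor_matrix`.
#' @export
normalize_to_normal_mean <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  normals <- sample_ids(x, "normal")
  tumors <- sample_ids(x, "tumor")
  if (length(normals) == 0) stop("no normal samples to normalize against")
  normal_mean <- rowMeans(x$values[, normals, drop = FALSE])
  out <- x$values[, tumors, drop = FALSE] - normal_mean
  class(out) <- c("norm_tumor_matrix", class(out))
  out
}

#' Aggregate normalized probeset signals to exon means
#'
#' The second scoring step: for each tumor, the normalized signals of the
#' probesets interrogating one exon are averaged (unweighted arithmetic mean)
#' into a single exon-level value. Output rows follow each gene model's
#' 5' to 3' exon order. Probesets present in the matrix but absent from the
#' models are dropped with a logged count; an exon none of whose probesets
#' appear in the matrix is dropped with a warning.
#'
#' @param norm a `norm_tumor_matrix` from [normalize_to_normal_mean()].
#' @param models a `gene_models` list from [build_gene_models()].
#' @return an object of class `exon_signal_matrix`: a list with `values`
#'   (exon-by-tumor matrix) and `exon_gene` (data.frame mapping each row to
#'   its `exon_id` and `gene_id`).
#' @export
aggregate_exons <- function(norm, models) {
  known <- unlist(lapply(models, gene_probesets), use.names = FALSE)
  extra <- setdiff(rownames(norm), known)
  if (length(extra) > 0)
    message("aggregate_exons: dropping ", length(extra),
            " probeset(s) absent from gene models")
  rows <- list()
  map <- list()
  for (model in models) {
    for (e in model$exons) {
      ps <- intersect(model$probesets_by_exon[[e]], rownames(norm))
      if (length(ps) == 0) {
        warning("exon ", e, " of gene ", model$gene_id,
                " has no probesets in the matrix; dropped")
        next
      }
      rows[[length(rows) + 1L]] <- colMeans(norm[ps, , drop = FALSE])
      map[[length(map) + 1L]] <- c(e, model$gene_id)
    }
  }
  if (length(rows) == 0) stop("no exons could be aggregated")
  values <- do.call(rbind, rows)
  map <- do.call(rbind, map)
  exon_gene <- data.frame(exon_id = map[, 1], gene_id = map[, 2],
                          stringsAsFactors = FALSE)
  rownames(values) <- exon_gene$exon_id
  structure(list(values = values, exon_gene = exon_gene),
            class = "exon_signal_matrix")
}

#' @export
print.exon_signal_matrix <- function(x, ...) {
  cat("exon_signal_matrix:", nrow(x$values), "exons x", ncol(x$values),
      "tumors,", length(unique(x$exon_gene$gene_id)), "genes\n")
  invisible(x)
}
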