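#' Read a probeset annotation table
#'
#' Reads the tab-separated probeset -> exon -> gene annotation used throughout
#' the pipeline and validates its invariants. Coordinates follow the BED
#' convention: 0-based, half-open (`start` inclusive, `end` exclusive).
#'
#' The file must carry a header row naming the seven columns
#' `probeset_id`, `gene_id`, `exon_id`, `chrom`, `start`, `end`, `strand`,
#' `order_index`. Lines starting with `#` are ignored. `order_index` is the
#' position of the probeset along the transcript, counted 5' to 3'.
#'
#' @param path path to the annotation TSV.
#' @return a `data.frame` of class `probeset_annotation`, one row per probeset.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("probeset_id", "gene_id", "exon_id", "chrom",
                "start", "end", "strand", "order_index")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0)
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  ann <- ann[, required]
  for (col in c("start", "end", "order_index")) {
    v <- suppressWarnings(as.integer(ann[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop("malformed ", col, " at annotation line ", bad[1] + 1L,
           " (value '", ann[[col]][bad[1]], "')")
    ann[[col]] <- v
  }
  validate_annotation(ann)
}

#' Validate a probeset annotation
#'
#' Enforces the annotation contract: unique probeset ids, each exon assigned
#' to exactly one gene, `start < end`, strand in `{+,-}`, and unique
#' non-negative `order_index` within each gene. Used by [read_annotation()]
#' and by the simulator; call it directly on hand-built tables.
#'
#' @param ann a data.frame with the seven annotation columns.
#' @return the validated annotation, classed `probeset_annotation`.
#' @export
validate_annotation <- function(ann) {
  dup <- ann$probeset_id[duplicated(ann$probeset_id)]
  if (length(dup) > 0)
    stop("duplicated probeset_id: ", paste(unique(dup), collapse = ", "))
  genes_per_exon <- tapply(ann$gene_id, ann$exon_id,
                           function(g) length(unique(g)))
  multi <- names(genes_per_exon)[genes_per_exon > 1]
  if (length(multi) > 0)
    stop("exon mapped to more than one gene: ", paste(multi, collapse = ", "))
  bad <- which(ann$start >= ann$end)
  if (length(bad) > 0)
    stop("start >= end for probeset ", ann$probeset_id[bad[1]])
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(ann$order_index < 0))
    stop("order_index must be non-negative")
  ord_dup <- tapply(ann$order_index, ann$gene_id, anyDuplicated)
  if (any(ord_dup > 0))
    stop("duplicated order_index within gene: ",
         paste(names(ord_dup)[ord_dup > 0], collapse = ", "))
  class(ann) <- c("probeset_annotation", "data.frame")
  ann
}

#' Write an annotation table to TSV
#'
#' @param ann a `probeset_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with too few probesets
#'
#' Restricts the analysis to genes interrogated by at least `min_probesets`
#' probesets (counted over the whole gene, not per exon), so that the max-min
#' exon score has an intragenic comparison to work with. The default of 3 is
#' the screening threshold used throughout; a single-exon gene with three
#' probesets survives.
#'
#' @param ann a `probeset_annotation`.
#' @param min_probesets minimum probesets per gene (>= 1).
#' @return the filtered annotation. Removed genes are reported via `message()`
#'   with their probeset counts; an empty result raises a warning, not an
#'   error.
#' @export
filter_min_probesets <- function(ann, min_probesets = 3) {
  stopifnot(is.numeric(min_probesets), min_probesets >= 1)
  counts <- table(ann$gene_id)
  drop <- names(counts)[counts < min_probesets]
  if (length(drop) > 0)
    message("filter_min_probesets: dropping ", length(drop), " gene(s): ",
            paste0(drop, " (", counts[drop], ")", collapse = ", "))
  out <- ann[!(ann$gene_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("filter_min_probesets: no genes survive min_probesets = ",
            min_probesets)
  class(out) <- c("probeset_annotation", "data.frame")
  out
}

#' Build per-gene models from an annotation
#'
#' Derives for every gene its ordered exon list and, within each exon, the
#' ordered probeset list. Exons are ordered along the direction of
#' transcription: ascending genomic start on the `+` strand, descending on
#' the `-` strand. Probesets within an exon are ordered by `order_index`.
#'
#' @param ann a validated `probeset_annotation`.
#' @return a named list of gene models (class `gene_models`); each element is
#'   a list with `gene_id`, `strand`, `exons` (exon ids, 5' to 3') and
#'   `probesets_by_exon` (named list of probeset id vectors).
#' @export
build_gene_models <- function(ann) {
  models <- lapply(split(as.data.frame(ann), ann$gene_id), function(g) {
    strand <- g$strand[1]
    exon_start <- tapply(g$start, g$exon_id, min)
    exon_order <- names(sort(exon_start, decreasing = (strand == "-")))
    probesets_by_exon <- lapply(exon_order, function(e) {
      ge <- g[g$exon_id == e, , drop = FALSE]
      ge$probeset_id[order(ge$order_index)]
    })
    names(probesets_by_exon) <- exon_order
    list(gene_id = g$gene_id[1], strand = strand, exons = exon_order,
         probesets_by_exon = probesets_by_exon)
  })
  class(models) <- "gene_models"
  models
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x), "genes,",
      sum(vapply(x, function(m) length(m$exons), 1L)), "exons\n")
  invisible(x)
}

# Ordered probesets of one gene, 5'->3' (exon order then within-exon order).
gene_probesets <- function(model) {
  unlist(model$probesets_by_exon, use.names = FALSE)
}
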