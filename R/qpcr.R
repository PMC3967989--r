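#' Fit a qPCR standard curve
#'
#' Ordinary least-squares fit of Ct against log10 input copy number from a
#' serial-dilution standard series, as used for absolute quantification. A
#' perfectly efficient assay doubles per cycle, giving a slope of
#' -1/log10(2) = -3.3219 Ct per 10-fold dilution and an efficiency of 1.
#'
#' @param copies input copy numbers (strictly positive, >= 3 points).
#' @param ct measured Ct values, same length.
#' @return an object of class `standard_curve` with `slope` (Ct per
#'   log10 copies), `intercept` (Ct at 1 copy), `r_squared`, `efficiency`
#'   (`10^(-1/slope) - 1`) and a logical `valid` flag (FALSE, with a
#'   warning, when the slope is non-negative).
#' @export
fit_standard_curve <- function(copies, ct) {
  if (length(copies) != length(ct)) stop("copies and ct lengths differ")
  if (length(copies) < 3) stop("need at least 3 standard points")
  if (any(!is.finite(copies)) || any(copies <= 0))
    stop("copies must be finite and strictly positive")
  if (any(!is.finite(ct))) stop("ct values must be finite")
  fit <- stats::lm(ct ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  valid <- slope < 0
  if (!valid) warning("standard curve slope is non-negative; flagging curve")
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1, valid = valid),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: slope %.4f, intercept %.2f, R^2 %.4f, efficiency %.3f\n",
    x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' Predicted Ct for a copy number
#' @param copies copy number(s), positive.
#' @param curve a `standard_curve`.
#' @export
predict_ct <- function(copies, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * log10(copies)
}

#' Absolute copy number from a Ct value
#'
#' Inverts the fitted standard curve: `copies = 10^((ct - intercept)/slope)`.
#'
#' @param ct Ct value(s), finite.
#' @param curve a valid `standard_curve` (slope < 0).
#' @export
ct_to_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!isTRUE(curve$valid)) stop("curve has non-negative slope")
  if (any(!is.finite(ct))) stop("ct must be finite")
  10^((ct - curve$intercept) / curve$slope)
}

#' Splicing index of a sample
#'
#' Proportion of the short isoform among total isoform copies:
#' `short / (short + long)`, in `[0, 1]`. Undefined (`NA`) when both copy
#' numbers are zero; such samples are excluded downstream with a logged
#' count. Because any per-sample reference-gene scaling (e.g. 18S
#' normalization) multiplies both channels alike, it cancels in the index.
#'
#' @param short_copies short-isoform absolute copies (>= 0), vectorized.
#' @param long_copies long-isoform (pooled) absolute copies (>= 0).
#' @return numeric vector of indices in `[0, 1]`, `NA` where undefined.
#' @export
splicing_index <- function(short_copies, long_copies) {
  if (any(short_copies < 0, na.rm = TRUE) ||
      any(long_copies < 0, na.rm = TRUE))
    stop("copy numbers must be non-negative")
  total <- short_copies + long_copies
  ifelse(total == 0, NA_real_, short_copies / total)
}

#' Compare splicing indices between tumor and normal cohorts
#'
#' Computes the per-sample splicing index and compares the tumor and normal
#' groups with a two-sided unequal-variance (Welch) two-sample t test, using
#' the Welch-Satterthwaite real-valued degrees of freedom. Samples with an
#' undefined index (zero total copies) are excluded with a logged count.
#'
#' @param table a data.frame with columns `sample_id`, `group` (`tumor` /
#'   `normal`), `short_copies`, `long_copies` and optionally
#'   `reference_copies` (positive; checked but not used — the reference
#'   scalar cancels in the index).
#' @return an object of class `splicing_index_result`: `indices` (named,
#'   per sample), `groups`, `mean_tumor`, `mean_normal`, `n_tumor`,
#'   `n_normal`, `t_statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(table) {
  required <- c("sample_id", "group", "short_copies", "long_copies")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0)
    stop("quant table missing column(s): ", paste(missing, collapse = ", "))
  if (!all(table$group %in% c("tumor", "normal")))
    stop("group must be 'tumor' or 'normal'")
  if ("reference_copies" %in% names(table) &&
      any(table$reference_copies <= 0))
    stop("reference_copies must be strictly positive")
  idx <- splicing_index(table$short_copies, table$long_copies)
  names(idx) <- table$sample_id
  drop <- sum(is.na(idx))
  if (drop > 0)
    message("compare_groups: excluding ", drop,
            " sample(s) with undefined splicing index")
  keep <- !is.na(idx)
  g <- table$group[keep]
  v <- idx[keep]
  if (sum(g == "tumor") < 2 || sum(g == "normal") < 2)
    stop("need >= 2 samples with a defined index in each group")
  tt <- stats::t.test(v[g == "tumor"], v[g == "normal"],
                      var.equal = FALSE, alternative = "two.sided")
  structure(list(
    indices = idx, groups = stats::setNames(table$group, table$sample_id),
    mean_tumor = mean(v[g == "tumor"]), mean_normal = mean(v[g == "normal"]),
    n_tumor = sum(g == "tumor"), n_normal = sum(g == "normal"),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  ), class = "splicing_index_result")
}

#' @export
print.splicing_index_result <- function(x, ...) {
  cat(sprintf(paste0(
    "splicing_index_result: tumor mean %.3f (n=%d), normal mean %.3f ",
    "(n=%d)\n  Welch t = %.3f, df = %.2f, p = %.4g\n"),
    x$mean_tumor, x$n_tumor, x$mean_normal, x$n_normal,
    x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Read an isoform quantification table
#'
#' TSV with columns `sample_id`, `group`, `gene`, `short_copies`,
#' `long_copies`, `reference_copies`.
#'
#' @param path quant TSV path.
#' @return a validated data.frame.
#' @export
read_quant <- function(path) {
  if (!file.exists(path)) stop("quant file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "gene", "short_copies", "long_copies",
                "reference_copies")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("quant table missing column(s): ", paste(missing, collapse = ", "))
  num <- c("short_copies", "long_copies", "reference_copies")
  for (col in num) {
    if (!is.numeric(tab[[col]]) || any(!is.finite(tab[[col]])))
      stop("non-finite values in ", col)
  }
  if (any(tab$short_copies < 0) || any(tab$long_copies < 0))
    stop("copy numbers must be non-negative")
  if (any(tab$reference_copies <= 0))
    stop("reference_copies must be strictly positive")
  tab
}

#' Per-gene Welch comparisons for a multi-gene quant table
#'
#' Runs [compare_groups()] once per gene in the table.
#'
#' @param table a quant data.frame (see [read_quant()]).
#' @return a data.frame with one row per gene: `gene`, `n_tumor`,
#'   `n_normal`, `mean_tumor`, `mean_normal`, `t_statistic`, `df`, `p_value`.
#' @export
validate_all_genes <- function(table) {
  res <- lapply(split(table, table$gene), function(g) {
    r <- compare_groups(g)
    data.frame(gene = g$gene[1], n_tumor = r$n_tumor, n_normal = r$n_normal,
               mean_tumor = r$mean_tumor, mean_normal = r$mean_normal,
               t_statistic = r$t_statistic, df = r$df, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
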