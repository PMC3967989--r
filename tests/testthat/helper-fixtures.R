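# Shared fixtures and independent reference implementations.

# Minimal two-gene annotation: GA has 2 exons x {2,1} probesets ('+'),
# GB has 1 exon x 3 probesets ('-').
tiny_annotation <- function() {
  validate_annotation(data.frame(
    probeset_id = c("pa1", "pa2", "pa3", "pb1", "pb2", "pb3"),
    gene_id = c("GA", "GA", "GA", "GB", "GB", "GB"),
    exon_id = c("GA.E1", "GA.E1", "GA.E2", "GB.E1", "GB.E1", "GB.E1"),
    chrom = "chr1",
    start = c(100L, 160L, 300L, 1000L, 1060L, 1120L),
    end = c(125L, 185L, 325L, 1025L, 1085L, 1145L),
    strand = c("+", "+", "+", "-", "-", "-"),
    order_index = c(0L, 1L, 2L, 2L, 1L, 0L),
    stringsAsFactors = FALSE))
}

# Deterministic tiny expression matrix over tiny_annotation() probesets:
# 2 tumors, 2 normals.
tiny_matrix <- function() {
  values <- matrix(
    c(5.0, 6.0, 5.0, 7.0,   # pa1: tumors 5,6; normals 5,7
      4.0, 8.0, 6.0, 6.0,   # pa2
      1.0, 2.0, 1.5, 2.5,   # pa3
      3.0, 3.0, 3.0, 3.0,   # pb1
      0.0, 1.0, 2.0, 4.0,   # pb2
      9.0, 9.5, 8.0, 8.5),  # pb3
    nrow = 6, byrow = TRUE,
    dimnames = list(c("pa1", "pa2", "pa3", "pb1", "pb2", "pb3"),
                    c("T1", "T2", "N1", "N2")))
  expr_matrix(values, c(T1 = "tumor", T2 = "tumor",
                        N1 = "normal", N2 = "normal"))
}

# Independent naive reference: triple loop (gene, tumor, exon) straight from
# the raw matrix and annotation, no shared code with the pipeline.
naive_mmes <- function(x, ann) {
  normals <- names(x$groups)[x$groups == "normal"]
  tumors <- names(x$groups)[x$groups == "tumor"]
  genes <- sort(unique(ann$gene_id))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(tumors),
                dimnames = list(genes, tumors))
  for (g in genes) {
    rows <- ann[ann$gene_id == g, ]
    for (t in tumors) {
      exon_vals <- c()
      for (e in unique(rows$exon_id)) {
        ps <- rows$probeset_id[rows$exon_id == e]
        vals <- c()
        for (p in ps) {
          nm <- mean(x$values[p, normals])
          vals <- c(vals, x$values[p, t] - nm)
        }
        exon_vals <- c(exon_vals, mean(vals))
      }
      out[g, t] <- max(exon_vals) - min(exon_vals)
    }
  }
  out
}

# Closed-form Welch t test (textbook formulas), independent of stats::t.test.
welch_reference <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Tiny run of the full scoring path: annotation + matrix -> mmes_table.
score_pipeline <- function(x, ann, min_probesets = 1) {
  ann <- suppressMessages(filter_min_probesets(ann, min_probesets))
  models <- build_gene_models(ann)
  exon_signals <- suppressMessages(
    aggregate_exons(normalize_to_normal_mean(x), models))
  mmes_score_all(exon_signals, models)
}
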