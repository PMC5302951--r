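# Differential miRNA expression: per-row two-tailed t-tests at a simple
# p < alpha cutoff (no fold-change filter, no multiplicity correction).

#' Two-sample t-test with degenerate-variance handling
#'
#' Classical two-tailed t-test between two groups of (log-scale) expression
#' values: pooled-variance Student (default), Welch-Satterthwaite, or
#' paired-difference. Inputs with no usable variance (both groups constant,
#' or constant paired differences) are reported as untestable rather than
#' raising an error, so matrix-wide scans never abort on flat rows.
#'
#' @param values_a,values_b numeric vectors (for `mode = "paired"`, equal
#'   length and ordered by patient).
#' @param mode `"pooled"`, `"welch"`, or `"paired"`.
#' @return list with `t`, `df`, `p` (two-tailed), and `testable`; the first
#'   three are `NA` when untestable.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6), mode = "pooled")
#' @export
two_sample_t <- function(values_a, values_b,
                         mode = c("pooled", "welch", "paired")) {
  mode <- match.arg(mode)
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (mode == "paired") {
    if (length(a) != length(b)) {
      stop("paired mode requires equal-length vectors", call. = FALSE)
    }
    if (length(a) < 2L) stop("paired mode requires >= 2 pairs", call. = FALSE)
    if (stats::var(a - b) == 0) {
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  testable = FALSE))
    }
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2L || length(b) < 2L) {
      stop("need >= 2 values per group", call. = FALSE)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  testable = FALSE))
    }
    ht <- stats::t.test(a, b, var.equal = (mode == "pooled"))
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, testable = TRUE)
}

#' Select differentially expressed miRNAs (DEMs) in one dataset
#'
#' Runs a two-tailed t-test per miRNA row between the tumour and normal
#' groups and selects rows with `p < alpha` (strict). `mean_diff` (tumour
#' mean minus normal mean, in the matrix's log-scale units) is recorded for
#' reporting only and never used for selection. Rows constant across all
#' samples are flagged untestable and excluded from DEM totals.
#'
#' @param dataset an [expression_dataset()].
#' @param alpha significance level (default 0.01, strict `<`).
#' @param mode test mode as in [two_sample_t()]; `"paired"` requires the
#'   dataset to carry patient pairings.
#' @param quiet suppress the summary message.
#' @return data.frame with one row per miRNA: `dataset_id`, `mirna`, `t`,
#'   `df`, `p`, `mean_diff`, `selected`, `testable`.
#' @export
select_dems <- function(dataset, alpha = 0.01,
                        mode = c("pooled", "welch", "paired"),
                        quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "expression_dataset"))
  tumor_ids <- names(dataset$groups)[dataset$groups == "TUMOR"]
  normal_ids <- names(dataset$groups)[dataset$groups == "NORMAL"]
  if (mode == "paired") {
    if (is.null(dataset$pairs)) {
      stop("paired mode requires a dataset with patient pairings",
           call. = FALSE)
    }
    # order both groups by patient id so rows align pairwise
    tumor_ids <- tumor_ids[order(dataset$pairs[tumor_ids])]
    normal_ids <- normal_ids[order(dataset$pairs[normal_ids])]
  }
  mat_t <- dataset$matrix[, tumor_ids, drop = FALSE]
  mat_n <- dataset$matrix[, normal_ids, drop = FALSE]
  rows <- lapply(seq_len(nrow(dataset$matrix)), function(i) {
    res <- two_sample_t(mat_t[i, ], mat_n[i, ], mode = mode)
    data.frame(dataset_id = dataset$dataset_id,
               mirna = rownames(dataset$matrix)[i],
               t = res$t, df = res$df, p = res$p,
               mean_diff = mean(mat_t[i, ]) - mean(mat_n[i, ]),
               selected = isTRUE(res$testable) && res$p < alpha,
               testable = res$testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!any(out$testable)) {
    warning(sprintf("select_dems(%s): no testable rows", dataset$dataset_id),
            call. = FALSE)
  }
  if (!quiet) {
    message(sprintf(
      "select_dems(%s): %d/%d rows selected at p < %g (%s mode, %d untestable)",
      dataset$dataset_id, sum(out$selected), nrow(out), alpha, mode,
      sum(!out$testable)))
  }
  out
}
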