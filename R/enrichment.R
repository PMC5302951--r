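# Per-miRNA hypergeometric over-representation of targets in cell-death
# gene sets, and the classified CD-miR set.

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= x)` for `X ~ Hypergeometric(N, M, n)`: the probability
#' that drawing `n` genes without replacement from a universe of `N` genes,
#' of which `M` belong to the category, yields at least `x` category genes.
#' Equivalently `1 - sum_{i=0}^{x-1} C(M,i) C(N-M,n-i) / C(N,n)`, but the
#' upper tail is summed directly in log space (log-binomials via
#' [lchoose()] combined with a log-sum-exp), so small p-values suffer no
#' cancellation and factorials never overflow.
#'
#' @param x observed category count (scalar or vector).
#' @param M category size.
#' @param n draw size (number of targets considered).
#' @param N universe size.
#' @return `P(X >= x)`, a probability in `[0, 1]`; `1` when `x = 0`,
#'   `0` when `x > min(n, M)`.
#' @examples
#' hypergeom_tail_p(2, 4, 3, 10) # 1/3
#' @export
hypergeom_tail_p <- function(x, M, n, N) {
  args <- cbind(x = x, M = M, n = n, N = N) # recycles; validates lengths
  vapply(seq_len(nrow(args)), function(i) {
    hypergeom_tail_p1(args[i, "x"], args[i, "M"], args[i, "n"], args[i, "N"])
  }, numeric(1))
}

hypergeom_tail_p1 <- function(x, M, n, N) {
  if (anyNA(c(x, M, n, N)) || any(c(x, M, n, N) %% 1 != 0)) {
    stop("hypergeom_tail_p: arguments must be integers", call. = FALSE)
  }
  if (x < 0 || n < 0 || M < 0 || x > n || n > N || M > N) {
    stop(sprintf(
      "hypergeom_tail_p: need 0 <= x <= n <= N and 0 <= M <= N (got x=%g, M=%g, n=%g, N=%g)",
      x, M, n, N), call. = FALSE)
  }
  if (x == 0) return(1)
  upper <- min(n, M)
  if (x > upper) return(0)
  i <- x:upper
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  m <- max(lt)
  min(exp(m + log(sum(exp(lt - m)))), 1)
}

#' Enrichment of one miRNA's targets in one cell-death category
#'
#' Assembles the hypergeometric quadruple for a single miRNA and category:
#' `N` = universe size, `M` = category size, `n` = the miRNA's targets
#' inside the universe (or all targets when `restrict_universe = FALSE`),
#' `x` = targets annotated to the category; `p` is the upper tail
#' `P(X >= x)`. A miRNA with no targets inside the universe is flagged
#' untestable (`testable = FALSE`, `p = 1`) rather than dropped, so the
#' universe accounting stays auditable.
#'
#' @param network a `target_network`.
#' @param annotation a `gene_annotation`.
#' @param mirna canonical miRNA id present in the network.
#' @param category `"APOPTOSIS"` or `"AUTOPHAGY"`.
#' @param restrict_universe count only targets inside the annotation
#'   universe as `n` (default). The unrestricted variant mis-specifies the
#'   hypergeometric model (targets outside the universe can never be
#'   category hits) and exists for sensitivity analysis only.
#' @return one-row data.frame: `mirna`, `category`, `N`, `M`, `n`, `x`,
#'   `p`, `testable`.
#' @export
enrich_mirna <- function(network, annotation, mirna,
                         category = CD_CATEGORIES,
                         restrict_universe = TRUE) {
  category <- match.arg(category)
  stopifnot(inherits(network, "target_network"),
            inherits(annotation, "gene_annotation"))
  targets <- network$adjacency[[mirna]]
  if (is.null(targets)) stop("unknown miRNA id: ", mirna, call. = FALSE)
  enrich_one(targets, annotation, mirna, category, restrict_universe)
}

enrich_one <- function(targets, annotation, mirna, category,
                       restrict_universe) {
  in_universe <- targets[targets %in% annotation$universe]
  n <- if (restrict_universe) length(in_universe) else length(targets)
  x <- sum(in_universe %in% annotation$categories[[category]])
  N <- length(annotation$universe)
  M <- length(annotation$categories[[category]])
  testable <- n > 0L
  p <- if (testable) hypergeom_tail_p(x, M, n, N) else 1
  data.frame(mirna = mirna, category = category, N = N, M = M, n = n,
             x = x, p = p, testable = testable, stringsAsFactors = FALSE)
}

#' Enrichment of every network miRNA against both cell-death categories
#'
#' @inheritParams enrich_mirna
#' @return data.frame with one row per miRNA x category, columns as in
#'   [enrich_mirna()].
#' @export
enrich_all <- function(network, annotation, restrict_universe = TRUE) {
  stopifnot(inherits(network, "target_network"),
            inherits(annotation, "gene_annotation"))
  rows <- lapply(network$mirna_universe, function(m) {
    do.call(rbind, lapply(CD_CATEGORIES, function(cat) {
      enrich_one(network$adjacency[[m]], annotation, m, cat,
                 restrict_universe)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the cell-death-related miRNA (CD-miR) set
#'
#' A miRNA is significant for a category when its enrichment p-value is
#' below `alpha` (strict) and it hits at least `min_x` category genes; the
#' count filter guards against single-target artifacts. miRNAs significant
#' for apoptosis only, autophagy only, or both are labelled
#' `APOPTOSIS_ONLY`, `AUTOPHAGY_ONLY`, or `DUAL`; each member is counted
#' once regardless of label.
#'
#' @inheritParams enrich_mirna
#' @param alpha significance level for the enrichment p-value
#'   (default 0.05, strict `<`).
#' @param min_x minimum category-gene hits (default 2).
#' @param adjust `"none"` (default; raw p-values, matching a simple
#'   per-test cutoff) or `"BH"` (Benjamini-Hochberg within each category).
#' @return an object of class `cdmir_set`: list with `labels` (named
#'   character vector, member miRNA -> label), `results` (the full
#'   [enrich_all()] table plus a `significant` column), and `thresholds`.
#' @export
build_cdmir_set <- function(network, annotation, alpha = 0.05, min_x = 2,
                            restrict_universe = TRUE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  res <- enrich_all(network, annotation, restrict_universe)
  p_used <- res$p
  if (adjust == "BH") {
    for (cat in CD_CATEGORIES) {
      idx <- res$category == cat
      p_used[idx] <- stats::p.adjust(res$p[idx], method = "BH")
    }
  }
  res$significant <- res$testable & p_used < alpha & res$x >= min_x
  sig_apop <- res$mirna[res$significant & res$category == "APOPTOSIS"]
  sig_auto <- res$mirna[res$significant & res$category == "AUTOPHAGY"]
  members <- union(sig_apop, sig_auto)
  labels <- ifelse(members %in% sig_apop & members %in% sig_auto, "DUAL",
                   ifelse(members %in% sig_apop, "APOPTOSIS_ONLY",
                          "AUTOPHAGY_ONLY"))
  names(labels) <- members
  structure(list(labels = labels, results = res,
                 thresholds = list(alpha_enrich = alpha, min_x = min_x,
                                   restrict_universe = restrict_universe,
                                   adjust = adjust)),
            class = "cdmir_set")
}

#' Member miRNAs of a CD-miR set
#'
#' @param cdmirs a `cdmir_set`.
#' @return character vector of canonical member ids.
#' @export
cdmir_members <- function(cdmirs) {
  stopifnot(inherits(cdmirs, "cdmir_set"))
  names(cdmirs$labels)
}

#' @export
print.cdmir_set <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("APOPTOSIS_ONLY", "AUTOPHAGY_ONLY", "DUAL")))
  cat(sprintf(
    "cdmir_set: %d miRNAs (apoptosis-only %d, autophagy-only %d, dual %d)\n",
    length(x$labels), tab["APOPTOSIS_ONLY"], tab["AUTOPHAGY_ONLY"],
    tab["DUAL"]))
  cat(sprintf("thresholds: p < %g, x >= %d, %s universe, adjust = %s\n",
              x$thresholds$alpha_enrich, x$thresholds$min_x,
              if (x$thresholds$restrict_universe) "restricted" else "full",
              x$thresholds$adjust))
  invisible(x)
}

#' Write enrichment results and CD-miR labels to TSV
#'
#' @param cdmirs a `cdmir_set`.
#' @param results_path TSV for the per-miRNA, per-category table.
#' @param labels_path optional TSV for the member label table.
#' @export
write_enrichment <- function(cdmirs, results_path, labels_path = NULL) {
  utils::write.table(cdmirs$results, results_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labels_path)) {
    df <- data.frame(mirna = names(cdmirs$labels),
                     label = unname(cdmirs$labels),
                     stringsAsFactors = FALSE)
    df <- df[order(df$mirna), , drop = FALSE]
    utils::write.table(df, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(results_path)
}
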