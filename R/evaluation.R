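# Evaluation of a predicted CD-miR set against a curated known list:
# Monte-Carlo resampling null for the overlap, plus its exact analytic
# twin (the resampled overlap is hypergeometric by construction).

with_preserved_seed <- function(seed, expr) {
  # explicit local seeding; never leaves global RNG state disturbed
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Overlap of a predicted set with a known set inside a universe
#'
#' Restricts both sets to the universe before counting, so miRNAs outside
#' the sampling frame (e.g. known miRNAs with no target predictions) never
#' inflate or deflate the comparison.
#'
#' @param predicted,known,universe character vectors of canonical miRNA ids.
#' @return list with `overlap`, `predicted_size`, `sample_size` (the
#'   known-list size within the universe).
#' @export
observed_overlap <- function(predicted, known, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  predicted <- intersect(unique(predicted), universe)
  known <- intersect(unique(known), universe)
  list(overlap = length(intersect(predicted, known)),
       predicted_size = length(predicted),
       sample_size = length(known))
}

check_overlap_counts <- function(universe_size, predicted_size, sample_size,
                                 observed) {
  if (predicted_size > universe_size || sample_size > universe_size ||
      observed > sample_size || observed > predicted_size ||
      min(universe_size, predicted_size, sample_size, observed) < 0) {
    stop(sprintf(
      "inconsistent overlap counts: universe=%g, predicted=%g, sample=%g, observed=%g",
      universe_size, predicted_size, sample_size, observed), call. = FALSE)
  }
}

#' Monte-Carlo tail probability of a set overlap
#'
#' Draws `n_draws` uniform subsets of size `sample_size` without
#' replacement from a universe of `universe_size` miRNAs and reports the
#' fraction of draws whose intersection with a fixed predicted subset of
#' size `predicted_size` is at least `observed` (inclusive). This is the
#' resampling null of the pipeline's evaluation; its analytic twin is
#' [exact_overlap_tail()]. Reproducible given `seed`; the global RNG state
#' is left untouched.
#'
#' @param universe_size,predicted_size,sample_size,observed overlap counts.
#' @param n_draws number of Monte-Carlo draws (default 10000).
#' @param seed RNG seed for the draws.
#' @return the fraction of draws with overlap `>= observed` (an integer
#'   multiple of `1/n_draws`).
#' @export
mc_overlap_pvalue <- function(universe_size, predicted_size, sample_size,
                              observed, n_draws = 10000L, seed = 1L) {
  check_overlap_counts(universe_size, predicted_size, sample_size, observed)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  # w.l.o.g. the predicted subset is {1, ..., predicted_size}; a uniform
  # subset draw then overlaps it in the count of sampled indices below it
  hits <- with_preserved_seed(seed, {
    sum(vapply(seq_len(n_draws), function(i) {
      sum(sample.int(universe_size, sample_size) <= predicted_size) >=
        observed
    }, logical(1)))
  })
  hits / n_draws
}

#' Exact tail probability of a set overlap
#'
#' Analytic twin of [mc_overlap_pvalue()]: the overlap of a uniform
#' `sample_size`-subset with a fixed `predicted_size`-subset of a
#' `universe_size` universe is hypergeometric, so the tail is
#' `P(X >= observed)` via [hypergeom_tail_p()]. Reported alongside the
#' Monte-Carlo estimate because the latter has granularity `1/n_draws`.
#'
#' @inheritParams mc_overlap_pvalue
#' @return `P(X >= observed)`.
#' @export
exact_overlap_tail <- function(universe_size, predicted_size, sample_size,
                               observed) {
  check_overlap_counts(universe_size, predicted_size, sample_size, observed)
  hypergeom_tail_p(observed, predicted_size, sample_size, universe_size)
}

#' Evaluate a predicted CD-miR set against a known cell-death miRNA list
#'
#' The sampling universe is the set of miRNAs with target predictions
#' (`network$mirna_universe`); the known list is restricted to it, the
#' observed overlap with the predicted set is counted, and both the
#' Monte-Carlo fraction and the exact hypergeometric tail are reported.
#' When some predicted miRNAs fall outside the universe (possible when the
#' prediction and network id spaces differ), a consistency note records
#' the discrepancy instead of silently reconciling it.
#'
#' @param cdmirs a `cdmir_set` (or a character vector of predicted ids).
#' @param known character vector of known cell-death miRNA ids.
#' @param network the `target_network` whose miRNAs form the universe.
#' @param n_draws Monte-Carlo draws (default 10000).
#' @param seed RNG seed.
#' @return an object of class `overlap_evaluation`: list with
#'   `universe_size`, `predicted_size`, `sample_size`, `observed_overlap`,
#'   `n_draws`, `seed`, `mc_fraction`, `exact_tail`, `consistency_note`.
#' @export
evaluate_prediction <- function(cdmirs, known, network,
                                n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(network, "target_network"))
  predicted <- if (inherits(cdmirs, "cdmir_set")) cdmir_members(cdmirs)
               else unique(as.character(cdmirs))
  universe <- network$mirna_universe
  if (length(intersect(known, universe)) == 0L) {
    stop("known list and miRNA universe are disjoint: cannot evaluate ",
         "overlap (check identifier canonicalization)", call. = FALSE)
  }
  ov <- observed_overlap(predicted, known, universe)
  note <- if (length(predicted) != ov$predicted_size) {
    sprintf("%d predicted miRNA(s) outside the %d-miRNA universe (counted set: %d)",
            length(predicted) - ov$predicted_size, length(universe),
            ov$predicted_size)
  } else {
    NA_character_
  }
  structure(
    list(universe_size = length(universe),
         predicted_size = ov$predicted_size,
         sample_size = ov$sample_size,
         observed_overlap = ov$overlap,
         n_draws = as.integer(n_draws),
         seed = as.integer(seed),
         mc_fraction = mc_overlap_pvalue(length(universe), ov$predicted_size,
                                         ov$sample_size, ov$overlap,
                                         n_draws, seed),
         exact_tail = exact_overlap_tail(length(universe), ov$predicted_size,
                                         ov$sample_size, ov$overlap),
         consistency_note = note),
    class = "overlap_evaluation")
}

#' @export
print.overlap_evaluation <- function(x, ...) {
  cat(sprintf(
    "overlap_evaluation: %d of %d known miRNAs recovered by %d predictions (universe %d)\n",
    x$observed_overlap, x$sample_size, x$predicted_size, x$universe_size))
  cat(sprintf("  Monte-Carlo P (>= observed, %d draws, seed %d): %.6g\n",
              x$n_draws, x$seed, x$mc_fraction))
  cat(sprintf("  exact hypergeometric tail: %.6g\n", x$exact_tail))
  if (!is.na(x$consistency_note)) {
    cat("  note:", x$consistency_note, "\n")
  }
  invisible(x)
}

#' Write an overlap evaluation as a one-row TSV
#'
#' @param evaluation an `overlap_evaluation`.
#' @param path output TSV path.
#' @export
write_evaluation <- function(evaluation, path) {
  df <- data.frame(
    universe_size = evaluation$universe_size,
    predicted_size = evaluation$predicted_size,
    sample_size = evaluation$sample_size,
    observed_overlap = evaluation$observed_overlap,
    n_draws = evaluation$n_draws,
    seed = evaluation$seed,
    mc_fraction = evaluation$mc_fraction,
    exact_tail = evaluation$exact_tail,
    consistency_note = evaluation$consistency_note,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
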