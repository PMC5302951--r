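# Intersection of per-dataset DEMs with the CD-miR set, known/novel
# splitting, the candidate report, and pipeline orchestration.

#' Intersect per-dataset DEMs with the CD-miR set
#'
#' The per-dataset candidate set is (selected DEMs) intersect (CD-miR
#' members); the union across datasets implements the "differentially
#' expressed in at least one dataset" rule defining context-specific
#' candidates.
#'
#' @param dem_results list of [select_dems()] data.frames (one per
#'   dataset), or a single such data.frame.
#' @param cdmirs a `cdmir_set`.
#' @return list with `per_dataset` (named list of candidate id vectors) and
#'   `union`.
#' @export
call_candidates <- function(dem_results, cdmirs) {
  stopifnot(inherits(cdmirs, "cdmir_set"))
  if (is.data.frame(dem_results)) dem_results <- list(dem_results)
  if (length(dem_results) == 0L) stop("need >= 1 DEM result", call. = FALSE)
  members <- cdmir_members(cdmirs)
  network_ids <- cdmirs$results$mirna
  all_dem_ids <- unique(unlist(lapply(dem_results, `[[`, "mirna")))
  if (length(intersect(all_dem_ids, unique(network_ids))) == 0L) {
    warning("DEM identifiers and network identifiers are disjoint: ",
            "candidate sets will be empty (check canonicalization)",
            call. = FALSE)
  }
  per_dataset <- lapply(dem_results, function(df) {
    intersect(df$mirna[df$selected], members)
  })
  names(per_dataset) <- vapply(dem_results, function(df) {
    if (nrow(df) > 0L) df$dataset_id[1L] else "empty"
  }, character(1))
  list(per_dataset = per_dataset,
       union = unique(unlist(per_dataset, use.names = FALSE)))
}

#' Split candidate miRNAs into known and novel
#'
#' @param candidates character vector of candidate ids (or a list of such
#'   vectors, split element-wise).
#' @param known character vector of known cell-death miRNA ids.
#' @return list with `known_overlap` and `novel` (for list input, a list of
#'   such pairs).
#' @export
split_known_novel <- function(candidates, known) {
  known <- unique(as.character(known))
  if (is.list(candidates)) {
    return(lapply(candidates, split_known_novel, known = known))
  }
  candidates <- unique(as.character(candidates))
  list(known_overlap = intersect(candidates, known),
       novel = setdiff(candidates, known))
}

#' Build the per-dataset candidate report
#'
#' One row per dataset: the number of selected DEMs, the number also in the
#' CD-miR set, the known/novel split of that intersection, and the novel
#' symbols, ordered by each miRNA's best (smallest) enrichment p-value
#' across the two categories and rendered in symbol dialect
#' (hyphen before `MIR`). `union_novel` deduplicates novel candidates
#' across datasets — the final prediction of the pipeline.
#'
#' @param dem_results list of [select_dems()] data.frames.
#' @param cdmirs a `cdmir_set`.
#' @param known character vector of known cell-death miRNA ids.
#' @return an object of class `candidate_report`: list with `rows` (a
#'   data.frame), `novel_by_dataset`, `union_novel`, and `thresholds`.
#' @export
build_report <- function(dem_results, cdmirs, known) {
  if (is.data.frame(dem_results)) dem_results <- list(dem_results)
  cand <- call_candidates(dem_results, cdmirs)
  known <- unique(as.character(known))
  # best enrichment p per miRNA orders novel symbols most-significant first
  best_p <- tapply(cdmirs$results$p, cdmirs$results$mirna, min)
  order_novel <- function(ids) ids[order(best_p[ids], ids)]
  novel_by_dataset <- list()
  rows <- lapply(seq_along(dem_results), function(k) {
    df <- dem_results[[k]]
    split <- split_known_novel(cand$per_dataset[[k]], known)
    novel <- order_novel(split$novel)
    novel_by_dataset[[names(cand$per_dataset)[k]]] <<- novel
    data.frame(
      dataset_id = names(cand$per_dataset)[k],
      n_dem = sum(df$selected),
      n_dem_and_cd = length(cand$per_dataset[[k]]),
      n_known = length(split$known_overlap),
      n_novel = length(novel),
      novel_symbols = paste(format_mirna_symbol(novel), collapse = ","),
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  union_novel <- order_novel(unique(unlist(novel_by_dataset,
                                           use.names = FALSE)))
  structure(
    list(rows = rows,
         novel_by_dataset = novel_by_dataset,
         union_novel = union_novel,
         thresholds = cdmirs$thresholds),
    class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate report (DEMs, DEM-and-CD-miRs, novel candidates)\n")
  hdr <- sprintf("%-12s %6s %10s %6s %6s  %s",
                 "dataset", "DEM", "DEM&CD", "known", "novel", "novel symbols")
  cat(hdr, "\n")
  for (i in seq_len(nrow(x$rows))) {
    r <- x$rows[i, ]
    cat(sprintf("%-12s %6d %10d %6d %6d  %s\n", r$dataset_id, r$n_dem,
                r$n_dem_and_cd, r$n_known, r$n_novel, r$novel_symbols))
  }
  cat(sprintf("union of novel candidates (%d): %s\n",
              length(x$union_novel),
              paste(format_mirna_symbol(x$union_novel), collapse = ", ")))
  invisible(x)
}

#' Write a candidate report as TSV plus a machine-readable JSON summary
#'
#' @param report a `candidate_report`.
#' @param path output TSV path for the per-dataset rows.
#' @param summary_path optional JSON path for counts, thresholds, and the
#'   novel union.
#' @export
write_report <- function(report, path, summary_path = NULL) {
  utils::write.table(report$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    summary <- list(
      datasets = report$rows$dataset_id,
      n_dem = report$rows$n_dem,
      n_dem_and_cd = report$rows$n_dem_and_cd,
      n_known = report$rows$n_known,
      n_novel = report$rows$n_novel,
      union_novel = as.character(format_mirna_symbol(report$union_novel)),
      thresholds = report$thresholds)
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Run the full CD-miR pipeline on in-memory objects
#'
#' Orchestrates enrichment classification, per-dataset DEM selection,
#' candidate reporting, and the known-list overlap evaluation.
#'
#' @param network a `target_network`.
#' @param annotation a `gene_annotation`.
#' @param datasets list of [expression_dataset()] objects.
#' @param known character vector of known cell-death miRNA ids.
#' @param alpha_enrich,min_x enrichment thresholds (see
#'   [build_cdmir_set()]).
#' @param alpha_dem DEM significance level (see [select_dems()]).
#' @param mode t-test mode.
#' @param n_draws,seed Monte-Carlo settings for the evaluation.
#' @param quiet suppress progress messages.
#' @return list with `cdmirs`, `dems` (list of data.frames), `report`, and
#'   `evaluation`.
#' @export
run_pipeline <- function(network, annotation, datasets, known,
                         alpha_enrich = 0.05, min_x = 2, alpha_dem = 0.01,
                         mode = c("pooled", "welch", "paired"),
                         n_draws = 10000L, seed = 1L, quiet = FALSE) {
  mode <- match.arg(mode)
  cdmirs <- build_cdmir_set(network, annotation, alpha = alpha_enrich,
                            min_x = min_x)
  dems <- lapply(datasets, select_dems, alpha = alpha_dem, mode = mode,
                 quiet = quiet)
  report <- build_report(dems, cdmirs, known)
  evaluation <- evaluate_prediction(cdmirs, known, network,
                                    n_draws = n_draws, seed = seed)
  list(cdmirs = cdmirs, dems = dems, report = report,
       evaluation = evaluation)
}

#' Run the pipeline on a scenario directory and write all outputs
#'
#' Reads the standard file layout written by [gen_scenario()] (`pairs.tsv`,
#' `annotation.tsv`, `universe.txt`, `expr_<id>.tsv` / `design_<id>.tsv`,
#' `known.txt`), runs [run_pipeline()], and writes `enrichment.tsv`,
#' `cdmir_labels.tsv`, `dem_<id>.tsv`, `report.tsv`, `evaluation.tsv` and
#' `summary.json` to `out_dir`. Given the same inputs, configuration and
#' seed, the outputs are byte-identical across runs.
#'
#' @param dir input scenario directory.
#' @param out_dir output directory (created if needed).
#' @inheritParams run_pipeline
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_pipeline_dir <- function(dir, out_dir,
                             alpha_enrich = 0.05, min_x = 2,
                             alpha_dem = 0.01,
                             mode = c("pooled", "welch", "paired"),
                             n_draws = 10000L, seed = 1L, quiet = TRUE) {
  mode <- match.arg(mode)
  network <- read_target_pairs(file.path(dir, "pairs.tsv"), quiet = quiet)
  annotation <- read_gene_annotation(
    file.path(dir, "annotation.tsv"),
    universe_path = file.path(dir, "universe.txt"))
  expr_files <- sort(list.files(dir, pattern = "^expr_.*\\.tsv$"))
  if (length(expr_files) == 0L) {
    stop("no expr_<id>.tsv files in ", dir, call. = FALSE)
  }
  datasets <- lapply(expr_files, function(f) {
    id <- sub("^expr_(.*)\\.tsv$", "\\1", f)
    read_expression(file.path(dir, f),
                    file.path(dir, sprintf("design_%s.tsv", id)),
                    dataset_id = id)
  })
  known <- read_id_list(file.path(dir, "known.txt"))
  res <- run_pipeline(network, annotation, datasets, known,
                      alpha_enrich = alpha_enrich, min_x = min_x,
                      alpha_dem = alpha_dem, mode = mode,
                      n_draws = n_draws, seed = seed, quiet = quiet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_enrichment(res$cdmirs, file.path(out_dir, "enrichment.tsv"),
                   file.path(out_dir, "cdmir_labels.tsv"))
  for (dem in res$dems) {
    utils::write.table(dem,
                       file.path(out_dir,
                                 sprintf("dem_%s.tsv", dem$dataset_id[1L])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_report(res$report, file.path(out_dir, "report.tsv"),
               file.path(out_dir, "summary.json"))
  write_evaluation(res$evaluation, file.path(out_dir, "evaluation.tsv"))
  invisible(res)
}
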