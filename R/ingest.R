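# Readers for the four pipeline inputs. All tabular inputs are TSV with a
# header; '#' lines and blank lines are skipped; column names configurable.

read_tsv_table <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path),
                               call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    blank.lines.skip = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

require_columns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s file %s lacks required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Construct a miRNA-target network from a pair table
#'
#' @param pairs data.frame with miRNA and gene columns (any names; the first
#'   two columns are used). miRNA ids are canonicalized and duplicate pairs
#'   collapsed.
#' @return an object of class `target_network`: a list with `adjacency`
#'   (named list, canonical miRNA id -> character vector of target genes),
#'   `n_pairs` (distinct pair count), `mirna_universe` and `gene_universe`.
#' @export
target_network <- function(pairs) {
  if (!is.data.frame(pairs) || ncol(pairs) < 2L) {
    stop("`pairs` must be a data.frame with at least two columns",
         call. = FALSE)
  }
  mirna <- canonicalize_mirna_id(as.character(pairs[[1L]]))
  gene <- trimws(as.character(pairs[[2L]]))
  keep <- nzchar(gene)
  mirna <- mirna[keep]
  gene <- gene[keep]
  if (length(mirna) == 0L) stop("no valid miRNA-gene pairs", call. = FALSE)
  dup <- duplicated(paste(mirna, gene, sep = "\r"))
  mirna <- mirna[!dup]
  gene <- gene[!dup]
  adjacency <- split(gene, mirna)
  net <- structure(
    list(adjacency = adjacency,
         n_pairs = length(gene),
         mirna_universe = names(adjacency),
         gene_universe = sort(unique(gene))),
    class = "target_network")
  validate_target_network(net)
  net
}

validate_target_network <- function(net) {
  sizes <- lengths(net$adjacency)
  stopifnot(all(sizes > 0L), net$n_pairs == sum(sizes),
            !any(vapply(net$adjacency, anyDuplicated, 1L) > 0L))
  invisible(net)
}

#' Read a miRNA-target pair table
#'
#' Reads a TSV of predicted miRNA-target interactions (one pair per row,
#' e.g. the intersection of two target-prediction algorithms), builds the
#' bipartite adjacency on canonical miRNA ids, and collapses duplicate
#' pairs, including duplicates that only appear after identifier
#' canonicalization merges naming dialects.
#'
#' @param path path to a TSV file with a header row.
#' @param mirna_col,gene_col column names holding the miRNA and gene ids.
#' @param quiet suppress the ingest summary message.
#' @return a [target_network()] object.
#' @export
read_target_pairs <- function(path, mirna_col = "mirna", gene_col = "gene",
                              quiet = FALSE) {
  df <- read_tsv_table(path, "pair table")
  require_columns(df, c(mirna_col, gene_col), "pair table", path)
  if (nrow(df) == 0L) stop("pair table contains zero valid pairs: ", path,
                           call. = FALSE)
  net <- target_network(df[, c(mirna_col, gene_col)])
  if (!quiet) {
    message(sprintf(
      "read_target_pairs: %d distinct pairs, %d miRNAs, %d genes (%s)",
      net$n_pairs, length(net$mirna_universe), length(net$gene_universe),
      path))
  }
  net
}

#' Write a target network back to pair-table form
#'
#' Inverse of [read_target_pairs()]: re-reading the written file reproduces
#' an identical adjacency.
#'
#' @param net a `target_network`.
#' @param path output TSV path.
#' @export
write_target_pairs <- function(net, path) {
  df <- data.frame(
    mirna = rep(names(net$adjacency), lengths(net$adjacency)),
    gene = unlist(net$adjacency, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("target_network: %d miRNAs, %d genes, %d pairs\n",
              length(x$mirna_universe), length(x$gene_universe), x$n_pairs))
  invisible(x)
}

CD_CATEGORIES <- c("APOPTOSIS", "AUTOPHAGY")

#' Construct a gene annotation (universe + cell-death categories)
#'
#' @param universe character vector of gene ids forming the background set.
#' @param apoptosis,autophagy character vectors of annotated gene ids; genes
#'   present in both are the dual-functional set. Both must be subsets of
#'   `universe`.
#' @return an object of class `gene_annotation`: list with `universe` and
#'   `categories` (named list `APOPTOSIS`/`AUTOPHAGY` of gene id vectors).
#' @export
gene_annotation <- function(universe, apoptosis, autophagy) {
  universe <- unique(trimws(as.character(universe)))
  universe <- universe[nzchar(universe)]
  apoptosis <- unique(as.character(apoptosis))
  autophagy <- unique(as.character(autophagy))
  stray <- setdiff(c(apoptosis, autophagy), universe)
  if (length(stray) > 0L) {
    stop(sprintf("annotated gene(s) absent from universe: %s%s",
                 paste(utils::head(stray, 5L), collapse = ", "),
                 if (length(stray) > 5L) ", ..." else ""), call. = FALSE)
  }
  structure(
    list(universe = universe,
         categories = list(APOPTOSIS = apoptosis, AUTOPHAGY = autophagy)),
    class = "gene_annotation")
}

#' Category size summary of a gene annotation
#'
#' @param annotation a `gene_annotation`.
#' @return named integer vector: `N` (universe), `M_apoptosis`,
#'   `M_autophagy`, `M_dual`.
#' @export
annotation_counts <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  c(N = length(annotation$universe),
    M_apoptosis = length(annotation$categories$APOPTOSIS),
    M_autophagy = length(annotation$categories$AUTOPHAGY),
    M_dual = length(intersect(annotation$categories$APOPTOSIS,
                              annotation$categories$AUTOPHAGY)))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cnt <- annotation_counts(x)
  cat(sprintf(
    "gene_annotation: N=%d genes; apoptosis=%d, autophagy=%d, dual=%d\n",
    cnt["N"], cnt["M_apoptosis"], cnt["M_autophagy"], cnt["M_dual"]))
  invisible(x)
}

#' Read a gene-category annotation table
#'
#' Reads a TSV mapping genes to cell-death categories (`APOPTOSIS` or
#' `AUTOPHAGY`; dual-functional genes appear once under each). The gene
#' universe defining the background of the hypergeometric test is, in order
#' of precedence: the explicit universe file (one gene per line) if given,
#' otherwise the union of annotated genes and the `background` vector.
#'
#' @param path path to a TSV with columns `gene` and `category`.
#' @param universe_path optional path to a one-gene-per-line universe file.
#' @param background optional character vector of extra background gene ids
#'   used when no universe file is given.
#' @param gene_col,category_col column names in the annotation file.
#' @return a [gene_annotation()] object.
#' @export
read_gene_annotation <- function(path, universe_path = NULL,
                                 background = NULL,
                                 gene_col = "gene",
                                 category_col = "category") {
  df <- read_tsv_table(path, "annotation")
  require_columns(df, c(gene_col, category_col), "annotation", path)
  if (nrow(df) == 0L) stop("annotation file is empty: ", path, call. = FALSE)
  gene <- trimws(as.character(df[[gene_col]]))
  category <- toupper(trimws(as.character(df[[category_col]])))
  bad <- setdiff(unique(category), CD_CATEGORIES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown category token(s) in %s: %s (expected %s)",
                 path, paste(bad, collapse = ", "),
                 paste(CD_CATEGORIES, collapse = "/")), call. = FALSE)
  }
  universe <- if (!is.null(universe_path)) {
    read_plain_lines(universe_path, "universe")
  } else {
    unique(c(gene, trimws(as.character(background))))
  }
  gene_annotation(universe,
                  apoptosis = gene[category == "APOPTOSIS"],
                  autophagy = gene[category == "AUTOPHAGY"])
}

#' Write a gene annotation to TSV (+ optional universe file)
#'
#' @param annotation a `gene_annotation`.
#' @param path annotation TSV path.
#' @param universe_path optional path for the one-gene-per-line universe.
#' @export
write_gene_annotation <- function(annotation, path, universe_path = NULL) {
  df <- data.frame(
    gene = c(annotation$categories$APOPTOSIS, annotation$categories$AUTOPHAGY),
    category = rep(CD_CATEGORIES, times = lengths(annotation$categories)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(universe_path)) {
    writeLines(annotation$universe, universe_path)
  }
  invisible(path)
}

read_plain_lines <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path),
                               call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop(sprintf("%s file contains no entries: %s", what, path), call. = FALSE)
  }
  lines
}

#' Read a plain list of miRNA identifiers
#'
#' One identifier per line; `#` comment lines and blank lines are skipped.
#' Identifiers are canonicalized and deduplicated, so a file mixing naming
#' dialects for the same molecule yields a single entry.
#'
#' @param path path to the list file.
#' @return character vector of unique canonical miRNA ids.
#' @export
read_id_list <- function(path) {
  unique(canonicalize_mirna_id(read_plain_lines(path, "id list")))
}

#' Construct an expression dataset (matrix + tumour/normal design)
#'
#' @param matrix numeric matrix, rows = miRNAs (rownames are canonicalized),
#'   columns = samples.
#' @param groups character vector (`"TUMOR"`/`"NORMAL"`) named by sample id,
#'   or unnamed in column order.
#' @param pairs optional patient ids named by sample id (or unnamed in
#'   column order); each patient must have exactly one TUMOR and one NORMAL
#'   sample.
#' @param dataset_id label for reporting.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, groups, pairs = NULL,
                               dataset_id = "dataset") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs miRNA rownames and sample colnames",
         call. = FALSE)
  }
  rownames(matrix) <- canonicalize_mirna_id(rownames(matrix))
  groups <- resolve_by_sample(groups, colnames(matrix), "group")
  groups <- toupper(groups)
  bad <- setdiff(unique(groups), c("TUMOR", "NORMAL"))
  if (length(bad) > 0L) {
    stop("group tokens must be TUMOR or NORMAL; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(c("TUMOR", "NORMAL") %in% groups)) {
    stop("both TUMOR and NORMAL groups must be non-empty", call. = FALSE)
  }
  if (!is.null(pairs)) {
    pairs <- resolve_by_sample(pairs, colnames(matrix), "pair")
    tab <- table(pairs, groups)
    if (!all(tab == 1L) || ncol(tab) != 2L) {
      stop("paired design invalid: each patient needs exactly one TUMOR ",
           "and one NORMAL sample", call. = FALSE)
    }
  }
  structure(list(dataset_id = dataset_id, matrix = matrix,
                 groups = groups, pairs = pairs),
            class = "expression_dataset")
}

resolve_by_sample <- function(x, samples, what) {
  x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x))) {
    if (length(x) != length(samples)) {
      stop(sprintf("unnamed %s vector length differs from sample count", what),
           call. = FALSE)
    }
    names(x) <- samples
  }
  missing <- setdiff(samples, names(x))
  if (length(missing) > 0L) {
    stop(sprintf("sample(s) missing a %s assignment: %s", what,
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x[samples]
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset '%s': %d miRNAs x %d samples (%d tumour, %d normal%s)\n",
    x$dataset_id, nrow(x$matrix), ncol(x$matrix),
    sum(x$groups == "TUMOR"), sum(x$groups == "NORMAL"),
    if (!is.null(x$pairs)) ", paired" else ""))
  invisible(x)
}

#' Read an expression matrix with its tumour/normal design
#'
#' The matrix TSV has a header row of sample ids and a first column of
#' miRNA ids; values are assumed pre-normalized on a log scale. The design
#' TSV has columns `sample`, `group` (`TUMOR`/`NORMAL`) and optionally
#' `pair` (patient id for pair-matched cohorts). Rows containing non-finite
#' values are dropped with a warning by default (`on_missing = "drop"`), or
#' rejected (`on_missing = "error"`).
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param design_path path to the design TSV.
#' @param dataset_id label for reporting; defaults to the matrix file name.
#' @param on_missing `"drop"` or `"error"` policy for non-finite values.
#' @return an [expression_dataset()] object.
#' @export
read_expression <- function(matrix_path, design_path,
                            dataset_id = NULL,
                            on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  }
  raw <- read_tsv_table(matrix_path, "expression matrix")
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column",
                           call. = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(raw[[1L]])
  design <- read_tsv_table(design_path, "design")
  require_columns(design, c("sample", "group"), "design", design_path)
  groups <- stats::setNames(as.character(design$group),
                            as.character(design$sample))
  pairs <- if ("pair" %in% names(design)) {
    stats::setNames(as.character(design$pair), as.character(design$sample))
  }
  bad_rows <- !apply(is.finite(mat), 1L, all)
  if (any(bad_rows)) {
    if (on_missing == "error") {
      stop(sprintf("%d row(s) with non-finite values in %s",
                   sum(bad_rows), matrix_path), call. = FALSE)
    }
    warning(sprintf(
      "read_expression(%s): dropped %d row(s) with non-finite values",
      dataset_id, sum(bad_rows)), call. = FALSE)
    mat <- mat[!bad_rows, , drop = FALSE]
  }
  expression_dataset(mat, groups, pairs, dataset_id)
}

#' Write an expression dataset as matrix + design TSVs
#'
#' @param dataset an `expression_dataset`.
#' @param matrix_path,design_path output TSV paths.
#' @export
write_expression <- function(dataset, matrix_path, design_path) {
  df <- data.frame(mirna = rownames(dataset$matrix), dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  design <- data.frame(sample = colnames(dataset$matrix),
                       group = unname(dataset$groups),
                       stringsAsFactors = FALSE)
  if (!is.null(dataset$pairs)) design$pair <- unname(dataset$pairs)
  utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}
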