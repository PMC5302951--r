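# Synthetic-data generators with planted ground truth. These emulate the
# four external inputs of the pipeline -- the target-prediction network,
# the apoptosis/autophagy gene annotation, paired tumour/normal expression
# matrices, and the curated known miRNA list -- so every stage is testable
# against known truth. All generators take explicit seeds and restore the
# global RNG state on exit.

PLANT_LABELS <- c("APOPTOSIS_ONLY", "AUTOPHAGY_ONLY", "DUAL")

#' Generate a gene annotation with controlled category sizes
#'
#' Draws `n_apoptosis + n_autophagy - n_dual` distinct genes from a
#' universe of `n_universe` and partitions them so the two categories
#' overlap in exactly `n_dual` dual-functional genes. Category sizes are
#' exact by construction.
#'
#' @param n_universe universe size (background gene count `N`).
#' @param n_apoptosis,n_autophagy,n_dual category sizes; `n_dual` genes are
#'   annotated to both.
#' @param seed RNG seed.
#' @return a [gene_annotation()] object.
#' @export
gen_annotation <- function(n_universe, n_apoptosis = 807,
                           n_autophagy = 114, n_dual = 25, seed = 1L) {
  if (n_dual > min(n_apoptosis, n_autophagy)) {
    stop("n_dual exceeds a category size", call. = FALSE)
  }
  if (n_apoptosis + n_autophagy - n_dual > n_universe) {
    stop("annotated genes exceed the universe size", call. = FALSE)
  }
  genes <- sprintf("G%05d", seq_len(n_universe))
  annotated <- with_preserved_seed(seed,
    sample(genes, n_apoptosis + n_autophagy - n_dual))
  apop_only <- annotated[seq_len(n_apoptosis - n_dual)]
  auto_only <- annotated[n_apoptosis - n_dual + seq_len(n_autophagy - n_dual)]
  dual <- annotated[n_apoptosis + n_autophagy - 2L * n_dual +
                      seq_len(n_dual)]
  gene_annotation(genes, apoptosis = c(apop_only, dual),
                  autophagy = c(auto_only, dual))
}

#' Generate a target network with planted category-enriched miRNAs
#'
#' Each miRNA receives a degree drawn uniformly from `degree_range` and
#' samples that many distinct target genes. Null miRNAs sample uniformly
#' from the universe (`null_mode = "uniform"`) or from unannotated genes
#' only (`"category_free"`, which forces zero category hits and therefore
#' an exactly known predicted set downstream). A planted miRNA draws each
#' target from its focal category with probability `enrichment_strength`
#' and uniformly otherwise; a `DUAL` miRNA splits that probability evenly
#' between the two categories. For `*_ONLY` labels the focal draws use the
#' category-exclusive genes, since dual-annotated genes would plant signal
#' for the other category and contradict the label. At `enrichment_strength = 1` the category
#' allocation is deterministic (all targets in-category; an even split for
#' `DUAL`), so extreme planting cannot miss the hit-count filter through a
#' rare draw.
#'
#' @param annotation a `gene_annotation` supplying the universe and
#'   categories.
#' @param n_mirnas total miRNA count.
#' @param degree_range integer `c(min, max)` target-set size range.
#' @param planted named integer vector with any of `APOPTOSIS_ONLY`,
#'   `AUTOPHAGY_ONLY`, `DUAL`: how many miRNAs to plant per label.
#' @param enrichment_strength probability in `[0, 1]` that a planted
#'   miRNA's target is drawn from its focal category.
#' @param null_mode `"uniform"` or `"category_free"` (see above).
#' @param seed RNG seed.
#' @return list with `network` (a `target_network`) and `truth` (list with
#'   `labels`, a named vector over all miRNAs including `"NULL"`, and
#'   `table`, a data.frame with per-miRNA degree and per-category hit
#'   tallies).
#' @export
gen_network <- function(annotation, n_mirnas, degree_range = c(20L, 60L),
                        planted = c(APOPTOSIS_ONLY = 0L,
                                    AUTOPHAGY_ONLY = 0L, DUAL = 0L),
                        enrichment_strength = 0.6,
                        null_mode = c("uniform", "category_free"),
                        seed = 1L) {
  null_mode <- match.arg(null_mode)
  stopifnot(inherits(annotation, "gene_annotation"),
            enrichment_strength >= 0, enrichment_strength <= 1)
  planted_full <- stats::setNames(rep(0L, 3L), PLANT_LABELS)
  if (length(planted) > 0L) {
    bad <- setdiff(names(planted), PLANT_LABELS)
    if (length(bad) > 0L) stop("unknown planted label(s): ",
                               paste(bad, collapse = ", "), call. = FALSE)
    planted_full[names(planted)] <- as.integer(planted)
  }
  if (sum(planted_full) > n_mirnas) {
    stop("planted counts exceed n_mirnas", call. = FALSE)
  }
  min_deg <- as.integer(degree_range[1L])
  max_deg <- as.integer(degree_range[2L])
  stopifnot(min_deg >= 1L, max_deg >= min_deg)
  universe <- annotation$universe
  apop <- annotation$categories$APOPTOSIS
  auto <- annotation$categories$AUTOPHAGY
  noncat <- setdiff(universe, c(apop, auto))
  # *_ONLY planting draws focal targets from the category-exclusive genes:
  # dual-annotated genes would otherwise plant signal for the other
  # category too, contradicting the label being planted
  apop_excl <- setdiff(apop, auto)
  auto_excl <- setdiff(auto, apop)
  if (max_deg > length(universe)) {
    stop("degree exceeds universe size", call. = FALSE)
  }
  if (enrichment_strength > 0) {
    if (planted_full["APOPTOSIS_ONLY"] > 0L && max_deg > length(apop_excl)) {
      stop("apoptosis-exclusive gene set too small for requested degrees",
           call. = FALSE)
    }
    if (planted_full["AUTOPHAGY_ONLY"] > 0L && max_deg > length(auto_excl)) {
      stop("autophagy-exclusive gene set too small for requested degrees",
           call. = FALSE)
    }
    if (planted_full["DUAL"] > 0L &&
        max_deg > min(length(apop), length(auto))) {
      stop("a category is too small for requested DUAL degrees",
           call. = FALSE)
    }
  }
  if (null_mode == "category_free" && max_deg > length(noncat)) {
    stop("unannotated gene pool too small for requested degrees",
         call. = FALSE)
  }
  mirnas <- sprintf("HSAMIR%04d", seq_len(n_mirnas))
  labels <- c(rep(PLANT_LABELS, times = planted_full),
              rep("NULL", n_mirnas - sum(planted_full)))
  names(labels) <- mirnas
  s <- enrichment_strength
  gen <- with_preserved_seed(seed, {
    degrees <- sample(seq.int(min_deg, max_deg), n_mirnas, replace = TRUE)
    adjacency <- lapply(seq_len(n_mirnas), function(i) {
      deg <- degrees[i]
      lbl <- labels[i]
      if (lbl == "NULL") {
        pool <- if (null_mode == "category_free") noncat else universe
        return(sample(pool, deg))
      }
      if (lbl == "DUAL") {
        k <- if (s == 1) c(deg %/% 2L, deg - deg %/% 2L, 0L)
             else drop(stats::rmultinom(1L, deg, c(s / 2, s / 2, 1 - s)))
        pool_a <- apop
        pool_b <- auto
      } else if (lbl == "APOPTOSIS_ONLY") {
        ka <- if (s == 1) deg else stats::rbinom(1L, deg, s)
        k <- c(ka, 0L, deg - ka)
        pool_a <- apop_excl
        pool_b <- auto
      } else {
        kb <- if (s == 1) deg else stats::rbinom(1L, deg, s)
        k <- c(0L, kb, deg - kb)
        pool_a <- apop
        pool_b <- auto_excl
      }
      t_a <- sample(pool_a, k[1L])
      t_b <- sample(setdiff(pool_b, t_a), k[2L])
      t_u <- sample(setdiff(universe, c(t_a, t_b)), k[3L])
      c(t_a, t_b, t_u)
    })
    list(degrees = degrees, adjacency = adjacency)
  })
  pairs <- data.frame(
    mirna = rep(mirnas, times = lengths(gen$adjacency)),
    gene = unlist(gen$adjacency, use.names = FALSE),
    stringsAsFactors = FALSE)
  network <- target_network(pairs)
  truth_table <- data.frame(
    mirna = mirnas, label = unname(labels), degree = gen$degrees,
    x_apoptosis = vapply(gen$adjacency, function(t) sum(t %in% apop), 1L),
    x_autophagy = vapply(gen$adjacency, function(t) sum(t %in% auto), 1L),
    stringsAsFactors = FALSE)
  list(network = network,
       truth = list(labels = labels, table = truth_table,
                    params = list(n_mirnas = n_mirnas,
                                  degree_range = c(min_deg, max_deg),
                                  planted = as.list(planted_full),
                                  enrichment_strength = s,
                                  null_mode = null_mode, seed = seed)))
}

#' Generate a paired tumour/normal expression dataset with planted DEMs
#'
#' Gaussian log-scale model: each patient x miRNA has a shared baseline
#' `Normal(mu0, tau)`; the normal sample adds `Normal(0, sigma)` noise, the
#' tumour sample adds the same noise law plus a shift `d * sigma` for
#' planted miRNAs (signed `d` gives up-/down-regulation). The shared
#' baseline induces the within-patient correlation that motivates
#' pair-matched designs; it cancels exactly in paired tests and inflates
#' group variances for unpaired ones.
#'
#' @param mirna_ids character vector of canonical miRNA ids (matrix rows).
#' @param n_pairs number of patients (each contributes one tumour and one
#'   normal sample).
#' @param dem_truth named numeric vector: planted miRNA id -> effect size
#'   `d` in units of `sigma`. Unnamed miRNAs are null.
#' @param sigma residual noise standard deviation.
#' @param tau patient-baseline standard deviation.
#' @param mu0 baseline mean (log-scale expression level).
#' @param dataset_id dataset label.
#' @param seed RNG seed.
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (the `dem_truth` vector).
#' @export
gen_expression <- function(mirna_ids, n_pairs, dem_truth = numeric(0),
                           sigma = 1, tau = 0.5, mu0 = 8,
                           dataset_id = "synthetic", seed = 1L) {
  stopifnot(n_pairs >= 2L, sigma > 0, tau >= 0)
  if (length(dem_truth) > 0L) {
    stopifnot(!is.null(names(dem_truth)),
              all(names(dem_truth) %in% mirna_ids))
  }
  n_mir <- length(mirna_ids)
  shift <- stats::setNames(rep(0, n_mir), mirna_ids)
  shift[names(dem_truth)] <- dem_truth * sigma
  mats <- with_preserved_seed(seed, {
    baseline <- matrix(stats::rnorm(n_mir * n_pairs, mu0, tau),
                       nrow = n_mir)
    normal <- baseline + matrix(stats::rnorm(n_mir * n_pairs, 0, sigma),
                                nrow = n_mir)
    tumor <- baseline + shift +
      matrix(stats::rnorm(n_mir * n_pairs, 0, sigma), nrow = n_mir)
    list(normal = normal, tumor = tumor)
  })
  patients <- sprintf("P%03d", seq_len(n_pairs))
  mat <- cbind(mats$tumor, mats$normal)
  rownames(mat) <- mirna_ids
  colnames(mat) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  groups <- stats::setNames(rep(c("TUMOR", "NORMAL"), each = n_pairs),
                            colnames(mat))
  pairs <- stats::setNames(rep(patients, 2L), colnames(mat))
  list(dataset = expression_dataset(mat, groups, pairs, dataset_id),
       truth = dem_truth)
}

#' Generate a known cell-death miRNA list from planted truth
#'
#' Samples a `coverage` fraction of the planted (non-null) miRNAs and adds
#' `contamination` null miRNAs, emulating a curated list that covers only
#' part of the truth and may carry entries the network cannot support.
#'
#' @param truth the `truth` element of [gen_network()].
#' @param coverage fraction in `[0, 1]` of planted miRNAs to include
#'   (rounded to the nearest count).
#' @param contamination number of null miRNAs to include.
#' @param seed RNG seed.
#' @return character vector of canonical miRNA ids.
#' @export
gen_known_list <- function(truth, coverage = 0.8, contamination = 0L,
                           seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1)
  planted <- names(truth$labels)[truth$labels != "NULL"]
  nulls <- names(truth$labels)[truth$labels == "NULL"]
  if (contamination > length(nulls)) {
    stop("contamination exceeds available null miRNAs", call. = FALSE)
  }
  n_true <- round(coverage * length(planted))
  with_preserved_seed(seed, {
    c(sample(planted, n_true),
      if (contamination > 0L) sample(nulls, contamination))
  })
}

scenario_profiles <- function() {
  list(
    tiny = list(
      n_universe = 50L, n_apoptosis = 12L, n_autophagy = 8L, n_dual = 2L,
      n_mirnas = 20L, degree_range = c(3L, 6L),
      planted = c(APOPTOSIS_ONLY = 4L, AUTOPHAGY_ONLY = 2L, DUAL = 1L),
      enrichment_strength = 0.9, null_mode = "uniform",
      datasets = list(ds1 = list(n_pairs = 6L, n_dem = 5L)),
      dem_effect = 3, sigma = 1, tau = 0.5,
      known_coverage = 0.8, known_contamination = 2L),
    paper_shape = list(
      n_universe = 16163L, n_apoptosis = 807L, n_autophagy = 114L,
      n_dual = 25L,
      n_mirnas = 629L, degree_range = c(20L, 60L),
      planted = c(APOPTOSIS_ONLY = 397L, AUTOPHAGY_ONLY = 17L, DUAL = 96L),
      enrichment_strength = 1, null_mode = "category_free",
      datasets = list(
        batch272 = list(n_pairs = 7L, n_novel = 5L, n_known_cd = 22L,
                        n_noncd = 3L),
        gse6188 = list(n_pairs = 52L, n_novel = 1L, n_known_cd = 19L,
                       n_noncd = 3L),
        gse13937 = list(n_pairs = 38L, n_novel = 4L, n_known_cd = 17L,
                        n_noncd = 4L),
        gse43732 = list(n_pairs = 119L, n_novel = 2L, n_known_cd = 38L,
                        n_noncd = 7L)),
      dem_effect = 3.5, sigma = 1, tau = 0.5,
      known_true = 158L, known_contamination = 18L))
}

#' Generate a complete synthetic scenario (all pipeline inputs + truth)
#'
#' The `"tiny"` profile is a sub-second smoke scenario (20 miRNAs, 50
#' genes, one expression dataset). The `"paper_shape"` profile mirrors the
#' scale typical of esophageal-carcinoma miRNA profiling studies: a
#' 629-miRNA network over a 16,163-gene universe, an 807/114/25
#' apoptosis/autophagy/dual annotation, four paired expression cohorts, and
#' a known list built as 158 planted plus 18 contaminant miRNAs (176 in
#' total) so that, with planting at strength 1 over category-free nulls,
#' the predicted set is exactly the 510 planted miRNAs and the evaluation
#' sees overlap 158 of sample 176 in universe 629 by construction.
#'
#' @param profile `"tiny"` or `"paper_shape"`.
#' @param seed integer master seed; sub-generators use fixed offsets of it.
#' @param out_dir optional directory; when given, all inputs are written in
#'   the standard layout (`pairs.tsv`, `annotation.tsv`, `universe.txt`,
#'   `expr_<id>.tsv`, `design_<id>.tsv`, `known.txt`) plus `truth.tsv`,
#'   `dem_truth.tsv` and `params.json`. A fixed (profile, seed) pair is
#'   byte-reproducible.
#' @return list with `profile`, `seed`, `annotation`, `network`, `truth`,
#'   `datasets` (list of `expression_dataset`), `dem_truth` (per-dataset
#'   named effect vectors), `known`, and `params`, invisibly when writing.
#' @export
gen_scenario <- function(profile = c("tiny", "paper_shape"), seed = 1L,
                         out_dir = NULL) {
  profile <- match.arg(profile)
  prm <- scenario_profiles()[[profile]]
  seed <- as.integer(seed)
  annotation <- gen_annotation(prm$n_universe, prm$n_apoptosis,
                               prm$n_autophagy, prm$n_dual, seed = seed + 1L)
  net <- gen_network(annotation, prm$n_mirnas, prm$degree_range,
                     planted = prm$planted,
                     enrichment_strength = prm$enrichment_strength,
                     null_mode = prm$null_mode, seed = seed + 2L)
  planted_ids <- names(net$truth$labels)[net$truth$labels != "NULL"]
  coverage <- if (!is.null(prm$known_true)) {
    prm$known_true / length(planted_ids)
  } else {
    prm$known_coverage
  }
  known <- gen_known_list(net$truth, coverage = coverage,
                          contamination = prm$known_contamination,
                          seed = seed + 3L)
  mirnas <- net$network$mirna_universe
  null_ids <- names(net$truth$labels)[net$truth$labels == "NULL"]
  novel_pool <- setdiff(planted_ids, known)
  dem_truth <- list()
  datasets <- list()
  ds_seed <- seed + 10L
  plan <- with_preserved_seed(seed + 4L, {
    lapply(prm$datasets, function(ds) {
      planted_dem <- if (!is.null(ds$n_novel)) {
        # Table-1-shaped planting: disjoint novel candidates per dataset,
        # plus known CD-miRs and some non-CD miRNAs
        novel <- sample(novel_pool, ds$n_novel)
        novel_pool <<- setdiff(novel_pool, novel)
        c(novel, sample(intersect(planted_ids, known), ds$n_known_cd),
          sample(null_ids, ds$n_noncd))
      } else {
        sample(mirnas, ds$n_dem)
      }
      stats::setNames(prm$dem_effect * sample(c(-1, 1), length(planted_dem),
                                              replace = TRUE),
                      planted_dem)
    })
  })
  for (id in names(prm$datasets)) {
    ds_seed <- ds_seed + 1L
    gx <- gen_expression(mirnas, prm$datasets[[id]]$n_pairs,
                         dem_truth = plan[[id]], sigma = prm$sigma,
                         tau = prm$tau, dataset_id = id, seed = ds_seed)
    datasets[[id]] <- gx$dataset
    dem_truth[[id]] <- gx$truth
  }
  params <- list(profile = profile, seed = seed, generator = prm)
  scenario <- list(profile = profile, seed = seed, annotation = annotation,
                   network = net$network, truth = net$truth,
                   datasets = datasets, dem_truth = dem_truth,
                   known = known, params = params)
  if (!is.null(out_dir)) {
    write_scenario(scenario, out_dir)
    return(invisible(scenario))
  }
  scenario
}

#' Write a scenario's input files in the standard layout
#'
#' @param scenario a [gen_scenario()] result.
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_target_pairs(scenario$network, file.path(dir, "pairs.tsv"))
  write_gene_annotation(scenario$annotation, file.path(dir, "annotation.tsv"),
                        file.path(dir, "universe.txt"))
  for (id in names(scenario$datasets)) {
    write_expression(scenario$datasets[[id]],
                     file.path(dir, sprintf("expr_%s.tsv", id)),
                     file.path(dir, sprintf("design_%s.tsv", id)))
  }
  writeLines(scenario$known, file.path(dir, "known.txt"))
  utils::write.table(scenario$truth$table, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dem_rows <- do.call(rbind, lapply(names(scenario$dem_truth), function(id) {
    d <- scenario$dem_truth[[id]]
    if (length(d) == 0L) return(NULL)
    data.frame(dataset_id = id, mirna = names(d), effect = unname(d),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dem_rows)) {
    utils::write.table(dem_rows, file.path(dir, "dem_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(scenario$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
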