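test_that("annotation generation hits requested category sizes exactly", {
  ann <- gen_annotation(10000, 807, 114, 25, seed = 2)
  expect_equal(unname(annotation_counts(ann)), c(10000L, 807L, 114L, 25L))
  # full overlap: every autophagy gene is dual
  ann2 <- gen_annotation(100, 10, 10, 10, seed = 2)
  expect_true(all(ann2$categories$AUTOPHAGY %in% ann2$categories$APOPTOSIS))
  expect_equal(unname(annotation_counts(ann2)["M_dual"]), 10L)
  # infeasible requests fail
  expect_error(gen_annotation(100, 10, 5, 8), "n_dual")
  expect_error(gen_annotation(50, 40, 20, 2), "exceed")
})

test_that("network generation respects degrees, labels, and feasibility", {
  ann <- gen_annotation(1000, 80, 40, 10, seed = 3)
  gen <- gen_network(ann, 50, c(5, 15),
                     planted = c(APOPTOSIS_ONLY = 5, AUTOPHAGY_ONLY = 3,
                                 DUAL = 2), enrichment_strength = 0.7,
                     seed = 4)
  expect_equal(length(gen$network$mirna_universe), 50L)
  degrees <- lengths(gen$network$adjacency)
  expect_true(all(degrees >= 5 & degrees <= 15))
  # truth labels partition the miRNA universe
  expect_setequal(names(gen$truth$labels), gen$network$mirna_universe)
  expect_equal(unname(table(gen$truth$labels)[c("APOPTOSIS_ONLY",
                                                "AUTOPHAGY_ONLY", "DUAL")]),
               c(5L, 3L, 2L), ignore_attr = TRUE)
  # degree larger than a supporting pool is refused
  expect_error(gen_network(ann, 10, c(50, 90), planted = c(DUAL = 1),
                           enrichment_strength = 1, seed = 1),
               "too small")
  expect_error(gen_network(ann, 10, c(5, 8), planted = c(DUAL = 20),
                           seed = 1), "exceed n_mirnas")
})

test_that("generator tallies agree with counts recomputed from the network", {
  ann <- gen_annotation(1000, 80, 40, 10, seed = 5)
  gen <- gen_network(ann, 40, c(5, 20),
                     planted = c(APOPTOSIS_ONLY = 6, DUAL = 4),
                     enrichment_strength = 0.8, seed = 6)
  tbl <- gen$truth$table
  for (i in seq_len(nrow(tbl))) {
    targets <- gen$network$adjacency[[tbl$mirna[i]]]
    expect_equal(length(targets), tbl$degree[i])
    expect_equal(sum(targets %in% ann$categories$APOPTOSIS),
                 tbl$x_apoptosis[i])
    expect_equal(sum(targets %in% ann$categories$AUTOPHAGY),
                 tbl$x_autophagy[i])
  }
})

test_that("enrichment strength spans null-equivalence to certain discovery", {
  ann <- gen_annotation(2000, 150, 80, 20, seed = 7)
  # strength 0: "planted" miRNAs are statistically null; discovery stays
  # near the significance level
  gen0 <- gen_network(ann, 400, c(20, 40),
                      planted = c(APOPTOSIS_ONLY = 400),
                      enrichment_strength = 0, seed = 8)
  cdm0 <- build_cdmir_set(gen0$network, ann)
  frac <- length(cdmir_members(cdm0)) / 400
  expect_lte(frac, 0.1 + 3 * sqrt(0.1 * 0.9 / 400)) # two categories tested
  # strength 1 with ample degree: all targets in-category, always found
  gen1 <- gen_network(ann, 20, c(10, 20),
                      planted = c(APOPTOSIS_ONLY = 20),
                      enrichment_strength = 1, seed = 9)
  tbl <- gen1$truth$table
  expect_true(all(tbl$x_apoptosis == tbl$degree))
  cdm1 <- build_cdmir_set(gen1$network, ann)
  expect_setequal(cdmir_members(cdm1), gen1$network$mirna_universe)
  expect_true(all(cdm1$labels == "APOPTOSIS_ONLY"))
})

test_that("category-free nulls never touch annotated genes", {
  ann <- gen_annotation(500, 50, 30, 5, seed = 10)
  gen <- gen_network(ann, 30, c(5, 10), null_mode = "category_free",
                     seed = 11)
  annotated <- unique(unlist(ann$categories))
  hits <- vapply(gen$network$adjacency,
                 function(t) sum(t %in% annotated), 1L)
  expect_true(all(hits == 0L))
})

test_that("expression generation plants signed effects for named rows", {
  ids <- sprintf("HSAMIR%04d", 1:50)
  truth <- c(HSAMIR0001 = 5, HSAMIR0002 = -5)
  gx <- gen_expression(ids, n_pairs = 15, dem_truth = truth, seed = 12)
  expect_equal(rownames(gx$dataset$matrix), ids)
  expect_equal(gx$truth, truth)
  res <- select_dems(gx$dataset, quiet = TRUE)
  expect_true(res$mean_diff[res$mirna == "HSAMIR0001"] > 0)
  expect_true(res$mean_diff[res$mirna == "HSAMIR0002"] < 0)
  # identical seed reproduces the matrix exactly
  gx2 <- gen_expression(ids, n_pairs = 15, dem_truth = truth, seed = 12)
  expect_identical(gx$dataset$matrix, gx2$dataset$matrix)
  # unknown planted id is refused
  expect_error(gen_expression(ids, 5, dem_truth = c(NOPE = 2)))
})

test_that("known-list composition follows coverage and contamination", {
  ann <- gen_annotation(500, 50, 30, 5, seed = 13)
  gen <- gen_network(ann, 40, c(5, 10),
                     planted = c(APOPTOSIS_ONLY = 10), seed = 14)
  planted <- names(gen$truth$labels)[gen$truth$labels != "NULL"]
  k_full <- gen_known_list(gen$truth, coverage = 1, contamination = 0,
                           seed = 15)
  expect_setequal(k_full, planted)
  k_cont <- gen_known_list(gen$truth, coverage = 0, contamination = 5,
                           seed = 15)
  expect_equal(length(intersect(k_cont, planted)), 0L)
  expect_equal(length(k_cont), 5L)
  expect_error(gen_known_list(gen$truth, coverage = 0, contamination = 1000),
               "contamination")
})

test_that("scenario files re-ingest cleanly and are byte-reproducible", {
  d1 <- file.path(tempdir(), "scen-a")
  d2 <- file.path(tempdir(), "scen-b")
  unlink(c(d1, d2), recursive = TRUE)
  gen_scenario("tiny", seed = 19, out_dir = d1)
  gen_scenario("tiny", seed = 19, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # every generated file re-ingests without warnings
  expect_no_warning({
    net <- read_target_pairs(file.path(d1, "pairs.tsv"), quiet = TRUE)
    ann <- read_gene_annotation(file.path(d1, "annotation.tsv"),
                                universe_path = file.path(d1, "universe.txt"))
    ds <- read_expression(file.path(d1, "expr_ds1.tsv"),
                          file.path(d1, "design_ds1.tsv"))
    known <- read_id_list(file.path(d1, "known.txt"))
  })
  s <- gen_scenario("tiny", seed = 19)
  expect_equal(lapply(net$adjacency, sort),
               lapply(s$network$adjacency, sort))
  expect_setequal(known, s$known)
})

test_that("a structure-free pipeline yields a null-calibrated candidate count", {
  # nothing planted anywhere: enrichment significance and DEM selection are
  # independent, so the candidate count is Binomial(n_sig, alpha_dem)
  ann <- gen_annotation(3000, 250, 60, 15, seed = 31)
  gen <- gen_network(ann, 1500, c(20, 50), seed = 32)
  cdm <- build_cdmir_set(gen$network, ann)
  n_sig <- length(cdmir_members(cdm))
  gx <- gen_expression(gen$network$mirna_universe, n_pairs = 10, tau = 0,
                       seed = 33)
  dem <- select_dems(gx$dataset, quiet = TRUE)
  n_cand <- length(call_candidates(list(dem), cdm)$union)
  expected <- 0.01 * n_sig
  slack <- 3 * sqrt(n_sig * 0.01 * 0.99)
  expect_lte(n_cand, expected + slack)
})
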