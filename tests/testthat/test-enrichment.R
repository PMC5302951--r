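test_that("hypergeometric tail matches hand-computed and frozen values", {
  # empty sum: P(X >= 0) = 1
  expect_equal(hypergeom_tail_p(0, 4, 3, 10), 1)
  # enumeration over all C(10,3) subsets gives 40/120
  expect_equal(hypergeom_tail_p(2, 4, 3, 10), 1 / 3, tolerance = 1e-12)
  # hand summation: [C(5,3)C(15,1) + C(5,4)C(15,0)] / C(20,4) = 155/4845
  expect_equal(hypergeom_tail_p(3, 5, 4, 20), 155 / 4845, tolerance = 1e-12)
  # published-scale overlap: value frozen from the log-space summation and
  # confirmed against stats::phyper; below the reported 3.8e-4 bound
  p_big <- hypergeom_tail_p(158, 510, 176, 629)
  expect_equal(p_big, 2.30975962044288e-04, tolerance = 1e-10)
  expect_lte(p_big, 3.8e-4)
})

test_that("tail probabilities equal exhaustive enumeration for all small cases", {
  for (N in 2:9) {
    for (n in 1:N) {
      subsets <- utils::combn(N, n)
      for (M in 0:N) {
        counts <- colSums(subsets <= M)
        for (x in 0:n) {
          expect_equal(hypergeom_tail_p(x, M, n, N), mean(counts >= x),
                       tolerance = 1e-10,
                       label = sprintf("(x=%d,M=%d,n=%d,N=%d)", x, M, n, N))
        }
      }
    }
  }
})

test_that("tail agrees with the distribution-function oracle at scale", {
  set.seed(81)
  for (i in 1:200) {
    N <- sample(20:5000, 1)
    M <- sample(0:N, 1)
    n <- sample(1:N, 1)
    x <- sample(0:n, 1)
    expect_equal(hypergeom_tail_p(x, M, n, N),
                 stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE),
                 tolerance = 1e-12,
                 label = sprintf("(x=%d,M=%d,n=%d,N=%d)", x, M, n, N))
  }
})

test_that("complement, symmetry and monotonicity properties hold", {
  set.seed(42)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    M <- sample(0:N, 1)
    n <- sample(1:N, 1)
    x <- sample(0:n, 1)
    # complement: P(X >= x) + P(X <= x-1) = 1, lower tail by direct sum
    lower <- if (x == 0) 0 else {
      sum(exp(lchoose(M, 0:(x - 1)) + lchoose(N - M, n - (0:(x - 1))) -
                lchoose(N, n)))
    }
    expect_equal(hypergeom_tail_p(x, M, n, N) + lower, 1, tolerance = 1e-9)
    # draw/marked exchangeability
    if (M >= 1 && x <= M) {
      expect_equal(hypergeom_tail_p(x, M, n, N),
                   hypergeom_tail_p(x, n, M, N), tolerance = 1e-12)
    }
  }
  # monotone: p never increases in x, never decreases in M
  p_in_x <- hypergeom_tail_p(0:10, 40, 10, 100)
  expect_true(all(diff(p_in_x) <= 1e-14))
  p_in_M <- vapply(10:90, function(M) hypergeom_tail_p(3, M, 10, 100),
                   numeric(1))
  expect_true(all(diff(p_in_M) >= -1e-14))
})

test_that("domain violations raise errors", {
  expect_error(hypergeom_tail_p(4, 2, 3, 10), "0 <= x <= n <= N")
  expect_error(hypergeom_tail_p(1, 11, 3, 10), "0 <= x <= n <= N")
  expect_error(hypergeom_tail_p(1, 2, 11, 10), "0 <= x <= n <= N")
  expect_error(hypergeom_tail_p(1.5, 2, 3, 10), "integers")
})

test_that("per-miRNA enrichment assembles the hypergeometric quadruple", {
  genes <- sprintf("G%05d", 1:20)
  ann <- gene_annotation(genes, apoptosis = genes[1:5],
                         autophagy = genes[6:7])
  net <- target_network(data.frame(
    mirna = c(rep("m1", 4), rep("m2", 3)),
    gene = c(genes[c(1, 2, 3, 10)], paste0("X", 1:3))))
  res <- enrich_mirna(net, ann, "M1", "APOPTOSIS")
  expect_equal(res[, c("N", "M", "n", "x")],
               data.frame(N = 20L, M = 5L, n = 4L, x = 3L),
               ignore_attr = TRUE)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)

  # all targets outside the universe: untestable, p = 1
  res2 <- enrich_mirna(net, ann, "M2", "APOPTOSIS")
  expect_false(res2$testable)
  expect_equal(res2$p, 1)
  expect_equal(res2$n, 0L)

  # targets in universe but none in category: p = 1, never significant
  net3 <- target_network(data.frame(mirna = "m3", gene = genes[10:14]))
  res3 <- enrich_mirna(net3, ann, "M3", "APOPTOSIS")
  expect_true(res3$testable)
  expect_equal(res3$x, 0L)
  expect_equal(res3$p, 1)

  expect_error(enrich_mirna(net, ann, "NOPE", "APOPTOSIS"), "unknown miRNA")
})

test_that("the universe restriction governs n", {
  genes <- sprintf("G%05d", 1:20)
  ann <- gene_annotation(genes, apoptosis = genes[1:5],
                         autophagy = genes[6:7])
  net <- target_network(data.frame(
    mirna = rep("m1", 5), gene = c(genes[1:3], "X1", "X2")))
  expect_equal(enrich_mirna(net, ann, "M1", "APOPTOSIS")$n, 3L)
  expect_equal(
    enrich_mirna(net, ann, "M1", "APOPTOSIS", restrict_universe = FALSE)$n,
    5L)
})

test_that("CD-miR classification applies both threshold rules", {
  # x = 1 with a tiny p still fails the x >= 2 filter: one apoptotic gene
  # in a 2-of-100 category gives p = 0.02 < 0.05 at a single draw
  genes <- sprintf("G%05d", 1:100)
  ann <- gene_annotation(genes, apoptosis = genes[1:2],
                         autophagy = genes[3:4])
  net <- target_network(data.frame(mirna = "m1", gene = genes[1]))
  expect_equal(enrich_mirna(net, ann, "M1", "APOPTOSIS")$p, 0.02,
               tolerance = 1e-12)
  cdm <- build_cdmir_set(net, ann)
  expect_equal(length(cdmir_members(cdm)), 0L)
})

test_that("classification recovers a planted label partition", {
  ann <- gen_annotation(2000, 120, 60, 15, seed = 21)
  gen <- gen_network(ann, 120, c(15, 30),
                     planted = c(APOPTOSIS_ONLY = 10, AUTOPHAGY_ONLY = 5,
                                 DUAL = 3),
                     enrichment_strength = 0.8, seed = 22)
  cdm <- build_cdmir_set(gen$network, ann)
  planted <- gen$truth$labels[gen$truth$labels != "NULL"]
  got <- cdm$labels[names(planted)]
  expect_gte(mean(!is.na(got) & got == planted), 0.9)
  # label classes are disjoint and sum to the member count
  expect_equal(sum(table(cdm$labels)), length(cdmir_members(cdm)))
  expect_false(any(duplicated(names(cdm$labels))))
})

test_that("dual significance yields the DUAL label, counted once", {
  ann <- gen_annotation(2000, 120, 60, 15, seed = 31)
  gen <- gen_network(ann, 10, c(20, 30), planted = c(DUAL = 4),
                     enrichment_strength = 1, seed = 32)
  cdm <- build_cdmir_set(gen$network, ann)
  planted <- names(gen$truth$labels)[gen$truth$labels == "DUAL"]
  expect_true(all(cdm$labels[planted] == "DUAL"))
  expect_equal(sum(cdmir_members(cdm) %in% planted), 4L)
})
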