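# Independent oracles used across tests.

# Exhaustive subset-enumeration tail probability: drawing n of N genes of
# which the first M are marked, the fraction of all C(N, n) subsets with at
# least x marked genes. Tractable for N <= ~14.
enum_tail_p <- function(x, M, n, N) {
  if (n == 0L) return(as.numeric(x == 0L))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= M) >= x)
}

# Closed-form pooled-variance Student t-test (the hand formula, independent
# of stats::t.test).
pooled_t_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Welch t-test by the hand formulas (Welch-Satterthwaite df).
welch_t_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small real cdmir_set whose members are forced significant: each member
# targets `hits` apoptosis genes in a 40-gene universe with 8 apoptotic
# genes; non-members target unannotated genes only.
make_toy_cdmirs <- function(members, non_members = character(0), hits = 4L) {
  genes <- sprintf("G%05d", 1:40)
  ann <- gene_annotation(genes, apoptosis = genes[1:8],
                         autophagy = genes[9:12])
  rows <- lapply(members, function(m) {
    data.frame(mirna = m, gene = genes[seq_len(hits)])
  })
  rows <- c(rows, lapply(non_members, function(m) {
    data.frame(mirna = m, gene = genes[20:23])
  }))
  net <- target_network(do.call(rbind, rows))
  build_cdmir_set(net, ann)
}

# A fabricated select_dems()-shaped result.
make_dem_result <- function(dataset_id, selected, unselected = character(0)) {
  mirna <- c(selected, unselected)
  data.frame(dataset_id = dataset_id, mirna = mirna,
             t = 0, df = 1, p = rep(c(0.001, 0.5),
                                    c(length(selected), length(unselected))),
             mean_diff = 0,
             selected = rep(c(TRUE, FALSE),
                            c(length(selected), length(unselected))),
             testable = TRUE, stringsAsFactors = FALSE)
}
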