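test_that("pseudobulk aggregation sums counts per type and sample", {
  counts <- Matrix::Matrix(matrix(c(1, 0, 2, 3,
                                    4, 5, 0, 1,
                                    0, 2, 2, 2), nrow = 3, byrow = TRUE),
                           sparse = TRUE)
  rownames(counts) <- c("g1", "g2", "g3")
  colnames(counts) <- paste0("cell", 1:4)
  meta <- data.frame(barcode = paste0("cell", 1:4),
                     cell_type = c("A", "A", "A", "B"),
                     sample = c("s1", "s2", "s1", "s1"),
                     condition = c("CS", "SD", "CS", "CS"))
  agg <- pseudobulkAggregate(counts, meta)
  expect_named(agg, c("A", "B"))
  # hand sums for type A: s1 = cells 1+3, s2 = cell 2
  expect_equal(as.numeric(agg$A[, "s1"]), c(1 + 2, 4 + 0, 0 + 2))
  expect_equal(as.numeric(agg$A[, "s2"]), c(0, 5, 2))
  expect_identical(attr(agg$A, "condition"), c("CS", "SD"))
  # one cell per sample: aggregate equals the input column
  expect_equal(as.numeric(agg$B[, "s1"]), as.numeric(counts[, 4]))
  # conservation within each type
  expect_equal(sum(agg$A), sum(counts[, 1:3]))

  meta$cell_type[2] <- NA
  expect_message(agg2 <- pseudobulkAggregate(counts, meta), "excluded 1")
  expect_equal(sum(agg2$A), sum(counts[, c(1, 3)]))

  meta$condition[3] <- "SD" # sample s1 in two conditions
  expect_error(pseudobulkAggregate(counts, meta), "nested")
})

test_that("DEG thresholds are inclusive for 'deg' and strict for 'overlap'", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    cell_type = "T1",
                    log2fc = c(0.1375, 0.10, -0.31, 0.3),
                    fdr = c(0.05, 0.001, 0.05, 0.049))
  deg <- filterDegs(tab, preset = "deg")
  expect_identical(deg$is_deg, c(TRUE, FALSE, TRUE, TRUE))
  ov <- filterDegs(tab, preset = "overlap")
  # log2(1.23) ~ 0.2987: |lfc| must exceed it and FDR must be < 0.05
  expect_identical(ov$is_deg, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(filterDegs(tab[, -3]), "missing columns")
})

test_that("DEG shares per class sum to one and count per type-row", {
  classMap <- c(T1 = "ExIT", T2 = "ExIT", T3 = "IN")
  deg <- data.frame(gene = sprintf("g%d", 1:40),
                    cell_type = rep(c("T1", "T2", "T3"), c(20, 10, 10)))
  sh <- degShareByClass(deg, classMap)
  expect_equal(unname(sh["ExIT"]), 0.75)
  expect_equal(sum(sh), 1, tolerance = 1e-12)

  one <- degShareByClass(data.frame(gene = "g", cell_type = "T3"), classMap)
  expect_equal(unname(one["IN"]), 1)

  expect_error(degShareByClass(data.frame(gene = "g", cell_type = "T9"),
                               classMap), "T9")
})

test_that("conditional DEG probability is a per-type rate with class ratios", {
  census <- data.frame(cell_type = c("A", "B"), class = c("ExIT", "IN"),
                       n_genes_expressed = c(10000, 5000))
  deg <- data.frame(gene = c(sprintf("g%d", 1:30), sprintf("h%d", 1:5)),
                    cell_type = rep(c("A", "B"), c(30, 5)))
  res <- conditionalDegProbability(census, deg)
  expect_equal(res$perType$probability, c(0.003, 0.001))
  ratios <- setNames(res$perClass$ratio_to_best_other, res$perClass$class)
  expect_equal(unname(ratios["ExIT"]), 3)

  # a type with no DEGs has probability zero
  census2 <- rbind(census, data.frame(cell_type = "C", class = "IN",
                                      n_genes_expressed = 2000))
  res2 <- conditionalDegProbability(census2, deg)
  expect_equal(res2$perType$probability[res2$perType$cell_type == "C"], 0)

  # invariant to duplicating a type's counts
  census3 <- census
  census3$n_genes_expressed <- census3$n_genes_expressed * 2
  deg3 <- rbind(deg, deg)
  res3 <- conditionalDegProbability(census3, deg3)
  expect_equal(res3$perType$probability, res$perType$probability)

  census4 <- rbind(census, data.frame(cell_type = "Z", class = "IN",
                                      n_genes_expressed = 0))
  expect_warning(conditionalDegProbability(census4, deg), "Z")
})

test_that("gene-set overlap tests match brute-force enumeration on small universes", {
  universe <- sprintf("G%02d", 1:20)
  geneSet <- universe[1:6]
  degs <- universe[c(4:8, 15)]
  res <- genesetOverlapTest(degs, geneSet, universe)
  expect_equal(res$overlap, 3)
  expect_equal(res$fold, 3 / (6 * 6 / 20))
  # brute force: enumerate every possible DEG draw of the same size
  combos <- utils::combn(20, 6)
  overlaps <- colSums(combos <= 6)
  expect_equal(res$hyperP, mean(overlaps >= 3), tolerance = 1e-12)

  disjoint <- genesetOverlapTest(universe[1:5], universe[6:10], universe)
  expect_equal(disjoint$overlap, 0)
  expect_equal(disjoint$hyperP, 1)

  same <- genesetOverlapTest(universe[1:5], universe[1:5], universe)
  expect_equal(same$fold, 20 / 5)

  expect_error(genesetOverlapTest("a", "b", character()), "empty")
})

test_that("symbols are harmonized case-insensitively with logged drops", {
  universe <- c("Dcc", "Gpc6", "Grin3a", "Kif17")
  expect_message(res <- genesetOverlapTest(c("DCC", "dcc"), c("gpc6", "DCC"),
                                           universe), "collisions")
  expect_equal(res$overlap, 1)
  expect_message(genesetOverlapTest("NotAGene", "Gpc6", universe), "dropped")
})

test_that("the k-set intersection p-value reduces to the hypergeometric tail", {
  for (N in c(8, 15)) {
    for (n1 in c(2, 5)) for (n2 in c(3, 7)) for (obs in 0:min(n1, n2)) {
      got <- multisetIntersectionP(c(n1, n2), N, observed = obs)$p.value
      ref <- if (obs <= 0) 1 else
        stats::phyper(obs - 1, n1, N - n1, n2, lower.tail = FALSE)
      expect_equal(got, min(1, ref), tolerance = 1e-12)
    }
  }
})

test_that("the 3-set intersection distribution matches exact enumeration", {
  # universe of 6; enumerate all (A, B, C) with sizes (3, 3, 2)
  N <- 6
  a <- utils::combn(N, 3)
  b <- utils::combn(N, 3)
  c3 <- utils::combn(N, 2)
  sizes <- numeric()
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    ab <- intersect(a[, i], b[, j])
    for (k in seq_len(ncol(c3))) {
      sizes <- c(sizes, length(intersect(ab, c3[, k])))
    }
  }
  for (obs in 0:2) {
    got <- multisetIntersectionP(c(3, 3, 2), N, observed = obs)$p.value
    expect_equal(got, mean(sizes >= obs), tolerance = 1e-12)
  }
  # expected size under independence
  got <- multisetIntersectionP(c(3, 3, 2), N, observed = 1)
  expect_equal(got$expected, 6 * (3 / 6) * (3 / 6) * (2 / 6), tolerance = 1e-12)

  expect_error(multisetIntersectionP(c(3, 9), 6, observed = 1), "larger")
  expect_error(multisetIntersectionP(list(letters[1:3]), 6), "two sets")
  # character sets: observed computed internally
  got2 <- multisetIntersectionP(list(c("a", "b", "c"), c("b", "c"),
                                     c("c", "d")), 6)
  expect_equal(got2$observed, 1)
})

test_that("UMI tables are matched across conditions and detect inflation", {
  perSample <- expand.grid(cell_type = sprintf("T%02d", 1:17),
                           sample = c("s1", "s2", "s3"),
                           condition = c("CS", "SD"),
                           stringsAsFactors = FALSE)
  perSample$sample <- paste(perSample$condition, perSample$sample)
  base <- rep(seq(2000, 8000, length.out = 17), 6)
  set.seed(5)
  perSample$median_umi <- base * ifelse(perSample$condition == "SD", 1.15, 1) *
    exp(rnorm(nrow(perSample), sd = 0.02))
  tab <- umiPerNucleusTable(perSample)
  expect_equal(nrow(tab$matchedMedians), 17L)
  w <- wilcoxonMatchedPairs(tab$matchedMedians$SD, tab$matchedMedians$CS,
                            alternative = "greater")
  expect_lt(w$p.value, 0.01)

  # identical medians in both conditions: all ties
  flat <- perSample
  flat$median_umi <- base
  tabF <- umiPerNucleusTable(flat)
  expect_error(wilcoxonMatchedPairs(tabF$matchedMedians$CS,
                                    tabF$matchedMedians$SD), "AllTies")

  # a type missing one condition is excluded with a warning
  part <- perSample[!(perSample$cell_type == "T01" &
                        perSample$condition == "SD"), ]
  expect_warning(tabP <- umiPerNucleusTable(part), "T01")
  expect_equal(nrow(tabP$matchedMedians), 16L)

  empty <- umiPerNucleusTable(perSample[0, ])
  expect_equal(nrow(empty$matchedMedians), 0L)
})

test_that("gene lists read one symbol per line, ignoring comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# curated list", "Dcc", "Gpc6", "", "Dcc", "Kif17"), path)
  expect_identical(readGeneSet(path), c("Dcc", "Gpc6", "Kif17"))
  expect_error(readGeneSet("no/such/file.txt"), "not found")
})
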