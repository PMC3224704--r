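make_toy_training <- function(n_per_class = 30, sep = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  df <- data.frame(upstream = sprintf("u%d", 1:n),
                   downstream = sprintf("d%d", 1:n),
                   class_score = NA_real_, cd_score = NA_real_,
                   ic_sim = NA_real_, conservation = 0L,
                   distance = c(rnorm(n_per_class, 0), rnorm(n_per_class, sep)),
                   r = c(rnorm(n_per_class, sep), rnorm(n_per_class, 0)),
                   label = rep(c("KOP", "NOP"), each = n_per_class))
  class(df) <- c("pair_features", "data.frame")
  df
}

test_that("AUC equals the Mann-Whitney statistic with half ties", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with trapezoidal ROC integration", {
  set.seed(23)
  for (i in 1:500) {
    n <- sample(10:60, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c(TRUE, FALSE)
    sc <- round(rnorm(n), sample(0:2, 1))   # rounding provokes ties
    roc <- roc_curve(sc, lab)
    trap <- sum(diff(roc$fpr) * (head(roc$recall, -1) + tail(roc$recall, -1)) / 2)
    expect_equal(auc(sc, lab), trap, tolerance = 1e-10)
  }
})

test_that("paired AUC comparison follows the one-tailed t distribution", {
  expect_equal(compare_auc_paired_ttest(c(0.9, 0.8), c(0.9, 0.8)), 0.5)
  a <- c(0.90, 0.91, 0.92, 0.93)
  b <- a - c(0.02, 0.03, 0.04, 0.03)
  d <- c(0.02, 0.03, 0.04, 0.03)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(compare_auc_paired_ttest(a, b),
               pt(t_oracle, df = 3, lower.tail = FALSE))
  expect_equal(compare_auc_paired_ttest(c(0.9, 0.8), c(0.85, 0.75)), 0)
  expect_error(compare_auc_paired_ttest(1:3 / 10, 1:4 / 10), "length")
})

test_that("a separable toy problem is classified perfectly", {
  pf <- make_toy_training(sep = 6)
  model <- train_classifier(pf, c("distance", "r"), "linear")
  scores <- predict(model, pf)
  expect_true(all(scores[pf$label == "KOP"] > 0))
  expect_true(all(scores[pf$label == "NOP"] < 0))
  expect_error(train_classifier(pf[pf$label == "KOP", ], c("distance", "r")),
               "both KOP and NOP")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  pf <- make_toy_training(n_per_class = 60, sep = 3, seed = 2)
  set.seed(31)
  pf$label <- sample(pf$label)
  cv <- cross_validate(pf, c("distance", "r"), "radial", seed = 31)
  expect_gte(cv$mean_auc, 0.35)
  expect_lte(cv$mean_auc, 0.65)
})

test_that("duplicating every positive leaves a separable linear margin alone", {
  pf <- make_toy_training(n_per_class = 20, sep = 8, seed = 3)
  probe <- make_toy_training(n_per_class = 15, sep = 8, seed = 4)
  m1 <- train_classifier(pf, c("distance", "r"), "linear", cost = 100)
  dup <- rbind(pf, pf[pf$label == "KOP", ])
  class(dup) <- class(pf)
  m2 <- train_classifier(dup, c("distance", "r"), "linear", cost = 100)
  s1 <- predict(m1, probe)
  s2 <- predict(m2, probe)
  expect_equal(s1, s2, tolerance = 0.05)
})

test_that("cross-validation is deterministic given the seed", {
  pf <- make_toy_training(n_per_class = 25, sep = 2, seed = 5)
  cv1 <- cross_validate(pf, c("distance", "r"), "radial", seed = 99)
  cv2 <- cross_validate(pf, c("distance", "r"), "radial", seed = 99)
  expect_identical(cv1$fold_aucs, cv2$fold_aucs)
  expect_identical(cv1$scores, cv2$scores)
  expect_equal(cv1$mean_auc, mean(cv1$fold_aucs))
  expect_length(cv1$fold_aucs, 10L)
  tiny <- pf[c(1:5, 26:30), ]
  class(tiny) <- class(pf)
  expect_error(cross_validate(tiny, c("distance", "r")), "at least 10")
})

test_that("genome prediction is stateless in pair order", {
  pf <- make_toy_training(sep = 5, seed = 6)
  model <- train_classifier(pf, c("distance", "r"), "radial")
  expect_length(predict_genome(model, pf[0, ]), 0L)
  perm <- sample(nrow(pf))
  s <- predict_genome(model, pf)
  expect_equal(predict_genome(model, pf[perm, ]), s[perm])
})

test_that("chaining positive pairs partitions the genome into units", {
  genes <- make_genes(start = c(100, 400, 800, 1300),
                      end = c(300, 700, 1200, 1500), strand = "+")
  pairs <- same_strand_adjacent_pairs(genes)
  map <- chain_operons(genes, pairs, c(TRUE, TRUE, FALSE))
  expect_equal(unname(lengths(map$units)), c(3L, 1L))
  expect_equal(map$units[[1]], c("g1", "g2", "g3"))

  mono <- chain_operons(genes, pairs, c(FALSE, FALSE, FALSE))
  expect_equal(length(mono$units), 4L)

  all_pos <- chain_operons(genes, pairs, c(TRUE, TRUE, TRUE))
  expect_equal(length(all_pos$units), 1L)
})

test_that("unit count equals gene count minus positive calls", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    starts <- cumsum(sample(50:500, n, replace = TRUE))
    ends <- starts + sample(30:200, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    genes <- make_genes(starts, ends, strands)
    pairs <- same_strand_adjacent_pairs(genes)
    calls <- runif(nrow(pairs)) < 0.5
    map <- chain_operons(genes, pairs, calls)
    expect_equal(length(map$units), n - sum(calls))
    expect_setequal(unlist(map$units), genes$gene_id)        # partition
    expect_equal(sum(lengths(map$units)), n)
  }
})

test_that("operon maps round-trip through TSV and export valid GFF3", {
  genes <- make_genes(start = c(100, 400, 800), end = c(300, 700, 1200),
                      strand = "+")
  pairs <- same_strand_adjacent_pairs(genes)
  map <- chain_operons(genes, pairs, c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_operon_map(map, path)
  back <- read_operon_map(path)
  expect_identical(back$units, map$units)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_operon_gff3(map, genes, gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  expect_length(lines, 1L + length(map$units))
  first <- strsplit(lines[2], "\t")[[1]]
  expect_identical(first[c(1, 3, 4, 5, 7)],
                   c("chr", "transcript", "100", "700", "+"))
})

test_that("minus-strand units are reported in transcription order", {
  genes <- make_genes(start = c(100, 400, 800), end = c(300, 700, 1200),
                      strand = "-")
  pairs <- same_strand_adjacent_pairs(genes)
  map <- chain_operons(genes, pairs, c(TRUE, TRUE))
  expect_equal(map$units[[1]], c("g3", "g2", "g1"))
})
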