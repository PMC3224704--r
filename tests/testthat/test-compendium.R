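test_that("expression tables round-trip through TSV with absent sentinels", {
  vals <- matrix(c(1.5, 2, 3, -0.25, 5, 6), 3, 2,
                 dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  mask <- matrix(FALSE, 3, 2)
  mask[2, 1] <- TRUE
  ds <- expression_dataset(vals, mask, "cDNA_gDNA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(ds, path)
  back <- read_expression_table(path, "cDNA_gDNA")
  expect_identical(back$absent_mask, ds$absent_mask)
  expect_equal(back$values[!mask], ds$values[!mask])
  expect_identical(sum(back$absent_mask), 1L)
})

test_that("malformed expression tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\ts1\ts2", path)
  expect_error(read_expression_table(path), "no data rows")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2\t3"), path)
  expect_error(read_expression_table(path), "ragged")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression_table(path), "duplicate")
})

test_that("filter statistics cover the gene union with correct conventions", {
  ds1 <- make_ds(matrix(c(1, 2, 3, 0, 0, 0), 2, 3, byrow = TRUE,
                        dimnames = list(c("gA", "gB"), NULL)),
                 matrix(c(rep(FALSE, 3), rep(TRUE, 3)), 2, 3, byrow = TRUE))
  ds2 <- make_ds(matrix(c(4, 5), 1, 2, dimnames = list("gC", NULL)),
                 platform = "cDNA_cDNA")
  st <- compute_filter_stats(ds1, ds2, probeset_genes = c("gA", "gC"))
  stA <- st[st$gene_id == "gA", ]
  expect_equal(stA$a, 0)
  expect_equal(stA$b, 1)          # sample sd of (1,2,3)
  expect_equal(st[st$gene_id == "gB", "a"], 1)   # fully masked
  expect_equal(st[st$gene_id == "gC", "a"], 1)   # absent from ds1 entirely
  expect_false(st[st$gene_id == "gB", "e"])      # not on the probeset
  expect_true(st[st$gene_id == "gC", "e"])
})

test_that("gene selection evaluates both disjuncts of the boolean filter", {
  # population of sd values puts the 25th percentile well below 1
  base <- data.frame(gene_id = sprintf("bg%d", 1:20),
                     a = 0.1, b = seq(1, 2, length.out = 20),
                     c = 0.1, d = seq(1, 2, length.out = 20),
                     e = TRUE, n1 = 10L, n2 = 10L)
  probe <- function(a, b, c, d, e)
    rbind(base, data.frame(gene_id = "probe", a = a, b = b, c = c, d = d,
                           e = e, n1 = 10L, n2 = 10L))
  # first disjunct: low absent fraction and high sd in dataset 1
  expect_true("probe" %in% select_genes(probe(0.10, 1.5, 0.30, 0, TRUE)))
  # e = FALSE defeats both disjuncts
  expect_false("probe" %in% select_genes(probe(0.10, 1.5, 0.10, 1.5, FALSE)))
  # second disjunct: passes via dataset 2 despite mediocre dataset-1 signal
  expect_true("probe" %in% select_genes(probe(0.25, 0, 0.15, 1.5, TRUE)))
  # fails both: too many absent calls in dataset 1
  expect_false("probe" %in% select_genes(probe(0.60, 1.5, 0.25, 1.5, TRUE)))
  expect_error(select_genes(base[0, ]), "empty")
})

test_that("relaxing the strict absent threshold can only grow the selection", {
  set.seed(7)
  st <- data.frame(gene_id = sprintf("g%d", 1:300),
                   a = runif(300), b = rexp(300),
                   c = runif(300), d = rexp(300),
                   e = runif(300) < 0.8, n1 = 10L, n2 = 10L)
  sel1 <- select_genes(st, filter_thresholds(absent_strict = 0.10))
  sel2 <- select_genes(st, filter_thresholds(absent_strict = 0.20))
  sel3 <- select_genes(st, filter_thresholds(absent_strict = 0.40))
  expect_true(all(sel1 %in% sel2))
  expect_true(all(sel2 %in% sel3))
})

test_that("k-NN imputation fills masked cells from present neighbours", {
  vals <- matrix(c(1, 2, 3,
                   1.1, 2.1, 3.1,
                   0.9, 1.9, 99,
                   5, 1, 2), 4, 3, byrow = TRUE)
  mask <- matrix(FALSE, 4, 3)
  mask[3, 3] <- TRUE
  ds <- make_ds(vals, mask)
  out <- impute_missing_knn(ds, k = 2)
  expect_false(any(out$absent_mask))
  # two nearest genes by profile are rows 1 and 2, present at sample 3
  expect_equal(out$values[3, 3], mean(c(3, 3.1)))
  expect_identical(out$values[!mask], vals[!mask])  # present cells untouched

  ident <- impute_missing_knn(make_ds(vals), k = 2)
  expect_identical(ident$values, make_ds(vals)$values)

  twin_vals <- matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE)
  twin_mask <- matrix(FALSE, 2, 3); twin_mask[1, 2] <- TRUE
  twin <- impute_missing_knn(make_ds(twin_vals, twin_mask), k = 1)
  expect_equal(twin$values[1, 2], 2)

  bad_mask <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3,
                     byrow = TRUE)
  expect_error(impute_missing_knn(make_ds(twin_vals, bad_mask)), "g01")
})

test_that("imputed values stay within the neighbour range", {
  set.seed(11)
  for (rep in 1:20) {
    vals <- matrix(rnorm(20 * 8), 20, 8)
    mask <- matrix(runif(160) < 0.1, 20, 8)
    mask[rowSums(!mask) == 0, ] <- FALSE
    ds <- make_ds(vals, mask)
    out <- impute_missing_knn(ds, k = 3)
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 2]
      pres <- vals[!mask[, s], s]
      expect_gte(out$values[idx[r, 1], s], min(pres) - 1e-12)
      expect_lte(out$values[idx[r, 1], s], max(pres) + 1e-12)
    }
  }
})

test_that("z-standardization yields exact zero mean and unit sd rows", {
  ds <- make_ds(matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(z_standardize(ds)$values[1, ]), c(-1, 0, 1))
  set.seed(3)
  big <- make_ds(matrix(rnorm(50 * 12, sd = 4, mean = 7), 50, 12))
  z <- z_standardize(big)
  expect_true(all(abs(rowMeans(z$values)) < 1e-10))
  expect_true(all(abs(apply(z$values, 1, sd) - 1) < 1e-10))
  expect_equal(z_standardize(z)$values, z$values, tolerance = 1e-12)
  expect_error(z_standardize(make_ds(matrix(c(2, 2, 2), 1, 3))), "g01")
})

test_that("concatenation respects order, identity and sample uniqueness", {
  a <- make_ds(matrix(1:6, 2, 3,
                      dimnames = list(c("gA", "gB"), c("a1", "a2", "a3"))))
  b <- make_ds(matrix(7:10, 2, 2,
                      dimnames = list(c("gA", "gB"), c("b1", "b2"))),
               platform = "cDNA_cDNA")
  cc <- concat_datasets(list(a, b))
  expect_identical(colnames(cc$values), c("a1", "a2", "a3", "b1", "b2"))
  expect_identical(concat_datasets(list(a))$values, a$values)
  disj <- make_ds(matrix(1:4, 2, 2,
                         dimnames = list(c("gX", "gY"), c("c1", "c2"))))
  expect_error(concat_datasets(list(a, disj)), "no genes common")
  clash <- make_ds(matrix(1:4, 2, 2,
                          dimnames = list(c("gA", "gB"), c("a1", "c2"))))
  expect_error(concat_datasets(list(a, clash)), "overlapping sample ids")
})
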