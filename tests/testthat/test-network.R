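test_that("MI estimation is symmetric and rank-invariant", {
  set.seed(51)
  x <- rnorm(200); y <- 0.8 * x + 0.6 * rnorm(200)
  expect_lt(abs(estimate_mi(x, y) - estimate_mi(y, x)), 1e-9)
  # strictly monotone transforms leave the copula untouched
  expect_equal(estimate_mi(exp(x), y), estimate_mi(x, y))
  expect_equal(estimate_mi(x, y^3), estimate_mi(x, y))
  expect_error(estimate_mi(rep(1, 200), y), "constant")
  expect_error(estimate_mi(x[1:10], y[1:10]), "at least 30")
})

test_that("self-dependency dominates MI over a matrix of profiles", {
  set.seed(52)
  m <- matrix(rnorm(20 * 100), 20, 100)
  x <- m[1, ]
  others <- apply(m[-1, ], 1, function(r) estimate_mi(x, r))
  expect_gt(estimate_mi(x, x), max(others))
})

test_that("the permutation-null threshold is monotone and tail-calibrated", {
  set.seed(53)
  vals <- matrix(rnorm(30 * 120), 30, 120,
                 dimnames = list(sprintf("c%02d", 1:30), NULL))
  cx <- structure(list(values = vals), class = "cistron_expr")
  t_hi <- mi_threshold_from_pvalue(cx, 1e-4, n_perm = 1e4, seed = 3)
  t_lo <- mi_threshold_from_pvalue(cx, 1e-6, n_perm = 1e4, seed = 3)
  expect_gt(as.numeric(t_lo), as.numeric(t_hi))
  t_all <- mi_threshold_from_pvalue(cx, 1, n_perm = 1e4, seed = 3)
  expect_lte(as.numeric(t_all), as.numeric(t_hi))
})

test_that("the exponential tail fit recovers a known null law", {
  set.seed(54)
  null <- rexp(1e5, rate = 1 / 0.02)    # survival exp(-m / 0.02)
  fit <- cistronet:::fit_exponential_tail(null)
  mi0 <- fit$lambda * (fit$alpha - log(1e-6))
  expect_lt(abs(mi0 - 0.02 * log(1e6)) / (0.02 * log(1e6)), 0.20)
})

test_that("DPI pruning follows the strict tolerance rule", {
  tri <- data.frame(a = c("x", "x", "y"), b = c("y", "z", "z"),
                    mi = c(0.5, 0.4, 0.1))
  kept <- apply_dpi(tri, 0.05)
  expect_equal(nrow(kept), 2L)
  expect_false(any(kept$mi == 0.1))
  # an edge exactly at (1 - eps) * min survives the strict inequality
  eps <- 0.05
  tri2 <- data.frame(a = c("x", "x", "y"), b = c("y", "z", "z"),
                     mi = c(0.5, 0.4, (1 - eps) * 0.4))
  expect_equal(nrow(apply_dpi(tri2, eps)), 3L)
  chain <- data.frame(a = c("x", "y"), b = c("y", "z"), mi = c(0.5, 0.1))
  expect_identical(apply_dpi(chain, 0.2), chain)
})

brute_force_dpi <- function(edges, eps) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi <- setNames(edges$mi, key(edges$a, edges$b))
  nodes <- unique(c(edges$a, edges$b))
  drop <- character()
  if (length(nodes) >= 3) {
    combs <- combn(sort(nodes), 3)
    for (i in seq_len(ncol(combs))) {
      v <- combs[, i]
      k <- c(key(v[1], v[2]), key(v[1], v[3]), key(v[2], v[3]))
      if (!all(k %in% names(mi))) next
      m <- mi[k]
      for (e in 1:3) if (m[e] < (1 - eps) * min(m[-e])) drop <- c(drop, k[e])
    }
  }
  edges[!key(edges$a, edges$b) %in% drop, , drop = FALSE]
}

test_that("DPI matches a brute-force all-triangles oracle", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", 1:n)
    all_pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(all_pairs)) < 0.25
    edges <- data.frame(a = all_pairs[keep, 1], b = all_pairs[keep, 2],
                        mi = runif(sum(keep), 0.01, 1))
    for (eps in c(0, 0.05, 0.2)) {
      got <- apply_dpi(edges, eps)
      want <- brute_force_dpi(edges, eps)
      expect_equal(got[order(got$a, got$b), ],
                   want[order(want$a, want$b), ], ignore_attr = TRUE)
    }
  }
})

test_that("zero tolerance prunes a superset of the default tolerance", {
  set.seed(56)
  for (i in 1:20) {
    nodes <- sprintf("n%d", 1:12)
    all_pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(all_pairs)) < 0.4
    edges <- data.frame(a = all_pairs[keep, 1], b = all_pairs[keep, 2],
                        mi = runif(sum(keep)))
    key <- function(e) paste(e$a, e$b)
    expect_true(all(key(apply_dpi(edges, 0)) %in% key(apply_dpi(edges, 0.05))))
  }
})

test_that("cistron aggregation averages member rows and drops empty units", {
  vals <- matrix(c(1, -1, 0, 3, 1, 0, 7, 8, 9), 3, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  expr <- expression_dataset(vals)
  map <- structure(list(units = list(TU1 = c("g1", "g2"), TU2 = "g3",
                                     TU3 = "g9"),
                        gene2unit = c(g1 = "TU1", g2 = "TU1", g3 = "TU2",
                                      g9 = "TU3")),
                   class = "operon_map")
  cx <- aggregate_cistron_expression(map, expr)
  expect_equal(unname(cx$values["TU1", ]), c(2, 0, 0))
  expect_equal(unname(cx$values["TU2", ]), c(7, 8, 9))
  expect_false("TU3" %in% rownames(cx$values))
})

test_that("a cistron is a regulator cistron when any member is flagged", {
  genes <- make_genes(start = c(1, 100, 200), end = c(50, 150, 250),
                      strand = "+", regulator = c(TRUE, FALSE, FALSE))
  map <- structure(list(units = list(TU1 = c("g1", "g2"), TU2 = "g3"),
                        gene2unit = c(g1 = "TU1", g2 = "TU1", g3 = "TU2")),
                   class = "operon_map")
  expect_equal(select_regulator_cistrons(map, genes), "TU1")
  genes$regulator <- c(TRUE, TRUE, TRUE)
  expect_setequal(select_regulator_cistrons(map, genes), c("TU1", "TU2"))
})

test_that("a hub with planted targets is recovered and DPI keeps hub edges", {
  set.seed(57)
  n <- 200
  hub <- rnorm(n)
  targets <- t(vapply(1:5, function(i) hub + 0.3 * rnorm(n), numeric(n)))
  noise <- matrix(rnorm(6 * n), 6, n)
  vals <- rbind(hub, targets, noise)
  rownames(vals) <- c("hub", sprintf("t%d", 1:5), sprintf("x%d", 1:6))
  cx <- structure(list(values = vals), class = "cistron_expr")
  net <- build_network(cx, "hub", network_config(p_threshold = 1e-6,
                                                 n_null_permutations = 1e4),
                       seed = 58)
  connected <- unique(c(net$edges$a, net$edges$b))
  expect_true(all(sprintf("t%d", 1:5) %in% connected))
  expect_true(all(net$edges$a == "hub" | net$edges$b == "hub"))
})

test_that("independent profiles produce few edges at nominal significance", {
  set.seed(59)
  vals <- matrix(rnorm(40 * 100), 40, 100,
                 dimnames = list(sprintf("c%02d", 1:40), NULL))
  cx <- structure(list(values = vals), class = "cistron_expr")
  regs <- sprintf("c%02d", 1:10)
  net <- build_network(cx, regs, network_config(p_threshold = 0.01,
                                                n_null_permutations = 1e4),
                       seed = 60)
  n_pairs <- 10 * 39 - choose(10, 2)
  expect_lte(nrow(net$edges), 0.01 * n_pairs * 3 + 5)
})

test_that("duplicate regulator profiles keep their mutual edge under DPI", {
  set.seed(61)
  r1 <- rnorm(120)
  vals <- rbind(r1 = r1, r2 = r1, t1 = r1 + 0.4 * rnorm(120),
                x1 = rnorm(120))
  cx <- structure(list(values = vals), class = "cistron_expr")
  net <- build_network(cx, c("r1", "r2"), network_config(p_threshold = 1e-4,
                                                         n_null_permutations = 1e4),
                       seed = 62)
  key <- paste(pmin(net$edges$a, net$edges$b),
               pmax(net$edges$a, net$edges$b))
  expect_true("r1 r2" %in% key)
})

test_that("the degree power law is fit on the log-log histogram", {
  # counts 400/k^2 over k in {1,2,4,5,10,20} form an exact power law
  k <- c(1, 2, 4, 5, 10, 20)
  deg <- rep(k, times = 400 / k^2)
  fit <- fit_degree_powerlaw(deg)
  expect_equal(fit$exponent, -2, tolerance = 1e-10)
  expect_error(fit_degree_powerlaw(rep(3, 10)), "at least 3")
  set.seed(63)
  g <- igraph::sample_pa(500, m = 2, directed = FALSE)
  pa_fit <- fit_degree_powerlaw(igraph::degree(g))
  expect_gte(pa_fit$exponent, -3.5)
  expect_lte(pa_fit$exponent, -1.5)
})

test_that("extract_modules yields hub-centred member sets", {
  edges <- data.frame(a = c("h1", "h1", "h1", "h2"),
                      b = c("t1", "t2", "t3", "t1"),
                      mi = c(0.5, 0.6, 0.7, 0.4))
  net <- structure(list(edges = edges, nodes = c("h1", "h2", "h3",
                                                 "t1", "t2", "t3"),
                        regulators = c("h1", "h2", "h3"), mi0 = 0.1,
                        config = NULL),
                   class = "regulatory_network")
  mods <- extract_modules(net)
  expect_equal(length(mods), 2L)          # h3 has no edges, no module
  expect_equal(length(mods$h1$members), 4L)
  expect_true("t1" %in% mods$h1$members && "t1" %in% mods$h2$members)
})
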