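#' Network inference settings
#'
#' @param p_threshold Significance level mapped to a mutual-information
#'   threshold by permutation-null tail extrapolation (default `1e-9`).
#' @param dpi_tolerance Data-processing-inequality tolerance \eqn{\epsilon}
#'   in `[0, 1)` (default 0.05): within a triangle an edge is pruned only
#'   when its MI falls below \eqn{(1-\epsilon)} times the smaller of the
#'   other two.
#' @param n_null_permutations Permutations used to build the null MI sample
#'   (default `1e5`).
#' @return A list of class `network_config`.
#' @export
network_config <- function(p_threshold = 1e-9, dpi_tolerance = 0.05,
                           n_null_permutations = 1e5) {
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0, 1)")
  if (!(dpi_tolerance >= 0 && dpi_tolerance < 1)) stop("dpi_tolerance must be in [0, 1)")
  structure(list(p_threshold = p_threshold, dpi_tolerance = dpi_tolerance,
                 n_null_permutations = n_null_permutations),
            class = "network_config")
}

#' Average gene expression to the cistron level
#'
#' One profile per transcription unit with at least one member present in
#' the expression matrix: the unweighted mean of the member rows. Units with
#' no selected member are dropped.
#'
#' @param operons An `operon_map`.
#' @param expr The standardized concatenated [expression_dataset()].
#' @param selected_genes Genes eligible for averaging (default: all rows of
#'   `expr`).
#' @return Object of class `cistron_expr`: `values` (cistron x sample
#'   matrix) and `members` (named list of the genes averaged per cistron).
#' @export
aggregate_cistron_expression <- function(operons, expr,
                                         selected_genes = rownames(expr$values)) {
  stopifnot(inherits(operons, "operon_map"), inherits(expr, "expr_dataset"))
  selected_genes <- intersect(selected_genes, rownames(expr$values))
  members <- lapply(operons$units, intersect, y = selected_genes)
  members <- members[lengths(members) > 0L]
  vals <- t(vapply(members, function(g)
    colMeans(expr$values[g, , drop = FALSE]), numeric(ncol(expr$values))))
  colnames(vals) <- colnames(expr$values)
  structure(list(values = vals, members = members), class = "cistron_expr")
}

#' @export
print.cistron_expr <- function(x, ...) {
  cat(sprintf("<cistron_expr> %d cistrons x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Cistrons containing at least one regulator gene
#'
#' @param operons An `operon_map`.
#' @param genes A `gene_table` with populated `regulator` flags.
#' @return Character vector of regulator cistron ids.
#' @export
select_regulator_cistrons <- function(operons, genes) {
  reg_genes <- genes$gene_id[genes$regulator]
  names(operons$units)[vapply(operons$units,
                              function(g) any(g %in% reg_genes), logical(1L))]
}

#' Copula transform of a profile
#'
#' Ranks scaled to the open unit interval (average ranks for ties), making
#' downstream MI estimation invariant to strictly monotone transforms of
#' the profile.
#'
#' @param x Numeric profile; constant profiles are rejected.
#' @return Values in (0, 1).
#' @export
copula_transform <- function(x) {
  if (stats::sd(x) == 0) stop("constant profile has no copula transform")
  rank(x, ties.method = "average") / (length(x) + 1)
}

mi_bandwidth <- function(u) {
  # Silverman reference rule for the bivariate case, shrunk by 0.7: MI is a
  # density *functional*, and undersmoothing relative to the density-MSE
  # optimum reduces the downward bias on strong dependencies.
  0.7 * stats::sd(u) * length(u)^(-1 / 6)
}

#' Mutual information between two profiles (copula kernel estimator)
#'
#' Copula-transforms each profile and estimates MI in nats with a Gaussian
#' product-kernel density estimate evaluated at the sample points, clamped
#' at zero. Deterministic given its inputs.
#'
#' @param x,y Numeric profiles of equal length (at least 30 samples).
#' @return Estimated MI in nats, non-negative.
#' @export
estimate_mi <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 30L) stop("need at least 30 samples for MI estimation")
  u <- copula_transform(x)
  v <- copula_transform(y)
  cpp_mi_pair(u, v, mi_bandwidth(u))
}

#' Map a significance level to an MI threshold by permutation null
#'
#' Builds a null MI sample by repeatedly permuting the pairing between
#' randomly chosen profile pairs from the matrix, fits an exponential tail
#' `log P(MI > m) = alpha - m / lambda` to the upper decile of the null, and
#' returns the MI value whose extrapolated tail probability equals `p`.
#' Levels far below the permutation resolution (such as `1e-9`) are reached
#' by this extrapolation. `p >= 1` returns the minimum of the null sample.
#'
#' @param cx A `cistron_expr` (or any matrix-bearing list with `values`).
#' @param p Significance level.
#' @param n_perm Total permutations (at least `1e4` for a stable tail).
#' @param seed Integer seed.
#' @param n_profile_pairs Number of distinct row pairs over which the
#'   permutations are spread.
#' @return MI threshold in nats, with the fitted `alpha` and `lambda` as
#'   attributes.
#' @export
mi_threshold_from_pvalue <- function(cx, p, n_perm = 1e5, seed = 1,
                                     n_profile_pairs = 100) {
  vals <- if (is.matrix(cx)) cx else cx$values
  if (nrow(vals) < 2L) stop("need at least two profiles")
  if (any(apply(vals, 1L, stats::sd) == 0))
    stop("degenerate (constant) profile in matrix")
  set.seed(seed)
  npair <- min(n_profile_pairs, choose(nrow(vals), 2L))
  per_pair <- ceiling(n_perm / npair)
  null <- vector("list", npair)
  for (b in seq_len(npair)) {
    ij <- sample.int(nrow(vals), 2L)
    u <- copula_transform(vals[ij[1L], ])
    v <- copula_transform(vals[ij[2L], ])
    null[[b]] <- cpp_mi_null(u, v, mi_bandwidth(u), per_pair)
  }
  null <- unlist(null)[seq_len(max(n_perm, 1L))]
  if (p >= 1) return(structure(min(null), alpha = NA_real_, lambda = NA_real_))
  fit <- fit_exponential_tail(null)
  structure(max(0, fit$lambda * (fit$alpha - log(p))),
            alpha = fit$alpha, lambda = fit$lambda, null_q99 = stats::quantile(null, 0.99, names = FALSE))
}

fit_exponential_tail <- function(null, tail_fraction = 0.10) {
  s <- sort(null, decreasing = TRUE)
  k <- max(10L, ceiling(length(s) * tail_fraction))
  m <- s[seq_len(k)]
  surv <- (seq_len(k) - 0.5) / length(s)       # P(MI > m_(i))
  keep <- m > 0
  if (sum(keep) < 3L) stop("null upper tail is degenerate")
  fit <- stats::lm(log(surv[keep]) ~ m[keep])
  lambda <- -1 / unname(stats::coef(fit)[2L])
  if (!is.finite(lambda) || lambda <= 0) stop("null tail is not decaying")
  list(alpha = unname(stats::coef(fit)[1L]), lambda = lambda)
}

#' Prune indirect edges with the data-processing inequality
#'
#' For every triangle in the graph, the edge `(i,j)` is marked for removal
#' when `MI_ij < (1 - tolerance) * min(MI_ik, MI_jk)` (strict inequality).
#' All triangles are evaluated against the original edge set and marked
#' edges are deleted afterwards, so the pruning is order-independent.
#'
#' @param edges Data frame with columns `a`, `b`, `mi` describing a simple
#'   undirected graph.
#' @param tolerance DPI tolerance \eqn{\epsilon} in `[0, 1)`.
#' @return The pruned edge data frame.
#' @export
apply_dpi <- function(edges, tolerance = 0.05) {
  if (!nrow(edges)) return(edges)
  if (any(edges$a == edges$b)) stop("self-edge in network")
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  tri <- igraph::triangles(g)
  if (!length(tri)) return(edges)
  vn <- igraph::V(g)$name
  tri <- matrix(vn[tri], ncol = 3L, byrow = TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  mi <- stats::setNames(edges$mi, key(edges$a, edges$b))
  drop <- character()
  for (t in seq_len(nrow(tri))) {
    k <- c(key(tri[t, 1L], tri[t, 2L]),
           key(tri[t, 1L], tri[t, 3L]),
           key(tri[t, 2L], tri[t, 3L]))
    m <- mi[k]
    for (e in 1:3)
      if (m[e] < (1 - tolerance) * min(m[-e])) drop <- c(drop, k[e])
  }
  edges[!key(edges$a, edges$b) %in% drop, , drop = FALSE]
}

#' Infer the regulator-centered mutual-information network
#'
#' Estimates MI between every regulator cistron and every other cistron
#' (regulator-regulator pairs counted once, no self-pairs), keeps pairs at
#' or above the MI threshold mapped from `config$p_threshold`, then applies
#' DPI pruning. Every surviving edge touches at least one regulator.
#'
#' @param cx A `cistron_expr`.
#' @param regulators Character vector of regulator cistron ids (must be rows
#'   of `cx$values`).
#' @param config A [network_config()].
#' @param seed Seed for the permutation-null calibration.
#' @param mi0 Optional precomputed MI threshold; skips calibration.
#' @return Object of class `regulatory_network`: `edges` (`a`, `b`, `mi`),
#'   `nodes`, `regulators`, `mi0` and `config`. An empty edge set is a valid
#'   result, not an error.
#' @export
build_network <- function(cx, regulators, config = network_config(), seed = 1,
                          mi0 = NULL) {
  stopifnot(inherits(cx, "cistron_expr"))
  vals <- cx$values
  regulators <- intersect(regulators, rownames(vals))
  if (!length(regulators)) stop("no regulator cistron present in the matrix")
  if (is.null(mi0))
    mi0 <- mi_threshold_from_pvalue(cx, config$p_threshold,
                                    n_perm = config$n_null_permutations,
                                    seed = seed)
  U <- t(apply(vals, 1L, copula_transform))
  ridx <- match(regulators, rownames(vals))
  M <- cpp_mi_matrix(U, ridx, mi_bandwidth(U[1L, ]))
  rownames(M) <- regulators
  colnames(M) <- rownames(vals)
  idx <- which(M >= as.numeric(mi0), arr.ind = TRUE)
  edges <- data.frame(a = regulators[idx[, 1L]],
                      b = rownames(vals)[idx[, 2L]],
                      mi = M[idx], row.names = NULL)
  k <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b), sep = "\r")
  edges <- edges[!duplicated(k) & edges$a != edges$b, , drop = FALSE]
  edges <- apply_dpi(edges, config$dpi_tolerance)
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = rownames(vals),
                 regulators = regulators, mi0 = as.numeric(mi0),
                 config = config),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d edges over %d connected cistrons (%d regulators; MI threshold %.4f nats)\n",
              nrow(x$edges), length(unique(c(x$edges$a, x$edges$b))),
              length(x$regulators), x$mi0))
  invisible(x)
}

#' Hub-centered network modules
#'
#' One module per regulator cistron with at least one surviving edge: the
#' hub plus its direct neighbours. A cistron may appear in several modules.
#'
#' @param net A `regulatory_network`.
#' @return Named list of modules, each a list with `hub` and `members`
#'   (hub included).
#' @export
extract_modules <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  mods <- list()
  for (hub in net$regulators) {
    nb <- unique(c(net$edges$b[net$edges$a == hub],
                   net$edges$a[net$edges$b == hub]))
    if (!length(nb)) next
    mods[[hub]] <- list(hub = hub, members = c(hub, setdiff(nb, hub)))
  }
  mods
}

#' Fit a power law to the regulator degree distribution
#'
#' Ordinary least squares of `log p(k)` on `log k` over the empirical degree
#' distribution of regulator nodes with degree >= 1 (zero-probability
#' degrees excluded), mirroring the `p = coefficient * k^exponent` form.
#'
#' @param net A `regulatory_network`, or a numeric vector of degrees.
#' @return List of class `degree_fit` with `coefficient`, `exponent` and the
#'   support (`k`, `p`).
#' @export
fit_degree_powerlaw <- function(net) {
  deg <- if (inherits(net, "regulatory_network")) {
    ends <- c(net$edges$a, net$edges$b)
    counts <- table(factor(ends, levels = net$regulators))
    as.numeric(counts[counts > 0])
  } else as.numeric(net[net > 0])
  tab <- table(deg)
  k <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(deg)
  if (length(k) < 3L) stop("need at least 3 distinct degree values")
  fit <- stats::lm(log(p) ~ log(k))
  structure(list(coefficient = exp(unname(stats::coef(fit)[1L])),
                 exponent = unname(stats::coef(fit)[2L]), k = k, p = p),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("<degree_fit> p = %.3g * k^%.3f over %d support points\n",
              x$coefficient, x$exponent, length(x$k)))
  invisible(x)
}

#' Write a network as a simple-interaction-format (SIF) file
#' @param net A `regulatory_network`.
#' @param path Output path.
#' @export
write_sif <- function(net, path) {
  writeLines(sprintf("%s\tmi\t%s", net$edges$a, net$edges$b), path)
  invisible(path)
}

#' Write the per-module MI matrix as TSV
#'
#' One row per (module, member) with the MI between member and hub.
#'
#' @param net A `regulatory_network`.
#' @param path Output path.
#' @export
write_module_mi <- function(net, path) {
  mods <- extract_modules(net)
  rows <- lapply(names(mods), function(h) {
    e <- net$edges[net$edges$a == h | net$edges$b == h, , drop = FALSE]
    other <- ifelse(e$a == h, e$b, e$a)
    data.frame(module = h, member = other, mi = e$mi)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), member = character(), mi = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
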