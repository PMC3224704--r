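#' One-sided Fisher enrichment of terms within a module
#'
#' For every annotation term carried by at least one module member, computes
#' the one-sided (enrichment) Fisher's exact p-value of the 2x2 table
#' in-module x has-term over the given universe; the hypergeometric upper
#' tail `P(X >= hits)` is used, which is identical to the one-sided Fisher
#' test.
#'
#' @param module_members Character vector of cistron ids (must be a subset
#'   of `universe`).
#' @param term_map Named list mapping cistron id to a character vector of
#'   annotation terms (union over member genes).
#' @param universe Character vector: all cistrons eligible for the test.
#' @return Data frame with `term`, `p_value`, `member_hits`,
#'   `universe_hits`.
#' @export
fisher_enrichment <- function(module_members, term_map, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(module_members %in% universe))
    stop("module members must lie within the universe")
  N <- length(universe)
  m <- length(module_members)
  terms <- unique(unlist(term_map[module_members], use.names = FALSE))
  if (!length(terms))
    return(data.frame(term = character(), p_value = numeric(),
                      member_hits = integer(), universe_hits = integer()))
  ann <- term_map[universe]
  res <- lapply(terms, function(tm) {
    K <- sum(vapply(ann, function(t) tm %in% t, logical(1L)))
    x <- sum(vapply(term_map[module_members], function(t) tm %in% t, logical(1L)))
    data.frame(term = tm,
               p_value = stats::phyper(x - 1L, K, N - K, m, lower.tail = FALSE),
               member_hits = x, universe_hits = K)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value), , drop = FALSE]
}

#' Storey q-values with bootstrap pi0 estimation
#'
#' Estimates the proportion of true nulls `pi0` over a lambda grid, selects
#' lambda by Storey's bootstrap criterion (minimum estimated mean squared
#' error around the most optimistic plug-in), and converts p-values to
#' monotone q-values. Setting `pi0 = 1` recovers Benjamini-Hochberg.
#'
#' @param p_values Numeric p-values in `[0, 1]`, at least 10 of them.
#' @param n_bootstrap Bootstrap resamples for the lambda choice.
#' @param lambda_grid Candidate lambda values.
#' @param seed Integer seed for the bootstrap.
#' @param pi0 Optional fixed pi0 (skips estimation when supplied).
#' @return Numeric q-values in the order of `p_values`, with the `pi0` used
#'   attached as an attribute.
#' @export
estimate_qvalues <- function(p_values, n_bootstrap = 100,
                             lambda_grid = seq(0.05, 0.90, by = 0.05),
                             seed = 1, pi0 = NULL) {
  p <- p_values
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10L) stop("need at least 10 p-values to estimate pi0")
    pi0_at <- function(pp, l) mean(pp > l) / (1 - l)
    plug <- vapply(lambda_grid, pi0_at, numeric(1L), pp = p)
    target <- min(plug)
    set.seed(seed)
    boot <- matrix(0, n_bootstrap, length(lambda_grid))
    for (b in seq_len(n_bootstrap)) {
      pb <- sample(p, m, replace = TRUE)
      boot[b, ] <- vapply(lambda_grid, pi0_at, numeric(1L), pp = pb)
    }
    mse <- colMeans((boot - target)^2)
    pi0 <- plug[which.min(mse)]
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  ranks <- rank(p, ties.method = "max")
  for (i in o) {
    running <- min(running, pi0 * m * p[i] / ranks[i])
    q[i] <- min(running, 1)
  }
  structure(q, pi0 = pi0)
}

#' Enrichment of all modules against one annotation scheme
#'
#' Runs [fisher_enrichment()] per module and pools every (module, term) test
#' into one q-value computation, so the FDR is controlled across the whole
#' scheme. When fewer than 10 tests are available, `pi0` falls back to 1
#' (Benjamini-Hochberg).
#'
#' @param modules Output of [extract_modules()].
#' @param term_map Named list mapping cistron id to annotation terms.
#' @param universe All cistrons in the analysis matrix.
#' @param seed Seed for the q-value bootstrap.
#' @return Data frame `module`, `term`, `p_value`, `q_value`,
#'   `member_hits`, `universe_hits`.
#' @export
enrich_modules <- function(modules, term_map, universe, seed = 1) {
  rows <- lapply(names(modules), function(id) {
    r <- fisher_enrichment(modules[[id]]$members, term_map, universe)
    if (nrow(r)) cbind(module = id, r) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(module = character(), term = character(),
                      p_value = numeric(), q_value = numeric(),
                      member_hits = integer(), universe_hits = integer()))
  out <- do.call(rbind, rows)
  q <- if (nrow(out) >= 10L) estimate_qvalues(out$p_value, seed = seed)
       else estimate_qvalues(out$p_value, pi0 = 1)
  out$q_value <- as.numeric(q)
  rownames(out) <- NULL
  out[, c("module", "term", "p_value", "q_value", "member_hits",
          "universe_hits")]
}

#' Cistron-level annotation from member genes
#'
#' @param operons An `operon_map`.
#' @param genes A `gene_table`.
#' @param what `"protein_class"`, `"go_bp"` or `"go_mf"`.
#' @return Named list: cistron id to the union of member-gene terms.
#' @export
cistron_annotation <- function(operons, genes,
                               what = c("protein_class", "go_bp", "go_mf")) {
  what <- match.arg(what)
  lapply(operons$units, function(g) {
    if (what == "protein_class") {
      cl <- genes[g, "protein_class"]
      unique(cl[!is.na(cl)])
    } else {
      unique(unlist(lapply(genes[g, what], split_terms), use.names = FALSE))
    }
  })
}
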