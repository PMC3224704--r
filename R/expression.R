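#' Expression dataset for one microarray platform
#'
#' Container for a genes x samples matrix of (log-scale) expression values
#' together with a boolean mask of absent calls. Masked cells hold undefined
#' values and must be imputed (see [impute_missing_knn()]) before any
#' downstream analysis.
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids).
#' @param absent_mask Logical matrix of the same dimensions; `TRUE` marks a
#'   cell flagged absent/missing. Defaults to all-`FALSE`.
#' @param platform_id Label for the platform the data came from, e.g.
#'   `"cDNA_gDNA"`, `"cDNA_cDNA"` or `"oligo_chip"`.
#' @return An object of class `expr_dataset` with elements `platform_id`,
#'   `values` and `absent_mask`.
#' @export
expression_dataset <- function(values, absent_mask = NULL, platform_id = "unknown") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (is.null(absent_mask))
    absent_mask <- matrix(FALSE, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  if (!is.logical(absent_mask) || !identical(dim(absent_mask), dim(values)))
    stop("`absent_mask` must be a logical matrix with the same dimensions as `values`")
  dimnames(absent_mask) <- dimnames(values)
  structure(list(platform_id = platform_id, values = values,
                 absent_mask = absent_mask),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> platform %s: %d genes x %d samples, %d absent calls\n",
              x$platform_id, nrow(x$values), ncol(x$values), sum(x$absent_mask)))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Read an expression table from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids. Cells
#' equal to `absent_sentinel` are flagged absent; their numeric value is
#' undefined until imputation.
#'
#' @param path Path to a tab-separated file.
#' @param platform_id Platform label stored on the returned dataset.
#' @param absent_sentinel String marking an absent call (default `"NA"`).
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(path, platform_id = "unknown",
                                  absent_sentinel = "NA") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression table has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  body <- fields[-1L]
  bad <- which(lengths(body) != ncol_expected)
  if (length(bad))
    stop("ragged row(s) in expression table (first at data row ", bad[1L], ")")
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in expression table: ",
         gene_ids[duplicated(gene_ids)][1L])
  sample_ids <- header[-1L]
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                  byrow = TRUE)
  mask <- cells == absent_sentinel
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  vals[mask] <- NA_real_
  if (any(is.na(vals) & !mask))
    stop("non-numeric cell that is not the absent sentinel in ", path)
  dimnames(vals) <- list(gene_ids, sample_ids)
  expression_dataset(vals, mask, platform_id)
}

#' Write an expression table to TSV
#'
#' Emits the dialect read by [read_expression_table()]: header
#' `gene_id<TAB>sample...`, absent cells as `absent_sentinel`.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path.
#' @param absent_sentinel String to write for masked cells.
#' @export
write_expression_table <- function(ds, path, absent_sentinel = "NA") {
  stopifnot(inherits(ds, "expr_dataset"))
  cells <- matrix(format_num(ds$values), nrow(ds$values), ncol(ds$values))
  cells[ds$absent_mask] <- absent_sentinel
  lines <- c(paste(c("gene_id", colnames(ds$values)), collapse = "\t"),
             paste(rownames(ds$values), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  gsub(" ", "", out, fixed = TRUE)
}

#' Filter thresholds for compendium gene selection
#'
#' @param absent_strict Maximum absent-call fraction in the dataset that
#'   carries the gene's dynamic signal (default 0.20).
#' @param absent_loose Maximum absent-call fraction tolerated in the other
#'   dataset (default 0.50).
#' @param sd_percentile Percentile rank (0-100) of the per-dataset standard
#'   deviation population used as the variability cutoff (default 25).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(absent_strict = 0.20, absent_loose = 0.50,
                              sd_percentile = 25) {
  if (!(absent_strict >= 0 && absent_strict <= absent_loose && absent_loose <= 1))
    stop("need 0 <= absent_strict <= absent_loose <= 1")
  if (sd_percentile < 0 || sd_percentile > 100)
    stop("sd_percentile must be in [0, 100]")
  structure(list(absent_strict = absent_strict, absent_loose = absent_loose,
                 sd_percentile = sd_percentile),
            class = "filter_thresholds")
}

sd_present <- function(v, mask) {
  x <- v[!mask]
  if (length(x) < 2L) 0 else stats::sd(x)
}

#' Per-gene filter statistics over two hybridization datasets
#'
#' For every gene in the union of the two datasets, computes the absent-call
#' fractions (`a`, `c`), the standard deviations over present values (`b`,
#' `d`; n-1 form, 0 when fewer than two present values) and the boolean
#' probeset-presence flag `e`. Genes missing from a dataset entirely get an
#' absent fraction of 1.
#'
#' @param ds1,ds2 [expression_dataset()] objects (the two spotted-array
#'   platforms).
#' @param probeset_genes Character vector of gene ids represented on the
#'   oligonucleotide chip.
#' @return A data frame with columns `gene_id`, `a`, `b`, `c`, `d`, `e` plus
#'   present-value counts `n1`, `n2` used when deriving percentile cutoffs.
#' @export
compute_filter_stats <- function(ds1, ds2, probeset_genes) {
  stopifnot(inherits(ds1, "expr_dataset"), inherits(ds2, "expr_dataset"))
  genes <- union(rownames(ds1$values), rownames(ds2$values))
  if (!length(genes)) stop("no genes in either dataset")
  one <- function(ds, g) {
    if (g %in% rownames(ds$values)) {
      m <- ds$absent_mask[g, ]
      c(frac = mean(m), sd = sd_present(ds$values[g, ], m),
        n = sum(!m))
    } else c(frac = 1, sd = 0, n = 0)
  }
  s1 <- t(vapply(genes, one, numeric(3L), ds = ds1))
  s2 <- t(vapply(genes, one, numeric(3L), ds = ds2))
  data.frame(gene_id = genes,
             a = s1[, "frac"], b = s1[, "sd"],
             c = s2[, "frac"], d = s2[, "sd"],
             e = genes %in% probeset_genes,
             n1 = as.integer(s1[, "n"]), n2 = as.integer(s2[, "n"]),
             row.names = NULL)
}

#' Select genes with adequate signal across the compendium
#'
#' A gene is retained when it shows good expression dynamics in one spotted
#' dataset (absent in at most `absent_strict` of samples and standard
#' deviation at or above the `sd_percentile`-th percentile of that dataset's
#' sd population), passes a looser absent-call bound in the other dataset,
#' and has a probeset on the oligo chip:
#'
#' \deqn{\{(a \le 0.20) \wedge (b \ge b_0) \wedge (c \le 0.50) \wedge e\}
#'   \vee \{(c \le 0.20) \wedge (d \ge d_0) \wedge (a \le 0.50) \wedge e\}}
#'
#' The sd cutoffs \eqn{b_0, d_0} are recomputed from the supplied data as
#' percentiles over genes with at least two present values in the respective
#' dataset; they are data-derived, not constants.
#'
#' @param stats Output of [compute_filter_stats()].
#' @param thresholds A [filter_thresholds()] object.
#' @return Character vector of selected gene ids, with the derived cutoffs
#'   attached as attributes `sd_cutoff_1` and `sd_cutoff_2`.
#' @export
select_genes <- function(stats, thresholds = filter_thresholds()) {
  if (!nrow(stats)) stop("empty filter statistics")
  th <- thresholds
  q <- th$sd_percentile / 100
  b0 <- stats::quantile(stats$b[stats$n1 >= 2L], q, names = FALSE)
  d0 <- stats::quantile(stats$d[stats$n2 >= 2L], q, names = FALSE)
  keep <- with(stats,
    (a <= th$absent_strict & b >= b0 & c <= th$absent_loose & e) |
    (c <= th$absent_strict & d >= d0 & a <= th$absent_loose & e))
  structure(stats$gene_id[keep], sd_cutoff_1 = b0, sd_cutoff_2 = d0)
}

#' Impute absent cells by k-nearest-neighbour averaging
#'
#' Each masked cell is replaced by the unweighted mean, at that sample, of
#' the `k` nearest genes. Distance between two genes is the root mean squared
#' difference over samples where both are present; candidate neighbours must
#' themselves be present at the target sample. If fewer than `k` eligible
#' neighbours exist, all of them are used; if none exists, the gene's own
#' mean over present values is used.
#'
#' @param ds An [expression_dataset()].
#' @param k Number of neighbours (default 15).
#' @return An [expression_dataset()] with a complete matrix and an all-false
#'   mask. Present cells are untouched.
#' @export
impute_missing_knn <- function(ds, k = 15) {
  stopifnot(inherits(ds, "expr_dataset"), k >= 1)
  vals <- ds$values
  mask <- ds$absent_mask
  npres <- rowSums(!mask)
  if (any(npres == 0L))
    stop("gene with no present values: ", rownames(vals)[npres == 0L][1L])
  if (!any(mask))
    return(expression_dataset(vals, NULL, ds$platform_id))
  pres <- !mask
  need <- which(rowSums(mask) > 0L)
  out <- vals
  for (g in need) {
    shared <- pres %*% pres[g, ]            # mutually present sample counts
    dd <- sweep(vals, 2L, vals[g, ])
    dd[!pres | !rep(pres[g, ], each = nrow(vals))] <- 0
    dd[is.na(dd)] <- 0
    d2 <- rowSums(dd^2) / pmax(shared[, 1L], 1L)
    d2[g] <- Inf
    d2[shared[, 1L] == 0L] <- Inf
    for (s in which(mask[g, ])) {
      elig <- which(pres[, s] & is.finite(d2))
      if (!length(elig)) {
        out[g, s] <- mean(vals[g, pres[g, ]])
        next
      }
      nb <- elig[order(d2[elig])][seq_len(min(k, length(elig)))]
      out[g, s] <- mean(vals[nb, s])
    }
  }
  expression_dataset(out, NULL, ds$platform_id)
}

#' Standardize every gene profile to mean 0 and sd 1
#'
#' Uses the sample (n-1) standard deviation. The matrix must be complete;
#' constant rows are rejected because they carry no usable signal (such rows
#' should have been removed by [select_genes()]).
#'
#' @param ds An [expression_dataset()] with an empty absent mask.
#' @return An [expression_dataset()] of z-scores.
#' @export
z_standardize <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (any(ds$absent_mask))
    stop("matrix contains absent calls; impute before standardizing")
  if (ncol(ds$values) < 2L) stop("need at least two samples")
  mu <- rowMeans(ds$values)
  s <- apply(ds$values, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene: ", rownames(ds$values)[s == 0][1L])
  expression_dataset((ds$values - mu) / s, NULL, ds$platform_id)
}

#' Concatenate per-platform datasets into one compendium matrix
#'
#' Column-binds the parts over a common, ordered gene set. Parts are expected
#' to be standardized per-dataset beforehand; sample ids must not collide
#' across parts.
#'
#' @param parts List of [expression_dataset()] objects.
#' @param gene_ids Genes to keep, in output row order. Defaults to the
#'   intersection of all parts' genes.
#' @return An [expression_dataset()] with `platform_id = "compendium"`.
#' @export
concat_datasets <- function(parts, gene_ids = NULL) {
  stopifnot(length(parts) >= 1L)
  lapply(parts, function(p) stopifnot(inherits(p, "expr_dataset")))
  if (is.null(gene_ids))
    gene_ids <- Reduce(intersect, lapply(parts, function(p) rownames(p$values)))
  if (!length(gene_ids)) stop("no genes common to all parts")
  all_samples <- unlist(lapply(parts, function(p) colnames(p$values)))
  if (anyDuplicated(all_samples))
    stop("overlapping sample ids across parts: ",
         all_samples[duplicated(all_samples)][1L])
  for (p in parts) {
    missing <- setdiff(gene_ids, rownames(p$values))
    if (length(missing))
      stop("gene(s) absent from platform ", p$platform_id, ": ",
           paste(utils::head(missing, 3L), collapse = ", "))
    if (any(p$absent_mask[gene_ids, ]))
      stop("platform ", p$platform_id, " still contains absent calls")
  }
  vals <- do.call(cbind, lapply(parts, function(p) p$values[gene_ids, , drop = FALSE]))
  expression_dataset(vals, NULL, "compendium")
}

#' Filter, impute, standardize and concatenate a three-platform compendium
#'
#' Convenience wrapper running the whole compendium stage: gene selection on
#' the two spotted-array datasets, per-dataset k-NN imputation of remaining
#' absent calls (including the oligo dataset), per-dataset z-standardization,
#' then column-wise concatenation.
#'
#' @param ds1,ds2,ds3 The cDNA:gDNA, cDNA:cDNA and oligo-chip datasets.
#' @param thresholds A [filter_thresholds()] object.
#' @param k Neighbour count for imputation.
#' @return A list with `expr` (the concatenated standardized
#'   [expression_dataset()]), `selected` (gene ids) and `stats`.
#' @export
build_compendium <- function(ds1, ds2, ds3, thresholds = filter_thresholds(),
                             k = 15) {
  stats <- compute_filter_stats(ds1, ds2, rownames(ds3$values))
  selected <- select_genes(stats, thresholds)
  subset_ds <- function(ds) {
    g <- intersect(selected, rownames(ds$values))
    expression_dataset(ds$values[g, , drop = FALSE],
                       ds$absent_mask[g, , drop = FALSE], ds$platform_id)
  }
  parts <- lapply(list(ds1, ds2, ds3), function(ds)
    z_standardize(impute_missing_knn(subset_ds(ds), k = k)))
  expr <- concat_datasets(parts, selected)
  list(expr = expr, selected = as.character(selected), stats = stats)
}
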