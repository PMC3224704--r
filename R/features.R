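#' Protein-class agreement score for a gene pair
#'
#' `+1` when both genes are assigned to the same class of the flat protein
#' classification scheme, `-1` when both are assigned but to different
#' classes, `NA` when either gene lacks an assignment.
#'
#' @param class_a,class_b Class labels or `NA`.
#' @return `+1`, `-1` or `NA_real_`.
#' @export
protein_class_score <- function(class_a, class_b) {
  if (is.na(class_a) || is.na(class_b)) return(NA_real_)
  if (class_a == class_b) 1 else -1
}

#' Pearson correlation between two expression profiles
#'
#' @param x,y Numeric profiles of equal length (at least 3 samples).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when either profile has
#'   zero variance.
#' @export
expression_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Read a gene-order conservation table
#'
#' TSV with columns `gene_a`, `gene_b`, `probability` (carried through but
#' unused) and `genome_count`: the number of genomes in which orthologs of
#' the adjacent pair occur in the same order.
#'
#' @param path Path to the TSV.
#' @return Data frame with those columns.
#' @export
read_conservation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_a = "character",
                                         gene_b = "character"))
  req <- c("gene_a", "gene_b", "genome_count")
  if (!all(req %in% names(df)))
    stop("conservation table lacks column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (any(df$genome_count < 0)) stop("negative genome count")
  df
}

#' Read a labeled training-pair table
#'
#' TSV with columns `gene_a`, `gene_b`, `label` where label is `KOP` (known
#' operon pair) or `NOP` (non-operon pair).
#'
#' @param path Path to the TSV.
#' @return Data frame with those columns.
#' @export
read_training_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_a = "character",
                                         gene_b = "character"))
  if (!all(c("gene_a", "gene_b", "label") %in% names(df)))
    stop("training table needs columns gene_a, gene_b, label")
  if (!all(df$label %in% c("KOP", "NOP")))
    stop("labels must be KOP or NOP")
  df
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Merge training-pair sources into one labeled set
#'
#' Positive (KOP) sources are unioned with duplicate pairs counted once.
#' Negative (NOP) sources are unioned the same way, and any negative pair
#' that occurs in a positive source is dropped: experimental evidence of
#' co-transcription overrides an earlier non-operon call.
#'
#' @param kop_sources,nop_sources Lists of data frames with columns `gene_a`,
#'   `gene_b` (e.g. from [read_training_pairs()] or plain two-column TSVs).
#' @return Data frame `gene_a`, `gene_b`, `label`, with counts `n_kop` and
#'   `n_nop` attached as attributes.
#' @export
assemble_training_set <- function(kop_sources, nop_sources) {
  bind <- function(lst) do.call(rbind, lapply(lst, function(d)
    data.frame(gene_a = as.character(d$gene_a),
               gene_b = as.character(d$gene_b))))
  kop <- bind(kop_sources)
  nop <- bind(nop_sources)
  kop <- kop[!duplicated(pair_key(kop$gene_a, kop$gene_b)), , drop = FALSE]
  nop <- nop[!duplicated(pair_key(nop$gene_a, nop$gene_b)), , drop = FALSE]
  nop <- nop[!pair_key(nop$gene_a, nop$gene_b) %in%
               pair_key(kop$gene_a, kop$gene_b), , drop = FALSE]
  out <- rbind(cbind(kop, label = "KOP"), cbind(nop, label = "NOP"))
  rownames(out) <- NULL
  structure(out, n_kop = nrow(kop), n_nop = nrow(nop))
}

#' Assemble the six-feature vector for every same-strand adjacent pair
#'
#' Computes, per pair: the protein-class score, the Czekanowski-Dice GO
#' overlap (averaged over the biological-process and molecular-function
#' namespaces where both genes carry terms), the information-content GO
#' similarity (same averaging), the gene-order conservation count (0 for
#' pairs absent from the table), the strand-aware intergenic distance, and
#' the Pearson correlation of the two expression profiles (`NA` when either
#' gene is not in the expression matrix). Training labels are attached where
#' available.
#'
#' @param pairs Output of [same_strand_adjacent_pairs()].
#' @param genes A `gene_table`.
#' @param conservation Optional conservation table
#'   ([read_conservation_table()]).
#' @param expr Optional [expression_dataset()] (the standardized compendium).
#' @param training Optional labeled pairs ([read_training_pairs()] or
#'   [assemble_training_set()]); labels referring to pairs that are not
#'   same-strand adjacent are an error.
#' @param dag_bp,dag_mf Optional [go_dag()] objects for the two namespaces.
#' @param ic_bp,ic_mf Matching [term_ic()] vectors.
#' @return Data frame of class `pair_features` with columns `upstream`,
#'   `downstream`, `class_score`, `cd_score`, `ic_sim`, `conservation`,
#'   `distance`, `r`, `label`.
#' @export
assemble_features <- function(pairs, genes, conservation = NULL, expr = NULL,
                              training = NULL, dag_bp = NULL, dag_mf = NULL,
                              ic_bp = NULL, ic_mf = NULL) {
  n <- nrow(pairs)
  up <- genes[pairs$upstream, ]
  dn <- genes[pairs$downstream, ]
  avg2 <- function(x, y) {
    v <- c(x, y)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  class_score <- mapply(protein_class_score, up$protein_class, dn$protein_class)
  cd <- numeric(n); ics <- numeric(n)
  for (i in seq_len(n)) {
    bp_a <- split_terms(up$go_bp[i]); bp_b <- split_terms(dn$go_bp[i])
    mf_a <- split_terms(up$go_mf[i]); mf_b <- split_terms(dn$go_mf[i])
    cd[i] <- avg2(czekanowski_dice(bp_a, bp_b), czekanowski_dice(mf_a, mf_b))
    sim_bp <- if (!is.null(dag_bp)) ic_similarity(bp_a, bp_b, dag_bp, ic_bp) else NA_real_
    sim_mf <- if (!is.null(dag_mf)) ic_similarity(mf_a, mf_b, dag_mf, ic_mf) else NA_real_
    ics[i] <- avg2(sim_bp, sim_mf)
  }
  cons <- integer(n)
  if (!is.null(conservation)) {
    tab <- stats::setNames(conservation$genome_count,
                           pair_key(conservation$gene_a, conservation$gene_b))
    hit <- tab[pair_key(pairs$upstream, pairs$downstream)]
    cons <- ifelse(is.na(hit), 0L, as.integer(hit))
  }
  dist <- vapply(seq_len(n), function(i)
    intergenic_distance(up[i, ], dn[i, ]), integer(1L))
  r <- rep(NA_real_, n)
  if (!is.null(expr)) {
    g <- rownames(expr$values)
    ok <- pairs$upstream %in% g & pairs$downstream %in% g
    r[ok] <- vapply(which(ok), function(i)
      expression_correlation(expr$values[pairs$upstream[i], ],
                             expr$values[pairs$downstream[i], ]), numeric(1L))
  }
  label <- rep(NA_character_, n)
  if (!is.null(training)) {
    keys <- pair_key(pairs$upstream, pairs$downstream)
    tkeys <- pair_key(training$gene_a, training$gene_b)
    miss <- !tkeys %in% keys
    if (any(miss))
      stop("training label on a pair that is not same-strand adjacent: ",
           training$gene_a[miss][1L], "-", training$gene_b[miss][1L])
    label[match(tkeys, keys)] <- training$label
  }
  out <- data.frame(upstream = pairs$upstream, downstream = pairs$downstream,
                    class_score = class_score, cd_score = cd, ic_sim = ics,
                    conservation = cons, distance = dist, r = r,
                    label = label, row.names = NULL)
  class(out) <- c("pair_features", "data.frame")
  out
}

# Feature columns that can be missing and get a companion presence indicator.
MISSABLE_FEATURES <- c("class_score", "cd_score", "ic_sim", "r")
ALL_FEATURES <- c("class_score", "cd_score", "ic_sim", "conservation",
                  "distance", "r")

#' Encode pair features for classification
#'
#' Standardizes each selected feature with the supplied (training) center and
#' scale, replaces missing values by 0 (the post-standardization mean) and
#' appends a 0/1 presence indicator for every selected feature that can be
#' missing.
#'
#' @param pf A `pair_features` data frame.
#' @param feature_subset Character vector of base feature names.
#' @param center,scale Named numeric vectors over `feature_subset`; computed
#'   from `pf` itself when `NULL`.
#' @return List with the model matrix `x` and the `center`/`scale` used.
#' @export
encode_features <- function(pf, feature_subset = ALL_FEATURES,
                            center = NULL, scale = NULL) {
  feature_subset <- match.arg(feature_subset, ALL_FEATURES, several.ok = TRUE)
  raw <- as.matrix(as.data.frame(pf)[, feature_subset, drop = FALSE])
  if (is.null(center)) {
    center <- apply(raw, 2L, function(v) mean(v, na.rm = TRUE))
    scale <- apply(raw, 2L, function(v) stats::sd(v, na.rm = TRUE))
    scale[!is.finite(scale) | scale == 0] <- 1
    center[!is.finite(center)] <- 0
  }
  x <- sweep(sweep(raw, 2L, center[feature_subset]), 2L,
             scale[feature_subset], "/")
  x[is.na(x)] <- 0
  ind <- feature_subset[feature_subset %in% MISSABLE_FEATURES]
  if (length(ind)) {
    pres <- !is.na(raw[, ind, drop = FALSE])
    colnames(pres) <- paste0("has_", ind)
    x <- cbind(x, pres + 0)
  }
  list(x = x, center = center, scale = scale, features = feature_subset)
}
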