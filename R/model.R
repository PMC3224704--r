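#' Train a maximum-margin operon-pair classifier
#'
#' Fits a support-vector machine on labeled pair features. Features are
#' standardized on the training data (the transformation is stored and
#' re-applied at prediction time); missing values are encoded as the
#' post-standardization mean with companion presence indicators.
#'
#' @param train A `pair_features` data frame with a `label` column containing
#'   `KOP`/`NOP` for the rows to train on (unlabeled rows are ignored).
#' @param feature_subset Base features to use (default: all six).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost Soft-margin cost parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / n_columns` of the encoded
#'   matrix (features have unit variance after standardization).
#' @param class_weights Optional named weights (`KOP`, `NOP`) to reweight the
#'   classes; by default the class imbalance is used as-is.
#' @return An object of class `operon_classifier`.
#' @export
train_classifier <- function(train, feature_subset = ALL_FEATURES,
                             kernel = c("radial", "linear"), cost = 1,
                             gamma = NULL, class_weights = NULL) {
  kernel <- match.arg(kernel)
  lab <- train$label
  keep <- !is.na(lab)
  train <- train[keep, , drop = FALSE]
  lab <- lab[keep]
  if (length(unique(lab)) < 2L)
    stop("training data must contain both KOP and NOP examples")
  enc <- encode_features(train, feature_subset)
  if (is.null(gamma)) gamma <- 1 / ncol(enc$x)
  y <- factor(lab, levels = c("KOP", "NOP"))
  fit <- e1071::svm(enc$x, y, kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE, class.weights = class_weights)
  # orient decision values so that positive always means KOP
  dv0 <- attr(stats::predict(fit, enc$x, decision.values = TRUE),
              "decision.values")[, 1L]
  flip <- if (mean(dv0[y == "KOP"]) >= mean(dv0[y == "NOP"])) 1 else -1
  structure(list(fit = fit, flip = flip, kernel = kernel,
                 features = feature_subset, center = enc$center,
                 scale = enc$scale),
            class = "operon_classifier")
}

#' Decision scores for pair features
#'
#' @param object An `operon_classifier`.
#' @param newdata A `pair_features` data frame.
#' @param ... Unused.
#' @return Numeric vector of decision scores; positive predicts
#'   co-transcription (KOP).
#' @export
predict.operon_classifier <- function(object, newdata, ...) {
  if (!nrow(newdata)) return(numeric())
  enc <- encode_features(newdata, object$features,
                         center = object$center, scale = object$scale)
  dv <- attr(stats::predict(object$fit, enc$x, decision.values = TRUE),
             "decision.values")[, 1L]
  unname(object$flip * dv)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly drawn positive scores
#' higher than a uniformly drawn negative, ties counted one half.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical or `KOP`/`NOP` vector; `TRUE`/`KOP` is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "KOP"
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("both classes must be represented")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve coordinates from decision scores
#'
#' @inheritParams auc
#' @return Data frame of `fpr` (fraction of negatives called positive) and
#'   `recall` (fraction of positives called positive) over all score
#'   thresholds, from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- labels == "KOP"
  o <- order(scores, decreasing = TRUE)
  lab <- as.logical(labels)[o]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  keep <- c(diff(scores[o]) != 0, TRUE)   # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / sum(!lab)),
             recall = c(0, tp[keep] / sum(lab)))
}

#' Stratified k-fold cross-validation of a pair classifier
#'
#' Splits labeled pairs into `n_folds` folds stratified by class using the
#' given seed, trains on the complement of each fold (feature
#' standardization recomputed within the fold) and scores the held-out
#' pairs.
#'
#' @inheritParams train_classifier
#' @param seed Integer seed controlling the fold assignment.
#' @param n_folds Number of folds (default 10).
#' @return Object of class `cv_result`: `fold_aucs`, `mean_auc`, `folds`
#'   (per-pair fold assignment), `scores`, `labels` and per-fold ROC curves.
#' @export
cross_validate <- function(train, feature_subset = ALL_FEATURES,
                           kernel = c("radial", "linear"), cost = 1,
                           gamma = NULL, class_weights = NULL, seed = 1,
                           n_folds = 10) {
  kernel <- match.arg(kernel)
  keep <- !is.na(train$label)
  pf <- train[keep, , drop = FALSE]
  tab <- table(pf$label)
  if (any(tab < n_folds))
    stop("need at least ", n_folds, " examples of each class")
  set.seed(seed)
  folds <- integer(nrow(pf))
  for (cl in names(tab)) {
    idx <- which(pf$label == cl)
    folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  scores <- numeric(nrow(pf))
  fold_aucs <- numeric(n_folds)
  rocs <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    model <- train_classifier(pf[folds != f, , drop = FALSE], feature_subset,
                              kernel, cost, gamma, class_weights)
    s <- predict(model, pf[folds == f, , drop = FALSE])
    scores[folds == f] <- s
    fold_aucs[f] <- auc(s, pf$label[folds == f])
    rocs[[f]] <- roc_curve(s, pf$label[folds == f])
  }
  structure(list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 folds = folds, scores = scores, labels = pf$label,
                 roc = rocs),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean AUC %.3f (sd %.3f)\n",
              length(x$fold_aucs), x$mean_auc, stats::sd(x$fold_aucs)))
  invisible(x)
}

#' One-tailed paired t-test on per-fold AUCs
#'
#' Tests H1: mean(a - b) > 0 over paired folds. Degenerate conventions: all
#' differences zero gives p = 0.5; zero-variance nonzero-mean differences
#' give p = 0 (mean > 0) or 1 (mean < 0).
#'
#' @param aucs_a,aucs_b Equal-length numeric vectors paired by fold.
#' @return One-tailed p-value.
#' @export
compare_auc_paired_ttest <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b)) stop("fold vectors differ in length")
  if (length(aucs_a) < 2L) stop("need at least 2 folds")
  d <- aucs_a - aucs_b
  if (all(d == 0)) return(0.5)
  if (stats::sd(d) == 0) return(if (mean(d) > 0) 0 else 1)
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  stats::pt(t, df = length(d) - 1L, lower.tail = FALSE)
}

#' Score every same-strand adjacent pair in the genome
#'
#' @param model An `operon_classifier`.
#' @param all_pairs A `pair_features` data frame covering the genome.
#' @return Numeric score per pair; a pair is called co-transcribed when its
#'   score is strictly positive.
#' @export
predict_genome <- function(model, all_pairs) {
  predict(model, all_pairs)
}

#' Chain positively-called adjacent pairs into transcription units
#'
#' Maximal runs of consecutive positive pairs form one polycistronic unit;
#' every gene not linked to a neighbour becomes monocistronic. A strand or
#' contig change always breaks a unit. The resulting units partition the
#' gene set.
#'
#' @param genes A `gene_table`.
#' @param pairs Same-strand adjacent pairs ([same_strand_adjacent_pairs()]).
#' @param calls Logical vector, one per row of `pairs`; `TRUE` means
#'   co-transcribed.
#' @return Object of class `operon_map`: list with `units` (named list of
#'   gene-id vectors in transcription order) and `gene2unit` (named vector).
#' @export
chain_operons <- function(genes, pairs, calls) {
  if (nrow(pairs) != length(calls)) stop("one call per pair required")
  comp <- seq_len(nrow(genes))                # union-find over genome order
  names(comp) <- genes$gene_id
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  pu <- match(pairs$upstream, genes$gene_id)
  pd <- match(pairs$downstream, genes$gene_id)
  if (any(is.na(pu) | is.na(pd))) stop("pair references unknown gene")
  if (any(abs(pu - pd) != 1L) ||
      any(genes$contig[pu] != genes$contig[pd]) ||
      any(genes$strand[pu] != genes$strand[pd]))
    stop("call on a pair that is not same-strand adjacent")
  for (i in which(calls)) comp[find(pu[i])] <- find(pd[i])
  root <- vapply(seq_along(comp), find, integer(1L))
  units <- split(genes$gene_id, root)
  # order genes within a unit in transcription direction
  units <- lapply(units, function(g) {
    o <- order(genes[g, "start"])
    if (genes[g[1L], "strand"] == "-") o <- rev(o)
    g[o]
  })
  # stable unit order: by genome position of first member
  first_pos <- vapply(units, function(g) min(genes[g, "start"]), numeric(1L))
  units <- units[order(vapply(units, function(g) genes[g[1L], "contig"],
                              character(1L)), first_pos)]
  names(units) <- sprintf("TU%05d", seq_along(units))
  gene2unit <- stats::setNames(rep(names(units), lengths(units)),
                               unlist(units))
  structure(list(units = units, gene2unit = gene2unit), class = "operon_map")
}

#' @export
print.operon_map <- function(x, ...) {
  sizes <- lengths(x$units)
  cat(sprintf("<operon_map> %d transcription units over %d genes (%d polycistronic)\n",
              length(x$units), sum(sizes), sum(sizes > 1L)))
  invisible(x)
}

#' @export
as.data.frame.operon_map <- function(x, ...) {
  data.frame(gene_id = unlist(x$units, use.names = FALSE),
             operon_id = rep(names(x$units), lengths(x$units)),
             row.names = NULL)
}

#' Write an operon map as a gene-to-unit TSV
#' @param map An `operon_map`.
#' @param path Output path.
#' @export
write_operon_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an operon map as GFF3, one feature per transcription unit
#'
#' Each unit becomes a `transcript` feature spanning its member genes, with
#' the unit id and member list in the attributes column.
#'
#' @param map An `operon_map`.
#' @param genes The `gene_table` the map was built from.
#' @param path Output path.
#' @export
write_operon_gff3 <- function(map, genes, path) {
  rows <- vapply(names(map$units), function(id) {
    g <- genes[map$units[[id]], , drop = FALSE]
    sprintf("%s\tcistronet\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;genes=%s",
            g$contig[1L], min(g$start), max(g$end), g$strand[1L], id,
            paste(g$gene_id, collapse = ","))
  }, character(1L))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read an operon map written by [write_operon_map()]
#' @param path Path to the TSV.
#' @return An `operon_map`.
#' @export
read_operon_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  units <- split(df$gene_id, df$operon_id)[unique(df$operon_id)]
  structure(list(units = units,
                 gene2unit = stats::setNames(df$operon_id, df$gene_id)),
            class = "operon_map")
}

#' Boundary F1 of a predicted pair calling against truth
#'
#' Treats each same-strand adjacent pair as a binary decision
#' (co-transcribed or not) and computes precision, recall and F1 of the
#' positive class.
#'
#' @param calls Logical predictions per pair.
#' @param truth Logical ground truth per pair.
#' @return Named vector `precision`, `recall`, `f1`.
#' @export
pair_call_f1 <- function(calls, truth) {
  tp <- sum(calls & truth)
  prec <- if (sum(calls)) tp / sum(calls) else 0
  rec <- if (sum(truth)) tp / sum(truth) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}
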