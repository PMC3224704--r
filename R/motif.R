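#' Extract the upstream region of a cistron
#'
#' Returns the `length` bp immediately 5' of the translational start of the
#' cistron's first gene (in transcription order), strand-aware: minus-strand
#' cistrons yield the reverse complement of the region to the right of the
#' gene. Regions are clipped at contig ends and returned uppercase.
#'
#' @param genome Named character vector (or `Biostrings::DNAStringSet`) of
#'   contig sequences.
#' @param genes A `gene_table`.
#' @param operons An `operon_map`.
#' @param cistron_id Transcription-unit id.
#' @param length Upstream length in bp (default 300).
#' @return A character scalar (possibly shorter than `length` at contig
#'   edges).
#' @export
extract_upstream <- function(genome, genes, operons, cistron_id, length = 300) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  first <- operons$units[[cistron_id]][1L]
  if (is.null(first)) stop("unknown cistron: ", cistron_id)
  g <- genes[first, ]
  if (!g$contig %in% names(genome)) stop("gene not on a loaded contig: ", first)
  contig <- genome[[g$contig]]
  L <- nchar(contig)
  if (g$strand == "+") {
    from <- max(1L, g$start - length)
    to <- g$start - 1L
    if (to < from) return("")
    toupper(substr(contig, from, to))
  } else {
    from <- g$end + 1L
    to <- min(L, g$end + length)
    if (to < from) return("")
    revcomp(toupper(substr(contig, from, to)))
  }
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Upstream regions for a set of cistrons
#'
#' @inheritParams extract_upstream
#' @param cistron_ids Character vector of transcription-unit ids.
#' @return Named character vector of upstream sequences.
#' @export
upstream_sequences <- function(genome, genes, operons, cistron_ids,
                               length = 300) {
  stats::setNames(vapply(cistron_ids, function(id)
    extract_upstream(genome, genes, operons, id, length), character(1L)),
    cistron_ids)
}

#' Zero-order background model from pooled upstream sequences
#'
#' Mononucleotide fractions pooled over all sequences; ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param sequences Character vector of DNA sequences.
#' @return Named numeric vector over `A`, `C`, `G`, `T` summing to 1.
#' @export
background_from_upstreams <- function(sequences) {
  chars <- strsplit(toupper(paste(sequences, collapse = "")), "")[[1L]]
  counts <- table(factor(chars[chars %in% c("A", "C", "G", "T")],
                         levels = c("A", "C", "G", "T")))
  if (sum(counts) == 0L) stop("no unambiguous bases in input")
  stats::setNames(as.numeric(counts) / sum(counts), c("A", "C", "G", "T"))
}

#' Shuffle sequence letters within each sequence
#'
#' Composition-preserving permutation of the letters of every sequence
#' independently. Uses R's RNG.
#'
#' @param sequences Character vector of sequences.
#' @param seed Optional integer seed.
#' @return Shuffled sequences (names preserved).
#' @export
shuffle_sequences <- function(sequences, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(sequences, function(s) {
    paste(sample(strsplit(s, "")[[1L]]), collapse = "")
  }, character(1L))
  stats::setNames(out, names(sequences))
}

seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(v)) stop("sequence contains non-ACGT characters")
  v
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# One EM run for a fixed width from a given PWM initialization.
# Sequences enter pre-windowed: WIND is the stacked window matrix (M x w),
# sid maps windows to sequences, bgwin the background log-probability of
# each window, bgseq the background log-likelihood of each full sequence.
em_zoops <- function(WIND, sid_index, nseq, m_per_seq, bgwin, bgseq, pwm, bg,
                     pseudocount, max_iter, tol) {
  w <- ncol(WIND)
  gamma <- 0.5
  logbg <- log(bg)
  obj_prev <- -Inf
  ll <- -Inf
  trace <- numeric()
  Z <- NULL
  for (iter in seq_len(max_iter)) {
    logpwm <- log(pwm)
    S <- -bgwin
    for (c in seq_len(w)) S <- S + logpwm[WIND[, c], c]
    # per-sequence posteriors and observed-data log likelihood
    ll <- 0
    Z <- numeric(length(S))
    for (s in seq_len(nseq)) {
      i <- sid_index[[s]]
      a <- log(gamma / m_per_seq[s]) + S[i]
      d <- logsumexp(c(log1p(-gamma), a))
      Z[i] <- exp(a - d)
      ll <- ll + bgseq[s] + d
    }
    # with pseudocounts the M-step maximizes the Dirichlet-penalized (MAP)
    # objective, so that is the quantity guaranteed non-decreasing
    obj <- ll + pseudocount * sum(logpwm)
    if (obj < obj_prev - 1e-8 * (1 + abs(obj_prev)))
      stop("EM objective decreased; this indicates a numerical fault")
    trace <- c(trace, obj)
    if (is.finite(obj_prev) && obj - obj_prev < tol * (1 + abs(obj))) break
    obj_prev <- obj
    # M-step
    counts <- matrix(pseudocount, 4L, w)
    for (c in seq_len(w)) {
      for (b in 1:4) counts[b, c] <- counts[b, c] + sum(Z[WIND[, c] == b])
    }
    pwm <- sweep(counts, 2L, colSums(counts), "/")
    gamma <- min(max(mean(vapply(seq_len(nseq), function(s)
      sum(Z[sid_index[[s]]]), numeric(1L))), 1e-4), 1 - 1e-4)
  }
  # site-level log-likelihood ratio: posterior-weighted evidence of the
  # aligned sites against background (free of the position-uncertainty
  # penalty, which would mask even a perfectly recovered motif)
  logpwm <- log(pwm)
  S <- -bgwin
  for (c in seq_len(w)) S <- S + logpwm[WIND[, c], c]
  list(pwm = pwm, gamma = gamma, loglik = ll, llr_sites = sum(Z * S),
       Z = Z, trace = trace)
}

pwm_from_window <- function(bases, w, strength = 0.7) {
  pwm <- matrix((1 - strength) / 3, 4L, w)
  pwm[cbind(bases, seq_len(w))] <- strength
  pwm
}

#' Discover one ungapped motif by ZOOPS expectation-maximization
#'
#' Fits a zero-or-one-occurrence-per-sequence motif model against a fixed
#' zero-order background, over a range of candidate widths. For each width,
#' `n_restarts` starting position-weight matrices are seeded from substrings
#' of the data, screened with a few EM iterations, and the best `n_refine`
#' are run to convergence; the reported motif is the width/start with the
#' smallest significance score.
#'
#' The significance score is a log10 E-value surrogate: the chi-square upper
#' tail of twice the model-vs-background log-likelihood ratio (degrees of
#' freedom = free motif parameters), Bonferroni-corrected for the number of
#' widths tried and candidate start positions. It is kept on the log10
#' scale so that strongly significant motifs remain comparable instead of
#' underflowing to zero; smaller is stronger. The decision rule used
#' downstream only ever compares this score between real and shuffled
#' inputs scored identically, so any monotone surrogate is faithful.
#'
#' @param sequences Character vector of at least 2 DNA sequences (ACGT
#'   only), each at least as long as the maximum width.
#' @param background Named base frequencies ([background_from_upstreams()]).
#' @param width_range Integer vector `c(min, max)` of motif widths tried
#'   (default 6 to 12).
#' @param n_restarts Substring-seeded starts screened per width.
#' @param n_refine Screened starts run to convergence per width.
#' @param pseudocount Dirichlet pseudocount added per PWM cell.
#' @param site_posterior Posterior threshold above which a sequence is
#'   reported as containing a site.
#' @param max_iter,tol EM iteration cap and relative convergence tolerance.
#' @param seed Optional integer seed (restart sampling).
#' @return Object of class `motif_result`: `pwm` (4 x width), `consensus`,
#'   `width`, `log_evalue` (log10), `sites` (per-sequence data frame),
#'   `n_members_with_site`, `gamma`, `loglik`, `loglik_trace`.
#' @export
discover_motif <- function(sequences, background, width_range = c(6, 12),
                           n_restarts = 20, n_refine = 4, pseudocount = 0.1,
                           site_posterior = 0.5, max_iter = 100, tol = 1e-6,
                           seed = NULL) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (!is.null(seed)) set.seed(seed)
  ints <- lapply(sequences, seq_to_int)
  lens <- lengths(ints)
  widths <- seq.int(width_range[1L], width_range[2L])
  if (any(lens < max(widths)))
    stop("sequence shorter than the maximum motif width")
  bg <- background[c("A", "C", "G", "T")]
  logbg <- log(bg)
  bgseq <- vapply(ints, function(v) sum(logbg[v]), numeric(1L))
  ll0 <- sum(bgseq)
  total_pos <- sum(lens - min(widths) + 1L)
  best <- NULL
  for (w in widths) {
    m_per_seq <- lens - w + 1L
    WIND <- do.call(rbind, lapply(ints, function(v) {
      idx <- outer(seq_len(length(v) - w + 1L) - 1L, seq_len(w), "+")
      matrix(v[idx], ncol = w)
    }))
    sid <- rep(seq_along(ints), m_per_seq)
    sid_index <- split(seq_along(sid), sid)
    bgwin <- numeric(nrow(WIND))
    for (c in seq_len(w)) bgwin <- bgwin + logbg[WIND[, c]]
    # candidate starts: words recurring beyond their background expectation
    # are almost surely motif-derived under a zero-or-one-site model, so
    # w-mers are ranked by observed count over background expectation;
    # random windows fill the remainder
    words <- do.call(paste0, as.data.frame(WIND))
    tab <- table(words)
    tab <- tab[tab >= 2L]
    if (length(tab)) {
      expected <- nrow(WIND) * vapply(strsplit(names(tab), ""),
                                      function(b) prod(bg[as.integer(b)]),
                                      numeric(1L))
      tab <- tab[order(as.numeric(tab) / expected, decreasing = TRUE)]
    }
    starts <- match(utils::head(names(tab), n_restarts), words)
    if (length(starts) < n_restarts)
      starts <- c(starts, sample.int(nrow(WIND),
                                     min(n_restarts - length(starts),
                                         nrow(WIND))))
    screened <- lapply(starts, function(i) {
      em_zoops(WIND, sid_index, length(ints), m_per_seq, bgwin, bgseq,
               pwm_from_window(WIND[i, ], w), bg, pseudocount,
               max_iter = 6L, tol = 0)
    })
    ll_short <- vapply(screened, `[[`, numeric(1L), "llr_sites")
    top <- order(ll_short, decreasing = TRUE)[seq_len(min(n_refine, length(screened)))]
    for (i in top) {
      fit <- em_zoops(WIND, sid_index, length(ints), m_per_seq, bgwin, bgseq,
                      screened[[i]]$pwm, bg, pseudocount, max_iter, tol)
      llr <- max(0, fit$llr_sites)
      log_e <- (stats::pchisq(2 * llr, df = 3 * w + 1, lower.tail = FALSE,
                              log.p = TRUE) +
                log(length(widths)) + log(total_pos)) / log(10)
      if (is.null(best) || log_e < best$log_evalue) {
        post <- vapply(seq_along(ints), function(s) max(fit$Z[sid == s]),
                       numeric(1L))
        pos <- vapply(seq_along(ints), function(s)
          which.max(fit$Z[sid == s]), integer(1L))
        best <- list(pwm = fit$pwm, width = w, log_evalue = log_e,
                     gamma = fit$gamma, loglik = fit$loglik,
                     loglik_trace = fit$trace,
                     sites = data.frame(sequence = seq_along(ints),
                                        posterior = post, position = pos,
                                        has_site = post >= site_posterior))
      }
    }
  }
  rownames(best$pwm) <- c("A", "C", "G", "T")
  best$consensus <- consensus_string(best$pwm)
  best$n_members_with_site <- sum(best$sites$has_site)
  class(best) <- "motif_result"
  best
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("<motif_result> %s (width %d), log10 E-value %.2f, sites in %d/%d sequences\n",
              x$consensus, x$width, x$log_evalue, x$n_members_with_site,
              nrow(x$sites)))
  invisible(x)
}

#' Consensus string of a position-weight matrix
#' @param pwm A 4 x width probability matrix with rows A, C, G, T.
#' @return Character scalar.
#' @export
consensus_string <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm, 2L, which.max)], collapse = "")
}

#' Shuffle-calibrated significance threshold for a module's motif
#'
#' Shuffles the letters of each sequence independently, rediscovers a motif
#' on each shuffled set with the identical configuration, and returns the
#' minimum of the shuffled significance scores. A motif found on the real
#' sequences is called significant only when its score beats every shuffled
#' score.
#'
#' @inheritParams discover_motif
#' @param n_shuffles Number of shuffled replicates (default 5).
#' @param seed Integer seed; shuffle `i` uses sub-seed `seed + i`.
#' @param ... Passed to [discover_motif()].
#' @return The minimum shuffled `log_evalue` (log10 scale), with the full
#'   vector attached as attribute `scores`.
#' @export
shuffle_evalue_threshold <- function(sequences, background, n_shuffles = 5,
                                     seed = 1, ...) {
  scores <- vapply(seq_len(n_shuffles), function(i) {
    sh <- shuffle_sequences(sequences, seed = seed + i)
    discover_motif(sh, background, seed = seed + i, ...)$log_evalue
  }, numeric(1L))
  structure(min(scores), scores = scores)
}

#' Is the real motif stronger than every shuffled one?
#'
#' Strict comparison of the real significance score against the
#' shuffle-derived threshold; both must come from identically configured
#' discovery runs.
#'
#' @param real_score,threshold Scores on the same (log10) scale.
#' @return Logical.
#' @export
call_module_motif <- function(real_score, threshold) {
  as.numeric(real_score) < as.numeric(threshold)
}

#' Motif discovery and shuffle calibration for every module
#'
#' @param modules Output of [extract_modules()].
#' @param upstreams Named character vector of upstream sequences per
#'   cistron.
#' @param background Zero-order background model.
#' @param n_shuffles Shuffled replicates per module.
#' @param seed Master seed; module `i` derives its own sub-seed.
#' @param min_members Smallest module analysed (default 3).
#' @param ... Passed to [discover_motif()].
#' @return Data frame with one row per analysed module: `module`, `width`,
#'   `consensus`, `log_evalue`, `log_evalue_threshold`, `n_members`,
#'   `n_members_with_site`, `significant`.
#' @export
analyze_module_motifs <- function(modules, upstreams, background,
                                  n_shuffles = 5, seed = 1, min_members = 3,
                                  ...) {
  rows <- list()
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    seqs <- upstreams[mod$members]
    seqs <- seqs[!is.na(seqs) & nchar(seqs) >= 12L]
    if (length(seqs) < min_members) next
    sub_seed <- seed * 1000L + i
    real <- discover_motif(seqs, background, seed = sub_seed, ...)
    thr <- shuffle_evalue_threshold(seqs, background, n_shuffles = n_shuffles,
                                    seed = sub_seed, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      module = names(modules)[i], width = real$width,
      consensus = real$consensus, log_evalue = real$log_evalue,
      log_evalue_threshold = as.numeric(thr),
      n_members = length(mod$members),
      n_members_with_site = real$n_members_with_site,
      significant = call_module_motif(real$log_evalue, thr))
  }
  if (!length(rows))
    return(data.frame(module = character(), width = integer(),
                      consensus = character(), log_evalue = numeric(),
                      log_evalue_threshold = numeric(), n_members = integer(),
                      n_members_with_site = integer(), significant = logical()))
  do.call(rbind, rows)
}

#' Shortlist modules with both functional enrichment and a shared motif
#'
#' A module is shortlisted when it has at least one term enriched below
#' `p_enrich` that survives the FDR cutoff, and a significant motif with a
#' site in the upstream region of every member. Modules enriched in both
#' annotation schemes (protein class and GO) are reported separately.
#'
#' @param enrichment_list Named list of enrichment data frames (one per
#'   annotation scheme, e.g. `protein_class`, `go`), as from
#'   [enrich_modules()].
#' @param motif_df Output of [analyze_module_motifs()].
#' @param p_enrich Enrichment p-value cutoff (default `1e-4`).
#' @param fdr q-value cutoff (default 0.01).
#' @return List with `shortlist`, `dual` (enriched in every scheme),
#'   `enriched` (per scheme) and `motif_ok` module id vectors.
#' @export
shortlist_modules <- function(enrichment_list, motif_df, p_enrich = 1e-4,
                              fdr = 0.01) {
  enriched <- lapply(enrichment_list, function(e)
    unique(e$module[e$p_value < p_enrich & e$q_value <= fdr]))
  enriched_any <- unique(unlist(enriched, use.names = FALSE))
  motif_ok <- motif_df$module[motif_df$significant &
                              motif_df$n_members_with_site == motif_df$n_members]
  list(shortlist = intersect(enriched_any, motif_ok),
       dual = Reduce(intersect, enriched),
       enriched = enriched, motif_ok = motif_ok)
}

#' Best column agreement between a found consensus and a reference motif
#'
#' Slides the reference along the found consensus (all overlaps) and
#' returns the maximum number of aligned positions with identical bases.
#'
#' @param consensus Found consensus string.
#' @param reference Reference (e.g. planted) consensus string.
#' @return Integer count of matching columns.
#' @export
motif_column_matches <- function(consensus, reference) {
  a <- strsplit(consensus, "")[[1L]]
  b <- strsplit(reference, "")[[1L]]
  best <- 0L
  for (off in seq(-length(b) + 1L, length(a) - 1L)) {
    i <- seq_along(b) + off
    ok <- i >= 1L & i <= length(a)
    best <- max(best, sum(a[i[ok]] == b[ok]))
  }
  best
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs Named list of `motif_result` objects (names become motif
#'   ids).
#' @param background Zero-order background frequencies.
#' @param path Output path.
#' @export
write_meme_minimal <- function(motifs, background, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[["A"]], background[["C"]],
                       background[["G"]], background[["T"]]), ""), con)
  for (id in names(motifs)) {
    m <- motifs[[id]]
    writeLines(sprintf("MOTIF %s %s", id, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
      m$width, m$n_members_with_site, 10^m$log_evalue), con)
    writeLines(apply(m$pwm, 2L, function(col)
      sprintf(" %.6f %.6f %.6f %.6f", col[1L], col[2L], col[3L], col[4L])), con)
    writeLines("", con)
  }
  invisible(path)
}
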