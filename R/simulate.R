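#' Configuration for the synthetic study generator
#'
#' Defaults describe a desk-scale bacterial genome with operon structure,
#' regulator-driven expression across three array platforms, and planted
#' promoter motifs: 1000 genes in geometric-length operons (mean 2), short
#' within-operon gaps (mean 20 bp) versus long boundary gaps (mean 150 bp),
#' 60 regulator cistrons with on average 8 target cistrons each, 200 samples
#' split over three platforms, and an upstream background matching a
#' high-GC genome.
#'
#' @param n_genes Number of genes.
#' @param operon_mean_length Mean operon length (geometric distribution).
#' @param gap_within_mean,gap_between_mean Mean intergenic gaps (bp) inside
#'   operons and at operon boundaries.
#' @param gene_length_mean Mean coding length (bp).
#' @param gap_shape Negative-binomial shape of the intergenic gaps; the
#'   default 1 gives the heavy-tailed, strongly overlapping distance
#'   distributions seen in real genomes, so distance alone is informative
#'   but far from clean.
#' @param n_regulators Number of regulator cistrons.
#' @param targets_per_regulator Mean targets per regulator.
#' @param n_samples Integer vector of samples per platform (3 platforms).
#' @param noise_sd Gene-level expression noise sd around the cistron latent
#'   profile (z-score units).
#' @param dep_noise_sd Noise sd on the regulator-to-target link.
#' @param nonlinear_fraction Fraction of links that are nonlinear (split
#'   between quadratic and sigmoidal).
#' @param absent_rate Per-cell absent-call probability.
#' @param p_share Probability that a within-operon gene shares its operon's
#'   protein class / GO terms.
#' @param class_unassigned_rate,go_unassigned_rate Per-gene probability of
#'   missing annotation.
#' @param class_share_between Probability that an operon inherits the
#'   protein class of the preceding operon (neighbouring operons often sit
#'   in related pathways, so boundary pairs share classes at a low
#'   background rate).
#' @param n_protein_classes Size of the flat protein classification scheme.
#' @param cons_mean_operon,cons_mean_boundary Poisson means of the
#'   gene-order conservation counts for pairs with ortholog support.
#' @param cons_rate_operon,cons_rate_boundary Probability that a
#'   true-operon (resp. boundary) pair has any ortholog support at all;
#'   pairs without support count 0 genomes, emulating the sparse coverage
#'   of ortholog databases.
#' @param motif_width Planted motif width (bp).
#' @param motif_identity Per-column probability that a planted instance
#'   keeps the consensus base.
#' @param upstream_length Upstream window length (bp).
#' @param background Base frequencies of intergenic sequence.
#' @param oligo_coverage Fraction of genes with a probeset on platform 3.
#' @param training_n_kop,training_n_nop Labeled pairs sampled from truth.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000, operon_mean_length = 2,
                             gap_within_mean = 20, gap_between_mean = 150,
                             gap_shape = 1, gene_length_mean = 900,
                             n_regulators = 60,
                             targets_per_regulator = 8,
                             n_samples = c(70, 70, 60), noise_sd = 0.6,
                             dep_noise_sd = 0.3, nonlinear_fraction = 0.25,
                             absent_rate = 0.05, p_share = 0.75,
                             class_unassigned_rate = 0.20,
                             go_unassigned_rate = 0.25,
                             class_share_between = 0.10,
                             n_protein_classes = 140,
                             cons_mean_operon = 12, cons_mean_boundary = 2,
                             cons_rate_operon = 0.35,
                             cons_rate_boundary = 0.10,
                             motif_width = 8, motif_identity = 0.9,
                             upstream_length = 300,
                             background = c(A = 0.153, C = 0.351,
                                            G = 0.347, T = 0.149),
                             oligo_coverage = 0.9,
                             training_n_kop = 425, training_n_nop = 131) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 10, operon_mean_length >= 1, length(n_samples) == 3L,
            all(n_samples > 0), nonlinear_fraction >= 0,
            nonlinear_fraction <= 1, absent_rate >= 0, absent_rate < 1,
            p_share >= 0, p_share <= 1, abs(sum(background) - 1) < 1e-9)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic genome with known operon structure
#'
#' Lays `n_genes` on a single contig: operon members share a strand and are
#' separated by short gaps; operon boundaries get long gaps and a freshly
#' drawn strand. The true transcription-unit map is recorded in the same
#' form that [chain_operons()] produces.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `genes` (a `gene_table`; annotation columns still
#'   empty) and `truth` (an `operon_map`).
#' @export
generate_genome <- function(cfg, seed = 1) {
  set.seed(seed)
  sizes <- integer()
  while (sum(sizes) < cfg$n_genes)
    sizes <- c(sizes, stats::rgeom(100L, prob = 1 / cfg$operon_mean_length) + 1L)
  sizes <- sizes[cumsum(sizes) <= cfg$n_genes]
  if (sum(sizes) < cfg$n_genes) sizes <- c(sizes, cfg$n_genes - sum(sizes))
  n_units <- length(sizes)
  strands <- sample(c("+", "-"), n_units, replace = TRUE)
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
  start <- integer(cfg$n_genes)
  end <- integer(cfg$n_genes)
  strand <- character(cfg$n_genes)
  unit_of <- integer(cfg$n_genes)
  pos <- 501L   # leave room for a full upstream window before the first gene
  g <- 0L
  for (u in seq_len(n_units)) {
    for (k in seq_len(sizes[u])) {
      g <- g + 1L
      len <- max(150L, round(stats::rnorm(1L, cfg$gene_length_mean, 200)))
      start[g] <- pos
      end[g] <- pos + len - 1L
      strand[g] <- strands[u]
      unit_of[g] <- u
      gap <- if (k < sizes[u])
        stats::rnbinom(1L, mu = cfg$gap_within_mean, size = cfg$gap_shape)
      else
        stats::rnbinom(1L, mu = cfg$gap_between_mean, size = cfg$gap_shape)
      pos <- end[g] + 1L + gap
    }
  }
  genes <- gene_table(data.frame(
    gene_id = gene_id, contig = "chr", start = start, end = end,
    strand = strand, protein_class = NA_character_, go_bp = "", go_mf = "",
    regulator = FALSE))
  units <- split(gene_id, unit_of)
  units <- lapply(seq_len(n_units), function(u)
    if (strands[u] == "+") units[[u]] else rev(units[[u]]))
  names(units) <- sprintf("TU%05d", seq_len(n_units))
  truth <- structure(list(units = units,
                          gene2unit = stats::setNames(
                            rep(names(units), lengths(units)), unlist(units))),
                     class = "operon_map")
  list(genes = genes, truth = truth)
}

make_toy_dag <- function(prefix, n1 = 6L, n2 = 4L, n3 = 3L) {
  parents <- list()
  root <- paste0(prefix, ":root")
  parents[[root]] <- character()
  leaves <- character()
  for (i in seq_len(n1)) {
    t1 <- sprintf("%s:%d", prefix, i)
    parents[[t1]] <- root
    for (j in seq_len(n2)) {
      t2 <- sprintf("%s:%d.%d", prefix, i, j)
      parents[[t2]] <- t1
      for (k in seq_len(n3)) {
        t3 <- sprintf("%s:%d.%d.%d", prefix, i, j, k)
        parents[[t3]] <- t2
        leaves <- c(leaves, t3)
      }
    }
  }
  list(dag = go_dag(parents), leaves = leaves)
}

#' Annotate a synthetic genome and draw gene-order conservation
#'
#' Within-operon genes share their operon's protein class and GO term sets
#' with probability `p_share`; other genes draw independently. Conservation
#' counts are Poisson with a high mean for true within-operon pairs and a
#' low mean for boundary pairs. Two three-level toy ontologies (biological
#' process, molecular function) are built and their corpus counts derived
#' from the generated annotations.
#'
#' @param genes A `gene_table` from [generate_genome()].
#' @param truth The matching true `operon_map`.
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with the annotated `genes`, `conservation` table, the two
#'   DAGs (`dag_bp`, `dag_mf`) with information contents (`ic_bp`,
#'   `ic_mf`).
#' @export
generate_annotations <- function(genes, truth, cfg, seed = 2) {
  set.seed(seed)
  bp <- make_toy_dag("BP")
  mf <- make_toy_dag("MF")
  classes <- sprintf("class_%03d", seq_len(cfg$n_protein_classes))
  units <- truth$units
  class_vec <- stats::setNames(character(nrow(genes)), genes$gene_id)
  bp_vec <- stats::setNames(character(nrow(genes)), genes$gene_id)
  mf_vec <- stats::setNames(character(nrow(genes)), genes$gene_id)
  draw_terms <- function(leaves) paste(sample(leaves, sample(2:4, 1L)),
                                       collapse = ";")
  prev_class <- NA_character_
  for (u in units) {
    u_class <- if (!is.na(prev_class) &&
                   stats::runif(1L) < cfg$class_share_between) prev_class
               else sample(classes, 1L)
    prev_class <- u_class
    u_bp <- draw_terms(bp$leaves)
    u_mf <- draw_terms(mf$leaves)
    for (g in u) {
      share <- stats::runif(1L) < cfg$p_share
      class_vec[g] <- if (share) u_class else sample(classes, 1L)
      bp_vec[g] <- if (share) u_bp else draw_terms(bp$leaves)
      mf_vec[g] <- if (share) u_mf else draw_terms(mf$leaves)
    }
  }
  drop_class <- stats::runif(nrow(genes)) < cfg$class_unassigned_rate
  drop_go <- stats::runif(nrow(genes)) < cfg$go_unassigned_rate
  class_vec[drop_class] <- NA_character_
  bp_vec[drop_go] <- ""
  mf_vec[drop_go] <- ""
  genes$protein_class <- unname(class_vec[genes$gene_id])
  genes$go_bp <- unname(bp_vec[genes$gene_id])
  genes$go_mf <- unname(mf_vec[genes$gene_id])
  reg_units <- sample(names(units), cfg$n_regulators)
  first_genes <- vapply(units[reg_units], `[[`, character(1L), 1L)
  genes$regulator <- genes$gene_id %in% first_genes
  genes <- gene_table(as.data.frame(genes))
  # conservation counts for every same-strand adjacent pair
  pairs <- same_strand_adjacent_pairs(genes)
  same_unit <- truth$gene2unit[pairs$upstream] == truth$gene2unit[pairs$downstream]
  covered <- stats::runif(nrow(pairs)) <
    ifelse(same_unit, cfg$cons_rate_operon, cfg$cons_rate_boundary)
  counts <- ifelse(same_unit,
                   stats::rpois(nrow(pairs), cfg$cons_mean_operon),
                   stats::rpois(nrow(pairs), cfg$cons_mean_boundary)) * covered
  conservation <- data.frame(gene_a = pairs$upstream, gene_b = pairs$downstream,
                             probability = round(stats::runif(nrow(pairs)), 3),
                             genome_count = counts)[counts > 0, , drop = FALSE]
  ann_counts <- function(col) {
    tab <- table(unlist(lapply(col, split_terms), use.names = FALSE))
    stats::setNames(as.numeric(tab), names(tab))
  }
  list(genes = genes, conservation = conservation,
       dag_bp = bp$dag, dag_mf = mf$dag,
       ic_bp = term_ic(bp$dag, ann_counts(genes$go_bp)),
       ic_mf = term_ic(mf$dag, ann_counts(genes$go_mf)))
}

#' Generate regulator-driven expression across three platforms
#'
#' Each transcription unit gets a latent profile over all samples:
#' regulator and unregulated cistrons are independent standard normals;
#' target cistrons are a (linear, quadratic or sigmoidal) link of their
#' hub's latent plus dependency noise, re-standardized. Member genes add
#' i.i.d. noise to their unit's latent. Samples are split across the three
#' platforms; platform 3 covers a random `oligo_coverage` subset of genes
#' (the probeset list); absent calls are sprinkled at `absent_rate`.
#'
#' @param genes Annotated `gene_table` (regulator flags set).
#' @param truth The true `operon_map`.
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `datasets` (three [expression_dataset()]s),
#'   `probeset_genes`, `edges` (true hub-to-target cistron edges with link
#'   type) and `latent` (unit x sample clean matrix).
#' @export
generate_expression <- function(genes, truth, cfg, seed = 3) {
  set.seed(seed)
  units <- truth$units
  n_units <- length(units)
  N <- sum(cfg$n_samples)
  reg_units <- select_regulator_cistrons(truth, genes)
  latent <- matrix(stats::rnorm(n_units * N), n_units, N,
                   dimnames = list(names(units), NULL))
  pool <- sample(setdiff(names(units), reg_units))
  edges <- list()
  for (hub in sample(reg_units)) {
    n_t <- min(max(1L, stats::rpois(1L, cfg$targets_per_regulator)),
               length(pool))
    if (n_t == 0L) break
    targets <- pool[seq_len(n_t)]
    pool <- pool[-seq_len(n_t)]
    links <- sample(c("linear", "quadratic", "sigmoid"), n_t, replace = TRUE,
                    prob = c(1 - cfg$nonlinear_fraction,
                             cfg$nonlinear_fraction / 2,
                             cfg$nonlinear_fraction / 2))
    for (i in seq_along(targets)) {
      h <- latent[hub, ]
      y <- switch(links[i],
                  linear = h,
                  quadratic = h^2,
                  sigmoid = tanh(2 * h))
      y <- y + cfg$dep_noise_sd * stats::rnorm(N)
      latent[targets[i], ] <- (y - mean(y)) / stats::sd(y)
    }
    edges[[hub]] <- data.frame(hub = hub, target = targets, link = links)
  }
  edges <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
  gene_unit <- truth$gene2unit[genes$gene_id]
  expr <- latent[gene_unit, , drop = FALSE] +
    cfg$noise_sd * matrix(stats::rnorm(nrow(genes) * N), nrow(genes), N)
  rownames(expr) <- genes$gene_id
  bounds <- cumsum(c(0L, cfg$n_samples))
  platforms <- c("cDNA_gDNA", "cDNA_cDNA", "oligo_chip")
  probeset_genes <- sort(sample(genes$gene_id,
                                round(cfg$oligo_coverage * nrow(genes))))
  datasets <- lapply(1:3, function(p) {
    cols <- (bounds[p] + 1L):bounds[p + 1L]
    vals <- expr[, cols, drop = FALSE]
    if (p == 3L) vals <- vals[probeset_genes, , drop = FALSE]
    colnames(vals) <- sprintf("%s_s%03d", platforms[p], seq_along(cols))
    mask <- matrix(stats::runif(length(vals)) < cfg$absent_rate,
                   nrow(vals), ncol(vals))
    allmasked <- rowSums(!mask) == 0L
    mask[allmasked, 1L] <- FALSE
    vals[mask] <- NA_real_
    expression_dataset(vals, mask, platforms[p])
  })
  list(datasets = datasets, probeset_genes = probeset_genes, edges = edges,
       latent = latent)
}

#' Generate a genome sequence with planted promoter motifs
#'
#' Samples the contig from the configured base frequencies, draws one
#' consensus motif per regulator module, and plants one (per-column
#' corrupted) instance in the upstream window of every module member,
#' strand-aware, at a uniform offset. Placements are recorded.
#'
#' @param genes Annotated `gene_table`.
#' @param truth The true `operon_map`.
#' @param edges True hub-to-target edges from [generate_expression()].
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `genome` (named character vector of contigs),
#'   `consensus` (named by hub) and `placements` (data frame: hub, unit,
#'   gene, offset within the upstream window, genomic start).
#' @export
generate_promoters <- function(genes, truth, edges, cfg, seed = 4) {
  set.seed(seed)
  if (cfg$upstream_length < cfg$motif_width)
    stop("motif wider than the upstream window")
  L <- max(genes$end) + 600L
  bases <- c("A", "C", "G", "T")
  contig <- sample(bases, L, replace = TRUE,
                   prob = cfg$background[bases])
  w <- cfg$motif_width
  hubs <- unique(edges$hub)
  consensus <- stats::setNames(
    vapply(hubs, function(h) paste(sample(bases, w, replace = TRUE),
                                   collapse = ""), character(1L)), hubs)
  placements <- list()
  for (h in hubs) {
    members <- c(h, edges$target[edges$hub == h])
    cons <- strsplit(consensus[[h]], "")[[1L]]
    for (u in members) {
      first <- truth$units[[u]][1L]
      g <- genes[first, ]
      inst <- vapply(cons, function(b)
        if (stats::runif(1L) < cfg$motif_identity) b
        else sample(setdiff(bases, b), 1L), character(1L))
      off <- sample.int(cfg$upstream_length - w + 1L, 1L) - 1L
      if (g$strand == "+") {
        gstart <- g$start - cfg$upstream_length + off
        contig[gstart:(gstart + w - 1L)] <- inst
      } else {
        gend <- g$end + cfg$upstream_length - off
        contig[(gend - w + 1L):gend] <- rev(c(A = "T", C = "G", G = "C",
                                              T = "A")[inst])
      }
      placements[[length(placements) + 1L]] <- data.frame(
        hub = h, unit = u, gene = first, offset = off,
        genomic_start = if (g$strand == "+") g$start - cfg$upstream_length + off
                        else g$end + cfg$upstream_length - off - w + 1L)
    }
  }
  list(genome = c(chr = paste(contig, collapse = "")),
       consensus = consensus,
       placements = do.call(rbind, placements))
}

#' Sample a labeled training set from the true operon map
#'
#' Known-operon pairs (KOP) are within-unit adjacent pairs; non-operon
#' pairs (NOP) are same-strand adjacent pairs spanning a unit boundary.
#'
#' @param genes A `gene_table`.
#' @param truth The true `operon_map`.
#' @param n_kop,n_nop Pairs sampled per class (capped at availability).
#' @param seed Integer seed.
#' @return Data frame `gene_a`, `gene_b`, `label`.
#' @export
sample_training_pairs <- function(genes, truth, n_kop = 425, n_nop = 131,
                                  seed = 5) {
  set.seed(seed)
  pairs <- same_strand_adjacent_pairs(genes)
  same <- truth$gene2unit[pairs$upstream] == truth$gene2unit[pairs$downstream]
  pick <- function(idx, n) idx[sample.int(length(idx), min(n, length(idx)))]
  ik <- pick(which(same), n_kop)
  inn <- pick(which(!same), n_nop)
  data.frame(gene_a = pairs$upstream[c(ik, inn)],
             gene_b = pairs$downstream[c(ik, inn)],
             label = rep(c("KOP", "NOP"), c(length(ik), length(inn))))
}

#' Generate and write a complete synthetic study
#'
#' Runs every generator stage with sub-seeds derived from the master seed
#' and writes the exact file formats the pipeline consumes, plus a `truth/`
#' directory for benchmarking.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [synthetic_config()].
#' @param seed Master seed; stage sub-seeds are `seed * 10 + 1..5`.
#' @return Invisibly, a list with all in-memory stage outputs.
#' @export
write_synthetic_study <- function(dir, cfg = synthetic_config(), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  gen <- generate_genome(cfg, seed * 10L + 1L)
  ann <- generate_annotations(gen$genes, gen$truth, cfg, seed * 10L + 2L)
  ex <- generate_expression(ann$genes, gen$truth, cfg, seed * 10L + 3L)
  prom <- generate_promoters(ann$genes, gen$truth, ex$edges, cfg,
                             seed * 10L + 4L)
  training <- sample_training_pairs(ann$genes, gen$truth,
                                    cfg$training_n_kop, cfg$training_n_nop,
                                    seed * 10L + 5L)
  write_annotation(ann$genes, file.path(dir, "annotation.tsv"))
  files <- c("expr_cdna_gdna.tsv", "expr_cdna_cdna.tsv", "expr_oligo.tsv")
  for (i in 1:3)
    write_expression_table(ex$datasets[[i]], file.path(dir, files[i]))
  writeLines(ex$probeset_genes, file.path(dir, "probeset.txt"))
  utils::write.table(ann$conservation, file.path(dir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(training, file.path(dir, "training.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(prom$genome),
    file.path(dir, "genome.fasta"))
  dag_tsv <- function(dag, path) {
    utils::write.table(
      data.frame(term = dag$terms,
                 parents = vapply(dag$parents, paste, character(1L),
                                  collapse = ";")),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  dag_tsv(ann$dag_bp, file.path(dir, "go_dag_bp.tsv"))
  dag_tsv(ann$dag_mf, file.path(dir, "go_dag_mf.tsv"))
  write_operon_map(gen$truth, file.path(dir, "truth", "operons.tsv"))
  utils::write.table(ex$edges, file.path(dir, "truth", "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prom$placements, file.path(dir, "truth", "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(as.list(prom$consensus), auto_unbox = TRUE),
             file.path(dir, "truth", "consensus.json"))
  invisible(list(genes = ann$genes, truth = gen$truth, annotations = ann,
                 expression = ex, promoters = prom, training = training))
}
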