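PIPELINE_DEFAULTS <- list(
  absent_strict = 0.20, absent_loose = 0.50, sd_percentile = 25,
  k_impute = 15, kernel = "radial", cost = 1,
  feature_subset = c("class_score", "cd_score", "ic_sim", "conservation",
                     "distance", "r"),
  p_threshold = 1e-9, dpi_tolerance = 0.05, n_null_permutations = 1e5,
  upstream_length = 300, n_shuffles = 5, p_enrich = 1e-4, fdr = 0.01,
  motif_width_min = 6, motif_width_max = 12, min_module_members = 3,
  seed = 1)

PIPELINE_INPUT_KEYS <- c("annotation", "expr_cdna_gdna", "expr_cdna_cdna",
                         "expr_oligo", "probeset", "conservation", "training",
                         "genome", "go_dag_bp", "go_dag_mf")

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for every missing
#' setting, rejects unknown keys and checks ranges. Defaults mirror the
#' standard analysis settings: MI significance `1e-9`, DPI tolerance 0.05,
#' 300 bp upstream windows, five shuffles, enrichment p `1e-4` at FDR 0.01.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  known <- c(names(PIPELINE_DEFAULTS), PIPELINE_INPUT_KEYS, "outdir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  with(cfg, {
    if (!(p_threshold > 0 && p_threshold < 1))
      stop("p_threshold must be in (0, 1)")
    if (!(dpi_tolerance >= 0 && dpi_tolerance < 1))
      stop("dpi_tolerance must be in [0, 1)")
    if (!(fdr > 0 && fdr <= 1)) stop("fdr must be in (0, 1]")
    if (!(absent_strict >= 0 && absent_strict <= absent_loose &&
          absent_loose <= 1))
      stop("need 0 <= absent_strict <= absent_loose <= 1")
    if (upstream_length < 1) stop("upstream_length must be positive")
    if (motif_width_min > motif_width_max) stop("empty motif width range")
    if (!kernel %in% c("radial", "linear")) stop("kernel must be radial or linear")
  })
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a term DAG written by [write_synthetic_study()]
#' @param path TSV with columns `term` and semicolon-separated `parents`.
#' @return A [go_dag()].
#' @export
read_go_dag <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  go_dag(stats::setNames(lapply(df$parents, split_terms), df$term))
}

read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Run the inference pipeline end-to-end or stage-by-stage
#'
#' Stages run in fixed order: `compendium` (filter/impute/standardize/
#' concatenate), `features` (pair feature assembly), `operons`
#' (cross-validated classifier, genome-wide prediction, unit chaining),
#' `network` (cistron aggregation, MI network, DPI, degree fit) and
#' `modules` (enrichment, motif discovery, shortlist). Each stage persists
#' its outputs as plain files under `outdir` and later stages reload them,
#' so any stage can be rerun in isolation.
#'
#' @param config A [validate_config()] result (or path / list accepted by
#'   it). Input paths must be set for the first requested stage.
#' @param stages Character subset of
#'   `c("compendium","features","operons","network","modules")`.
#' @param outdir Output directory (default `config$outdir`).
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(config, stages = c("compendium", "features",
                                            "operons", "network", "modules"),
                         outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  all_stages <- c("compendium", "features", "operons", "network", "modules")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  outdir <- outdir %||% cfg$outdir %||% stop("no output directory configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report_path <- file.path(outdir, "report.json")
  report <- if (file.exists(report_path))
    jsonlite::read_json(report_path, simplifyVector = TRUE) else list()
  report$seed <- cfg$seed
  need <- function(key) cfg[[key]] %||%
    stop("config is missing required input path: ", key)
  artifact <- function(name) {
    p <- file.path(outdir, name)
    if (!file.exists(p))
      stop("missing upstream artifact ", name,
           "; rerun the stage that produces it")
    p
  }
  genes <- NULL
  load_genes <- function() genes %||% read_annotation(need("annotation"))

  if ("compendium" %in% stages) {
    message("[compendium] filtering and assembling the expression matrix")
    ds1 <- read_expression_table(need("expr_cdna_gdna"), "cDNA_gDNA")
    ds2 <- read_expression_table(need("expr_cdna_cdna"), "cDNA_cDNA")
    ds3 <- read_expression_table(need("expr_oligo"), "oligo_chip")
    probes <- readLines(need("probeset"))
    stats <- compute_filter_stats(ds1, ds2, probes)
    selected <- select_genes(stats, filter_thresholds(cfg$absent_strict,
                                                      cfg$absent_loose,
                                                      cfg$sd_percentile))
    comp <- build_compendium(ds1, ds2, ds3,
                             filter_thresholds(cfg$absent_strict,
                                               cfg$absent_loose,
                                               cfg$sd_percentile),
                             k = cfg$k_impute)
    write_expression_table(comp$expr, file.path(outdir, "compendium.tsv"))
    writeLines(comp$selected, file.path(outdir, "selected_genes.txt"))
    report$genes_selected <- length(comp$selected)
  }
  if ("features" %in% stages) {
    message("[features] assembling pair features")
    genes <- load_genes()
    expr <- read_expression_table(artifact("compendium.tsv"), "compendium")
    pairs <- same_strand_adjacent_pairs(genes)
    cons <- if (!is.null(cfg$conservation))
      read_conservation_table(cfg$conservation) else NULL
    training <- if (!is.null(cfg$training))
      read_training_pairs(cfg$training) else NULL
    dag_bp <- if (!is.null(cfg$go_dag_bp)) read_go_dag(cfg$go_dag_bp) else NULL
    dag_mf <- if (!is.null(cfg$go_dag_mf)) read_go_dag(cfg$go_dag_mf) else NULL
    count_terms <- function(col) {
      tab <- table(unlist(lapply(col, split_terms), use.names = FALSE))
      stats::setNames(as.numeric(tab), names(tab))
    }
    pf <- assemble_features(pairs, genes, cons, expr, training,
                            dag_bp = dag_bp, dag_mf = dag_mf,
                            ic_bp = if (!is.null(dag_bp))
                              term_ic(dag_bp, count_terms(genes$go_bp)),
                            ic_mf = if (!is.null(dag_mf))
                              term_ic(dag_mf, count_terms(genes$go_mf)))
    utils::write.table(pf, file.path(outdir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$n_pairs <- nrow(pf)
    report$n_labeled <- sum(!is.na(pf$label))
  }
  if ("operons" %in% stages) {
    message("[operons] training classifier and chaining transcription units")
    genes <- load_genes()
    pf <- utils::read.delim(artifact("features.tsv"),
                            stringsAsFactors = FALSE)
    class(pf) <- c("pair_features", "data.frame")
    cv <- cross_validate(pf, cfg$feature_subset, cfg$kernel, cost = cfg$cost,
                         seed = cfg$seed)
    model <- train_classifier(pf, cfg$feature_subset, cfg$kernel,
                              cost = cfg$cost)
    scores <- predict_genome(model, pf)
    calls <- scores > 0
    map <- chain_operons(genes, pf[, c("upstream", "downstream")], calls)
    utils::write.table(data.frame(pf[, c("upstream", "downstream")],
                                  score = scores, call = calls),
                       file.path(outdir, "pair_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_operon_map(map, file.path(outdir, "operon_map.tsv"))
    report$cv_mean_auc <- cv$mean_auc
    report$n_units <- length(map$units)
    report$n_polycistronic <- sum(lengths(map$units) > 1L)
    report$n_positive_pairs <- sum(calls)
  }
  if ("network" %in% stages) {
    message("[network] inferring the mutual-information network")
    genes <- load_genes()
    expr <- read_expression_table(artifact("compendium.tsv"), "compendium")
    map <- read_operon_map(artifact("operon_map.tsv"))
    cx <- aggregate_cistron_expression(map, expr)
    regulators <- intersect(select_regulator_cistrons(map, genes),
                            rownames(cx$values))
    net <- build_network(cx, regulators,
                         network_config(cfg$p_threshold, cfg$dpi_tolerance,
                                        cfg$n_null_permutations),
                         seed = cfg$seed)
    utils::write.table(net$edges, file.path(outdir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_sif(net, file.path(outdir, "network.sif"))
    write_module_mi(net, file.path(outdir, "module_mi.tsv"))
    writeLines(regulators, file.path(outdir, "regulator_cistrons.txt"))
    fit <- tryCatch(fit_degree_powerlaw(net), error = function(e) NULL)
    report$n_cistrons <- nrow(cx$values)
    report$n_regulator_cistrons <- length(regulators)
    report$n_edges <- nrow(net$edges)
    report$n_network_nodes <- length(unique(c(net$edges$a, net$edges$b)))
    report$mi_threshold <- net$mi0
    if (!is.null(fit)) {
      report$powerlaw_coefficient <- fit$coefficient
      report$powerlaw_exponent <- fit$exponent
    }
  }
  if ("modules" %in% stages) {
    message("[modules] enrichment and motif analysis")
    genes <- load_genes()
    map <- read_operon_map(artifact("operon_map.tsv"))
    edges <- utils::read.delim(artifact("network_edges.tsv"),
                               stringsAsFactors = FALSE)
    regulators <- readLines(artifact("regulator_cistrons.txt"))
    expr <- read_expression_table(artifact("compendium.tsv"), "compendium")
    cx <- aggregate_cistron_expression(map, expr)
    net <- structure(list(edges = edges, nodes = rownames(cx$values),
                          regulators = regulators, mi0 = NA_real_,
                          config = NULL),
                     class = "regulatory_network")
    mods <- extract_modules(net)
    universe <- rownames(cx$values)
    class_map <- cistron_annotation(map, genes, "protein_class")
    bp_map <- cistron_annotation(map, genes, "go_bp")
    mf_map <- cistron_annotation(map, genes, "go_mf")
    go_map <- stats::setNames(Map(union, bp_map, mf_map), names(map$units))
    enr_class <- enrich_modules(mods, class_map, universe, seed = cfg$seed)
    enr_go <- enrich_modules(mods, go_map, universe, seed = cfg$seed)
    utils::write.table(enr_class, file.path(outdir, "enrichment_class.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr_go, file.path(outdir, "enrichment_go.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genome <- read_genome_fasta(need("genome"))
    ups <- upstream_sequences(genome, genes, map, names(map$units),
                              cfg$upstream_length)
    background <- background_from_upstreams(ups)
    motifs <- analyze_module_motifs(mods, ups, background,
                                    n_shuffles = cfg$n_shuffles,
                                    seed = cfg$seed,
                                    min_members = cfg$min_module_members,
                                    width_range = c(cfg$motif_width_min,
                                                    cfg$motif_width_max))
    utils::write.table(motifs, file.path(outdir, "motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    short <- shortlist_modules(list(protein_class = enr_class, go = enr_go),
                               motifs, cfg$p_enrich, cfg$fdr)
    writeLines(short$shortlist, file.path(outdir, "shortlist.txt"))
    report$n_modules <- length(mods)
    report$n_enriched_modules <-
      length(unique(unlist(short$enriched, use.names = FALSE)))
    report$n_motif_significant <- sum(motifs$significant)
    report$n_shortlisted <- length(short$shortlist)
    report$n_dual_enriched <- length(short$dual)
  }
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), report_path)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
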