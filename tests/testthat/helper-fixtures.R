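# Shared fixture builders; everything is generated in code at test time.

make_ds <- function(vals, mask = NULL, platform = "cDNA_gDNA") {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  expression_dataset(vals, mask, platform)
}

make_genes <- function(start, end, strand, contig = "chr",
                       class = NA_character_, bp = "", mf = "",
                       regulator = FALSE) {
  n <- length(start)
  gene_table(data.frame(
    gene_id = sprintf("g%d", seq_len(n)), contig = rep_len(contig, n),
    start = start, end = end, strand = strand,
    protein_class = rep_len(class, n), go_bp = rep_len(bp, n),
    go_mf = rep_len(mf, n), regulator = rep_len(regulator, n)))
}

# 4-term toy ontology: root -> {x, y}, x -> z, with direct annotation
# counts z=1, x=1, y=2 (cumulative: z=1, x=2, y=2, root=4)
toy_dag <- function() {
  dag <- go_dag(list(root = character(), x = "root", y = "root", z = "x"))
  list(dag = dag, ic = term_ic(dag, c(z = 1, x = 1, y = 2)))
}

sample_bg_seqs <- function(n, L, bg = c(A = 0.153, C = 0.351,
                                        G = 0.347, T = 0.149)) {
  vapply(seq_len(n), function(i)
    paste(sample(names(bg), L, replace = TRUE, prob = bg), collapse = ""),
    character(1L))
}

plant_motif <- function(seqs, consensus, identity = 0.9) {
  w <- nchar(consensus)
  cc <- strsplit(consensus, "")[[1L]]
  vapply(seqs, function(s) {
    inst <- vapply(cc, function(b)
      if (stats::runif(1L) < identity) b
      else sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    off <- sample.int(nchar(s) - w + 1L, 1L)
    paste0(substr(s, 1L, off - 1L), paste(inst, collapse = ""),
           substr(s, off + w, nchar(s)))
  }, character(1L))
}

training_source_dir <- function() {
  system.file("extdata", "training_sources_synthetic", package = "cistronet")
}

read_source <- function(f) {
  utils::read.delim(file.path(training_source_dir(), f),
                    colClasses = "character")
}
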