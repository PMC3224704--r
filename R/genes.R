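#' Read a gene annotation table
#'
#' Flat TSV with one row per gene and columns `gene_id`, `contig`, `start`,
#' `end`, `strand` (`+`/`-`), `protein_class` (empty when unassigned),
#' `go_bp` and `go_mf` (semicolon-separated GO term ids, possibly empty) and
#' `regulator` (`0`/`1`). Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @return A data frame of class `gene_table`, sorted by contig then start.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         contig = "character",
                                         protein_class = "character",
                                         go_bp = "character",
                                         go_mf = "character"))
  gene_table(df)
}

#' Construct/validate a gene table
#'
#' @param df Data frame with the columns described in [read_annotation()].
#' @return The validated, sorted data frame with class `gene_table`.
#' @export
gene_table <- function(df) {
  req <- c("gene_id", "contig", "start", "end", "strand", "protein_class",
           "go_bp", "go_mf", "regulator")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id: ", df$gene_id[duplicated(df$gene_id)][1L])
  if (any(df$start > df$end)) stop("gene with start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$protein_class[is.na(df$protein_class) | df$protein_class == ""] <- NA_character_
  df$go_bp[is.na(df$go_bp)] <- ""
  df$go_mf[is.na(df$go_mf)] <- ""
  df$regulator <- as.logical(df$regulator)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- df$gene_id
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Write a gene table as TSV
#' @param genes A `gene_table`.
#' @param path Output path.
#' @export
write_annotation <- function(genes, path) {
  out <- as.data.frame(genes)
  out$regulator <- as.integer(out$regulator)
  out$protein_class[is.na(out$protein_class)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate same-strand adjacent gene pairs
#'
#' Every consecutive couple of genes on the same contig and strand yields one
#' pair, oriented upstream to downstream in the direction of transcription
#' (for minus-strand couples the right-hand gene is upstream).
#'
#' @param genes A `gene_table` sorted by contig then start (as produced by
#'   [read_annotation()]); unsorted input is rejected.
#' @return Data frame with columns `upstream`, `downstream`, `contig`,
#'   `strand`.
#' @export
same_strand_adjacent_pairs <- function(genes) {
  if (is.unsorted(order(genes$contig, genes$start)) ||
      !identical(order(genes$contig, genes$start), seq_len(nrow(genes))))
    stop("genes must be sorted by contig then start")
  n <- nrow(genes)
  if (n < 2L)
    return(data.frame(upstream = character(), downstream = character(),
                      contig = character(), strand = character()))
  i <- seq_len(n - 1L)
  ok <- genes$contig[i] == genes$contig[i + 1L] &
        genes$strand[i] == genes$strand[i + 1L]
  i <- i[ok]
  plus <- genes$strand[i] == "+"
  data.frame(upstream = ifelse(plus, genes$gene_id[i], genes$gene_id[i + 1L]),
             downstream = ifelse(plus, genes$gene_id[i + 1L], genes$gene_id[i]),
             contig = genes$contig[i], strand = genes$strand[i],
             row.names = NULL)
}

#' Intergenic distance of an adjacent same-strand pair
#'
#' Gap length in bp between the upstream gene's stop and the downstream
#' gene's start, in strand-aware (transcription-order) coordinates: abutting
#' genes have distance 0 and overlapping coding regions give negative values.
#'
#' @param upstream,downstream Single rows of a `gene_table` (or lists with
#'   `start`, `end`, `strand`), adjacent on the same contig and strand, with
#'   `upstream` first in transcription order.
#' @return Integer distance in bp.
#' @export
intergenic_distance <- function(upstream, downstream) {
  if (!identical(upstream$strand, downstream$strand))
    stop("pair must share a strand")
  if (upstream$strand == "+")
    as.integer(downstream$start - upstream$end - 1L)
  else
    as.integer(upstream$start - downstream$end - 1L)
}
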