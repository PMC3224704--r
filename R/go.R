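#' Directed acyclic ontology of terms
#'
#' Minimal is-a ontology representation: a named list mapping each term to
#' its parent terms. Terms without parents are roots. Used for
#' information-content semantic similarity between gene annotation sets.
#'
#' @param parents Named list; names are term ids, elements are character
#'   vectors of parent term ids (empty for roots).
#' @return Object of class `go_dag` with elements `parents`, `terms` and the
#'   transitive `ancestors` closure (each includes the term itself).
#' @export
go_dag <- function(parents) {
  terms <- names(parents)
  if (is.null(terms) || anyDuplicated(terms)) stop("parents must be uniquely named")
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown)) stop("parent term not in DAG: ", unknown[1L])
  anc <- vector("list", length(terms))
  names(anc) <- terms
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    res <- t
    for (p in parents[[t]]) res <- union(res, get_anc(p))
    anc[[t]] <<- res
    res
  }
  for (t in terms) get_anc(t)
  structure(list(parents = parents, terms = terms, ancestors = anc),
            class = "go_dag")
}

#' Information content of ontology terms from corpus annotation counts
#'
#' The frequency of a term is the number of annotations to the term or any
#' of its descendants; `IC(t) = -log(freq(t) / freq(root))`. Root terms have
#' IC 0.
#'
#' @param dag A [go_dag()].
#' @param counts Named numeric vector of direct annotation counts per term
#'   (terms absent from `counts` count 0).
#' @return Named numeric vector of IC values in nats.
#' @export
term_ic <- function(dag, counts) {
  stopifnot(inherits(dag, "go_dag"))
  direct <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  common <- intersect(names(counts), dag$terms)
  direct[common] <- counts[common]
  cum <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (t in dag$terms)           # each term's count flows up to all ancestors
    cum[dag$ancestors[[t]]] <- cum[dag$ancestors[[t]]] + direct[t]
  roots <- dag$terms[lengths(dag$parents) == 0L]
  total <- max(cum[roots])
  if (total <= 0) stop("corpus counts are all zero")
  ic <- -log(pmax(cum, .Machine$double.xmin) / total)
  ic[cum == 0] <- -log(1 / total)   # unseen terms get the maximal finite IC
  ic
}

#' Lin semantic similarity between two single terms
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))` where MICA is the common ancestor with
#' the highest information content. Zero when the only shared ancestor is an
#' uninformative root, or when both terms themselves carry no information.
#'
#' @param t1,t2 Term ids present in the DAG.
#' @param dag A [go_dag()].
#' @param ic Output of [term_ic()].
#' @return Similarity in `[0, 1]`.
#' @export
lin_similarity <- function(t1, t2, dag, ic) {
  for (t in c(t1, t2))
    if (!t %in% dag$terms) stop("term not in DAG: ", t)
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  if (!length(common)) return(0)
  mica <- max(ic[common])
  denom <- ic[[t1]] + ic[[t2]]
  if (denom <= 0) return(0)
  min(1, 2 * mica / denom)
}

#' Information-content similarity between two annotation sets
#'
#' Best-match average of pairwise Lin similarities: for each term in one set
#' take the best match in the other, average, and symmetrize by averaging
#' the two directions. `NA` when either set is empty.
#'
#' @param terms_a,terms_b Character vectors of term ids.
#' @inheritParams lin_similarity
#' @return Similarity in `[0, 1]`, or `NA_real_`.
#' @export
ic_similarity <- function(terms_a, terms_b, dag, ic) {
  terms_a <- unique(terms_a[nzchar(terms_a)])
  terms_b <- unique(terms_b[nzchar(terms_b)])
  if (!length(terms_a) || !length(terms_b)) return(NA_real_)
  S <- outer(terms_a, terms_b,
             Vectorize(function(x, y) lin_similarity(x, y, dag, ic)))
  mean(c(mean(apply(S, 1L, max)), mean(apply(S, 2L, max))))
}

#' Czekanowski-Dice overlap of two GO term sets
#'
#' `2c / (a + b)` where `a` and `b` are the set sizes and `c` the size of the
#' intersection. `NA` (not 0) when either set is empty, since absence of
#' annotation is not evidence of dissimilarity.
#'
#' @param terms_a,terms_b Character vectors of term ids.
#' @return Score in `[0, 1]`, or `NA_real_`.
#' @export
czekanowski_dice <- function(terms_a, terms_b) {
  terms_a <- unique(terms_a[nzchar(terms_a)])
  terms_b <- unique(terms_b[nzchar(terms_b)])
  a <- length(terms_a)
  b <- length(terms_b)
  if (a == 0L || b == 0L) return(NA_real_)
  2 * length(intersect(terms_a, terms_b)) / (a + b)
}

split_terms <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1L]]
}
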