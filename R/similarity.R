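#' Mutations recurrent in the pooled catalog
#'
#' Returns the mutation keys observed in at least `recurrent_min` distinct
#' donors across the whole pooled (PanCancer) catalog. This is the
#' mutation subset from which gene-level cancer-type profiles are built.
#'
#' @param table a `recurrence_table` with `"PanCancer"` scope.
#' @param recurrent_min minimum donor count (default 2).
#' @return data.table of key columns (`chromosome`, `start`, `ref`,
#'   `alt`), possibly empty.
#' @export
pan_recurrent_set <- function(table, recurrent_min = 2L) {
  stopifnot(inherits(table, "recurrence_table"))
  if (!identical(table$scope, "PanCancer")) {
    stop("pan_recurrent_set requires a PanCancer-scoped recurrence table")
  }
  table$counts[recurrence >= recurrent_min, KEY_COLUMNS, with = FALSE]
}

#' Gene-level donor-count matrix over cancer types
#'
#' Builds the cancer-type x gene matrix whose cell (t, g) is the number
#' of distinct donors of type t carrying at least one recurrent mutation
#' in gene g. Only genes harboring recurrent mutations appear as columns;
#' a donor counts once per gene no matter how many recurrent mutations it
#' carries there. Calls with empty gene labels are excluded (their number
#' is reported via a message).
#'
#' @param catalog a `mut_catalog`.
#' @param recurrent data.table of mutation keys, from
#'   [pan_recurrent_set()].
#' @return Integer matrix, rows = cancer types (sorted), columns = genes
#'   (sorted); errors if no recurrent key has a gene label.
#' @export
gene_donor_matrix <- function(catalog, recurrent) {
  recurrent <- as.data.table(recurrent)
  stopifnot(all(KEY_COLUMNS %in% names(recurrent)))
  if (nrow(recurrent) == 0L) stop("no recurrent mutations supplied")
  rec_calls <- catalog$calls[recurrent, on = KEY_COLUMNS, nomatch = NULL]
  n_no_gene <- sum(rec_calls$gene == "")
  if (n_no_gene > 0L) {
    message("gene_donor_matrix: excluding ", n_no_gene,
            " call(s) of recurrent mutations without a gene label")
    rec_calls <- rec_calls[gene != ""]
  }
  if (nrow(rec_calls) == 0L) {
    stop("no recurrent mutation carries a gene label")
  }
  cells <- rec_calls[, .(n_donors = uniqueN(donor_id)),
                     by = .(cancer_type, gene)]
  types <- sort(unique(catalog$roster$cancer_type))
  genes <- sort(unique(cells$gene))
  m <- matrix(0L, nrow = length(types), ncol = length(genes),
              dimnames = list(types, genes))
  m[cbind(match(cells$cancer_type, types), match(cells$gene, genes))] <-
    cells$n_donors
  m
}

#' Cosine similarity between cancer-type gene profiles
#'
#' Pairwise cosine similarity `s(t, u) = <v_t, v_u> / (|v_t| |v_u|)`
#' between the rows of a gene donor-count matrix. Since the vectors are
#' non-negative, entries lie in \[0, 1\], with 1 on the diagonal.
#'
#' @param m matrix from [gene_donor_matrix()] (rows = cancer types).
#' @return Symmetric similarity matrix; errors naming any cancer type
#'   whose profile is all-zero.
#' @export
cosine_similarity_matrix <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  zero <- rownames(m)[norms == 0]
  if (length(zero) > 0L) {
    stop("cancer type(s) with all-zero gene profile: ",
         paste(zero, collapse = ", "))
  }
  s <- tcrossprod(m / norms)
  s <- (s + t(s)) / 2
  s[s > 1] <- 1
  s[s < 0] <- 0
  diag(s) <- 1
  s
}

#' Hierarchical clustering of cancer types
#'
#' Agglomerative clustering of cancer types on the distance
#' `1 - cosine similarity`, with average linkage by default. Labels are
#' sorted lexicographically beforehand so that ties are broken
#' deterministically.
#'
#' @param sim similarity matrix from [cosine_similarity_matrix()].
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return An [stats::hclust] tree over the cancer-type labels.
#' @export
hierarchical_dendrogram <- function(sim, linkage = "average") {
  stopifnot(is.matrix(sim))
  if (nrow(sim) < 2L) stop("need at least 2 cancer types to cluster")
  ord <- order(rownames(sim))
  d <- stats::as.dist(1 - sim[ord, ord, drop = FALSE])
  hc <- stats::hclust(d, method = linkage)
  attr(hc, "linkage") <- linkage
  hc
}

#' Serialize a dendrogram as Newick text
#'
#' Converts the merge tree to Newick with ultrametric branch lengths
#' under the height-halving convention: leaves sit at depth equal to half
#' the height of their first merge, so the path length between two leaves
#' equals the merge height of their lowest common cluster. Two types
#' merging at height 0.2 therefore serialize as `(A:0.1,B:0.1);`.
#' Re-parsing (e.g. with [ape::read.tree()]) recovers the topology and
#' heights.
#'
#' @param dendrogram an [stats::hclust] tree, e.g. from
#'   [hierarchical_dendrogram()].
#' @return Newick string (with trailing `;`).
#' @export
to_newick <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "hclust"))
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy)
}
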