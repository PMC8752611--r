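# Cluster-verse and gene-verse summaries: interaction counts per ordered
# cluster pair, per-cluster autocrine/paracrine totals, network edge tables,
# the distinct interaction-pair (gene-verse) table and dot-plot data.

#' Count interactions per ordered cluster pair
#'
#' Totals (number of records) or weighted totals (sum of interaction scores)
#' for every ordered cluster pair (clust_a, clust_b). Directed counts keep
#' (A,B) and (B,A) distinct; the diagonal holds autocrine interactions.
#'
#' @param cci A standardized [cci_table()].
#' @param weighted If \code{TRUE}, sum interaction scores instead of counting.
#' @param viewpoint Optional cluster; only pairs involving it are counted
#'   (other cells are zero).
#' @return A square numeric matrix over the cluster universe, class
#'   \code{cci_counts}, with attributes \code{weighted} and \code{viewpoint}.
#' @export
count_interactions <- function(cci, weighted = FALSE, viewpoint = NULL) {
  stopifnot(inherits(cci, "cci_table"))
  cl <- cci$clusters
  r <- cci$records
  if (!is.null(viewpoint)) {
    if (!viewpoint %in% cl) {
      cc_stop(paste0("unknown viewpoint cluster: ", viewpoint), "cciverse_cluster_error")
    }
    r <- r[r$clust_a == viewpoint | r$clust_b == viewpoint, , drop = FALSE]
  }
  m <- matrix(0, length(cl), length(cl), dimnames = list(clust_a = cl, clust_b = cl))
  if (nrow(r)) {
    w <- if (weighted) r$score else rep(1, nrow(r))
    agg <- rowsum(w, group = couplet_id("", r$clust_a, r$clust_b))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    m[cbind(match(key[, 2], cl), match(key[, 3], cl))] <- agg[, 1]
  }
  structure(m, class = c("cci_counts", class(m)),
            weighted = weighted, viewpoint = viewpoint)
}

#' @export
print.cci_counts <- function(x, ...) {
  cat(sprintf("Interaction counts (%s%s):\n",
              if (attr(x, "weighted")) "weighted, sum of scores" else "total",
              if (!is.null(attr(x, "viewpoint")))
                paste0(", viewpoint ", attr(x, "viewpoint")) else ""))
  print(unclass(structure(x, weighted = NULL, viewpoint = NULL)), ...)
  invisible(x)
}

#' Per-cluster autocrine and paracrine totals
#'
#' Each paracrine record contributes once to \emph{both} participating
#' clusters' totals; an autocrine record contributes once to its single
#' cluster, flagged autocrine.
#'
#' @param cci A standardized [cci_table()].
#' @return Data frame with columns \code{cluster}, \code{autocrine},
#'   \code{paracrine}, \code{total} (one row per cluster in the universe).
#' @export
per_cluster_totals <- function(cci) {
  stopifnot(inherits(cci, "cci_table"))
  r <- cci$records
  if (!nrow(r)) cc_warn("table has no records", "cciverse_empty_warning")
  cl <- cci$clusters
  auto <- r$clust_a == r$clust_b
  count_in <- function(labels) tabulate(match(labels, cl), nbins = length(cl))
  autocrine <- count_in(r$clust_a[auto])
  paracrine <- count_in(r$clust_a[!auto]) + count_in(r$clust_b[!auto])
  data.frame(cluster = cl, autocrine = autocrine, paracrine = paracrine,
             total = autocrine + paracrine, stringsAsFactors = FALSE)
}

#' Network edge table from interaction counts
#'
#' One edge per nonzero ordered cluster pair; self-loops represent autocrine
#' communication and can be hidden, as can paracrine edges.
#'
#' @param counts A \code{cci_counts} matrix from [count_interactions()].
#' @param hide One of \code{"none"}, \code{"autocrine"}, \code{"paracrine"}.
#' @return Data frame with columns \code{source}, \code{target}, \code{value}.
#' @export
network_edges <- function(counts, hide = c("none", "autocrine", "paracrine")) {
  hide <- match.arg(hide)
  stopifnot(inherits(counts, "cci_counts"))
  idx <- which(unclass(counts) != 0, arr.ind = TRUE)
  cl <- rownames(counts)
  edges <- data.frame(source = cl[idx[, 1]], target = cl[idx[, 2]],
                      value = counts[idx], stringsAsFactors = FALSE)
  if (hide == "autocrine") edges <- edges[edges$source != edges$target, , drop = FALSE]
  if (hide == "paracrine") edges <- edges[edges$source == edges$target, , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

ensembl_url <- function(genes) {
  vapply(split_genes(genes), function(g)
    paste0("https://www.ensembl.org/Homo_sapiens/Gene/Summary?g=", g, collapse = ";"),
    "")
}

uniprot_url <- function(genes) {
  vapply(split_genes(genes), function(g)
    paste0("https://www.uniprot.org/uniprotkb?query=gene:", g, collapse = ";"), "")
}

#' Gene-verse table of distinct interaction pairs
#'
#' Lists each distinct interaction pair found in the CCI data once, with its
#' component gene symbols and types, the number of couplets (cluster pairs)
#' it occurs in, its mean score, and deterministic Ensembl/UniProt URL
#' columns for each component's genes.
#'
#' @param cci A standardized [cci_table()].
#' @return Data frame, one row per distinct interaction pair (first-appearance
#'   order).
#' @export
unique_int_pairs <- function(cci) {
  stopifnot(inherits(cci, "cci_table"))
  r <- cci$records
  first <- !duplicated(r$int_pair)
  u <- r[first, c("int_pair", "comp_a", "comp_b", "genes_a", "genes_b",
                  "type_a", "type_b"), drop = FALSE]
  rownames(u) <- NULL
  if (!nrow(u)) {
    u$n_couplets <- integer(0); u$mean_score <- numeric(0)
    u$ensembl_a <- u$ensembl_b <- u$uniprot_a <- u$uniprot_b <- character(0)
    return(u)
  }
  idx <- match(r$int_pair, u$int_pair)
  u$n_couplets <- tabulate(idx, nbins = nrow(u))
  u$mean_score <- as.vector(rowsum(r$score, idx)) / u$n_couplets
  u$display <- pair_display(u$int_pair)
  u$ensembl_a <- ensembl_url(u$genes_a)
  u$ensembl_b <- ensembl_url(u$genes_b)
  u$uniprot_a <- uniprot_url(u$genes_a)
  u$uniprot_b <- uniprot_url(u$genes_b)
  u
}

#' Dot-plot data for selected interaction pairs
#'
#' Long-format table of (interaction pair, cluster pair) couplets restricted
#' to the user's selection; cluster pairs are rendered \code{"c1::c2"}. Rows
#' follow the interaction-pair selection order, then lexicographic cluster
#' pairs.
#'
#' @param cci A standardized [cci_table()].
#' @param int_pairs Character vector of interaction-pair ids to keep.
#' @param clusters Optional cluster selection; both sides of a couplet must be
#'   selected. \code{NULL} keeps all.
#' @return Data frame with columns \code{int_pair}, \code{cluster_pair},
#'   \code{score}, \code{p_value}.
#' @export
dotplot_data <- function(cci, int_pairs, clusters = NULL) {
  stopifnot(inherits(cci, "cci_table"), length(int_pairs) > 0)
  r <- cci$records
  keep <- r$int_pair %in% int_pairs
  if (!is.null(clusters)) keep <- keep & r$clust_a %in% clusters & r$clust_b %in% clusters
  out <- r[keep, , drop = FALSE]
  if (!nrow(out)) cc_warn("selection matches no couplet", "cciverse_empty_warning")
  out <- data.frame(int_pair = out$int_pair,
                    cluster_pair = if (nrow(out)) paste0(out$clust_a, "::", out$clust_b)
                                   else character(0),
                    score = out$score, p_value = out$p_value,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$int_pair, int_pairs), out$cluster_pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}
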