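# Interaction-pair modules: subset the CCI data by viewpoint and
# communication flow, embed the binary annotation profiles of the in-scope
# interaction pairs in 2-D with UMAP (cosine metric), define modules by
# hierarchical clustering of the embedding (euclidean distance, ward.D2),
# choose the number of modules by the elbow (WSS maximum curvature) or
# average silhouette width, and test functional-term specificity per module
# with a one-sided permutation test on the module-ratio statistic.

FLOWS <- c("directed-outgoing", "directed-incoming", "undirected")

norm_flow <- function(flow) {
  flow <- match.arg(tolower(flow),
                    c(FLOWS, "outgoing", "incoming"))
  switch(flow, outgoing = "directed-outgoing", incoming = "directed-incoming", flow)
}

#' Subset a CCI table by viewpoint and communication flow
#'
#' Communication flows are defined relative to a viewpoint cluster:
#' \emph{directed-outgoing} keeps ligand-receptor records whose ligand is
#' expressed by the viewpoint (any receiver, including the viewpoint itself);
#' \emph{directed-incoming} keeps ligand-receptor records whose receptor side
#' is the viewpoint; \emph{undirected} keeps ligand-ligand and
#' receptor-receptor records with the viewpoint on either side. Records with
#' \code{"unknown"} molecular types are excluded from all flows.
#'
#' @param cci A standardized [cci_table()].
#' @param viewpoint Cluster of interest (must be in the cluster universe).
#' @param flow One of \code{"directed-outgoing"}, \code{"directed-incoming"},
#'   \code{"undirected"} (short forms \code{"outgoing"}/\code{"incoming"}
#'   accepted).
#' @return List with \code{cci} (the subset table) and \code{int_pairs}
#'   (distinct interaction-pair ids of the subset, first-appearance order).
#' @export
subset_by_flow <- function(cci, viewpoint, flow) {
  stopifnot(inherits(cci, "cci_table"))
  if (!cci$standardized) cc_stop("subset_by_flow requires a standardized table",
                                 "cciverse_config_error")
  if (!viewpoint %in% cci$clusters) {
    cc_stop(paste0("unknown viewpoint cluster: ", viewpoint), "cciverse_cluster_error")
  }
  flow <- norm_flow(flow)
  r <- cci$records
  keep <- switch(flow,
    "directed-outgoing" = r$type_a == "L" & r$type_b == "R" & r$clust_a == viewpoint,
    "directed-incoming" = r$type_a == "L" & r$type_b == "R" & r$clust_b == viewpoint,
    "undirected" = ((r$type_a == "L" & r$type_b == "L") |
                    (r$type_a == "R" & r$type_b == "R")) &
                   (r$clust_a == viewpoint | r$clust_b == viewpoint))
  sub <- r[keep, , drop = FALSE]
  if (!nrow(sub)) {
    cc_warn(sprintf("no records for viewpoint '%s', flow '%s'", viewpoint, flow),
            "cciverse_empty_warning")
  }
  out <- cci_table(sub, clusters = cci$clusters, source_tool = cci$source_tool,
                   provenance = c(cci$provenance,
                                  sprintf("subset_by_flow(%s, %s)", viewpoint, flow)),
                   standardized = TRUE, has_pvalue = cci$has_pvalue)
  list(cci = out, int_pairs = unique(sub$int_pair))
}

#' Embed interaction pairs in two dimensions with UMAP
#'
#' Runs UMAP on binary term-annotation profiles using cosine similarity as
#' the distance metric, so the embedding reflects functional similarity of
#' interaction pairs. Deterministic for a fixed seed.
#'
#' @param ann_mat Binary matrix (rows = interaction pairs, columns = terms);
#'   every row must have at least one annotation.
#' @param seed Integer seed (default 42).
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1);
#'   \code{n_neighbors} is clamped to \code{nrow - 1} with a warning.
#' @return Numeric matrix \code{n x 2} with the input rownames.
#' @export
embed_int_pairs <- function(ann_mat, seed = 42, n_neighbors = 15, min_dist = 0.1) {
  ann_mat <- as.matrix(ann_mat)
  n <- nrow(ann_mat)
  if (n < 2L) cc_stop("need at least 2 interaction pairs to embed", "cciverse_config_error")
  if (any(rowSums(ann_mat) == 0)) {
    cc_stop("every interaction pair must be annotated by at least one term",
            "cciverse_config_error")
  }
  if (n_neighbors >= n) {
    cc_warn(sprintf("n_neighbors=%d clamped to %d (n-1)", n_neighbors, n - 1L),
            "cciverse_param_warning")
    n_neighbors <- n - 1L
  }
  n_neighbors <- max(2L, as.integer(n_neighbors))
  # cosine distances ignore an all-zero column; padding keeps the embedding
  # dimension below the feature count for single-term scopes
  if (ncol(ann_mat) < 2L) ann_mat <- cbind(ann_mat, 0L)
  # random (seed-deterministic) initialization: binary profiles carry many
  # exact duplicates, which degrade PCA initialization to rank 1 and can
  # disconnect the spectral initialization's graph
  coords <- uwot::umap(ann_mat, n_neighbors = n_neighbors, min_dist = min_dist,
                       metric = "cosine", init = "random", seed = as.integer(seed),
                       n_threads = 1, n_sgd_threads = 1, batch = TRUE)
  rownames(coords) <- rownames(ann_mat)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

relabel_by_size <- function(assignment) {
  sizes <- table(assignment)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- map[assignment]
  names(out) <- names(assignment)
  out
}

#' Cluster an embedding into interaction-pair modules
#'
#' Agglomerative hierarchical clustering (euclidean distance, Ward's
#' criterion, \code{ward.D2}) of the 2-D coordinates, cut at \code{k}
#' modules. Module ids are relabeled 1..k by decreasing size (ties keep the
#' lower original label).
#'
#' @param coords Numeric matrix of 2-D coordinates with rownames.
#' @param k Number of modules, \code{1 <= k <= nrow(coords)}.
#' @return List with \code{assignment} (named integer vector) and
#'   \code{hclust} (the dendrogram).
#' @export
cluster_modules <- function(coords, k) {
  n <- nrow(coords)
  if (k < 1 || k > n) cc_stop(sprintf("k=%d outside 1..%d", k, n), "cciverse_param_error")
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  assignment <- relabel_by_size(stats::cutree(hc, k = k))
  list(assignment = assignment, hclust = hc)
}

wss_of <- function(coords, assignment) {
  sum(vapply(split(seq_len(nrow(coords)), assignment), function(idx) {
    x <- coords[idx, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }, 0))
}

# Elbow as the point of maximum curvature of the WSS curve, located as the
# k with maximum perpendicular distance to the chord joining the curve's
# endpoints (Kneedle-style geometric reading). The distance is computed on
# log(WSS): within-cluster variance shrinks multiplicatively as true groups
# split apart, and on well-separated embeddings the raw first drop dwarfs
# the rest of the curve, masking the true elbow; the log curve bends
# sharpest where WSS stops shrinking by factors. Ties take the smallest k.
elbow_point <- function(ks, wss) {
  y <- log(pmax(wss, max(wss) * 1e-12))
  x1 <- ks[1]; y1 <- y[1]
  x2 <- ks[length(ks)]; y2 <- y[length(y)]
  chord <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (chord == 0) return(ks[1])
  d <- abs((y2 - y1) * ks - (x2 - x1) * y + x2 * y1 - y2 * x1) / chord
  ks[which.max(d)]
}

#' Choose the number of interaction-pair modules
#'
#' Computes, for k = 1..k_max cuts of the Ward dendrogram, (i) the total
#' within-cluster sum of squares (WSS) and (ii) the average silhouette width
#' (k >= 2). The elbow k is the point of maximum curvature of the WSS curve,
#' found as the maximum perpendicular distance to the chord joining
#' (1, WSS(1)) and (k_max, WSS(k_max)); the silhouette k maximizes the
#' average silhouette width.
#'
#' @param coords Numeric 2-D coordinate matrix, \code{nrow >= 3}.
#' @param k_max Largest k scanned; default \code{min(10, n - 1)}.
#' @return List with \code{k_elbow}, \code{k_silhouette}, \code{k_range},
#'   \code{wss} and \code{silhouette} (curves over \code{k_range};
#'   silhouette is \code{NA} at k = 1).
#' @export
choose_k <- function(coords, k_max = NULL) {
  n <- nrow(coords)
  if (n < 3L) cc_stop("need at least 3 points to scan k", "cciverse_param_error")
  k_max <- as.integer(k_max %||% min(10L, n - 1L))
  if (k_max < 2L || k_max > n - 1L) {
    cc_stop(sprintf("k_max=%d outside 2..%d", k_max, n - 1L), "cciverse_param_error")
  }
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  ks <- seq_len(k_max)
  cuts <- stats::cutree(hc, k = ks)            # n x k_max matrix
  wss <- vapply(ks, function(k) wss_of(coords, cuts[, k]), 0)
  if (wss[1] <= .Machine$double.eps * n) {
    cc_warn("all points are (numerically) identical; choosing k = 1",
            "cciverse_degenerate_warning")
    return(list(k_elbow = 1L, k_silhouette = 1L, k_range = ks, wss = wss,
                silhouette = c(NA_real_, rep(0, k_max - 1L))))
  }
  d <- stats::dist(coords)
  sil <- c(NA_real_, vapply(ks[-1], function(k) {
    mean(cluster::silhouette(cuts[, k], d)[, "sil_width"])
  }, 0))
  list(k_elbow = as.integer(elbow_point(ks, wss)),
       k_silhouette = as.integer(ks[-1][which.max(sil[-1])]),
       k_range = ks, wss = wss, silhouette = sil)
}

#' Define interaction-pair modules
#'
#' End-to-end pipeline: subset the CCI data by viewpoint and flow, restrict
#' the annotation matrix to the in-scope interaction pairs (dropping pairs no
#' term annotates -- only annotated pairs are considered), embed with UMAP,
#' choose k (elbow by default) and cluster. When 10 or fewer unique annotated
#' interaction pairs are in scope, a single module is defined to prevent
#' noisy results from too few data points (coordinates are still produced
#' when at least two pairs are present).
#'
#' @param cci A standardized [cci_table()].
#' @param viewpoint Viewpoint cluster.
#' @param flow Communication flow (see [subset_by_flow()]).
#' @param ann A \code{cci_annotation} covering the table's interaction pairs.
#' @param k Number of modules, or \code{"auto"} (default) for the elbow
#'   choice.
#' @param seed Seed for the UMAP embedding (default 42).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param k_max Largest k scanned by [choose_k()].
#' @return A \code{cci_modules} object: interaction pairs in scope, 2-D
#'   coordinates, module assignment, chosen \code{k}, \code{k_elbow} /
#'   \code{k_silhouette} diagnostics with their curves, the dendrogram, the
#'   subset table and restricted annotation matrix, and the seed.
#' @export
define_modules <- function(cci, viewpoint, flow, ann, k = "auto", seed = 42,
                           n_neighbors = 15, min_dist = 0.1, k_max = NULL) {
  sub <- subset_by_flow(cci, viewpoint, flow)
  m <- annotation_matrix(ann, pairs = intersect(sub$int_pairs, rownames(ann$matrix)))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  n <- nrow(m)
  if (!n) cc_stop("no annotated interaction pair in scope", "cciverse_empty_error")

  coords <- if (n >= 2L) {
    embed_int_pairs(m, seed = seed, n_neighbors = n_neighbors, min_dist = min_dist)
  } else {
    matrix(0, 1, 2, dimnames = list(rownames(m), c("UMAP1", "UMAP2")))
  }

  diag_k <- NULL
  if (n <= 10L) {
    if (!identical(k, "auto") && !identical(k, 1) && !identical(k, 1L)) {
      cc_warn(sprintf("only %d annotated interaction pairs in scope; forcing k = 1", n),
              "cciverse_param_warning")
    }
    k <- 1L
  } else if (identical(k, "auto")) {
    diag_k <- choose_k(coords, k_max = k_max)
    k <- diag_k$k_elbow
  } else {
    k <- as.integer(k)
    diag_k <- tryCatch(choose_k(coords, k_max = k_max), error = function(e) NULL)
  }

  cl <- if (n == 1L) {
    list(assignment = stats::setNames(1L, rownames(m)), hclust = NULL)
  } else {
    cluster_modules(coords, k)
  }
  structure(
    list(int_pairs = rownames(m), coords = coords, assignment = cl$assignment,
         k = as.integer(k),
         k_elbow = diag_k$k_elbow, k_silhouette = diag_k$k_silhouette,
         wss = diag_k$wss, silhouette = diag_k$silhouette,
         k_range = diag_k$k_range,
         hclust = cl$hclust, seed = seed, viewpoint = viewpoint,
         flow = norm_flow(flow), cci = sub$cci, ann_matrix = m),
    class = "cci_modules")
}

#' @export
print.cci_modules <- function(x, ...) {
  cat(sprintf("Interaction-pair modules: viewpoint '%s', flow %s\n", x$viewpoint, x$flow))
  cat(sprintf("%d annotated interaction pairs in %d module(s)", length(x$int_pairs), x$k))
  if (!is.null(x$k_elbow)) {
    cat(sprintf(" (elbow k = %d, silhouette k = %d)", x$k_elbow, x$k_silhouette))
  }
  cat("\nmodule sizes: ", paste(table(x$assignment), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cci_modules <- function(object, ...) {
  print(object)
  for (mid in sort(unique(object$assignment))) {
    p <- names(object$assignment)[object$assignment == mid]
    cat(sprintf("module %d (%d pairs): %s\n", mid, length(p),
                paste(utils::head(pair_display(p), 5), collapse = "; ")))
  }
  invisible(object)
}

#' Plot an interaction-pair module result
#'
#' @param x A \code{cci_modules}.
#' @param type \code{"umap"} (embedding colored by module), \code{"wss"} /
#'   \code{"silhouette"} (model-selection curves) or \code{"dendrogram"}.
#' @param ... Passed to the underlying base-graphics call.
#' @return \code{x}, invisibly.
#' @export
plot.cci_modules <- function(x, type = c("umap", "wss", "silhouette", "dendrogram"), ...) {
  type <- match.arg(type)
  if (type == "umap") {
    graphics::plot(x$coords, col = x$assignment, pch = 19,
                   main = sprintf("Interaction-pair modules (k = %d)", x$k), ...)
  } else if (type == "wss") {
    if (is.null(x$wss)) cc_stop("no WSS curve stored (k was forced)", "cciverse_config_error")
    graphics::plot(x$k_range, x$wss, type = "b", xlab = "number of modules k",
                   ylab = "total within-cluster sum of squares", ...)
    graphics::abline(v = x$k_elbow, lty = 2)
  } else if (type == "silhouette") {
    if (is.null(x$silhouette)) cc_stop("no silhouette curve stored", "cciverse_config_error")
    graphics::plot(x$k_range, x$silhouette, type = "b", xlab = "number of modules k",
                   ylab = "average silhouette width", ...)
    graphics::abline(v = x$k_silhouette, lty = 2)
  } else {
    if (is.null(x$hclust)) cc_stop("no dendrogram stored", "cciverse_config_error")
    graphics::plot(x$hclust, labels = FALSE, main = "Ward dendrogram of UMAP coordinates",
                   xlab = "", sub = "", ...)
  }
  invisible(x)
}

# Shared permutation core for module- and condition-specificity tests.
# A: binary pairs x terms matrix; assignment: integer/character vector over
# rows of A. Statistic: per (group, term) ratio = annotated-in-group / group
# size. One shuffle per iteration is shared across all terms. p = proportion
# of permuted ratios >= observed (optionally the (b+1)/(m+1) estimator).
perm_ratio_test <- function(A, assignment, n_perm = 1000, seed = 42, alpha = 0.05,
                            smoothed = FALSE, group_label = "module") {
  A <- as.matrix(A)
  n <- nrow(A)
  if (length(assignment) != n) {
    cc_stop("assignment must cover every row of the annotation matrix",
            "cciverse_param_error")
  }
  if (n_perm < 1) cc_stop("n_perm must be >= 1", "cciverse_param_error")
  if (!ncol(A)) cc_stop("annotation matrix has no terms", "cciverse_empty_error")
  fac <- factor(assignment)
  groups <- levels(fac)
  gi <- as.integer(fac)
  sizes <- tabulate(gi, nbins = length(groups))
  if (length(groups) < 2L) {
    cc_warn(sprintf("single %s: the ratio statistic is invariant under permutation; all p-values are 1",
                    group_label), "cciverse_degenerate_warning")
  }
  obs <- rowsum(A, gi) / sizes  # groups x terms

  set.seed(as.integer(seed))
  # one shuffled assignment (without replacement) per iteration, shared by
  # all terms; counts via crossprod of the 0/1 membership with A
  perm_assign <- matrix(gi[vapply(seq_len(n_perm), function(i) sample.int(n),
                                  integer(n))], nrow = n)
  exceed <- matrix(0L, length(groups), ncol(A))
  for (g in seq_along(groups)) {
    counts <- crossprod(perm_assign == g, A) / sizes[g]    # n_perm x terms
    exceed[g, ] <- colSums(counts >= rep(obs[g, ], each = n_perm) - 1e-12)
  }
  p <- if (smoothed) (exceed + 1) / (n_perm + 1) else exceed / n_perm

  out <- data.frame(
    term = rep(colnames(A), each = length(groups)),
    group = rep(groups, times = ncol(A)),
    group_size = rep(sizes, times = ncol(A)),
    ratio = as.vector(obs),
    p_value = as.vector(p),
    stringsAsFactors = FALSE)
  names(out)[names(out) == "group"] <- group_label
  names(out)[names(out) == "group_size"] <- paste0(group_label, "_size")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term, out[[group_label]]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  class(out) <- c("cci_term_test", class(out))
  out
}

#' Test functional-term specificity per module
#'
#' One-sided permutation test on the module-ratio statistic: for each
#' (term, module), the observed ratio is the proportion of the module's
#' interaction pairs annotated to the term. The module assignment is
#' shuffled \code{n_perm} times (without replacement, preserving module
#' sizes; one shuffle per iteration shared across terms) and the empirical
#' p-value is the proportion of permuted ratios greater than or equal to the
#' observed ratio. Terms are ranked by p-value; significance defaults to
#' p < 0.05.
#'
#' @param x A \code{cci_modules} result, or a named assignment vector.
#' @param ann_mat Binary annotation matrix over the assigned pairs (taken
#'   from \code{x} when \code{x} is a \code{cci_modules}).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the shuffles (default 42).
#' @param alpha Significance threshold (default 0.05).
#' @param smoothed Use the (b+1)/(m+1) p-value estimator instead of the plain
#'   proportion (default \code{FALSE}; the plain proportion can be 0).
#' @return A \code{cci_term_test} data frame with columns \code{term},
#'   \code{module}, \code{module_size}, \code{ratio}, \code{p_value},
#'   \code{significant}, ranked by p-value.
#' @export
test_term_specificity <- function(x, ann_mat = NULL, n_perm = 1000, seed = 42,
                                  alpha = 0.05, smoothed = FALSE) {
  if (inherits(x, "cci_modules")) {
    assignment <- x$assignment
    ann_mat <- ann_mat %||% x$ann_matrix
  } else {
    assignment <- x
    if (is.null(ann_mat)) cc_stop("ann_mat is required when x is an assignment vector",
                                  "cciverse_param_error")
    if (!is.null(names(assignment)) && !is.null(rownames(ann_mat))) {
      if (!setequal(names(assignment), rownames(ann_mat))) {
        cc_stop("assignment names do not match annotation matrix rows",
                "cciverse_param_error")
      }
      ann_mat <- ann_mat[names(assignment), , drop = FALSE]
    }
  }
  perm_ratio_test(ann_mat, assignment, n_perm = n_perm, seed = seed,
                  alpha = alpha, smoothed = smoothed, group_label = "module")
}

#' @export
print.cci_term_test <- function(x, n = 10, ...) {
  cat(sprintf("Permutation test (%d permutations, alpha = %g): %d significant of %d (term, group) pairs\n",
              attr(x, "n_perm"), attr(x, "alpha"), sum(x$significant), nrow(x)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Serialize a dendrogram as a Newick string
#'
#' Writes an \code{hclust} tree in Newick format with merge heights as branch
#' lengths, for exchange with standard tree tooling.
#'
#' @param hc An \code{stats::hclust} object.
#' @return A single Newick string (terminated by \code{";"}).
#' @export
hclust_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", gsub("[,;:()[:space:]]", "_", labels[-i]), parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g", node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", node(hc$merge[n, 1], h), ",", node(hc$merge[n, 2], h), ");")
}

#' Circle-plot link data for one module
#'
#' Links are the couplets of the module's interaction pairs: each link runs
#' from the ligand component (source cluster) to the receptor component
#' (target cluster) and carries the interaction score scaled to a z-score
#' across the module's links, clipped to [-2, 2]. Zero-variance scores scale
#' to 0.
#'
#' @param cci_sub The subset [cci_table()] the modules were defined on
#'   (e.g. \code{result$cci}).
#' @param result A \code{cci_modules}.
#' @param module_id Module id in \code{1..k}.
#' @return Data frame with columns \code{ligand}, \code{receptor},
#'   \code{source_cluster}, \code{target_cluster}, \code{score},
#'   \code{scaled_score}.
#' @export
circleplot_data <- function(cci_sub, result, module_id) {
  stopifnot(inherits(cci_sub, "cci_table"), inherits(result, "cci_modules"))
  if (!module_id %in% seq_len(result$k)) {
    cc_stop(sprintf("module_id %s outside 1..%d", module_id, result$k),
            "cciverse_param_error")
  }
  pairs <- names(result$assignment)[result$assignment == module_id]
  r <- cci_sub$records[cci_sub$records$int_pair %in% pairs, , drop = FALSE]
  if (!nrow(r)) {
    cc_warn(sprintf("module %d has no couplet in the given table", module_id),
            "cciverse_empty_warning")
  }
  s <- r$score
  # population (1/n) standard deviation; zero variance scales to 0
  sd_pop <- sqrt(mean((s - mean(s))^2))
  z <- if (length(s) > 1 && sd_pop > 0) (s - mean(s)) / sd_pop else rep(0, length(s))
  out <- data.frame(ligand = complex_display(r$comp_a),
                    receptor = complex_display(r$comp_b),
                    source_cluster = r$clust_a, target_cluster = r$clust_b,
                    score = s, scaled_score = pmin(2, pmax(-2, z)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
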