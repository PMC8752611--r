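# Multi-condition comparison: per-cell-type count differences, couplets and
# interaction pairs unique to one condition, and condition-specific
# significant functional terms (the module-ratio permutation test with the
# module assignment replaced by a condition assignment).

#' Bundle per-condition CCI tables
#'
#' @param ... Named [cci_table()] objects (or a single named list of them);
#'   at least two conditions with unique labels. Cluster labels are compared
#'   verbatim across conditions, so harmonizing them is the caller's
#'   responsibility.
#' @return A \code{condition_set}: list with \code{conditions} (named list)
#'   and \code{clusters} (union universe, first-appearance order).
#' @export
condition_set <- function(...) {
  conds <- list(...)
  if (length(conds) == 1L && is.list(conds[[1]]) && !inherits(conds[[1]], "cci_table")) {
    conds <- conds[[1]]
  }
  if (length(conds) < 2L) {
    cc_stop("a condition set needs at least two conditions", "cciverse_param_error")
  }
  if (is.null(names(conds)) || any(!nzchar(names(conds))) || anyDuplicated(names(conds))) {
    cc_stop("conditions must carry unique, non-empty labels", "cciverse_param_error")
  }
  if (!all(vapply(conds, inherits, TRUE, "cci_table"))) {
    cc_stop("every condition must be a cci_table", "cciverse_param_error")
  }
  clusters <- unique(unlist(lapply(conds, `[[`, "clusters"), use.names = FALSE))
  structure(list(conditions = conds, clusters = clusters), class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("Condition set: %d conditions (%s), %d clusters in the union universe\n",
              length(x$conditions), paste(names(x$conditions), collapse = ", "),
              length(x$clusters)))
  invisible(x)
}

couplet_frame <- function(cci) {
  r <- cci$records
  data.frame(int_pair = r$int_pair, clust_a = r$clust_a, clust_b = r$clust_b,
             id = couplet_id(r$int_pair, r$clust_a, r$clust_b),
             stringsAsFactors = FALSE)
}

# Per-cluster interaction counts restricted to flow classes, on a fixed
# cluster universe. Directed records (L-R) count as outgoing for clust_a and
# incoming for clust_b; undirected (L-L/R-R) records count once per
# participating side (autocrine: once).
flow_cluster_counts <- function(cci, clusters, flows) {
  r <- cci$records
  directed <- r$type_a == "L" & r$type_b == "R"
  undirected <- (r$type_a == "L" & r$type_b == "L") | (r$type_a == "R" & r$type_b == "R")
  nb <- length(clusters)
  cnt <- function(labels) tabulate(match(labels, clusters), nbins = nb)
  out <- numeric(nb)
  if ("outgoing" %in% flows) out <- out + cnt(r$clust_a[directed])
  if ("incoming" %in% flows) out <- out + cnt(r$clust_b[directed])
  if ("undirected" %in% flows) {
    auto <- r$clust_a == r$clust_b
    out <- out + cnt(r$clust_a[undirected]) + cnt(r$clust_b[undirected & !auto])
  }
  out
}

#' Compare interaction counts between two conditions
#'
#' Per-cell-type interaction counts (restricted to the selected flow classes)
#' for two conditions, their difference, and a radar table of counts between
#' each cell type and every partner, partners ordered alphabetically.
#'
#' @param cs A [condition_set()].
#' @param cond_x,cond_y Condition labels; the difference is
#'   \code{count_x - count_y}.
#' @param flows Subset of \code{c("outgoing", "incoming", "undirected")}.
#' @return List with \code{totals} (data frame \code{cluster},
#'   \code{count_x}, \code{count_y}, \code{difference}) and \code{radar}
#'   (data frame \code{cluster}, \code{partner}, \code{count_x},
#'   \code{count_y}).
#' @export
compare_counts <- function(cs, cond_x, cond_y,
                           flows = c("outgoing", "incoming", "undirected")) {
  stopifnot(inherits(cs, "condition_set"))
  flows <- match.arg(flows, several.ok = TRUE)
  for (cond in c(cond_x, cond_y)) {
    if (!cond %in% names(cs$conditions)) {
      cc_stop(paste0("unknown condition label: ", cond), "cciverse_param_error")
    }
  }
  cl <- cs$clusters
  cx <- flow_cluster_counts(cs$conditions[[cond_x]], cl, flows)
  cy <- flow_cluster_counts(cs$conditions[[cond_y]], cl, flows)
  totals <- data.frame(cluster = cl, count_x = cx, count_y = cy,
                       difference = cx - cy, stringsAsFactors = FALSE)

  partner_counts <- function(cci) {
    r <- cci$records
    directed <- r$type_a == "L" & r$type_b == "R"
    undirected <- (r$type_a == "L" & r$type_b == "L") |
                  (r$type_a == "R" & r$type_b == "R")
    rows <- list()
    if ("outgoing" %in% flows) {
      rows <- c(rows, list(data.frame(cluster = r$clust_a[directed],
                                      partner = r$clust_b[directed])))
    }
    if ("incoming" %in% flows) {
      rows <- c(rows, list(data.frame(cluster = r$clust_b[directed],
                                      partner = r$clust_a[directed])))
    }
    if ("undirected" %in% flows) {
      auto <- r$clust_a == r$clust_b
      rows <- c(rows, list(data.frame(cluster = r$clust_a[undirected],
                                      partner = r$clust_b[undirected]),
                           data.frame(cluster = r$clust_b[undirected & !auto],
                                      partner = r$clust_a[undirected & !auto])))
    }
    all <- do.call(rbind, rows)
    if (is.null(all) || !nrow(all)) return(stats::setNames(integer(0), character(0)))
    tapply(rep(1L, nrow(all)), paste(all$cluster, all$partner, sep = "\r"), sum)
  }
  px <- partner_counts(cs$conditions[[cond_x]])
  py <- partner_counts(cs$conditions[[cond_y]])
  keys <- sort(union(names(px), names(py)))
  ab <- if (length(keys)) do.call(rbind, strsplit(keys, "\r", fixed = TRUE)) else
    matrix(character(0), 0, 2)
  radar <- data.frame(cluster = ab[, 1], partner = ab[, 2],
                      count_x = as.integer(ifelse(is.na(px[keys]), 0, px[keys])),
                      count_y = as.integer(ifelse(is.na(py[keys]), 0, py[keys])),
                      stringsAsFactors = FALSE)
  radar <- radar[order(radar$cluster, radar$partner), , drop = FALSE]
  rownames(radar) <- NULL
  list(totals = totals, radar = radar)
}

#' Couplets unique to one condition
#'
#' A couplet (interaction pair in a specific ordered cluster pair) is unique
#' to a condition when it is present there and absent from every other
#' condition. Optional interaction-pair and cluster filters are applied
#' before uniqueness is assessed. Pie fractions give each condition's share
#' of all unique couplets (0 with a warning when every couplet is shared).
#'
#' @param cs A [condition_set()].
#' @param int_pair_filter Optional set of interaction-pair ids to keep.
#' @param cluster_filter Optional set of clusters (both sides must match).
#' @return List with \code{unique} (named list of data frames
#'   \code{int_pair}, \code{clust_a}, \code{clust_b}) and \code{fractions}
#'   (named numeric).
#' @export
unique_couplets <- function(cs, int_pair_filter = NULL, cluster_filter = NULL) {
  stopifnot(inherits(cs, "condition_set"))
  frames <- lapply(cs$conditions, function(cci) {
    f <- unique(couplet_frame(cci))
    if (!is.null(int_pair_filter)) f <- f[f$int_pair %in% int_pair_filter, , drop = FALSE]
    if (!is.null(cluster_filter)) {
      f <- f[f$clust_a %in% cluster_filter & f$clust_b %in% cluster_filter, , drop = FALSE]
    }
    f
  })
  uniq <- lapply(names(frames), function(lbl) {
    others <- unlist(lapply(frames[setdiff(names(frames), lbl)], `[[`, "id"),
                     use.names = FALSE)
    f <- frames[[lbl]]
    out <- f[!f$id %in% others, c("int_pair", "clust_a", "clust_b"), drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(uniq) <- names(frames)
  sizes <- vapply(uniq, nrow, 0L)
  if (sum(sizes) == 0) {
    cc_warn("every couplet is shared between conditions; fractions reported as 0",
            "cciverse_empty_warning")
    fractions <- stats::setNames(rep(0, length(uniq)), names(uniq))
  } else {
    fractions <- sizes / sum(sizes)
  }
  list(unique = uniq, fractions = fractions)
}

#' Interaction pairs unique to one condition
#'
#' An interaction pair is unique to a condition when it occurs in at least
#' one couplet there and in no couplet of any other condition (cluster pairs
#' are ignored).
#'
#' @param cs A [condition_set()].
#' @return Named list of character vectors of interaction-pair ids.
#' @export
unique_int_pairs_by_condition <- function(cs) {
  stopifnot(inherits(cs, "condition_set"))
  sets <- lapply(cs$conditions, function(cci) unique(cci$records$int_pair))
  out <- lapply(names(sets), function(lbl) {
    others <- unlist(sets[setdiff(names(sets), lbl)], use.names = FALSE)
    setdiff(sets[[lbl]], others)
  })
  stats::setNames(out, names(sets))
}

#' Condition-specific significant functional terms
#'
#' Applies the module-ratio permutation test with the module assignment
#' replaced by a condition assignment: the universe is the union of
#' condition-unique interaction pairs, each labeled by its condition; the
#' statistic is, per (term, condition), the proportion of the condition's
#' unique pairs annotated to the term. Conditions with no unique pair are
#' excluded with a warning.
#'
#' @param cs A [condition_set()].
#' @param annotations Named list of \code{cci_annotation} objects, one per
#'   condition (term columns are united across conditions; a term absent
#'   from a condition's annotation counts as not annotating its pairs).
#' @param n_perm,seed,alpha,smoothed As in [test_term_specificity()].
#' @return A \code{cci_term_test} data frame with columns \code{term},
#'   \code{condition}, \code{condition_size}, \code{ratio}, \code{p_value},
#'   \code{significant}.
#' @export
test_condition_terms <- function(cs, annotations, n_perm = 1000, seed = 42,
                                 alpha = 0.05, smoothed = FALSE) {
  stopifnot(inherits(cs, "condition_set"))
  miss <- setdiff(names(cs$conditions), names(annotations))
  if (length(miss)) {
    cc_stop(paste0("missing annotation for condition(s): ", paste(miss, collapse = ", ")),
            "cciverse_param_error")
  }
  uniq <- unique_int_pairs_by_condition(cs)
  empty <- names(uniq)[vapply(uniq, length, 0L) == 0L]
  if (length(empty)) {
    cc_warn(paste0("condition(s) without unique interaction pairs excluded: ",
                   paste(empty, collapse = ", ")), "cciverse_empty_warning")
    uniq <- uniq[setdiff(names(uniq), empty)]
  }
  if (length(uniq) < 2L) {
    cc_stop("fewer than two conditions with unique interaction pairs; comparison undefined",
            "cciverse_param_error")
  }
  terms <- unique(unlist(lapply(annotations[names(uniq)],
                                function(a) colnames(a$matrix)), use.names = FALSE))
  if (!length(terms)) cc_stop("no annotated term in any condition", "cciverse_empty_error")
  blocks <- lapply(names(uniq), function(lbl) {
    m <- annotations[[lbl]]$matrix
    pairs <- uniq[[lbl]]
    block <- matrix(0L, length(pairs), length(terms),
                    dimnames = list(pairs, terms))
    present <- intersect(pairs, rownames(m))
    common <- intersect(terms, colnames(m))
    block[present, common] <- m[present, common]
    block
  })
  A <- do.call(rbind, blocks)
  assignment <- rep(names(uniq), vapply(uniq, length, 0L))
  perm_ratio_test(A, assignment, n_perm = n_perm, seed = seed, alpha = alpha,
                  smoothed = smoothed, group_label = "condition")
}

#' Sunburst restricted to one condition's unique interaction pairs
#'
#' Delegates to [sunburst_data()] on the condition's own table with
#' \code{restrict_pairs} set to the interaction pairs unique to that
#' condition, so only condition-specific communication contributes. Section
#' values are the (weighted) interaction totals per cell type.
#'
#' @param cs A [condition_set()].
#' @param condition Condition label.
#' @param term Functional term name.
#' @param ann The condition's \code{cci_annotation}.
#' @param weighted Use summed scores instead of couplet counts.
#' @return A \code{cci_sunburst}.
#' @export
condition_sunburst <- function(cs, condition, term, ann, weighted = FALSE) {
  stopifnot(inherits(cs, "condition_set"))
  if (!condition %in% names(cs$conditions)) {
    cc_stop(paste0("unknown condition label: ", condition), "cciverse_param_error")
  }
  uniq <- unique_int_pairs_by_condition(cs)[[condition]]
  sunburst_data(cs$conditions[[condition]], term, ann, weighted = weighted,
                restrict_pairs = uniq)
}
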