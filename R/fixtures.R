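# Deterministic synthetic fixtures: CCI tables with planted interaction-pair
# module structure, matching GMT collections, and multi-condition sets with
# condition-unique pairs. Gene symbols are synthesized (GENE0001, ...) so
# fixtures can never accidentally match a real gene-set collection.

#' Specify a synthetic CCI fixture
#'
#' All randomness downstream of a spec is fixed by its seed. Defaults model a
#' small single-cell study: 6 cell clusters, 30 interaction pairs in the
#' viewpoint's outgoing scope split into 3 planted functional modules of 10,
#' a fifth of components being 2-subunit complexes, lognormal interaction
#' scores and small-skewed p-values.
#'
#' @param n_clusters Number of cell clusters (labels \code{C1..Cn};
#'   \code{C1} is the designated viewpoint).
#' @param n_int_pairs Number of distinct interaction pairs.
#' @param frac_complex Probability that a component is a 2-subunit complex.
#' @param frac_autocrine Probability that a record is autocrine
#'   (\code{clust_a == clust_b}).
#' @param frac_undirected Probability that a pair is receptor-receptor
#'   (undirected) instead of ligand-receptor.
#' @param score_meanlog,score_sdlog Lognormal parameters for scores.
#' @param pval_shape1,pval_shape2 Beta parameters for p-values.
#' @param n_modules Number of planted functional modules (balanced sizes).
#' @param terms_per_module Planted module-specific terms per module.
#' @param n_background_terms Background terms annotating random pair subsets.
#' @param background_rate Probability a pair joins a background term.
#' @param max_extra_couplets Extra cluster-pairs per interaction pair beyond
#'   the first (0..max, uniform).
#' @param extra_sender_rate Probability a pair gains one extra couplet sent
#'   by a non-viewpoint cluster.
#' @param n_conditions Number of conditions for [make_condition_fixture()].
#' @param n_shared Interaction pairs present in every condition.
#' @param n_unique Interaction pairs unique to each condition.
#' @param seed Integer seed fixing all randomness.
#' @return A validated \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_clusters = 6, n_int_pairs = 30, frac_complex = 0.2,
                         frac_autocrine = 0.1, frac_undirected = 0.1,
                         score_meanlog = 0, score_sdlog = 0.5,
                         pval_shape1 = 0.5, pval_shape2 = 3,
                         n_modules = 3, terms_per_module = 3,
                         n_background_terms = 10, background_rate = 0.25,
                         max_extra_couplets = 2, extra_sender_rate = 0.3,
                         n_conditions = 3, n_shared = 10, n_unique = 5,
                         seed = 42) {
  spec <- list(n_clusters = n_clusters, n_int_pairs = n_int_pairs,
               frac_complex = frac_complex, frac_autocrine = frac_autocrine,
               frac_undirected = frac_undirected, score_meanlog = score_meanlog,
               score_sdlog = score_sdlog, pval_shape1 = pval_shape1,
               pval_shape2 = pval_shape2, n_modules = n_modules,
               terms_per_module = terms_per_module,
               n_background_terms = n_background_terms,
               background_rate = background_rate,
               max_extra_couplets = max_extra_couplets,
               extra_sender_rate = extra_sender_rate,
               n_conditions = n_conditions, n_shared = n_shared,
               n_unique = n_unique, seed = seed)
  counts <- c("n_clusters", "n_int_pairs", "n_modules", "terms_per_module",
              "n_background_terms", "max_extra_couplets", "n_conditions",
              "n_shared", "n_unique")
  for (f in counts) {
    if (spec[[f]] < 0) cc_stop(paste0(f, " must be >= 0"), "cciverse_spec_error")
  }
  for (f in c("frac_complex", "frac_autocrine", "frac_undirected",
              "background_rate", "extra_sender_rate")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      cc_stop(paste0(f, " must lie in [0, 1]"), "cciverse_spec_error")
    }
  }
  if (n_clusters < 2) cc_stop("need at least 2 clusters", "cciverse_spec_error")
  if (n_modules > n_int_pairs) {
    cc_stop("more planted modules than interaction pairs", "cciverse_spec_error")
  }
  structure(spec, class = "fixture_spec")
}

# Synthesize n interaction pairs with globally unique genes, starting the
# gene counter at `start`. Returns a data frame of components/genes/types.
synth_pairs <- function(n, frac_complex, frac_undirected, start = 1L) {
  gene_ctr <- start - 1L
  next_genes <- function(k) {
    g <- sprintf("GENE%04d", gene_ctr + seq_len(k))
    gene_ctr <<- gene_ctr + k
    g
  }
  comp <- function() paste(next_genes(1L + (stats::runif(1) < frac_complex)),
                           collapse = "+")
  out <- data.frame(comp_a = character(n), comp_b = character(n),
                    type_a = character(n), type_b = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    out$comp_a[i] <- comp()
    out$comp_b[i] <- comp()
    if (stats::runif(1) < frac_undirected) {
      out$type_a[i] <- "R"; out$type_b[i] <- "R"
    } else {
      out$type_a[i] <- "L"; out$type_b[i] <- "R"
    }
  }
  out$int_pair <- pair_id(out$comp_a, out$comp_b)
  out$genes_a <- out$comp_a
  out$genes_b <- out$comp_b
  attr(out, "next_gene") <- gene_ctr + 1L
  out
}

# Couplets for one pair: the first (and any extra) couplet is sent by the
# viewpoint C1 so every pair is in the viewpoint's outgoing scope; each
# record is autocrine with probability frac_autocrine (at most one autocrine
# couplet per pair, since couplets are distinct).
synth_couplets <- function(spec, clusters) {
  viewpoint <- clusters[1]
  m <- 1L + sample.int(spec$max_extra_couplets + 1L, 1L) - 1L
  auto <- stats::runif(m) < spec$frac_autocrine
  n_auto <- min(1L, sum(auto))
  n_para <- min(sum(!auto), spec$n_clusters - 1L)
  others <- sample(setdiff(clusters, viewpoint), n_para)
  cb <- c(if (n_auto) viewpoint, others)
  out <- data.frame(clust_a = rep(viewpoint, length(cb)), clust_b = cb,
                    stringsAsFactors = FALSE)
  if (stats::runif(1) < spec$extra_sender_rate && spec$n_clusters > 2L) {
    ca <- sample(setdiff(clusters, viewpoint), 1L)
    out <- rbind(out, data.frame(clust_a = ca,
                                 clust_b = sample(setdiff(clusters, ca), 1L)))
  }
  out
}

#' Generate a synthetic CCI table with planted module structure
#'
#' Produces a standardized [cci_table()] whose interaction pairs all occur in
#' the outgoing scope of the viewpoint cluster \code{C1}, together with the
#' planted ground truth (module label and genes per pair) for recovery tests.
#'
#' @param spec A [fixture_spec()].
#' @return List with \code{cci} (standardized [cci_table()]), \code{truth}
#'   (data frame \code{int_pair}, \code{module}, \code{genes_a},
#'   \code{genes_b}, \code{type_a}, \code{type_b}), \code{viewpoint}
#'   (\code{"C1"}) and \code{spec}.
#' @export
make_cci <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  clusters <- paste0("C", seq_len(spec$n_clusters))
  pairs <- synth_pairs(spec$n_int_pairs, spec$frac_complex, spec$frac_undirected)
  module <- if (spec$n_modules > 0) {
    sort(rep_len(seq_len(spec$n_modules), spec$n_int_pairs))
  } else {
    rep(NA_integer_, spec$n_int_pairs)
  }

  recs <- lapply(seq_len(spec$n_int_pairs), function(i) {
    cp <- synth_couplets(spec, clusters)
    data.frame(int_pair = pairs$int_pair[i],
               comp_a = pairs$comp_a[i], comp_b = pairs$comp_b[i],
               genes_a = pairs$genes_a[i], genes_b = pairs$genes_b[i],
               clust_a = cp$clust_a, clust_b = cp$clust_b,
               type_a = pairs$type_a[i], type_b = pairs$type_b[i],
               score = NA_real_, p_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  records$score <- stats::rlnorm(nrow(records), spec$score_meanlog, spec$score_sdlog)
  records$p_value <- stats::rbeta(nrow(records), spec$pval_shape1, spec$pval_shape2)

  cci <- cci_table(records, clusters = clusters, source_tool = "synthetic",
                   provenance = sprintf("make_cci(seed=%d)", spec$seed),
                   standardized = TRUE, has_pvalue = TRUE)
  truth <- data.frame(int_pair = pairs$int_pair, module = module,
                      genes_a = pairs$genes_a, genes_b = pairs$genes_b,
                      type_a = pairs$type_a, type_b = pairs$type_b,
                      stringsAsFactors = FALSE)
  list(cci = cci, truth = truth, viewpoint = clusters[1], spec = spec)
}

truth_gene_sets <- function(truth, idx) {
  toupper(unique(unlist(split_genes(c(truth$genes_a[idx], truth$genes_b[idx])))))
}

#' Generate GMT collections matching a planted fixture
#'
#' Builds two gene-set collections: a \code{"planted"} source whose
#' module-specific terms contain exactly all genes (every complex subunit) of
#' one module's pairs, so the all-components annotation rule fires for that
#' module and no other pair; and a \code{"background"} source whose terms
#' cover random pair subsets. Every pair is annotated by at least one term.
#'
#' @param spec The [fixture_spec()] used for [make_cci()].
#' @param truth The ground-truth table returned by [make_cci()].
#' @return List of two \code{gene_set_collection}s (\code{planted},
#'   \code{background}).
#' @export
make_gmt <- function(spec, truth) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1000L)
  terms <- list()
  for (m in sort(unique(truth$module[!is.na(truth$module)]))) {
    genes <- truth_gene_sets(truth, which(truth$module == m))
    for (t in seq_len(spec$terms_per_module)) {
      terms[[sprintf("MODULE%d_TERM%d", m, t)]] <- genes
    }
  }
  planted <- gene_set_collection(terms, "planted")

  bg <- list()
  for (j in seq_len(spec$n_background_terms)) {
    take <- which(stats::runif(nrow(truth)) < spec$background_rate)
    if (!length(take)) take <- sample.int(nrow(truth), 1L)
    bg[[sprintf("BACKGROUND_TERM%d", j)]] <- truth_gene_sets(truth, take)
  }
  background <- gene_set_collection(bg, "background")
  list(planted = planted, background = background)
}

#' Generate a multi-condition fixture with condition-unique pairs
#'
#' Builds \code{n_conditions} standardized CCI tables sharing \code{n_shared}
#' interaction pairs (same couplets everywhere) and carrying \code{n_unique}
#' pairs found only in that condition, plus GMT collections with one planted
#' term per condition covering exactly its unique pairs' genes (and
#' background terms over all pairs).
#'
#' @param spec A [fixture_spec()] with \code{n_conditions >= 2}.
#' @return List with \code{conditions} (a [condition_set()]),
#'   \code{collections} (planted + background \code{gene_set_collection}s),
#'   and \code{truth} (data frame \code{int_pair}, \code{condition} --
#'   \code{"shared"} or a condition label -- plus genes and types).
#' @export
make_condition_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_conditions < 2L) {
    cc_stop("condition fixtures need n_conditions >= 2", "cciverse_spec_error")
  }
  set.seed(spec$seed + 2000L)
  clusters <- paste0("C", seq_len(spec$n_clusters))
  labels <- paste0("cond", seq_len(spec$n_conditions))
  n_total <- spec$n_shared + spec$n_conditions * spec$n_unique
  if (n_total < 1L) cc_stop("condition fixture has no interaction pairs",
                            "cciverse_spec_error")
  pairs <- synth_pairs(n_total, spec$frac_complex, spec$frac_undirected)
  owner <- c(rep("shared", spec$n_shared), rep(labels, each = spec$n_unique))

  shared_couplets <- lapply(seq_len(spec$n_shared), function(i)
    synth_couplets(spec, clusters))

  tables <- lapply(labels, function(lbl) {
    idx <- c(seq_len(spec$n_shared), which(owner == lbl))
    recs <- lapply(idx, function(i) {
      cp <- if (owner[i] == "shared") shared_couplets[[i]] else
        synth_couplets(spec, clusters)
      data.frame(int_pair = pairs$int_pair[i],
                 comp_a = pairs$comp_a[i], comp_b = pairs$comp_b[i],
                 genes_a = pairs$genes_a[i], genes_b = pairs$genes_b[i],
                 clust_a = cp$clust_a, clust_b = cp$clust_b,
                 type_a = pairs$type_a[i], type_b = pairs$type_b[i],
                 score = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, recs)
    records$score <- stats::rlnorm(nrow(records), spec$score_meanlog, spec$score_sdlog)
    records$p_value <- stats::rbeta(nrow(records), spec$pval_shape1, spec$pval_shape2)
    cci_table(records, clusters = clusters, source_tool = "synthetic",
              provenance = sprintf("make_condition_fixture(seed=%d, %s)", spec$seed, lbl),
              standardized = TRUE, has_pvalue = TRUE)
  })
  names(tables) <- labels

  terms <- list()
  for (lbl in labels) {
    idx <- which(owner == lbl)
    if (length(idx)) {
      terms[[sprintf("%s_TERM", toupper(lbl))]] <- truth_gene_sets(pairs, idx)
    }
  }
  bg <- list()
  for (j in seq_len(spec$n_background_terms)) {
    take <- which(stats::runif(n_total) < spec$background_rate)
    if (!length(take)) take <- sample.int(n_total, 1L)
    bg[[sprintf("BACKGROUND_TERM%d", j)]] <- truth_gene_sets(pairs, take)
  }
  collections <- list(planted = gene_set_collection(terms, "planted"),
                      background = gene_set_collection(bg, "background"))
  truth <- data.frame(int_pair = pairs$int_pair, condition = owner,
                      genes_a = pairs$genes_a, genes_b = pairs$genes_b,
                      type_a = pairs$type_a, type_b = pairs$type_b,
                      stringsAsFactors = FALSE)
  list(conditions = condition_set(tables), collections = collections, truth = truth)
}

#' Write fixture files to a directory
#'
#' Writes the custom-schema CCI table (\code{cci.tsv}), a typing table
#' (\code{typing.tsv}), the planted and background GMT files and the ground
#' truth (\code{truth.tsv}). Byte-identical for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  fx <- make_cci(spec)
  gmts <- make_gmt(spec, fx$truth)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cci_table(fx$cci, file.path(dir, "cci.tsv"))
  comps <- split_pair_id(fx$truth$int_pair)
  typing <- unique(data.frame(
    component = c(comps$comp_a, comps$comp_b),
    type = c(fx$truth$type_a, fx$truth$type_b), stringsAsFactors = FALSE))
  utils::write.table(typing, file.path(dir, "typing.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(gmts$planted, file.path(dir, "planted.gmt"))
  write_gmt(gmts$background, file.path(dir, "background.gmt"))
  utils::write.table(fx$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
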