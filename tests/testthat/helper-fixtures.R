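# Small in-code fixtures shared across test files.

# Build a cci_table from compact per-record arguments; genes default to the
# component strings.
mk_cci <- function(int_pair, clust_a, clust_b, type_a = "L", type_b = "R",
                   score = 1, p_value = NA_real_, standardized = TRUE, ...) {
  comps <- cciverse:::split_pair_id(int_pair)
  n <- length(int_pair)
  records <- data.frame(
    int_pair = int_pair, comp_a = comps$comp_a, comp_b = comps$comp_b,
    genes_a = comps$comp_a, genes_b = comps$comp_b,
    clust_a = clust_a, clust_b = clust_b,
    type_a = rep_len(type_a, n), type_b = rep_len(type_b, n),
    score = rep_len(score, n), p_value = rep_len(p_value, n),
    stringsAsFactors = FALSE)
  cci_table(records, standardized = standardized, ...)
}

# Write a custom-schema TSV from raw columns (types may be empty strings).
write_custom_tsv <- function(path, int_pair, clustA, clustB, typeA, typeB,
                             score, p_value = NULL) {
  df <- data.frame(int_pair = int_pair, clustA = clustA, clustB = clustB,
                   typeA = typeA, typeB = typeB, score = score,
                   stringsAsFactors = FALSE)
  if (!is.null(p_value)) df$p_value <- p_value
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Hand-made CellPhoneDB v2 means/pvalues fixture in a temp directory.
write_cpdb_fixture <- function(dir, cluster_pairs = c("T|Macro", "Macro|Macro"),
                               means = matrix(c(0.5, 0.2), 1),
                               pvals = matrix(c(0.01, 1.0), 1),
                               gene_a = "LIGX", gene_b = "RECY",
                               receptor_a = "False", receptor_b = "True",
                               partner_a = "simple:P1", partner_b = "simple:P2") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(means)
  meta <- data.frame(
    id_cp_interaction = paste0("CPI-", seq_len(n)),
    interacting_pair = paste(gene_a, gene_b, sep = "_"),
    partner_a = partner_a, partner_b = partner_b,
    gene_a = gene_a, gene_b = gene_b, secreted = "True",
    receptor_a = receptor_a, receptor_b = receptor_b,
    annotation_strategy = "curated", is_integrin = "False",
    stringsAsFactors = FALSE, check.names = FALSE)
  m <- cbind(meta, as.data.frame(means))
  names(m)[(ncol(meta) + 1):ncol(m)] <- cluster_pairs
  p <- cbind(meta, as.data.frame(pvals))
  names(p)[(ncol(meta) + 1):ncol(p)] <- cluster_pairs
  utils::write.table(m, file.path(dir, "means.txt"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(p, file.path(dir, "pvalues.txt"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dir
}

# Random standardized table for property tests (plain records, no planted
# structure): clusters A..E, simple single-gene pairs.
random_cci <- function(seed, n_records = 40, n_clusters = 4, n_pairs = 12) {
  set.seed(seed)
  clusters <- LETTERS[seq_len(n_clusters)]
  pairs <- paste0("LG", seq_len(n_pairs), "_RC", seq_len(n_pairs))
  idx <- sample.int(n_pairs, n_records, replace = TRUE)
  ca <- sample(clusters, n_records, replace = TRUE)
  cb <- sample(clusters, n_records, replace = TRUE)
  keep <- !duplicated(paste(idx, ca, cb))
  mk_cci(pairs[idx][keep], ca[keep], cb[keep],
         score = round(stats::runif(sum(keep), 0, 2), 3),
         p_value = round(stats::runif(sum(keep)), 3))
}
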