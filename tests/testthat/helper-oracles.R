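# Independent oracles: brute-force implementations kept deliberately naive
# and separate from the package's code paths.

# All n! permutations of 1..n as an (n!) x n matrix (n <= 8).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact permutation p-values for the group-ratio statistic by enumerating
# every permutation of the assignment vector.
exact_perm_p <- function(A, assignment) {
  A <- as.matrix(A)
  n <- nrow(A)
  fac <- factor(assignment)
  gi <- as.integer(fac)
  sizes <- tabulate(gi)
  ratio_of <- function(asg) {
    sapply(seq_len(ncol(A)), function(t)
      sapply(seq_along(sizes), function(g) sum(A[asg == g, t]) / sizes[g]))
  }
  obs <- ratio_of(gi)
  perms <- all_permutations(n)
  hits <- matrix(0, length(sizes), ncol(A))
  for (r in seq_len(nrow(perms))) {
    hits <- hits + (ratio_of(gi[perms[r, ]]) >= obs - 1e-12)
  }
  list(obs = obs, p = hits / nrow(perms), groups = levels(fac))
}

# Naive annotation oracle: set inclusion of every gene of both components.
naive_annotation <- function(pairs_df, collections) {
  genes <- Map(function(a, b) toupper(c(strsplit(a, "+", fixed = TRUE)[[1]],
                                        strsplit(b, "+", fixed = TRUE)[[1]])),
               pairs_df$genes_a, pairs_df$genes_b)
  all_terms <- list()
  for (coll in collections) {
    for (tn in names(coll$terms)) {
      key <- tolower(tn)
      all_terms[[key]] <- union(all_terms[[key]] %||% character(0),
                                toupper(coll$terms[[tn]]))
    }
  }
  out <- matrix(0L, length(genes), length(all_terms),
                dimnames = list(pairs_df$int_pair, names(all_terms)))
  for (i in seq_along(genes)) for (j in seq_along(all_terms)) {
    # per-source check, OR-merged: a pair is annotated when some single
    # source's gene set contains all of its genes
    hit <- FALSE
    for (coll in collections) {
      tn <- names(coll$terms)[tolower(names(coll$terms)) == names(all_terms)[j]]
      if (length(tn) && all(genes[[i]] %in% toupper(coll$terms[[tn]]))) hit <- TRUE
    }
    out[i, j] <- as.integer(hit)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive per-cluster-pair counts by a double loop.
naive_counts <- function(cci, weighted = FALSE) {
  cl <- cci$clusters
  m <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  r <- cci$records
  for (i in seq_len(nrow(r))) {
    w <- if (weighted) r$score[i] else 1
    m[r$clust_a[i], r$clust_b[i]] <- m[r$clust_a[i], r$clust_b[i]] + w
  }
  m
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
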