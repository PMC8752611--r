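# Interaction-pair module definition and the term-specificity permutation test.

flow_fixture <- function() {
  mk_cci(c("L1_R1", "L2_R2", "RR1_RR2", "L3_R3"),
         c("V", "B", "V", "V"), c("B", "V", "B", "V"),
         type_a = c("L", "L", "R", "L"), type_b = c("R", "R", "R", "R"),
         score = 1:4)
}

test_that("flow subsetting selects the documented record classes", {
  cci <- flow_fixture()
  out <- subset_by_flow(cci, "V", "outgoing")
  expect_setequal(out$int_pairs, c("L1_R1", "L3_R3"))  # includes autocrine V->V
  inc <- subset_by_flow(cci, "V", "incoming")
  expect_setequal(inc$int_pairs, c("L2_R2", "L3_R3"))
  und <- subset_by_flow(cci, "V", "undirected")
  expect_equal(und$int_pairs, "RR1_RR2")
  expect_error(subset_by_flow(cci, "nope", "outgoing"),
               class = "cciverse_cluster_error")
  expect_warning(subset_by_flow(mk_cci("L_R", "A", "B"), "B", "outgoing"),
                 class = "cciverse_empty_warning")
})

planted_profiles <- function(n_per_group = 10, groups = 2, bg = 0) {
  blocks <- lapply(seq_len(groups), function(g) {
    m <- matrix(0L, n_per_group, 3 * groups + bg)
    m[, (3 * (g - 1) + 1):(3 * g)] <- 1L
    m
  })
  m <- do.call(rbind, blocks)
  rownames(m) <- paste0("P", seq_len(nrow(m)), "_Q", seq_len(nrow(m)))
  colnames(m) <- paste0("T", seq_len(ncol(m)))
  m
}

test_that("embedding separates planted groups and is deterministic", {
  m <- planted_profiles(10, 2)
  # neighbor scale below the group size so the fuzzy graph stays group-local
  coords <- embed_int_pairs(m, seed = 1, n_neighbors = 8)
  expect_equal(dim(coords), c(20L, 2L))
  d <- as.matrix(dist(coords))
  within <- c(d[1:10, 1:10][upper.tri(diag(10))], d[11:20, 11:20][upper.tri(diag(10))])
  between <- d[1:10, 11:20]
  # within-group (duplicate-profile) distances stay below between-group ones
  expect_lt(max(within), min(between))
  expect_identical(coords, embed_int_pairs(m, seed = 1, n_neighbors = 8))
  expect_false(identical(coords, embed_int_pairs(m, seed = 2, n_neighbors = 8)))
})

test_that("embedding validates its input and clamps n_neighbors", {
  m <- planted_profiles(3, 2)
  expect_warning(embed_int_pairs(m, seed = 1, n_neighbors = 50),
                 class = "cciverse_param_warning")
  expect_error(embed_int_pairs(m[1, , drop = FALSE]), class = "cciverse_config_error")
  m0 <- m; m0[2, ] <- 0L
  expect_error(embed_int_pairs(m0), class = "cciverse_config_error")
})

test_that("module clustering cuts, relabels by size and recovers planted clouds", {
  set.seed(4)
  coords <- rbind(matrix(rnorm(40, 0), ncol = 2),
                  matrix(rnorm(20, 10), ncol = 2))
  rownames(coords) <- paste0("p", 1:30)
  out <- cluster_modules(coords, 2)
  expect_equal(unname(out$assignment[1:20]), rep(1L, 20))  # bigger cloud is module 1
  expect_equal(unname(out$assignment[21:30]), rep(2L, 10))
  expect_equal(unique(cluster_modules(coords, 1)$assignment), 1L)
  expect_equal(sort(unique(cluster_modules(coords, 30)$assignment)), 1:30)
  expect_error(cluster_modules(coords, 31), class = "cciverse_param_error")
})

test_that("model selection finds planted k and WSS is non-increasing", {
  set.seed(9)
  coords <- rbind(matrix(rnorm(20, 0, 0.3), ncol = 2),
                  matrix(rnorm(20, 6, 0.3), ncol = 2),
                  matrix(c(rnorm(10, 12, 0.3), rnorm(10, 0, 0.3)), ncol = 2))
  ck <- choose_k(coords, k_max = 8)
  expect_equal(ck$k_elbow, 3L)
  expect_equal(ck$k_silhouette, 3L)
  expect_true(all(diff(ck$wss) <= 1e-9))
  expect_true(is.na(ck$silhouette[1]))
  # degenerate geometry: identical points
  same <- matrix(1, 5, 2)
  expect_warning(ck0 <- choose_k(same, k_max = 3),
                 class = "cciverse_degenerate_warning")
  expect_equal(ck0$k_elbow, 1L)
})

test_that("ten or fewer annotated pairs force a single module", {
  fx <- make_cci(fixture_spec(seed = 3, n_int_pairs = 10, n_modules = 2,
                              frac_undirected = 0))
  ann <- annotate_int_pairs(fx$cci, make_gmt(fx$spec, fx$truth))
  res <- suppressWarnings(define_modules(fx$cci, "C1", "outgoing", ann))
  expect_equal(res$k, 1L)
  expect_equal(unname(unique(res$assignment)), 1L)
  expect_equal(nrow(res$coords), 10)  # coordinates still produced
  # 11 pairs: k comes from the elbow and the assignment covers all pairs
  fx11 <- make_cci(fixture_spec(seed = 4, n_int_pairs = 11, n_modules = 2,
                                frac_undirected = 0))
  ann11 <- annotate_int_pairs(fx11$cci, make_gmt(fx11$spec, fx11$truth))
  res11 <- suppressWarnings(define_modules(fx11$cci, "C1", "outgoing", ann11))
  expect_gte(res11$k, 1L)
  expect_setequal(names(res11$assignment), fx11$truth$int_pair)
  expect_equal(sum(table(res11$assignment)), 11L)
})

test_that("planted three-module structure is recovered with k = auto", {
  fx <- make_cci(fixture_spec(seed = 21, frac_undirected = 0))
  ann <- annotate_int_pairs(fx$cci, make_gmt(fx$spec, fx$truth))
  res <- define_modules(fx$cci, "C1", "outgoing", ann, seed = 21)
  expect_equal(res$k, 3L)
  expect_equal(ari(res$assignment[fx$truth$int_pair], fx$truth$module), 1)
  # assignment is a partition of the in-scope pairs
  expect_equal(length(res$assignment), length(res$int_pairs))
  expect_true(all(res$assignment %in% seq_len(res$k)))
})

test_that("permutation p-values match exact enumeration on small cases", {
  # hand case: term matching one 2-pair module among 4 pairs -> p = 1/6
  A <- cbind(t_m1 = c(1, 1, 0, 0), t_split = c(1, 0, 1, 0), t_all = c(1, 1, 1, 1))
  rownames(A) <- letters[1:4]
  assign <- stats::setNames(c(1L, 1L, 2L, 2L), letters[1:4])
  tt <- test_term_specificity(assign, A, n_perm = 10000, seed = 11)
  df <- as.data.frame(tt)
  p_m1 <- df$p_value[df$term == "t_m1" & df$module == "1"]
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_lt(abs(p_m1 - 1 / 6), 3 * se)
  # split term: observed ratio 0.5 in each module, exact p = 5/6
  p_split <- df$p_value[df$term == "t_split" & df$module == "1"]
  se2 <- sqrt((5 / 6) * (1 / 6) / 10000)
  expect_lt(abs(p_split - 5 / 6), 3 * se2)
  # a term annotating every pair has an invariant statistic: p = 1 exactly
  expect_equal(df$p_value[df$term == "t_all"], c(1, 1))

  # random small fixtures vs full enumeration
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:8, 1)
    A2 <- matrix(rbinom(n * 3, 1, 0.5), n,
                 dimnames = list(paste0("p", 1:n), paste0("t", 1:3)))
    A2[, 1] <- pmax(A2[, 1], c(1, rep(0, n - 1)))  # avoid all-zero columns
    asg <- sample(rep_len(1:2, n))
    exact <- exact_perm_p(A2, asg)
    mc <- as.data.frame(test_term_specificity(asg, A2, n_perm = 20000, seed = seed))
    for (i in seq_len(nrow(mc))) {
      g <- match(mc$module[i], exact$groups)
      t <- match(mc$term[i], colnames(A2))
      pe <- exact$p[g, t]
      tol <- 4 * sqrt(max(pe * (1 - pe), 1e-4) / 20000)
      expect_lt(abs(mc$p_value[i] - pe), tol + 1e-12)
    }
  }
})

test_that("degenerate permutation settings are reported", {
  A <- cbind(t1 = c(1, 0, 1))
  expect_warning(tt <- test_term_specificity(c(1L, 1L, 1L), A, n_perm = 50),
                 class = "cciverse_degenerate_warning")
  expect_equal(as.data.frame(tt)$p_value, 1)
  expect_error(test_term_specificity(c(1L, 2L, 1L), A, n_perm = 0),
               class = "cciverse_param_error")
  expect_error(test_term_specificity(c(1L, 2L), A),
               class = "cciverse_param_error")
})

test_that("circle-plot links carry clipped z-scored interaction scores", {
  cci <- mk_cci(paste0("L", 1:3, "_R", 1:3), "V", c("A", "B", "C"), score = c(1, 2, 3))
  ann <- annotate_int_pairs(cci, gene_set_collection(
    list(t = c(paste0("L", 1:3), paste0("R", 1:3))), "s"))
  res <- suppressWarnings(define_modules(cci, "V", "outgoing", ann))
  links <- circleplot_data(res$cci, res, 1)
  expect_equal(links$scaled_score, c(-1, 0, 1) * 1.2247449, tolerance = 1e-3)
  expect_equal(links$source_cluster, rep("V", 3))
  # equal scores -> all zero; outlier -> clipped
  cci_eq <- mk_cci(paste0("L", 1:3, "_R", 1:3), "V", c("A", "B", "C"), score = 2)
  res_eq <- suppressWarnings(define_modules(cci_eq, "V", "outgoing", ann))
  expect_equal(circleplot_data(res_eq$cci, res_eq, 1)$scaled_score, rep(0, 3))
  cci_out <- mk_cci(paste0("L", 1:6, "_R", 1:6), "V", c("A", "B", "C", "A", "B", "C"),
                    score = c(1, 1, 1, 1, 1, 100))
  ann_out <- annotate_int_pairs(cci_out, gene_set_collection(
    list(t = c(paste0("L", 1:6), paste0("R", 1:6))), "s"))
  res_out <- suppressWarnings(define_modules(cci_out, "V", "outgoing", ann_out))
  expect_equal(max(circleplot_data(res_out$cci, res_out, 1)$scaled_score), 2)
  expect_error(circleplot_data(res$cci, res, 99), class = "cciverse_param_error")
})

test_that("dendrograms serialize to readable newick", {
  skip_if_not_installed("ape")
  coords <- matrix(rnorm(20), ncol = 2,
                   dimnames = list(paste0("L", 1:10, "_R", 1:10), NULL))
  hc <- stats::hclust(dist(coords), method = "ward.D2")
  tree <- ape::read.tree(text = hclust_newick(hc))
  expect_equal(sort(tree$tip.label), sort(rownames(coords)))
  expect_equal(tree$Nnode, 9)
})
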