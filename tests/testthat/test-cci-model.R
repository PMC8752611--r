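# Parsing, standardization and filtering of CCI tables.

test_that("custom schema parsing maps fields and splits complexes", {
  path <- write_custom_tsv(withr::local_tempfile(fileext = ".tsv"),
                           int_pair = c("compA_compB", "BMP7_ACVR1+ACVR2A"),
                           clustA = c("T", "NK"), clustB = c("Macro", "CAF"),
                           typeA = c("L", "L"), typeB = c("R", "R"),
                           score = c(0.5, 1.2))
  cci <- read_cci_table(path)
  expect_s3_class(cci, "cci_table")
  expect_equal(nrow(cci$records), 2)
  expect_setequal(cci$clusters, c("T", "NK", "Macro", "CAF"))
  expect_equal(cci$records$comp_b[2], "ACVR1+ACVR2A")
  expect_equal(cciverse:::split_genes(cci$records$genes_b[2])[[1]],
               c("ACVR1", "ACVR2A"))
  expect_false(cci$has_pvalue)
  expect_equal(pair_display("BMP7_ACVR1+ACVR2A"), "BMP7 & (ACVR1+ACVR2A)")
})

test_that("custom schema errors name the problem", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("int_pair\tclustA\tclustB\ttypeA\tscore", bad)  # typeB missing
  expect_error(read_cci_table(bad), "typeB", class = "cciverse_schema_error")

  empty <- write_custom_tsv(withr::local_tempfile(fileext = ".tsv"),
                            character(0), character(0), character(0),
                            character(0), character(0), numeric(0))
  expect_error(read_cci_table(empty), class = "cciverse_empty_error")

  nonnum <- write_custom_tsv(withr::local_tempfile(fileext = ".tsv"),
                             c("A_B", "C_D"), c("T", "T"), c("M", "M"),
                             c("L", "L"), c("R", "R"), c("0.5", "high"))
  expect_error(read_cci_table(nonnum), "2", class = "cciverse_parse_error")
})

test_that("duplicate couplets are rejected at construction", {
  expect_error(
    mk_cci(c("A_B", "A_B"), c("T", "T"), c("M", "M")),
    class = "cciverse_duplicate_error")
})

test_that("cellphonedb melt produces one record per finite mean cell", {
  dir <- write_cpdb_fixture(withr::local_tempdir())
  cci <- read_cellphonedb(dir)
  expect_equal(nrow(cci$records), 2)  # 1 pair x 2 cluster-pair columns
  expect_equal(cci$records$clust_a, c("T", "Macro"))
  expect_equal(cci$records$clust_b, c("Macro", "Macro"))
  expect_equal(cci$records$score, c(0.5, 0.2))
  # p-value 1.0 kept: no implicit filtering
  expect_equal(cci$records$p_value, c(0.01, 1.0))
  # receptor flag on partner B only -> L-R typing
  expect_equal(unique(cci$records$type_a), "L")
  expect_equal(unique(cci$records$type_b), "R")
})

test_that("cellphonedb NA mean cells are skipped and shape mismatch errors", {
  dir <- write_cpdb_fixture(withr::local_tempdir(),
                            means = matrix(c(0.7, NA), 1),
                            pvals = matrix(c(0.2, 0.3), 1))
  cci <- read_cellphonedb(dir)
  expect_equal(nrow(cci$records), 1)

  dir2 <- write_cpdb_fixture(withr::local_tempdir())
  pv <- utils::read.table(file.path(dir2, "pvalues.txt"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  utils::write.table(pv[, -ncol(pv)], file.path(dir2, "pvalues.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cellphonedb(dir2), class = "cciverse_consistency_error")

  dir3 <- withr::local_tempdir()
  writeLines("foo\tbar", file.path(dir3, "means.txt"))
  writeLines("foo\tbar", file.path(dir3, "pvalues.txt"))
  expect_error(read_cellphonedb(dir3), "receptor_a",
               class = "cciverse_dialect_error")
})

test_that("standardization swaps receptor-ligand records preserving flow", {
  cci <- mk_cci(c("compX_compY", "compL_compR"),
                c("Macro", "T"), c("Mal", "B"),
                type_a = c("R", "L"), type_b = c("L", "R"),
                score = c(2, 3), standardized = FALSE)
  std <- standardize_cci(cci)
  r <- std$records
  expect_equal(r$int_pair[1], "compY_compX")
  expect_equal(r$clust_a[1], "Mal")
  expect_equal(r$clust_b[1], "Macro")
  expect_equal(r$type_a[1], "L")
  expect_equal(r$type_b[1], "R")
  # already L-R row untouched
  expect_equal(r$int_pair[2], "compL_compR")
  expect_equal(r$clust_a[2], "T")
  expect_true(std$standardized)
  # idempotent
  expect_equal(standardize_cci(std)$records, std$records)
})

test_that("reordering preserves (ligand cluster, receptor cluster, score) triples", {
  set.seed(1)
  n <- 20
  types <- sample(c("LR", "RL"), n, replace = TRUE)
  cci <- mk_cci(paste0("L", 1:n, "_R", 1:n),
                sample(LETTERS[1:4], n, TRUE), sample(LETTERS[1:4], n, TRUE),
                type_a = ifelse(types == "LR", "L", "R"),
                type_b = ifelse(types == "LR", "R", "L"),
                score = runif(n), standardized = FALSE)
  std <- standardize_cci(cci)
  lig_clust <- ifelse(types == "LR", cci$records$clust_a, cci$records$clust_b)
  rec_clust <- ifelse(types == "LR", cci$records$clust_b, cci$records$clust_a)
  expect_setequal(paste(std$records$clust_a, std$records$clust_b, std$records$score),
                  paste(lig_clust, rec_clust, cci$records$score))
})

test_that("typing gaps and contradictions are handled as documented", {
  path <- write_custom_tsv(withr::local_tempfile(fileext = ".tsv"),
                           c("known_mystery", "AL_AR"), c("T", "T"), c("M", "B"),
                           typeA = c("L", "L"), typeB = c("", "R"), score = c(1, 2))
  raw <- read_cci_table(path)
  typing <- data.frame(component = c("known", "AL"), type = c("R", "R"))
  expect_warning(expect_warning(
    std <- standardize_cci(raw, typing = typing),
    class = "cciverse_typing_warning"), class = "cciverse_typing_warning")
  r <- std$records
  expect_equal(r$type_b[r$comp_b == "mystery"], "unknown")
  expect_equal(r$type_a[r$int_pair == "AL_AR"], "L")  # input wins over curated
  # unknown-typed records are excluded from directed flows
  sub <- suppressWarnings(subset_by_flow(std, "T", "outgoing"))
  expect_equal(sub$int_pairs, "AL_AR")
})

test_that("the bundled synthetic curated typing table reads and applies", {
  typing <- read_typing_table(
    system.file("extdata", "synthetic_curated_typing.tsv", package = "cciverse"))
  expect_true(all(typing$type %in% c("L", "R")))
  path <- write_custom_tsv(withr::local_tempfile(fileext = ".tsv"),
                           "BMP7_ACVR1+ACVR2A", "NK", "CAF", "", "", 1.5)
  std <- standardize_cci(read_cci_table(path), typing = typing)
  expect_equal(std$records$type_a, "L")
  expect_equal(std$records$type_b, "R")
})

test_that("filtering obeys thresholds, cluster sets and p-value semantics", {
  cci <- mk_cci(paste0("P", 1:3, "_Q", 1:3), c("A", "A", "B"), c("B", "C", "B"),
                score = c(0.1, 0.5, 0.9), p_value = c(0.01, 0.2, 0.6))
  expect_equal(nrow(filter_cci(cci, min_score = 0.5)$records), 2)
  expect_equal(nrow(filter_cci(cci, keep_clusters = c("A", "B"))$records), 2)
  expect_equal(nrow(filter_cci(cci, max_pval = 0.05)$records), 1)
  # identity filter
  expect_equal(filter_cci(cci, min_score = 0, max_pval = 1,
                          keep_clusters = cci$clusters)$records,
               cci$records)
  # p filter is a no-op when the table has no p-value column
  nop <- mk_cci("P_Q", "A", "B", score = 1)
  expect_equal(nrow(filter_cci(nop, max_pval = 0.001)$records), 1)
  # but a missing p in a p-carrying table fails the filter
  withp <- mk_cci(c("P_Q", "R_S"), c("A", "A"), c("B", "B"),
                  score = 1, p_value = c(0.01, NA), has_pvalue = TRUE)
  expect_equal(filter_cci(withp, max_pval = 0.05)$records$int_pair, "P_Q")
  expect_warning(filter_cci(cci, min_score = 10), class = "cciverse_empty_warning")
  expect_error(filter_cci(cci, keep_clusters = "Z"), class = "cciverse_cluster_error")
})

test_that("filtering is monotone in its thresholds", {
  cci <- random_cci(11)
  for (s in c(0, 0.3, 0.6, 0.9, 1.4)) {
    n1 <- nrow(filter_cci(cci, min_score = s)$records)
    n2 <- nrow(suppressWarnings(filter_cci(cci, min_score = s + 0.3)$records))
    expect_lte(n2, n1)
  }
  for (p in c(1, 0.7, 0.4, 0.1)) {
    n1 <- nrow(suppressWarnings(filter_cci(cci, max_pval = p)$records))
    n2 <- nrow(suppressWarnings(filter_cci(cci, max_pval = p - 0.1)$records))
    expect_lte(n2, n1)
  }
})

test_that("write/read round-trips a standardized table field-by-field", {
  cci <- suppressWarnings(standardize_cci(random_cci(5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cci_table(cci, path)
  back <- suppressWarnings(standardize_cci(read_cci_table(path)))
  expect_equal(back$records, cci$records)
  expect_equal(back$clusters, cci$clusters)
})
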