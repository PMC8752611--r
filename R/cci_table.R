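# The unified cell-cell interaction (CCI) data model.
#
# A `cci_table` holds one record per (interaction pair, cluster pair):
# the two molecular components (single genes or "+"-joined multi-subunit
# complexes), their gene symbols, the two communicating clusters, the
# molecular types (L = ligand, R = receptor, possibly "unknown" after
# standardization), a non-negative interaction score and an optional p-value.

RECORD_COLS <- c("int_pair", "comp_a", "comp_b", "genes_a", "genes_b",
                 "clust_a", "clust_b", "type_a", "type_b", "score", "p_value")

#' Construct a CCI table
#'
#' Low-level constructor and validator for the standardized cell-cell
#' interaction container used throughout the package. Most users will create
#' tables with [read_cci_table()] or [read_cellphonedb()] instead.
#'
#' @param records Data frame with columns \code{int_pair}, \code{comp_a},
#'   \code{comp_b}, \code{genes_a}, \code{genes_b} (gene symbols,
#'   \code{"+"}-joined within a complex), \code{clust_a}, \code{clust_b},
#'   \code{type_a}, \code{type_b} (\code{"L"}, \code{"R"}, \code{"unknown"} or
#'   \code{NA}), \code{score}, \code{p_value}.
#' @param clusters Optional ordered cluster universe; defaults to first
#'   appearance order in the records.
#' @param source_tool Label for the tool the predictions came from.
#' @param provenance Character vector of operations applied so far.
#' @param standardized Logical; has [standardize_cci()] been applied?
#' @param has_pvalue Logical; did the input carry a p-value column? When
#'   \code{FALSE}, p-value filters in [filter_cci()] are no-ops.
#' @return An object of class \code{cci_table}.
#' @export
cci_table <- function(records, clusters = NULL, source_tool = "custom",
                      provenance = character(), standardized = FALSE,
                      has_pvalue = !all(is.na(records$p_value))) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(RECORD_COLS, names(records))
  if (length(missing_cols)) {
    cc_stop(paste0("records are missing column(s): ", paste(missing_cols, collapse = ", ")),
            "cciverse_schema_error")
  }
  records <- as.data.frame(records[RECORD_COLS], stringsAsFactors = FALSE)
  rownames(records) <- NULL

  if (nrow(records)) {
    if (any(!is.finite(records$score))) {
      cc_stop("interaction scores must be finite numbers", "cciverse_parse_error")
    }
    if (any(records$score < 0)) {
      cc_stop("interaction scores must be non-negative", "cciverse_parse_error")
    }
    pv <- records$p_value
    if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
      cc_stop("p-values must lie in [0, 1]", "cciverse_parse_error")
    }
    ok_type <- c("L", "R", "unknown", NA_character_)
    if (!all(records$type_a %in% ok_type) || !all(records$type_b %in% ok_type)) {
      cc_stop("molecular types must be 'L', 'R', 'unknown' or NA", "cciverse_parse_error")
    }
    dup <- duplicated(couplet_id(records$int_pair, records$clust_a, records$clust_b))
    if (any(dup)) {
      cc_stop(sprintf(
        "duplicate (int_pair, clust_a, clust_b) couplet(s) at row(s): %s",
        paste(which(dup), collapse = ", ")), "cciverse_duplicate_error")
    }
    if (standardized && any(records$type_a == "R" & records$type_b == "L", na.rm = TRUE)) {
      cc_stop("a standardized table may not contain receptor-ligand ordered records",
              "cciverse_parse_error")
    }
  }

  seen <- unique(c(records$clust_a, records$clust_b))
  if (is.null(clusters)) {
    clusters <- seen
  } else {
    clusters <- as.character(clusters)
    if (!all(seen %in% clusters)) {
      cc_stop("cluster universe does not cover all labels present in the records",
              "cciverse_parse_error")
    }
  }

  structure(
    list(records = records, clusters = clusters, source_tool = source_tool,
         provenance = provenance, standardized = standardized,
         has_pvalue = has_pvalue),
    class = "cci_table")
}

#' @export
print.cci_table <- function(x, ...) {
  cat(sprintf("CCI table (%s%s): %d records, %d interaction pairs, %d clusters\n",
              x$source_tool, if (x$standardized) ", standardized" else ", raw",
              nrow(x$records), length(unique(x$records$int_pair)),
              length(x$clusters)))
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance) cat("  - ", p, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cci_table <- function(object, ...) {
  r <- object$records
  auto <- sum(r$clust_a == r$clust_b)
  cat(sprintf("%d records (%d autocrine, %d paracrine) across %d clusters\n",
              nrow(r), auto, nrow(r) - auto, length(object$clusters)))
  if (nrow(r)) {
    cat(sprintf("score range: [%g, %g]; p-values: %s\n",
                min(r$score), max(r$score),
                if (object$has_pvalue) "present" else "absent"))
    flows <- table(paste(r$type_a, r$type_b, sep = "-"))
    cat("flow classes: ", paste(names(flows), flows, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Read a CCI table in the custom schema
#'
#' Parses a tab- or comma-separated table with mandatory columns
#' \code{int_pair} (canonical id \code{compA_compB}; \code{"+"} joins subunits
#' of a complex), \code{clustA}, \code{clustB}, \code{typeA}, \code{typeB}
#' (\code{L}/\code{R}, may be empty), \code{score}, and an optional
#' \code{p_value} column. Standardization is \emph{not} applied; see
#' [standardize_cci()].
#'
#' @param path Path to the file. Separator is inferred from the extension
#'   (\code{.csv} is comma-separated, anything else tab-separated) unless
#'   \code{sep} is given.
#' @param sep Optional field separator override.
#' @return A raw [cci_table()].
#' @export
read_cci_table <- function(path, sep = NULL) {
  if (!file.exists(path)) cc_stop(paste0("no such file: ", path), "cciverse_io_error")
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  mandatory <- c("int_pair", "clustA", "clustB", "typeA", "typeB", "score")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    cc_stop(paste0("custom CCI schema is missing mandatory column(s): ",
                   paste(miss, collapse = ", ")), "cciverse_schema_error")
  }
  if (!nrow(df)) cc_stop("CCI table contains no records", "cciverse_empty_error")

  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) & !is.na(df$score) & nzchar(df$score))
  if (length(bad)) {
    cc_stop(sprintf("non-numeric score value(s) at row(s): %s",
                    paste(bad, collapse = ", ")), "cciverse_parse_error")
  }
  has_pvalue <- "p_value" %in% names(df)
  p_value <- if (has_pvalue) {
    pv <- suppressWarnings(as.numeric(df$p_value))
    badp <- which(is.na(pv) & !is.na(df$p_value) & nzchar(df$p_value) & df$p_value != "NA")
    if (length(badp)) {
      cc_stop(sprintf("non-numeric p_value at row(s): %s", paste(badp, collapse = ", ")),
              "cciverse_parse_error")
    }
    pv
  } else {
    rep(NA_real_, nrow(df))
  }

  comps <- split_pair_id(df$int_pair)
  validate_complexes(comps$comp_a, "component A")
  validate_complexes(comps$comp_b, "component B")
  norm_type <- function(x) {
    x <- toupper(trimws(x))
    x[!nzchar(x) | x == "NA"] <- NA_character_
    if (!all(x %in% c("L", "R", NA_character_))) {
      cc_stop("typeA/typeB values must be 'L' or 'R' (or empty)", "cciverse_parse_error")
    }
    x
  }
  records <- data.frame(
    int_pair = df$int_pair,
    comp_a = comps$comp_a, comp_b = comps$comp_b,
    genes_a = comps$comp_a, genes_b = comps$comp_b,
    clust_a = df$clustA, clust_b = df$clustB,
    type_a = norm_type(df$typeA), type_b = norm_type(df$typeB),
    score = score, p_value = p_value,
    stringsAsFactors = FALSE)

  cci_table(records, source_tool = "custom",
            provenance = paste0("read_cci_table(", basename(path), ")"),
            has_pvalue = has_pvalue)
}

#' Write a CCI table in the custom schema
#'
#' Inverse of [read_cci_table()]: writes the tab-separated custom schema
#' (columns \code{int_pair}, \code{clustA}, \code{clustB}, \code{typeA},
#' \code{typeB}, \code{score} and, when present in the table, \code{p_value}).
#'
#' @param cci A [cci_table()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cci_table <- function(cci, path) {
  stopifnot(inherits(cci, "cci_table"))
  r <- cci$records
  out <- data.frame(int_pair = r$int_pair, clustA = r$clust_a, clustB = r$clust_b,
                    typeA = r$type_a, typeB = r$type_b, score = r$score,
                    stringsAsFactors = FALSE)
  if (cci$has_pvalue) out$p_value <- r$p_value
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CellPhoneDB v2 output
#'
#' Melts the wide CellPhoneDB v2 \code{means} and \code{pvalues} tables (rows =
#' interacting pairs, columns = \code{"A|B"} cluster-pair combinations) into a
#' long [cci_table()]. One record is produced per finite mean cell; the score
#' is the CellPhoneDB mean (the average expression of the interacting genes)
#' and the p-value comes from the matching cell of the p-values table. Partner
#' typing is taken from the \code{receptor_a}/\code{receptor_b} flags; missing
#' flags are left \code{NA} for [standardize_cci()] to fill from a curated
#' typing table. No filtering is applied (a mean with p-value 1 is kept).
#'
#' @param dir Directory containing \code{means.txt} and \code{pvalues.txt}
#'   (\code{.tsv} also accepted).
#' @return A raw [cci_table()] with \code{source_tool = "cellphonedb_v2"}.
#' @export
read_cellphonedb <- function(dir) {
  find1 <- function(stems) {
    for (s in stems) for (ext in c(".txt", ".tsv")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    cc_stop(sprintf("CellPhoneDB v2 file not found in '%s' (expected one of: %s)",
                    dir, paste0(stems, ".txt", collapse = ", ")), "cciverse_io_error")
  }
  means_path <- find1("means")
  pvals_path <- find1("pvalues")
  rd <- function(p) utils::read.table(p, header = TRUE, sep = "\t", quote = "",
                                      stringsAsFactors = FALSE, check.names = FALSE,
                                      comment.char = "")
  means <- rd(means_path)
  pvals <- rd(pvals_path)

  meta_cols <- c("id_cp_interaction", "interacting_pair", "partner_a", "partner_b",
                 "gene_a", "gene_b", "secreted", "receptor_a", "receptor_b",
                 "annotation_strategy", "is_integrin")
  need <- c("id_cp_interaction", "interacting_pair", "partner_a", "partner_b",
            "gene_a", "gene_b", "receptor_a", "receptor_b")
  cp_cols <- function(df) setdiff(names(df), meta_cols)
  if (!all(need %in% names(means)) || !length(grep("\\|", cp_cols(means)))) {
    cc_stop(paste0("unrecognized CellPhoneDB dialect; expected metadata headers [",
                   paste(need, collapse = ", "),
                   "] plus 'A|B' cluster-pair columns"), "cciverse_dialect_error")
  }
  cpairs <- cp_cols(means)
  if (!all(grepl("\\|", cpairs))) {
    cc_stop("unrecognized CellPhoneDB dialect: non-'A|B' data column present",
            "cciverse_dialect_error")
  }
  if (!identical(sort(cpairs), sort(cp_cols(pvals))) ||
      nrow(means) != nrow(pvals) ||
      !identical(means$id_cp_interaction, pvals$id_cp_interaction)) {
    cc_stop("means and pvalues tables disagree in shape or interaction ids",
            "cciverse_consistency_error")
  }
  pvals <- pvals[, c("id_cp_interaction", cpairs)]

  # Component string: the gene symbol for simple partners, the complex name
  # for "complex:" partners. "_" is reserved in canonical ids, so any "_" in
  # a complex name is mapped to "-"; gene membership of complexes is supplied
  # later through the gene_map argument of standardize_cci().
  comp_of <- function(gene, partner) {
    cx <- sub("^complex:", "", partner)
    cx <- gsub("_", "-", cx, fixed = TRUE)
    ifelse(!is.na(gene) & nzchar(gene), gene, cx)
  }
  comp_a <- comp_of(means$gene_a, means$partner_a)
  comp_b <- comp_of(means$gene_b, means$partner_b)
  flag <- function(x) {
    x <- toupper(as.character(x))
    ifelse(is.na(x) | !nzchar(x), NA, x %in% c("TRUE", "T", "1"))
  }
  ra <- flag(means$receptor_a)
  rb <- flag(means$receptor_b)
  type_a <- ifelse(is.na(ra), NA_character_, ifelse(ra, "R", "L"))
  type_b <- ifelse(is.na(rb), NA_character_, ifelse(rb, "R", "L"))

  recs <- vector("list", length(cpairs))
  for (j in seq_along(cpairs)) {
    cp <- cpairs[j]
    m <- suppressWarnings(as.numeric(means[[cp]]))
    keep <- is.finite(m)
    if (!any(keep)) next
    cl <- strsplit(cp, "|", fixed = TRUE)[[1]]
    if (length(cl) != 2L) {
      cc_stop(sprintf("cluster-pair column '%s' is not of the form 'A|B'", cp),
              "cciverse_dialect_error")
    }
    recs[[j]] <- data.frame(
      int_pair = pair_id(comp_a[keep], comp_b[keep]),
      comp_a = comp_a[keep], comp_b = comp_b[keep],
      genes_a = comp_a[keep], genes_b = comp_b[keep],
      clust_a = cl[1], clust_b = cl[2],
      type_a = type_a[keep], type_b = type_b[keep],
      score = m[keep],
      p_value = suppressWarnings(as.numeric(pvals[[cp]]))[keep],
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(records)) cc_stop("CellPhoneDB tables contain no finite mean cells",
                                "cciverse_empty_error")
  cci_table(records, source_tool = "cellphonedb_v2",
            provenance = paste0("read_cellphonedb(", basename(dir), ")"),
            has_pvalue = TRUE)
}

#' Read a curated ligand/receptor typing table
#'
#' Two-column tab-separated table mapping component strings to molecular type
#' (\code{L} or \code{R}); used by [standardize_cci()] to fill types the
#' prediction tool did not provide. The package ships a small synthetic
#' example under \code{inst/extdata/synthetic_curated_typing.tsv}.
#'
#' @param path Path to the TSV (headers \code{component}, \code{type}).
#' @return Data frame with columns \code{component}, \code{type}.
#' @export
read_typing_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("component", "type") %in% names(df))) {
    cc_stop("typing table must have columns 'component' and 'type'",
            "cciverse_schema_error")
  }
  df$type <- toupper(trimws(df$type))
  if (!all(df$type %in% c("L", "R"))) {
    cc_stop("typing table 'type' values must be 'L' or 'R'", "cciverse_schema_error")
  }
  df
}

#' Standardize a CCI table
#'
#' Applies the three preprocessing steps that turn raw tool output into the
#' standardized model consumed by every downstream analysis: (1) map
#' components to gene symbols via \code{gene_map}; (2) fill missing molecular
#' types from the curated \code{typing} table (a type already provided by the
#' input wins over a contradictory curated one, with a warning); (3) reorder
#' receptor-ligand records to ligand-receptor, exchanging components, clusters
#' and types together so the communication flow is preserved. Ligand-ligand
#' and receptor-receptor records are left as they are. Components typed by
#' neither source get type \code{"unknown"} (with a warning) and are excluded
#' from flow-directed analyses.
#'
#' @param cci A [cci_table()].
#' @param typing Curated typing table (data frame with \code{component},
#'   \code{type}, or a path readable by [read_typing_table()]); may be
#'   \code{NULL}.
#' @param gene_map Optional data frame with columns \code{component},
#'   \code{genes} (\code{"+"}-joined gene symbols) overriding the gene
#'   membership of named components (used for, e.g., CellPhoneDB complexes).
#' @return The standardized [cci_table()]. Idempotent.
#' @export
standardize_cci <- function(cci, typing = NULL, gene_map = NULL) {
  stopifnot(inherits(cci, "cci_table"))
  r <- cci$records
  if (is.character(typing)) typing <- read_typing_table(typing)

  if (!is.null(gene_map)) {
    if (!all(c("component", "genes") %in% names(gene_map))) {
      cc_stop("gene_map must have columns 'component' and 'genes'", "cciverse_schema_error")
    }
    ia <- match(r$comp_a, gene_map$component)
    ib <- match(r$comp_b, gene_map$component)
    r$genes_a[!is.na(ia)] <- gene_map$genes[ia[!is.na(ia)]]
    r$genes_b[!is.na(ib)] <- gene_map$genes[ib[!is.na(ib)]]
    validate_complexes(r$genes_a[!is.na(ia)], "mapped gene set")
    validate_complexes(r$genes_b[!is.na(ib)], "mapped gene set")
  }

  fill_side <- function(type, comp) {
    if (is.null(typing)) return(type)
    cur <- typing$type[match(comp, typing$component)]
    clash <- !is.na(type) & type %in% c("L", "R") & !is.na(cur) & cur != type
    if (any(clash)) {
      cc_warn(sprintf(
        "curated typing contradicts input typing for component(s) %s; keeping the input type",
        paste(unique(comp[clash]), collapse = ", ")), "cciverse_typing_warning")
    }
    ifelse(is.na(type), cur, type)
  }
  r$type_a <- fill_side(r$type_a, r$comp_a)
  r$type_b <- fill_side(r$type_b, r$comp_b)
  gap <- is.na(r$type_a) | is.na(r$type_b)
  if (any(gap)) {
    untyped <- unique(c(r$comp_a[is.na(r$type_a)], r$comp_b[is.na(r$type_b)]))
    cc_warn(sprintf(
      "no molecular type for component(s) %s; records kept with type 'unknown' and excluded from flow-directed analyses",
      paste(untyped, collapse = ", ")), "cciverse_typing_warning")
    r$type_a[is.na(r$type_a)] <- "unknown"
    r$type_b[is.na(r$type_b)] <- "unknown"
  }

  swap <- r$type_a == "R" & r$type_b == "L"
  if (any(swap)) {
    s <- r[swap, ]
    r[swap, c("comp_a", "comp_b")] <- s[, c("comp_b", "comp_a")]
    r[swap, c("genes_a", "genes_b")] <- s[, c("genes_b", "genes_a")]
    r[swap, c("clust_a", "clust_b")] <- s[, c("clust_b", "clust_a")]
    r[swap, c("type_a", "type_b")] <- list("L", "R")
    r$int_pair[swap] <- pair_id(r$comp_a[swap], r$comp_b[swap])
  }

  cci_table(r, clusters = cci$clusters, source_tool = cci$source_tool,
            provenance = c(cci$provenance, "standardize_cci"),
            standardized = TRUE, has_pvalue = cci$has_pvalue)
}

#' Filter a CCI table
#'
#' Subsets the table by cluster membership, minimum interaction score and
#' maximum p-value; the subset (with its recorded provenance) propagates to
#' all downstream analyses. A p-value filter on a table that has no p-value
#' column is a no-op; on a table that has one, records with a missing p-value
#' fail the filter.
#'
#' @param cci A [cci_table()].
#' @param keep_clusters Clusters to retain (both sides of a record must be in
#'   the set), or \code{NULL} for all.
#' @param min_score Minimum score (inclusive), or \code{NULL}.
#' @param max_pval Maximum p-value (inclusive), or \code{NULL}.
#' @return The filtered [cci_table()]; an empty result warns but is returned.
#' @export
filter_cci <- function(cci, keep_clusters = NULL, min_score = NULL, max_pval = NULL) {
  stopifnot(inherits(cci, "cci_table"))
  r <- cci$records
  keep <- rep(TRUE, nrow(r))
  prov <- character()
  clusters <- cci$clusters

  if (!is.null(keep_clusters)) {
    unknown <- setdiff(keep_clusters, cci$clusters)
    if (length(unknown)) {
      cc_stop(paste0("unknown cluster(s): ", paste(unknown, collapse = ", ")),
              "cciverse_cluster_error")
    }
    keep <- keep & r$clust_a %in% keep_clusters & r$clust_b %in% keep_clusters
    clusters <- intersect(clusters, keep_clusters)
    prov <- c(prov, paste0("keep_clusters={", paste(keep_clusters, collapse = ","), "}"))
  }
  if (!is.null(min_score)) {
    stopifnot(is.finite(min_score))
    keep <- keep & r$score >= min_score
    prov <- c(prov, paste0("min_score=", min_score))
  }
  if (!is.null(max_pval) && cci$has_pvalue) {
    stopifnot(is.finite(max_pval))
    keep <- keep & !is.na(r$p_value) & r$p_value <= max_pval
    prov <- c(prov, paste0("max_pval=", max_pval))
  }
  out <- r[keep, , drop = FALSE]
  if (!nrow(out)) cc_warn("filter removed every record", "cciverse_empty_warning")
  cci_table(out, clusters = clusters, source_tool = cci$source_tool,
            provenance = c(cci$provenance, paste0("filter_cci(", paste(prov, collapse = "; "), ")")),
            standardized = cci$standardized, has_pvalue = cci$has_pvalue)
}
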