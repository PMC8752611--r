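# Function-verse: annotate interaction pairs with functional terms from
# gene-set collections (GMT files), rank terms, and build sunburst data.
#
# The annotation rule: a term annotates an interaction pair only when ALL
# gene symbols of ALL components (every subunit of a multi-subunit complex)
# belong to the term's gene set.

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: one gene set per line as
#' \code{term<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path Path to the GMT file.
#' @param source Source label for the collection (e.g. a database name);
#'   defaults to the file name without extension.
#' @return A \code{gene_set_collection}: list with \code{source} and
#'   \code{terms} (named list of character gene vectors).
#' @export
read_gmt <- function(path, source = NULL) {
  if (!file.exists(path)) cc_stop(paste0("no such file: ", path), "cciverse_io_error")
  source <- source %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    cc_stop(sprintf("GMT line(s) %s have fewer than 3 fields",
                    paste(which(short), collapse = ", ")), "cciverse_parse_error")
  }
  terms <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(terms) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(terms))) {
    cc_stop("duplicate term names within one GMT source", "cciverse_parse_error")
  }
  if (any(vapply(terms, length, 1L) == 0L)) {
    cc_stop("GMT contains an empty gene set", "cciverse_parse_error")
  }
  gene_set_collection(terms, source)
}

#' Construct a gene-set collection
#'
#' @param terms Named list mapping term names to character vectors of gene
#'   symbols (non-empty, unique names).
#' @param source Source label.
#' @return A \code{gene_set_collection}.
#' @export
gene_set_collection <- function(terms, source) {
  stopifnot(is.list(terms), length(names(terms)) == length(terms))
  if (anyDuplicated(names(terms))) {
    cc_stop("term names must be unique within a source", "cciverse_parse_error")
  }
  if (any(vapply(terms, length, 1L) == 0L)) {
    cc_stop("gene sets must be non-empty", "cciverse_parse_error")
  }
  structure(list(source = source, terms = terms), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d terms, %d distinct genes\n",
              x$source, length(x$terms), length(unique(unlist(x$terms)))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$terms), function(i) {
    paste(c(names(collection$terms)[i], collection$source, collection$terms[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Gene lists per pair from a cci_table or a unique_int_pairs()-style frame;
# matching is case-insensitive (both sides upper-cased).
pair_gene_lists <- function(x) {
  u <- if (inherits(x, "cci_table")) unique_int_pairs(x) else x
  stopifnot(all(c("int_pair", "genes_a", "genes_b") %in% names(u)))
  genes <- Map(function(a, b) toupper(c(a, b)), split_genes(u$genes_a), split_genes(u$genes_b))
  names(genes) <- u$int_pair
  genes
}

#' Annotate interaction pairs with functional terms
#'
#' Builds the binary interaction-pairs-by-terms matrix: the entry for
#' (pair, term) is 1 exactly when every gene of every component of the pair
#' (including all subunits of a complex) is contained in the term's gene set.
#' Identically named terms (case-insensitive) from different sources are
#' merged into one column whose sources are concatenated; a pair is annotated
#' by the merged column when any of the sources' gene sets annotates it.
#' Terms annotating no pair are dropped. Gene matching is case-insensitive.
#'
#' @param x A standardized [cci_table()] or a data frame with columns
#'   \code{int_pair}, \code{genes_a}, \code{genes_b}.
#' @param collections A \code{gene_set_collection} or list of them.
#' @return A \code{cci_annotation}: list with \code{matrix} (binary, rows =
#'   interaction pairs, columns = terms) and \code{term_info} (data frame
#'   \code{term}, \code{sources}, \code{n_int_pairs}).
#' @export
annotate_int_pairs <- function(x, collections) {
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  if (!length(collections) ||
      !all(vapply(collections, inherits, TRUE, "gene_set_collection"))) {
    cc_stop("'collections' must be one or more gene_set_collection objects",
            "cciverse_config_error")
  }
  genes <- pair_gene_lists(x)
  n <- length(genes)
  if (!n) cc_stop("no interaction pairs to annotate", "cciverse_empty_error")

  cols <- list()     # canonical (lower-case) term name -> 0/1 vector
  display <- list()  # canonical -> first-seen spelling
  sources <- list()  # canonical -> character vector of sources
  for (coll in collections) {
    for (i in seq_along(coll$terms)) {
      tname <- names(coll$terms)[i]
      tset <- toupper(coll$terms[[i]])
      hit <- vapply(genes, function(g) all(g %in% tset), TRUE)
      key <- tolower(tname)
      if (is.null(cols[[key]])) {
        cols[[key]] <- as.integer(hit)
        display[[key]] <- tname
        sources[[key]] <- coll$source
      } else {
        cols[[key]] <- pmax(cols[[key]], as.integer(hit))
        sources[[key]] <- union(sources[[key]], coll$source)
      }
    }
  }
  keep <- vapply(cols, sum, 0) > 0
  cols <- cols[keep]
  if (!length(cols)) {
    mat <- matrix(0L, nrow = n, ncol = 0, dimnames = list(names(genes), NULL))
    return(structure(list(matrix = mat,
                          term_info = data.frame(term = character(0),
                                                 sources = character(0),
                                                 n_int_pairs = integer(0))),
                     class = "cci_annotation"))
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- names(genes)
  colnames(mat) <- unlist(display[names(cols)])
  info <- data.frame(
    term = colnames(mat),
    sources = vapply(sources[names(cols)], paste, "", collapse = ","),
    n_int_pairs = as.integer(colSums(mat)),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  structure(list(matrix = mat, term_info = info), class = "cci_annotation")
}

#' @export
print.cci_annotation <- function(x, ...) {
  m <- x$matrix
  cat(sprintf("Annotation matrix: %d interaction pairs x %d terms (%d pairs annotated by >=1 term)\n",
              nrow(m), ncol(m), sum(rowSums(m) > 0)))
  invisible(x)
}

#' Extract (a subset of) the binary annotation matrix
#'
#' @param ann A \code{cci_annotation}.
#' @param pairs Optional interaction-pair ids to restrict the rows to (order
#'   preserved); ids absent from the matrix are an error.
#' @param drop_unannotated Drop rows with no annotation after subsetting.
#' @return Binary integer matrix.
#' @export
annotation_matrix <- function(ann, pairs = NULL, drop_unannotated = FALSE) {
  stopifnot(inherits(ann, "cci_annotation"))
  m <- ann$matrix
  if (!is.null(pairs)) {
    missing <- setdiff(pairs, rownames(m))
    if (length(missing)) {
      cc_stop(paste0("interaction pair(s) absent from annotation: ",
                     paste(missing, collapse = ", ")), "cciverse_config_error")
    }
    m <- m[pairs, , drop = FALSE]
  }
  if (drop_unannotated && nrow(m)) m <- m[rowSums(m) > 0, , drop = FALSE]
  m
}

#' Rank functional terms by number of annotated interaction pairs
#'
#' @param ann A \code{cci_annotation}.
#' @return \code{term_info} sorted by descending \code{n_int_pairs}, ties
#'   broken alphabetically by term.
#' @export
rank_terms <- function(ann) {
  stopifnot(inherits(ann, "cci_annotation"))
  info <- ann$term_info
  info <- info[order(-info$n_int_pairs, info$term), , drop = FALSE]
  rownames(info) <- NULL
  info
}

#' Sunburst data for one functional term
#'
#' Considers every couplet whose interaction pair is annotated to the term
#' (optionally intersected with \code{restrict_pairs}, as used for
#' condition-specific pairs). The inner ring groups couplets by the cluster
#' expressing the first component (\code{clust_a}); the outer ring nests the
#' cluster expressing the second component (\code{clust_b}) under its inner
#' section. Section values are couplet counts (total mode) or summed scores
#' (weighted mode); widths are normalized within each ring and sections are
#' arranged in descending value order (ties alphabetical).
#'
#' @param cci A standardized [cci_table()].
#' @param term Term name (as displayed in the annotation).
#' @param ann The \code{cci_annotation} for the table's pairs.
#' @param weighted Use summed scores instead of couplet counts.
#' @param restrict_pairs Optional set of interaction-pair ids to intersect
#'   with the annotated set.
#' @return A \code{cci_sunburst}: list with \code{term}, \code{weighted},
#'   \code{total}, \code{inner} (data frame \code{clust_a}, \code{value},
#'   \code{width}) and \code{outer} (data frame \code{clust_a},
#'   \code{clust_b}, \code{value}, \code{width}, \code{int_pairs}).
#' @export
sunburst_data <- function(cci, term, ann, weighted = FALSE, restrict_pairs = NULL) {
  stopifnot(inherits(cci, "cci_table"), inherits(ann, "cci_annotation"))
  m <- ann$matrix
  ti <- match(tolower(term), tolower(colnames(m)))
  if (is.na(ti)) cc_stop(paste0("term not present in annotation: ", term),
                         "cciverse_config_error")
  pairs <- rownames(m)[m[, ti] == 1]
  if (!is.null(restrict_pairs)) pairs <- intersect(pairs, restrict_pairs)
  r <- cci$records[cci$records$int_pair %in% pairs, , drop = FALSE]
  empty <- structure(list(term = term, weighted = weighted, total = 0,
                          inner = data.frame(clust_a = character(0), value = numeric(0),
                                             width = numeric(0)),
                          outer = data.frame(clust_a = character(0), clust_b = character(0),
                                             value = numeric(0), width = numeric(0),
                                             int_pairs = character(0))),
                     class = "cci_sunburst")
  if (!nrow(r)) {
    cc_warn(paste0("term '", term, "' annotates no couplet in this table"),
            "cciverse_empty_warning")
    return(empty)
  }
  w <- if (weighted) r$score else rep(1, nrow(r))

  inner_val <- tapply(w, r$clust_a, sum)
  inner <- data.frame(clust_a = names(inner_val), value = as.vector(inner_val),
                      stringsAsFactors = FALSE)
  inner <- inner[order(-inner$value, inner$clust_a), , drop = FALSE]
  inner$width <- inner$value / sum(inner$value)

  key <- paste(r$clust_a, r$clust_b, sep = "\r")
  outer_val <- tapply(w, key, sum)
  ab <- do.call(rbind, strsplit(names(outer_val), "\r", fixed = TRUE))
  pairs_by_key <- tapply(r$int_pair, key, function(p) paste(sort(unique(p)), collapse = ","))
  outer <- data.frame(clust_a = ab[, 1], clust_b = ab[, 2],
                      value = as.vector(outer_val),
                      int_pairs = as.vector(pairs_by_key[names(outer_val)]),
                      stringsAsFactors = FALSE)
  # nest outer sections under the inner ordering, descending within a section
  outer <- outer[order(match(outer$clust_a, inner$clust_a), -outer$value, outer$clust_b), ,
                 drop = FALSE]
  outer$width <- outer$value / sum(outer$value)
  rownames(inner) <- rownames(outer) <- NULL
  structure(list(term = term, weighted = weighted, total = sum(w),
                 inner = inner, outer = outer[, c("clust_a", "clust_b", "value",
                                                 "width", "int_pairs")]),
            class = "cci_sunburst")
}

#' @export
print.cci_sunburst <- function(x, ...) {
  cat(sprintf("Sunburst for term '%s' (%s): total %g\n", x$term,
              if (x$weighted) "weighted" else "total counts", x$total))
  for (i in seq_len(nrow(x$inner))) {
    cat(sprintf("  %s [%g]\n", x$inner$clust_a[i], x$inner$value[i]))
    o <- x$outer[x$outer$clust_a == x$inner$clust_a[i], , drop = FALSE]
    for (j in seq_len(nrow(o))) {
      cat(sprintf("    -> %s [%g] (%s)\n", o$clust_b[j], o$value[j], o$int_pairs[j]))
    }
  }
  invisible(x)
}

#' Export sunburst data as nested JSON
#'
#' @param sb A \code{cci_sunburst}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sunburst_json <- function(sb, path) {
  stopifnot(inherits(sb, "cci_sunburst"))
  children <- lapply(seq_len(nrow(sb$inner)), function(i) {
    ca <- sb$inner$clust_a[i]
    o <- sb$outer[sb$outer$clust_a == ca, , drop = FALSE]
    list(name = ca, value = sb$inner$value[i], width = sb$inner$width[i],
         children = lapply(seq_len(nrow(o)), function(j) {
           list(name = o$clust_b[j], value = o$value[j], width = o$width[j],
                int_pairs = strsplit(o$int_pairs[j], ",", fixed = TRUE)[[1]])
         }))
  })
  obj <- list(term = sb$term, weighted = sb$weighted, total = sb$total,
              inner = children)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export an annotation matrix as sparse triplets
#'
#' Writes one row per nonzero (interaction pair, term) entry, tab-separated.
#'
#' @param ann A \code{cci_annotation}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_triplets <- function(ann, path) {
  stopifnot(inherits(ann, "cci_annotation"))
  idx <- which(ann$matrix == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(int_pair = rownames(ann$matrix)[idx[, 1]],
                    term = colnames(ann$matrix)[idx[, 2]],
                    value = 1L, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
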