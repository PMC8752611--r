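# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish schema problems from data
# problems programmatically (the CLI maps them to exit codes).
cc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cciverse_error"), call = call))
}

cc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cciverse_warning")))
}

# Canonical id: components joined by "_", genes within a complex by "+".
# "_" is therefore reserved and may not appear inside a component name.
pair_id <- function(comp_a, comp_b) paste(comp_a, comp_b, sep = "_")

split_pair_id <- function(id) {
  parts <- strsplit(id, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    cc_stop(sprintf(
      "interaction-pair id must contain exactly one '_' separator; offending row(s): %s",
      paste(which(bad), collapse = ", ")), "cciverse_parse_error")
  }
  list(comp_a = vapply(parts, `[[`, "", 1L), comp_b = vapply(parts, `[[`, "", 2L))
}

split_genes <- function(comp) strsplit(comp, "+", fixed = TRUE)

# Display form: "BMP7 & (ACVR1+ACVR2A)" -- multi-subunit complexes are
# parenthesized, the two components joined with " & ".
complex_display <- function(comp) {
  multi <- grepl("+", comp, fixed = TRUE)
  ifelse(multi, paste0("(", comp, ")"), comp)
}

#' Display form of an interaction-pair id
#'
#' Converts canonical storage ids (\code{"BMP7_ACVR1+ACVR2A"}) to the display
#' notation \code{"BMP7 & (ACVR1+ACVR2A)"} used in figures and tables.
#'
#' @param id Character vector of canonical interaction-pair ids.
#' @return Character vector of display strings.
#' @export
pair_display <- function(id) {
  parts <- split_pair_id(id)
  paste(complex_display(parts$comp_a), complex_display(parts$comp_b), sep = " & ")
}

validate_complexes <- function(comp, what = "component") {
  genes <- split_genes(comp)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    if (length(g) < 1L || any(!nzchar(g))) {
      cc_stop(sprintf("%s '%s' (row %d) has an empty gene symbol", what, comp[i], i),
              "cciverse_parse_error")
    }
    if (anyDuplicated(g)) {
      cc_stop(sprintf("%s '%s' (row %d) repeats a gene within a complex", what, comp[i], i),
              "cciverse_parse_error")
    }
  }
  invisible(comp)
}

couplet_id <- function(int_pair, clust_a, clust_b) {
  paste(int_pair, clust_a, clust_b, sep = "\r")
}
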