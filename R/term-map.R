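#' Term namespaces understood by the pipeline
#' @keywords internal
.namespaces <- c("GO_BP", "GO_CC", "GO_MF", "KEGG_pathway", "EC", "keyword")

#' Construct a term map
#'
#' Many-to-many association between ESTs and functional terms (GO
#' categories, KEGG pathways, EC numbers or free-text keywords).
#' Duplicate pairs collapse to a single membership.
#'
#' @param term_id,est_id character vectors of equal length
#' @param namespace a single namespace, or a vector parallel to `term_id`;
#'   one of `r paste(.namespaces, collapse = ", ")`
#' @return data.frame of class `term_map` with columns `term_id`,
#'   `est_id`, `namespace`
#' @export
term_map <- function(term_id, est_id, namespace = "GO_BP") {
  stopifnot(length(term_id) == length(est_id))
  if (length(namespace) == 1) namespace <- rep(namespace, length(term_id))
  bad <- setdiff(unique(namespace), .namespaces)
  if (length(bad))
    stop("unknown namespace(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df <- unique(data.frame(term_id = as.character(term_id),
                          est_id = as.character(est_id),
                          namespace = as.character(namespace),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("term_map", "data.frame")
  df
}

# re-stamp the class after subsetting
restrict_term_map <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("term_map", "data.frame")
  df
}

#' Read a two-column EST-to-term mapping from TSV
#'
#' Columns `est_id` and `term_id` (header required); pairs are
#' deduplicated. A message reports how many terms and ESTs were mapped.
#'
#' @param path TSV path (`#` comment lines skipped)
#' @param namespace namespace assigned to every pair; a `namespace`
#'   column in the file takes precedence
#' @export
read_term_map <- function(path, namespace = "GO_BP") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("est_id", "term_id"))
    if (!col %in% names(raw))
      stop("mandatory column `", col, "` missing from ", path, call. = FALSE)
  if ("namespace" %in% names(raw)) namespace <- raw$namespace
  tm <- term_map(raw$term_id, raw$est_id, namespace)
  message(sprintf("read %d pairs: %d terms over %d ESTs [%s]",
                  nrow(tm), length(unique(tm$term_id)),
                  length(unique(tm$est_id)),
                  paste(unique(tm$namespace), collapse = ",")))
  tm
}

#' Write a term map as TSV
#' @param map a [term_map()]
#' @param path output path
#' @export
write_term_map <- function(map, path) {
  stopifnot(inherits(map, "term_map"))
  utils::write.table(map[, c("est_id", "term_id", "namespace")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Term membership as a named list of EST id sets
#' @param map a [term_map()]
#' @param universe optional character vector; memberships are intersected
#'   with it (term sizes are then sizes *within* the universe)
#' @export
term_sets <- function(map, universe = NULL) {
  stopifnot(inherits(map, "term_map"))
  if (!is.null(universe)) map <- map[map$est_id %in% universe, , drop = FALSE]
  split(map$est_id, map$term_id)
}

#' Per-term membership counts
#' @inheritParams term_sets
#' @export
term_sizes <- function(map, universe = NULL) {
  lengths(term_sets(map, universe))
}

#' Select ESTs whose description matches a keyword
#'
#' Case-insensitive substring match on the free-text `description` column,
#' e.g. `keyword_subset(tab, "dehydrogenase")` to pull all ESTs with
#' unspecific dehydrogenase annotations.
#'
#' @param table an [est_table()] with a `description` column
#' @param pattern regular expression matched against descriptions
#' @return character vector of matching est_ids
#' @export
keyword_subset <- function(table, pattern) {
  stopifnot(inherits(table, "est_table"))
  if (!"description" %in% names(table$ests))
    stop("table has no description column", call. = FALSE)
  d <- table$ests$description
  table$ests$est_id[!is.na(d) & grepl(pattern, d, ignore.case = TRUE)]
}
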