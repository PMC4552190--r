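#' Conditions recognised in a two-condition nitrogen-deprivation design
#' @keywords internal
.conditions <- c("N_replete", "N_depleted")

#' Construct an annotated EST expression table
#'
#' The central container of the pipeline: one row per assembled EST
#' (expressed sequence tag, i.e. a non-redundant transcript contig), with
#' its length, per-sample read counts and/or FPKM values, an optional
#' best-hit annotation, and an optional term map (GO / KEGG / EC
#' memberships).
#'
#' @param ests data.frame with columns `est_id` (unique character) and
#'   `length_bp` (positive integer); optional `best_hit_id` and
#'   `description` columns are carried through.
#' @param design data.frame with columns `sample_id`, `condition`
#'   (`"N_replete"` or `"N_depleted"`) and `replicate`.
#' @param counts optional numeric matrix (EST x sample) of non-negative
#'   read counts; columns must match `design$sample_id`.
#' @param fpkm optional numeric matrix (EST x sample) of non-negative,
#'   finite FPKM values, same samples as `counts` when both are present.
#' @param annotations optional [term_map()] restricted to these ESTs.
#'
#' @return An object of class `est_table`.
#' @seealso [read_est_table()], [apply_filter()], [add_fpkm()]
#' @export
est_table <- function(ests, design, counts = NULL, fpkm = NULL,
                      annotations = NULL) {
  stopifnot(is.data.frame(ests), is.data.frame(design))
  if (!all(c("est_id", "length_bp") %in% names(ests)))
    stop("`ests` needs columns est_id and length_bp", call. = FALSE)
  ests$est_id <- as.character(ests$est_id)
  if (anyDuplicated(ests$est_id))
    stop("est_ids must be unique", call. = FALSE)
  if (any(!is.finite(ests$length_bp)) || any(ests$length_bp < 1))
    stop("length_bp must be >= 1 for every EST", call. = FALSE)
  if (!all(c("sample_id", "condition", "replicate") %in% names(design)))
    stop("`design` needs columns sample_id, condition, replicate",
         call. = FALSE)
  bad <- setdiff(unique(design$condition), .conditions)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)

  fix_mat <- function(m, what, integerish = FALSE) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != nrow(ests))
      stop(what, " must have one row per EST", call. = FALSE)
    if (is.null(colnames(m)))
      stop(what, " must have sample_id column names", call. = FALSE)
    if (!all(colnames(m) %in% design$sample_id))
      stop(what, " columns must appear in the design", call. = FALSE)
    if (any(!is.finite(m)) || any(m < 0))
      stop(what, " values must be finite and non-negative", call. = FALSE)
    rownames(m) <- ests$est_id
    m
  }
  counts <- fix_mat(counts, "counts")
  fpkm <- fix_mat(fpkm, "fpkm")
  if (!is.null(counts) && !is.null(fpkm) &&
      !setequal(colnames(counts), colnames(fpkm)))
    stop("counts and fpkm must share the same samples", call. = FALSE)

  if (!is.null(annotations)) {
    stopifnot(inherits(annotations, "term_map"))
    missing_ids <- setdiff(annotations$est_id, ests$est_id)
    if (length(missing_ids))
      stop("annotations refer to ", length(missing_ids),
           " est_id(s) absent from the table; use set_annotations() to ",
           "attach a map with unmatched ids", call. = FALSE)
  }

  structure(
    list(ests = ests, design = design, counts = counts, fpkm = fpkm,
         annotations = annotations),
    class = "est_table")
}

#' @export
print.est_table <- function(x, ...) {
  cat(sprintf("est_table: %d ESTs, %d sample(s) [%s]\n",
              nrow(x$ests), nrow(x$design),
              paste(table(x$design$condition), names(table(x$design$condition)),
                    collapse = ", ")))
  cat(sprintf("  counts: %s; fpkm: %s; annotations: %s\n",
              if (is.null(x$counts)) "absent" else "present",
              if (is.null(x$fpkm)) "absent" else "present",
              if (is.null(x$annotations)) "absent" else
                sprintf("%d terms", length(unique(x$annotations$term_id)))))
  invisible(x)
}

#' Number of ESTs in a table
#' @param x an `est_table`
#' @export
n_ests <- function(x) nrow(x$ests)

#' Attach a term map to an EST table
#'
#' Pairs referring to ESTs absent from the table are tolerated (annotation
#' files typically cover the pre-filter assembly) but dropped with a
#' message.
#'
#' @param table an [est_table()]
#' @param map a [term_map()]
#' @return the table with `annotations` set
#' @export
set_annotations <- function(table, map) {
  stopifnot(inherits(table, "est_table"), inherits(map, "term_map"))
  keep <- map$est_id %in% table$ests$est_id
  if (!all(keep))
    message(sum(!keep), " annotation pair(s) refer to ESTs absent from the ",
            "table and were dropped")
  table$annotations <- restrict_term_map(map[keep, , drop = FALSE])
  table
}

# infer condition/replicate from conventional sample ids (NR_1, ND_2, ...)
.infer_design <- function(sample_ids) {
  m <- regmatches(sample_ids, regexec("^(NR|ND)_?([0-9]+)$", sample_ids))
  ok <- lengths(m) == 3
  if (!all(ok))
    stop("cannot infer conditions from sample name(s): ",
         paste(sample_ids[!ok], collapse = ", "),
         "; supply an explicit `design`", call. = FALSE)
  data.frame(
    sample_id = sample_ids,
    condition = ifelse(vapply(m, `[`, "", 2) == "NR", "N_replete",
                       "N_depleted"),
    replicate = as.integer(vapply(m, `[`, "", 3)),
    stringsAsFactors = FALSE)
}

#' Read an annotated EST expression table from TSV
#'
#' Expected columns: `est_id`, `length_bp`, one or more `count_<sample>`
#' columns, optional `fpkm_<sample>` columns, optional `best_hit_id` and
#' `description`. Lines starting with `#` are skipped. Sample conditions
#' are inferred from the conventional ids `NR_<rep>` / `ND_<rep>`
#' (nitrogen-replete / -depleted) unless `design` is given.
#'
#' @param path TSV file path
#' @param design optional data.frame (`sample_id`, `condition`,
#'   `replicate`) overriding name-based inference
#' @return an [est_table()]; row order of the file is preserved
#' @export
read_est_table <- function(path, design = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("est_id", "length_bp"))
    if (!col %in% names(raw))
      stop("mandatory column `", col, "` missing from ", path, call. = FALSE)
  count_cols <- grep("^count_", names(raw), value = TRUE)
  fpkm_cols <- grep("^fpkm_", names(raw), value = TRUE)
  if (!length(count_cols) && !length(fpkm_cols))
    stop("no count_<sample> or fpkm_<sample> columns in ", path,
         call. = FALSE)

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s in column `%s`, line %d of %s",
                   what, col, bad[1] + 1L, path), call. = FALSE)
    v
  }
  length_bp <- num("length_bp", "length")
  bad_len <- which(!(length_bp >= 1))
  if (length(bad_len))
    stop(sprintf("invalid length_bp (%s) at line %d of %s",
                 raw$length_bp[bad_len[1]], bad_len[1] + 1L, path),
         call. = FALSE)

  grab <- function(cols, what) {
    if (!length(cols)) return(NULL)
    vals <- lapply(cols, num, what = what)
    matrix(unlist(vals), nrow = nrow(raw), ncol = length(cols),
           dimnames = list(NULL, sub(paste0("^", what, "_"), "", cols)))
  }
  counts <- grab(count_cols, "count")
  fpkm <- grab(fpkm_cols, "fpkm")
  samples <- colnames(if (!is.null(counts)) counts else fpkm)
  if (is.null(design)) design <- .infer_design(samples)

  keep <- c("est_id", intersect(c("best_hit_id", "description"), names(raw)))
  ests <- raw[, keep, drop = FALSE]
  ests$length_bp <- length_bp
  est_table(ests, design, counts = counts, fpkm = fpkm)
}

#' Write an EST table as TSV
#'
#' Inverse of [read_est_table()]: numeric values are written at full
#' precision so a read/write cycle round-trips exactly.
#'
#' @param table an [est_table()]
#' @param path output path
#' @export
write_est_table <- function(table, path) {
  stopifnot(inherits(table, "est_table"))
  out <- data.frame(est_id = table$ests$est_id,
                    length_bp = table$ests$length_bp,
                    stringsAsFactors = FALSE)
  add_mat <- function(out, m, prefix) {
    if (is.null(m)) return(out)
    for (s in colnames(m))
      out[[paste0(prefix, "_", s)]] <- sprintf("%.17g", m[, s])
    out
  }
  out <- add_mat(out, table$counts, "count")
  out <- add_mat(out, table$fpkm, "fpkm")
  for (col in intersect(c("best_hit_id", "description"), names(table$ests)))
    out[[col]] <- table$ests[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' EST retention policy
#'
#' Assembly-level quality thresholds applied before any functional
#' analysis: keep ESTs strictly longer than `min_length_bp`, with summed
#' read count across all samples strictly above `min_total_count`, and
#' (optionally) with no zero FPKM in any sample. The strict inequalities
#' mean an EST of exactly 300 bp or exactly 40 summed counts is removed.
#'
#' @param min_length_bp exclusive length threshold in base pairs
#' @param min_total_count exclusive threshold on the summed read count
#' @param drop_any_zero_fpkm drop ESTs with a zero FPKM in any sample
#' @export
filter_policy <- function(min_length_bp = 300, min_total_count = 40,
                          drop_any_zero_fpkm = TRUE) {
  if (min_length_bp < 0 || min_total_count < 0)
    stop("filter thresholds must be non-negative", call. = FALSE)
  structure(list(min_length_bp = min_length_bp,
                 min_total_count = min_total_count,
                 drop_any_zero_fpkm = isTRUE(drop_any_zero_fpkm)),
            class = "filter_policy")
}

#' Filter an EST table
#'
#' @param table an [est_table()]
#' @param policy a [filter_policy()]
#' @return list with `table` (the retained ESTs, annotations restricted
#'   accordingly) and `report`, a data.frame of ESTs failing each rule
#'   (an EST may fail several) plus the overall numbers kept/removed.
#'   Filtering is idempotent: re-filtering the result removes nothing.
#' @export
apply_filter <- function(table, policy = filter_policy()) {
  stopifnot(inherits(table, "est_table"), inherits(policy, "filter_policy"))
  n <- n_ests(table)
  fail_len <- !(table$ests$length_bp > policy$min_length_bp)
  if (is.null(table$counts)) {
    if (policy$min_total_count > 0)
      stop("count-based filtering requires counts", call. = FALSE)
    fail_cnt <- rep(FALSE, n)
  } else {
    fail_cnt <- !(rowSums(table$counts) > policy$min_total_count)
  }
  if (policy$drop_any_zero_fpkm) {
    if (is.null(table$fpkm))
      stop("drop_any_zero_fpkm requires fpkm values", call. = FALSE)
    fail_zero <- apply(table$fpkm == 0, 1, any)
  } else fail_zero <- rep(FALSE, n)

  keep <- !(fail_len | fail_cnt | fail_zero)
  out <- table
  out$ests <- table$ests[keep, , drop = FALSE]
  rownames(out$ests) <- NULL
  if (!is.null(out$counts)) out$counts <- out$counts[keep, , drop = FALSE]
  if (!is.null(out$fpkm)) out$fpkm <- out$fpkm[keep, , drop = FALSE]
  if (!is.null(out$annotations)) {
    ann_keep <- out$annotations$est_id %in% out$ests$est_id
    out$annotations <- restrict_term_map(
      out$annotations[ann_keep, , drop = FALSE])
  }
  report <- data.frame(
    rule = c("length", "total_count", "zero_fpkm"),
    removed = c(sum(fail_len), sum(fail_cnt), sum(fail_zero)))
  attr(report, "n_input") <- n
  attr(report, "n_kept") <- sum(keep)
  list(table = out, report = report)
}

#' Read a tabular homology hit file
#'
#' Parses the standard 12-column tabular layout of sequence-similarity
#' searches (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query/subject start/end, e-value, bit score).
#' Extra columns are ignored; `#` comment lines are skipped.
#'
#' @param path file path
#' @return data.frame with at least `query_id`, `subject_id`,
#'   `identity_pct`, `evalue`
#' @export
read_blast_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 12)
    stop("expected >= 12 tabular columns in ", path, call. = FALSE)
  hits <- data.frame(
    query_id = as.character(raw[[1]]), subject_id = as.character(raw[[2]]),
    identity_pct = as.numeric(raw[[3]]), alignment_length = as.integer(raw[[4]]),
    evalue = as.numeric(raw[[11]]), bit_score = as.numeric(raw[[12]]),
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0, na.rm = TRUE))
    stop("negative e-value in ", path, call. = FALSE)
  hits
}

#' Summarise cross-transcriptome homology from precomputed hits
#'
#' A query EST is "homologous" when it has at least one hit below the
#' e-value cutoff. Among the homologous queries the fraction carrying a
#' functional annotation (membership in `annotated_ids`) is reported —
#' the standard "known vs novel sequence" breakdown for a de novo
#' transcriptome.
#'
#' @param hits data.frame as from [read_blast_hits()] (needs `query_id`
#'   and `evalue`)
#' @param query_ids character vector: the full query universe
#' @param evalue_max strict e-value cutoff (> 0)
#' @param annotated_ids optional character vector of annotated query ids
#' @return list with `n_queries`, `n_homologous`, `pct_homologous`, and —
#'   when `annotated_ids` is given — `n_annotated`, `pct_annotated`
#'   (percent of homologous queries that are annotated; 0 with a warning
#'   when nothing is homologous). Percentages are invariant to hit-row
#'   order.
#' @export
homology_overlap_summary <- function(hits, query_ids, evalue_max = 1e-5,
                                     annotated_ids = NULL) {
  if (!length(query_ids)) stop("empty query set", call. = FALSE)
  if (!(evalue_max > 0)) stop("evalue_max must be > 0", call. = FALSE)
  hom <- unique(hits$query_id[hits$evalue < evalue_max])
  hom <- intersect(hom, query_ids)
  out <- list(n_queries = length(query_ids),
              n_homologous = length(hom),
              pct_homologous = 100 * length(hom) / length(query_ids))
  if (!is.null(annotated_ids)) {
    ann <- intersect(hom, annotated_ids)
    out$n_annotated <- length(ann)
    if (!length(hom)) {
      warning("no homologous queries; annotated fraction reported as 0")
      out$pct_annotated <- 0
    } else {
      out$pct_annotated <- 100 * length(ann) / length(hom)
    }
  }
  out
}
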