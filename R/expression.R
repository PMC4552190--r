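#' Fragments Per Kilobase per Million mapped fragments
#'
#' `fpkm[i, s] = counts[i, s] / (length_bp[i] / 1000) / (library_size[s] / 1e6)`,
#' i.e. linear in the count and inversely linear in transcript length and
#' sequencing depth.
#'
#' @param counts numeric matrix (EST x sample) of read counts
#' @param lengths_bp per-EST transcript lengths in base pairs (>= 1)
#' @param library_sizes per-sample total mapped fragments (> 0); defaults
#'   to the column sums of `counts`
#' @return matrix of FPKM values, same dimnames as `counts`
#' @export
compute_fpkm <- function(counts, lengths_bp,
                         library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths_bp) == nrow(counts),
            length(library_sizes) == ncol(counts))
  if (any(lengths_bp < 1)) stop("lengths_bp must be >= 1", call. = FALSE)
  if (any(library_sizes <= 0))
    stop("library sizes must be positive", call. = FALSE)
  sweep(counts / (lengths_bp / 1000), 2, library_sizes / 1e6, "/")
}

#' Compute and attach FPKM to an EST table
#' @param table an [est_table()] carrying counts
#' @param library_sizes see [compute_fpkm()]
#' @export
add_fpkm <- function(table, library_sizes = colSums(table$counts)) {
  stopifnot(inherits(table, "est_table"))
  if (is.null(table$counts)) stop("table has no counts", call. = FALSE)
  table$fpkm <- compute_fpkm(table$counts, table$ests$length_bp,
                             library_sizes)
  table
}

#' Average replicate FPKM within each condition
#'
#' @param fpkm matrix (EST x sample)
#' @param design data.frame (`sample_id`, `condition`, `replicate`)
#' @return matrix (EST x condition) of arithmetic replicate means
#' @export
average_replicates <- function(fpkm, design) {
  conds <- unique(design$condition)
  out <- vapply(conds, function(cc) {
    cols <- design$sample_id[design$condition == cc]
    rowMeans(fpkm[, cols, drop = FALSE])
  }, numeric(nrow(fpkm)))
  out <- matrix(out, nrow = nrow(fpkm),
                dimnames = list(rownames(fpkm), conds))
  out
}

#' Between-condition expression ratio and log2 fold change
#'
#' Ratio is depleted over replete (treatment over control); both condition
#' means must be positive — zero-FPKM ESTs are expected to have been
#' removed by the upstream filter.
#'
#' @param cond_means matrix (EST x condition) from [average_replicates()]
#' @return data.frame with `est_id`, `ratio`, `log_fc` (log2 of ratio)
#' @export
compute_ratio <- function(cond_means) {
  stopifnot(all(.conditions %in% colnames(cond_means)))
  num <- cond_means[, "N_depleted"]
  den <- cond_means[, "N_replete"]
  if (any(num <= 0) || any(den <= 0))
    stop("condition means must be positive; filter zero-FPKM ESTs first",
         call. = FALSE)
  data.frame(est_id = rownames(cond_means), ratio = num / den,
             log_fc = log2(num / den), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Expression summary of an EST table
#'
#' Convenience wrapper: ensures FPKM is present, averages replicates and
#' computes the depleted/replete ratio in one pass.
#'
#' @param table an [est_table()] with counts and/or fpkm
#' @param strict_ratio error on non-positive condition means (the
#'   contract after zero-FPKM filtering); when `FALSE`, such ESTs get an
#'   `NA` ratio with a message
#' @return list of class `expression_summary` with `est_ids`, `fpkm`,
#'   `cond_means`, `ratio`, `log_fc`
#' @export
summarize_expression <- function(table, strict_ratio = FALSE) {
  stopifnot(inherits(table, "est_table"))
  if (is.null(table$fpkm)) table <- add_fpkm(table)
  cm <- average_replicates(table$fpkm, table$design)
  ok <- cm[, "N_depleted"] > 0 & cm[, "N_replete"] > 0
  if (!all(ok)) {
    if (strict_ratio)
      stop(sum(!ok), " EST(s) have a non-positive condition mean; ",
           "filter zero-FPKM ESTs first", call. = FALSE)
    message(sum(!ok), " EST(s) have a zero condition mean; ",
            "ratio set to NA (apply the zero-FPKM filter to avoid this)")
  }
  ratio <- ifelse(ok, cm[, "N_depleted"] / cm[, "N_replete"], NA_real_)
  structure(list(est_ids = table$ests$est_id, fpkm = table$fpkm,
                 cond_means = cm,
                 ratio = stats::setNames(ratio, table$ests$est_id),
                 log_fc = stats::setNames(log2(ratio), table$ests$est_id)),
            class = "expression_summary")
}

#' Rank ESTs by expression level or by response ratio
#'
#' Rank 1 is the largest key. `by_level` ranks on the nitrogen-replete
#' condition mean (the log-phase abundance before deprivation);
#' `by_ratio` on the depleted/replete ratio. Ties break lexicographically
#' on est_id so the ordering is fully deterministic.
#'
#' @param expr an `expression_summary` (or a matrix of condition means)
#' @param mode `"by_level"` or `"by_ratio"`
#' @param level_condition condition whose mean is the `by_level` key
#' @return data.frame of class `est_ranking`: `rank`, `est_id`, `key`
#'   (non-increasing); a permutation of the input ESTs
#' @export
rank_ests <- function(expr, mode = c("by_level", "by_ratio"),
                      level_condition = "N_replete") {
  mode <- match.arg(mode)
  if (inherits(expr, "expression_summary")) {
    key <- switch(mode,
                  by_level = expr$cond_means[, level_condition],
                  by_ratio = expr$ratio)
    ids <- expr$est_ids
  } else {
    cm <- as.matrix(expr)
    key <- switch(mode,
                  by_level = cm[, level_condition],
                  by_ratio = cm[, "N_depleted"] / cm[, "N_replete"])
    ids <- rownames(cm)
  }
  o <- order(-key, ids)
  out <- data.frame(rank = seq_along(ids), est_id = ids[o],
                    key = unname(key[o]), stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("est_ranking", "data.frame")
  out
}

#' Stand-in per-EST differential-expression test
#'
#' Exact two-sided binomial test of each EST's pooled nitrogen-depleted
#' read count against the depleted share of the total library size: counts
#' are summed across replicates within condition, and under the null of no
#' expression change the depleted fraction of an EST's reads should match
#' the depleted fraction of all mapped fragments. Calibrated under
#' Poisson-level replicate noise; with strong biological overdispersion it
#' is anti-conservative, which is why externally computed p-values (e.g.
#' from a dedicated count model) can be supplied to
#' [apply_de_thresholds()] instead.
#'
#' @param counts matrix (EST x sample) of raw read counts
#' @param design sample design data.frame
#' @param library_sizes per-sample totals (defaults to column sums)
#' @return named vector of two-sided p-values (1 for ESTs with no reads)
#' @export
de_binomial_test <- function(counts, design,
                             library_sizes = colSums(counts)) {
  dep <- design$sample_id[design$condition == "N_depleted"]
  x <- rowSums(counts[, dep, drop = FALSE])
  n <- rowSums(counts)
  p0 <- sum(library_sizes[match(dep, colnames(counts))]) / sum(library_sizes)
  p <- vapply(seq_along(x), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(round(x[i]), round(n[i]), p0)$p.value
  }, numeric(1))
  stats::setNames(p, rownames(counts))
}

#' Flag differentially expressed ESTs
#'
#' Joint threshold on effect size and significance: up-regulated means
#' `log_fc > log2(fold_change_min)` with `p < p_max`; down-regulated is
#' the mirrored condition. ESTs without a p-value are excluded with a
#' warning.
#'
#' @param log_fc named numeric vector of log2 fold changes
#' @param p_values named numeric vector of p-values in \[0, 1\]
#' @param fold_change_min minimum fold change (default 2)
#' @param p_max maximum p-value (default 0.05)
#' @return list of class `de_flags`: `up`, `down` (disjoint est_id sets),
#'   `thresholds`, `p_values`
#' @export
apply_de_thresholds <- function(log_fc, p_values, fold_change_min = 2,
                                p_max = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  ids <- names(log_fc)
  p <- p_values[ids]
  missing <- is.na(p)
  if (any(missing)) {
    warning(sum(missing), " EST(s) lack a p-value and were excluded")
    ids <- ids[!missing]; log_fc <- log_fc[!missing]; p <- p[!missing]
  }
  lfc_min <- log2(fold_change_min)
  structure(list(
    up = ids[log_fc > lfc_min & p < p_max],
    down = ids[log_fc < -lfc_min & p < p_max],
    thresholds = c(fold_change_min = fold_change_min, p_max = p_max),
    p_values = p), class = "de_flags")
}
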