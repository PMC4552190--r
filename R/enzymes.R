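#' Group ESTs into an enzyme panel by EC number
#'
#' Restricts an EC-namespace term map to a proposed enzyme list and to the
#' ESTs present in a table. An enzyme is "detected" when at least one EST
#' is associated with its EC number; an EST mapped to several EC numbers
#' contributes to each of them.
#'
#' @param table an [est_table()]
#' @param ec_map a [term_map()] with namespace `"EC"`
#' @param panel_ecs character vector of EC numbers defining the panel
#' @param panel_name label carried through reports
#' @return list of class `enzyme_panel`: `panel_name`, `enzymes` (named
#'   list EC -> est_ids, detected enzymes only), `panel_ecs`,
#'   `n_detected`, `copy_number` (ESTs per detected enzyme)
#' @export
group_by_enzyme <- function(table, ec_map, panel_ecs,
                            panel_name = "panel") {
  stopifnot(inherits(table, "est_table"), inherits(ec_map, "term_map"))
  if (!length(panel_ecs)) stop("empty panel list", call. = FALSE)
  if (!all(ec_map$namespace == "EC"))
    stop("ec_map must use the EC namespace", call. = FALSE)
  sets <- term_sets(ec_map, universe = table$ests$est_id)
  sets <- sets[names(sets) %in% panel_ecs]
  sets <- sets[lengths(sets) > 0]
  structure(list(panel_name = panel_name, enzymes = sets,
                 panel_ecs = panel_ecs, n_detected = length(sets),
                 copy_number = lengths(sets)),
            class = "enzyme_panel")
}

#' @export
print.enzyme_panel <- function(x, ...) {
  cat(sprintf("enzyme_panel '%s': %d of %d EC numbers detected (%d ESTs)\n",
              x$panel_name, x$n_detected, length(x$panel_ecs),
              length(unique(unlist(x$enzymes)))))
  invisible(x)
}

#' Summative enzyme-level expression and fold-change flags
#'
#' The expression of an enzyme is the sum of the condition-mean FPKM of
#' all ESTs encoding it. An enzyme is flagged when the summative level
#' changes more than `fold_min`-fold in either direction between
#' conditions. Enzymes with a zero sum in one condition get an undefined
#' ratio, are never flagged, and trigger a warning.
#'
#' @param panel an [group_by_enzyme()] panel
#' @param expr an `expression_summary` (member ESTs must be present)
#' @param fold_min fold-change threshold (default 2)
#' @return data.frame per enzyme: `ec`, `n_ests`, `sum_replete`,
#'   `sum_depleted`, `ratio` (depleted/replete), `fold`
#'   (max of ratio and its inverse), `direction`, `flagged`
#' @export
summative_levels_and_flags <- function(panel, expr, fold_min = 2) {
  stopifnot(inherits(panel, "enzyme_panel"),
            inherits(expr, "expression_summary"))
  miss <- setdiff(unlist(panel$enzymes), rownames(expr$cond_means))
  if (length(miss))
    stop("panel ESTs missing from the expression summary: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  rows <- lapply(names(panel$enzymes), function(ec) {
    ids <- panel$enzymes[[ec]]
    s_rep <- sum(expr$cond_means[ids, "N_replete"])
    s_dep <- sum(expr$cond_means[ids, "N_depleted"])
    if (s_rep > 0 && s_dep > 0) {
      ratio <- s_dep / s_rep
      fold <- max(ratio, 1 / ratio)
      direction <- if (ratio >= 1) "up" else "down"
      flagged <- fold > fold_min
    } else {
      ratio <- NA_real_; fold <- NA_real_
      direction <- NA_character_; flagged <- FALSE
    }
    data.frame(ec = ec, n_ests = length(ids), sum_replete = s_rep,
               sum_depleted = s_dep, ratio = ratio, fold = fold,
               direction = direction, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$ratio)))
    warning(sum(is.na(out$ratio)),
            " enzyme(s) have a zero summative level in one condition; ",
            "ratio undefined, not flagged")
  rownames(out) <- NULL
  out
}

#' Significance of the overlap between two detected enzyme sets
#'
#' Given a proposed enzyme universe of size `universe_size` in which one
#' study detected `a` enzymes and another detected `b`, tests whether an
#' observed overlap of `k` shared enzymes is larger than expected under
#' random draws: `p = P[X >= k]`, `X ~ Hypergeometric(universe_size, b,
#' a)`, computed by exact summation of the hypergeometric mass.
#'
#' @param universe_size size of the proposed enzyme list
#' @param a,b sizes of the two detected sets (each <= universe)
#' @param k observed overlap (<= min(a, b))
#' @return list of class `panel_overlap`: inputs, `expected` overlap and
#'   `p_value`
#' @export
panel_overlap_test <- function(universe_size, a, b, k) {
  if (a > universe_size || b > universe_size)
    stop("set sizes exceed the universe", call. = FALSE)
  if (k > min(a, b)) stop("impossible overlap: k > min(a, b)", call. = FALSE)
  if (k < max(0, a + b - universe_size))
    stop("impossible overlap: k below the forced minimum", call. = FALSE)
  # exact upper tail: sum of dhyper over k..min(a,b)
  p <- sum(stats::dhyper(k:min(a, b), b, universe_size - b, a))
  structure(list(universe_size = universe_size, a = a, b = b, k = k,
                 expected = a * b / universe_size, p_value = min(1, p)),
            class = "panel_overlap")
}

#' @export
print.panel_overlap <- function(x, ...) {
  cat(sprintf(
    "panel overlap: %d shared of (%d, %d) in universe %d; expected %.2f, p = %.4g\n",
    x$k, x$a, x$b, x$universe_size, x$expected, x$p_value))
  invisible(x)
}

#' Per-EST report for an enzyme panel
#'
#' Long-form table, one row per (enzyme, member EST), with both condition
#' means, the expression ratio and the EST's differential-expression
#' marker — the per-copy view that accompanies the summative panel.
#'
#' @param panel an enzyme panel
#' @param expr an `expression_summary`
#' @param flags optional `de_flags`; adds a `de_flag` column
#'   (`"up"`/`"down"`/`""`)
#' @return data.frame: `ec`, `est_id`, `fpkm_replete`, `fpkm_depleted`,
#'   `ratio`, `de_flag`
#' @export
per_est_panel_report <- function(panel, expr, flags = NULL) {
  stopifnot(inherits(panel, "enzyme_panel"),
            inherits(expr, "expression_summary"))
  if (!length(panel$enzymes))
    return(data.frame(ec = character(), est_id = character(),
                      fpkm_replete = numeric(), fpkm_depleted = numeric(),
                      ratio = numeric(), de_flag = character()))
  rows <- lapply(names(panel$enzymes), function(ec) {
    ids <- panel$enzymes[[ec]]
    data.frame(ec = ec, est_id = ids,
               fpkm_replete = expr$cond_means[ids, "N_replete"],
               fpkm_depleted = expr$cond_means[ids, "N_depleted"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio <- out$fpkm_depleted / out$fpkm_replete
  out$de_flag <- ""
  if (!is.null(flags)) {
    stopifnot(inherits(flags, "de_flags"))
    out$de_flag[out$est_id %in% flags$up] <- "up"
    out$de_flag[out$est_id %in% flags$down] <- "down"
  }
  rownames(out) <- NULL
  out
}
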