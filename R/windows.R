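#' Sliding-window geometry over a ranking
#'
#' @param window_size number of consecutive ranks per window (default
#'   1024 ESTs)
#' @param step offset between successive window starts (default 512
#'   ESTs); must not exceed the window size
#' @export
window_spec <- function(window_size = 1024, step = 512) {
  stopifnot(window_size >= 1, step >= 1)
  if (step > window_size)
    stop("step must not exceed window_size", call. = FALSE)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step)), class = "window_spec")
}

#' Enumerate full-size windows over N ranks
#'
#' Windows start at ranks 1, 1+s, 1+2s, ... and each spans exactly `w`
#' consecutive ranks; only full windows are kept, so trailing ranks beyond
#' the last full window are not covered. The count is
#' `floor((N - w) / s) + 1` — 23 windows for the default geometry over a
#' 12,292-EST universe.
#'
#' @param N universe size (must be >= window size)
#' @param spec a [window_spec()]
#' @return data.frame `window` (1-based index), `start`, `end` (closed
#'   rank interval)
#' @export
make_windows <- function(N, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  w <- spec$window_size; s <- spec$step
  if (N < w)
    stop("universe (", N, ") smaller than window size (", w, ")",
         call. = FALSE)
  starts <- seq.int(1L, N - w + 1L, by = s)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + w - 1L)
}

#' Term eligibility and flagging policy for window enrichment
#'
#' Terms enter the analysis only when they have strictly more than
#' `min_term_size` member ESTs inside the ranked universe; a (term,
#' window) pair is flagged when its density fold exceeds `fold_min` and
#' its Bonferroni-adjusted p-value is below `alpha`.
#'
#' @param min_term_size exclusive membership threshold (default 30)
#' @param fold_min density-fold threshold (default 2)
#' @param alpha family-wise significance level (default 0.05)
#' @export
eligibility_policy <- function(min_term_size = 30, fold_min = 2,
                               alpha = 0.05) {
  stopifnot(min_term_size > 0, fold_min > 0, alpha > 0)
  structure(list(min_term_size = min_term_size, fold_min = fold_min,
                 alpha = alpha), class = "eligibility_policy")
}

#' Bonferroni adjustment
#' @param p_raw raw p-value(s)
#' @param m number of tests in the family (>= 1)
#' @return `min(1, m * p_raw)`
#' @export
bonferroni_adjust <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, m * p_raw)
}

# upper-tail binomial probability P[X >= x], X ~ Binomial(n, p)
.binom_upper <- function(x, n, p) {
  stats::pbinom(x - 1, n, p, lower.tail = FALSE)
}

#' Sliding-window term enrichment along a ranking
#'
#' For each eligible term and each window, counts the term's member ESTs
#' whose ranks fall in the window (`x`) and tests the upper tail of
#' `Binomial(n = window size, p0 = K/N)`, where `K` is the term's
#' membership in the ranked universe of size `N` — successes are the
#' term-associated ESTs present among the window's trials. The fold is
#' the window density over the background density, `(x/n) / (K/N)`.
#' Bonferroni families: `"terms_by_windows"` (the conservative default,
#' m = eligible terms x windows) or `"per_term"` (m = windows).
#'
#' @param ranking an `est_ranking` from [rank_ests()]
#' @param terms a [term_map()]; memberships are restricted to the ranked
#'   universe, terms left empty are skipped with a message
#' @param spec a [window_spec()]
#' @param policy an [eligibility_policy()]
#' @param family Bonferroni family definition
#' @return data.frame, one row per (eligible term, window): `term_id`,
#'   `namespace`, `window`, `start`, `x`, `n`, `K`, `N`, `p0`, `fold`,
#'   `p_raw`, `p_adj`, `flagged`
#' @export
window_term_enrichment <- function(ranking, terms, spec = window_spec(),
                                   policy = eligibility_policy(),
                                   family = c("terms_by_windows",
                                              "per_term")) {
  stopifnot(inherits(ranking, "est_ranking"), inherits(terms, "term_map"))
  family <- match.arg(family)
  N <- nrow(ranking)
  win <- make_windows(N, spec)
  rank_of <- stats::setNames(ranking$rank, ranking$est_id)

  in_universe <- terms$est_id %in% ranking$est_id
  dropped <- setdiff(unique(terms$term_id),
                     unique(terms$term_id[in_universe]))
  if (length(dropped))
    message(length(dropped), " term(s) have no members in the ranked ",
            "universe and were skipped")
  terms <- terms[in_universe, , drop = FALSE]
  sets <- split(terms$est_id, terms$term_id)
  ns <- vapply(split(terms$namespace, terms$term_id), `[`, "", 1)
  K <- lengths(sets)
  eligible <- names(sets)[K > policy$min_term_size]
  if (!length(eligible)) {
    out <- data.frame(term_id = character(), namespace = character(),
                      window = integer(), start = integer(), x = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p0 = numeric(), fold = numeric(), p_raw = numeric(),
                      p_adj = numeric(), flagged = logical())
    return(out)
  }

  m <- switch(family,
              terms_by_windows = length(eligible) * nrow(win),
              per_term = nrow(win))
  res <- lapply(eligible, function(tid) {
    ranks <- sort(unname(rank_of[sets[[tid]]]))
    k <- length(ranks)
    # members per window: ranks in [start, end]
    x <- vapply(seq_len(nrow(win)), function(i)
      sum(ranks >= win$start[i] & ranks <= win$end[i]), integer(1))
    p0 <- k / N
    fold <- (x / spec$window_size) / p0
    p_raw <- .binom_upper(x, spec$window_size, p0)
    data.frame(term_id = tid, namespace = unname(ns[tid]),
               window = win$window, start = win$start, x = x,
               n = spec$window_size, K = k, N = N, p0 = p0, fold = fold,
               p_raw = p_raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni_adjust(out$p_raw, m)
  out$flagged <- out$fold > policy$fold_min & out$p_adj < policy$alpha
  attr(out, "family") <- family
  attr(out, "m") <- m
  rownames(out) <- NULL
  out
}

#' Term-by-window density-ratio matrix
#'
#' Reshapes a [window_term_enrichment()] result into a terms x windows
#' matrix of density folds, the tabular mirror of the usual enrichment
#' heat map.
#'
#' @param enrichment result of [window_term_enrichment()]
#' @export
enrichment_matrix <- function(enrichment) {
  terms <- unique(enrichment$term_id)
  wins <- sort(unique(enrichment$window))
  m <- matrix(NA_real_, length(terms), length(wins),
              dimnames = list(terms, paste0("w", wins)))
  m[cbind(match(enrichment$term_id, terms),
          match(enrichment$window, wins))] <- enrichment$fold
  m
}

#' Enrichment of one term among the top-k ranks
#'
#' Same binomial statistic as the window analysis, applied to the single
#' block of the `k` highest ranks: with `x` term members among the top
#' `k`, fold = `(x/k) / (K/N)` and the p-value is the upper binomial tail
#' at background rate `K/N`.
#'
#' @param ranking an `est_ranking`
#' @param members character vector: the term's member est_ids
#' @param k block size (<= N)
#' @return list `x`, `k`, `K`, `N`, `fold`, `p_raw`
#' @export
top_k_term_enrichment <- function(ranking, members, k) {
  stopifnot(inherits(ranking, "est_ranking"), length(members) > 0)
  N <- nrow(ranking)
  if (k > N) stop("k exceeds the universe size", call. = FALSE)
  members <- intersect(members, ranking$est_id)
  K <- length(members)
  if (!K) stop("term has no members in the ranked universe", call. = FALSE)
  x <- sum(ranking$est_id[seq_len(k)] %in% members)
  p0 <- K / N
  list(x = x, k = k, K = K, N = N, fold = (x / k) / p0,
       p_raw = .binom_upper(x, k, p0))
}

#' Term over-representation within an EST subset
#'
#' Classic gene-set over-representation of a fixed subset (e.g. all ESTs
#' annotated with "dehydrogenase") against each term: the overlap `x` of
#' subset and term membership is tested with the one-sided hypergeometric
#' upper tail (equivalently a one-sided Fisher exact test) on the 2x2
#' subset-by-term table within the universe.
#'
#' @param subset character vector of est_ids, a subset of `universe`
#' @param terms a [term_map()]
#' @param universe character vector: the reference EST universe
#' @param fold_min,alpha flagging thresholds (fold > `fold_min` and
#'   Bonferroni-adjusted p < `alpha`)
#' @return data.frame per term: `term_id`, `namespace`, `K`, `x`,
#'   `expected`, `fold`, `p_raw`, `p_adj`, `flagged`
#' @export
subset_pathway_enrichment <- function(subset, terms, universe,
                                      fold_min = 2, alpha = 0.05) {
  stopifnot(inherits(terms, "term_map"))
  if (!length(subset)) stop("empty subset", call. = FALSE)
  if (!all(subset %in% universe))
    stop("subset must be contained in the universe", call. = FALSE)
  subset <- unique(subset)
  N <- length(unique(universe))
  sets <- term_sets(terms, universe = universe)
  sets <- sets[lengths(sets) > 0]
  ns <- vapply(split(terms$namespace, terms$term_id), `[`, "", 1)
  m <- length(sets)
  rows <- lapply(names(sets), function(tid) {
    K <- length(sets[[tid]])
    x <- length(intersect(subset, sets[[tid]]))
    expected <- length(subset) * K / N
    # P[X >= x], X ~ Hypergeometric(K term, N-K non-term, |subset| draws)
    p <- stats::phyper(x - 1, K, N - K, length(subset), lower.tail = FALSE)
    data.frame(term_id = tid, namespace = unname(ns[tid]), K = K, x = x,
               expected = expected, fold = x / expected, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p_raw, m)
  out$flagged <- out$fold > fold_min & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Window distribution of differential-expression flags
#'
#' Where do the up- and down-regulated ESTs sit along a ranking? For each
#' window the member counts of the up and down sets are reported together
#' with their density ratio against the set's background density — the
#' summary behind the observation that ESTs up-regulated on nitrogen
#' deprivation tend to be the least abundant ones beforehand.
#'
#' @param flags a `de_flags` object from [apply_de_thresholds()]
#' @param ranking an `est_ranking`
#' @param spec a [window_spec()]
#' @return data.frame per window: `window`, `start`, `up`, `down`,
#'   `up_density_ratio`, `down_density_ratio` (NA for an empty flag set)
#' @export
flagged_set_window_distribution <- function(flags, ranking,
                                            spec = window_spec()) {
  stopifnot(inherits(flags, "de_flags"), inherits(ranking, "est_ranking"))
  extra <- setdiff(c(flags$up, flags$down), ranking$est_id)
  if (length(extra))
    stop("flagged ids absent from the ranked universe: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  N <- nrow(ranking)
  win <- make_windows(N, spec)
  rank_of <- stats::setNames(ranking$rank, ranking$est_id)
  count_in <- function(ids) {
    r <- unname(rank_of[ids])
    vapply(seq_len(nrow(win)), function(i)
      sum(r >= win$start[i] & r <= win$end[i]), integer(1))
  }
  up <- count_in(flags$up)
  down <- count_in(flags$down)
  ratio <- function(x, k) {
    if (k == 0) return(rep(NA_real_, length(x)))
    (x / spec$window_size) / (k / N)
  }
  data.frame(window = win$window, start = win$start, up = up, down = down,
             up_density_ratio = ratio(up, length(flags$up)),
             down_density_ratio = ratio(down, length(flags$down)))
}
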