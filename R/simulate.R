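# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# inverse-CDF draw from a log-normal truncated to [lo, hi]
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  flo <- stats::plnorm(lo, meanlog, sdlog)
  fhi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, flo, fhi), meanlog, sdlog)
}

#' Describe a term to plant along the ranking
#'
#' @param term_id identifier of the planted term
#' @param size total membership K
#' @param windows window index/indices whose ranks the term should crowd
#' @param multiplier target density multiplier over background (>= 1)
#' @param namespace term namespace
#' @export
plant_term <- function(term_id, size, windows = 1, multiplier = 3,
                       namespace = "GO_BP") {
  stopifnot(multiplier >= 1, size >= 1)
  list(term_id = term_id, size = as.integer(size),
       windows = as.integer(windows), multiplier = multiplier,
       namespace = namespace)
}

#' Configuration of the synthetic transcriptome generator
#'
#' Defaults emulate the annotated-transcriptome conditions the analysis
#' targets: 12,292 ESTs in a two-condition (nitrogen replete/depleted),
#' two-replicate design; log-normal lengths truncated to \[301, 8268\] bp
#' with median near 663; heavy-tailed per-EST total read counts floored
#' at 42 with median near 174; negative-binomial replicate noise
#' (dispersion 0.1, typical of bulk RNA-seq biological replicates; 0
#' gives Poisson); a background catalog of 44 eligible GO-like terms
#' assigned uniformly at random; and a differential-expression structure
#' of 593/12292 up- and 116/12292 down-regulated ESTs, placed among the
#' low- and high-abundance ESTs respectively.
#'
#' @param n_ests universe size
#' @param n_replicates replicates per condition
#' @param length_meanlog,length_sdlog,length_range length distribution
#'   (log-normal, truncated; bp)
#' @param count_meanlog,count_sdlog,min_total_count distribution of the
#'   per-EST baseline total read count (log-normal, floored)
#' @param dispersion negative-binomial dispersion of replicate counts
#'   (variance `mu + dispersion * mu^2`); 0 for Poisson
#' @param n_background_terms,term_size_meanlog,term_size_sdlog,term_size_range
#'   background term catalog (sizes log-normal, truncated; the default
#'   range keeps every term above the eligibility threshold)
#' @param planted_terms list of [plant_term()] descriptions
#' @param de_up_fraction,de_down_fraction fractions of ESTs truly up-/
#'   down-regulated on deprivation
#' @param de_up_logfc_range,de_down_logfc_range magnitude ranges (log2)
#'   of the planted effects
#' @param de_placement_quantile up-regulated ESTs are drawn from the
#'   lowest, down-regulated from the highest, this fraction of baseline
#'   abundances
#' @param window [window_spec()] that planted window indices refer to
#' @export
generator_config <- function(
    n_ests = 12292, n_replicates = 2,
    length_meanlog = log(610), length_sdlog = 0.6,
    length_range = c(301, 8268),
    count_meanlog = log(50), count_sdlog = 2, min_total_count = 42,
    dispersion = 0.1,
    n_background_terms = 44, term_size_meanlog = log(70),
    term_size_sdlog = 0.5, term_size_range = c(31, 400),
    planted_terms = list(),
    de_up_fraction = 593 / 12292, de_down_fraction = 116 / 12292,
    de_up_logfc_range = c(2, 12), de_down_logfc_range = c(1.5, 4.5),
    de_placement_quantile = 0.25,
    window = window_spec()) {
  stopifnot(n_ests >= 1, n_replicates >= 1, dispersion >= 0,
            length_range[1] >= 1, min_total_count >= 0)
  for (pt in planted_terms)
    if (pt$multiplier < 1) stop("density multipliers must be >= 1",
                                call. = FALSE)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate an annotated two-condition EST table with known truth
#'
#' Samples lengths and baseline expression, plants the configured
#' differential-expression structure, draws per-sample counts, derives
#' FPKM through [compute_fpkm()] (so normalisation code is exercised on
#' every fixture), ranks ESTs by level, and finally assigns term
#' memberships: background terms uniformly at random, planted terms with
#' an exact number of members placed inside their target windows (the
#' remainder uniform outside), so the realised density multiplier matches
#' the target up to rounding. Deterministic given `seed`.
#'
#' @param config a [generator_config()]
#' @param seed integer seed
#' @return list with `table` (an [est_table()] with annotations) and
#'   `truth` (planted-term realisation and per-EST DE labels)
#' @export
generate_table <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, .generate_table_impl(config, seed))
}

.generate_table_impl <- function(cfg, seed) {
  n <- cfg$n_ests
  est_id <- sprintf("EST%05d", seq_len(n))
  lengths <- round(rlnorm_trunc(n, cfg$length_meanlog, cfg$length_sdlog,
                                cfg$length_range[1], cfg$length_range[2]))
  # baseline total count across all samples (nitrogen-replete scale)
  total0 <- rlnorm_trunc(n, cfg$count_meanlog, cfg$count_sdlog,
                         lo = cfg$min_total_count)

  # differential-expression structure: ups among the least-abundant,
  # downs among the most-abundant baseline ESTs
  n_up <- round(cfg$de_up_fraction * n)
  n_down <- round(cfg$de_down_fraction * n)
  ord <- order(total0)
  q <- max(cfg$de_placement_quantile, (n_up + n_down) / n)
  low_pool <- ord[seq_len(ceiling(q * n))]
  high_pool <- rev(ord)[seq_len(ceiling(q * n))]
  up_idx <- sample(low_pool, n_up)
  down_idx <- sample(setdiff(high_pool, up_idx), n_down)
  # effect magnitudes: exponential above the lower bound, capped at the
  # upper bound, so a handful of effects reach the extreme while most
  # stay modest (the shape real DE logFC spectra show); the scale is set
  # so the expected maximum sits near the cap
  rlfc <- function(k, range) {
    if (!k) return(numeric(0))
    scale <- (range[2] - range[1]) / max(1, log(k))
    pmin(range[1] + stats::rexp(k, rate = 1 / scale), range[2])
  }
  lfc <- numeric(n)
  lfc[up_idx] <- rlfc(n_up, cfg$de_up_logfc_range)
  lfc[down_idx] <- -rlfc(n_down, cfg$de_down_logfc_range)

  nrep <- cfg$n_replicates
  samples <- c(paste0("NR_", seq_len(nrep)), paste0("ND_", seq_len(nrep)))
  design <- .infer_design(samples)
  mu0 <- total0 / (2 * nrep)
  mu <- cbind(matrix(mu0, n, nrep),
              matrix(mu0 * 2^lfc, n, nrep))
  colnames(mu) <- samples
  draw <- function(m) {
    if (cfg$dispersion > 0)
      stats::rnbinom(length(m), mu = m, size = 1 / cfg$dispersion)
    else stats::rpois(length(m), m)
  }
  counts <- matrix(draw(mu), n, length(samples),
                   dimnames = list(est_id, samples))

  label <- rep("null", n)
  label[up_idx] <- "up"; label[down_idx] <- "down"
  ests <- data.frame(est_id = est_id, length_bp = lengths,
                     description = ifelse(label == "null", "",
                                          paste0("planted ", label)),
                     stringsAsFactors = FALSE)
  tab <- est_table(ests, design, counts = counts)
  tab <- add_fpkm(tab)

  # level ranking of the realised table drives membership placement
  cm <- average_replicates(tab$fpkm, tab$design)
  ranking <- rank_ests(cm, mode = "by_level")
  id_at_rank <- ranking$est_id

  planted_rows <- list()
  pairs <- list()
  win <- if (length(cfg$planted_terms)) make_windows(n, cfg$window)
  for (pt in cfg$planted_terms) {
    wr <- win[win$window %in% pt$windows, , drop = FALSE]
    if (nrow(wr) != length(pt$windows))
      stop("planted window index out of range for term ", pt$term_id,
           call. = FALSE)
    w_ranks <- unlist(Map(seq.int, wr$start, wr$end))
    w_ranks <- unique(w_ranks)
    x_t <- round(pt$multiplier * pt$size / n * length(w_ranks))
    if (x_t > min(pt$size, length(w_ranks)))
      stop("infeasible planting for term ", pt$term_id,
           ": target occupancy ", x_t, " exceeds capacity", call. = FALSE)
    inside <- sample(w_ranks, x_t)
    outside <- sample(setdiff(seq_len(n), w_ranks), pt$size - x_t)
    members <- id_at_rank[c(inside, outside)]
    pairs[[length(pairs) + 1]] <-
      data.frame(term_id = pt$term_id, est_id = members,
                 namespace = pt$namespace, stringsAsFactors = FALSE)
    planted_rows[[length(planted_rows) + 1]] <- data.frame(
      term_id = pt$term_id,
      windows = paste(pt$windows, collapse = ","),
      size = pt$size, target_multiplier = pt$multiplier,
      achieved_multiplier = (x_t / length(w_ranks)) / (pt$size / n),
      x_in_windows = x_t, stringsAsFactors = FALSE)
  }
  if (cfg$n_background_terms > 0) {
    sizes <- round(rlnorm_trunc(cfg$n_background_terms,
                                cfg$term_size_meanlog, cfg$term_size_sdlog,
                                cfg$term_size_range[1],
                                cfg$term_size_range[2]))
    for (i in seq_len(cfg$n_background_terms)) {
      pairs[[length(pairs) + 1]] <- data.frame(
        term_id = sprintf("GO:SIM%04d", i),
        est_id = sample(est_id, sizes[i]),
        namespace = "GO_BP", stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, pairs)
  map <- if (is.null(ann)) NULL else
    term_map(ann$term_id, ann$est_id, ann$namespace)
  if (!is.null(map)) tab$annotations <- map

  truth <- list(
    seed = seed,
    ranking_mode = "by_level",
    planted = if (length(planted_rows)) do.call(rbind, planted_rows)
              else data.frame(),
    de = data.frame(est_id = est_id, label = label, true_log_fc = lfc,
                    stringsAsFactors = FALSE))
  list(table = tab, truth = truth)
}

#' Generate replicate growth curves around a template
#'
#' Multiplicative log-normal noise on a biomass-trajectory template;
#' `noise_sd = 0` reproduces the template in every replicate.
#'
#' @param template_days sampling days
#' @param template_cdw template CDW trajectory (g/L)
#' @param n_replicates number of replicate trajectories
#' @param noise_sd SD of the log-scale measurement noise
#' @param seed integer seed
#' @return a [growth_series()]
#' @export
generate_growth_series <- function(template_days, template_cdw,
                                   n_replicates = 3, noise_sd = 0,
                                   seed = 1) {
  stopifnot(noise_sd >= 0, length(template_days) == length(template_cdw))
  with_seed(seed, {
    cdw <- vapply(seq_len(n_replicates), function(j)
      template_cdw * exp(stats::rnorm(length(template_cdw), 0, noise_sd)),
      numeric(length(template_cdw)))
    growth_series(template_days,
                  matrix(cdw, ncol = n_replicates,
                         dimnames = list(NULL,
                                         paste0("rep", seq_len(n_replicates)))))
  })
}

#' Export a generated dataset as plain-text fixture files
#'
#' Writes `ests.tsv` (the [read_est_table()] dialect), `terms.tsv`
#' (the [read_term_map()] dialect) and `truth.json` into `dir`.
#' Numeric values are written at full precision, so re-reading
#' reproduces the table exactly; the same seed yields byte-identical
#' files.
#'
#' @param table an [est_table()]
#' @param truth the truth component of [generate_table()]
#' @param dir writable output directory (created if absent)
#' @return invisibly, the paths written
#' @export
export_fixture <- function(table, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ests = file.path(dir, "ests.tsv"),
             terms = file.path(dir, "terms.tsv"),
             truth = file.path(dir, "truth.json"))
  write_est_table(table, paths[["ests"]])
  if (!is.null(table$annotations))
    write_term_map(table$annotations, paths[["terms"]])
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(paths)
}
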