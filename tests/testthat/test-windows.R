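test_that("window geometry matches the full-window enumeration oracle", {
  expect_equal(nrow(make_windows(12292)), 23)
  expect_equal(nrow(make_windows(1024)), 1)

  w3 <- make_windows(2048)
  expect_equal(w3$start, c(1, 513, 1025))
  expect_equal(w3$end, c(1024, 1536, 2048))

  expect_error(make_windows(1000), "smaller than")
  expect_error(window_spec(10, 20), "step")

  # spot-check several universe sizes and geometries against brute force
  for (N in c(1024, 1025, 1535, 1536, 3000, 5000)) {
    for (geom in list(c(1024, 512), c(100, 100), c(97, 13))) {
      if (N < geom[1]) next
      win <- make_windows(N, window_spec(geom[1], geom[2]))
      expect_equal(win$start, windows_oracle(N, geom[1], geom[2]))
      expect_true(all(win$end - win$start + 1 == geom[1]))
    }
  }
})

test_that("every covered rank is hit by the expected number of windows", {
  # half-overlapping windows: interior covered ranks belong to exactly
  # two windows, the leading and trailing step-width margins to one
  spec <- window_spec(1024, 512)
  win <- make_windows(12292, spec)
  cover <- integer(12292)
  for (i in seq_len(nrow(win)))
    cover[win$start[i]:win$end[i]] <- cover[win$start[i]:win$end[i]] + 1L
  last <- max(win$end)
  expect_true(all(cover[1:512] == 1))
  expect_true(all(cover[(last - 511):last] == 1))
  expect_true(all(cover[513:(last - 512)] == 2))
  expect_true(all(cover[(last + 1):12292] == 0))  # trailing ranks uncovered
})

test_that("window enrichment equals exact brute-force counting on small universes", {
  set.seed(91)
  for (rep in 1:5) {
    N <- sample(40:200, 1)
    w <- sample(10:min(60, N), 1)
    s <- sample(5:w, 1)
    rk <- fixed_ranking(N)
    terms <- term_map(
      term_id = paste0("T", sample(3, 120, replace = TRUE)),
      est_id = rk$est_id[sample(N, 120, replace = TRUE)])
    res <- window_term_enrichment(rk, terms, window_spec(w, s),
                                  eligibility_policy(min_term_size = 1))
    sets <- term_sets(terms)
    starts <- windows_oracle(N, w, s)
    for (i in seq_len(nrow(res))) {
      row <- res[i, ]
      members <- sets[[row$term_id]]
      ranks <- match(members, rk$est_id)
      x_oracle <- sum(ranks >= starts[row$window] &
                        ranks <= starts[row$window] + w - 1)
      expect_identical(row$x, x_oracle)
      expect_equal(row$p_raw,
                   binom_tail_oracle(x_oracle, w, length(members) / N),
                   tolerance = 1e-12)
      expect_equal(row$fold, (x_oracle / w) / (length(members) / N))
    }
  }
})

test_that("a fully loaded toy window reproduces the closed-form tail", {
  # N=10, term of 5, window of 4 holding 4 members: p0 = 0.5,
  # fold = 2, upper tail = 5 * 0.5^4 = ... exact sum below
  rk <- fixed_ranking(10)
  terms <- term_map(rep("T", 5), rk$est_id[c(1, 2, 3, 4, 8)])
  res <- window_term_enrichment(rk, terms, window_spec(4, 3),
                                eligibility_policy(min_term_size = 1))
  w1 <- res[res$window == 1, ]
  expect_equal(w1$x, 4L)
  expect_equal(w1$fold, 2)
  expect_equal(w1$p_raw, 0.5^4 * choose(4, 4) + 0)  # only X = 4 term
  expect_equal(w1$p_raw, 0.0625)
})

test_that("enrichment p-values respect Bonferroni family bookkeeping", {
  expect_equal(bonferroni_adjust(0.001, 23), 0.023)
  expect_equal(bonferroni_adjust(0.01, 2369), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)

  rk <- fixed_ranking(100)
  terms <- term_map(rep(c("A", "B"), each = 40),
                    c(rk$est_id[1:40], rk$est_id[sample(100, 40)]))
  spec <- window_spec(20, 10)
  cons <- window_term_enrichment(rk, terms, spec,
                                 eligibility_policy(min_term_size = 30))
  per <- window_term_enrichment(rk, terms, spec,
                                eligibility_policy(min_term_size = 30),
                                family = "per_term")
  m_cons <- 2 * nrow(make_windows(100, spec))
  expect_equal(cons$p_adj, pmin(1, m_cons * cons$p_raw))
  expect_equal(per$p_adj, pmin(1, (m_cons / 2) * per$p_raw))
})

test_that("terms at or below the eligibility size are excluded", {
  rk <- fixed_ranking(200)
  terms <- term_map(c(rep("small", 30), rep("big", 31)),
                    rk$est_id[c(1:30, 100:130)])
  res <- window_term_enrichment(rk, terms, window_spec(50, 25))
  expect_setequal(unique(res$term_id), "big")  # K > 30 strictly
})

test_that("upper-tail p is monotone non-increasing in the window count", {
  rk <- fixed_ranking(100)
  # place x of the 20 term members inside the top-20 block, for each x
  ps <- vapply(0:20, function(x) {
    members <- c(rk$est_id[seq_len(x)],
                 rk$est_id[seq(21, length.out = 20 - x)])
    top_k_term_enrichment(rk, members, k = 20)$p_raw
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_equal(ps[1], 1)  # x = 0: the tail covers everything
})

test_that("top-k enrichment reproduces the light-harvesting configuration", {
  # 21 of the top 30 ranks from a 36-member term in a 12,292 universe
  rk <- fixed_ranking(12292)
  members <- c(rk$est_id[1:21], rk$est_id[5000:5014])  # K = 36
  res <- top_k_term_enrichment(rk, members, k = 30)
  expect_equal(res$x, 21)
  expect_equal(res$K, 36)
  expect_equal(round(res$fold, 0), 239)
  expect_equal(res$fold, (21 / 30) / (36 / 12292))
  expect_lt(res$p_raw, 1e-26)

  # no member in the block: closed-form complement
  res0 <- top_k_term_enrichment(rk, rk$est_id[1000:1035], k = 30)
  expect_equal(res0$fold, 0)
  expect_equal(res0$p_raw, 1)
  none <- top_k_term_enrichment(rk, rk$est_id[12000:12035], k = 100)
  expect_equal(none$x, 0)

  # the whole universe as the block: fold is exactly 1
  resN <- top_k_term_enrichment(rk, members, k = 12292)
  expect_equal(resN$fold, 1)
})

test_that("subset over-representation uses the exact hypergeometric tail", {
  rk <- fixed_ranking(40)
  universe <- rk$est_id
  terms <- term_map(c(rep("T1", 8), rep("T2", 10)),
                    c(universe[1:8], universe[20:29]))
  # degenerate: the subset IS one term's membership
  res <- subset_pathway_enrichment(universe[1:8], terms, universe)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$fold, 40 / 8)
  expect_equal(r1$p_raw, 1 / choose(40, 8))

  expect_error(subset_pathway_enrichment(character(0), terms, universe),
               "empty")
  expect_error(subset_pathway_enrichment("zz", terms, universe),
               "contained")
})

test_that("null subsets are almost never flagged after Bonferroni", {
  set.seed(17)
  universe <- sprintf("u%03d", 1:400)
  terms <- term_map(rep(sprintf("T%02d", 1:20), each = 40),
                    unlist(lapply(1:20, function(i) sample(universe, 40))))
  n_flagged <- 0; n_terms <- 0
  for (i in 1:200) {
    subs <- sample(universe, 60)
    res <- subset_pathway_enrichment(subs, terms, universe)
    n_flagged <- n_flagged + sum(res$flagged)
    n_terms <- n_terms + nrow(res)
  }
  expect_lte(n_flagged / n_terms, 0.05)
})

test_that("flag window distributions handle empty and saturating sets", {
  rk <- fixed_ranking(2048)
  empty <- structure(list(up = character(0), down = character(0),
                          thresholds = c(2, 0.05), p_values = numeric(0)),
                     class = "de_flags")
  d0 <- flagged_set_window_distribution(empty, rk)
  expect_true(all(d0$up == 0) && all(d0$down == 0))
  expect_true(all(is.na(d0$up_density_ratio)))

  full <- structure(list(up = rk$est_id, down = character(0),
                         thresholds = c(2, 0.05), p_values = numeric(0)),
                    class = "de_flags")
  d1 <- flagged_set_window_distribution(full, rk)
  expect_true(all(d1$up_density_ratio == 1))

  bad <- structure(list(up = "missing", down = character(0),
                        thresholds = c(2, 0.05), p_values = numeric(0)),
                   class = "de_flags")
  expect_error(flagged_set_window_distribution(bad, rk), "absent")
})
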