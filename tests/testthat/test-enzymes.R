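test_that("EC grouping detects enzymes and honours many-to-many mapping", {
  tab <- tiny_table(n = 5)
  ec <- term_map(c("1.1.1.1", "1.1.1.1", "1.1.1.1", "2.3.1.86", "6.2.1.3"),
                 c("e01", "e02", "e03", "e04", "e02"), namespace = "EC")
  panel <- group_by_enzyme(tab, ec, panel_ecs = c("1.1.1.1", "2.3.1.86",
                                                  "4.2.1.17", "1.3.3.6",
                                                  "2.3.1.9"))
  expect_equal(panel$n_detected, 2)  # two panel ECs have members
  expect_equal(unname(panel$copy_number["1.1.1.1"]), 3L)

  # an EST mapped to two ECs contributes to both enzymes
  panel2 <- group_by_enzyme(tab, ec, panel_ecs = c("1.1.1.1", "6.2.1.3"))
  expect_true("e02" %in% panel2$enzymes[["1.1.1.1"]])
  expect_true("e02" %in% panel2$enzymes[["6.2.1.3"]])

  expect_error(group_by_enzyme(tab, ec, character(0)), "empty panel")
  go <- term_map("T", "e01", "GO_BP")
  expect_error(group_by_enzyme(tab, go, "1.1.1.1"), "EC namespace")
})

test_that("summative enzyme levels sum members and flag 2-fold changes", {
  counts <- rbind(c(10, 10, 21, 21),    # e01
                  c(20, 20, 42, 42),    # e02
                  c(30, 30, 64, 64),    # e03: enzyme A sums 60 -> 127
                  c(40, 40, 85, 85),    # e04: enzyme B 40 -> 85, up
                  c(85, 85, 40, 40))    # e05: enzyme C 85 -> 40, down
  tab <- tiny_table(n = 5, counts = counts)
  tab$fpkm <- counts * 1.0  # identity normalisation keeps arithmetic visible
  colnames(tab$fpkm) <- colnames(tab$counts)
  rownames(tab$fpkm) <- tab$ests$est_id
  expr <- summarize_expression(tab)
  ec <- term_map(c("A", "A", "A", "B", "C"),
                 c("e01", "e02", "e03", "e04", "e05"), namespace = "EC")
  panel <- group_by_enzyme(tab, ec, panel_ecs = c("A", "B", "C"))
  res <- summative_levels_and_flags(panel, expr)

  a <- res[res$ec == "A", ]
  expect_equal(a$sum_replete, 60)
  expect_equal(a$sum_depleted, 127)
  expect_equal(a$ratio, 127 / 60)
  expect_true(a$flagged)

  b <- res[res$ec == "B", ]
  expect_equal(b$ratio, 85 / 40)   # 2.125-fold increase
  expect_identical(b$direction, "up")
  expect_true(b$flagged)

  cc <- res[res$ec == "C", ]
  expect_equal(cc$fold, 85 / 40)   # mirrored decrease flags down
  expect_identical(cc$direction, "down")
  expect_true(cc$flagged)
})

test_that("zero summative level yields undefined ratio and no flag", {
  counts <- rbind(c(0, 0, 50, 50), c(5, 5, 5, 5))
  tab <- tiny_table(n = 2, counts = counts)
  tab$fpkm <- counts * 1.0
  colnames(tab$fpkm) <- colnames(tab$counts)
  rownames(tab$fpkm) <- tab$ests$est_id
  expr <- suppressMessages(summarize_expression(tab))
  ec <- term_map(c("A", "B"), c("e01", "e02"), namespace = "EC")
  panel <- group_by_enzyme(tab, ec, c("A", "B"))
  expect_warning(res <- summative_levels_and_flags(panel, expr), "zero")
  expect_true(is.na(res$ratio[res$ec == "A"]))
  expect_false(res$flagged[res$ec == "A"])
})

test_that("splitting an EST across pseudo-copies preserves summative levels", {
  counts <- rbind(c(30, 30, 12, 12), c(18, 18, 40, 40))
  tab <- tiny_table(n = 2, counts = counts)
  tab$fpkm <- counts * 1.0
  colnames(tab$fpkm) <- colnames(tab$counts)
  rownames(tab$fpkm) <- tab$ests$est_id
  ec <- term_map(c("A", "A"), c("e01", "e02"), namespace = "EC")
  panel <- group_by_enzyme(tab, ec, "A")
  whole <- summative_levels_and_flags(panel, summarize_expression(tab))

  # split e01 into two half-level pseudo-ESTs on the same enzyme
  counts2 <- rbind(counts[1, ] / 2, counts[1, ] / 2, counts[2, ])
  tab2 <- tiny_table(n = 3, counts = counts2)
  tab2$fpkm <- counts2 * 1.0
  colnames(tab2$fpkm) <- colnames(tab2$counts)
  rownames(tab2$fpkm) <- tab2$ests$est_id
  ec2 <- term_map(c("A", "A", "A"), c("e01", "e02", "e03"),
                  namespace = "EC")
  panel2 <- group_by_enzyme(tab2, ec2, "A")
  split <- summative_levels_and_flags(panel2, summarize_expression(tab2))
  expect_equal(split$sum_replete, whole$sum_replete)
  expect_equal(split$sum_depleted, whole$sum_depleted)
  expect_equal(split$ratio, whole$ratio)
})

test_that("panel overlap test equals brute-force enumeration on small universes", {
  set.seed(23)
  for (i in 1:6) {
    N_u <- sample(6:12, 1)
    a <- sample(2:(N_u - 1), 1)
    b <- sample(2:(N_u - 1), 1)
    k <- sample(max(0, a + b - N_u):min(a, b), 1)
    res <- panel_overlap_test(N_u, a, b, k)
    expect_equal(res$p_value, overlap_tail_oracle(N_u, a, b, k),
                 tolerance = 1e-12)
  }
})

test_that("panel overlap handles null-centre, forced and impossible overlaps", {
  # overlap at its expectation is unremarkable
  res <- panel_overlap_test(50, 20, 20, k = 8)  # expected 8
  expect_gt(res$p_value, 0.2)
  expect_equal(res$expected, 8)

  # complete forced overlap: p = 1
  expect_equal(panel_overlap_test(10, 10, 10, 10)$p_value, 1)

  expect_error(panel_overlap_test(55, 20, 19, 20), "impossible")
  expect_error(panel_overlap_test(10, 9, 9, 1), "forced minimum")
  expect_error(panel_overlap_test(10, 11, 5, 2), "exceed")
})

test_that("shared-enzyme overlap of the VLCFA panels is significant", {
  # 55 proposed enzymes, 20 detected here, 19 detected previously,
  # 11 shared: exact upper tail (cross-checked against Fisher's exact)
  res <- panel_overlap_test(55, 20, 19, 11)
  fisher <- fisher.test(matrix(c(11, 20 - 11, 19 - 11, 55 - 20 - 19 + 11),
                               2, 2), alternative = "greater")
  expect_equal(res$p_value, fisher$p.value, tolerance = 1e-10)
  expect_lt(res$p_value, 0.05)
})

test_that("per-EST panel reports carry levels, ratios and DE markers", {
  counts <- rbind(c(10, 10, 30, 30), c(50, 50, 10, 10), c(5, 5, 5, 5))
  tab <- tiny_table(n = 3, counts = counts)
  tab$fpkm <- counts * 1.0
  colnames(tab$fpkm) <- colnames(tab$counts)
  rownames(tab$fpkm) <- tab$ests$est_id
  expr <- summarize_expression(tab)
  ec <- term_map(c("A", "A", "B"), c("e01", "e02", "e03"), namespace = "EC")
  panel <- group_by_enzyme(tab, ec, c("A", "B"))
  flags <- structure(list(up = "e01", down = "e02",
                          thresholds = c(2, 0.05), p_values = numeric(0)),
                     class = "de_flags")
  rep <- per_est_panel_report(panel, expr, flags)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$de_flag[rep$est_id == "e01"], "up")
  expect_equal(rep$de_flag[rep$est_id == "e02"], "down")
  expect_equal(rep$de_flag[rep$est_id == "e03"], "")
  expect_equal(rep$ratio[rep$est_id == "e01"], 3)

  empty_panel <- structure(list(panel_name = "x", enzymes = list(),
                                panel_ecs = "Z", n_detected = 0L,
                                copy_number = integer(0)),
                           class = "enzyme_panel")
  expect_equal(nrow(per_est_panel_report(empty_panel, expr)), 0)
})
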