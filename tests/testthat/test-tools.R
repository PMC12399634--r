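test_that("tool_frequencies reproduces category-level proportions", {
  frame <- default_coding_frame()
  # spread 824 environmental / 566 supply / 292 demand references evenly
  # over each category's five sub-tools
  per_cat <- c(environmental = 824L, supply = 566L, demand = 292L)
  counts <- integer(0)
  for (ct in names(per_cat)) {
    subs <- frame$subtool[frame$category == ct]
    base <- per_cat[[ct]] %/% 5L
    cc <- setNames(rep(base, 5), subs)
    cc[1] <- cc[1] + per_cat[[ct]] - sum(cc)
    counts <- c(counts, cc)
  }
  segs <- segments_from_counts(counts)
  rep_ <- tool_frequencies(segs, frame)
  expect_equal(rep_$total, 1682)
  bc <- rep_$by_category
  expect_equal(bc$overall_pct[bc$category == "environmental"], 48.99)
  expect_equal(bc$overall_pct[bc$category == "supply"], 33.65)
  expect_equal(bc$overall_pct[bc$category == "demand"], 17.36)
})

test_that("tool_frequencies counts, proportions and invariants hold", {
  single <- data.frame(doc_id = "D1", subtool = "Pilot Projects")
  r1 <- tool_frequencies(single)
  expect_equal(r1$total, 1)
  expect_equal(r1$by_subtool$overall_pct[r1$by_subtool$subtool ==
                                           "Pilot Projects"], 100)
  expect_equal(r1$by_category$count[r1$by_category$category == "demand"], 1)

  # hand tally on a small fixed multinomial draw
  segs <- data.frame(
    doc_id = c("D1", "D1", "D2", "D2", "D2", "D3"),
    subtool = c("Infrastructure", "Infrastructure", "Goal Planning",
                "Tax Incentives", "Infrastructure", "Goal Planning"),
    stringsAsFactors = FALSE)
  r2 <- tool_frequencies(segs)
  bs <- r2$by_subtool
  expect_equal(bs$count[bs$subtool == "Infrastructure"], 3)
  expect_equal(bs$count[bs$subtool == "Goal Planning"], 2)
  expect_equal(bs$overall_pct[bs$subtool == "Infrastructure"], 50)
  expect_equal(bs$within_category_pct[bs$subtool == "Goal Planning"],
               round_half_up(100 * 2 / 3, 2))
  # category count equals the sum of its sub-tool counts; percentages
  # sum to 100 within rounding slack
  bc <- r2$by_category
  for (ct in bc$category)
    expect_equal(bc$count[bc$category == ct],
                 sum(bs$count[bs$category == ct]))
  expect_equal(sum(bs$overall_pct), 100, tolerance = 0.05)
  used <- bc$category[bc$count > 0]
  for (ct in used)
    expect_equal(sum(bs$within_category_pct[bs$category == ct]), 100,
                 tolerance = 0.05)

  # order invariance
  r3 <- tool_frequencies(segs[sample(nrow(segs)), ])
  expect_equal(r3$by_subtool, r2$by_subtool)

  expect_error(tool_frequencies(data.frame(doc_id = "D1",
                                           subtool = "Nonexistent Tool")),
               "Nonexistent Tool")
})

test_that("category_coverage counts distinct documents once per category", {
  segs <- data.frame(
    doc_id = c("D1", "D2", "D2"),
    subtool = c("Goal Planning", "Goal Planning", "Tax Incentives"),
    stringsAsFactors = FALSE)
  cov <- category_coverage(segs)
  expect_equal(cov[["environmental"]], 2)
  expect_equal(cov[["supply"]], 0)
  expect_equal(cov[["demand"]], 0)

  # planted coverage recovered exactly from a generated fixture
  frame <- default_coding_frame()
  want <- c(environmental = 52L, supply = 50L, demand = 46L)
  segs2 <- do.call(rbind, lapply(names(want), function(ct) {
    data.frame(doc_id = sprintf("D%02d", seq_len(want[[ct]])),
               subtool = frame$subtool[frame$category == ct][1],
               stringsAsFactors = FALSE)
  }))
  expect_equal(category_coverage(segs2, frame)[names(want)], want)
  expect_true(all(category_coverage(segs2, frame) <=
                    length(unique(segs2$doc_id))))
})

test_that("cohen_kappa matches direct formula evaluation", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)

  # 2x2 confusion counts (45, 5, 5, 45)
  a <- rep(c("x", "x", "y", "y"), c(45, 5, 5, 45))
  b <- rep(c("x", "y", "x", "y"), c(45, 5, 5, 45))
  res <- cohen_kappa(a, b)
  expect_equal(res$p_o, 0.90)
  expect_equal(res$p_e, 0.50)
  expect_equal(res$kappa, 0.80)

  expect_error(cohen_kappa(character(0), character(0)), "zero")

  # degenerate identical single-label coders
  expect_equal(cohen_kappa(rep("a", 5), rep("a", 5))$kappa, 1)
})

test_that("kappa is near zero for independent coders", {
  set.seed(1)
  for (s in 1:5) {
    a <- sample(c("supply", "environmental", "demand", "none"), 1000,
                replace = TRUE)
    b <- sample(a)             # independent permutation, same marginals
    expect_lt(abs(cohen_kappa(a, b)$kappa), 0.1)
  }
})

test_that("kappa identities: bounded by one, uniform-marginal relation", {
  set.seed(2)
  for (i in 1:20) {
    n <- 50
    a <- sample(c("u", "v"), n, replace = TRUE)
    b <- sample(c("u", "v"), n, replace = TRUE)
    res <- cohen_kappa(a, b)
    expect_lte(res$kappa, 1)
  }
  # with exactly uniform marginals over C = 2 labels, p_e = 1/2 and
  # kappa = (p_o - 1/2) / (1/2) = 2 p_o - 1
  a <- rep(c("u", "v"), 25)
  b <- c(rep("u", 25), rep("v", 25))
  res <- cohen_kappa(a, b)
  expect_equal(res$p_e, 0.5)
  expect_equal(res$kappa, 2 * res$p_o - 1)
})

test_that("coding_frame rejects duplicate sub-tool names", {
  expect_error(coding_frame(list(a = c("T1", "T2"), b = c("T2"))), "T2")
  frame <- default_coding_frame()
  expect_equal(nrow(frame), 15)
  expect_equal(unname(table(frame$category)[c("supply", "environmental",
                                              "demand")]),
               rep(5L, 3), ignore_attr = TRUE)
})
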