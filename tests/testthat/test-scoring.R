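test_that("gaussian transform matches its closed form", {
  expect_identical(gaussian_pvalue(0, 0.125), 1.0)
  expect_equal(gaussian_pvalue(0.125 * sqrt(2), 0.125), exp(-1),
               tolerance = 1e-12)
  expect_equal(gaussian_pvalue(1, 0.125), exp(-32), tolerance = 1e-9)
  # strictly decreasing in t
  t_grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(gaussian_pvalue(t_grid, 0.125)) < 0))
  expect_error(gaussian_pvalue(1.2, 0.125), "\\[0, 1\\]")
  expect_error(gaussian_pvalue(0.5, -1), "positive")
})

test_that("bandwidth fitting recovers the generating h", {
  # deterministic sample with exceedance exactly exp(-x^2 / 2 h^2)
  n <- 1e4
  p <- (seq_len(n) - 0.5) / n
  for (h in c(0.125, 0.2)) {
    x <- pmin(1, h * sqrt(-2 * log(1 - p)))
    h_hat <- fit_smoothing_factor(x)
    expect_equal(h_hat, h, tolerance = if (h == 0.125) 0.005 else 0.01)
  }
})

test_that("bandwidth fitting rejects degenerate samples", {
  expect_error(fit_smoothing_factor(rep(0, 1000)), "degenerate")
  expect_error(fit_smoothing_factor(stats::runif(50)), "at least 100")
})

test_that("pr_score equals the mean of pairwise p-values", {
  params <- scoring_params()
  q <- make_fp(1:10, "q")
  # two exact copies of the query: both p-values are exp(-32)
  fam <- list(make_fp(1:10, "m1"), make_fp(1:10, "m2"))
  expect_equal(pr_score(q, fam, params), exp(-32), tolerance = 1e-20)
  # hand-built members with p-values 0.2 and 0.4 average to 0.3
  t_for_p <- function(p, h = 0.125) h * sqrt(-2 * log(p))
  expect_equal(mean(gaussian_pvalue(t_for_p(c(0.2, 0.4)), 0.125)), 0.3,
               tolerance = 1e-12)
  expect_error(pr_score(q, list(), params), "no members")
})

test_that("pr_score matches the independent brute-force oracle", {
  set.seed(101)
  params <- scoring_params()
  for (i in 1:300) {
    q <- make_fp(sample.int(300, sample(5:50, 1)), "q")
    members <- lapply(seq_len(sample(1:15, 1)), function(j) {
      make_fp(sample.int(300, sample(5:50, 1)), paste0("m", j))
    })
    got <- pr_score(q, members, params)
    want <- oracle_pr_score(q$features,
                            lapply(members, function(m) m$features),
                            params$h)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pr_score is monotone in member similarity and invariant to duplication", {
  params <- scoring_params()
  q <- make_fp(1:20, "q")
  far <- make_fp(101:120, "far")
  near <- make_fp(c(1:15, 101:105), "near")
  base <- list(make_fp(c(1:10, 201:210), "m"))
  expect_gt(pr_score(q, c(base, list(far)), params),
            pr_score(q, c(base, list(near)), params))
  # duplicating every member leaves the mean unchanged
  fam <- list(near, far)
  expect_equal(pr_score(q, c(fam, fam), params), pr_score(q, fam, params),
               tolerance = 1e-15)
})

test_that("gaussian_pvalue of tanimoto is symmetric in its molecules", {
  set.seed(77)
  for (i in 1:50) {
    a <- make_fp(sample.int(80, sample(3:30, 1)))
    b <- make_fp(sample.int(80, sample(3:30, 1)))
    expect_identical(gaussian_pvalue(tanimoto(a, b), 0.125),
                     gaussian_pvalue(tanimoto(b, a), 0.125))
  }
})

test_that("predict_targets ranks the matching family first", {
  params <- scoring_params()
  # family A: clones of the query; B and C: far away
  fps <- list(q = make_fp(1:20, "q"),
              a1 = make_fp(1:20, "a1"), a2 = make_fp(1:20, "a2"),
              b1 = make_fp(101:125, "b1"), b2 = make_fp(101:126, "b2"),
              c1 = make_fp(201:230, "c1"))
  fams <- family_set(list(
    new_family("A", c("a1", "a2"), stage = "refined", parent_id = "A0"),
    new_family("B", c("b1", "b2"), stage = "refined", parent_id = "B0"),
    new_family("C", "c1", stage = "refined", parent_id = "C0")
  ))
  preds <- predict_targets(fps$q, fams, fps, params)
  expect_equal(preds$family_id[1], "A")
  expect_equal(preds$pr_score[1], exp(-32), tolerance = 1e-20)
  expect_true(all(preds$pr_score[-1] > 0.5))
  expect_equal(preds$rank, seq_len(nrow(preds)))
  expect_equal(preds$significant, preds$pr_score <= params$alpha)
  expect_equal(sum(preds$significant), 1)
})

test_that("predict_targets excludes the query from its own family", {
  params <- scoring_params()
  fps <- list(q = make_fp(1:20, "q"), a = make_fp(c(1:15, 31:35), "a"),
              b = make_fp(41:70, "b"))
  fams <- family_set(list(
    new_family("FA", c("q", "a"), stage = "filtered"),
    new_family("FB", c("q", "b"), stage = "filtered"),
    new_family("FQ", "q", stage = "filtered")
  ))
  preds <- predict_targets(fps$q, fams, fps, params)
  # FQ emptied by self-exclusion: omitted and reported
  expect_false("FQ" %in% preds$family_id)
  expect_equal(attr(preds, "omitted"), "FQ")
  # FA scored against {a} only
  expect_equal(preds$pr_score[preds$family_id == "FA"],
               gaussian_pvalue(tanimoto(fps$q, fps$a), params$h))
  # without self-exclusion the query's own fingerprint dominates
  preds2 <- predict_targets(fps$q, fams, fps, params, exclude_self = FALSE)
  expect_equal(preds2$pr_score[preds2$family_id == "FQ"], exp(-32),
               tolerance = 1e-20)
})

test_that("known activity is annotated from activity records", {
  params <- scoring_params()
  fps <- list(q = make_fp(1:20, "q"), a = make_fp(c(1:18, 31:32), "a"),
              b = make_fp(41:70, "b"))
  fams <- family_set(list(
    new_family("FA.c1", "a", stage = "refined", parent_id = "FA"),
    new_family("FB", "b", stage = "filtered")
  ))
  activities <- rbind(act_row("q", "FA", "IC50", 1, "uM"),
                      act_row("q", "FB", "IC50", 900, "uM"))
  preds <- predict_targets(fps$q, fams, fps, params, activities = activities)
  expect_equal(preds$known_activity[preds$family_id == "FA.c1"], "active")
  expect_equal(preds$known_activity[preds$family_id == "FB"], "inactive")
})

test_that("scoring parameter validation rejects impossible values", {
  expect_error(scoring_params(h = 0), "positive")
  expect_error(scoring_params(alpha = 1), "\\(0, 1\\)")
})
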