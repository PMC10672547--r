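test_that("perfect separation gives AUC 1 and a Youden cutoff between the classes", {
  r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  cut <- youden_cutoff(r)
  expect_equal(cut$J, 1)
  expect_gt(cut$cutoff, 2)
  expect_lt(cut$cutoff, 3)
  expect_equal(cut$orientation, "high")
})

test_that("an uninformative marker gives AUC 0.5 and J 0", {
  r <- roc_curve(rep(2.5, 10), c(rep(0, 5), rep(1, 5)))
  expect_equal(r$auc, 0.5)
  expect_equal(youden_cutoff(r)$J, 0)
})

test_that("AUC equals the pairwise Mann-Whitney statistic to 1e-12", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    marker <- sample(seq(0, 5, by = 0.5), n, replace = TRUE) # force ties
    event <- rbinom(n, 1, 0.4)
    if (sum(event) == 0 || sum(event) == n) next
    r <- roc_curve(marker, event)
    expect_equal(r$auc, auc_pairwise_oracle(marker, event),
                 tolerance = 1e-12)
  }
})

test_that("youden_cutoff matches exhaustive search over all thresholds", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(8:60, 1)
    marker <- round(stats::rnorm(n, mean = 2), sample(0:2, 1))
    event <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(event) == 0 || sum(event) == n) next
    cut <- youden_cutoff(roc_curve(marker, event))
    expect_equal(cut$J, youden_exhaustive_oracle(marker, event),
                 tolerance = 1e-12)
    expect_gte(cut$J, 0)
  }
})

test_that("relabeling events flips orientation but preserves |J|", {
  set.seed(303)
  marker <- stats::rnorm(60)
  event <- as.integer(marker + stats::rnorm(60, sd = 0.8) > 0)
  c1 <- youden_cutoff(roc_curve(marker, event))
  c2 <- youden_cutoff(roc_curve(marker, 1L - event))
  expect_equal(c1$J, c2$J, tolerance = 1e-12)
  expect_false(c1$orientation == c2$orientation)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  marker <- c(stats::rnorm(40, 1), stats::rnorm(40))
  event <- rep(c(1, 0), each = 40)
  ours <- roc_curve(marker, event)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(event, marker, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("dichotomize keeps the boundary value in the lower group and flags empty groups", {
  g <- dichotomize(c(10, 21.1, 25), 21.1)
  expect_equal(as.character(g), c("low", "low", "high"))
  expect_warning(dichotomize(c(1, 2, 3), 10), "empty group")
  expect_error(dichotomize(c(1, 2), Inf), "finite")
})

test_that("single-class labels are an analysis error", {
  expect_error(roc_curve(c(1, 2, 3), c(1, 1, 1)), "both classes")
})
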