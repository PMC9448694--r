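test_that("Pearson correlation and regression fit agree with closed forms", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(a, rep(1, 4)), "variance")
  fit <- regression_fit(a, 2 * a + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  # independence: R^2 near zero in simulation
  with_seed(1, {
    x <- rnorm(5000); y <- rnorm(5000)
    expect_lt(regression_fit(x, y)$r_squared, 0.01)
    # identity R^2 = r^2 for the simple linear fit
    u <- rnorm(100); v <- u + rnorm(100)
    expect_equal(regression_fit(u, v)$r_squared, pearson_r(u, v)^2,
                 tolerance = 1e-12)
  })
})

test_that("Q-Q pairs compare matched empirical quantiles", {
  a <- with_seed(2, rnorm(500))
  qq <- qq_pairs(a, sample(a))          # same values, any order
  expect_equal(qq$qa, qq$qb)
  expect_equal(qq$prob, (1:100 - 0.5) / 100)
  qq_shift <- qq_pairs(a, a + 10)
  expect_equal(qq_shift$qb - qq_shift$qa, rep(10, 100))
  # two large samples from one distribution: small, shrinking gap
  with_seed(3, {
    gap_n <- function(n) max(abs({q <- qq_pairs(rnorm(n), rnorm(n)); q$qa - q$qb}))
    expect_lt(gap_n(10000), 0.15)
  })
  expect_error(qq_pairs(numeric(0), a), "empty")
})

test_that("confusion matrix, sensitivity and specificity match a manual tally", {
  truth <- c("awake", "awake", "moderate", "moderate", "moderate",
             "deep", "deep", "deep", "deep", "awake")
  pred  <- c("awake", "moderate", "moderate", "moderate", "deep",
             "deep", "deep", "moderate", "deep", "awake")
  rep_ <- classification_report(truth, pred)
  expect_equal(sum(rep_$confusion), 10)
  expect_equal(rep_$accuracy, 7 / 10)
  expect_equal(unname(rep_$sensitivity["awake"]), 2 / 3)
  expect_equal(unname(rep_$sensitivity["moderate"]), 2 / 3)
  expect_equal(unname(rep_$sensitivity["deep"]), 3 / 4)
  # specificity of "awake": TN = 7 non-awake truths, none predicted awake
  expect_equal(unname(rep_$specificity["awake"]), 1)
  # marginals are the label histograms
  expect_equal(as.integer(rowSums(rep_$confusion)), c(3L, 3L, 4L))
  expect_equal(as.integer(colSums(rep_$confusion)),
               as.integer(table(factor(pred, state_levels()))))
  # degenerate predictor: accuracy equals the predicted class prevalence
  all_mod <- classification_report(truth, rep("moderate", 10))
  expect_equal(all_mod$accuracy, 3 / 10)
  # perfect prediction
  expect_equal(classification_report(truth, truth)$accuracy, 1)
  expect_error(classification_report(truth, c(pred[-10], "asleep")), "level")
})

test_that("RMSE is the root mean squared difference", {
  a <- c(1, 2, 3)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 4), 4)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(a, 1:4), "length")
})

test_that("metrics are invariant to common reordering of the pairs", {
  with_seed(4, {
    a <- runif(200, 0, 100); b <- pmin(pmax(a + rnorm(200, sd = 8), 0), 100)
    perm <- sample(200)
    expect_equal(pearson_r(a, b), pearson_r(a[perm], b[perm]))
    expect_equal(rmse(a, b), rmse(a[perm], b[perm]))
    r1 <- classification_report(classify_state(a), classify_state(b))
    r2 <- classification_report(classify_state(a[perm]), classify_state(b[perm]))
    expect_equal(r1$confusion, r2$confusion)
  })
})

test_that("the pooled report populates every metric and drops blank pairs", {
  with_seed(5, {
    ref <- runif(300, 0, 100)
    pred <- pmin(pmax(ref + rnorm(300, sd = 5), 0), 100)
    ref[50:60] <- NA                       # blanked reference span
    rep_ <- evaluate_index(pred, ref)
    expect_equal(rep_$n, 289)
    expect_equal(rep_$n_dropped, 11)
    expect_true(is.finite(rep_$pearson_r) && rep_$pearson_r > 0.9)
    expect_true(is.finite(rep_$rmse))
    expect_equal(rep_$r_squared, rep_$pearson_r^2, tolerance = 1e-12)
    expect_equal(nrow(rep_$qq), 100)
    expect_equal(sum(rep_$confusion), 289)
    path <- withr::local_tempfile(fileext = ".json")
    write_report_json(rep_, path)
    js <- jsonlite::read_json(path)
    expect_equal(js$pearson_r, rep_$pearson_r, tolerance = 1e-12)
    expect_equal(js$accuracy, rep_$accuracy, tolerance = 1e-12)
  })
})
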