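toy_table <- function(counts, seed = 1) {
  set.seed(seed)
  labs <- rep(names(counts), counts)
  data.table::data.table(label = labs,
                         volume_cc = rlnorm(sum(counts), log(0.15), 0.8))
}

test_that("465 regions at the study's class mix split 279/93/93", {
  tab <- toy_table(c("GP3" = 242, "GP4Crib-" = 176, "GP4Crib+" = 47))
  out <- split_dataset(tab, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(sum(out$split == "train"), 279)
  expect_equal(sum(out$split == "validation"), 93)
  expect_equal(sum(out$split == "test"), 93)
  # per-class proportions preserved to +/- 1 region
  for (lb in unique(tab$label)) {
    n <- sum(tab$label == lb)
    for (s in c("train", "validation", "test")) {
      frac <- c(train = 0.6, validation = 0.2, test = 0.2)[[s]]
      got <- sum(out$label == lb & out$split == s)
      expect_lte(abs(got - n * frac), 1)
    }
  }
})

test_that("exact-divisibility splits and purity under reruns", {
  tab <- toy_table(c("GP3" = 10))
  out <- split_dataset(tab, c(0.6, 0.2, 0.2), seed = 3)
  expect_equal(unname(table(out$split)[c("train", "validation", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  out2 <- split_dataset(tab, c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(out$split, out2$split)
  out3 <- split_dataset(tab, c(0.6, 0.2, 0.2), seed = 4)
  expect_false(identical(out$split, out3$split))
})

test_that("volume distributions are balanced across splits", {
  tab <- toy_table(c("GP3" = 300), seed = 5)
  out <- split_dataset(tab, seed = 6)
  meds <- tapply(out$volume_cc, out$split, median)
  expect_lt((max(meds) - min(meds)) / min(meds), 0.25)
})

test_that("logistic fit recovers known coefficients (weak penalty)", {
  set.seed(7)
  n <- 5000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x1"))
  eta <- 1.0 - 2.0 * x[, 1]
  y <- rbinom(n, 1, plogis(eta))
  m <- fit_logistic(x, y, C = 1e6, max_iter = 500, class_weight = NULL)
  expect_lt(abs(m$intercept - 1.0) / 1.0, 0.1)
  expect_lt(abs(m$coefficients[["x1"]] + 2.0) / 2.0, 0.1)
  # independent cross-check: unpenalised ML via stats::glm
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(m$intercept, unname(coef(g)[1]), tolerance = 1e-2)
  expect_equal(unname(m$coefficients[1]), unname(coef(g)[2]),
               tolerance = 1e-2)
})

test_that("class weighting and separation behave as specified", {
  # equal class counts: balanced weights are both exactly 1
  y <- rep(c(0, 1), 10)
  w <- cribromics:::balanced_class_weights(y)
  expect_equal(unname(w), c(1, 1))
  y2 <- c(rep(0, 30), rep(1, 10))
  w2 <- cribromics:::balanced_class_weights(y2)
  expect_equal(unname(w2), c(40 / 60, 40 / 20))
  # two well-separated clusters: coefficient sign follows cluster order
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "x1"))
  yy <- rep(c(0, 1), each = 20)
  expect_warning(m <- fit_logistic(x, yy, C = 1e6, max_iter = 5,
                                   tol = 1e-14),
                 "iteration cap")
  expect_gt(m$coefficients[["x1"]], 0)
  expect_error(fit_logistic(x, rep(1, 40)), "both classes")
})

test_that("predicted probabilities follow the logistic formula", {
  m <- logistic_model(1.96, c(adc90 = -1.74))
  # the published boundary value gives P very close to 0.5
  expect_equal(predict_probability(m, c(adc90 = 1.13)), 0.5,
               tolerance = 0.01)
  expect_equal(predict_probability(m, c(adc90 = 0)), 1 / (1 + exp(-1.96)),
               tolerance = 1e-12)
  # zero weights: P = 0.5 whatever the input
  m0 <- logistic_model(0, c(adc90 = 0))
  expect_equal(predict_probability(m0, c(adc90 = 123)), 0.5)
  expect_error(predict_probability(m, c(other = 1)), "adc90")
  # monotone decreasing in the feature (negative coefficient)
  xs <- data.frame(adc90 = seq(0, 3, by = 0.1))
  expect_true(all(diff(predict_probability(m, xs)) < 0))
  # labels at the 0.5 threshold
  expect_equal(predict_label(m, data.frame(adc90 = c(0.5, 2))), c(1L, 0L))
})

test_that("the 1D decision boundary is -w0/w1", {
  expect_equal(decision_boundary_1d(logistic_model(1.96, c(f = -1.74))),
               1.96 / 1.74, tolerance = 1e-12)
  expect_equal(round(decision_boundary_1d(
    logistic_model(1.96, c(f = -1.74))), 2), 1.13)
  expect_equal(decision_boundary_1d(logistic_model(0, c(f = -3))), 0)
  expect_equal(decision_boundary_1d(logistic_model(2, c(f = -4))), 0.5)
  expect_error(decision_boundary_1d(logistic_model(1, c(f = 0))), "zero")
  expect_error(decision_boundary_1d(logistic_model(1, c(a = 1, b = 2))),
               "one feature")
})

cv_table <- function(n = 120, informative = TRUE, seed = 11) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.25)
  sig <- if (informative) y * 3 else 0
  tab <- data.table::data.table(
    label = ifelse(y == 1, "GP4Crib+", "GP3"),
    volume_cc = rlnorm(n, log(0.15), 0.5),
    target = y,
    fsig = sig + rnorm(n, 0, 0.3),
    fnoise1 = rnorm(n), fnoise2 = rnorm(n), fnoise3 = rnorm(n))
  split_dataset(tab, seed = seed)
}

test_that("CV selects one feature when only one carries signal", {
  tab <- cv_table(informative = TRUE)
  r <- mrmr_rank(as.matrix(tab[tab$split == "train",
                               c("fsig", "fnoise1", "fnoise2", "fnoise3"),
                               with = FALSE]),
                 tab$target[tab$split == "train"])
  expect_equal(r$features[1], "fsig")
  sel <- suppressWarnings(select_feature_count_cv(tab, r, k_max = 4, seed = 1))
  expect_equal(sel$k, 1)
  # k_max larger than the candidate count is capped
  sel2 <- suppressWarnings(select_feature_count_cv(tab, r, k_max = 50, seed = 1))
  expect_lte(nrow(sel2$trace), 4)
})

test_that("all-noise features give chance-level CV balanced accuracy", {
  tab <- cv_table(informative = FALSE, seed = 13)
  r <- mrmr_rank(as.matrix(tab[tab$split == "train",
                               c("fsig", "fnoise1", "fnoise2", "fnoise3"),
                               with = FALSE]),
                 tab$target[tab$split == "train"])
  sel <- suppressWarnings(select_feature_count_cv(tab, r, k_max = 4, seed = 2))
  expect_lt(max(abs(sel$trace$cv_balanced_accuracy - 0.5)), 0.2)
})
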