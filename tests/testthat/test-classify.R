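test_that("naive Bayes fitting matches hand-computed moments", {
  x <- data.frame(f = c(0, 1, 2, 3))
  y <- c("A", "A", "B", "B")
  m <- fit_naive_bayes(x, y)
  expect_equal(m$stats$A$prior, 0.5)
  expect_equal(m$stats$B$prior, 0.5)
  expect_equal(unname(m$stats$A$mean), 0.5)
  expect_equal(unname(m$stats$B$mean), 2.5)
  expect_equal(unname(m$stats$A$var), 0.25)  # population variance, n = 2
  expect_equal(unname(m$stats$B$var), 0.25)

  # single class -> prior 1
  m1 <- fit_naive_bayes(data.frame(f = 1:3), rep("only", 3))
  expect_equal(m1$stats$only$prior, 1)

  # constant feature within a class stays finite via the variance floor
  m2 <- fit_naive_bayes(data.frame(f = c(5, 5, 1, 2)), c("A", "A", "B", "B"))
  expect_gt(m2$stats$A$var, 0)
  p <- predict_class(m2, c(f = 5))
  expect_true(all(is.finite(as.numeric(p[c("A", "B")]))))
  expect_error(fit_naive_bayes(data.frame(f = numeric(0)), character(0)),
               "empty")
})

test_that("posteriors are normalized, symmetric at the midpoint, and match the oracle", {
  m <- fit_naive_bayes(data.frame(f = c(0, 1, 2, 3)), c("A", "A", "B", "B"))
  p <- predict_class(m, c(f = 1.5))
  expect_equal(p$A, 0.5, tolerance = 1e-12)
  expect_equal(p$B, 0.5, tolerance = 1e-12)
  expect_equal(p$class, "A")  # tie goes to the first declared class
  p2 <- predict_class(m, c(f = 0.5))
  expect_equal(p2$class, "A")
  expect_gt(p2$A, 0.99)

  set.seed(42)
  for (rep in 1:10) {
    n <- 30
    x <- matrix(rnorm(n * 4, sd = 3), n, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- sample(c("c1", "c2", "c3"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
    if (length(unique(y)) < 3) next
    mod <- fit_naive_bayes(x, y)
    xnew <- rnorm(4, sd = 3); names(xnew) <- paste0("f", 1:4)
    got <- as.numeric(predict_class(mod, xnew)[mod$classes])
    want <- unname(oracle_nb_posterior(mod, xnew))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
  expect_error(predict_class(m, c(f = NaN)), "non-finite.*'f'")
  expect_error(predict_class(m, c(g = 1)), "missing feature")
})

test_that("fitting recovers known class Gaussians and ignores row order", {
  set.seed(7)
  n <- 10000
  y <- rep(c("A", "B"), each = n / 2)
  x <- data.frame(f = c(rnorm(n / 2, 2, 1), rnorm(n / 2, -1, 2)))
  m <- fit_naive_bayes(x, y)
  se_a <- 1 / sqrt(n / 2); se_b <- 2 / sqrt(n / 2)
  expect_lt(abs(m$stats$A$mean - 2), 3 * se_a)
  expect_lt(abs(m$stats$B$mean + 1), 3 * se_b)
  perm <- sample(n)
  m2 <- fit_naive_bayes(x[perm, , drop = FALSE], y[perm])
  expect_equal(m2$stats$A$mean, m$stats$A$mean, tolerance = 1e-12)
  expect_equal(m2$stats$B$var, m$stats$B$var, tolerance = 1e-12)
})

test_that("cross-validation is deterministic, perfect on separated classes, chance on noise", {
  set.seed(1)
  x <- data.frame(f = c(rnorm(20, -10), rnorm(20, 10)))
  y <- rep(c("lo", "hi"), each = 20)
  cv <- cross_validate(x, y, k = 20, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$n_correct + cv$n_incorrect, 40)
  cv2 <- cross_validate(x, y, k = 20, seed = 3)
  expect_identical(cv[c("accuracy", "confusion", "fold_assignments")],
                   cv2[c("accuracy", "confusion", "fold_assignments")])

  # permuted labels, 3 balanced classes: chance level ~ 1/3
  accs <- vapply(1:50, function(s) {
    set.seed(s + 200)
    xp <- data.frame(f1 = rnorm(48), f2 = rnorm(48))
    yp <- sample(rep(c("a", "b", "c"), 16))
    cross_validate(xp, yp, k = 12, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.1)

  # stratification keeps every fold's class mix near the global mix
  yq <- rep(c("a", "b"), c(30, 10))
  folds <- vapply(1:10, function(i) 0, numeric(1))
  cvq <- cross_validate(data.frame(f = rnorm(40)), yq, k = 10, seed = 1)
  tab <- table(cvq$fold_assignments, yq)
  expect_true(all(tab[, "a"] == 3) && all(tab[, "b"] == 1))
  expect_error(cross_validate(data.frame(f = 1:3), c("a", "b", "a"), k = 5),
               "k exceeds")
})

test_that("best-first selection recovers a planted feature and matches exhaustive search", {
  set.seed(9)
  n <- 60
  y <- rep(c("a", "b", "c"), each = n / 3)
  x <- data.frame(inf = c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 6)),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                  n4 = rnorm(n), n5 = rnorm(n))
  sel <- select_features_best_first(x, y, k = 10, seed = 2)
  expect_true("inf" %in% sel$selected_features)
  expect_gte(sel$score, sel$baseline_score)

  # all-noise: selected score stays near the majority-class rate
  set.seed(10)
  xn <- data.frame(n1 = rnorm(45), n2 = rnorm(45))
  yn <- sample(rep(c("a", "b", "c"), 15))
  seln <- select_features_best_first(xn, yn, k = 9, seed = 4)
  expect_lt(seln$score, 1 / 3 + 0.25)

  # equals exhaustive search on small instances
  for (s in 1:6) {
    set.seed(s + 50)
    ne <- 30
    ye <- rep(c("a", "b"), each = 15)
    xe <- data.frame(matrix(rnorm(ne * 4), ne, 4))
    xe$f_good <- ifelse(ye == "a", 0, 2) + rnorm(ne, sd = 0.8)
    feats <- names(xe)
    best_ex <- 0
    for (sz in 1:length(feats)) {
      for (cmb in utils::combn(feats, sz, simplify = FALSE)) {
        a <- cross_validate(xe, ye, features = cmb, k = 10, seed = 1)$accuracy
        if (a > best_ex) best_ex <- a
      }
    }
    sel_bf <- select_features_best_first(xe, ye, k = 10, seed = 1)
    expect_equal(sel_bf$score, best_ex)
  }
})

test_that("training-table accuracy beats the largest prior on separable data", {
  set.seed(3)
  x <- data.frame(f = c(rnorm(30, 0, 0.5), rnorm(10, 6, 0.5)))
  y <- rep(c("big", "small"), c(30, 10))
  m <- fit_naive_bayes(x, y)
  acc <- mean(predict_class(m, x)$class == y)
  expect_gte(acc, 30 / 40)
})
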