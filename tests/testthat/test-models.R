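test_that("builtin discriminant models carry the published coefficients verbatim", {
  eq2 <- builtin_model("eq2_raw")
  expect_equal(eq2$intercept, -1.6772)
  expect_equal(unname(eq2$terms["Dose03"]), 0.1204)
  expect_equal(unname(eq2$terms["pod"]), 0.0112)
  expect_equal(eq2$ref_coef, 0)
  expect_equal(eq2$n_train, 2446L)
  expect_equal(eq2$chi_sq, 222.839)

  eq3 <- builtin_model("eq3_ma")
  expect_equal(eq3$intercept, 17.04)
  expect_equal(eq3$ref_coef, -34.04)
  expect_equal(unname(eq3$terms["d.Dose01.TypeCat"]), 0.6244)
  expect_equal(unname(eq3$terms["d.pdw.ClotGeneCat"]), -0.2648)
  expect_equal(eq3$chi_sq, 2919.95)

  eq4 <- builtin_model("eq4_ed")
  expect_equal(eq4$intercept, 17.81)
  expect_equal(eq4$ref_coef, -34.83)
  expect_equal(unname(eq4$terms["ed.Diclofenac.PKGeneCat"]), 40.92)
  expect_equal(eq4$chi_sq, 2952.951)
  expect_error(builtin_model("eq5"), "arg")
})

zero_row <- function(model) {
  cols <- c(if (model$ref_coef != 0) "f_ref", names(model$terms))
  tibble::as_tibble(as.list(stats::setNames(rep(0, length(cols)), cols)))
}

test_that("linear scoring is the stated affine form", {
  for (nm in c("eq2_raw", "eq3_ma", "eq4_ed")) {
    m <- builtin_model(nm)
    expect_equal(score_linear(zero_row(m), m)$score, m$intercept)
  }
  # f_ref = 0.5, all deviations zero
  m3 <- builtin_model("eq3_ma")
  row <- zero_row(m3); row$f_ref <- 0.5
  expect_equal(score_linear(row, m3)$score, 17.04 - 34.04 * 0.5)

  # random feature vectors agree with a by-hand dot product to 1e-12
  withr::with_seed(99, {
    for (nm in c("eq2_raw", "eq3_ma", "eq4_ed")) {
      m <- builtin_model(nm)
      row <- zero_row(m)
      row[] <- lapply(row, function(x) stats::rnorm(1))
      hand <- m$intercept +
        (if (m$ref_coef != 0) m$ref_coef * row$f_ref else 0) +
        sum(m$terms * unlist(row[names(m$terms)]))
      expect_equal(score_linear(row, m)$score, hand, tolerance = 1e-12)
    }
  })
  expect_equal(score_linear(zero_row(builtin_model("eq2_raw")),
                            builtin_model("eq2_raw"))$class, "Out")
})

test_that("scoring refuses missing terms and level mismatches", {
  m <- builtin_model("eq3_ma")
  row <- zero_row(m)
  row$d.Dose01.TypeCat <- NULL
  expect_error(score_linear(row, m), "d\\.Dose01\\.TypeCat")

  cases <- fixture_cases()
  means <- fit_group_means(cases)
  edfeats <- build_features(cases, means, cases, pt_config("ed"))
  expect_error(score_linear(edfeats, m), "level")
})

make_two_class <- function(n = 100, sep = 10, p_noise = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("Out", "Within"), each = n / 2)
    df <- tibble::tibble(
      x = stats::rnorm(n, ifelse(y == "Within", sep / 2, -sep / 2), 1),
      output_class = y
    )
    if (p_noise > 0) {
      for (j in seq_len(p_noise)) df[[paste0("z", j)]] <- stats::rnorm(n)
    }
    attr(df, "feature_names") <- setdiff(names(df), "output_class")
    df
  })
}

test_that("LDA separates well-separated classes and orients the score", {
  df <- make_two_class(n = 200, sep = 10)
  m <- fit_lda(df, lambda = 1e-8)
  expect_gt(unname(m$terms["x"]), 0)
  sc <- score_linear(df, m)
  expect_equal(mean(sc$class == df$output_class), 1.0)
  expect_equal(m$n_train, 200L)
  expect_gt(m$chi_sq, 100)
  expect_error(fit_lda(df[df$output_class == "Out", ]), "single class")
})

test_that("LDA training accuracy under label shuffling matches prevalence", {
  df <- make_two_class(n = 200, sep = 0, p_noise = 1)
  accs <- withr::with_seed(7, vapply(1:20, function(i) {
    d <- df
    d$output_class <- sample(d$output_class)
    m <- fit_lda(d)
    mean(score_linear(d, m)$class == d$output_class)
  }, numeric(1)))
  prev <- 0.5
  se <- sqrt(prev * (1 - prev) / 200)
  expect_lt(abs(mean(accs) - prev), 3 * se)
})

test_that("LDA drops constant and duplicated feature columns", {
  df <- make_two_class(n = 100, sep = 4)
  df$const <- 1
  df$x_copy <- df$x
  attr(df, "feature_names") <- c("x", "const", "x_copy")
  expect_warning(expect_warning(m <- fit_lda(df), "constant"), "duplicated")
  expect_setequal(names(m$terms), "x")
})

test_that("the LDA boundary is invariant to affine feature rescaling", {
  df <- make_two_class(n = 200, sep = 3, p_noise = 2, seed = 3)
  m1 <- fit_lda(df, lambda = 1e-10)
  df2 <- df
  df2$x <- 100 * df$x + 7
  m2 <- fit_lda(df2, lambda = 1e-10)
  s1 <- score_linear(df, m1)$score
  s2 <- score_linear(df2, m2)$score
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("fit_lda agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  df <- make_two_class(n = 300, sep = 2, p_noise = 3, seed = 5)
  cols <- attr(df, "feature_names")
  m <- fit_lda(df, lambda = 1e-12)
  ref <- MASS::lda(as.matrix(df[cols]), grouping = df$output_class)
  # discriminant directions are proportional
  w <- c(m$terms[cols])
  v <- ref$scaling[cols, 1]
  cosang <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
  expect_equal(cosang, 1, tolerance = 1e-6)
  # and the implied classifications agree
  sc <- score_linear(df, m)$class
  pc <- as.character(stats::predict(ref, as.matrix(df[cols]))$class)
  expect_equal(sc, pc)
})

test_that("forward stepwise finds the informative feature and honours the expert set", {
  hits <- withr::with_seed(31, vapply(1:20, function(i) {
    n <- 500
    y <- rep(c("Out", "Within"), each = n / 2)
    df <- tibble::tibble(signal = stats::rnorm(n, ifelse(y == "Within", 1, -1), 1))
    for (j in 1:20) df[[paste0("noise", j)]] <- stats::rnorm(n)
    df$output_class <- y
    attr(df, "feature_names") <- setdiff(names(df), "output_class")
    sel <- forward_stepwise(df)
    length(sel) > 0 && sel[1] == "signal"
  }, logical(1)))
  expect_gte(sum(hits), 18L)

  df <- make_two_class(n = 100, sep = 0, p_noise = 3)
  expect_equal(forward_stepwise(df, p_enter = 0), character(0))
  sel <- forward_stepwise(df, expert_set = "z1", p_enter = 0)
  expect_equal(sel, "z1")  # zero-effect expert variable still forced in
  expect_error(forward_stepwise(df, expert_set = "nope"), "nope")
})

test_that("score calibration is a monotone logistic map", {
  withr::with_seed(13, {
    scores <- stats::rnorm(400)
    labels <- ifelse(stats::runif(400) < stats::plogis(2 * scores),
                     "Within", "Out")
  })
  cal <- fit_calibration(scores, labels)
  p <- posterior_probability(cal, c(-50, -1, 0, 1, 50))
  expect_true(all(diff(p) >= 0))
  expect_lt(p[1], 0.01)
  expect_gt(p[5], 0.99)
  mid <- -cal$coef[1] / cal$coef[2]
  expect_equal(unname(posterior_probability(cal, mid)), 0.5)
  expect_error(posterior_probability(list(), 0), "fit_calibration")
})

test_that("tidy and glance summarise linear models", {
  m <- builtin_model("eq3_ma")
  td <- tidy(m)
  expect_equal(td$term[1:2], c("(Intercept)", "f_ref"))
  expect_equal(td$estimate[1:2], c(17.04, -34.04))
  expect_equal(nrow(td), 11)
  gl <- glance(m)
  expect_equal(gl$n_train, 2446L)
  expect_equal(gl$level, "ma")
})

test_that("ML adapters fit, predict and leave the features untouched", {
  cases <- fixture_cases(n = 60, seed = 77)
  means <- fit_group_means(cases)
  f <- build_features(cases, means, cases, pt_config("raw"))
  before <- rlang::hash(as.data.frame(f))

  # 1-NN regression on its own distinct training rows is exact
  fit1 <- fit_ml(f, ml_spec("regression", "KNN", seed = 1, k = 1))
  expect_equal(predict(fit1, f), f$inr)

  # RF with a fixed seed refits identically
  fit2a <- fit_ml(f, ml_spec("regression", "RF", seed = 9, ntree = 50))
  fit2b <- fit_ml(f, ml_spec("regression", "RF", seed = 9, ntree = 50))
  expect_equal(predict(fit2a, f), predict(fit2b, f))

  # SVM separates a linearly separable fixture perfectly in training
  df <- make_two_class(n = 80, sep = 8)
  df$case_id <- as.character(1:80); df$inr <- 2
  fit3 <- fit_ml(df, ml_spec("classification", "SVM", seed = 2,
                             kernel = "linear"))
  expect_equal(mean(predict(fit3, df) == df$output_class), 1.0)

  expect_equal(rlang::hash(as.data.frame(f)), before)
  expect_error(ml_spec("regression", "NaiveBayes"), "task")
  expect_error(ml_spec("classification", "LR"), "task")
})

test_that("the remaining battery members run on both tasks they support", {
  cases <- fixture_cases(n = 80, seed = 15)
  means <- fit_group_means(cases)
  f <- build_features(cases, means, cases, pt_config("ma",
                                                     f_ref_min_size = 1L))
  for (alg in c("LR", "MLP", "Bagging")) {
    fit <- fit_ml(f, ml_spec("regression", alg, seed = 3))
    expect_length(predict(fit, f), nrow(f))
  }
  for (alg in c("LDA", "Logistic", "NaiveBayes", "KNN", "RF")) {
    fit <- suppressWarnings(fit_ml(f, ml_spec("classification", alg,
                                              seed = 3, k = 3)))
    p <- predict(fit, f)
    expect_true(all(p %in% c("Within", "Out")))
  }
})
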