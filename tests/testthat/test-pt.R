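test_that("presets map to the documented hyperparameter triples", {
  raw <- pt_config("raw"); ma <- pt_config("ma"); ed <- pt_config("ed")
  expect_equal(c(raw$alpha, raw$q, raw$r), c(0, 1, 1))
  expect_equal(c(ma$alpha, ma$q, ma$r), c(1, 1, 1))
  expect_equal(c(ed$alpha, ed$q, ed$r), c(1, 2, 0.5))
  expect_error(pt_config("ma", alpha = 0.5), "alpha")
})

test_that("group means are per-label training means with a global back-off column", {
  cases <- fixture_cases()
  means <- fit_group_means(cases)
  gm <- means$group_means
  # hand check one cell
  sel <- cases$surgery_type == "MVR"
  expect_equal(gm$mean[gm$partition == "TypeCat" & gm$label == "MVR" &
                         gm$variable == "Dose01"],
               mean(cases$Dose01[sel]))
  expect_equal(gm$n[gm$partition == "TypeCat" & gm$label == "MVR" &
                      gm$variable == "Dose01"][1], sum(sel))
  expect_equal(means$global_means$mean[means$global_means$variable == "age"],
               mean(cases$age))
  # every observed (partition, label) pair present
  expect_setequal(unique(gm$label[gm$partition == "PKGeneCat"]),
                  unique(cases$CYP2C9))
  expect_error(fit_group_means(cases[0, ]), "empty")
})

test_that("first-order deviations centre each training group at zero", {
  cases <- fixture_cases()
  means <- fit_group_means(cases)
  D <- pt_first_order(cases, means, "TypeCat", pt_config("ma"))
  for (lab in unique(cases$surgery_type)) {
    expect_lt(max(abs(colSums(D[cases$surgery_type == lab, , drop = FALSE]))),
              1e-9)
  }
  # alpha = 0 reduces to the raw variables
  D0 <- pt_first_order(cases, means, "TypeCat", pt_config("raw"))
  expect_equal(D0[, "Dose01"], cases$Dose01, ignore_attr = TRUE)
})

test_that("unseen labels back off to the global mean", {
  cases <- fixture_cases()
  means <- fit_group_means(cases)
  new <- cases[1, ]
  new$surgery_type <- "TVR"  # never observed in the fixture
  D <- pt_first_order(new, means, "TypeCat", pt_config("ma"))
  expect_equal(D[1, "age"],
               new$age - means$global_means$mean[
                 means$global_means$variable == "age"],
               ignore_attr = TRUE)
})

test_that("second-order distances satisfy the norm identities", {
  ed <- pt_config("ed")
  expect_equal(pt_second_order(c(a = 3, b = 4), c("a", "b"), ed), 5)
  expect_equal(pt_second_order(c(a = 0, b = 0), c("a", "b"), ed), 0)
  expect_equal(pt_second_order(c(a = -2), "a", ed), 2)
  expect_error(pt_second_order(c(a = 1), character(0), ed), "empty")
  expect_error(pt_second_order(c(a = 1), c("a", "zz"), ed), "zz")
})

test_that("the reference prior estimates conditional prevalence with back-off", {
  scheme <- partition_scheme(partitions = c(PKGeneCat = "CYP2C9"),
                             variable_groups = list(), window = 1L)
  train <- tibble::tibble(
    case_id = as.character(1:8),
    CYP2C9 = rep(c("*1/*1", "*1/*3"), c(4, 4)),
    inr = rep(2, 8),
    output_class = c("Within", "Within", "Within", "Out",
                     "Out", "Out", "Out", "Within")
  )
  attr(train, "scheme") <- scheme
  class(train) <- c("ptml_cases", class(train))
  cfg <- pt_config("ma", f_ref_mode = "joint", f_ref_min_size = 1L)
  f <- reference_function(train, train, cfg)
  expect_equal(f[1], 0.75)
  expect_equal(f[5], 0.25)
  # back-off: unseen label vector falls back to the global prevalence
  new <- train[1, ]; new$CYP2C9 <- "*2/*2"
  expect_equal(reference_function(train, new, cfg), 0.5)
  # min-size back-off
  cfg10 <- pt_config("ma", f_ref_min_size = 10L)
  expect_equal(reference_function(train, train, cfg10), rep(0.5, 8))
  # all-Within training data give probability 1
  train2 <- train; train2$output_class <- "Within"
  expect_equal(reference_function(train2, train2, cfg)[1], 1.0)
  expect_error(reference_function(train[0, ], train, cfg), "no training")
})

test_that("feature tables have the documented shape per level", {
  cases <- fixture_cases()
  means <- fit_group_means(cases)
  raw <- build_features(cases, means, cases, pt_config("raw"))
  expect_equal(feature_names(raw), means$global_means$variable)
  expect_equal(raw$Dose01, cases$Dose01)  # identity reduction

  ma <- build_features(cases, means, cases, pt_config("ma"))
  # 2 partitions x 5 variables + f_ref
  expect_length(feature_names(ma), 2 * 5 + 1)
  expect_equal(feature_names(ma)[1], "f_ref")
  expect_true(all(ma$f_ref >= 0 & ma$f_ref <= 1))

  ed <- build_features(cases, means, cases, pt_config("ed"))
  expect_length(feature_names(ed), 2 * 2 + 1)  # 2 partitions x 2 groups + f_ref
  E <- as.matrix(ed[setdiff(feature_names(ed), "f_ref")])
  expect_true(all(E >= 0))
})

test_that("ed with singleton groups equals |delta| of the ma level", {
  cases <- fixture_cases()
  scheme <- attr(cases, "scheme")
  scheme$variable_groups <- list(Dose01 = "Dose01", age = "age")
  attr(cases, "scheme") <- scheme
  means <- fit_group_means(cases)
  ma <- build_features(cases, means, cases, pt_config("ma"))
  ed <- build_features(cases, means, cases, pt_config("ed"))
  expect_equal(ed$ed.Dose01.TypeCat, abs(ma$d.Dose01.TypeCat))
  expect_equal(ed$ed.age.PKGeneCat, abs(ma$d.age.PKGeneCat))
})

test_that("a naive per-case double loop reproduces the table-wide transform", {
  cases <- fixture_cases(n = 30)
  scheme <- attr(cases, "scheme")
  means <- fit_group_means(cases)
  cfg <- pt_config("ma", f_ref_min_size = 1L)
  ma <- build_features(cases, means, cases, cfg)
  ed <- build_features(cases, means, cases,
                       pt_config("ed", f_ref_min_size = 1L))
  vars <- means$global_means$variable
  gm <- means$group_means
  for (i in seq_len(nrow(cases))) {
    # naive f_ref: prevalence among cases sharing the full label vector
    match_i <- cases$surgery_type == cases$surgery_type[i] &
      cases$CYP2C9 == cases$CYP2C9[i]
    expect_equal(ma$f_ref[i], mean(cases$output_class[match_i] == "Within"))
    for (pname in names(scheme$partitions)) {
      lab <- as.character(cases[[scheme$partitions[[pname]]]][i])
      for (v in vars) {
        mu <- gm$mean[gm$partition == pname & gm$label == lab &
                        gm$variable == v]
        expect_equal(ma[[sprintf("d.%s.%s", v, pname)]][i],
                     cases[[v]][i] - mu)
      }
      for (g in names(scheme$variable_groups)) {
        members <- scheme$variable_groups[[g]]
        d2 <- sum(vapply(members, function(v) {
          mu <- gm$mean[gm$partition == pname & gm$label == lab &
                          gm$variable == v]
          (cases[[v]][i] - mu)^2
        }, numeric(1)))
        expect_equal(ed[[sprintf("ed.%s.%s", g, pname)]][i], sqrt(d2))
      }
    }
  }
})

test_that("refitting means on the centred columns yields zero (idempotent centering)", {
  cases <- fixture_cases()
  means <- fit_group_means(cases)
  ma <- build_features(cases, means, cases, pt_config("ma"))
  # per (partition, label): the deviation column of that partition re-averages to 0
  for (pname in c("TypeCat", "PKGeneCat")) {
    col <- attr(cases, "scheme")$partitions[[pname]]
    for (lab in unique(cases[[col]])) {
      idx <- cases[[col]] == lab
      dcols <- grep(sprintf("\\.%s$", pname), names(ma), value = TRUE)
      expect_lt(max(abs(colMeans(ma[idx, dcols]))), 1e-9)
    }
  }
})

test_that("fitted group means serialise to JSON and back", {
  cases <- fixture_cases()
  means <- fit_group_means(cases)
  path <- withr::local_tempfile(fileext = ".json")
  write_group_means(means, path)
  back <- read_group_means(path)
  expect_equal(as.data.frame(back$group_means),
               as.data.frame(means$group_means))
  expect_equal(back$fitted_on, means$fitted_on)
  ma1 <- build_features(cases, means, cases, pt_config("ma"))
  ma2 <- build_features(cases, back, cases, pt_config("ma"))
  expect_equal(as.data.frame(ma1), as.data.frame(ma2))
})
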