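#' Construct a linear IFPTML scoring model
#'
#' A linear model here is a discriminant scoring function
#' `score = a0 + a1 * f_ref + sum_k a_k * feature_k` over a feature table
#' of a stated data level; `score > 0` classifies a case as `Within`.
#'
#' @param intercept Intercept `a0`.
#' @param ref_coef Coefficient `a1` of the reference prior `f_ref`
#'   (0 for raw-level models, which carry no reference prior term).
#' @param terms Named numeric vector: feature name -> coefficient.
#' @param level Data level the terms resolve against (`raw`/`ma`/`ed`).
#' @param n_train,chi_sq,source Optional fit metadata.
#' @return An object of class `ptml_linear_model`.
#' @seealso [builtin_model()], [score_linear()], [fit_lda()]
#' @export
linear_model <- function(intercept, ref_coef = 0, terms = numeric(),
                         level = c("raw", "ma", "ed"),
                         n_train = NA_integer_, chi_sq = NA_real_,
                         source = "user") {
  level <- match.arg(level)
  terms <- unlist(terms)
  stopifnot(is.numeric(intercept), is.numeric(ref_coef),
            all(is.finite(c(intercept, ref_coef, terms))))
  m <- list(intercept = intercept, ref_coef = ref_coef, terms = terms,
            level = level, n_train = n_train, chi_sq = chi_sq,
            source = source)
  class(m) <- "ptml_linear_model"
  m
}

#' Built-in fitted discriminant models for the three data levels
#'
#' Reference coefficient sets of the linear Within/Out discriminant fitted
#' on a 246-patient cardiac-surgery warfarin cohort (2446 training cases),
#' one per data level: `eq2_raw` scores raw variables (day-3 dose,
#' postoperative day, co-medications, neutrophil fraction, plateletcrit,
#' albumin), `eq3_ma` scores first-order deviations plus the reference
#' prior, and `eq4_ed` scores group Euclidean distances plus the
#' reference prior. Term names are mapped into this package's feature
#' namespace (e.g. `d.Dose01.TypeCat`, `ed.Probiotics.VKPKGeneCat`); drug
#' tokens use the generic names (cefuroxime for cefuroxime sodium, hdl_chol
#' for high-density cholesterol, pdw for platelet distribution width,
#' albumin for human albumin).
#'
#' @param name One of `"eq2_raw"`, `"eq3_ma"`, `"eq4_ed"`.
#' @return A `ptml_linear_model` with the published coefficients verbatim.
#' @export
#' @examples
#' m <- builtin_model("eq3_ma")
#' m$intercept
builtin_model <- function(name = c("eq2_raw", "eq3_ma", "eq4_ed")) {
  name <- match.arg(name)
  switch(name,
    eq2_raw = linear_model(
      intercept = -1.6772,
      ref_coef = 0,
      terms = c(Dose03 = 0.1204, pod = 0.0112,
                cefoperazone = 0.1188, ceftriaxone = 0.9305,
                ticarcillin = 0.1086, tigecycline = 12.84,
                spironolactone = 9.82, neutrophil = -0.0644,
                plateletcrit = 2.264, albumin = -0.019),
      level = "raw", n_train = 2446L, chi_sq = 222.839,
      source = "builtin eq2_raw"),
    eq3_ma = linear_model(
      intercept = 17.04,
      ref_coef = -34.04,
      terms = c(d.Dose01.TypeCat = 0.6244,
                d.cefuroxime.TypeCat = -1.137,
                d.Dose01.PKGeneCat = -0.5472,
                d.bifidobacterium.PKGeneCat = -6.191,
                d.albumin.VKPKGeneCat = -0.162,
                d.cefuroxime.NRGeneCat = 0.8073,
                d.hdl_chol.NRGeneCat = -1.585,
                d.Dose03.ClotGeneCat = 0.3398,
                d.pdw.ClotGeneCat = -0.2648),
      level = "ma", n_train = 2446L, chi_sq = 2919.95,
      source = "builtin eq3_ma"),
    eq4_ed = linear_model(
      intercept = 17.81,
      ref_coef = -34.83,
      terms = c(ed.Dose.TypeCat = 0.115,
                ed.Diuretic.TypeCat = -0.1031,
                ed.Diuretic.PKGeneCat = -0.1314,
                ed.Aspirin.PKGeneCat = 10.93,
                ed.Diclofenac.PKGeneCat = 40.92,
                ed.Blood_cell_count.PKGeneCat = -0.0104,
                ed.DEMO.PDGeneCat = -0.069,
                ed.DEMO.VKPKGeneCat = 0.0302,
                ed.Probiotics.VKPKGeneCat = -0.6514),
      level = "ed", n_train = 2446L, chi_sq = 2952.951,
      source = "builtin eq4_ed"))
}

#' Score cases with a linear model
#'
#' Computes `a0 + a1 * f_ref + sum a_k * feature_k` for every row. Every
#' model term must be present in `features`; a missing term is an error,
#' never a silent zero. The classification decision is `score > 0 ->
#' Within`.
#'
#' @param features A `ptml_features` table (or any data frame with the
#'   model's term columns, plus `f_ref` when `ref_coef != 0`).
#' @param model A `ptml_linear_model`.
#' @return Tibble with `case_id` (if present), `score`, `class`.
#' @export
#' @examples
#' m <- builtin_model("eq2_raw")
#' row <- tibble::as_tibble(as.list(stats::setNames(
#'   rep(0, length(m$terms)), names(m$terms))))
#' score_linear(row, m)$score  # the intercept
score_linear <- function(features, model) {
  stopifnot(inherits(model, "ptml_linear_model"))
  lvl <- feature_level(features)
  if (!is.null(lvl) && lvl != model$level) {
    rlang::abort(sprintf("model level `%s` does not match feature level `%s`.",
                         model$level, lvl))
  }
  needed <- names(model$terms)
  if (model$ref_coef != 0) needed <- c("f_ref", needed)
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    rlang::abort(sprintf("feature table lacks model term(s): %s",
                         paste(missing, collapse = ", ")))
  }
  score <- rep(model$intercept, nrow(features))
  if (model$ref_coef != 0) score <- score + model$ref_coef * features$f_ref
  if (length(model$terms)) {
    score <- score +
      as.vector(as.matrix(features[names(model$terms)]) %*% model$terms)
  }
  tibble::tibble(
    case_id = if ("case_id" %in% names(features)) features$case_id else
      as.character(seq_along(score)),
    score = score,
    class = ifelse(score > 0, "Within", "Out")
  )
}

#' Fit a two-class linear discriminant on a feature table
#'
#' Classic two-class LDA with pooled within-class covariance: the
#' discriminant direction is `w = S^-1 (mu_Within - mu_Out)` and the
#' intercept centres the boundary between the class means with a
#' log-prior offset. The pooled covariance is ridge-regularised with
#' `lambda * mean(diag(S))` added to the diagonal (escalated tenfold up
#' to 1e-2 if the solve fails), so near-collinear perturbation features
#' remain fittable. Constant features are dropped with a warning;
#' duplicated feature columns keep only their first copy. The fitted
#' object records the training size and Bartlett's chi-square of the
#' discriminant (from Wilks' lambda via Hotelling's T^2).
#'
#' @param features A `ptml_features` table with an `output_class` column,
#'   or a plain data frame of predictors when `labels` is given.
#' @param labels Optional character/factor vector of `Within`/`Out`.
#' @param lambda Ridge fraction of the mean covariance diagonal.
#' @param columns Optional subset of feature columns to use.
#' @return A `ptml_linear_model` (level taken from `features`).
#' @export
fit_lda <- function(features, labels = features$output_class,
                    lambda = 1e-6, columns = NULL) {
  cols <- columns %||% feature_names(features)
  y <- as.character(labels)
  if (length(unique(y)) < 2L) {
    rlang::abort("training data contain a single class.")
  }
  X <- as.matrix(features[cols])
  keep <- apply(X, 2L, function(c) stats::sd(c) > 0)
  if (any(!keep)) {
    rlang::warn(sprintf("dropping constant feature(s): %s",
                        paste(utils::head(cols[!keep], 5), collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  dup <- duplicated(t(X))
  if (any(dup)) {
    rlang::warn(sprintf("dropping duplicated feature column(s): %s",
                        paste(utils::head(colnames(X)[dup], 5),
                              collapse = ", ")))
    X <- X[, !dup, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) {
    rlang::abort("more features than cases; reduce the feature set.")
  }
  w_idx <- y == "Within"
  n1 <- sum(w_idx); n0 <- n - n1
  mu1 <- colMeans(X[w_idx, , drop = FALSE])
  mu0 <- colMeans(X[!w_idx, , drop = FALSE])
  S1 <- stats::cov(X[w_idx, , drop = FALSE])
  S0 <- stats::cov(X[!w_idx, , drop = FALSE])
  S <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n - 2)
  ridge <- lambda * mean(diag(S))
  w <- NULL
  lam <- ridge
  repeat {
    w <- tryCatch(solve(S + diag(lam, p), mu1 - mu0), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    lam <- max(lam, .Machine$double.eps) * 10
    if (lam > 1e-2 * mean(diag(S)) + 1e-8) {
      rlang::abort("pooled covariance could not be stably inverted.")
    }
  }
  a0 <- -sum(w * (mu1 + mu0)) / 2 + log(n1 / n0)
  d2 <- sum((mu1 - mu0) * w)  # Mahalanobis distance^2 (ridge metric)
  t2 <- (n1 * n0 / n) * d2
  wilks <- 1 / (1 + t2 / (n - 2))
  chi_sq <- -(n - 1 - (p + 2) / 2) * log(wilks)
  ref_coef <- if ("f_ref" %in% names(w)) unname(w[["f_ref"]]) else 0
  terms <- w[setdiff(names(w), "f_ref")]
  linear_model(intercept = a0, ref_coef = ref_coef, terms = terms,
               level = feature_level(features) %||% "raw",
               n_train = n, chi_sq = chi_sq, source = "fit_lda")
}

#' Forward-stepwise feature selection with a forced expert set
#'
#' Greedy forward selection for the two-class discriminant: the expert
#' set is always included; remaining candidates are added by largest
#' F-to-enter (partial F of the candidate in a linear model of the 0/1
#' class indicator on the current selection) while its p-value is below
#' `p_enter`. Ties break deterministically by column order.
#'
#' @param features Feature table.
#' @param labels `Within`/`Out` labels (default `features$output_class`).
#' @param expert_set Feature names always included.
#' @param p_enter Entry threshold on the F-test p-value.
#' @param max_terms Cap on the number of selected features.
#' @return Character vector of selected feature names (expert set first).
#' @export
forward_stepwise <- function(features, labels = features$output_class,
                             expert_set = character(), p_enter = 0.05,
                             max_terms = Inf) {
  cols <- feature_names(features)
  bad <- setdiff(expert_set, cols)
  if (length(bad)) {
    rlang::abort(sprintf("expert_set name(s) not in feature namespace: %s",
                         paste(bad, collapse = ", ")))
  }
  y <- as.numeric(as.character(labels) == "Within")
  X <- as.matrix(features[cols])
  selected <- expert_set
  candidates <- setdiff(cols, expert_set)
  rss <- function(sel) {
    Z <- cbind(1, X[, sel, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    sum(fit$residuals^2)
  }
  rss_cur <- rss(selected)
  while (length(candidates) > 0 && length(selected) < max_terms) {
    rss_new <- vapply(candidates, function(v) rss(c(selected, v)), numeric(1))
    df2 <- length(y) - length(selected) - 2L
    f <- (rss_cur - rss_new) / (rss_new / df2)
    best <- which.max(f)  # first max: deterministic tie-break by column order
    p <- stats::pf(f[best], 1, df2, lower.tail = FALSE)
    if (!is.finite(p) || p >= p_enter) break
    selected <- c(selected, candidates[best])
    rss_cur <- rss_new[best]
    candidates <- candidates[-best]
  }
  selected
}

#' Calibrate discriminant scores to posterior probabilities
#'
#' Fits a logistic link of the training labels on the training scores;
#' `posterior_probability()` then maps any score monotonically into
#' [0, 1].
#'
#' @param scores Numeric training scores.
#' @param labels Training `Within`/`Out` labels.
#' @return An object of class `ptml_calibration`.
#' @export
fit_calibration <- function(scores, labels) {
  y <- as.numeric(as.character(labels) == "Within")
  fit <- stats::glm(y ~ scores, family = stats::binomial())
  structure(list(coef = stats::coef(fit)), class = "ptml_calibration")
}

#' @rdname fit_calibration
#' @param calibration A fitted `ptml_calibration`.
#' @param scores Scores to map.
#' @return Numeric vector of probabilities.
#' @export
posterior_probability <- function(calibration, scores) {
  if (!inherits(calibration, "ptml_calibration")) {
    rlang::abort("`calibration` must be fitted with fit_calibration().")
  }
  eta <- calibration$coef[1] + calibration$coef[2] * scores
  stats::plogis(eta)
}

#' @export
print.ptml_linear_model <- function(x, ...) {
  cat(sprintf("<ptml_linear_model> level=%s, %d terms (%s)\n",
              x$level, length(x$terms), x$source))
  cat(sprintf("  score = %.4g%s + ...\n", x$intercept,
              if (x$ref_coef != 0) sprintf(" %+.4g*f_ref", x$ref_coef) else ""))
  if (!is.na(x$n_train)) {
    cat(sprintf("  n_train = %d, chi^2 = %.6g\n", x$n_train, x$chi_sq))
  }
  invisible(x)
}

#' Tidy a linear IFPTML model
#' @param x A `ptml_linear_model`.
#' @param ... Unused.
#' @return Tibble with one row per model term (intercept and reference
#'   prior included).
#' @export
tidy.ptml_linear_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)",
             if (x$ref_coef != 0) "f_ref",
             names(x$terms)),
    estimate = c(x$intercept,
                 if (x$ref_coef != 0) x$ref_coef,
                 unname(x$terms))
  )
}

#' @rdname tidy.ptml_linear_model
#' @export
glance.ptml_linear_model <- function(x, ...) {
  tibble::tibble(level = x$level, n_terms = length(x$terms),
                 n_train = x$n_train, chi_sq = x$chi_sq, source = x$source)
}
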