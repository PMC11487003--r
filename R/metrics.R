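#' Split a case table into training and validation sets
#'
#' `mode = "case"` samples rows uniformly, with a training size of
#' `round(fraction * N)`; `mode = "patient"` assigns whole patients to one
#' side (sampling `round(fraction * n_patients)` patients into training),
#' which avoids the optimistic bias of splitting correlated visits of one
#' patient across both sides. Deterministic for a given seed.
#'
#' @param cases A `ptml_cases` table.
#' @param fraction Training fraction, in (0, 1).
#' @param mode `"case"` or `"patient"`.
#' @param seed Integer seed (required: the split is a stochastic step).
#' @return Named list with `train` and `validation` tables.
#' @export
#' @examples
#' # round(0.75 * 3261) == 2446
split_train_validation <- function(cases, fraction = 0.75,
                                   mode = c("case", "patient"), seed) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  idx <- withr::with_seed(seed, {
    if (mode == "case") {
      n_train <- round(fraction * nrow(cases))
      seq_len(nrow(cases)) %in% sample.int(nrow(cases), n_train)
    } else {
      ids <- unique(cases$patient_id)
      n_train <- round(fraction * length(ids))
      cases$patient_id %in% sample(ids, n_train)
    }
  })
  if (!any(idx) || all(idx)) {
    rlang::abort("split leaves one side empty; adjust `fraction`.")
  }
  scheme <- attr(cases, "scheme")
  list(train = new_cases(cases[idx, ], scheme),
       validation = new_cases(cases[!idx, ], scheme))
}

#' Regression metrics: correlation, MAE, RMSE, RAE, RRSE
#'
#' Pearson correlation between observed and predicted values; mean
#' absolute error; root mean square error; relative absolute error
#' `100 * sum|e| / sum|obs - mean(obs)|` and root relative squared error
#' `100 * sqrt(sum e^2 / sum (obs - mean(obs))^2)` (both in %, with the
#' normaliser taken from the same evaluation set).
#'
#' @param obs,pred Numeric vectors of equal length >= 2.
#' @return A one-row tibble of class `ptml_reg_metrics` with columns
#'   `corr`, `mae`, `rmse`, `rae`, `rrse`, `n`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(2, 2, 2))  # RAE = RRSE = 100
regression_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  if (stats::sd(obs) == 0) {
    rlang::abort("`obs` is constant: correlation, RAE and RRSE are undefined.")
  }
  e <- pred - obs
  dev <- obs - mean(obs)
  out <- tibble::tibble(
    # constant predictions have no defined correlation; report NA quietly
    corr = if (stats::sd(pred) == 0) NA_real_ else stats::cor(obs, pred),
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    rae = 100 * sum(abs(e)) / sum(abs(dev)),
    rrse = 100 * sqrt(sum(e^2) / sum(dev^2)),
    n = length(obs)
  )
  class(out) <- c("ptml_reg_metrics", class(out))
  out
}

#' Predicted bias and its three bins
#'
#' `predicted_bias()` returns `PB = 100 * (pred - obs) / obs` (%); a
#' prediction is "ideal" when it falls in the closed middle band
#' `-20 <= PB <= 20`. `pb_bins()` tabulates the percentage of cases in
#' the bands `PB < -20`, `-20 <= PB <= 20` and `PB > 20`.
#'
#' @param obs Observed INR values, all > 0.
#' @param pred Predicted values.
#' @return `predicted_bias()`: numeric vector (%). `pb_bins()`: one-row
#'   tibble `pb_low`, `pb_ideal`, `pb_high` (percentages summing to 100).
#' @export
#' @examples
#' predicted_bias(2.0, 2.2)  # +10, ideal
predicted_bias <- function(obs, pred) {
  if (any(obs <= 0)) rlang::abort("observed values must be positive.")
  100 * (pred - obs) / obs
}

#' @rdname predicted_bias
#' @export
pb_bins <- function(obs, pred) {
  pb <- predicted_bias(obs, pred)
  n <- length(pb)
  tibble::tibble(
    pb_low = 100 * sum(pb < -20) / n,
    pb_ideal = 100 * sum(pb >= -20 & pb <= 20) / n,
    pb_high = 100 * sum(pb > 20) / n
  )
}

#' Classification metrics for the Within/Out task
#'
#' Per-class TPR, FPR, precision, recall, F-measure and (when scores are
#' supplied) ROC area, with each class in turn taken as positive; overall
#' accuracy (%), sensitivity `Sn` (TPR of Within), specificity `Sp` (TNR
#' of Within) and the chi-square of the 2x2 confusion table (1 df, no
#' continuity correction).
#'
#' @param obs,pred Character vectors of `Within`/`Out` labels.
#' @param scores Optional numeric scores oriented towards `Within` (used
#'   for ROC areas; omitted when absent).
#' @return A list of class `ptml_class_metrics`: tibbles `per_class` and
#'   `overall`.
#' @export
classification_metrics <- function(obs, pred, scores = NULL) {
  obs <- as.character(obs); pred <- as.character(pred)
  bad <- setdiff(unique(c(obs, pred)), c("Within", "Out"))
  if (length(bad)) {
    rlang::abort(sprintf("labels outside {Within, Out}: %s",
                         paste(bad, collapse = ", ")))
  }
  per_class <- dplyr::bind_rows(lapply(c("Out", "Within"), function(pos) {
    tp <- sum(obs == pos & pred == pos)
    fn <- sum(obs == pos & pred != pos)
    fp <- sum(obs != pos & pred == pos)
    tn <- sum(obs != pos & pred != pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tibble::tibble(
      class = pos,
      tpr = rec,
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      precision = prec,
      recall = rec,
      f_measure = if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
        2 * prec * rec / (prec + rec)
      } else NA_real_,
      roc_area = if (!is.null(scores) && length(unique(obs)) == 2) {
        s <- if (pos == "Within") scores else -scores
        as.numeric(pROC::auc(pROC::roc(
          response = obs, predictor = s, levels = c(
            setdiff(c("Within", "Out"), pos), pos),
          direction = "<", quiet = TRUE)))
      } else NA_real_
    )
  }))
  tab <- table(factor(obs, c("Out", "Within")),
               factor(pred, c("Out", "Within")))
  chi <- if (all(dim(tab) == 2) && all(rowSums(tab) > 0) &&
             all(colSums(tab) > 0)) {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  } else NA_real_
  overall <- tibble::tibble(
    accuracy = 100 * mean(obs == pred),
    sn = 100 * per_class$tpr[per_class$class == "Within"],
    sp = 100 * (1 - per_class$fpr[per_class$class == "Within"]),
    chi_sq = unname(chi),
    n = length(obs)
  )
  structure(list(per_class = per_class, overall = overall),
            class = "ptml_class_metrics")
}

#' @export
print.ptml_class_metrics <- function(x, ...) {
  cat("<ptml_class_metrics>\n")
  print(x$per_class)
  print(x$overall)
  invisible(x)
}

#' Univariate screening of every input variable against both outputs
#'
#' Advisory screen run before modelling: each continuous variable is
#' tested against the continuous INR output (Pearson correlation) and the
#' Within/Out class (Wilcoxon rank-sum); each categorical label column is
#' tested against the INR (Mann-Whitney for 2 levels, Kruskal-Wallis for
#' more) and against the class (Pearson chi-square). Variables with a
#' single distinct value are flagged as degenerate, not tested. The
#' report never drops variables itself: expert-selected variables stay in
#' the model regardless of their p-value.
#'
#' @param cases A labelled `ptml_cases` table.
#' @param alpha Significance threshold (flag only).
#' @return Tibble: `variable`, `role`, `outcome`, `test`, `statistic`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
univariate_screen <- function(cases, alpha = 0.05) {
  scheme <- cases_scheme(cases)
  cont <- intersect(registered_continuous(scheme), names(cases))
  cats <- intersect(unname(scheme$partitions), names(cases))
  rows <- list()
  add <- function(variable, role, outcome, test, statistic, p, degenerate) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      variable = variable, role = role, outcome = outcome, test = test,
      statistic = statistic, p_value = p,
      significant = !is.na(p) & p < alpha, degenerate = degenerate)
  }
  y_cont <- cases$inr
  y_cat <- cases$output_class
  for (vn in cont) {
    x <- cases[[vn]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      add(vn, "continuous", "inr", "pearson", NA_real_, NA_real_, TRUE)
      add(vn, "continuous", "class", "wilcoxon", NA_real_, NA_real_, TRUE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(x, y_cont))
    add(vn, "continuous", "inr", "pearson",
        unname(ct$estimate), ct$p.value, FALSE)
    wt <- suppressWarnings(stats::wilcox.test(x ~ factor(y_cat)))
    add(vn, "continuous", "class", "wilcoxon",
        unname(wt$statistic), wt$p.value, FALSE)
  }
  for (vn in cats) {
    x <- factor(cases[[vn]])
    if (nlevels(droplevels(x)) < 2L) {
      add(vn, "categorical", "inr", "kruskal", NA_real_, NA_real_, TRUE)
      add(vn, "categorical", "class", "chisq", NA_real_, NA_real_, TRUE)
      next
    }
    if (nlevels(droplevels(x)) == 2L) {
      kt <- suppressWarnings(stats::wilcox.test(y_cont ~ droplevels(x)))
      add(vn, "categorical", "inr", "mann-whitney",
          unname(kt$statistic), kt$p.value, FALSE)
    } else {
      kt <- stats::kruskal.test(y_cont ~ droplevels(x))
      add(vn, "categorical", "inr", "kruskal",
          unname(kt$statistic), kt$p.value, FALSE)
    }
    ch <- suppressWarnings(stats::chisq.test(table(x, y_cat)))
    add(vn, "categorical", "class", "chisq",
        unname(ch$statistic), ch$p.value, FALSE)
  }
  dplyr::bind_rows(rows)
}
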