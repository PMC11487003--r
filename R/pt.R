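#' Perturbation-theory operator configuration
#'
#' The general operator applies, per continuous variable and categorical
#' partition, `(v_k - alpha * <v_k(s)>)^q` and aggregates variable groups
#' as `(sum_k delta_k^q)^r`. Three presets correspond to the three data
#' levels of the analysis: `raw` (alpha = 0, q = 1, r = 1: untransformed
#' variables), `ma` (alpha = 1, q = 1, r = 1: first-order deviations from
#' the group moving average) and `ed` (alpha = 1, q = 2, r = 1/2:
#' second-order Euclidean distances over variable groups).
#'
#' @param level Preset name, one of `"raw"`, `"ma"`, `"ed"`.
#' @param alpha,q,r Hyperparameters; defaults follow the preset. `alpha`
#'   switches the moving-average centering off (0) or on (1), `q` is the
#'   moment power and `r` the distance power.
#' @param min_group_size Minimum training-group size before the group mean
#'   backs off to the global mean (default 1: any observed label is used).
#' @param f_ref_mode Conditioning set of the reference prior: `"joint"`
#'   (full label vector), `"partition"` (one partition, see
#'   `f_ref_partition`), or `"global"` (overall prevalence).
#' @param f_ref_min_size Minimum matching training count before the
#'   reference prior backs off to the global prevalence.
#' @param f_ref_partition Partition used when `f_ref_mode = "partition"`.
#' @return An object of class `pt_config`.
#' @export
#' @examples
#' pt_config("ed")
pt_config <- function(level = c("ma", "raw", "ed"),
                      alpha = NULL, q = NULL, r = NULL,
                      min_group_size = 1L,
                      f_ref_mode = c("joint", "partition", "global"),
                      f_ref_min_size = 10L,
                      f_ref_partition = NULL) {
  level <- match.arg(level)
  preset <- switch(level,
                   raw = c(alpha = 0, q = 1, r = 1),
                   ma  = c(alpha = 1, q = 1, r = 1),
                   ed  = c(alpha = 1, q = 2, r = 0.5))
  cfg <- list(
    level = level,
    alpha = alpha %||% preset[["alpha"]],
    q = q %||% preset[["q"]],
    r = r %||% preset[["r"]],
    min_group_size = as.integer(min_group_size),
    f_ref_mode = match.arg(f_ref_mode),
    f_ref_min_size = as.integer(f_ref_min_size),
    f_ref_partition = f_ref_partition
  )
  stopifnot(cfg$alpha %in% c(0, 1), cfg$q > 0, cfg$r > 0,
            cfg$min_group_size >= 1L)
  class(cfg) <- "pt_config"
  cfg
}

#' @export
print.pt_config <- function(x, ...) {
  cat(sprintf("<pt_config> level=%s (alpha=%g, q=%g, r=%g), f_ref=%s\n",
              x$level, x$alpha, x$q, x$r, x$f_ref_mode))
  invisible(x)
}

#' Fit group moving averages on a training case table
#'
#' For every (partition, label, continuous variable) triple observed in
#' the training table, stores the mean of the variable over training
#' cases carrying that label, together with the group size; global means
#' are stored per variable for back-off. Means are fitted on the training
#' table only and frozen, so validation or prediction rows are always
#' transformed with training-time expectations (no leakage).
#'
#' @param train A `ptml_cases` training table (imputed, no `NA` among
#'   registered variables).
#' @param scheme Scheme; defaults to the one attached to `train`.
#' @return An object of class `ptml_group_means`: list with tibbles
#'   `group_means` (partition, label, variable, mean, n) and
#'   `global_means` (variable, mean), plus `fitted_on` and the scheme.
#' @export
fit_group_means <- function(train, scheme = cases_scheme(train)) {
  if (nrow(train) == 0) rlang::abort("training table is empty.")
  vars <- intersect(registered_continuous(scheme), names(train))
  X <- as.matrix(train[vars])
  if (anyNA(X)) {
    rlang::abort("training table has missing values; run impute_missing() first.")
  }
  gm <- vector("list", length(scheme$partitions))
  for (i in seq_along(scheme$partitions)) {
    pname <- names(scheme$partitions)[i]
    col <- scheme$partitions[[i]]
    if (!col %in% names(train)) {
      rlang::abort(sprintf("partition label column `%s` absent from table.", col))
    }
    lab <- as.character(train[[col]])
    sums <- rowsum(X, lab)
    n <- as.vector(table(lab)[rownames(sums)])
    means <- sums / n
    gm[[i]] <- tibble::tibble(
      partition = pname,
      label = rep(rownames(means), times = ncol(means)),
      variable = rep(colnames(means), each = nrow(means)),
      mean = as.vector(means),
      n = rep(n, times = ncol(means))
    )
  }
  out <- list(
    group_means = dplyr::bind_rows(gm),
    global_means = tibble::tibble(variable = vars,
                                  mean = unname(colMeans(X))),
    fitted_on = nrow(train),
    scheme = scheme
  )
  class(out) <- "ptml_group_means"
  out
}

#' @export
print.ptml_group_means <- function(x, ...) {
  cat(sprintf("<ptml_group_means> %d partitions x %d variables, fitted on %d cases\n",
              length(unique(x$group_means$partition)),
              nrow(x$global_means), x$fitted_on))
  invisible(x)
}

#' Serialise fitted group means to JSON
#' @param means A `ptml_group_means`.
#' @param path File path.
#' @return `read_group_means()` returns a `ptml_group_means`.
#' @export
write_group_means <- function(means, path) {
  sch <- unclass(means$scheme)
  sch$partitions <- as.list(sch$partitions)  # keep names through JSON
  jsonlite::write_json(
    list(group_means = means$group_means,
         global_means = means$global_means,
         fitted_on = means$fitted_on,
         scheme = sch),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_group_means
#' @export
read_group_means <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    group_means = tibble::as_tibble(x$group_means),
    global_means = tibble::as_tibble(x$global_means),
    fitted_on = x$fitted_on,
    scheme = partition_scheme(
      partitions = unlist(x$scheme$partitions),
      variable_groups = lapply(x$scheme$variable_groups, unlist),
      extra_continuous = unlist(x$scheme$extra_continuous) %||% character(),
      target_interval = x$scheme$target_interval,
      window = x$scheme$window,
      name = x$scheme$name
    )
  )
  class(out) <- "ptml_group_means"
  out
}

# expectation matrix for one partition: rows follow `labels`, columns `vars`;
# back-off to the global mean for unseen labels or groups below min size
partition_mean_matrix <- function(means, partition, labels, vars,
                                  min_group_size = 1L) {
  gm <- means$group_means
  gm <- gm[gm$partition == partition & gm$variable %in% vars, , drop = FALSE]
  glob <- stats::setNames(means$global_means$mean, means$global_means$variable)
  M <- matrix(rep(glob[vars], each = length(labels)),
              nrow = length(labels),
              dimnames = list(NULL, vars))
  if (nrow(gm)) {
    wide <- tidyr::pivot_wider(gm[c("label", "variable", "mean")],
                               names_from = "variable", values_from = "mean")
    sizes <- gm$n[match(wide$label, gm$label)]
    ok_labels <- wide$label[sizes >= min_group_size]
    idx <- match(labels, wide$label)
    use <- !is.na(idx) & wide$label[pmax(idx, 1L)] %in% ok_labels
    if (any(use)) {
      M[use, ] <- as.matrix(wide[idx[use], vars, drop = FALSE])
    }
  }
  M
}

#' First-order perturbation-theory deviations
#'
#' Computes `delta = v_k - alpha * <v_k(s)>` for every registered
#' continuous variable against one partition's training moving averages.
#' Labels unseen in training (or whose group is smaller than
#' `min_group_size`) back off to the global training mean. With
#' `alpha = 0` the raw values are returned unchanged.
#'
#' @param cases A `ptml_cases` table (or any data frame holding the
#'   registered variables and the partition's label column).
#' @param means A fitted `ptml_group_means`.
#' @param partition Partition name.
#' @param cfg A [pt_config()].
#' @return Numeric matrix of deviations, one column per variable.
#' @export
pt_first_order <- function(cases, means, partition, cfg = pt_config("ma")) {
  scheme <- means$scheme
  vars <- means$global_means$variable
  missing <- setdiff(vars, names(cases))
  if (length(missing)) {
    rlang::abort(sprintf("unregistered/absent variable(s): %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  X <- as.matrix(cases[vars])
  if (cfg$alpha == 0) return(X)
  col <- scheme$partitions[[partition]]
  M <- partition_mean_matrix(means, partition, as.character(cases[[col]]),
                             vars, cfg$min_group_size)
  X - cfg$alpha * M
}

#' Second-order (distance) aggregation of deviations
#'
#' Aggregates a group of first-order deviations as
#' `(sum_k delta_k^q)^r`. Under the `ed` preset (q = 2, r = 1/2) this is
#' the Euclidean norm of the group's deviation vector.
#'
#' @param deltas Named numeric vector, or a matrix with named columns, of
#'   first-order deviations.
#' @param group Character vector naming the group members.
#' @param cfg A [pt_config()].
#' @return A scalar (or one value per matrix row).
#' @export
#' @examples
#' pt_second_order(c(a = 3, b = 4), c("a", "b"), pt_config("ed")) # 5
pt_second_order <- function(deltas, group, cfg = pt_config("ed")) {
  if (length(group) == 0) rlang::abort("empty variable group.")
  if (is.matrix(deltas)) {
    missing <- setdiff(group, colnames(deltas))
  } else {
    missing <- setdiff(group, names(deltas))
  }
  if (length(missing)) {
    rlang::abort(sprintf("deviations missing for group member(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (is.matrix(deltas)) {
    rowSums(deltas[, group, drop = FALSE]^cfg$q)^cfg$r
  } else {
    sum(deltas[group]^cfg$q)^cfg$r
  }
}

#' Reference function: prior probability of the Within class
#'
#' Estimates, for each case, the training prevalence of the `Within`
#' output among cases matching the case's conditioning labels. In
#' `"joint"` mode the full label vector is matched, backing off to the
#' global prevalence when fewer than `f_ref_min_size` training cases
#' match; `"partition"` conditions on a single partition with the same
#' back-off; `"global"` always uses the overall prevalence.
#'
#' @param train Labelled training `ptml_cases` table.
#' @param cases Table of cases to score (default: the training table).
#' @param cfg A [pt_config()].
#' @param scheme Scheme; defaults to the one attached to `train`.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
reference_function <- function(train, cases = train, cfg = pt_config("ma"),
                               scheme = cases_scheme(train)) {
  if (nrow(train) == 0) rlang::abort("no training rows.")
  global <- mean(train$output_class == "Within")
  if (cfg$f_ref_mode == "global") {
    return(rep(global, nrow(cases)))
  }
  cols <- if (cfg$f_ref_mode == "joint") {
    unname(scheme$partitions)
  } else {
    part <- cfg$f_ref_partition %||% names(scheme$partitions)[1]
    unname(scheme$partitions[[part]])
  }
  key_of <- function(df) {
    do.call(paste, c(lapply(df[cols], as.character), sep = "\r"))
  }
  tk <- key_of(train)
  counts <- table(tk)
  within <- tapply(train$output_class == "Within", tk, mean)
  ck <- key_of(cases)
  idx <- match(ck, names(counts))
  out <- rep(global, nrow(cases))
  ok <- !is.na(idx) & as.vector(counts)[pmax(idx, 1L)] >= cfg$f_ref_min_size
  out[ok] <- as.vector(within)[idx[ok]]
  out
}

#' Build the feature table for a data level
#'
#' Transforms a case table into the model-ready feature table of the
#' configured level: `raw` passes the registered continuous variables
#' through unchanged; `ma` emits one deviation column
#' `d.<variable>.<Partition>` per (variable, partition) pair plus the
#' reference prior `f_ref`; `ed` emits one distance column
#' `ed.<group>.<Partition>` per (variable group, partition) pair plus
#' `f_ref`. Column order is partition-major, then variable/group in
#' scheme order. Group means and the reference prior are always taken
#' from the training table / fitted means, never from `cases` itself.
#'
#' @param cases Case table to transform.
#' @param means A fitted `ptml_group_means`.
#' @param train Labelled training table used for the reference prior
#'   (ignored for the `raw` level).
#' @param cfg A [pt_config()].
#' @return A tibble of class `ptml_features` carrying `case_id`, `inr`,
#'   `output_class`, the feature columns, and attributes `level`,
#'   `feature_names`, `config`.
#' @export
build_features <- function(cases, means, train = cases,
                           cfg = pt_config("ma")) {
  scheme <- means$scheme
  keep <- tibble::tibble(case_id = cases$case_id,
                         inr = cases$inr,
                         output_class = cases$output_class)
  if (cfg$level == "raw") {
    vars <- means$global_means$variable
    feats <- tibble::as_tibble(as.matrix(cases[vars]))
    out <- dplyr::bind_cols(keep, feats)
    return(new_features(out, names(feats), cfg, means))
  }
  f_ref <- reference_function(train, cases, cfg, scheme)
  blocks <- list(tibble::tibble(f_ref = f_ref))
  for (pname in names(scheme$partitions)) {
    D <- pt_first_order(cases, means, pname, pt_config("ma",
                        min_group_size = cfg$min_group_size))
    if (cfg$level == "ma") {
      colnames(D) <- sprintf("d.%s.%s", colnames(D), pname)
      blocks[[length(blocks) + 1L]] <- tibble::as_tibble(D)
    } else {
      gs <- scheme$variable_groups
      E <- vapply(names(gs), function(g) {
        pt_second_order(D, gs[[g]], cfg)
      }, numeric(nrow(D)))
      if (!is.matrix(E)) E <- matrix(E, nrow = 1L,
                                     dimnames = list(NULL, names(gs)))
      colnames(E) <- sprintf("ed.%s.%s", colnames(E), pname)
      blocks[[length(blocks) + 1L]] <- tibble::as_tibble(E)
    }
  }
  feats <- dplyr::bind_cols(blocks)
  if (anyDuplicated(names(feats))) {
    rlang::abort("feature column namespace collision.")
  }
  out <- dplyr::bind_cols(keep, feats)
  new_features(out, names(feats), cfg, means)
}

new_features <- function(df, feature_names, cfg, means) {
  attr(df, "level") <- cfg$level
  attr(df, "feature_names") <- feature_names
  attr(df, "config") <- cfg
  attr(df, "fitted_on") <- means$fitted_on
  class(df) <- c("ptml_features", class(df))
  df
}

#' Feature column names of a feature table
#' @param features A `ptml_features` table.
#' @return Character vector.
#' @export
feature_names <- function(features) {
  fn <- attr(features, "feature_names")
  fn %||% setdiff(names(features), c("case_id", "inr", "output_class"))
}

#' Data level of a feature table
#' @param features A `ptml_features` table.
#' @return `"raw"`, `"ma"` or `"ed"` (or `NULL`).
#' @export
feature_level <- function(features) attr(features, "level")
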