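#' Bagged-tree ensemble classification of specimens with OOB error
#'
#' A random-forest classifier over the coded gill-raker traits, following
#' the standard recipe (a forest of 1000 trees by default, each grown on a
#' bootstrap sample with random feature subsets at every split).
#' Categorical traits are one-hot encoded; filament length enters as the
#' plate average ([mean_filament_length()]). Error rates are out-of-bag:
#' each specimen is predicted by majority vote of the trees that did not
#' sample it. Variable importance is OOB permutation importance (mean
#' decrease in accuracy), permuting all dummy columns of a trait jointly so
#' the ranking is over the parent features. Reproducible for a fixed seed.
#'
#' Two importance measures are reported. `marginal_error` retrains the
#' forest on each feature alone and records its standalone OOB error - the
#' per-characteristic error rate used in the published trait-usefulness
#' ordering (lower = more useful); this defines the feature ranking.
#' `importance` is classical OOB permutation importance (mean decrease in
#' accuracy), reported for comparison.
#'
#' @param train specimen data.frame with a `true_species` column (>= 2
#'   species present).
#' @param features subset of
#'   `c("arrangement","color","middle_lobe","terminal_lobe","length")`.
#' @param n_trees number of trees (>= 1; default 1000).
#' @param seed integer RNG seed.
#' @return Object of class `ensemble_report`: list with `per_class_error`,
#'   `total_error`, `confusion` (true x predicted counts),
#'   `marginal_error` (named, standalone per-feature OOB error),
#'   `importance` (named, mean decrease in accuracy), `oob_pred`,
#'   `classes`, plus the call parameters.
#' @export
ensemble_classify <- function(train,
                              features = c("arrangement", "color",
                                           "middle_lobe", "terminal_lobe",
                                           "length"),
                              n_trees = 1000, seed = 1) {
  all_feats <- c(names(trait_levels()), "length")
  features <- match.arg(features, all_feats, several.ok = TRUE)
  if (is.null(train$true_species) || any(is.na(train$true_species)))
    stop("training data must carry true_species for every specimen")
  if (n_trees < 1) stop("n_trees must be >= 1")
  classes <- sort(unique(train$true_species))
  if (length(classes) < 2) stop("need at least 2 species in training data")
  y <- match(train$true_species, classes) - 1L

  enc <- .encode_features(train, features)
  fit <- .forest_cpp(enc$X, y, enc$group, length(classes), length(features),
                     as.integer(n_trees), max(1L, floor(sqrt(ncol(enc$X)))),
                     as.double(seed))
  votes <- fit$votes
  pred <- ifelse(fit$oob_times > 0,
                 classes[max.col(votes, ties.method = "first")],
                 NA_character_)
  truth <- train$true_species
  scored <- !is.na(pred)
  confusion <- table(true = factor(truth[scored], levels = classes),
                     predicted = factor(pred[scored], levels = classes))
  per_class <- vapply(classes, function(cl) {
    in_cl <- scored & truth == cl
    if (!any(in_cl)) return(NA_real_)
    mean(pred[in_cl] != cl)
  }, numeric(1))
  total <- mean(pred[scored] != truth[scored])
  importance <- setNames(fit$importance, features)

  marginal_error <- vapply(features, function(f) {
    e1 <- .encode_features(train, f)
    f1 <- .forest_cpp(e1$X, y, e1$group, length(classes), 1L,
                      as.integer(n_trees),
                      max(1L, floor(sqrt(ncol(e1$X)))), as.double(seed))
    p1 <- ifelse(f1$oob_times > 0,
                 classes[max.col(f1$votes, ties.method = "first")],
                 NA_character_)
    s1 <- !is.na(p1)
    mean(p1[s1] != truth[s1])
  }, numeric(1))

  structure(list(per_class_error = per_class, total_error = total,
                 confusion = confusion, marginal_error = marginal_error,
                 importance = importance,
                 oob_pred = setNames(pred, train$id),
                 n_unscored = sum(!scored), classes = classes,
                 features = features, n_trees = n_trees,
                 mtry = max(1L, floor(sqrt(ncol(enc$X)))), seed = seed),
            class = "ensemble_report")
}

# one-hot design matrix and 0-based column-to-feature map
.encode_features <- function(train, features) {
  lv <- trait_levels()
  cols <- list()
  group <- integer(0)
  for (g in seq_along(features)) {
    f <- features[g]
    if (f == "length") {
      cols[[f]] <- matrix(mean_filament_length(train), ncol = 1,
                          dimnames = list(NULL, "length"))
      group <- c(group, g - 1L)
    } else {
      x <- as.character(train[[f]])
      if (!all(x %in% lv[[f]])) stop("NA or invalid values in trait ", f)
      oh <- vapply(lv[[f]], function(l) as.numeric(x == l),
                   numeric(length(x)))
      colnames(oh) <- paste0(f, ".", lv[[f]])
      cols[[f]] <- oh
      group <- c(group, rep(g - 1L, ncol(oh)))
    }
  }
  list(X = do.call(cbind, cols), group = group)
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("Bagged-tree OOB classification report (", x$n_trees, " trees)\n",
      sep = "")
  cat(sprintf("  total OOB error: %.2f%%\n", 100 * x$total_error))
  for (cl in x$classes)
    cat(sprintf("  %-18s %6.2f%%\n", cl, 100 * x$per_class_error[cl]))
  me <- sort(x$marginal_error)
  cat("  per-feature standalone OOB error (lower = more useful):\n")
  for (f in names(me))
    cat(sprintf("    %-14s %5.2f%%  (permutation importance %.4f)\n",
                f, 100 * me[f], x$importance[f]))
  invisible(x)
}

#' Feature-importance ranking of an ensemble report
#'
#' Ranks the parent features by how useful each is on its own: ascending
#' standalone OOB error (`marginal_error`), the per-characteristic error
#' rate that defines the published trait-usefulness ordering. The
#' permutation importance is carried along for reference. Exact ties share
#' a rank (min rank) and are flagged rather than broken silently.
#'
#' @param report an `ensemble_report` from [ensemble_classify()].
#' @return data.frame with columns `feature`, `marginal_error`,
#'   `importance`, `rank`, `tied`, ordered from most to least useful.
#' @export
variable_importance_check <- function(report) {
  stopifnot(inherits(report, "ensemble_report"))
  me <- report$marginal_error
  rk <- rank(me, ties.method = "min")
  tied <- duplicated(me) | duplicated(me, fromLast = TRUE)
  out <- data.frame(feature = names(me), marginal_error = unname(me),
                    importance = unname(report$importance[names(me)]),
                    rank = unname(rk), tied = unname(tied),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$feature), , drop = FALSE]
}
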