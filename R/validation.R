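#' Seeded k-fold partition
#'
#' Random permutation of `1:n` split into `k` contiguous blocks whose sizes
#' differ by at most one; no stratification.
#'
#' @param n number of records.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed.
#' @return a `fold_plan`: list with `k`, `seed` and `assignments` (fold id per
#'   record index).
#' @export
kfold_indices <- function(n, k = 10L, seed = NULL) {
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k records (n = ", n, ", k = ", k, ")")
  with_seed(seed, {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
    structure(list(k = k, seed = seed, assignments = fold), class = "fold_plan")
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC with midrank tie correction:
#' `AUC = (R+ - n+(n+ + 1)/2) / (n+ n-)`, where `R+` is the rank sum of the
#' positive scores. Equals the probability that a random positive outscores a
#' random negative, ties counting one half. Invariant under strictly
#' increasing score transforms.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (logical, or 0/1).
#' @return AUC in \[0, 1\], or `NA` (with a warning) when only one class is
#'   present — an undefined AUC, deliberately not reported as 0.5.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(as.integer(as.logical(labels)))
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be equal-length and complete")
  n1 <- as.numeric(sum(labels)); n0 <- as.numeric(sum(!labels))
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated one-vs-rest ROC/AUC per loss group
#'
#' The full validation protocol: split the cohort into `k` disjoint folds,
#' fit the network on each training complement ([fit_bn()] with Laplace
#' smoothing `alpha`, default 1 so sparse held-out configurations never score
#' exactly zero), score every held-out record for each loss group `g` by the
#' posterior `P(loss_group = g | predictors)`, and compute one-vs-rest AUCs —
#' per fold, and pooled over the joined out-of-fold predictions (the primary
#' figure). Fold/group combinations where the held-out set lacks one class
#' yield an undefined (`NA`) AUC, flagged rather than dropped.
#'
#' @param data cohort data frame containing all DAG variables (or
#'   `age_years`).
#' @param dag network structure, default [canonical_dag()].
#' @param k number of folds (default 10).
#' @param alpha Laplace smoothing used in the per-fold fits.
#' @param seed integer seed for the fold split.
#' @param target outcome variable, default `"loss_group"`.
#' @return an `auc_report`: list with `per_group_pooled` (named vector),
#'   `per_group_per_fold` (`k x groups` matrix), `folds` and `n`.
#' @export
cross_validated_auc <- function(data, dag = canonical_dag(), k = 10L,
                                alpha = 1, seed = NULL,
                                target = "loss_group") {
  data <- prepare_bn_data(data, dag$nodes)
  data <- coerce_states(data, dag$nodes)
  if (anyNA(data[dag$nodes])) stop("missing values in model variables")
  n <- nrow(data)
  plan <- kfold_indices(n, k, seed)
  states <- levels(data[[target]])
  scores <- matrix(NA_real_, n, length(states), dimnames = list(NULL, states))
  for (f in seq_len(k)) {
    test <- plan$assignments == f
    fit <- fit_bn(dag, data[!test, , drop = FALSE], alpha = alpha)
    fit$response <- target
    scores[test, ] <- predict(fit, data[test, , drop = FALSE], target = target)
  }
  y <- data[[target]]
  per_fold <- matrix(NA_real_, k, length(states),
                     dimnames = list(paste0("fold", seq_len(k)), states))
  for (f in seq_len(k)) for (g in states) {
    test <- plan$assignments == f
    lab <- y[test] == g
    if (any(lab) && any(!lab))
      per_fold[f, g] <- roc_auc(scores[test, g], lab)
  }
  pooled <- vapply(states, function(g) {
    lab <- y == g
    if (any(lab) && any(!lab)) roc_auc(scores[, g], lab) else NA_real_
  }, 0)
  structure(list(per_group_pooled = pooled, per_group_per_fold = per_fold,
                 folds = plan, n = n, alpha = alpha, groups = states),
            class = "auc_report")
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated one-vs-rest AUC (n = %d, alpha = %g)\n",
              x$folds$k, x$n, x$alpha))
  cat("pooled (joined folds):\n")
  print(round(x$per_group_pooled, 4))
  und <- colSums(is.na(x$per_group_per_fold))
  if (any(und > 0))
    cat("undefined per-fold AUCs (single-class test folds):",
        paste(sprintf("%s:%d", names(und)[und > 0], und[und > 0]),
              collapse = " "), "\n")
  invisible(x)
}

#' Export an AUC report as JSON
#'
#' @param report an [cross_validated_auc()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_auc_json <- function(report, path) {
  jsonlite::write_json(
    list(k = report$folds$k, n = report$n, alpha = report$alpha,
         seed = report$folds$seed,
         pooled = as.list(report$per_group_pooled),
         per_fold = as.data.frame(report$per_group_per_fold)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
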