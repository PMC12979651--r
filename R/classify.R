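# Logistic fitting by IRLS with an optional ridge penalty. The ridge path
# is engaged automatically when the unpenalised likelihood degenerates
# (perfect separation), keeping coefficients finite; the fit is flagged.
fit_logistic <- function(X, y, lambda = 0, maxit = 100) {
  stopifnot(is.matrix(X), nrow(X) == length(y), lambda < 1e6)
  p_dim <- ncol(X)
  beta <- numeric(p_dim)
  pen <- diag(rep(lambda, p_dim), p_dim)
  if (lambda > 0) pen[1, 1] <- 0 # never penalise the intercept
  H <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + pen
    g <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      return(fit_logistic(X, y, lambda = max(lambda * 10, 1e-4), maxit = maxit))
    }
    beta <- beta + step
    if (max(abs(step)) < 1e-9) break
    if (lambda == 0 && max(abs(beta)) > 30) {
      # separation: restart with ridge stabilisation
      out <- fit_logistic(X, y, lambda = 1e-4, maxit = maxit)
      out$separated <- TRUE
      return(out)
    }
  }
  vcov <- tryCatch(solve(H), error = function(e) NULL)
  list(coef = beta, fitted = plogis(drop(X %*% beta)), vcov = vcov,
       lambda = lambda, separated = lambda > 0)
}

#' Rao score test for adding predictors to a logistic model
#'
#' For each candidate column, computes Rao's (efficient score) test of the
#' hypothesis that its coefficient is zero when added to the current
#' logistic model: the score and the information are evaluated at the
#' null-restricted maximum-likelihood fit, and the statistic is compared
#' to a chi-squared distribution with one degree of freedom. This is the
#' entry/exit criterion of [stepwise_select()].
#'
#' @param y 0/1 response vector.
#' @param X_null Design matrix of the null model (including an intercept
#'   column).
#' @param X_cand Matrix of candidate columns (one test per column).
#' @return A tibble with `term`, `statistic`, `p`. Candidates that are
#'   collinear with the null design get `p = 1`.
#' @export
rao_score_test <- function(y, X_null, X_cand) {
  X_cand <- as.matrix(X_cand)
  fit <- fit_logistic(X_null, y)
  mu <- fit$fitted
  w <- pmax(mu * (1 - mu), 1e-10)
  U <- drop(crossprod(X_cand, y - mu))
  XtWX <- crossprod(X_null * w, X_null)
  B <- crossprod(X_null * w, X_cand)
  sol <- tryCatch(solve(XtWX, B), error = function(e) NULL)
  if (is.null(sol)) sol <- qr.solve(XtWX, B)
  V <- colSums(X_cand * (X_cand * w)) - colSums(B * sol)
  ok <- unname(V > 1e-10)
  stat <- unname(ifelse(ok, U^2 / V, 0))
  tibble::tibble(
    term = colnames(X_cand) %||% paste0("x", seq_len(ncol(X_cand))),
    statistic = stat,
    p = ifelse(ok, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  )
}

#' Bidirectional stepwise logistic feature selection by score test
#'
#' Greedy bidirectional elimination: at each iteration the excluded
#' feature with the smallest Rao score-test p value enters if that p is
#' below `alpha`, then the included feature with the largest score-test p
#' value (tested against the model containing the other included
#' features) leaves if its p is at or above `alpha`. Iteration stops at a
#' fixed point; ties break by column order, so the procedure is
#' deterministic for a given input order. Features are standardised
#' internally.
#'
#' @param data Data frame containing the outcome and candidate columns.
#' @param outcome Name of the binary outcome column (positive class
#'   `"ADHD"` for factors, or the maximum level of a 0/1 vector).
#' @param candidates Candidate feature column names (default: all numeric
#'   columns except the outcome).
#' @param alpha Entry/exit significance threshold (default 0.035).
#' @param max_steps Safety cap on iterations.
#' @return Character vector of selected features, with the step trace in
#'   the `"trace"` attribute.
#' @export
stepwise_select <- function(data, outcome = "group", candidates = NULL,
                            alpha = 0.035, max_steps = 100) {
  y <- binary_outcome(data[[outcome]])
  candidates <- candidates %||%
    setdiff(names(data)[vapply(data, is.numeric, TRUE)], outcome)
  X <- scale(as.matrix(data[, candidates, drop = FALSE]))
  X[is.nan(X)] <- 0 # constant columns
  n <- nrow(X)
  included <- character(0)
  trace <- list()
  seen <- character(0)

  design <- function(feats) {
    cbind(`(Intercept)` = rep(1, n),
          X[, feats, drop = FALSE])
  }

  for (step in seq_len(max_steps)) {
    changed <- FALSE
    excluded <- setdiff(candidates, included)
    if (length(excluded)) {
      sc <- rao_score_test(y, design(included), X[, excluded, drop = FALSE])
      best <- which.min(sc$p)
      if (sc$p[best] < alpha) {
        included <- c(included, excluded[best])
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = step, action = "add", feature = excluded[best],
          p = sc$p[best])
        changed <- TRUE
      }
    }
    if (length(included)) {
      p_rm <- vapply(included, function(f) {
        rest <- setdiff(included, f)
        rao_score_test(y, design(rest), X[, f, drop = FALSE])$p
      }, 1)
      worst <- which.max(p_rm)
      if (p_rm[worst] >= alpha) {
        removed <- included[worst]
        included <- setdiff(included, removed)
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = step, action = "remove", feature = removed,
          p = p_rm[worst])
        changed <- TRUE
      }
    }
    state <- paste(sort(included), collapse = "|")
    if (!changed || state %in% seen) break
    seen <- c(seen, state)
  }
  attr(included, "trace") <- dplyr::bind_rows(trace)
  included
}

binary_outcome <- function(v) {
  if (is.factor(v) || is.character(v)) {
    lv <- unique(as.character(v))
    pos <- if ("ADHD" %in% lv) "ADHD" else sort(lv)[1]
    as.integer(as.character(v) == pos)
  } else {
    as.integer(v == max(v))
  }
}

# rank-based (midrank) AUC of scores for a 0/1 outcome
auc_midrank <- function(scores, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for a confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between predicted
#' and true labels.
#'
#' @param confusion A square contingency table or matrix of counts
#'   (predictions in rows, truth in columns).
#' @return Kappa in `[-1, 1]`; `NA` when chance agreement is 1.
#' @examples
#' compute_kappa(matrix(c(20, 2, 3, 21), 2))
#' @export
compute_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m), all(m >= 0), sum(m) > 0)
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' @rdname compute_kappa
#' @param kappa A kappa value.
#' @return `kappa_label()`: the conventional agreement band
#'   (poor/slight/fair/moderate/substantial/perfect).
#' @export
kappa_label <- function(kappa) {
  stopifnot(is.numeric(kappa))
  lab <- cut(kappa, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
             labels = c("poor", "slight", "fair", "moderate",
                        "substantial", "perfect"))
  paste(as.character(lab), "agreement")
}

#' Repeated stratified cross-validated logistic classification
#'
#' Fits a logistic model on the selected features under k-fold
#' cross-validation with class-stratified fold assignment, repeated
#' `repeats` times. Within each repetition the out-of-fold predicted
#' probabilities are pooled and scored once: accuracy, precision, recall
#' and F1 at a 0.5 threshold, AUC by midranks, and Cohen's kappa from the
#' pooled confusion table. Reported metrics are means over repetitions.
#' Features are standardised; an empty feature set yields a
#' prevalence-only model (AUC 0.5), so a null screen degrades gracefully.
#'
#' @param data Data frame with outcome and features.
#' @param outcome Binary outcome column (positive class `"ADHD"`).
#' @param features Feature column names.
#' @param k Number of folds (default 5).
#' @param repeats Number of repetitions (default 50).
#' @param seed Integer seed for fold assignment.
#' @param threshold Probability threshold for the positive class.
#' @return A `gc_cv_report`: `summary` (mean metrics), `per_repetition`
#'   metric traces, full-data `coefficients` (estimate, z, p per feature),
#'   `features`, `seed`, and the number of fold redraws forced by a
#'   single-class fold. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
cross_validate <- function(data, outcome = "group", features,
                           k = 5, repeats = 50, seed = 1, threshold = 0.5) {
  y <- binary_outcome(data[[outcome]])
  stopifnot(length(unique(y)) == 2)
  n <- length(y)
  if (length(features)) {
    X <- scale(as.matrix(data[, features, drop = FALSE]))
    X[is.nan(X)] <- 0
  } else {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  if (!is.null(seed)) set.seed(as.integer(seed))

  redraws <- 0L
  per_rep <- purrr::map(seq_len(repeats), function(rep_i) {
    folds <- stratified_folds(y, k)
    while (!folds_ok(y, folds, k)) {
      redraws <<- redraws + 1L
      folds <- stratified_folds(y, k)
    }
    prob <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- fit_logistic(Xd[!test, , drop = FALSE], y[!test])
      prob[test] <- plogis(drop(Xd[test, , drop = FALSE] %*% fit$coef))
    }
    pred <- as.integer(prob > threshold)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(
      repetition = rep_i,
      auc = auc_midrank(prob, y),
      accuracy = (tp + tn) / n,
      precision = precision, recall = recall, f1 = f1,
      kappa = compute_kappa(matrix(c(tn, fp, fn, tp), 2))
    )
  }) |> dplyr::bind_rows()

  full_fit <- fit_logistic(Xd, y)
  se <- if (!is.null(full_fit$vcov)) sqrt(diag(full_fit$vcov)) else
    rep(NA_real_, ncol(Xd))
  coefs <- tibble::tibble(
    term = colnames(Xd),
    estimate = full_fit$coef,
    z = full_fit$coef / se,
    p = 2 * pnorm(-abs(full_fit$coef / se))
  )

  structure(
    list(
      summary = dplyr::summarise(
        per_rep,
        dplyr::across(c("auc", "accuracy", "precision", "recall",
                        "f1", "kappa"), ~ mean(.x, na.rm = TRUE))
      ),
      per_repetition = per_rep,
      coefficients = coefs,
      features = features,
      k = k, repeats = repeats, seed = seed, n = n,
      positive_class = "ADHD",
      separated = isTRUE(full_fit$separated),
      redraws = redraws
    ),
    class = "gc_cv_report"
  )
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

folds_ok <- function(y, folds, k) {
  all(vapply(seq_len(k), function(f)
    length(unique(y[folds != f])) == 2, TRUE))
}

#' Importance-based feature pruning
#'
#' Evaluates feature importance as the absolute Wald z of each coefficient
#' in the full-data logistic fit, then iteratively removes the least
#' important feature among those not significant at `alpha`, re-running
#' the cross-validation after each removal. A removal is kept only while
#' the mean AUC does not decrease (by more than `tol`); pruning stops at
#' the first AUC drop or when every remaining feature is significant.
#'
#' @param report A [cross_validate()] report for the starting model.
#' @param data,outcome As in [cross_validate()].
#' @param alpha Significance level defining "insignificant" features.
#' @param tol Tolerated AUC decrease per removal (default 0: strict
#'   non-decrease).
#' @return The final `gc_cv_report`, with a `"pruning"` attribute tracing
#'   each attempted removal.
#' @export
prune_by_importance <- function(report, data, outcome = "group",
                                alpha = 0.05, tol = 0) {
  stopifnot(inherits(report, "gc_cv_report"))
  trace <- list()
  repeat {
    feats <- report$features
    if (length(feats) <= 1) break
    co <- report$coefficients[report$coefficients$term != "(Intercept)", ]
    nonsig <- co[!is.na(co$p) & co$p >= alpha, , drop = FALSE]
    if (!nrow(nonsig)) break
    drop_f <- nonsig$term[which.min(abs(nonsig$z))]
    cand <- cross_validate(data, outcome, setdiff(feats, drop_f),
                           k = report$k, repeats = report$repeats,
                           seed = report$seed)
    kept <- cand$summary$auc >= report$summary$auc - tol
    trace[[length(trace) + 1]] <- tibble::tibble(
      feature = drop_f, auc_before = report$summary$auc,
      auc_after = cand$summary$auc, removed = kept)
    if (!kept) break
    report <- cand
  }
  attr(report, "pruning") <- dplyr::bind_rows(trace)
  report
}
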