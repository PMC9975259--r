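#' Significance stars
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

assert_feature_table <- function(table, need_features = feature_names()) {
  miss <- setdiff(c("group", need_features), names(table))
  if (length(miss))
    stopf("feature table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyNA(table[need_features])) stopf("feature table has missing cells")
  invisible(table)
}

#' Two-group comparison of one metric (Student's t-test)
#'
#' Classical pooled-variance two-sided t-test between exactly two groups;
#' Welch's unequal-variance form is available by flag.
#'
#' @param table feature table (one row per sample, `group` column).
#' @param metric feature column to compare.
#' @param welch use Welch's correction instead of the pooled form.
#' @return Object of class `group_test`: statistic, df, p-value, stars.
#' @export
two_group_test <- function(table, metric, welch = FALSE) {
  g <- factor(table$group)
  if (nlevels(g) != 2L) stopf("two_group_test needs exactly two groups")
  if (any(tabulate(g) < 2L)) stopf("each group needs n >= 2")
  x <- table[[metric]][g == levels(g)[1]]
  y <- table[[metric]][g == levels(g)[2]]
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(x) + length(y) - 2), p.value = 1)
  } else {
    tt <- t.test(x, y, var.equal = !welch)
  }
  structure(list(test = if (welch) "Welch t" else "Student t",
                 metric = metric, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 pairs = NULL, stars = significance_stars(tt$p.value)),
            class = "group_test")
}

#' Three-group comparison: one-way ANOVA with Tukey HSD post-hoc
#'
#' @param table feature table with three groups.
#' @param metric feature column to compare.
#' @return A `group_test` with the ANOVA F statistic and p-value plus a
#'   `pairs` data frame of Tukey-adjusted pairwise p-values and stars.
#' @export
three_group_anova_tukey <- function(table, metric) {
  g <- factor(table$group)
  if (nlevels(g) != 3L) stopf("three_group_anova_tukey needs three groups")
  if (any(tabulate(g) < 2L)) stopf("each group needs n >= 2")
  df <- data.frame(value = table[[metric]], group = g)
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      stars = significance_stars(tk[, "p adj"]),
                      row.names = NULL)
  structure(list(test = "one-way ANOVA + Tukey HSD", metric = metric,
                 statistic = an[["F value"]][1], df = an[["Df"]],
                 p_value = an[["Pr(>F)"]][1], pairs = pairs,
                 stars = significance_stars(an[["Pr(>F)"]][1])),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s on %s: statistic %.3f, p = %.3g %s\n",
              x$test, x$metric, x$statistic, x$p_value, x$stars))
  if (!is.null(x$pairs)) {
    cat("  Tukey-adjusted pairs:\n")
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("    %-20s p_adj = %.3g %s\n", x$pairs$pair[i],
                  x$pairs$p_adj[i], x$pairs$stars[i]))
  }
  invisible(x)
}

#' Multicollinearity screen (Pearson correlations)
#'
#' Full pairwise Pearson correlation matrix of the six features; pairs with
#' `|r| >= threshold` are flagged as offending, and constant columns (whose
#' correlation is undefined) are flagged as degenerate.
#'
#' @param table feature table (needs at least 3 samples).
#' @param threshold absolute-correlation flag threshold.
#' @param features feature columns to screen.
#' @return Object of class `collinearity_report`: `r` matrix, `flagged`
#'   pairs data frame, `degenerate` feature names, `threshold`.
#' @export
collinearity_screen <- function(table, threshold = 0.7,
                                features = feature_names()) {
  X <- as.matrix(table[features])
  if (nrow(X) < 3L) stopf("need at least 3 samples")
  degenerate <- features[apply(X, 2, sd) == 0]
  r <- suppressWarnings(cor(X))
  diag(r) <- 1
  idx <- which(upper.tri(r) & (is.na(r) | abs(r) >= threshold),
               arr.ind = TRUE)
  flagged <- data.frame(feature_a = features[idx[, 1]],
                        feature_b = features[idx[, 2]],
                        r = r[idx])
  structure(list(r = r, flagged = flagged, degenerate = degenerate,
                 threshold = threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf("<collinearity_report> |r| >= %.2f flags: %d",
              x$threshold, nrow(x$flagged)))
  if (length(x$degenerate))
    cat(sprintf(" (degenerate: %s)", paste(x$degenerate, collapse = ", ")))
  cat("\n")
  if (nrow(x$flagged))
    print(x$flagged)
  invisible(x)
}

# --- pooled-covariance linear discriminant (closed form) ----------------

fit_pooled_lda <- function(X, y, priors = NULL, ridge = 1e-6) {
  y <- factor(y)
  K <- nlevels(y)
  p <- ncol(X)
  n <- nrow(X)
  priors <- priors %||% rep(1 / K, K)
  means <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(X[y == l, , drop = FALSE])))
  S <- matrix(0, p, p)
  for (l in levels(y)) {
    Xl <- X[y == l, , drop = FALSE]
    if (nrow(Xl) > 1) S <- S + crossprod(scale(Xl, scale = FALSE))
  }
  S <- S / (n - K)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  regularized <- FALSE
  if (is.null(Sinv) || rcond(S) < 1e-12) {
    scl <- mean(diag(S))           # zero when all features are constant
    if (!is.finite(scl) || scl <= 0) scl <- 1
    S <- S + ridge * scl * diag(p)
    Sinv <- solve(S)
    regularized <- TRUE
    warning(sprintf("singular pooled covariance; ridge %g applied", ridge))
  }
  list(levels = levels(y), means = means, Sinv = Sinv, priors = priors,
       regularized = regularized)
}

predict_pooled_lda <- function(fit, X) {
  K <- length(fit$levels)
  delta <- sapply(seq_len(K), function(k) {
    mu <- fit$means[k, ]
    drop(X %*% (fit$Sinv %*% mu)) - 0.5 * drop(mu %*% fit$Sinv %*% mu) +
      log(fit$priors[k])
  })
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  factor(fit$levels[max.col(delta, ties.method = "first")],
         levels = fit$levels)
}

#' Linear discriminant classification with resubstitution and LOOCV accuracy
#'
#' Fits a linear discriminant with pooled within-class covariance and equal
#' priors on the chosen feature subset (features are z-scored first, which
#' leaves the discriminant's predictions unchanged but conditions the
#' covariance). Reports the original classification accuracy (OCA,
#' resubstitution) and the cross-validated classification accuracy (CVCA,
#' leave-one-out with a full refit per fold), with confusion matrices for
#' both. A singular pooled covariance is ridge-regularized with a recorded
#' epsilon and a warning.
#'
#' @param table feature table.
#' @param labels class labels (default the `group` column).
#' @param feature_subset feature columns to use (default all six).
#' @param priors class priors (default equal).
#' @param ridge ridge epsilon applied only on singularity.
#' @return Object of class `classification_report` with `oca`, `cvca`
#'   (percent), `confusion` (train and cv tables), the subset, and the fit.
#' @export
lda_classify <- function(table, labels = table$group,
                         feature_subset = feature_names(),
                         priors = NULL, ridge = 1e-6) {
  y <- factor(labels)
  if (nlevels(y) < 2L) stopf("need at least two classes")
  if (any(tabulate(y) < 2L)) stopf("each class needs n >= 2")
  if (!length(feature_subset)) stopf("feature subset must be non-empty")
  X <- scale(as.matrix(table[feature_subset]))
  X[, attr(X, "scaled:scale") == 0] <- 0
  n <- nrow(X)
  fit <- fit_pooled_lda(X, y, priors, ridge)
  pred_train <- predict_pooled_lda(fit, X)
  cv_pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fi <- fit_pooled_lda(X[-i, , drop = FALSE], y[-i], priors, ridge)
    cv_pred[i] <- predict_pooled_lda(fi, X[i, , drop = FALSE])
  }
  structure(list(feature_subset = feature_subset,
                 oca = 100 * mean(pred_train == y),
                 cvca = 100 * mean(cv_pred == y),
                 confusion = list(train = table(truth = y, predicted = pred_train),
                                  cv = table(truth = y, predicted = cv_pred)),
                 roc = NULL, auc = NA_real_, model = fit,
                 classifier = "lda"),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s on {%s}\n", x$classifier,
              paste(x$feature_subset, collapse = ", ")))
  if (is.finite(x$oca)) cat(sprintf("  OCA  %.1f%%\n", x$oca))
  if (is.finite(x$cvca)) cat(sprintf("  CVCA %.1f%%\n", x$cvca))
  if (is.finite(x$auc)) cat(sprintf("  AUC  %.3f\n", x$auc))
  if (!is.null(x$confusion$cv)) {
    cat("  LOOCV confusion:\n")
    print(x$confusion$cv)
  }
  invisible(x)
}

# --- ridge-regularized logistic regression (IRLS) -----------------------

fit_ridge_logistic <- function(X, y01, lambda = 1e-3, max_iter = 200,
                               tol = 1e-10) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)))  # intercept unpenalized
  b <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    bn <- solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z))
    if (max(abs(bn - b)) < tol) { b <- drop(bn); break }
    b <- drop(bn)
  }
  b
}

#' ROC curve and trapezoidal AUC from scores
#'
#' Sweeps the decision threshold over the score values, collecting
#' (false positive rate, true positive rate) points from (0,0) to (1,1);
#' the area under the curve is computed by the trapezoidal rule (which, at
#' tied scores, equals the Mann-Whitney concordance with the half-tie
#' convention).
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param positive logical: which observations belong to the positive class.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- positive[ord]
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stopf("need both classes to build a ROC curve")
  keep <- c(diff(s) != 0, TRUE)  # group tied scores into single points
  tpr <- c(0, cumsum(pos)[keep] / np)
  fpr <- c(0, cumsum(!pos)[keep] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Logistic-regression discriminant with ROC / AUC
#'
#' Fits a logistic model on the chosen (z-scored) feature subset using
#' iteratively reweighted least squares with light L2 regularization
#' (`lambda`, intercept unpenalized) so that the fit - and hence the AUC -
#' stays defined under the complete separation that strongly separated
#' cohorts produce. The ROC curve is swept over the predicted
#' probabilities and the AUC computed by the trapezoidal rule. By default
#' scores are resubstitution scores; `cv = TRUE` uses leave-one-out
#' predicted probabilities instead.
#'
#' @param table feature table.
#' @param labels binary class labels (default `group`).
#' @param feature_subset feature columns to use.
#' @param positive label of the positive class (default the second factor
#'   level).
#' @param lambda ridge strength.
#' @param cv use leave-one-out cross-validated scores.
#' @return A `classification_report` with `roc`, `auc`, and accuracy at
#'   the 0.5 probability threshold as `oca` (and `cvca` when `cv = TRUE`).
#' @export
logistic_roc_auc <- function(table, labels = table$group,
                             feature_subset = feature_names(),
                             positive = NULL, lambda = 1e-3, cv = FALSE) {
  y <- factor(labels)
  if (nlevels(y) != 2L) stopf("logistic ROC needs exactly two classes")
  if (any(tabulate(y) < 2L)) stopf("each class needs n >= 2")
  positive <- positive %||% levels(y)[2]
  y01 <- as.numeric(y == positive)
  X <- scale(as.matrix(table[feature_subset]))
  X[, attr(X, "scaled:scale") == 0] <- 0
  b <- fit_ridge_logistic(X, y01, lambda)
  scores <- plogis(drop(cbind(1, X) %*% b))
  cv_scores <- NULL
  if (cv) {
    n <- nrow(X)
    cv_scores <- vapply(seq_len(n), function(i) {
      bi <- fit_ridge_logistic(X[-i, , drop = FALSE], y01[-i], lambda)
      plogis(drop(c(1, X[i, ]) %*% bi))
    }, numeric(1))
  }
  use <- cv_scores %||% scores
  rc <- roc_curve(use, y01 == 1)
  acc <- function(s) 100 * mean((s >= 0.5) == (y01 == 1))
  structure(list(feature_subset = feature_subset,
                 oca = acc(scores),
                 cvca = if (cv) acc(cv_scores) else NA_real_,
                 confusion = NULL, roc = rc$roc, auc = rc$auc,
                 scores = use, positive = positive,
                 model = list(coefficients = b, lambda = lambda),
                 classifier = "logistic"),
            class = "classification_report")
}

#' Exhaustive feature-subset search
#'
#' Evaluates every subset of the six features in the requested size range:
#' linear discriminant OCA and LOOCV CVCA plus logistic AUC per subset.
#' Rows are ranked by CVCA, then AUC, then OCA, then smaller subset size
#' (parsimony on exact ties), then enumeration order - a declared,
#' deterministic convention.
#'
#' @param table feature table.
#' @param labels binary class labels.
#' @param min_size,max_size subset size range (1..6).
#' @param lambda logistic ridge strength.
#' @return Data frame of class `subset_search`: one dot-notation column
#'   per feature (filled circle = included), `size`, `oca`, `cvca`, `auc`,
#'   `rank`, sorted best first.
#' @export
subset_search <- function(table, labels = table$group, min_size = 1,
                          max_size = 6, lambda = 1e-3) {
  feats <- feature_names()
  assert_feature_table(table)
  rows <- list()
  for (sz in min_size:max_size) {
    for (cmb in as.data.frame(combn(6, sz))) {
      sub <- feats[cmb]
      ld <- lda_classify(table, labels, sub)
      lr <- logistic_roc_auc(table, labels, sub, lambda = lambda)
      dots <- ifelse(seq_len(6) %in% cmb, "\u25cf", "")
      rows[[length(rows) + 1]] <-
        data.frame(t(setNames(dots, paste0("f", 1:6))),
                   size = sz, subset = paste(cmb, collapse = "+"),
                   oca = ld$oca, cvca = ld$cvca, auc = lr$auc)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$cvca, -out$auc, -out$oca, out$size)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("subset_search", "data.frame")
  out
}

#' @export
print.subset_search <- function(x, n = 10, ...) {
  cat(sprintf("<subset_search> %d subsets (features 1-6); top %d:\n",
              nrow(x), min(n, nrow(x))))
  print.data.frame(head(as.data.frame(x), n), right = FALSE)
  invisible(x)
}

# --- exact t-SNE (small n) ---------------------------------------------

tsne_exact <- function(X, perplexity, n_iter = 500, seed = 1,
                       exaggeration = 4, lr = 100) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    di <- D2[i, -i]
    for (it in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P / sum(P), 1e-12)
  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exaggeration else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    inc <- mom * inc - lr * grad
    Y <- Y + inc
    Y <- scale(Y, scale = FALSE)
  }
  Y
}

#' 2D sample embedding of the feature table (t-SNE)
#'
#' Standardizes the chosen features and embeds the samples into two
#' dimensions with an exact t-distributed stochastic neighbor embedding
#' (pairwise similarities in feature space matched against a Student-t
#' kernel in the plane), the visualization used to display multi-metric
#' clustering of sample groups. Deterministic for a given seed.
#'
#' @param table feature table (n >= 5 samples).
#' @param feature_subset features to embed on.
#' @param seed RNG seed for the embedding initialization.
#' @param perplexity neighborhood-size parameter, must be `< n`.
#' @param n_iter gradient iterations.
#' @return Data frame `sample_id`, `group`, `tsne1`, `tsne2` plus the
#'   z-scored features (for gradient coloring).
#' @export
visne_embed <- function(table, feature_subset = feature_names(), seed = 1,
                        perplexity = min(10, (nrow(table) - 1) %/% 3),
                        n_iter = 500) {
  n <- nrow(table)
  if (n < 5) stopf("need at least 5 samples to embed")
  if (perplexity >= n) stopf("perplexity must be smaller than n")
  X <- scale(as.matrix(table[feature_subset]))
  X[, attr(X, "scaled:scale") == 0] <- 0
  Y <- tsne_exact(X, perplexity, n_iter = n_iter, seed = seed)
  out <- data.frame(sample_id = table$sample_id %||% seq_len(n),
                    group = table$group %||% NA_character_,
                    tsne1 = Y[, 1], tsne2 = Y[, 2])
  cbind(out, as.data.frame(X))
}

#' Simulate a feature-level cohort with tissue-like effect directions
#'
#' Draws per-sample feature vectors (six metrics, `[0, 1]`) for groups of
#' skin-like tissue. Relative to the normal baseline, the scar group moves
#' in the directions reported for hypertrophic tissue: higher directional
#' variance and waviness for both fiber types, lower collagen coverage,
#' higher elastin coverage. The boundary (`adjacent`) group is modeled as
#' the most aligned/straight with the sparsest elastin and intermediate
#' collagen coverage. Features are independent Gaussians around the group
#' means, truncated to `[0.01, 0.99]`.
#'
#' @param n_per_group named integer vector of group sizes, e.g.
#'   `c(normal = 20, scar = 20)` (optionally `adjacent`).
#' @param effect_size group separation in noise-SD units.
#' @param noise_sd within-group standard deviation of each feature.
#' @param signal_features features that carry the group effect; the rest
#'   are pure noise around the baseline.
#' @param seed RNG seed.
#' @return Feature table: `sample_id`, `group`, six feature columns.
#' @export
simulate_feature_cohort <- function(n_per_group = c(normal = 20, scar = 20),
                                    effect_size = 4, noise_sd = 0.05,
                                    signal_features = feature_names(),
                                    seed = 1) {
  feats <- feature_names()
  baseline <- c(variance_collagen = 0.30, waviness_collagen = 0.20,
                coverage_collagen = 0.80, variance_elastin = 0.35,
                waviness_elastin = 0.25, coverage_elastin = 0.40)
  direction <- list(
    normal   = c(0, 0, 0, 0, 0, 0),
    scar     = c(+1, +1, -1, +1, +1, +1),
    adjacent = c(-0.5, -0.5, -0.25, -0.5, -0.5, -1))
  rows <- with_seed(seed, {
    do.call(rbind, lapply(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      dir <- direction[[g]]
      dir[!(feats %in% signal_features)] <- 0
      mu <- baseline + effect_size * noise_sd * dir
      X <- sapply(seq_len(6), function(j) rnorm(n, mu[j], noise_sd))
      if (n == 1) X <- matrix(X, nrow = 1)
      X <- pmin(pmax(X, 0.01), 0.99)
      df <- data.frame(sample_id = sprintf("%s_%02d", g, seq_len(n)),
                       group = g, X)
      names(df) <- c("sample_id", "group", feats)
      df
    }))
  })
  rownames(rows) <- NULL
  rows
}
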