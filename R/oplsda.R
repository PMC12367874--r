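#' Fit an OPLS-DA model (single predictive component)
#'
#' Orthogonal projections to latent structures, discriminant version, for a
#' binary class vector coded 0/1 (1 = structural cardiotoxin). `n_orth`
#' components of class-orthogonal variation are extracted and removed: at
#' each round the PLS1 weight `w` is computed from the current (deflated)
#' matrix, the candidate loading `p` is projected off `w`
#' (`w_orth = p - (w'p)w`), and the matrix is deflated by the orthogonal
#' score-loading product. The final predictive component is a one-component
#' PLS1 fit on the filtered matrix. With `n_orth = 0` the model is exactly
#' PLS1.
#'
#' @param X Samples x features numeric matrix, complete (post-imputation).
#'   Mean-centred internally.
#' @param y Class vector (0/1 or logical); both classes must be present.
#' @param n_orth Number of orthogonal components (default 1).
#' @return An `OplsDaModel`: centering vectors, predictive component
#'   (`w`, `p`, `t`, `q`), orthogonal components (`w_orth`, `p_orth`,
#'   `t_orth` per component), `features`, `y_mean`, `y`, `threshold` (0.5).
#' @export
fit_oplsda <- function(X, y, n_orth = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (anyNA(X)) stop("X contains missing values; impute first")
  if (length(unique(y)) < 2L) stop("y has a single class")
  if (n_orth < 0L) stop("n_orth must be >= 0")
  if (n_orth >= min(nrow(X) - 1L, ncol(X))) {
    stop("n_orth (", n_orth, ") >= rank bound of X")
  }
  x_center <- colMeans(X)
  Xc <- sweep(X, 2L, x_center)
  y_mean <- mean(y)
  yc <- y - y_mean
  orth <- list()
  for (a in seq_len(n_orth)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate weight vector (no class covariance)")
    w <- w / nw
    t_pred <- drop(Xc %*% w)
    p <- drop(crossprod(Xc, t_pred)) / sum(t_pred^2)
    w_o <- p - sum(w * p) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) {
      stop("orthogonal component ", a, " is degenerate; reduce n_orth")
    }
    w_o <- w_o / nwo
    t_o <- drop(Xc %*% w_o)
    p_o <- drop(crossprod(Xc, t_o)) / sum(t_o^2)
    Xc <- Xc - tcrossprod(t_o, p_o)
    orth[[a]] <- list(w_orth = w_o, p_orth = p_o, t_orth = t_o)
  }
  w <- drop(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate predictive weight vector")
  w <- w / nw
  t_pred <- drop(Xc %*% w)
  p <- drop(crossprod(Xc, t_pred)) / sum(t_pred^2)
  q <- sum(yc * t_pred) / sum(t_pred^2)
  structure(
    list(features = colnames(X), x_center = x_center, y_mean = y_mean,
         y = y, n_orth = n_orth,
         w = w, p = p, t = t_pred, q = q, orth = orth, threshold = 0.5),
    class = "OplsDaModel")
}

#' @export
print.OplsDaModel <- function(x, ...) {
  cat("OPLS-DA model:", length(x$w), "features, 1 predictive +",
      x$n_orth, "orthogonal component(s)\n")
  cat("  class balance:", sum(x$y == 1), "positive /",
      sum(x$y == 0), "negative\n")
  invisible(x)
}

#' Predict continuous class values from an OPLS-DA model
#'
#' New samples are centred with the training means, the orthogonal
#' variation is removed sequentially, and the filtered projection is mapped
#' through the predictive regression coefficient plus the class-mean
#' offset. Values near 1 indicate the positive (structural cardiotoxin)
#' class.
#'
#' @param object An `OplsDaModel`.
#' @param newdata Samples x features matrix with the training features.
#' @param ... Unused.
#' @return Numeric vector of continuous predictions.
#' @export
predict.OplsDaModel <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X))) {
    X <- X[, object$features, drop = FALSE]
  }
  Xc <- sweep(X, 2L, object$x_center)
  for (oc in object$orth) {
    t_o <- drop(Xc %*% oc$w_orth)
    Xc <- Xc - tcrossprod(t_o, oc$p_orth)
  }
  drop(Xc %*% object$w) * object$q + object$y_mean
}

#' Variable importance in projection (VIP) scores
#'
#' For the single predictive component: `VIP_j = sqrt(p_feat * (w_j /
#' ||w||)^2)`, i.e. `sqrt(p_feat) * |w_j|` since the weights are unit-norm.
#' VIP is computed from the predictive component only (orthogonal
#' components carry no class information by construction). The squared
#' VIPs average to 1 over features, so VIP >= 1 marks an above-average
#' contributor.
#'
#' @param model An `OplsDaModel`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "OplsDaModel"))
  p_feat <- length(model$w)
  v <- sqrt(p_feat * model$w^2 / sum(model$w^2))
  names(v) <- model$features
  v
}

#' Refine an OPLS-DA model by VIP-based feature selection
#'
#' Fits an initial model on the full feature set, retains features with
#' VIP >= `threshold` (inclusive), and refits the full OPLS-DA on the
#' retained subset.
#'
#' @param X Samples x features matrix.
#' @param y Class vector (0/1).
#' @param threshold VIP threshold (default 1.0).
#' @param n_orth Orthogonal components for both fits (default 1).
#' @return List with `initial` and `refined` models, `retained` feature
#'   names, and `vip` (initial-model VIP scores).
#' @export
refine_by_vip <- function(X, y, threshold = 1.0, n_orth = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  initial <- fit_oplsda(X, y, n_orth)
  v <- vip(initial)
  keep <- which(v >= threshold)
  if (!length(keep)) {
    stop("no feature reaches VIP >= ", threshold,
         " (max VIP ", signif(max(v), 4), "); lower the threshold")
  }
  refined <- fit_oplsda(X[, keep, drop = FALSE], y, n_orth)
  list(initial = initial, refined = refined,
       retained = colnames(X)[keep], vip = v)
}

assign_stratified_folds <- function(y, k, max_tries = 100L) {
  n <- length(y)
  if (k < 2L || k > n) stop("k must be in [2, n]")
  if (k == n) return(sample(n))  # leave-one-out
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y[fold != f])) == 2L && sum(fold != f) >= 3L
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training set")
}

#' Stratified k-fold cross-validation of the OPLS-DA pipeline
#'
#' Class-stratified folds; the full pipeline (centering, orthogonal
#' filtering, PLS fit and — when `vip_threshold` is given — VIP selection)
#' is re-fit inside each training fold only, so refinement-induced
#' selection bias is controlled. Every sample is predicted exactly once,
#' out of fold.
#'
#' @param X Samples x features matrix.
#' @param y Class vector (0/1).
#' @param k Number of folds (default 5; `k = n` gives leave-one-out).
#' @param n_orth Orthogonal components (default 1).
#' @param vip_threshold Optional in-fold VIP selection threshold.
#' @return List with `predictions` (per-sample, out of fold), `fold`
#'   (assignments), `q2` (1 - PRESS/TSS), `auc`.
#' @export
kfold_cv <- function(X, y, k = 5L, n_orth = 1L, vip_threshold = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  fold <- assign_stratified_folds(y, k)
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (!any(!tr)) next
    Xtr <- X[tr, , drop = FALSE]
    if (!is.null(vip_threshold)) {
      rf <- refine_by_vip(Xtr, y[tr], vip_threshold, n_orth)
      keep <- rf$retained
      model <- rf$refined
      pred[!tr] <- predict(model, X[!tr, keep, drop = FALSE])
    } else {
      model <- fit_oplsda(Xtr, y[tr], n_orth)
      pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
    }
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(predictions = pred, fold = fold, q2 = 1 - press / tss,
       auc = roc(pred, y)$auc)
}

#' Receiver operating characteristic curve and AUC
#'
#' Threshold sweep over the unique prediction values; the area under the
#' curve is computed by the trapezoidal rule, which equals the
#' Mann-Whitney statistic with half credit for ties.
#'
#' @param predictions Continuous predictions (higher = more positive).
#' @param y Class vector (0/1); both classes required.
#' @return List with `points` (data.frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc <- function(predictions, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("roc: y has a single class")
  ok <- !is.na(predictions)
  predictions <- predictions[ok]; y <- y[ok]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  thr <- c(Inf, sort(unique(predictions), decreasing = TRUE))
  tpr <- vapply(thr, function(s) sum(predictions >= s & y == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(s) sum(predictions >= s & y == 0) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, tpr = tpr, fpr = fpr), auc = auc)
}

#' Permutation test of OPLS-DA model validity
#'
#' The class labels are permuted `B` times and the full cross-validated
#' statistic (CV AUC by default, Q2 optionally) recomputed per permutation.
#' `p = (1 + #\{null >= observed\}) / (B + 1)`; the model is declared valid
#' when p < 0.05. A degenerate observed statistic (all predictions
#' identical) yields p = 1 with a warning.
#'
#' @param X Samples x features matrix.
#' @param y Class vector (0/1).
#' @param B Number of permutations (>= 19; default 99).
#' @param k CV folds (default 5).
#' @param n_orth Orthogonal components (default 1).
#' @param statistic `"auc"` or `"q2"`.
#' @param vip_threshold Optional in-fold VIP selection.
#' @return A `ValidationReport` list: `observed`, `null` (length B),
#'   `p_value`, `valid`, `statistic`, plus the observed CV `predictions`
#'   and `auc`/`q2`.
#' @export
permutation_test <- function(X, y, B = 99L, k = 5L, n_orth = 1L,
                             statistic = c("auc", "q2"),
                             vip_threshold = NULL) {
  statistic <- match.arg(statistic)
  if (B < 19L) stop("B must be >= 19")
  cv <- kfold_cv(X, y, k, n_orth, vip_threshold)
  obs <- if (statistic == "auc") cv$auc else cv$q2
  if (length(unique(round(cv$predictions, 12))) == 1L) {
    warning("degenerate statistic: all predictions identical")
    return(structure(list(observed = obs, null = rep(NA_real_, B),
                          p_value = 1, valid = FALSE, statistic = statistic,
                          cv = cv), class = "ValidationReport"))
  }
  null <- vapply(seq_len(B), function(b) {
    yp <- sample(y)
    cvb <- kfold_cv(X, yp, k, n_orth, vip_threshold)
    if (statistic == "auc") cvb$auc else cvb$q2
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (B + 1)
  structure(list(observed = obs, null = null, p_value = p,
                 valid = p < 0.05, statistic = statistic, cv = cv),
            class = "ValidationReport")
}

#' Overlap of predictive feature sets across exposure durations
#'
#' Venn partition sizes and pairwise overlap fractions
#' (`|A intersect B| / |A union B|`) of the VIP >= 1 feature sets from the
#' initial full-feature models of each duration.
#'
#' @param sets Named list of character vectors (one per duration).
#' @return List with `pairwise` (data.frame `set_a`, `set_b`,
#'   `n_intersect`, `n_union`, `overlap_pct`) and `venn` (named partition
#'   counts for up to 3 sets).
#' @export
duration_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    ni <- length(intersect(a, b)); nu <- length(union(a, b))
    data.frame(set_a = p[1], set_b = p[2], n_intersect = ni, n_union = nu,
               overlap_pct = if (nu == 0) 0 else 100 * ni / nu,
               stringsAsFactors = FALSE)
  }))
  venn <- NULL
  if (length(sets) == 3L) {
    a <- sets[[1]]; b <- sets[[2]]; c <- sets[[3]]
    abc <- length(intersect(intersect(a, b), c))
    venn <- c(
      stats::setNames(c(
        length(setdiff(setdiff(a, b), c)),
        length(setdiff(setdiff(b, a), c)),
        length(setdiff(setdiff(c, a), b))), paste0(nm, "_only")),
      stats::setNames(c(
        length(setdiff(intersect(a, b), c)),
        length(setdiff(intersect(a, c), b)),
        length(setdiff(intersect(b, c), a))),
        c(paste0(nm[1], "_", nm[2]), paste0(nm[1], "_", nm[3]),
          paste0(nm[2], "_", nm[3]))),
      stats::setNames(abc, paste(nm, collapse = "_")))
  }
  list(pairwise = pw, venn = venn)
}
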