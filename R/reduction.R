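#' Logistic principal component analysis of a binary phenotype matrix
#'
#' Low-rank factorization of binary data minimizing the Bernoulli deviance
#' of projected natural parameters. Each observation's natural parameter is
#' modeled as `theta = 1 mu' + (T - 1 mu') U U'`, where `T = m (2X - 1)`
#' caps the saturated natural parameters at scale `m` and `U` is a
#' column-orthonormal loading matrix. The fit uses majorization-
#' minimization: the logistic loss is majorized by a quadratic with
#' curvature 1/4, giving closed-form updates for `mu` (column means of the
#' working response) and `U` (top-k eigenvectors of a working cross-product
#' matrix). Initialization is the singular value decomposition of the
#' centered capped natural parameters, so the fit is deterministic.
#'
#' @param X Binary (0/1 or logical) matrix, individuals x terms. Columns
#'   with no carriers are dropped with a message.
#' @param k Number of components.
#' @param m Scale of the capped natural parameters (default 4; see
#'   [cv_logistic_pca()] for cross-validated selection).
#' @param tol Relative deviance change declaring convergence.
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`
#'   rather than raising an error.
#' @param min_count Minimum number of carriers for a column to enter the
#'   fit (default 2, dropping private terms that carry no shared signal).
#' @return An object of class `logistic_pca`: list with `loadings`
#'   (terms x k, orthonormal columns), `scores` (individuals x k), `mu`,
#'   `m`, `deviance`, `null_deviance`, `deviance_explained` (per-component
#'   and cumulative fractions), `iterations`, `converged`, `dropped`
#'   (excluded column names).
#' @examples
#' X <- matrix(rbinom(200, 1, 0.4), 20, 10,
#'             dimnames = list(paste0("P", 1:20), paste0("T", 1:10)))
#' fit <- fit_logistic_pca(X, k = 2)
#' glance(fit)
#' @export
fit_logistic_pca <- function(X, k = 3, m = 4, tol = 1e-6, max_iter = 1000,
                             min_count = 2) {
  X <- as.matrix(X) * 1
  if (!all(X %in% c(0, 1))) stop("X must be binary", call. = FALSE)
  counts <- colSums(X)
  drop <- counts < min_count
  if (any(drop)) {
    message(sum(drop), " column(s) below min_count dropped")
    dropped <- colnames(X)[drop]
    X <- X[, !drop, drop = FALSE]
  } else dropped <- character(0)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p)) stop("k exceeds matrix dimensions", call. = FALSE)

  Tm <- m * (2 * X - 1)
  pbar <- pmin(pmax(colMeans(X), 0.5 / n), 1 - 0.5 / n)
  mu <- stats::qlogis(pbar)
  Tc <- sweep(Tm, 2, mu)
  U <- svd(Tc, nu = 0, nv = k)$v

  dev_of <- function(theta) {
    q <- 2 * X - 1
    2 * sum(log1p(exp(-q * theta)))
  }
  null_dev <- dev_of(matrix(mu, n, p, byrow = TRUE))

  dev <- Inf; it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    P <- tcrossprod(U)
    theta <- matrix(mu, n, p, byrow = TRUE) + sweep(Tm, 2, mu) %*% P
    dev_new <- dev_of(theta)
    Z <- theta + 4 * (X - stats::plogis(theta))
    mu <- colMeans(Z - Tm %*% P)
    Tc <- sweep(Tm, 2, mu)
    Zc <- sweep(Z, 2, mu)
    B <- crossprod(Tc, Zc)
    B <- B + t(B) - crossprod(Tc)
    U <- eigen(B, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    if (is.finite(dev) && abs(dev - dev_new) / (abs(dev) + 1e-12) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }

  # final pass with converged U
  Tc <- sweep(Tm, 2, mu)
  scores <- Tc %*% U

  # orient each component so its score tracks the presence of its
  # top-loading term
  for (j in seq_len(k)) {
    top <- which.max(abs(U[, j]))
    if (stats::cor(scores[, j], X[, top]) < 0) {
      U[, j] <- -U[, j]
      scores[, j] <- -scores[, j]
    }
  }

  # nested deviance profile over leading components
  dev_k <- vapply(0:k, function(j) {
    Pj <- if (j == 0) matrix(0, p, p) else
      tcrossprod(U[, seq_len(j), drop = FALSE])
    dev_of(matrix(mu, n, p, byrow = TRUE) + Tc %*% Pj)
  }, numeric(1))
  expl <- tibble::tibble(
    component = seq_len(k),
    deviance_explained = (dev_k[-(k + 1)] - dev_k[-1]) / dev_k[1],
    cumulative = 1 - dev_k[-1] / dev_k[1]
  )

  dimnames(U) <- list(colnames(X), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  structure(
    list(loadings = U, scores = scores, mu = stats::setNames(mu, colnames(X)),
         m = m, k = k, deviance = dev_k[k + 1], null_deviance = dev_k[1],
         deviance_explained = expl, iterations = it, converged = converged,
         dropped = dropped),
    class = "logistic_pca"
  )
}

#' @export
print.logistic_pca <- function(x, ...) {
  cat("<logistic_pca> k =", x$k, " m =", x$m,
      " deviance explained =",
      sprintf("%.1f%%", 100 * max(x$deviance_explained$cumulative)),
      if (!x$converged) " [not converged]", "\n")
  invisible(x)
}

#' Cross-validated selection of the natural-parameter scale
#'
#' Five-fold cross-validation of the held-out Bernoulli deviance over a
#' grid of `m` values, holding out individuals (rows). Held-out scores are
#' the projections of the held-out capped natural parameters onto the
#' training loadings.
#'
#' @inheritParams fit_logistic_pca
#' @param m_grid Candidate scales (default `c(2, 4, 6, 8, 10)`).
#' @param folds Number of folds.
#' @param seed Optional seed for the fold split.
#' @return A tibble with columns `m` and `cv_deviance`, with the chosen `m`
#'   (minimum held-out deviance) in attribute `"best_m"`.
#' @export
cv_logistic_pca <- function(X, k = 3, m_grid = c(2, 4, 6, 8, 10), folds = 5,
                            seed = NULL, min_count = 2, ...) {
  X <- as.matrix(X) * 1
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(X)))
  res <- purrr::map_dbl(m_grid, function(m) {
    sum(purrr::map_dbl(seq_len(folds), function(f) {
      tr <- X[fold != f, , drop = FALSE]
      te <- X[fold == f, , drop = FALSE]
      keep <- colSums(tr) >= min_count & colSums(tr) < nrow(tr)
      fit <- fit_logistic_pca(tr[, keep, drop = FALSE], k = k, m = m,
                              min_count = 0, ...)
      tek <- te[, keep, drop = FALSE][, names(fit$mu), drop = FALSE]
      Tc <- sweep(m * (2 * tek - 1), 2, fit$mu)
      theta <- sweep(Tc %*% tcrossprod(fit$loadings), 2, fit$mu, `+`)
      q <- 2 * tek - 1
      2 * sum(log1p(exp(-q * theta)))
    }))
  })
  out <- tibble::tibble(m = m_grid, cv_deviance = res)
  attr(out, "best_m") <- m_grid[which.min(res)]
  out
}

#' Evaluate a score vector against binary labels
#'
#' Computes the ROC curve, the rank-statistic AUC with midrank tie
#' correction, the Youden-optimal cutoff (ties resolved toward higher
#' sensitivity), the precision-recall curve, the F1 score at the Youden
#' cutoff, and empirical positive/negative predictive value sweeps over
#' score thresholds in both directions.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (or coercible): `TRUE` is the positive
#'   class. Both classes must be present.
#' @return An object of class `classifier_eval`: list with scalars `auc`,
#'   `cutoff`, `sensitivity`, `specificity`, `precision`, `f1` and tibbles
#'   `roc` (`threshold`, `sensitivity`, `specificity`), `pr` (`threshold`,
#'   `recall`, `precision`) and `ppv` (`threshold`, `ppv`, `npv`).
#' @export
evaluate_component <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)

  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(labels & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!labels & scores < t) / n0, numeric(1))
  roc <- tibble::tibble(threshold = thr, sensitivity = sens,
                        specificity = spec)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]  # ties -> higher sensitivity
  cutoff <- thr[best]

  prec <- vapply(thr, function(t) {
    pred <- scores >= t
    if (!any(pred)) NA_real_ else sum(labels & pred) / sum(pred)
  }, numeric(1))
  pr <- tibble::tibble(threshold = thr, recall = sens, precision = prec)
  prec_c <- prec[best]
  f1 <- if (is.na(prec_c) || prec_c + sens[best] == 0) 0 else
    2 * prec_c * sens[best] / (prec_c + sens[best])

  ppv <- tibble::tibble(
    threshold = thr,
    ppv = prec,
    npv = vapply(thr, function(t) {
      pred <- scores < t
      if (!any(pred)) NA_real_ else sum(!labels & pred) / sum(pred)
    }, numeric(1))
  )

  structure(
    list(auc = auc, cutoff = cutoff, sensitivity = sens[best],
         specificity = spec[best], precision = prec_c, f1 = f1,
         roc = roc, pr = pr, ppv = ppv, n_pos = n1, n_neg = n0),
    class = "classifier_eval"
  )
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf(
    "<classifier_eval> AUC %.3f | cutoff %.3g | sens %.2f spec %.2f F1 %.2f\n",
    x$auc, x$cutoff, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Predict variant function (GoF vs LoF) from phenotype component scores
#'
#' Uses the component scores of a fitted [fit_logistic_pca()] model to
#' classify variants as gain- or loss-of-function. The discriminating
#' component is oriented so that higher scores mean GoF, a Youden-optimal
#' cutoff is estimated from the functionally labeled subset, and every
#' individual (labeled or not) is classified by thresholding. The empirical
#' positive predictive value at each individual's score is read off the
#' labeled subset: for a GoF call, the fraction of GoF among labeled
#' individuals scoring at least as high; for a LoF call, the fraction of
#' LoF among labeled individuals scoring at least as low.
#'
#' @param variants Variant tibble with columns `individual_id`, `hgvs_p`
#'   and `functional` (`"GoF"`, `"LoF"` or `"unclassified"`; see
#'   [assign_function()]).
#' @param fit A [`logistic_pca`][fit_logistic_pca] model whose score rows
#'   are named by individual id.
#' @param component Which component to use; `NULL` (default) picks the
#'   component with the highest AUC on the labeled subset.
#' @return A tibble: `individual_id`, `hgvs_p`, `functional`, `score`
#'   (oriented), `predicted`, `ppv`; the chosen component index is in
#'   attribute `"component"` and its [evaluate_component()] result in
#'   attribute `"eval"`. A recurrent variant appears once per carrier, so
#'   phenotypically different carriers can receive different calls.
#' @export
predict_variant_function <- function(variants, fit, component = NULL) {
  v <- variants[variants$individual_id %in% rownames(fit$scores), ]
  labeled <- v$functional %in% c("GoF", "LoF")
  if (!any(labeled)) stop("no functionally labeled individuals", call. = FALSE)
  if (!any(v$functional[labeled] == "GoF") ||
      !any(v$functional[labeled] == "LoF")) {
    stop("need both GoF and LoF labels", call. = FALSE)
  }
  S <- fit$scores[v$individual_id, , drop = FALSE]
  is_gof <- v$functional == "GoF"

  orient <- function(s) {
    if (mean(s[labeled & is_gof]) < mean(s[labeled & !is_gof])) -s else s
  }
  if (is.null(component)) {
    aucs <- apply(S, 2, function(s) {
      evaluate_component(orient(s)[labeled], is_gof[labeled])$auc
    })
    component <- unname(which.max(aucs))
  }
  s <- unname(orient(S[, component]))
  eval <- evaluate_component(s[labeled], is_gof[labeled])

  sl <- s[labeled]; gl <- is_gof[labeled]
  ppv_at <- function(si, call_gof) {
    idx <- if (call_gof) sl >= si else sl <= si
    if (!any(idx)) {
      # beyond every labeled score: carry the most extreme labeled value
      idx <- if (call_gof) sl == max(sl) else sl == min(sl)
    }
    if (call_gof) mean(gl[idx]) else mean(!gl[idx])
  }
  predicted <- ifelse(s >= eval$cutoff, "GoF", "LoF")
  ppv <- purrr::map2_dbl(s, predicted == "GoF", ppv_at)

  out <- tibble::tibble(
    individual_id = v$individual_id, hgvs_p = v$hgvs_p,
    functional = v$functional, score = unname(s),
    predicted = predicted, ppv = ppv
  )
  attr(out, "component") <- component
  attr(out, "eval") <- eval
  out
}
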