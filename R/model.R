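# LASSO feature selection (glmnet), sparse multiple linear regression by
# expectation maximization, repeated-split bootstrap evaluation and
# coefficient ranking.

#' Model configuration
#'
#' @param nBoot number of random 80/20 splits (study value 50).
#' @param trainFraction training fraction (study value 0.8).
#' @param lassoCvFolds folds for the LASSO cross-validation (default 5).
#' @param emMaxIter,emTol EM iteration cap and convergence tolerance on
#'   the largest coefficient change (defaults 500, 1e-6).
#' @param emLambda L1 penalty weight of the EM's Laplace prior on the
#'   standardized scale (default 1e-3; LASSO has already removed
#'   irrelevant features, so the EM refit applies only mild shrinkage).
#' @param pruneTol coefficients below this magnitude are set to exactly
#'   zero (default 1e-8).
#' @param lassoRule penalty choice, `"1se"` (default, biases towards
#'   sparsity) or `"min"`.
#' @param seed integer seed.
#' @return a validated list of class `ModelConfig`.
#' @export
modelConfig <- function(nBoot = 50L, trainFraction = 0.8, lassoCvFolds = 5L,
                        emMaxIter = 500L, emTol = 1e-6, emLambda = 1e-3,
                        pruneTol = 1e-8, lassoRule = c("1se", "min"),
                        seed = 1L) {
  lassoRule <- match.arg(lassoRule)
  stopifnot(trainFraction > 0, trainFraction < 1, emTol > 0, pruneTol > 0,
            emLambda >= 0, nBoot >= 1, lassoCvFolds >= 2, emMaxIter >= 1)
  structure(list(nBoot = as.integer(nBoot), trainFraction = trainFraction,
                 lassoCvFolds = as.integer(lassoCvFolds),
                 emMaxIter = as.integer(emMaxIter), emTol = emTol,
                 emLambda = emLambda, pruneTol = pruneTol,
                 lassoRule = lassoRule, seed = as.integer(seed)),
            class = "ModelConfig")
}

#' LASSO feature selection
#'
#' L1-penalized linear regression with the penalty chosen by k-fold
#' cross-validation; by default the 1-SE rule, which biases towards
#' sparser models. Columns are standardized internally. The empty set is
#' a legitimate result (pure-noise responses usually return it).
#'
#' Uses the caller's RNG stream for the CV fold assignment, so results are
#' reproducible under `set.seed()`.
#'
#' @param X numeric matrix (polymers x descriptors, named columns).
#' @param y numeric response aligned with the rows of `X`.
#' @param config a [modelConfig()].
#' @return character vector of selected descriptor names.
#' @export
lassoSelect <- function(X, y, config = modelConfig()) {
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("no variance to model")
  if (nrow(X) < config$lassoCvFolds)
    stop("need at least as many samples as CV folds")
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  Xk <- X[, keep, drop = FALSE]
  if (!ncol(Xk)) return(character())
  foldid <- sample(rep_len(seq_len(config$lassoCvFolds), nrow(Xk)))
  cv <- glmnet::cv.glmnet(Xk, y, alpha = 1, foldid = foldid,
                          standardize = TRUE,
                          grouped = nrow(Xk) >= 3 * config$lassoCvFolds)
  lam <- if (config$lassoRule == "1se") cv$lambda.1se else cv$lambda.min
  co <- as.matrix(stats::coef(cv, s = lam))[-1L, 1L]
  names(co)[co != 0]
}

# Penalized log-likelihood of the EM objective on the standardized scale
# (sigma^2 = 1): -(1/2)||y - Xw||^2 - lambda * sum|w|.
.emObjective <- function(Xs, ys, w, lambda) {
  r <- ys - as.numeric(Xs %*% w)
  -0.5 * sum(r^2) - lambda * sum(abs(w))
}

#' Sparse multiple linear regression by expectation maximization
#'
#' Fits a Bayesian linear model under a Laplace (double-exponential)
#' sparsity prior, using the prior's representation as a scale mixture of
#' normals: conditionally on a per-coefficient variance tau_j, w_j ~
#' N(0, tau_j) and tau_j is exponentially distributed. Treating the tau_j
#' as latent variables gives an EM algorithm whose
#'
#' * E-step computes the expected inverse scale of each coefficient,
#'   `u_j = lambda / |w_j|`, from the current estimate, and whose
#' * M-step solves the weighted ridge system
#'   `(X'X + diag(lambda / |w_j|)) w = X'y`
#'
#' on the standardized design. Each M-step solves a quadratic surrogate
#' that touches and majorizes the L1 penalty at the current iterate, so
#' the penalized log-likelihood is non-decreasing at every iteration
#' (asserted; the trace is returned in the `objective` slot). Coefficients
#' whose magnitude falls below `pruneTol` are frozen at exactly zero and
#' leave the active set. The intercept is fit on the unstandardized
#' response.
#'
#' @param X numeric matrix of the (LASSO-selected) descriptors; may have
#'   zero columns, which yields an intercept-only fit at `mean(y)`.
#' @param y numeric response.
#' @param config a [modelConfig()].
#' @return a [SparseFit-class] with coefficients on the original
#'   descriptor scale.
#' @export
emSparseRegression <- function(X, y, config = modelConfig()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  if (p == 0L)
    return(new("SparseFit", selected = character(), coefficients = numeric(),
               intercept = mean(y), converged = TRUE, nIter = 0L,
               objective = numeric(), xCenter = numeric(), xScale = numeric()))
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(p))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1      # constant columns carry no signal; coef stays 0
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  ym <- mean(y)
  ys <- y - ym
  lambda <- config$emLambda
  XtX <- crossprod(Xs)
  Xty <- as.numeric(crossprod(Xs, ys))
  # init: ridge solution (stable for p close to or above n)
  w <- tryCatch(solve(XtX + diag(1e-6, p), Xty),
                error = function(e) rep(1e-3, p))
  active <- rep(TRUE, p)
  obj <- .emObjective(Xs, ys, w, lambda)
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < config$emMaxIter) {
    it <- it + 1L
    wOld <- w
    # freeze vanishing coefficients at exactly zero (the E-step weight
    # lambda/|w| diverges as w -> 0); frozen coefficients never re-enter
    active[abs(w) < config$pruneTol] <- FALSE
    w[!active] <- 0
    if (!any(active)) { converged <- TRUE; break }
    objPruned <- .emObjective(Xs, ys, w, lambda)
    ai <- which(active)
    u <- lambda / abs(w[ai])               # E-step: expected inverse scales
    A <- XtX[ai, ai, drop = FALSE]
    diag(A) <- diag(A) + u
    wNew <- tryCatch(solve(A, Xty[ai]), error = function(e) {
      diag(A) <- diag(A) + 1e-10           # ridge-jitter retry
      solve(A, Xty[ai])
    })
    w[ai] <- wNew
    objNew <- .emObjective(Xs, ys, w, lambda)
    # MM guarantee: the M-step maximizes a minorizer touching at the
    # (pruned) current iterate, so the objective cannot decrease
    if (objNew < objPruned - 1e-8 * max(1, abs(objPruned)))
      stop(sprintf("EM objective decreased at iteration %d (%.10g -> %.10g)",
                   it, objPruned, objNew))
    obj <- objNew
    trace <- c(trace, obj)
    if (max(abs(w - wOld)) < config$emTol) { converged <- TRUE; break }
  }
  w[abs(w) < config$pruneTol] <- 0
  sel <- colnames(X)[w != 0]
  coefOrig <- (w / scl)[w != 0]
  names(coefOrig) <- sel
  intercept <- ym - sum(coefOrig * ctr[w != 0])
  new("SparseFit", selected = sel, coefficients = coefOrig,
      intercept = intercept, converged = converged, nIter = it,
      objective = trace, xCenter = ctr, xScale = scl)
}

#' Repeated-split bootstrap evaluation
#'
#' For each of `nBoot` random 80/20 splits (repeated random subsampling
#' without replacement; 80/20 proportions are incompatible with classical
#' with-replacement bootstrap sizing): LASSO selection and the EM sparse
#' fit on the training split only (standardization parameters included, so
#' there is no leakage), then test RMSE and test R^2 with SStot about the
#' test-split mean. A test split with zero response variance records an NA
#' R^2 and is excluded from summaries. `lassoMode = "single"` instead runs
#' the LASSO once on the full data before splitting (the leakier variant).
#'
#' @param X numeric descriptor matrix (named columns).
#' @param y numeric response.
#' @param config a [modelConfig()]; `config$seed` makes the result
#'   bit-reproducible.
#' @param lassoMode `"per-split"` (default) or `"single"`.
#' @return a [BootstrapResult-class].
#' @export
bootstrapEvaluate <- function(X, y, config = modelConfig(),
                              lassoMode = c("per-split", "single")) {
  lassoMode <- match.arg(lassoMode)
  n <- nrow(X)
  stopifnot(n >= 10, length(y) == n)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$nBoot)
  singleSel <- if (lassoMode == "single") lassoSelect(X, y, config) else NULL
  rmse <- r2 <- rep(NA_real_, config$nBoot)
  fits <- vector("list", config$nBoot)
  testIdx <- vector("list", config$nBoot)
  nTrain <- max(2L, floor(config$trainFraction * n))
  for (b in seq_len(config$nBoot)) {
    set.seed(seeds[b])
    tr <- sort(sample.int(n, nTrain))
    te <- setdiff(seq_len(n), tr)
    sel <- if (lassoMode == "single") singleSel
           else lassoSelect(X[tr, , drop = FALSE], y[tr], config)
    fit <- emSparseRegression(X[tr, sel, drop = FALSE], y[tr], config)
    pred <- predict(fit, X[te, , drop = FALSE])
    res <- y[te] - pred
    rmse[b] <- sqrt(mean(res^2))
    sstot <- sum((y[te] - mean(y[te]))^2)
    r2[b] <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
    fits[[b]] <- fit
    testIdx[[b]] <- te
  }
  allFeat <- colnames(X)
  freq <- vapply(allFeat, function(f)
    mean(vapply(fits, function(ft) f %in% ft@selected, logical(1))),
    numeric(1))
  new("BootstrapResult", rmse = rmse, r2 = r2, selectionFrequency = freq,
      fits = fits, seeds = as.integer(seeds %% .Machine$integer.max),
      testIndices = testIdx)
}

#' Rank descriptors across bootstrap fits
#'
#' Per feature: selection frequency, mean coefficient over the fits where
#' it was selected, and the sign consensus ("+", "-", or "mixed"); sorted
#' by |mean coefficient|. "Significant" features are those selected in
#' more than `freqMin` of the fits (default 50%).
#'
#' @param fits a [BootstrapResult-class] or a list of
#'   [SparseFit-class] objects.
#' @param freqMin significance threshold on selection frequency.
#' @return data.frame: `feature`, `frequency`, `mean_coefficient`, `sign`,
#'   `significant`, sorted by decreasing |mean coefficient|.
#' @export
rankCoefficients <- function(fits, freqMin = 0.5) {
  if (is(fits, "BootstrapResult")) fits <- fits@fits
  stopifnot(length(fits) >= 1)
  feats <- sort(unique(unlist(lapply(fits, function(f) f@selected))))
  rows <- lapply(feats, function(f) {
    co <- unlist(lapply(fits, function(ft) ft@coefficients[f]))
    co <- co[!is.na(co)]
    sgn <- if (all(co > 0)) "+" else if (all(co < 0)) "-" else "mixed"
    data.frame(feature = f, frequency = length(co) / length(fits),
               mean_coefficient = mean(co), sign = sgn)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), frequency = numeric(),
               mean_coefficient = numeric(), sign = character())
  out$significant <- out$frequency > freqMin
  out <- out[order(-abs(out$mean_coefficient)), ]
  rownames(out) <- NULL
  out
}
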