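## Regularized partial-correlation network: graphical lasso + EBIC tuning.

#' Graphical lasso configuration
#'
#' @param gamma EBIC hyperparameter; 0 reduces EBIC to BIC, 0.5 (the
#'   default) favours sparser models
#' @param nLambda number of penalties on the log-spaced path
#' @param lambdaMinRatio smallest penalty as a fraction of lambda_max (the
#'   largest absolute off-diagonal correlation)
#' @param tol relative convergence tolerance of the coordinate descent
#' @param maxIter outer iteration cap
#' @return list of class `GlassoConfig`
#' @export
glassoConfig <- function(gamma = 0.5, nLambda = 100L, lambdaMinRatio = 0.01,
                         tol = 1e-4, maxIter = 200L) {
  stopifnot(gamma >= 0, nLambda >= 1, lambdaMinRatio > 0,
            lambdaMinRatio <= 1, tol > 0, maxIter >= 1)
  structure(list(gamma = gamma, nLambda = as.integer(nLambda),
                 lambdaMinRatio = lambdaMinRatio, tol = tol,
                 maxIter = as.integer(maxIter)),
            class = "GlassoConfig")
}

asCorMatrix <- function(S) {
  if (is(S, "CorrelationMatrix")) S@rho else as.matrix(S)
}

#' Fit the graphical lasso at one penalty
#'
#' Maximizes `log det Theta - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|`
#' by blockwise coordinate descent (lasso regressions on the current
#' covariance estimate). The diagonal is unpenalized, so any
#' `lambda >= max |S_ij|` yields the fully disconnected model.
#'
#' @param S correlation matrix (or [CorrelationMatrix-class])
#' @param lambda penalty, >= 0
#' @param cfg a [glassoConfig()]
#' @param warm optional warm start (list with `W` and `B` from a previous
#'   fit at a nearby penalty)
#' @return list with `Theta` (precision estimate), `partials`
#'   (partial-correlation matrix, zero diagonal), `W`, `B`, `converged`
#' @export
glassoFit <- function(S, lambda, cfg = glassoConfig(), warm = NULL) {
  S <- asCorMatrix(S)
  stopifnot(lambda >= 0)
  fit <- .glassoCpp(S, lambda, cfg$tol, cfg$maxIter,
                    W_init = warm$W, B_init = warm$B)
  if (!fit$converged)
    stop(sprintf(
      "graphical lasso did not converge in %d iterations (max update %.3g)",
      cfg$maxIter, fit$maxdiff))
  Theta <- fit$Theta
  d <- sqrt(diag(Theta))
  partials <- -Theta / tcrossprod(d)
  diag(partials) <- 0
  partials[abs(partials) < 1e-10] <- 0   # structural-zero guard
  partials <- (partials + t(partials)) / 2
  dimnames(Theta) <- dimnames(partials) <- dimnames(S)
  list(Theta = Theta, partials = partials, W = fit$W, B = fit$B,
       converged = fit$converged)
}

#' Extended Bayesian Information Criterion of a fitted precision matrix
#'
#' `EBIC = -2 l(Theta) + E log n + 4 E gamma log p` with
#' `l = (n/2)(log det Theta - tr(S Theta))` and E the number of nonzero
#' off-diagonal pairs. With `gamma = 0` this is the ordinary BIC.
#'
#' @param Theta positive-definite precision estimate
#' @param S the correlation matrix the model was fit to
#' @param n sample size
#' @param gamma EBIC hyperparameter
#' @return the EBIC value (smaller is better)
#' @export
ebic <- function(Theta, S, n, gamma) {
  S <- asCorMatrix(S)
  ch <- tryCatch(chol(Theta), error = function(e) NULL)
  if (is.null(ch)) stop("Theta must be positive definite")
  p <- ncol(Theta)
  E <- sum(abs(Theta[upper.tri(Theta)]) > 1e-10)
  ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(S * Theta))
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' EBIC-tuned graphical lasso over a penalty path
#'
#' Evaluates a log-spaced path of `cfg$nLambda` penalties from
#' `lambda_max = max |S_ij|` (the empty network) down to
#' `lambdaMinRatio * lambda_max`, with warm starts, and returns the network
#' minimizing the EBIC at the configured gamma. The likelihood is evaluated
#' at the penalized estimate (no post-selection refit). Ties are broken
#' toward the larger penalty (the sparser model).
#'
#' @param S correlation matrix (or [CorrelationMatrix-class])
#' @param n sample size behind S
#' @param cfg a [glassoConfig()]
#' @return a [WeightedNetwork-class] carrying the selected weights, the
#'   selected penalty, and the full path (lambda, nEdges, loglik, ebic)
#' @export
ebicGlasso <- function(S, n, cfg = glassoConfig()) {
  Sm <- asCorMatrix(S)
  checkSquareLabelled(Sm, "correlation matrix")
  p <- ncol(Sm)
  lmax <- max(abs(Sm[row(Sm) != col(Sm)]))
  if (lmax < 1e-10) {
    # diagonal S: the unpenalized MLE is already the empty network
    w <- matrix(0, p, p, dimnames = dimnames(Sm))
    ll <- -(n / 2) * p
    path <- data.frame(lambda = 0, nEdges = 0L, loglik = ll, ebic = -2 * ll)
    return(new("WeightedNetwork", weights = w, lambdaSelected = 0,
               ebicPath = path, gamma = cfg$gamma, n = as.numeric(n)))
  }
  lambdas <- exp(seq(log(lmax), log(lmax * cfg$lambdaMinRatio),
                     length.out = cfg$nLambda))
  warm <- NULL
  fits <- vector("list", length(lambdas))
  path <- data.frame(lambda = lambdas, nEdges = NA_integer_,
                     loglik = NA_real_, ebic = NA_real_)
  for (k in seq_along(lambdas)) {
    fit <- glassoFit(Sm, lambdas[k], cfg, warm = warm)
    warm <- fit
    fits[[k]] <- fit
    Theta <- fit$Theta
    ch <- chol(Theta)
    ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(Sm * Theta))
    E <- sum(abs(fit$partials[upper.tri(Theta)]) > 1e-10)
    path$nEdges[k] <- E
    path$loglik[k] <- ll
    path$ebic[k] <- -2 * ll + E * log(n) + 4 * E * cfg$gamma * log(p)
  }
  best <- which(path$ebic <= min(path$ebic) + 0)[1]  # first = largest lambda
  w <- fits[[best]]$partials
  new("WeightedNetwork", weights = w, lambdaSelected = lambdas[best],
      ebicPath = path, gamma = cfg$gamma, n = as.numeric(n))
}

#' KKT residual of a graphical-lasso solution
#'
#' Stationarity check of the penalized objective: for nonzero entries
#' `|W_ij - S_ij - lambda sign(Theta_ij)|`, for zero entries
#' `max(0, |W_ij - S_ij| - lambda)`, with `W = Theta^-1`. Reported as the
#' maximum over off-diagonal entries; the diagonal must satisfy
#' `W_ii = S_ii`.
#'
#' @param Theta precision estimate
#' @param S correlation matrix
#' @param lambda penalty used in the fit
#' @return the maximum subgradient violation
#' @export
glassoKkt <- function(Theta, S, lambda) {
  S <- asCorMatrix(S)
  W <- solve(Theta)
  G <- W - S
  off <- row(W) != col(W)
  nz <- off & abs(Theta) > 1e-10
  z <- off & !nz
  r1 <- if (any(nz)) max(abs(G[nz] - lambda * sign(Theta[nz]))) else 0
  r2 <- if (any(z)) max(0, max(abs(G[z])) - lambda) else 0
  r3 <- max(abs(diag(G)))
  max(r1, r2, r3)
}

#' Edge list of a weighted network
#'
#' @param net a [WeightedNetwork-class]
#' @return data.frame with columns node_a, node_b, weight (nonzero edges
#'   only, upper-triangle order)
#' @export
networkEdgeList <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  w <- net@weights
  idx <- which(upper.tri(w) & abs(w) > 1e-10, arr.ind = TRUE)
  lab <- nodeLabels(net)
  data.frame(node_a = lab[idx[, 1]], node_b = lab[idx[, 2]],
             weight = w[idx], stringsAsFactors = FALSE)
}
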