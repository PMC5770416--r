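scale_cols <- function(x, center = NULL, scl = NULL) {
  center <- center %||% colMeans(x)
  xc <- sweep(x, 2, center, "-")
  if (is.null(scl)) {
    scl <- sqrt(colSums(xc^2) / (nrow(x) - 1))
  }
  if (any(scl == 0))
    stop("zero-variance column(s): ",
         paste(utils::head(colnames(x)[scl == 0], 5), collapse = ", "))
  list(x = sweep(xc, 2, scl, "/"), center = center, scale = scl)
}

# Soft-threshold a loading vector so that at most `keep` entries are nonzero,
# ties at the threshold broken by lexicographic feature id (smaller id wins a
# place in the support via the ordering; a tied excluded magnitude shrinks the
# boundary entry to zero, so the nonzero count never exceeds `keep`).
soft_threshold_keep <- function(w, keep) {
  p <- length(w)
  if (keep >= p) return(w)
  ord <- order(-abs(w), names(w))
  lambda <- abs(w[ord[keep + 1]])
  sign(w) * pmax(abs(w) - lambda, 0)
}

#' Sparse partial least squares (regression mode)
#'
#' NIPALS-style sPLS coupling a miRNA predictor block `X` to an mRNA response
#' block `Y`. Per component the cross-covariance matrix \eqn{M = X^T Y} of the
#' (centered, unit-scaled, then deflated) blocks is formed; the Y-loading `v`
#' is initialized from the dominant right singular vector of `M`, and the
#' update \eqn{u \propto soft(Mv, \lambda_u)}, \eqn{v \propto soft(M^T u,
#' \lambda_v)} is iterated, with the soft-threshold levels set so at most
#' `keepX` / `keepY` loadings are nonzero (ties at the boundary broken by
#' feature-id order). Loadings are unit-normalized each iteration. After
#' convergence the scores \eqn{\xi = Xu}, \eqn{\omega = Yv} are computed and
#' both blocks are deflated by regression on \eqn{\xi} (regression mode), so
#' successive X-scores are mutually orthogonal.
#'
#' @param X Observation x miRNA matrix.
#' @param Y Observation x mRNA matrix (same rows as `X`).
#' @param keepX,keepY Number of predictor / response features retained per
#'   component (recycled to `n_comp`). Defaults keep all.
#' @param n_comp Number of components (default 1).
#' @param max_iter,tol Convergence controls: stop when the largest loading
#'   change is below `tol` (default 1e-6) or after `max_iter` (default 500)
#'   iterations, in which case the model is returned with
#'   `converged = FALSE` and a warning.
#' @return List of class `"spls_model"`: `X_loadings`, `Y_loadings` (feature x
#'   component, unit-norm on their support), `X_scores`, `Y_scores`,
#'   `keepX`, `keepY`, `n_comp`, `converged`, `iterations`, plus the scaling
#'   parameters and per-component deflation/regression vectors needed by
#'   [predict_spls()].
#' @export
spls_fit <- function(X, Y, keepX = ncol(X), keepY = ncol(Y), n_comp = 1,
                     max_iter = 500, tol = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must share observation rows")
  if (nrow(X) < 2) stop("need at least 2 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  keepX <- pmin(rep_len(keepX, n_comp), ncol(X))
  keepY <- pmin(rep_len(keepY, n_comp), ncol(Y))
  if (any(keepX < 1) || any(keepY < 1)) stop("keepX/keepY must be >= 1")

  sx <- scale_cols(X); sy <- scale_cols(Y)
  Xc <- sx$x; Yc <- sy$x
  n <- nrow(Xc)
  U <- matrix(0, ncol(X), n_comp, dimnames = list(colnames(X), NULL))
  V <- matrix(0, ncol(Y), n_comp, dimnames = list(colnames(Y), NULL))
  XI <- matrix(0, n, n_comp)
  OM <- matrix(0, n, n_comp)
  Cx <- matrix(0, ncol(X), n_comp)   # X deflation regression vectors
  Dy <- matrix(0, ncol(Y), n_comp)   # Y regression vectors on the score
  converged <- logical(n_comp)
  iterations <- integer(n_comp)

  d_ref <- NA_real_
  for (h in seq_len(n_comp)) {
    M <- crossprod(Xc, Yc)
    sv <- svd(M, nu = 1, nv = 1)
    if (h == 1) {
      d_ref <- sv$d[1]
      if (d_ref <= 0)
        stop("X and Y have zero cross-covariance; cannot fit a component")
    } else if (sv$d[1] <= max(d_ref, 1) * 1e-12) {
      # the deflated blocks carry no remaining shared signal: the requested
      # component count exceeds the effective rank, so truncate the model
      warning("cross-covariance exhausted after ", h - 1,
              " component(s); truncating from ", n_comp)
      n_comp <- h - 1L
      U <- U[, seq_len(n_comp), drop = FALSE]
      V <- V[, seq_len(n_comp), drop = FALSE]
      XI <- XI[, seq_len(n_comp), drop = FALSE]
      OM <- OM[, seq_len(n_comp), drop = FALSE]
      Cx <- Cx[, seq_len(n_comp), drop = FALSE]
      Dy <- Dy[, seq_len(n_comp), drop = FALSE]
      keepX <- keepX[seq_len(n_comp)]
      keepY <- keepY[seq_len(n_comp)]
      converged <- converged[seq_len(n_comp)]
      iterations <- iterations[seq_len(n_comp)]
      break
    }
    v <- drop(sv$v)
    names(v) <- colnames(Y)
    # deterministic sign: largest-magnitude entry positive
    i0 <- which.max(abs(v))
    if (v[i0] < 0) v <- -v
    u <- stats::setNames(numeric(ncol(X)), colnames(X))
    for (it in seq_len(max_iter)) {
      u_old <- u; v_old <- v
      u <- soft_threshold_keep(drop(M %*% v), keepX[h])
      nu <- sqrt(sum(u^2))
      if (nu == 0) stop("X loading collapsed to zero in component ", h)
      u <- u / nu
      v <- soft_threshold_keep(drop(crossprod(M, u)), keepY[h])
      nv <- sqrt(sum(v^2))
      if (nv == 0) stop("Y loading collapsed to zero in component ", h)
      v <- v / nv
      if (max(abs(u - u_old), abs(v - v_old)) < tol) {
        converged[h] <- TRUE
        iterations[h] <- it
        break
      }
      iterations[h] <- it
    }
    if (!converged[h])
      warning("sPLS component ", h, " did not converge in ", max_iter,
              " iterations")
    xi <- drop(Xc %*% u)
    omega <- drop(Yc %*% v)
    ss <- sum(xi^2)
    if (ss == 0) stop("degenerate zero score in component ", h)
    cx <- drop(crossprod(Xc, xi)) / ss
    dy <- drop(crossprod(Yc, xi)) / ss
    Xc <- Xc - tcrossprod(xi, cx)
    Yc <- Yc - tcrossprod(xi, dy)
    U[, h] <- u; V[, h] <- v; XI[, h] <- xi; OM[, h] <- omega
    Cx[, h] <- cx; Dy[, h] <- dy
  }
  structure(list(X_loadings = U, Y_loadings = V, X_scores = XI, Y_scores = OM,
                 keepX = keepX, keepY = keepY, n_comp = n_comp,
                 converged = converged, iterations = iterations,
                 x_center = sx$center, x_scale = sx$scale,
                 y_center = sy$center, y_scale = sy$scale,
                 x_defl = Cx, y_reg = Dy),
            class = "spls_model")
}

#' Predict the response block from a fitted sPLS model
#'
#' Applies the training centering/scaling and the per-component deflation
#' chain to new predictor rows, then reconstructs Y from the component scores
#' and the training regression vectors. With `selected_only = TRUE`,
#' response columns with a zero loading on every component are predicted as
#' their (scaled) mean of zero -- the criterion used by [tune_spls_keepy()].
#'
#' @param model A fitted [spls_fit()] model.
#' @param newX New observation x miRNA matrix (training columns).
#' @param selected_only Restrict the reconstruction to selected Y columns.
#' @return List with `scores` (observation x component) and `Y_scaled`
#'   (predictions on the scaled response scale).
#' @export
predict_spls <- function(model, newX, selected_only = FALSE) {
  newX <- as.matrix(newX)
  xt <- sweep(sweep(newX, 2, model$x_center, "-"), 2, model$x_scale, "/")
  n <- nrow(xt)
  scores <- matrix(0, n, model$n_comp)
  yhat <- matrix(0, n, nrow(model$Y_loadings))
  colnames(yhat) <- rownames(model$Y_loadings)
  for (h in seq_len(model$n_comp)) {
    xi <- drop(xt %*% model$X_loadings[, h])
    scores[, h] <- xi
    d <- model$y_reg[, h]
    if (selected_only) d <- d * (model$Y_loadings[, h] != 0)
    yhat <- yhat + tcrossprod(xi, d)
    xt <- xt - tcrossprod(xi, model$x_defl[, h])
  }
  list(scores = scores, Y_scaled = yhat)
}

#' Tune the number of retained response features by leave-one-out error
#'
#' For each `keepY` in the grid, fits the sPLS model on all observations but
#' one and measures the squared prediction error of the held-out response row
#' (on the training-scaled response scale; columns never selected predict
#' zero, their scaled mean). Returns the grid value with minimal mean error;
#' ties (within `1e-10` relative) resolve to the smallest `keepY`.
#'
#' @param X,Y Observation-matched predictor / response matrices.
#' @param keepY_grid Candidate `keepY` values (non-empty).
#' @param keepX,n_comp Passed to [spls_fit()].
#' @return List with `keepY` (chosen value) and `loo_mse` (named vector over
#'   the grid).
#' @export
tune_spls_keepy <- function(X, Y, keepY_grid, keepX = ncol(X), n_comp = 1) {
  if (length(keepY_grid) == 0) stop("keepY grid must be non-empty")
  keepY_grid <- sort(unique(pmin(as.integer(keepY_grid), ncol(Y))))
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations to tune by leave-one-out")
  mse <- sapply(keepY_grid, function(k) {
    err <- vapply(seq_len(n), function(i) {
      fit <- spls_fit(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                      keepX = keepX, keepY = k, n_comp = n_comp)
      pred <- predict_spls(fit, X[i, , drop = FALSE], selected_only = TRUE)
      ytest <- (Y[i, ] - fit$y_center) / fit$y_scale
      mean((ytest - drop(pred$Y_scaled))^2)
    }, numeric(1))
    mean(err)
  })
  names(mse) <- keepY_grid
  best <- min(mse)
  chosen <- keepY_grid[which(mse <= best * (1 + 1e-10) + 1e-15)][1]
  list(keepY = chosen, loo_mse = mse)
}
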