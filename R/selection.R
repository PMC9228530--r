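# Shared helpers and result container for the sparse compositional
# selectors (clr_lasso, coda_lasso, selbal).

get_counts <- function(x) {
  if (inherits(x, "feature_table")) x$counts else as.matrix(x)
}

# Rank-based AUC of `score` for discriminating the second level of `y`.
rank_auc <- function(score, y) {
  y <- as.factor(y)
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment, deterministic under the active RNG state.
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(as.factor(y))) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

selection_result <- function(method, taxa, coefficient, direction,
                             role = NA_character_, score = NA_real_,
                             groups) {
  out <- tibble::tibble(taxon = taxa, coefficient = coefficient,
                        role = role, direction = direction)
  structure(out, class = c("selection_result", class(out)),
            method = method, score = score, groups = groups)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s> %d taxa selected, CV AUC %.3f\n",
              attr(x, "method"), nrow(x), attr(x, "score")))
  NextMethod()
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), n_selected = nrow(x),
                 score = attr(x, "score"))
}

#' Sparse CLR-lasso taxon selection
#'
#' CLR-transforms the (pseudocounted, closed) counts and fits an
#' L1-penalized logistic classifier over the glmnet path; the penalty is
#' the smallest on the path yielding at most `max_taxa` nonzero
#' coefficients. The direction of each selected taxon is the group its
#' coefficient sign points to; the discrimination score is a
#' cross-validated AUC at the chosen penalty.
#'
#' @param table A [feature_table()] or a features-by-samples count matrix.
#' @param metadata Metadata tibble with two group levels.
#' @param max_taxa Hard cap on selected taxa, default 20.
#' @param cv_folds Folds for the AUC estimate, default 5.
#' @param pseudocount Added before the CLR, default 1.
#' @param seed Integer seed (fold assignment).
#' @return A `selection_result`.
#' @export
clr_lasso <- function(table, metadata, max_taxa = 20, cv_folds = 5,
                      pseudocount = 1, seed = 1L) {
  counts <- get_counts(table)
  g <- align_groups(colnames(counts), metadata)
  lev <- levels(g)
  x <- t(clr_transform(counts, pseudocount))
  fit <- glmnet::glmnet(x, g, family = "binomial", alpha = 1,
                        standardize = FALSE)
  ok <- which(fit$df <= max_taxa & fit$df > 0)
  if (length(ok) == 0) stop("no penalty on the path selects 1..max_taxa taxa")
  pick <- ok[which.min(fit$lambda[ok])]
  lambda <- fit$lambda[pick]
  beta <- as.numeric(fit$beta[, pick])
  sel <- which(beta != 0)
  score <- withr::with_seed(as.integer(seed), {
    fold <- make_folds(g, cv_folds)
    pred <- numeric(length(g))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      # fit the whole path (glmnet converges poorly on a lone small
      # lambda) and evaluate at the chosen penalty
      ffit <- glmnet::glmnet(x[tr, , drop = FALSE], g[tr],
                             family = "binomial", alpha = 1,
                             standardize = FALSE)
      pred[!tr] <- as.numeric(stats::predict(ffit, x[!tr, , drop = FALSE],
                                             s = lambda))
    }
    rank_auc(pred, g)
  })
  selection_result("clr_lasso",
                   taxa = colnames(x)[sel],
                   coefficient = beta[sel],
                   direction = ifelse(beta[sel] > 0, lev[2], lev[1]),
                   score = score, groups = lev)
}

# Soft-thresholding prox of lambda*||.||_1 restricted to the zero-sum
# hyperplane: beta = soft(v - mu, tl) with mu chosen so sum(beta) = 0
# (sum is continuous, piecewise linear and non-increasing in mu).
prox_zero_sum <- function(v, tl) {
  if (tl <= 0) return(v - mean(v))
  soft <- function(mu) {
    d <- v - mu
    z <- abs(d) - tl
    z[z < 0] <- 0
    z * sign(d)
  }
  f <- function(mu) sum(soft(mu))
  # f is continuous, piecewise linear and non-increasing in mu with knots
  # at v +/- tl; locate the bracketing knots, then interpolate exactly
  knots <- sort(c(v - tl, v + tl))
  lo <- 1L; hi <- length(knots)
  flo <- f(knots[lo])
  if (flo <= 0) return(soft(knots[lo]) - 0)  # degenerate: root at/left of first knot
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (f(knots[mid]) > 0) lo <- mid else hi <- mid
  }
  flo <- f(knots[lo]); fhi <- f(knots[hi])
  mu <- if (flo == fhi) knots[lo] else
    knots[lo] + flo * (knots[hi] - knots[lo]) / (flo - fhi)
  b <- soft(mu)
  b - mean(b)  # exact zero-sum (residual shift < 1e-12)
}

coda_lasso_path <- function(Z, y01, lambda_grid, maxit = 150, tol = 1e-5,
                            init = NULL, stop_over = NULL) {
  n <- nrow(Z)
  L <- (svd(cbind(1, Z), nu = 0, nv = 0)$d[1]^2) / (4 * n)
  step <- 1 / L
  m <- ncol(Z)
  beta <- if (is.null(init)) numeric(m) else init$beta
  b0 <- if (is.null(init)) 0 else init$b0
  out <- vector("list", length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    yb <- beta; yb0 <- b0; tk <- 1
    for (it in seq_len(maxit)) {
      eta <- as.numeric(yb0 + Z %*% yb)
      p <- stats::plogis(eta)
      gb <- as.numeric(crossprod(Z, p - y01)) / n
      gb0 <- mean(p - y01)
      bnew <- prox_zero_sum(yb - step * gb, step * lam)
      b0new <- yb0 - step * gb0
      tknew <- (1 + sqrt(1 + 4 * tk^2)) / 2
      yb <- bnew + ((tk - 1) / tknew) * (bnew - beta)
      yb0 <- b0new + ((tk - 1) / tknew) * (b0new - b0)
      dlt <- max(abs(bnew - beta), abs(b0new - b0))
      beta <- bnew; b0 <- b0new; tk <- tknew
      if (dlt < tol) break
    }
    nnz <- sum(abs(beta) > 1e-9)
    out[[li]] <- list(lambda = lam, beta = beta, b0 = b0, nnz = nnz)
    if (!is.null(stop_over) && nnz > stop_over) break
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Coda-lasso: zero-sum-constrained sparse log-contrast selection
#'
#' Penalized logistic regression of the group label on log-transformed
#' pseudocounted abundances under the zero-sum (log-contrast) constraint
#' on the coefficients, solved by accelerated proximal gradient with an
#' exact constrained soft-thresholding step. The penalty is the smallest
#' on a decreasing grid yielding at most `max_taxa` nonzero coefficients.
#'
#' @inheritParams clr_lasso
#' @param n_lambda Length of the penalty grid, default 30.
#' @return A `selection_result` (coefficients sum to zero).
#' @export
coda_lasso <- function(table, metadata, max_taxa = 20, cv_folds = 5,
                       pseudocount = 1, n_lambda = 30, seed = 1L) {
  counts <- get_counts(table)
  g <- align_groups(colnames(counts), metadata)
  lev <- levels(g)
  y01 <- as.numeric(g == lev[2])
  Z <- t(log(counts + pseudocount))
  n <- nrow(Z)
  p0 <- rep(mean(y01), n)
  g0 <- as.numeric(crossprod(Z, p0 - y01)) / n
  lam_max <- (max(g0) - min(g0)) / 2
  grid <- exp(seq(log(lam_max * 0.999), log(lam_max * 1e-3),
                  length.out = n_lambda))
  # stop the path once the support saturates (all features, or over the cap)
  path <- coda_lasso_path(Z, y01, grid,
                          stop_over = min(max_taxa, ncol(Z) - 1))
  nnz <- vapply(path, function(s) s$nnz, integer(1))
  ok <- which(nnz > 0 & nnz <= max_taxa)
  if (length(ok) == 0) stop("no penalty on the grid selects 1..max_taxa taxa")
  pick <- max(ok)  # smallest lambda satisfying the cap
  beta <- path[[pick]]$beta
  warm <- path[[pick]]
  sel <- which(abs(beta) > 1e-9)
  score <- withr::with_seed(as.integer(seed), {
    fold <- make_folds(g, cv_folds)
    pred <- numeric(n)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fp <- coda_lasso_path(Z[tr, , drop = FALSE], y01[tr],
                            path[[pick]]$lambda, init = warm)[[1]]
      pred[!tr] <- as.numeric(fp$b0 + Z[!tr, , drop = FALSE] %*% fp$beta)
    }
    rank_auc(pred, g)
  })
  selection_result("coda_lasso",
                   taxa = colnames(Z)[sel],
                   coefficient = beta[sel],
                   direction = ifelse(beta[sel] > 0, lev[2], lev[1]),
                   score = score, groups = lev)
}
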