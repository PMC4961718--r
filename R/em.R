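#' EM configuration
#'
#' Controls the multivariate-normal EM used for imputation and for the
#' parameter estimates behind Little's MCAR test.
#'
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the observed-data log-likelihood
#'   change between iterations.
#' @param ridge nonnegative value added to the covariance diagonal at each
#'   M-step (stabilizes nearly singular problems; 0 = plain ML).
#' @param seed optional integer; the start is deterministic (observed
#'   means / available-case covariance), the seed is kept for
#'   reproducibility bookkeeping of any stochastic extension.
#' @return An object of class `em_config`.
#' @export
em_config <- function(max_iter = 500L, tol = 1e-6, ridge = 0, seed = NULL) {
  stopifnot(max_iter >= 1, tol > 0, ridge >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 ridge = ridge, seed = seed), class = "em_config")
}

# missingness patterns: list of (obs index vector, row indices)
na_patterns <- function(x) {
  key <- apply(is.na(x), 1L, function(r) paste(which(r), collapse = ","))
  idx <- split(seq_len(nrow(x)), key)
  lapply(idx, function(rows) {
    list(obs = which(!is.na(x[rows[1L], ])), rows = rows)
  })
}

# core MVN EM: returns mu, sigma, loglik trace, converged flag.
# Columns are standardized internally (available-case mean/sd) so the
# ridge is scale-free; estimates are mapped back before returning.
# Log-likelihood changes are unaffected by the affine rescaling.
em_mvn <- function(x, cfg = em_config()) {
  stopifnot(is.matrix(x), is.numeric(x))
  p <- ncol(x)
  keep <- rowSums(!is.na(x)) > 0L
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows with observed data")
  ctr0 <- colMeans(x, na.rm = TRUE)
  scl0 <- apply(x, 2L, stats::sd, na.rm = TRUE)
  scl0[!is.finite(scl0) | scl0 == 0] <- 1
  x <- sweep(sweep(x, 2L, ctr0), 2L, scl0, "/")
  pats <- na_patterns(x)

  mu <- colMeans(x, na.rm = TRUE)
  if (anyNA(mu)) stop("a variable has no observed values")
  sigma <- stats::cov(x, use = "pairwise.complete.obs")
  sigma[!is.finite(sigma)] <- 0
  # make the start safely positive definite
  sigma <- sigma + diag(max(cfg$ridge, 1e-8 * mean(diag(sigma)), 1e-12), p)
  if (inherits(tryCatch(chol(sigma), error = identity), "error"))
    sigma <- diag(apply(x, 2L, stats::var, na.rm = TRUE), p)

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    ll <- 0
    for (pat in pats) {
      O <- pat$obs; rows <- pat$rows; nR <- length(rows)
      xo <- x[rows, O, drop = FALSE]
      soo <- sigma[O, O, drop = FALSE]
      ch <- tryCatch(chol(soo), error = function(e)
        stop("singular covariance during EM; increase ridge"))
      ctr <- sweep(xo, 2L, mu[O])
      # log-likelihood of the observed block
      qf <- backsolve(ch, t(ctr), transpose = TRUE)
      ll <- ll - 0.5 * (nR * (length(O) * log(2 * pi) +
                              2 * sum(log(diag(ch)))) + sum(qf^2))
      xhat <- x[rows, , drop = FALSE]
      if (length(O) < p) {
        M <- setdiff(seq_len(p), O)
        B <- sigma[M, O, drop = FALSE] %*% chol2inv(ch)   # regression of M on O
        xhat[, M] <- matrix(mu[M], nR, length(M), byrow = TRUE) +
          ctr %*% t(B)
        cc <- sigma[M, M, drop = FALSE] - B %*% sigma[O, M, drop = FALSE]
        t2[M, M] <- t2[M, M] + nR * cc
      }
      t1 <- t1 + colSums(xhat)
      t2 <- t2 + crossprod(xhat)
    }
    loglik <- c(loglik, ll)
    mu <- t1 / n
    sigma <- t2 / n - tcrossprod(mu)
    if (cfg$ridge > 0) sigma <- sigma + diag(cfg$ridge, p)
    if (it > 1L && abs(loglik[it] - loglik[it - 1L]) < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && length(pats) > 1L && cfg$max_iter > 1L) {
    cond <- structure(class = c("licur_em_nonconvergence", "error",
                                "condition"),
                      list(message = sprintf(
                        "EM did not converge in %d iterations (last change %.3g)",
                        cfg$max_iter,
                        abs(diff(utils::tail(loglik, 2L)))),
                        call = sys.call(-1), loglik = loglik))
    stop(cond)
  }
  list(mu = ctr0 + mu * scl0, sigma = sigma * tcrossprod(scl0),
       loglik = loglik, converged = TRUE,
       iterations = length(loglik), kept = keep)
}

#' Impute missing values by multivariate-normal EM
#'
#' Fits a multivariate normal to the incomplete matrix by
#' expectation-maximization (maximum likelihood; all missingness patterns
#' contribute) and replaces every missing cell by its conditional mean
#' given the observed cells of its row at the converged parameters.
#' Observed cells are untouched. Rows with no observed cells cannot be
#' imputed and raise an error.
#'
#' @param x numeric matrix with `NA` for missing cells.
#' @param cfg an [em_config()].
#' @return completed matrix with attributes `iterations`, `loglik`
#'   (per-iteration observed-data log-likelihood), `mu` and `sigma`.
#' @export
em_impute <- function(x, cfg = em_config()) {
  stopifnot(is.matrix(x))
  if (!anyNA(x)) return(x)
  if (any(rowSums(!is.na(x)) == 0L))
    stop("rows with all cells missing cannot be imputed")
  fm <- colMeans(is.na(x))
  if (any(fm >= 0.5))
    warning("variable(s) with >= 50% missing: ",
            paste(colnames(x)[fm >= 0.5], collapse = ", "))
  fit <- em_mvn(x, cfg)
  out <- x
  for (pat in na_patterns(x)) {
    O <- pat$obs
    if (length(O) == ncol(x)) next
    M <- setdiff(seq_len(ncol(x)), O)
    B <- fit$sigma[M, O, drop = FALSE] %*% solve(fit$sigma[O, O, drop = FALSE])
    ctr <- sweep(x[pat$rows, O, drop = FALSE], 2L, fit$mu[O])
    out[pat$rows, M] <- matrix(fit$mu[M], length(pat$rows), length(M),
                               byrow = TRUE) + ctr %*% t(B)
  }
  structure(out, iterations = fit$iterations, loglik = fit$loglik,
            mu = fit$mu, sigma = fit$sigma)
}

#' Little's test of missing completely at random
#'
#' Compares, for every missingness pattern, the observed-variable means of
#' that pattern with the EM (maximum-likelihood) estimates:
#' chi2 = sum_j n_j (ybar_j - mu_j)' Sigma_j^{-1} (ybar_j - mu_j) over the
#' observed subsets, with df = sum_j p_j - p. A non-significant result is
#' consistent with MCAR and licenses EM single imputation.
#'
#' @param x numeric matrix with `NA` for missing cells.
#' @param cfg an [em_config()] for the parameter estimates.
#' @return An object of class `mcar_test`: `chi2`, `df`, `p_value`,
#'   `n_patterns`, `applicable` (`FALSE` when the data are complete --
#'   a single pattern -- in which case no test is computed).
#' @export
little_mcar <- function(x, cfg = em_config()) {
  stopifnot(is.matrix(x))
  keep <- rowSums(!is.na(x)) > 0L
  x <- x[keep, , drop = FALSE]
  pats <- na_patterns(x)
  if (length(pats) < 2L) {
    return(structure(list(chi2 = NA_real_, df = NA_integer_,
                          p_value = NA_real_, n_patterns = length(pats),
                          applicable = FALSE), class = "mcar_test"))
  }
  fit <- em_mvn(x, cfg)
  small <- vapply(pats, function(p) length(p$rows) < length(p$obs),
                  logical(1))
  if (any(small))
    warning(sum(small), " pattern(s) have fewer cases than observed ",
            "variables; the chi-square approximation may be poor")
  chi2 <- 0
  df <- -ncol(x)
  for (pat in pats) {
    O <- pat$obs
    ybar <- colMeans(x[pat$rows, O, drop = FALSE])
    dlt <- ybar - fit$mu[O]
    chi2 <- chi2 + length(pat$rows) *
      drop(crossprod(dlt, solve(fit$sigma[O, O, drop = FALSE], dlt)))
    df <- df + length(O)
  }
  structure(list(chi2 = chi2, df = as.integer(df),
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 n_patterns = length(pats), applicable = TRUE),
            class = "mcar_test")
}

#' @export
print.mcar_test <- function(x, ...) {
  if (!x$applicable) {
    cat("Little's MCAR test: not applicable (single missingness pattern)\n")
  } else {
    cat(sprintf(
      "Little's MCAR test: chi2 = %.1f, df = %d, p = %.3g (%d patterns)\n",
      x$chi2, x$df, x$p_value, x$n_patterns))
  }
  invisible(x)
}
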