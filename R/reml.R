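align_phenotypes <- function(y, kernel) {
  y <- tibble::as_tibble(y)
  stopifnot(all(c("id", "y_adj") %in% names(y)))
  miss <- setdiff(y$id, kernel$ids)
  if (length(miss) > 0) {
    stop("phenotyped individual(s) absent from the kernel: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  y
}

# Restricted log-likelihood pieces after rotating by the kernel eigenbasis.
# v = sigma2_a * d + sigma2_e are the eigenvalues of V; X is the intercept.
rll_rotated <- function(ytil, xtil, d, sigma2_a, sigma2_e) {
  v <- sigma2_a * d + sigma2_e
  if (any(v <= 0)) return(-Inf)
  xwx <- sum(xtil^2 / v)
  beta <- sum(xtil * ytil / v) / xwx
  r <- ytil - xtil * beta
  -0.5 * (sum(log(v)) + log(xwx) + sum(r^2 / v) +
            (length(ytil) - 1) * log(2 * pi))
}

#' REML variance components for a single-kernel animal model
#'
#' Fits `y = 1 mu + a + e` with `a ~ N(0, sigma2_a K)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood. The kernel is
#' first rescaled to unit mean diagonal, so `sigma2_a` is the genetic
#' variance on the phenotypic scale and `h2 = sigma2_a / (sigma2_a +
#' sigma2_e)` is comparable across kernels whose raw diagonals differ
#' (dosage, IBS and epistasis kernels all scale differently) and invariant
#' to multiplying the kernel by a constant. The rescaled kernel is
#' eigendecomposed once (after adding a small diagonal ridge) and the
#' restricted likelihood is profiled down to a one-dimensional search over
#' the variance ratio `lambda = sigma2_a / sigma2_e` by Brent's method.
#' The standard error of the heritability is obtained from the inverse
#' observed information at the optimum via the delta method.
#'
#' @param y Adjusted phenotypes: a tibble with `id` and `y_adj` (see
#'   [adjust_phenotypes()]); only individuals present here are used.
#' @param kernel A `gp_kernel` covering at least the phenotyped individuals.
#' @param ridge Diagonal ridge added at solve time only (default 1e-6).
#' @param h2_bounds Search bounds for the heritability (default
#'   `c(1e-4, 1 - 1e-4)`); an estimate pinned at a bound is flagged
#'   `boundary`, not an error.
#' @return An object of class `reml_fit`: list with `sigma2_a`, `sigma2_e`,
#'   `h2`, `se_h2`, `lambda`, `loglik` (restricted), `converged`,
#'   `boundary`, `kernel_scale` (the mean-diagonal divisor), `n`.
#' @export
reml_kernel <- function(y, kernel, ridge = 1e-6,
                        h2_bounds = c(1e-4, 1 - 1e-4)) {
  stopifnot(inherits(kernel, "gp_kernel"))
  y <- align_phenotypes(y, kernel)
  idx <- match(y$id, kernel$ids)
  K <- kernel$K[idx, idx, drop = FALSE]
  n <- nrow(K)
  if (n < 2) stop("need at least two phenotyped individuals", call. = FALSE)
  kscale <- mean(diag(K))
  if (kscale <= 0) stop("kernel has non-positive mean diagonal", call. = FALSE)
  K <- K / kscale
  eg <- eigen(K + diag(ridge, n), symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    stop("kernel is not positive semidefinite after the ridge", call. = FALSE)
  }
  d <- pmax(eg$values, 0)
  ytil <- crossprod(eg$vectors, y$y_adj)[, 1]
  xtil <- crossprod(eg$vectors, rep(1, n))[, 1]
  # profile over log(lambda); sigma2_e is profiled out analytically
  prof <- function(tl) {
    lam <- exp(tl)
    w <- lam * d + 1
    xwx <- sum(xtil^2 / w)
    beta <- sum(xtil * ytil / w) / xwx
    r <- ytil - xtil * beta
    rss <- sum(r^2 / w)
    se2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(se2) + sum(log(w)) + log(xwx) + (n - 1) +
              (n - 1) * log(2 * pi))
  }
  lo <- log(h2_bounds[1] / (1 - h2_bounds[1]))
  hi <- log(h2_bounds[2] / (1 - h2_bounds[2]))
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  lam <- exp(opt$maximum)
  w <- lam * d + 1
  xwx <- sum(xtil^2 / w)
  beta <- sum(xtil * ytil / w) / xwx
  rss <- sum((ytil - xtil * beta)^2 / w)
  sigma2_e <- rss / (n - 1)
  sigma2_a <- lam * sigma2_e
  h2 <- lam / (1 + lam)
  boundary <- h2 <= h2_bounds[1] * 1.01 || h2 >= 1 - (1 - h2_bounds[2]) * 1.01
  se_h2 <- h2_standard_error(ytil, xtil, d, sigma2_a, sigma2_e)
  structure(
    list(sigma2_a = sigma2_a, sigma2_e = sigma2_e, h2 = h2, se_h2 = se_h2,
         lambda = lam, loglik = rll_rotated(ytil, xtil, d, sigma2_a, sigma2_e),
         converged = TRUE, boundary = boundary, kernel_scale = kscale, n = n),
    class = "reml_fit"
  )
}

h2_standard_error <- function(ytil, xtil, d, sigma2_a, sigma2_e) {
  f <- function(th) rll_rotated(ytil, xtil, d, th[1], th[2])
  th <- c(sigma2_a, sigma2_e)
  hs <- pmax(abs(th), sigma2_e + sigma2_a) * 1e-4
  Hm <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0)
    ei[i] <- hs[i]; ej[j] <- hs[j]
    Hm[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                   f(th - ei + ej) + f(th - ei - ej)) / (4 * hs[i] * hs[j])
  }
  info <- tryCatch(solve(-Hm), error = function(e) NULL)
  if (is.null(info) || any(!is.finite(info))) return(NA_real_)
  s <- sigma2_a + sigma2_e
  grad <- c(sigma2_e, -sigma2_a) / s^2
  v <- drop(t(grad) %*% info %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_)
  sqrt(v)
}

#' Predict direct genomic values by BLUP
#'
#' Solves the mixed-model equations on the phenotyped (training)
#' individuals and propagates the genetic effects to every individual in
#' the kernel through the relationship matrix:
#' `a_hat = sigma2_a K[, train] V^{-1} (y - mu_hat)` with
#' `V = sigma2_a K[train, train] + sigma2_e I`. Individuals absent from `y`
#' (the masked validation set) thus receive DGVs without contributing
#' records.
#'
#' @param y Training phenotypes (tibble with `id`, `y_adj`); masked
#'   individuals are simply left out.
#' @param kernel A `gp_kernel` covering all individuals to predict.
#' @param vc A `reml_fit` from [reml_kernel()] (normally fitted on `y`).
#' @param ridge Diagonal ridge used in the training solve (default 1e-6).
#' @return A tibble with `id` and `dgv` for every individual in the kernel,
#'   in kernel order.
#' @export
predict_dgv <- function(y, kernel, vc, ridge = 1e-6) {
  stopifnot(inherits(kernel, "gp_kernel"), inherits(vc, "reml_fit"))
  y <- align_phenotypes(y, kernel)
  tr <- match(y$id, kernel$ids)
  kscale <- vc$kernel_scale %||% 1
  Ktt <- kernel$K[tr, tr, drop = FALSE] / kscale
  nt <- length(tr)
  V <- vc$sigma2_a * (Ktt + diag(ridge, nt)) + diag(vc$sigma2_e, nt)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("singular training system; consider a larger ridge", call. = FALSE)
  })
  one <- rep(1, nt)
  mu <- drop(crossprod(one, Vi %*% y$y_adj)) / drop(crossprod(one, Vi %*% one))
  resid <- y$y_adj - mu
  a_all <- vc$sigma2_a *
    ((kernel$K[, tr, drop = FALSE] / kscale) %*% (Vi %*% resid))
  tibble::tibble(id = kernel$ids, dgv = unname(drop(a_all)))
}
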