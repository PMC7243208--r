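#' Random cross-validation layouts
#'
#' Assigns `n` individuals to `k` near-equal folds (sizes differ by at most
#' one), independently for each replicate. Deterministic given `seed`; the
#' caller's RNG state is untouched.
#'
#' @param n Number of individuals.
#' @param k Folds per replicate (default 5).
#' @param reps Replicates (default 20).
#' @param seed Integer seed.
#' @return A tibble with columns `replicate`, `index` (1..n) and `fold`.
#' @export
make_cv_layouts <- function(n, k = 5, reps = 20, seed = 1) {
  if (n < k) stop("need at least as many individuals as folds", call. = FALSE)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(reps), function(r) {
      fold_sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      tibble::tibble(
        replicate = r,
        index = sample.int(n),
        fold = rep(seq_len(k), fold_sizes)
      ) |> dplyr::arrange(.data$index)
    })
  })
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted genetic values and adjusted
#' phenotypes over the validation individuals, divided by the square root
#' of the trait heritability.
#'
#' @param dgv,y_adj Numeric vectors over the same validation individuals.
#' @param h2 Heritability in (0, 1].
#' @return Scalar accuracy.
#' @export
gp_accuracy <- function(dgv, y_adj, h2) {
  stopifnot(h2 > 0, h2 <= 1, length(dgv) == length(y_adj))
  if (length(dgv) < 3) stop("need at least 3 validation individuals", call. = FALSE)
  if (stats::sd(dgv) == 0 || stats::sd(y_adj) == 0) {
    stop("zero variance in DGV or phenotype: accuracy undefined", call. = FALSE)
  }
  stats::cor(dgv, y_adj) / sqrt(h2)
}

#' Bias regression of phenotype on DGV
#'
#' Ordinary least-squares slope of the adjusted phenotype on the DGV over
#' the validation individuals. A slope of 1 indicates unbiased prediction;
#' values greater than 1 indicate deflated DGVs, values below 1 inflated
#' ones.
#'
#' @param y_adj,dgv Numeric vectors over the same validation individuals.
#' @return Named list with `slope` and its standard error `se`.
#' @export
bias_regression <- function(y_adj, dgv) {
  stopifnot(length(dgv) == length(y_adj))
  if (length(dgv) < 3) stop("need at least 3 validation individuals", call. = FALSE)
  if (stats::sd(dgv) == 0) stop("zero DGV variance: slope undefined", call. = FALSE)
  fit <- stats::lm(y_adj ~ dgv)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["dgv", "Estimate"]), se = unname(sm["dgv", "Std. Error"]))
}

#' Replicated k-fold cross-validation of a genomic prediction model
#'
#' For every replicate and fold, variance components are re-estimated by
#' REML on the training portion and DGVs are predicted for the held-out
#' fold. Validation predictions of all folds are pooled per replicate; the
#' replicate's accuracy is the pooled correlation divided by `sqrt(h2)` and
#' its bias is the pooled regression slope of phenotype on DGV. Across
#' replicates, the mean slope is tested against 1 using the replicate
#' standard deviation as the dispersion of the estimate (CV replicates
#' re-use the same records and are strongly correlated, so the naive
#' standard error of the mean would grossly overstate precision): the flag
#' is set when `|mean - 1| > t(0.975, reps - 1) * SD`.
#'
#' @param y Adjusted phenotypes (tibble with `id`, `y_adj`) for all
#'   individuals in the kernel.
#' @param kernel A `gp_kernel` covering all phenotyped individuals.
#' @param layouts Fold assignments from [make_cv_layouts()] over the rows
#'   of `y`.
#' @param h2 Heritability used in the accuracy denominator; default is the
#'   full-data REML estimate for this kernel (estimated once, before CV).
#' @param ridge Diagonal ridge for REML and the BLUP solve.
#' @return An object of class `cv_result`: list with `replicates` (tibble:
#'   `replicate`, `accuracy`, `bias`), `summary` (one-row tibble with means,
#'   SDs, the bias t-test p-value and significance flag), `h2`, `model`,
#'   `class_tag`.
#' @export
run_cv <- function(y, kernel, layouts, h2 = NULL, ridge = 1e-6) {
  stopifnot(inherits(kernel, "gp_kernel"))
  y <- align_phenotypes(y, kernel)
  n <- nrow(y)
  stopifnot(all(layouts$index %in% seq_len(n)))
  if (is.null(h2)) {
    h2 <- reml_kernel(y, kernel, ridge = ridge)$h2
  }
  reps <- sort(unique(layouts$replicate))
  per_rep <- purrr::map_dfr(reps, function(r) {
    lay <- layouts[layouts$replicate == r, ]
    fold_of <- integer(n)
    fold_of[lay$index] <- lay$fold
    dgv <- numeric(n)
    for (f in sort(unique(lay$fold))) {
      val <- which(fold_of == f)
      train_y <- y[-val, ]
      vc <- reml_kernel(train_y, kernel, ridge = ridge)
      pred <- predict_dgv(train_y, kernel, vc, ridge = ridge)
      dgv[val] <- pred$dgv[match(y$id[val], pred$id)]
    }
    b <- bias_regression(y$y_adj, dgv)
    tibble::tibble(
      replicate = r,
      accuracy = gp_accuracy(dgv, y$y_adj, h2),
      bias = b$slope
    )
  })
  nr <- nrow(per_rep)
  mb <- mean(per_rep$bias)
  sb <- stats::sd(per_rep$bias)
  tstat <- if (nr > 1 && sb > 0) (mb - 1) / sb else NA_real_
  pval <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df = nr - 1) else NA_real_
  summary <- tibble::tibble(
    model = kernel$model,
    class_tag = kernel$class_tag,
    n_replicates = nr,
    mean_accuracy = mean(per_rep$accuracy),
    sd_accuracy = stats::sd(per_rep$accuracy),
    mean_bias = mb,
    sd_bias = sb,
    bias_p_value = pval,
    bias_significant = isTRUE(pval < 0.05)
  )
  structure(
    list(replicates = per_rep, summary = summary, h2 = h2,
         model = kernel$model, class_tag = kernel$class_tag),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat("<cv_result> model ", x$model,
      if (!identical(x$class_tag, "all")) paste0(" | ", x$class_tag),
      ": accuracy ", sprintf("%.3f (%.3f)", s$mean_accuracy, s$sd_accuracy),
      ", bias ", sprintf("%.3f (%.3f)", s$mean_bias, s$sd_bias),
      if (s$bias_significant) " [bias != 1, p < 0.05]",
      "\n", sep = "")
  invisible(x)
}
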