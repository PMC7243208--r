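#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on biallelic genotype counts: the p-value is the
#' total probability, under HWE conditional on the allele counts, of all
#' heterozygote counts whose probability does not exceed that of the observed
#' count (no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb Counts of the three genotype classes.
#' @return p-value in (0, 1]; monomorphic markers return 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(length(n_aa) == 1L, n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab        # rarer allele recount below
  if (n == 0L) return(1)
  n_minor <- min(n_a, 2L * n - n_a)
  if (n_minor == 0L) return(1)
  # heterozygote count has the parity of the minor-allele count
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  n_hom_minor <- (n_minor - hets) / 2
  n_hom_major <- n - hets - n_hom_minor
  logp <- lgamma(n + 1) - lgamma(n_hom_minor + 1) - lgamma(hets + 1) -
    lgamma(n_hom_major + 1) + hets * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  if (length(obs) == 0L) return(0)  # impossible parity => inconsistent input
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

hwe_p_values <- function(d) {
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
}

#' Apply marker and individual quality-control filters
#'
#' Marker filters (call rate, minor-allele frequency, Hardy-Weinberg exact
#' test) are assessed jointly on the input matrix and failing markers removed
#' first; the individual call-rate filter is then applied on the surviving
#' markers. All thresholds are strict (`>`): a marker with MAF exactly equal
#' to `maf_min` is removed. Minor-allele frequencies in the result are
#' recomputed from the retained data.
#'
#' @param g A [phased_genotypes] object (may contain missing cells).
#' @param snp_call_rate Minimum marker call rate (keep if call rate is
#'   strictly greater). Default 0.90.
#' @param maf_min Minimum minor-allele frequency, default 0.01.
#' @param hwe_p_min Minimum HWE exact p-value, default 1e-6.
#' @param ind_call_rate Minimum individual call rate, default 0.90.
#' @return A filtered [phased_genotypes] object with a `qc_report` attribute:
#'   a tibble of removal counts per filter.
#' @export
apply_qc <- function(g, snp_call_rate = 0.90, maf_min = 0.01,
                     hwe_p_min = 1e-6, ind_call_rate = 0.90) {
  stopifnot(inherits(g, "phased_genotypes"))
  d <- dosage(g)
  cr <- colMeans(!is.na(d))
  maf <- marker_maf(g)
  hwe <- hwe_p_values(d)
  fail_cr <- cr <= snp_call_rate
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_hwe <- hwe <= hwe_p_min
  keep_m <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep_m)) {
    stop("all markers removed by QC filters", call. = FALSE)
  }
  d2 <- d[, keep_m, drop = FALSE]
  icr <- rowMeans(!is.na(d2))
  keep_i <- icr > ind_call_rate
  if (!any(keep_i)) {
    stop("all individuals removed by the call-rate filter", call. = FALSE)
  }
  out <- subset_genotypes(g, individuals = which(keep_i), markers = which(keep_m))
  attr(out, "qc_report") <- tibble::tibble(
    filter = c("marker_call_rate", "marker_maf", "marker_hwe",
               "markers_removed", "individual_call_rate"),
    threshold = c(snp_call_rate, maf_min, hwe_p_min, NA, ind_call_rate),
    n_removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe),
                  sum(!keep_m), sum(!keep_i))
  )
  out
}

#' QC removal report
#'
#' @param g A [phased_genotypes] object returned by [apply_qc()].
#' @return The `qc_report` tibble, or `NULL` if `g` was not QC-filtered.
#' @export
qc_report <- function(g) attr(g, "qc_report")

#' Pre-adjust phenotypes for environmental fixed effects
#'
#' Fits an ordinary least-squares model of the trait on the fixed effects and
#' returns the residuals as the adjusted phenotype used by all downstream
#' prediction models. The default design matches a fattening-cohort design:
#' sex, year, body weight at entry and days on feed.
#'
#' @param pheno A data frame with an `id` column, the trait, and the
#'   fixed-effect columns named in `formula`.
#' @param formula Model formula for the adjustment; the left-hand side names
#'   the trait column.
#' @return A tibble with columns `id` and `y_adj`, in the input row order;
#'   `mean(y_adj)` is zero up to numerical tolerance.
#' @export
adjust_phenotypes <- function(pheno,
                              formula = trait ~ sex + year + entry_weight +
                                fattening_days) {
  pheno <- tibble::as_tibble(pheno)
  stopifnot("id" %in% names(pheno))
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(pheno))
  if (length(missing_cols) > 0) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(formula, data = pheno)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0) {
    stop("singular fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = pheno$id, y_adj = unname(stats::resid(fit)))
}
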