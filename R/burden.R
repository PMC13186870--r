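#' LASSO burden weights for a scan window
#'
#' Fits `argmin_b 0.5 * ||y - X b||^2 + lambda * ||b||_1` on offspring
#' additive genotype codes (0/1/2) against the offspring phenotype, with the
#' L1 penalty chosen by 5-fold cross-validation (policy `"cv_min"`, the
#' default) or fixed.  If every coefficient is shrunk to zero (or the
#' phenotype is constant) the weights fall back to equal weights
#' `1/sqrt(p)` with the fallback flag set, so a window is never silently
#' dropped for lack of signal.
#'
#' @param X Numeric matrix of offspring genotypes (individuals by window
#'   variants).
#' @param y Numeric phenotype vector (0/1).
#' @param lambda_policy `"cv_min"` or a fixed non-negative number.
#' @param seed Seed fixing the cross-validation folds.
#' @return List with `b` (weight vector), `lambda` and `fallback`.
#' @export
fit_burden_weights <- function(X, y, lambda_policy = "cv_min", seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  if (p < 1L) abort("window must contain at least one variant.")
  fallback <- list(b = rep(1 / sqrt(p), p), lambda = NA_real_,
                   fallback = TRUE)
  if (stats::var(y) == 0) {
    warn("constant phenotype: falling back to equal burden weights.")
    return(fallback)
  }
  if (n < 10L) return(fallback)
  fixed <- is.numeric(lambda_policy)
  if (p == 1L) {
    b <- univariate_lasso(drop(X), y,
                          lambda = if (fixed) lambda_policy else NULL,
                          seed = seed)
    lam <- attr(b, "lambda")
    if (b == 0) return(fallback)
    return(list(b = as.numeric(b), lambda = lam, fallback = FALSE))
  }
  if (fixed) {
    # glmnet's gaussian objective is RSS/(2n) + s * ||b||_1, so the fixed
    # penalty on the 0.5 * RSS + lambda * ||b||_1 scale maps to s = lambda/n
    fit <- glmnet::glmnet(X, y, family = "gaussian", standardize = FALSE)
    b <- as.numeric(coef(fit, s = lambda_policy / n, exact = TRUE,
                         x = X, y = y))[-1L]
    lam <- lambda_policy
  } else {
    withr_seed(seed)
    foldid <- sample(rep_len(seq_len(5L), n))
    cv <- tryCatch(
      glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                        standardize = FALSE),
      error = function(e) NULL
    )
    if (is.null(cv)) return(fallback)  # degenerate design (e.g. constant X)
    b <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
    lam <- cv$lambda.min
  }
  if (all(b == 0)) return(fallback)
  list(b = b, lambda = lam, fallback = FALSE)
}

# closed-form lasso for a single predictor: soft-threshold of the OLS
# covariance, with lambda chosen by 5-fold CV on a glmnet-style grid
univariate_lasso <- function(x, y, lambda = NULL, seed = 1L) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    out <- 0
    attr(out, "lambda") <- NA_real_
    return(out)
  }
  soft <- function(z, l) sign(z) * pmax(abs(z) - l, 0)
  est <- function(xc, yc, l) soft(sum(xc * yc), l) / sum(xc^2)
  if (is.null(lambda)) {
    n <- length(y)
    lmax <- abs(sum(xc * yc))
    grid <- lmax * 10^seq(0, -3, length.out = 50L)
    withr_seed(seed)
    foldid <- sample(rep_len(seq_len(5L), n))
    errs <- vapply(grid, function(l) {
      se <- 0
      for (f in seq_len(5L)) {
        tr <- foldid != f
        xt <- x[tr] - mean(x[tr])
        yt <- y[tr] - mean(y[tr])
        b <- if (sum(xt^2) > 0) est(xt, yt, l * sum(tr) / n) else 0
        pred <- mean(y[tr]) + b * (x[!tr] - mean(x[tr]))
        se <- se + sum((y[!tr] - pred)^2)
      }
      se
    }, numeric(1))
    lambda <- grid[which.min(errs)]
  }
  out <- est(xc, yc, lambda)
  attr(out, "lambda") <- lambda
  out
}

#' Weighted burden FBAT score for one window
#'
#' Compares the observed transmission of the weighted allele burden to its
#' Mendelian expectation conditional on the parental haplotypes.  For trio
#' `i` with offspring burden `B_i = sum_j b_j x_ij`, each parent transmits
#' either of its two window haplotypes with probability 1/2 independently,
#' which gives the exact conditional mean `E[B_i]` and variance
#' `Var[B_i]`.  The score is `U = sum_i (y_i - mu)(B_i - E[B_i])`, its
#' variance `V = sum_i (y_i - mu)^2 Var[B_i]`, and `Z = U / sqrt(V)`.
#' `y_i` is the offspring phenotype; parents may themselves be affected
#' without invalidating the test, since the expectation conditions on their
#' genotypes.  Trios with a missing genotype in the window are dropped.
#'
#' @param hap Haplotype matrix (original or knockoff, shaped like
#'   `cohort$haplotypes`).
#' @param cohort The `triokf_cohort` (pedigree and phenotypes).
#' @param variant_idx Column indices of the window's member variants.
#' @param b Burden weight vector over the member variants.
#' @param mu Phenotype offset on the dichotomous trait, default 0: affected
#'   offspring drive the score and unaffected offspring drop out, the
#'   classical choice for affected-proband designs.  A non-zero offset
#'   (e.g. the population prevalence) down-weights rather than removes
#'   unaffected offspring.  Passing `mu = NULL` uses the in-sample offspring
#'   prevalence, which is inadvisable in ascertained cohorts: the many
#'   unaffected type 2 children then carry the larger weight
#'   `(1 - mu)^2 > mu^2` and their transmission noise drowns the affected
#'   offsprings' signal.
#' @return List with `Z`, `dir` (sign of `Z`), `n_informative` (trios with
#'   positive transmission variance); `Z` is `NA` when no trio is
#'   informative (`V = 0`), never 0 by convention.
#' @export
fbat_burden_z <- function(hap, cohort, variant_idx, b, mu = 0) {
  ped <- complete_trios(cohort)
  if (!nrow(ped)) return(list(Z = NA_real_, dir = NA_real_, n_informative = 0L))
  burden <- drop(hap[, variant_idx, drop = FALSE] %*% b)
  ids <- cohort$individuals$id
  row1 <- function(who) 2L * match(who, ids) - 1L
  f1 <- burden[row1(ped$father)]; f2 <- burden[row1(ped$father) + 1L]
  m1 <- burden[row1(ped$mother)]; m2 <- burden[row1(ped$mother) + 1L]
  o1 <- burden[row1(ped$offspring)]; o2 <- burden[row1(ped$offspring) + 1L]
  y <- cohort$individuals$phenotype[match(ped$offspring, ids)]
  ok <- complete.cases(f1, f2, m1, m2, o1, o2, y)
  if (!any(ok)) return(list(Z = NA_real_, dir = NA_real_, n_informative = 0L))
  if (is.null(mu)) mu <- mean(y[ok])  # in-sample prevalence, on request
  if (mu == 1) mu <- 0                  # constant y: offset cancels anyway
  B <- (o1 + o2)[ok]
  E <- ((f1 + f2) / 2 + (m1 + m2) / 2)[ok]
  Vi <- (((f1 - f2) / 2)^2 + ((m1 - m2) / 2)^2)[ok]
  w <- y[ok] - mu
  U <- sum(w * (B - E))
  V <- sum(w^2 * Vi)
  if (V <= 0)
    return(list(Z = NA_real_, dir = NA_real_, n_informative = 0L))
  Z <- U / sqrt(V)
  list(Z = Z, dir = sign(Z), n_informative = sum(Vi > 0 & w != 0))
}

#' Two-sided normal p-value from a Z score
#'
#' @param z Z score (finite).
#' @return `2 * (1 - pnorm(|z|))`.
#' @examples
#' z_to_p(3.242)
#' @export
z_to_p <- function(z) 2 * pnorm(-abs(z))

#' Knockoff contrast statistic for one window
#'
#' `W = |Z| / median_m |Z*_m|`: the original score against the median of the
#' knockoff scores.  Undefined knockoff scores are dropped from the median
#' with a warning; `W` is `NA` if the median is zero or no knockoff score is
#' defined.
#'
#' @param Z Original window score.
#' @param Zstar Numeric vector of `M` knockoff scores.
#' @return List with `W` and `p_burden = z_to_p(Z)`.
#' @export
window_statistic <- function(Z, Zstar) {
  if (!length(Zstar)) abort("at least one knockoff score is required.")
  if (is.na(Z)) return(list(W = NA_real_, p_burden = NA_real_))
  zs <- Zstar[!is.na(Zstar)]
  if (length(zs) < length(Zstar))
    warn("undefined knockoff score(s) dropped from the W median.")
  if (!length(zs)) return(list(W = NA_real_, p_burden = z_to_p(Z)))
  med <- median(abs(zs))
  W <- if (med == 0) NA_real_ else abs(Z) / med
  list(W = W, p_burden = z_to_p(Z))
}
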