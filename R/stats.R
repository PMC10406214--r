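#' Fit a multivariate linear model with a focal predictor
#'
#' Ordinary least squares of \code{response} on a focal predictor plus
#' covariates (sex, BMI and education by default; age and interaction terms
#' where requested). Sex is coded as a single indicator. Perfect
#' collinearity raises an error naming the offending columns. Complete-case
#' analysis: rows with missing values in any model column are dropped.
#'
#' @param data participant-level data.frame.
#' @param response dependent-variable column name.
#' @param focal predictor of interest (its row is flagged in the output).
#' @param covariates character vector of covariate column names.
#' @param interactions optional character vector of interaction terms in
#'   formula syntax (e.g. \code{"lc_contrast:age"}).
#' @return A list of class \code{model_result}: \code{table} (term,
#'   estimate, se, t, p, ci_lo, ci_hi, focal flag), \code{focal} (that row),
#'   \code{n}, \code{df}, \code{formula}.
#' @export
fit_linear_model <- function(data, response, focal,
                             covariates = c("sex", "bmi", "education"),
                             interactions = NULL) {
  terms_rhs <- c(focal, covariates, interactions)
  if (anyDuplicated(terms_rhs))
    stop("duplicate model terms: ",
         paste(terms_rhs[duplicated(terms_rhs)], collapse = ", "))
  fml <- stats::as.formula(paste(response, "~", paste(terms_rhs, collapse = " + ")))
  base_vars <- unique(unlist(strsplit(terms_rhs, ":", fixed = TRUE)))
  use <- stats::complete.cases(data[, c(response, base_vars)])
  d <- data[use, , drop = FALSE]
  if (is.character(d$sex)) d$sex <- factor(d$sex)
  n <- nrow(d)
  if (n < length(terms_rhs) + 3)
    stop("too few complete cases for the model")
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("perfect collinearity among predictors: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  tab <- data.frame(term = rownames(sm$coefficients),
                    estimate = sm$coefficients[, 1],
                    se = sm$coefficients[, 2],
                    t = sm$coefficients[, 3],
                    p = sm$coefficients[, 4],
                    ci_lo = ci[, 1], ci_hi = ci[, 2],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  # the focal term's fitted name may carry a factor level suffix
  focal_row <- which(tab$term == focal)
  if (length(focal_row) == 0)
    focal_row <- grep(paste0("^", focal), tab$term)[1]
  tab$focal <- seq_len(nrow(tab)) == focal_row
  out <- list(table = tab, focal = tab[focal_row, , drop = FALSE],
              n = n, df = fit$df.residual, formula = fml, fit = fit)
  class(out) <- "model_result"
  out
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("Linear model (n = %d, residual df = %d): %s\n", x$n, x$df,
              deparse(x$formula)))
  print(x$table[, c("term", "estimate", "se", "t", "p", "ci_lo", "ci_hi")],
        digits = 4)
  invisible(x)
}

#' The three structural-functional LC models
#'
#' Convenience wrapper fitting (i) LC contrast ~ age + covariates,
#' (ii) LC response ~ age + covariates, and (iii) LC response ~
#' LC contrast + age + LC contrast x age + covariates, with sex, BMI and
#' education as covariates throughout.
#'
#' @param data table with columns \code{lc_contrast}, \code{lc_response},
#'   \code{age}, \code{sex}, \code{bmi}, \code{education}.
#' @param add_age_group if TRUE, a binary age-group indicator is added as
#'   an extra covariate to each model.
#' @return Named list of \code{model_result}s:
#'   \code{contrast_age}, \code{response_age}, \code{response_contrast}.
#' @export
lc_models <- function(data, add_age_group = FALSE) {
  covs <- c("sex", "bmi", "education")
  if (add_age_group) {
    data$age_group <- as.integer(data$group == "older")
    covs <- c(covs, "age_group")
  }
  list(
    contrast_age = fit_linear_model(data, "lc_contrast", "age", covs),
    response_age = fit_linear_model(data, "lc_response", "age", covs),
    response_contrast = fit_linear_model(
      data, "lc_response", "lc_contrast", c("age", covs),
      interactions = "lc_contrast:age")
  )
}

# One-tailed (or two-tailed) power of the t-test of a single regression
# coefficient: df = n - n_covariates - 2, noncentrality sqrt(n * f2),
# f2 = r^2 / (1 - r^2).
.regression_power <- function(r, alpha, n, n_covariates, tails) {
  df <- n - n_covariates - 2
  if (df < 1) stop("sample too small for the requested model")
  ncp <- sqrt(n * r^2 / (1 - r^2))
  if (tails == 1) {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  }
}

#' Minimum detectable effect size (sensitivity analysis)
#'
#' Inverts the power function of the test of a single coefficient in a
#' multiple regression with \code{n_covariates} additional predictors: the
#' smallest correlation-type effect size |r| whose test reaches the
#' requested power at level \code{alpha}, using the noncentral t
#' distribution with \code{df = n - n_covariates - 2} and noncentrality
#' \code{sqrt(n * f2)}, \code{f2 = r^2 / (1 - r^2)}; solved by bisection to
#' |delta r| < 1e-6. This mirrors the "linear multiple regression, fixed
#' model, single regression coefficient" sensitivity computation.
#'
#' @param alpha significance level (0 < alpha < 1).
#' @param power target power (0 < power < 1).
#' @param n sample size.
#' @param n_covariates number of non-tested predictors (default 3).
#' @param tails 1 (default, one-sided) or 2.
#' @return A list: \code{r}, \code{R2} (= r^2), \code{f2}, \code{df},
#'   \code{achieved_power}.
#' @export
min_detectable_effect <- function(alpha = 0.05, power = 0.8, n = 52,
                                  n_covariates = 3, tails = 1) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  if (n <= 1) stop("'n' must exceed 1")
  lo <- 1e-8; hi <- 1 - 1e-8
  if (.regression_power(hi, alpha, n, n_covariates, tails) < power)
    stop("requested power unreachable for any r < 1")
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (.regression_power(mid, alpha, n, n_covariates, tails) < power)
      lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  list(r = r, R2 = r^2, f2 = r^2 / (1 - r^2), df = n - n_covariates - 2,
       achieved_power = .regression_power(r, alpha, n, n_covariates, tails))
}

#' Achieved power at a given effect size
#'
#' The noncentral-t power of the single-coefficient regression test at
#' effect size r (see \code{\link{min_detectable_effect}} for the
#' parameterization); the exact inverse of the sensitivity analysis.
#'
#' @param r correlation-type effect size, 0 < r < 1.
#' @inheritParams min_detectable_effect
#' @return Achieved power in (0, 1).
#' @export
power_at_effect <- function(r, alpha = 0.05, n = 52, n_covariates = 3,
                            tails = 1) {
  if (r <= 0 || r >= 1) stop("'r' must be in (0, 1)")
  .regression_power(r, alpha, n, n_covariates, tails)
}

#' Monte-Carlo cross-check of the regression power function
#'
#' Simulates \code{reps} datasets under the fixed-predictor convention the
#' analytic sensitivity analysis assumes: per dataset, the focal predictor
#' is orthogonalized against the intercept and covariates and rescaled so
#' its partialled sum of squares equals n (the design carries exactly the
#' nominal effect), the response is \code{r * x} plus matched Gaussian
#' noise, and the focal coefficient is tested in the full regression.
#' (With fully random predictors the realized power falls measurably below
#' the fixed-design value because the sample partial sum of squares is
#' chi-square distributed around its nominal value.)
#'
#' @inheritParams power_at_effect
#' @param reps number of simulated datasets.
#' @param seed optional integer seed.
#' @return Simulated power (rejection fraction).
#' @export
simulate_power <- function(r, alpha = 0.05, n = 52, n_covariates = 3,
                           tails = 1, reps = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- n - n_covariates - 2
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    x <- stats::rnorm(n)
    Z <- matrix(stats::rnorm(n * n_covariates), n)
    xt <- qr.resid(qr(cbind(1, Z)), x)
    x <- xt * sqrt(n) / sqrt(sum(xt^2))
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(n)
    X <- cbind(1, x, Z)
    qrX <- qr(X)
    b <- qr.coef(qrX, y)
    resid <- y - X %*% b
    s2 <- sum(resid^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    tval <- b[2] / sqrt(s2 * XtXinv[2, 2])
    p <- if (tails == 1) stats::pt(tval, df, lower.tail = FALSE)
         else 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    rej[i] <- p < alpha
  }
  mean(rej)
}
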