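#' Default demographic structure of the study cohort
#'
#' Per-group mean, SD, and range for each covariate, plus the proportion of
#' women, mirroring the demographic table of a two-group LC aging study:
#' a young group (18-29 years) and a late middle-aged group (53-70 years),
#' with body-mass index (BMI), education, and depression (BDI), anxiety
#' (BAI) and sleep-quality (PSQI) questionnaire scores.
#'
#' @return A named list with entries \code{young} and \code{older}; each is a
#'   list of \code{c(mean, sd, min, max)} vectors per variable and
#'   \code{p_female}.
#' @export
cohort_defaults <- function() {
  list(
    young = list(
      age       = c(mean = 22.15, sd = 3.27, min = 18,   max = 29),
      bmi       = c(mean = 21.96, sd = 3.11, min = 17.2, max = 28.4),
      education = c(mean = 14.41, sd = 2.28, min = 12,   max = 20),
      bdi       = c(mean = 6.97,  sd = 4.4,  min = 0,    max = 20),
      bai       = c(mean = 4,     sd = 2.9,  min = 0,    max = 11),
      psqi      = c(mean = 4.65,  sd = 1.95, min = 1,    max = 9),
      p_female  = 29 / 34
    ),
    older = list(
      age       = c(mean = 61.05, sd = 5.3,  min = 53,   max = 70),
      bmi       = c(mean = 24.9,  sd = 3.52, min = 19.4, max = 30.9),
      education = c(mean = 14.58, sd = 2.63, min = 9,    max = 19),
      bdi       = c(mean = 5.58,  sd = 4.05, min = 0,    max = 14),
      bai       = c(mean = 3.16,  sd = 3.13, min = 0,    max = 9),
      psqi      = c(mean = 3.95,  sd = 2.22, min = 0,    max = 8),
      p_female  = 14 / 19
    )
  )
}

# Moments of N(mu, sigma) truncated to [a, b], by log-space trapezoid
# quadrature on a fine grid: stable for arbitrarily extreme mu/sigma
# (analytic formulas underflow once the truncation probability does).
trunc_moments <- function(mu, sigma, a, b, n_grid = 2049L) {
  xs <- seq(a, b, length.out = n_grid)
  ld <- stats::dnorm(xs, mu, sigma, log = TRUE)
  w <- exp(ld - max(ld))
  w[c(1L, n_grid)] <- w[c(1L, n_grid)] / 2
  Z <- sum(w)
  m <- sum(w * xs) / Z
  v <- sum(w * (xs - m)^2) / Z
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Find (mu, sigma) of the parent normal so that truncation to [a, b] has the
# requested mean and SD. Needed because truncating N(target mean, target sd)
# shifts both moments (e.g. young age: truncated mean 22.65, SD 2.56).
# Nested 1D solves: for each sigma, mu is chosen so the truncated mean hits
# the target (monotone in mu), then sigma is solved for the SD. A truncated
# normal on [a, b] cannot exceed the uniform-limit SD (b - a)/sqrt(12); if
# the target SD is beyond that (possible when matching small-sample
# empirical summaries), sigma saturates and the closest achievable SD is
# used.
match_trunc_normal <- function(target_mean, target_sd, a, b) {
  tm <- unname(target_mean); ts <- unname(target_sd)
  a <- unname(a); b <- unname(b)
  key <- paste(tm, ts, a, b, sep = "|")
  cached <- .trunc_cache[[key]]
  if (!is.null(cached)) return(cached)
  width <- b - a
  mu_for <- function(sigma) {
    span <- 40 * (width + sigma)
    stats::uniroot(function(mu) trunc_moments(mu, sigma, a, b)[1] - tm,
                   interval = c(a - span, b + span),
                   tol = 1e-12, extendInt = "yes")$root
  }
  sd_gap <- function(ls) {
    s <- exp(ls)
    trunc_moments(mu_for(s), s, a, b)[2] - ts
  }
  lo <- log(max(ts / 20, width / 1000)); hi <- log(100 * width)
  sigma <- if (sd_gap(hi) < 0) exp(hi)
  else if (sd_gap(lo) > 0) exp(lo)
  else exp(stats::uniroot(sd_gap, c(lo, hi), tol = 1e-12)$root)
  out <- c(mu = mu_for(sigma), sigma = sigma)
  .trunc_cache[[key]] <- out
  out
}

# memoised truncated-normal solutions (solving is deterministic)
.trunc_cache <- new.env(parent = emptyenv())

# Inverse-CDF sampling from a truncated normal via the same log-space grid
# used for the moments (stable even when the parent parameters are extreme;
# piecewise-linear inversion on a 2049-point grid).
rtruncnorm <- function(n, mu, sigma, a, b, n_grid = 2049L) {
  xs <- seq(a, b, length.out = n_grid)
  ld <- stats::dnorm(xs, mu, sigma, log = TRUE)
  w <- exp(ld - max(ld))
  cw <- c(0, cumsum((w[-1] + w[-n_grid]) / 2))
  cdf <- cw / cw[n_grid] + seq(0, 1e-12, length.out = n_grid)
  stats::approx(cdf, xs, xout = stats::runif(n), rule = 2)$y
}

#' Generate a synthetic study cohort
#'
#' Draws participant-level covariates per age group from truncated normal
#' distributions whose post-truncation mean and SD match the configured
#' group summaries (see \code{\link{cohort_defaults}}), so that sample
#' moments converge to the configured values as n grows. Sex is Bernoulli
#' with the configured proportion of women; questionnaire scores are kept
#' within their observed ranges.
#'
#' @param n_young,n_older non-negative group sizes.
#' @param seed optional integer seed (fixing it makes the draw reproducible).
#' @param defaults cohort structure, as returned by \code{cohort_defaults()}.
#' @return A data.frame with one row per participant: \code{id}, \code{group}
#'   ("young"/"older"), \code{age}, \code{sex} ("F"/"M"), \code{bmi},
#'   \code{education}, \code{bdi}, \code{bai}, \code{psqi},
#'   \code{usable_structural}, \code{usable_physio} (both TRUE; exclusions
#'   are planted downstream by the pipeline).
#' @export
generate_cohort <- function(n_young, n_older, seed = NULL,
                            defaults = cohort_defaults()) {
  if (n_young < 0 || n_older < 0) stop("group sizes must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  draw_group <- function(n, group, cfg) {
    vars <- c("age", "bmi", "education", "bdi", "bai", "psqi")
    cols <- lapply(vars, function(v) {
      p <- cfg[[v]]
      par <- match_trunc_normal(p["mean"], p["sd"], p["min"], p["max"])
      rtruncnorm(n, par["mu"], par["sigma"], p["min"], p["max"])
    })
    names(cols) <- vars
    data.frame(group = rep(group, n),
               age = cols$age,
               sex = ifelse(stats::runif(n) < cfg$p_female, "F", "M"),
               bmi = cols$bmi, education = cols$education,
               bdi = cols$bdi, bai = cols$bai, psqi = cols$psqi,
               stringsAsFactors = FALSE)
  }
  out <- rbind(draw_group(n_young, "young", defaults$young),
               draw_group(n_older, "older", defaults$older))
  n <- nrow(out)
  out <- cbind(id = sprintf("sub-%03d", seq_len(n)), out,
               stringsAsFactors = FALSE)
  if (n == 0) out$id <- character(0)
  out$usable_structural <- rep(TRUE, n)
  out$usable_physio <- rep(TRUE, n)
  rownames(out) <- NULL
  out
}

#' Compare a covariate between the two age groups
#'
#' Continuous variables are compared with a Welch (unequal-variance)
#' two-sample t-test; sex composition with a Pearson chi-square test on the
#' 2x2 table (no continuity correction).
#'
#' @param data participant table with a \code{group} column.
#' @param variable column name to compare.
#' @return A list with \code{test} ("welch" or "chisq"), \code{statistic},
#'   \code{p}, and per-group summaries.
#' @export
compare_groups <- function(data, variable) {
  stopifnot(variable %in% names(data), "group" %in% names(data))
  g <- data$group
  if (length(unique(g)) != 2L) stop("need exactly two nonempty groups")
  x <- data[[variable]]
  if (is.numeric(x)) {
    sds <- tapply(x, g, stats::sd)
    if (all(sds == 0, na.rm = TRUE))
      stop("zero variance in both groups: t-test undefined")
    tt <- stats::t.test(x ~ g)
    list(test = "welch", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         means = tapply(x, g, mean), sds = sds)
  } else {
    tab <- table(g, x)
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(test = "chisq", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value, table = tab)
  }
}
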