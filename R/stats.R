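#' Scaled mass index (SMI) body condition
#'
#' Standardizes each individual's mass to the reference length \code{L0}
#' through the standardized-major-axis (SMA) allometry of mass on length:
#' \deqn{SMI_i = m_i (L_0 / L_i)^{b_{SMA}},}
#' where \eqn{b_{SMA}} is the OLS slope of \eqn{\ln m} on \eqn{\ln L} divided
#' by the Pearson correlation of \eqn{\ln m} and \eqn{\ln L}.
#'
#' @param mass positive numeric vector of body masses (g).
#' @param svl positive numeric vector of snout-vent lengths (mm), same length.
#' @param L0 reference length; default the arithmetic mean of \code{svl}.
#' @return numeric vector of SMI values, with \code{b_sma} and \code{L0}
#'   attached as attributes.
#' @export
scaled_mass_index <- function(mass, svl, L0 = mean(svl)) {
  check_that(length(mass) == length(svl) && length(mass) >= 3,
             "need >= 3 paired mass/svl values")
  check_that(all(mass > 0) && all(svl > 0), "mass and svl must be positive")
  lm_ <- log(mass); ll <- log(svl)
  if (stats::var(ll) == 0) {
    stop("slope undefined: zero variance in svl", call. = FALSE)
  }
  b_ols <- stats::cov(lm_, ll) / stats::var(ll)
  r <- stats::cor(lm_, ll)
  if (!is.finite(r) || r == 0) {
    stop("slope undefined: mass and svl are uncorrelated", call. = FALSE)
  }
  b_sma <- b_ols / r
  out <- mass * (L0 / svl)^b_sma
  attr(out, "b_sma") <- b_sma
  attr(out, "L0") <- L0
  out
}

#' Finite-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n - k - 1}.}
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed coefficients plus variance
#'   components).
#' @param n number of observations; must exceed \code{k + 1}.
#' @return the AICc value.
#' @examples
#' aicc(-7, 3, 10)  # 24
#' @export
aicc <- function(loglik, k, n) {
  check_that(is.numeric(loglik) && is.numeric(k) && is.numeric(n),
             "loglik, k, n must be numeric")
  if (any(n <= k + 1)) {
    stop("AICc correction undefined: n <= k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Exhaustive ranking over a declared candidate set (order-independent, unlike
#' greedy stepwise selection). Computes per model the AICc, the difference to
#' the best model, and Akaike weights
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}. Ties are broken by
#' fewer parameters, then label order.
#'
#' @param candidates list of fitted candidates as returned by [fit_lmm()], or
#'   any list of lists each holding \code{label}, \code{loglik}, \code{k},
#'   \code{n}.
#' @return a \code{model_comparison} tibble with columns \code{label, k,
#'   loglik, AICc, delta_AICc, weight}, sorted ascending by AICc.
#' @export
rank_models <- function(candidates) {
  check_that(is.list(candidates) && length(candidates) >= 1,
             "need at least one candidate")
  ns <- vapply(candidates, function(m) as.double(m$n), numeric(1))
  if (length(unique(ns)) != 1L) {
    stop("candidates fitted on different numbers of observations", call. = FALSE)
  }
  tab <- tibble::tibble(
    label  = vapply(candidates, function(m) as.character(m$label), character(1)),
    k      = vapply(candidates, function(m) as.double(m$k), numeric(1)),
    loglik = vapply(candidates, function(m) as.double(m$loglik), numeric(1)),
    n      = ns
  )
  tab$AICc <- aicc(tab$loglik, tab$k, tab$n)
  ord <- order(tab$AICc, tab$k, tab$label)
  tab <- tab[ord, ]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  tab$n <- NULL
  class(tab) <- c("model_comparison", class(tab))
  tab
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Random-intercept linear mixed model, fitted by (unrestricted) maximum
#' likelihood so that AICc values are comparable across fixed-effect
#' structures. The parameter count \code{k} is the number of fixed-effect
#' coefficients plus two variance components (random-intercept and residual
#' variance). When the grouping factor has a single level, or the
#' between-group variance is zero, the fit degenerates to ordinary least
#' squares (fitted with \code{lm}; \code{k} then counts the residual variance
#' as its single variance component plus a zero between-group component for
#' comparability).
#'
#' @param data data frame of observations.
#' @param response name of the numeric response column.
#' @param fixed character vector of fixed-effect term labels (may be
#'   \code{character(0)} for intercept-only).
#' @param random_intercept name of the grouping column for the random
#'   intercept (e.g. survey year).
#' @param label model label for ranking tables; default built from the terms.
#' @return list with \code{label, loglik, k, n, coefficients, sigma, fit,
#'   formula}.
#' @export
fit_lmm <- function(data, response, fixed = character(0),
                    random_intercept = "year", label = NULL) {
  check_that(response %in% names(data), "response column not found")
  check_that(random_intercept %in% names(data), "grouping column not found")
  rhs_fixed <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (is.null(label)) label <- paste0(response, " ~ ", rhs_fixed)
  data[[random_intercept]] <- factor(data[[random_intercept]])
  single_group <- nlevels(data[[random_intercept]]) < 2L

  if (single_group) {
    f <- stats::as.formula(paste(response, "~", rhs_fixed))
    fit <- stats::lm(f, data = data)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("singular design: collinear terms ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    ll <- as.numeric(stats::logLik(fit))
    k <- length(stats::coef(fit)) + 2  # residual + (zero) group variance
    return(list(label = label, loglik = ll, k = k, n = stats::nobs(fit),
                coefficients = stats::coef(fit), sigma = stats::sigma(fit),
                fit = fit, formula = f))
  }

  X_full <- stats::model.matrix(stats::as.formula(paste("~", rhs_fixed)), data)
  if (qr(X_full)$rank < ncol(X_full)) {
    stop("singular design: collinear fixed-effect terms in ", rhs_fixed,
         call. = FALSE)
  }
  f <- stats::as.formula(paste0(response, " ~ ", rhs_fixed,
                                " + (1 | ", random_intercept, ")"))
  fit <- lme4::lmer(f, data = data, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  list(label = label, loglik = as.numeric(stats::logLik(fit)),
       k = length(fe) + 2, n = stats::nobs(fit),
       coefficients = fe, sigma = stats::sigma(fit), fit = fit, formula = f)
}

#' Ordinary least-squares regression summary
#'
#' Simple linear regression of \code{y} on \code{x} with the usual
#' coefficient of determination and two-sided slope test.
#'
#' @param y,x numeric vectors, at least 3 points, \code{var(x) > 0}.
#' @return list with \code{slope, intercept, r_squared, p_value, slope_se, n}.
#' @export
linear_regression <- function(y, x) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  check_that(length(x) >= 3, "need >= 3 complete points")
  if (stats::var(x) == 0) stop("var(x) = 0: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       slope_se = sm$coefficients[2, 2],
       n = length(x))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. The null distribution is
#' exact (full enumeration of sign patterns) when at most 25 nonzero
#' differences are present and there are no ties among them; the tie-corrected
#' normal approximation with continuity correction is used otherwise. The
#' method actually used is recorded in the result.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with \code{statistic} (V), \code{p_value}, \code{n_used},
#'   \code{method}.
#' @export
paired_signed_rank <- function(a, b) {
  check_that(length(a) == length(b), "a and b must have equal length")
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    stop("degenerate data: all paired differences are zero", call. = FALSE)
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_used = length(nz),
       method = if (exact) "exact" else "normal approximation")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test. Exact null by enumeration when the combined sample
#' size is at most 20 and the data are tie-free; tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param group_a,group_b numeric vectors, both nonempty.
#' @return list with \code{statistic} (W for \code{group_a}), \code{p_value},
#'   \code{n}, \code{method}.
#' @export
rank_sum_test <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n_comb <- length(group_a) + length(group_b)
  exact <- n_comb <= 20 && !any(duplicated(c(group_a, group_b)))
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = c(length(group_a), length(group_b)),
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard tie-corrected H statistic referred to a chi-square distribution
#' with (number of groups - 1) degrees of freedom. With all observations tied
#' the statistic is reported as 0 with p = 1 (the tie correction makes H 0/0;
#' the no-information convention is documented here rather than erroring).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length; at least two distinct groups.
#' @return list with \code{H, df, p_value, n}.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                n = length(values)))
  }
  ht <- stats::kruskal.test(values, groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = length(values))
}

#' Tukey-adjusted pairwise contrasts between group means
#'
#' All pairwise mean differences from a one-way linear model, with single-step
#' family-wise adjustment over the studentized multivariate-t distribution
#' (Tukey contrasts via \pkg{multcomp}). If the single-step computation fails,
#' Holm-adjusted t-tests are used and flagged. Groups with fewer than two
#' observations are dropped from the model and their pairs reported as
#' skipped.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length.
#' @param adjust \code{"single-step"} (default) or \code{"holm"}.
#' @return tibble with columns \code{pair, estimate, p_adjusted, method,
#'   skipped}.
#' @export
pairwise_contrasts <- function(values, groups, adjust = c("single-step", "holm")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  check_that(nlevels(groups) >= 2, "need at least two groups")
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  keep <- !(groups %in% small)
  g <- droplevels(groups[keep]); v <- values[keep]
  skipped_rows <- NULL
  if (length(small)) {
    pairs_sk <- unlist(lapply(small, function(s)
      paste(s, setdiff(levels(groups), s), sep = " - ")))
    skipped_rows <- tibble::tibble(pair = pairs_sk, estimate = NA_real_,
                                   p_adjusted = NA_real_, method = "skipped",
                                   skipped = TRUE)
  }
  check_that(nlevels(g) >= 2, "fewer than two groups with >= 2 observations")
  dat <- data.frame(v = v, g = g)
  fit <- stats::lm(v ~ g, data = dat)
  res <- NULL
  if (adjust == "single-step") {
    res <- tryCatch({
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
      sm <- summary(gl, test = multcomp::adjusted("single-step"))
      tibble::tibble(pair = rownames(sm$linfct),
                     estimate = as.numeric(sm$test$coefficients),
                     p_adjusted = as.numeric(sm$test$pvalues),
                     method = "single-step", skipped = FALSE)
    }, error = function(e) NULL)
  }
  if (is.null(res)) {
    lv <- levels(g)
    combs <- utils::combn(lv, 2)
    est <- numeric(ncol(combs)); pv <- numeric(ncol(combs))
    for (i in seq_len(ncol(combs))) {
      xa <- v[g == combs[2, i]]; xb <- v[g == combs[1, i]]
      est[i] <- mean(xa) - mean(xb)
      pv[i] <- stats::t.test(xa, xb, var.equal = TRUE)$p.value
    }
    res <- tibble::tibble(pair = paste(combs[2, ], combs[1, ], sep = " - "),
                          estimate = est,
                          p_adjusted = stats::p.adjust(pv, "holm"),
                          method = "holm", skipped = FALSE)
  }
  if (!is.null(skipped_rows)) res <- rbind(res, skipped_rows)
  res
}
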