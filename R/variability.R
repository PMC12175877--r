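# Severity and variability statistics for intensive longitudinal scores:
# RMSSD, coefficient of variation, ICC, skewness, group-mean centering.

#' Root mean square of successive differences
#'
#' Moment-to-moment variability of an ordered series: the square root of the
#' mean squared difference between consecutive observed values. Pairs are
#' consecutive *observed* check-ins; with `max_gap_hours` set and a timestamp
#' vector supplied, successive-difference chains are broken at longer gaps.
#'
#' @param x Numeric series in time order (NAs dropped).
#' @param ts Optional timestamps aligned with `x`.
#' @param max_gap_hours Optional gap (hours) beyond which pairs are skipped.
#' @return RMSSD, or `NA` (flagged with a warning) for fewer than 2 values.
#' @export
rmssd <- function(x, ts = NULL, max_gap_hours = NULL) {
  keep <- !is.na(x)
  x <- x[keep]
  if (!is.null(ts)) ts <- ts[keep]
  if (length(x) < 2) {
    warning("rmssd undefined for fewer than 2 observations", call. = FALSE)
    return(NA_real_)
  }
  d <- diff(x)
  if (!is.null(max_gap_hours) && !is.null(ts)) {
    gap <- as.numeric(difftime(ts[-1], ts[-length(ts)], units = "hours"))
    d <- d[gap <= max_gap_hours]
    if (length(d) == 0) {
      warning("rmssd undefined: no successive pairs within the gap limit",
              call. = FALSE)
      return(NA_real_)
    }
  }
  sqrt(mean(d^2))
}

#' Coefficient of variation
#'
#' Scale-free dispersion, SD divided by mean. Undefined (flagged `NA`) when
#' the mean is 0, as happens for all-zero control series.
#'
#' @param x Numeric series (NAs dropped).
#' @return SD/mean, or `NA` when the mean is 0 or fewer than 2 values remain.
#' @export
coef_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    warning("coefficient of variation undefined for fewer than 2 observations",
            call. = FALSE)
    return(NA_real_)
  }
  m <- mean(x)
  if (m == 0) {
    warning("coefficient of variation undefined for zero mean", call. = FALSE)
    return(NA_real_)
  }
  stats::sd(x) / m
}

#' Moment coefficient of skewness
#'
#' Unadjusted g1 = m3 / m2^(3/2) over the pooled values.
#'
#' @param x Numeric series (NAs dropped).
#' @return g1, or `NA` (flagged) for fewer than 3 values or zero SD.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) {
    warning("skewness undefined for fewer than 3 observations", call. = FALSE)
    return(NA_real_)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("skewness undefined for zero variance", call. = FALSE)
    return(NA_real_)
  }
  mean((x - m)^3) / m2^1.5
}

# Profiled restricted-likelihood criterion for the one-way random-intercept
# model, as a function of gamma = var_between / var_within. Valid for
# unbalanced group sizes; reduces to the ANOVA moment estimator exactly in
# the balanced case (when the estimate is interior).
one_way_reml <- function(x, participant) {
  k <- as.vector(table(participant))
  ybar <- as.vector(tapply(x, participant, mean))
  ssw <- sum((x - ybar[match(participant, names(table(participant)))])^2)
  n <- length(x)
  if (ssw == 0) {
    # no within-person variance at all: the between share is everything
    return(c(var_between = stats::var(ybar), var_within = 0))
  }
  crit <- function(gamma) {
    w <- k / (1 + k * gamma)
    mu <- sum(w * ybar) / sum(w)
    rss <- ssw + sum(w * (ybar - mu)^2)
    s2 <- rss / (n - 1)
    (n - 1) * log(s2) + sum(log(1 + k * gamma)) + log(sum(w))
  }
  # stationarity condition of the profiled criterion (envelope theorem for
  # the GLS mean); solved by root-finding for full precision
  grad <- function(gamma) {
    w <- k / (1 + k * gamma)
    mu <- sum(w * ybar) / sum(w)
    d <- ybar - mu
    s <- ssw + sum(w * d^2)
    -(n - 1) * sum(w^2 * d^2) / s + sum(w) - sum(w^2) / sum(w)
  }
  if (grad(0) >= 0) {
    gamma <- 0  # boundary: no between-person variance
  } else {
    opt <- stats::optimize(function(t) crit(exp(t)), c(-30, 10), tol = 1e-9)
    g0 <- exp(opt$minimum)
    lo <- g0 / 2; hi <- g0 * 2
    for (i in 1:60) {
      if (grad(lo) < 0 && grad(hi) > 0) break
      if (grad(lo) >= 0) lo <- lo / 2
      if (grad(hi) <= 0) hi <- hi * 2
    }
    gamma <- if (grad(lo) < 0 && grad(hi) > 0) {
      stats::uniroot(grad, c(lo, hi), tol = 1e-13)$root
    } else g0
    if (crit(0) <= crit(gamma)) gamma <- 0
  }
  w <- k / (1 + k * gamma)
  mu <- sum(w * ybar) / sum(w)
  s2 <- (ssw + sum(w * (ybar - mu)^2)) / (n - 1)
  c(var_between = gamma * s2, var_within = s2)
}

#' Intraclass correlation from a random-intercept decomposition
#'
#' Share of total variance attributable to between-person differences:
#' variance components come from a restricted-maximum-likelihood one-way
#' random-intercept decomposition (valid for unbalanced data; the
#' between-person variance is truncated at 0 on the boundary), and the ICC
#' is between / (between + within), truncated to `[0, 1]`. `1 - ICC` is the
#' within-person share.
#'
#' @param x Repeated scores (long).
#' @param participant Participant id aligned with `x`.
#' @return ICC value with attributes `var_between` and `var_within`; `NA`
#'   (flagged) for degenerate input (zero total variance, < 2 participants,
#'   or no participant with >= 2 observations).
#' @export
icc <- function(x, participant) {
  keep <- !is.na(x)
  x <- x[keep]
  participant <- as.character(participant[keep])
  if (length(unique(participant)) < 2 ||
      max(table(participant)) < 2 ||
      stats::var(x) == 0) {
    warning("icc undefined for degenerate input", call. = FALSE)
    return(NA_real_)
  }
  vc <- tryCatch(one_way_reml(x, participant), error = function(e) NULL)
  if (is.null(vc) || !all(is.finite(vc))) {
    warning("icc undefined: variance decomposition failed", call. = FALSE)
    return(NA_real_)
  }
  vb <- vc[["var_between"]]
  vw <- vc[["var_within"]]
  if (vb + vw == 0) {
    warning("icc undefined for zero total variance", call. = FALSE)
    return(NA_real_)
  }
  out <- min(1, max(0, vb / (vb + vw)))
  attr(out, "var_between") <- vb
  attr(out, "var_within") <- vw
  out
}

#' Group-mean (person-mean) centering
#'
#' Subtracts each participant's own mean from each of their scores, so the
#' centered values express deviation from the person's average (per-person
#' mean of the output is 0). Idempotent.
#'
#' @param x Scores.
#' @param participant Aligned participant ids.
#' @return Centered scores.
#' @export
group_mean_center <- function(x, participant) {
  x - stats::ave(x, as.character(participant),
                 FUN = function(v) mean(v, na.rm = TRUE))
}
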