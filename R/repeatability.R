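# Repeatability statistics: within-subject and group coefficients of
# variation (root-mean-square method), Bland-Altman bias and limits of
# agreement, paired mean differences, and an exact Mann-Whitney U test for
# comparing CoV distributions between study arms.

#' Within-subject coefficient of variation (root-mean-square method)
#'
#' For two measurements of the same quantity on one subject, the
#' within-subject standard deviation of a duplicate pair is
#' \code{|x1 - x2| / sqrt(2)}, and the CoV is that SD as a percentage of the
#' pair mean.
#'
#' @param x1,x2 the two measurements (same units); vectorised over pairs.
#' @return CoV in percent.
#' @export
subject_cov <- function(x1, x2) {
  m <- (x1 + x2) / 2
  if (any(m <= 0))
    stop("pair mean must be > 0 for a coefficient of variation")
  100 * (abs(x1 - x2) / sqrt(2)) / m
}

#' Group coefficient of variation
#'
#' The root mean square of the per-subject CoVs: square each subject's CoV,
#' average, take the square root.
#'
#' @param covs per-subject CoVs in percent.
#' @return group CoV in percent.
#' @export
group_cov <- function(covs) {
  if (length(covs) == 0L) stop("need at least one subject CoV")
  sqrt(mean(covs^2))
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences \code{d = x2 - x1}; bias is their mean and the limits of
#' agreement are \code{bias +/- 1.96 * SD(d)} (sample SD). The (mean,
#' difference) points are returned for plotting.
#'
#' @param x1,x2 paired measurements, same subjects in the same order.
#' @param subject optional subject identifiers.
#' @return An object of class \code{bland_altman}: list with \code{bias},
#'   \code{sd_diff}, \code{loa_lower}, \code{loa_upper}, \code{means},
#'   \code{diffs}, \code{n}.
#' @export
bland_altman <- function(x1, x2, subject = NULL) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < 2L) stop("need at least 2 pairs")
  d <- x2 - x1
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_d,
         loa_lower = bias - 1.96 * sd_d, loa_upper = bias + 1.96 * sd_d,
         means = (x1 + x2) / 2, diffs = d, n = length(d),
         subject = subject),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, limits of agreement (%.3f, %.3f), n = %d\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of pair",
                              ylab = "difference (scan 2 - scan 1)", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab,
                 ylim = range(c(x$diffs, x$loa_lower, x$loa_upper)), ...)
  graphics::abline(h = x$bias)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 3)
  invisible(x)
}

#' Paired mean difference with its observed 95\% interval
#'
#' Mean of the paired differences with, by default, the interval
#' \code{mean +/- 1.96 * SD(d)} describing the spread of observed
#' differences (the limits of agreement). A true confidence interval of the
#' mean (\code{SD/sqrt(n)}) is available via \code{interval = "ci_mean"}.
#'
#' @param x1,x2 paired measurements.
#' @param interval \code{"loa"} (default) or \code{"ci_mean"}.
#' @return list with \code{mean_diff}, \code{lower}, \code{upper},
#'   \code{interval}.
#' @export
paired_mean_difference <- function(x1, x2, interval = c("loa", "ci_mean")) {
  interval <- match.arg(interval)
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < 2L) stop("need at least 2 pairs")
  d <- x2 - x1
  m <- mean(d)
  s <- stats::sd(d)
  half <- if (interval == "loa") 1.96 * s else 1.96 * s / sqrt(length(d))
  list(mean_diff = m, lower = m - half, upper = m + half,
       interval = interval)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. For small
#' tie-free samples (\code{min(n) <= 8} and \code{n_a + n_b <= 20}) the null
#' distribution of U is enumerated exactly over all arrangements of the
#' ranks; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param group_a,group_b numeric samples.
#' @return list with \code{U} (for \code{group_a}), \code{p_value},
#'   \code{method}.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  comb <- c(group_a, group_b)
  r <- rank(comb)
  has_ties <- any(duplicated(comb))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (!has_ties && min(na, nb) <= 8L && na + nb <= 20L) {
    # exact enumeration: U depends only on which ranks group A occupies
    sets <- utils::combn(na + nb, na)
    u_null <- colSums(matrix(sets, nrow = na)) - na * (na + 1) / 2
    p_le <- mean(u_null <= U + 1e-9)
    p_ge <- mean(u_null >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(comb)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu)
      z <- (abs(z) - 0.5) / sqrt(sigma2)  # continuity correction toward mean
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method)
}

#' Repeatability summary table for paired measurements
#'
#' Builds, per quantity, the paired analysis used to summarise a
#' scan-rescan or interval design: observed mean difference with its
#' interval, per-subject CoVs and the group CoV.
#'
#' @param data data frame in long format with columns \code{subject},
#'   \code{quantity}, \code{x1}, \code{x2}.
#' @return data frame with one row per quantity: \code{n}, \code{mean_diff},
#'   \code{lower}, \code{upper}, \code{group_cov_pct}.
#' @export
repeatability_summary <- function(data) {
  stopifnot(all(c("subject", "quantity", "x1", "x2") %in% names(data)))
  out <- lapply(split(data, data$quantity), function(dq) {
    pm <- paired_mean_difference(dq$x1, dq$x2)
    covs <- subject_cov(dq$x1, dq$x2)
    data.frame(quantity = dq$quantity[1], n = nrow(dq),
               mean_diff = pm$mean_diff, lower = pm$lower, upper = pm$upper,
               group_cov_pct = group_cov(covs))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
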