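# Probe-level association statistics: biweight midcorrelation, moderated-t
# regression with empirical-Bayes variance shrinkage, BH adjustment,
# genomic inflation, and cross-stratum concordance.

#' Biweight midcorrelation
#'
#' Robust correlation using median/MAD-based biweights:
#' \eqn{u_i = (x_i - med(x)) / (c \cdot MAD(x))} with raw (unscaled) MAD,
#' weight \eqn{w_i = (1 - u_i^2)^2 \, 1[|u_i| < 1]}, and the weighted
#' cross-product normalized by the per-vector root sums of squared
#' weighted deviations. Falls back to Pearson correlation (with a message)
#' for a vector whose MAD is zero but variance is not; returns `NA` with a
#' warning when a vector is entirely constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param c Biweight tuning constant (default 9).
#' @return Correlation in \[-1, 1\].
#' @export
bicor <- function(x, y, c = 9) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  wdev <- function(v, nm) {
    if (var(v) == 0) {
      warning("bicor: constant vector (", nm, "); returning NA")
      return(NULL)
    }
    m <- median(v)
    s <- median(abs(v - m))      # raw MAD, no consistency constant
    if (s == 0) {
      message("bicor: zero MAD in ", nm, "; falling back to Pearson weights")
      d <- v - mean(v)
      return(d)
    }
    u <- (v - m) / (c * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    w * (v - m)
  }
  a <- wdev(x, "x")
  b <- wdev(y, "y")
  if (is.null(a) || is.null(b)) return(NA_real_)
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# Project an exposure onto the orthogonal complement of the covariate
# design attached to a residual matrix (Frisch-Waugh-Lovell), returning
# the adjusted exposure and matching residual degrees of freedom.
adjust_exposure_to_design <- function(residuals, exposure, adjust = TRUE) {
  X <- attr(residuals, "design")
  if (!adjust || is.null(X))
    return(list(exposure = exposure, df_resid = NULL))
  if (nrow(X) != length(exposure))
    stop("exposure length does not match the design", call. = FALSE)
  list(exposure = qr.resid(qr(X), exposure),
       df_resid = ncol(residuals) - ncol(X) - 1L)
}

# Row-wise bicor of a matrix against one vector; used per-probe.
bicor_rows <- function(mat, y, c = 9) {
  n <- ncol(mat)
  med <- apply(mat, 1, median)
  dev <- mat - med
  madr <- apply(abs(dev), 1, median)
  u <- dev / (c * madr)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  # Pearson fallback rows (zero MAD): mean-centered, unit weights
  fb <- which(madr == 0)
  if (length(fb)) {
    dev[fb, ] <- mat[fb, , drop = FALSE] - rowMeans(mat[fb, , drop = FALSE])
    w[fb, ] <- 1
  }
  my <- median(y)
  sy <- median(abs(y - my))
  if (sy == 0) {
    by <- y - mean(y)
  } else {
    uy <- (y - my) / (c * sy)
    by <- (1 - uy^2)^2 * (abs(uy) < 1) * (y - my)
  }
  a <- w * dev
  num <- as.vector(a %*% by)
  num / (sqrt(rowSums(a^2)) * sqrt(sum(by^2)))
}

# Newton inversion of the trigamma function (monotone decreasing on R+).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

# Fit the scaled-F prior (d0, s0^2) to per-probe residual variances by
# matching the first two moments of log s^2 (digamma/trigamma inversion).
fit_variance_prior <- function(s2, df, df_ceiling = 1e7) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- var(e) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    # variances more concentrated than chi-square sampling alone: no
    # residual spread for the prior to explain -> infinite prior df
    df_prior <- df_ceiling
    s0 <- exp(mean(e))
  } else {
    df_prior <- min(2 * trigamma_inverse(ev), df_ceiling)
    s0 <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
  }
  list(df_prior = df_prior, var_prior = s0)
}

#' Moderated-t association of each probe with an exposure
#'
#' Per probe, fits the simple regression of adjusted methylation on the
#' exposure, then shrinks the residual variances toward a common prior
#' fitted across probes by matching the first two moments of
#' \eqn{\log s_g^2} to a scaled-F model (closed form via digamma/trigamma
#' inversion). The moderated t-statistic uses the posterior variance
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)} with
#' \eqn{d + d_0} degrees of freedom. The biweight midcorrelation of each
#' probe with the exposure is reported alongside as the effect scale.
#'
#' @param residuals Probes x samples residual matrix (see [residualize()]).
#' @param exposure Numeric exposure vector (one value per sample,
#'   non-constant).
#' @param prior_df Optional override of the prior degrees of freedom
#'   \eqn{d_0} (0 recovers the ordinary t-test); `NULL` (default)
#'   estimates it.
#' @param threshold Unadjusted p-value threshold defining the
#'   `significant` flag (default 1e-7).
#' @param df_resid Residual degrees of freedom \eqn{d} per probe; defaults
#'   to `n - 2`. When the residual matrix was adjusted for `k` covariate
#'   columns and the exposure is adjusted for the same design, pass
#'   `n - k - 1` so the test is calibrated.
#' @return A data frame of class `ewas_table` (`probe_id`, `bicor_r`,
#'   `slope`, `t`, `p`, `p_bh`, `significant`) with the variance-prior fit
#'   in attributes `df_prior`, `var_prior`, `df_total`.
#' @export
moderated_fit <- function(residuals, exposure, prior_df = NULL,
                          threshold = 1e-7, df_resid = NULL) {
  n <- ncol(residuals)
  if (length(exposure) != n)
    stop("exposure length must equal the number of samples", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (var(exposure) == 0) stop("exposure is constant", call. = FALSE)
  xc <- exposure - mean(exposure)
  sxx <- sum(xc^2)
  yc <- residuals - rowMeans(residuals)
  slope <- as.vector(yc %*% xc) / sxx
  rss <- rowSums(yc^2) - slope^2 * sxx
  rss <- pmax(rss, 0)
  df <- if (is.null(df_resid)) n - 2 else df_resid
  if (df < 1) stop("residual degrees of freedom must be >= 1", call. = FALSE)
  s2 <- rss / df
  if (is.null(prior_df)) {
    pr <- fit_variance_prior(s2, df)
  } else {
    pr <- list(df_prior = prior_df,
               var_prior = if (prior_df > 0) mean(s2) else NA_real_)
  }
  d0 <- pr$df_prior
  s2_post <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(pr$var_prior, length(s2))
             else (d0 * pr$var_prior + df * s2) / (d0 + df)
  se <- sqrt(s2_post / sxx)
  tstat <- slope / se
  df_total <- df + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(probe_id = rownames(residuals),
                    bicor_r = bicor_rows(residuals, exposure),
                    slope = slope, t = tstat, p = p,
                    p_bh = bh_adjust(p),
                    significant = p < threshold)
  rownames(out) <- NULL
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- pr$var_prior
  attr(out, "df_total") <- df_total
  attr(out, "threshold") <- threshold
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1), via
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median observed association chi-square divided by the
#' null median of \eqn{\chi^2_1} (0.4549364). Accepts two-sided p-values
#' or z-scores (only \eqn{z^2} is used).
#'
#' @param p Two-sided p-values, or
#' @param z z-scores (give exactly one of the two).
#' @return The inflation factor \eqn{\lambda}.
#' @export
genomic_inflation <- function(p = NULL, z = NULL) {
  if (is.null(p) == is.null(z))
    stop("give exactly one of p or z", call. = FALSE)
  if (!is.null(z)) {
    chisq <- z^2
  } else {
    if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
    if (any(p == 0)) {
      warning("p-values of exactly 0 clamped to smallest positive double")
      p <- pmax(p, .Machine$double.xmin)
    }
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  median(chisq) / qchisq(0.5, df = 1)
}

#' Signed z-scores from two-sided p-values
#'
#' The standard construction for inflation diagnostics:
#' \eqn{z = sign \cdot \Phi^{-1}(1 - p/2)}.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param sign Effect signs (e.g. `sign(slope)`).
#' @return z-score vector.
#' @export
z_from_p <- function(p, sign) {
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  qnorm(p / 2, lower.tail = FALSE) * ifelse(sign >= 0, 1, -1)
}

#' Cross-stratum concordance of effect estimates
#'
#' Pearson correlation, over a probe subset, of the effect estimates from
#' two association tables (e.g. cases-only vs controls-only EWAS over the
#' probes significant in the pooled analysis).
#'
#' @param table_a,table_b `ewas_table` data frames.
#' @param probes Probe ids to compare (>= 3, present in both tables).
#' @param measure Column to correlate, `"bicor_r"` (default) or `"slope"`.
#' @return Pearson correlation.
#' @export
stratified_concordance <- function(table_a, table_b, probes,
                                   measure = c("bicor_r", "slope")) {
  measure <- match.arg(measure)
  if (length(probes) < 3)
    stop("need at least 3 probes", call. = FALSE)
  ia <- match(probes, table_a$probe_id)
  ib <- match(probes, table_b$probe_id)
  if (anyNA(ia) || anyNA(ib))
    stop("some probes are missing from one of the tables", call. = FALSE)
  cor(table_a[[measure]][ia], table_b[[measure]][ib])
}

#' Run the probe-level EWAS
#'
#' Convenience wrapper: moderated fit plus annotation columns and an
#' inflation estimate from the moderated-t p-values. When the residual
#' matrix carries its covariate design (as produced by [residualize()])
#' the exposure is projected onto the design's orthogonal complement
#' before association (the Frisch-Waugh-Lovell partial regression), and
#' the residual degrees of freedom are reduced accordingly; this is what
#' keeps the test calibrated when the exposure itself is correlated with
#' the covariates.
#'
#' @param residuals Probes x samples residual matrix.
#' @param annot Annotation aligned to (a superset of) the residual rows.
#' @param exposure Exposure vector (e.g. copper count).
#' @param threshold Significance threshold on the unadjusted p (default
#'   1e-7).
#' @param adjust_exposure Adjust the exposure for the residual matrix's
#'   design (default TRUE when the design is available).
#' @return `ewas_table` with `chromosome`, `position`, `gene` columns and
#'   attribute `lambda`.
#' @export
run_ewas <- function(residuals, annot, exposure, threshold = 1e-7,
                     adjust_exposure = TRUE) {
  adj <- adjust_exposure_to_design(residuals, exposure, adjust_exposure)
  tab <- moderated_fit(residuals, adj$exposure, threshold = threshold,
                       df_resid = adj$df_resid)
  m <- match(tab$probe_id, annot$probe_id)
  tab$chromosome <- annot$chromosome[m]
  tab$position <- annot$position[m]
  tab$gene <- annot$gene[m]
  attr(tab, "lambda") <- genomic_inflation(p = tab$p)
  tab
}
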