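# Statistical battery.
#
# Every test returns a one-row (or per-effect) `gaze_stat` tibble with a
# common column contract: name, statistic, df1, df2, p_value, effect_size,
# effect_type, ci_low, ci_high, correction. Cluster-robust tests are
# implemented from their defining formulas on unweighted cluster means,
# the informative-cluster-size-robust choice.

gaze_stat <- function(name, statistic, df1 = NA_real_, df2 = NA_real_,
                      p_value = NA_real_, effect_size = NA_real_,
                      effect_type = NA_character_, ci_low = NA_real_,
                      ci_high = NA_real_, correction = "none",
                      estimate = NA_real_) {
  out <- tibble::tibble(name = name, statistic = statistic, df1 = df1,
                        df2 = df2, p_value = p_value, estimate = estimate,
                        effect_size = effect_size,
                        effect_type = effect_type, ci_low = ci_low,
                        ci_high = ci_high, correction = correction)
  class(out) <- c("gaze_stat", class(out))
  out
}

#' @export
print.gaze_stat <- function(x, ...) {
  cat("<gaze_stat>\n")
  NextMethod()
}

# Normalized orthogonal contrast rows (k-1 x k) via QR of centred helmert.
ortho_contrasts <- function(k) {
  h <- stats::contr.helmert(k)
  q <- qr.Q(qr(h))
  t(q)
}

# Greenhouse-Geisser epsilon for one within effect: Y is the subject x cell
# matrix, C the orthonormal contrast rows spanning the effect.
gg_epsilon <- function(Y, C) {
  S <- stats::cov(Y %*% t(C))
  d <- nrow(S)
  if (d < 2) return(1)
  sum(diag(S))^2 / (d * sum(S^2))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate repeated-measures ANOVA for one or two
#' within-subject factors on a complete balanced long table. For every
#' effect the sphericity correction factor (epsilon) is estimated from the
#' covariance of the orthonormalised effect contrasts and applied to the
#' degrees of freedom; both generalized eta-squared (subject variance and
#' all error strata in the denominator) and partial eta-squared are
#' reported.
#'
#' @param data Long tibble.
#' @param subject,value Column names (strings) of the subject id and the
#'   dependent variable.
#' @param within Character vector of one or two within-factor column names.
#' @return A `gaze_stat` tibble with one row per effect; `df1`/`df2` are
#'   the Greenhouse-Geisser-corrected degrees of freedom and `epsilon` is
#'   attached as a column.
#' @examples
#' d <- tidyr::expand_grid(s = factor(1:6), roi = c("a", "b", "c"))
#' d$y <- stats::rnorm(nrow(d))
#' rm_anova(d, subject = "s", value = "y", within = "roi")
#' @export
rm_anova <- function(data, subject, value, within) {
  stopifnot(length(within) %in% 1:2)
  f <- lapply(within, function(w) factor(data[[w]]))
  s <- factor(data[[subject]])
  y <- data[[value]]
  if (anyNA(y)) stop("missing values in the response", call. = FALSE)
  cell <- interaction(rev(f), drop = FALSE)
  tab <- table(s, cell)
  if (any(tab != 1)) {
    stop("design must be complete and balanced with one observation per ",
         "subject and cell", call. = FALSE)
  }
  n <- nlevels(s)
  ks <- vapply(f, nlevels, 1L)
  ncell <- prod(ks)

  # Subject x cell matrix, cells ordered with the first factor slowest.
  Y <- matrix(0, n, ncell)
  cell_index <- if (length(f) == 1) as.integer(f[[1]])
                else (as.integer(f[[1]]) - 1) * ks[2] + as.integer(f[[2]])
  Y[cbind(as.integer(s), cell_index)] <- y

  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  ss_subject <- ncell * sum((subj_means - grand)^2)

  effects <- if (length(f) == 1) list(within[1]) else
    list(within[1], within[2], within)

  mean_vec <- function(k) matrix(1 / sqrt(k), 1, k)
  # Sums of squares at or below this are floating-point residue of an
  # exactly-null effect, not evidence.
  tiny <- 1e-12 * max(sum((Y - grand)^2), 1)
  ss_err_all <- 0
  details <- list()
  for (eff in effects) {
    Cs <- lapply(seq_along(f), function(j) {
      if (within[j] %in% eff) ortho_contrasts(ks[j]) else mean_vec(ks[j])
    })
    C <- Reduce(kronecker, Cs)
    scores <- Y %*% t(C)
    df1 <- nrow(C)
    ss_eff <- n * sum(colMeans(scores)^2)
    ss_err <- sum(sweep(scores, 2, colMeans(scores))^2)
    df2 <- df1 * (n - 1)
    eps <- if (ss_eff + ss_err <= tiny) 1 else gg_epsilon(Y, C)
    details[[paste(eff, collapse = ":")]] <-
      list(ss_eff = ss_eff, ss_err = ss_err, df1 = df1, df2 = df2, eps = eps)
    ss_err_all <- ss_err_all + ss_err
  }
  denom_g <- ss_subject + ss_err_all

  rows <- lapply(names(details), function(nm) {
    d <- details[[nm]]
    msf <- d$ss_eff / d$df1
    mse <- d$ss_err / d$df2
    F <- if (d$ss_err <= tiny) {
      if (d$ss_eff <= tiny) 0 else Inf
    } else msf / mse
    p <- if (is.infinite(F)) 0
         else stats::pf(F, d$eps * d$df1, d$eps * d$df2, lower.tail = FALSE)
    out <- gaze_stat(
      name = nm, statistic = F, df1 = d$eps * d$df1, df2 = d$eps * d$df2,
      p_value = p,
      effect_size = d$ss_eff / (d$ss_eff + denom_g),
      effect_type = "ges",
      correction = if (d$eps < 1) "greenhouse_geisser" else "none")
    out$pes <- d$ss_eff / (d$ss_eff + d$ss_err)
    out$epsilon <- d$eps
    out
  })
  dplyr::bind_rows(rows)
}

#' Paired (or one-sample) t test with Cohen's d
#'
#' @param x,y Numeric vectors of equal length; with `y = NULL` a one-sample
#'   test of `x` against `mu`.
#' @param mu Null value of the mean (difference).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param k_bonferroni Size of the comparison family; the p value is
#'   multiplied by it (capped at 1).
#' @return A one-row `gaze_stat`; `effect_size` is Cohen's d of the
#'   differences (`NA` with a zero-variance flag in `correction` when the
#'   differences are constant).
#' @export
paired_tests <- function(x, y = NULL, mu = 0,
                         alternative = c("two.sided", "greater", "less"),
                         k_bonferroni = 1) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  if (length(d) < 2) stop("need at least two pairs", call. = FALSE)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == mu) {
      # x == y (+ mu): no effect, no evidence.
      return(gaze_stat("paired_t", statistic = 0, df1 = length(d) - 1,
                       p_value = 1, estimate = mean(d), effect_size = 0,
                       effect_type = "cohens_d"))
    }
    return(gaze_stat("paired_t", statistic = NA_real_, df1 = length(d) - 1,
                     estimate = mean(d) - mu,
                     effect_type = "cohens_d",
                     correction = "degenerate_zero_variance"))
  }
  ht <- stats::t.test(d, mu = mu, alternative = alternative)
  gaze_stat("paired_t", statistic = unname(ht$statistic),
            df1 = unname(ht$parameter),
            p_value = min(1, k_bonferroni * ht$p.value),
            estimate = mean(d),
            effect_size = (mean(d) - mu) / sd_d, effect_type = "cohens_d",
            ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
            correction = if (k_bonferroni > 1)
              paste0("bonferroni_", k_bonferroni) else "none")
}

#' Wilcoxon signed-rank test with effect size r
#'
#' One-sample (against `mu`) or paired signed-rank test. Zero differences
#' are dropped; the exact null distribution is used for n <= 25 without
#' ties among the absolute differences, otherwise the normal approximation
#' with continuity correction. The effect size is Wilcoxon's
#' `r = |z| / sqrt(n)` from the (continuity-corrected) normal
#' approximation.
#'
#' @param x Numeric vector.
#' @param y Optional paired vector.
#' @param mu Null location.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param k_bonferroni Comparison-family size for Bonferroni correction.
#' @return A one-row `gaze_stat` with the V statistic.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 k_bonferroni = 1) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x - mu else x - y - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(gaze_stat("wilcoxon_v", NA_real_, effect_type = "wilcoxon_r",
                     correction = "degenerate_all_zero"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))

  m <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  if (ties) {
    tie_tab <- table(abs(d))
    sigma2 <- sigma2 - sum(tie_tab^3 - tie_tab) / 48
  }
  cc <- 0.5
  z <- switch(alternative,
    two.sided = (V - m - sign(V - m) * cc) / sqrt(sigma2),
    greater = (V - m - cc) / sqrt(sigma2),
    less = (V - m + cc) / sqrt(sigma2))
  if (alternative == "two.sided" && V == m) z <- 0

  if (n <= 25 && !ties) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::psignrank(V, n),
                                 stats::psignrank(V - 1, n,
                                                  lower.tail = FALSE))),
      greater = stats::psignrank(V - 1, n, lower.tail = FALSE),
      less = stats::psignrank(V, n))
    exact <- TRUE
  } else {
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    p <- min(1, p)
    exact <- FALSE
  }
  gaze_stat("wilcoxon_v", statistic = V,
            p_value = min(1, k_bonferroni * p),
            estimate = stats::median(d) + mu,
            effect_size = abs(z) / sqrt(n), effect_type = "wilcoxon_r",
            correction = paste0(if (exact) "exact" else "normal_approx",
                                if (k_bonferroni > 1)
                                  paste0(",bonferroni_", k_bonferroni)
                                else ""))
}

# Per-cluster category proportions from a long table of cluster ids and
# category labels.
cluster_proportions <- function(cluster, category, levels) {
  tab <- table(cluster, factor(category, levels = levels))
  sizes <- rowSums(tab)
  keep <- sizes > 0
  if (any(!keep)) warning("dropping clusters with zero observations")
  list(p = sweep(tab[keep, , drop = FALSE], 1, sizes[keep], "/"),
       sizes = sizes[keep])
}

#' Cluster-robust chi-square goodness-of-fit test
#'
#' Tests whether category proportions, estimated as the unweighted mean of
#' per-cluster (per-participant) proportions, match null proportions
#' `pi0`. The statistic is a Wald-type quadratic form in the first k-1
#' category proportions using the empirical between-cluster covariance of
#' the cluster proportions; with M clusters it is referred to its
#' Hotelling T-squared null distribution (an F distribution after
#' rescaling), which keeps the test calibrated at moderate cluster counts.
#' Cramer's V is computed from the statistic with the total observation
#' count N (trials, not clusters): `V = sqrt(chisq / (N * (k - 1)))`.
#'
#' @param cluster Cluster (participant) identifier per observation.
#' @param category Category label per observation.
#' @param pi0 Named or ordered null proportions (must sum to 1).
#' @param levels Category levels; defaults to the names of `pi0` or the
#'   sorted unique categories.
#' @return A one-row `gaze_stat` with Cramer's V as effect size.
#' @export
clustered_gof <- function(cluster, category, pi0, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (!is.null(names(pi0))) names(pi0) else sort(unique(category))
  }
  stopifnot(length(pi0) == length(levels))
  if (abs(sum(pi0) - 1) > 1e-8) stop("pi0 must sum to 1", call. = FALSE)
  cp <- cluster_proportions(cluster, category, levels)
  M <- nrow(cp$p)
  if (M < 2) stop("need at least two clusters", call. = FALSE)
  k <- length(levels)
  D <- sweep(cp$p[, -k, drop = FALSE], 2, pi0[-k])
  dbar <- colMeans(D)
  N <- sum(cp$sizes)
  if (max(abs(D)) < 1e-12) {
    # Every cluster sits exactly on the null proportions.
    return(gaze_stat("clustered_gof_chisq", statistic = 0, df1 = k - 1,
                     df2 = M - (k - 1), p_value = 1, effect_size = 0,
                     effect_type = "cramers_v"))
  }
  S <- stats::cov(D)
  qf <- tryCatch(M * drop(t(dbar) %*% solve(S, dbar)),
                 error = function(e) stop("singular between-cluster ",
                                          "covariance", call. = FALSE))
  df1 <- k - 1
  # Hotelling rescaling: (M - p) / (p (M - 1)) T^2 ~ F(p, M - p).
  Fstat <- (M - df1) / (df1 * (M - 1)) * qf
  p <- stats::pf(Fstat, df1, M - df1, lower.tail = FALSE)
  gaze_stat("clustered_gof_chisq", statistic = qf, df1 = df1, df2 = M - df1,
            p_value = p,
            effect_size = sqrt(qf / (N * (k - 1))),
            effect_type = "cramers_v")
}

#' Cluster-robust one-sample proportion test
#'
#' Tests the mean of per-cluster success proportions against `pi0`. The
#' estimate is the unweighted mean of cluster proportions; its standard
#' error is the between-cluster standard deviation over sqrt(M). The
#' statistic is the resulting z ratio, referred to a t distribution with
#' M - 1 degrees of freedom (exact if cluster proportions were normal),
#' with the matching confidence interval. The effect size is the average
#' of the per-cluster Cohen's h against `pi0`.
#'
#' @param successes,totals Integer vectors per cluster.
#' @param pi0 Null proportion.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param k_bonferroni Comparison-family size.
#' @param conf_level Confidence level of the interval on the mean cluster
#'   proportion.
#' @return A one-row `gaze_stat`.
#' @export
clustered_prop_test <- function(successes, totals, pi0 = 0.5,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                k_bonferroni = 1, conf_level = 0.95) {
  alternative <- match.arg(alternative)
  stopifnot(length(successes) == length(totals))
  keep <- totals > 0
  if (any(!keep)) warning("dropping clusters with zero observations")
  successes <- successes[keep]
  totals <- totals[keep]
  M <- length(totals)
  if (M < 2) {
    stop("need at least two clusters for a variance estimate", call. = FALSE)
  }
  p_i <- successes / totals
  est <- mean(p_i)
  se <- stats::sd(p_i) / sqrt(M)
  if (se == 0 && est == pi0) {
    h_i <- 2 * asin(sqrt(p_i)) - 2 * asin(sqrt(pi0))
    return(gaze_stat("clustered_prop_z", statistic = 0, df1 = M - 1,
                     p_value = 1, estimate = est, effect_size = mean(h_i),
                     effect_type = "cohens_h", ci_low = est, ci_high = est))
  }
  z <- (est - pi0) / se
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(z), M - 1),
    greater = stats::pt(z, M - 1, lower.tail = FALSE),
    less = stats::pt(z, M - 1))
  tq <- stats::qt(1 - (1 - conf_level) / 2, M - 1)
  h_i <- 2 * asin(sqrt(p_i)) - 2 * asin(sqrt(pi0))
  gaze_stat("clustered_prop_z", statistic = z, df1 = M - 1,
            p_value = min(1, k_bonferroni * p),
            estimate = est,
            effect_size = mean(h_i), effect_type = "cohens_h",
            ci_low = est - tq * se, ci_high = est + tq * se,
            correction = if (k_bonferroni > 1)
              paste0("bonferroni_", k_bonferroni) else "none")
}
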