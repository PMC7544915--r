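#' Library normalization factors
#'
#' Two interchangeable normalizations behind one contract:
#' * `TMM` — trimmed mean of M-values against a reference sample (the sample
#'   whose upper-quartile CPM is closest to the mean). Log-ratios are trimmed
#'   30% on M and 5% on A, remaining M-values averaged with inverse
#'   asymptotic-variance (library-size) weights; factors are centered to
#'   geometric mean 1.
#' * `median_of_ratios` — per-sample median of per-gene ratios to the
#'   geometric-mean pseudo-reference, over genes with no zero count, centered
#'   to geometric mean 1.
#'
#' @param counts count matrix.
#' @param method `"TMM"` or `"median_of_ratios"`.
#' @param logratio_trim,abs_expr_trim TMM trim fractions on M and A.
#' @return object of class `norm_factors`: `factors` (geometric mean 1),
#'   `lib_sizes`, `eff_lib` (effective library sizes used to normalize
#'   counts) and `method`.
#' @export
normalization_factors <- function(counts, method = c("TMM", "median_of_ratios"),
                                  logratio_trim = 0.30, abs_expr_trim = 0.05) {
  method <- match.arg(method)
  lib <- library_sizes(counts)
  if (method == "TMM") {
    p <- sweep(counts, 2, lib, "/")
    f75 <- apply(p, 2, quantile, probs = 0.75)
    ref <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
      if (j == ref) return(1)
      tmm_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                 logratio_trim, abs_expr_trim)
    }, numeric(1))
    f <- f / exp(mean(log(f)))
  } else {
    usable <- rowSums(counts == 0) == 0
    if (!any(usable)) stop("no genes without zeros; cannot compute median-of-ratios")
    lgeo <- rowMeans(log(counts[usable, , drop = FALSE]))
    f <- apply(counts[usable, , drop = FALSE], 2,
               function(x) median(exp(log(x) - lgeo)))
    f <- f / exp(mean(log(f)))
  }
  names(f) <- colnames(counts)
  eff <- if (method == "TMM") lib * f else f * exp(mean(log(lib)))
  structure(list(factors = f, lib_sizes = lib, eff_lib = eff, method = method),
            class = "norm_factors")
}

tmm_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_expr_trim) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_expr_trim) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep) || sum(w[keep]) == 0) return(1)
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

# Counts scaled to a common (geometric-mean) effective library size.
normalized_counts <- function(counts, nf) {
  common <- exp(mean(log(nf$eff_lib)))
  sweep(counts, 2, nf$eff_lib / common, "/")
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion estimated on normalized counts from the moment
#' relation `var = mu + phi * mu^2`, pooled across groups (weights
#' `n_g - 1`), floored at zero, then shrunk toward a lowess mean-dispersion
#' trend with weight `shrink_weight`.
#'
#' @param counts count matrix.
#' @param groups factor/character of group membership per sample; groups with
#'   fewer than 2 samples are ignored in estimation.
#' @param nf `norm_factors` object (default TMM on `counts`).
#' @param shrink_weight weight of the trend in the shrunk estimate
#'   (default 0.5).
#' @return named numeric vector of dispersions (>= 0), one per gene.
#' @export
nb_dispersion <- function(counts, groups, nf = NULL, shrink_weight = 0.5) {
  if (is.null(nf)) nf <- normalization_factors(counts)
  z <- normalized_counts(counts, nf)
  groups <- as.factor(as.character(groups))
  num <- rep(0, nrow(z)); den <- rep(0, nrow(z))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    mu <- rowMeans(z[, idx, drop = FALSE])
    v <- apply(z[, idx, drop = FALSE], 1, var)
    ok <- mu > 0
    phi_g <- rep(0, nrow(z))
    phi_g[ok] <- (v[ok] - mu[ok]) / mu[ok]^2
    num <- num + phi_g * (length(idx) - 1)
    den <- den + (length(idx) - 1)
  }
  if (all(den == 0)) stop("no group with >= 2 samples")
  phi <- pmax(0, num / den)
  mu_all <- rowMeans(z)
  ok <- mu_all > 0
  trend <- rep(0, length(phi))
  if (sum(ok) >= 10) {
    fit <- lowess(log(mu_all[ok]), phi[ok], f = 0.5)
    trend[ok] <- pmax(0, approx(fit$x, fit$y, xout = log(mu_all[ok]), rule = 2)$y)
  }
  out <- (1 - shrink_weight) * phi + shrink_weight * trend
  names(out) <- rownames(counts)
  out
}

# Conditional two-sided NB exact p-value for one gene.
# ya, yb: equalized group pseudo-sums; na, nb: group sizes; phi: dispersion.
# Conditional on the total t, the split is beta-binomial BB(t, na/phi,
# nb/phi). Up to `exact_cap` the pmf is enumerated exactly (log-pmf built by
# the cheap increment recursion); above it the test uses the distribution's
# limits: binomial when the shape total dominates t (tiny dispersion), else
# the Beta(na/phi, nb/phi) continuous limit of the split proportion.
nb_exact_pvalue <- function(ya, yb, na, nb, phi, exact_cap = 20000) {
  if (phi < 0) stop("dispersion must be >= 0")
  t <- ya + yb
  if (t == 0) return(1)
  if (phi < 1e-8) return(binom_twosided(ya, t, na / (na + nb)))
  a <- na / phi; b <- nb / phi
  if (t <= exact_cap) {
    k <- seq_len(t)
    d <- log((k + a - 1) / k) + log((t - k + 1) / (t - k + b))
    lp <- c(0, cumsum(d))
    lp <- lp - max(lp)
    pr <- exp(lp)
    return(min(1, sum(pr[lp <= lp[ya + 1] + 1e-10]) / sum(pr)))
  }
  if (a + b > 3 * t) return(binom_twosided(ya, t, na / (na + nb)))
  beta_twosided(ya / t, a, b)
}

# Two-sided binomial "probability as small or smaller" p-value.
binom_twosided <- function(x, n, p) {
  lp <- dbinom(0:n, n, p, log = TRUE)
  min(1, sum(exp(lp[lp <= lp[x + 1] + 1e-10])))
}

# Two-sided density-based tail of Beta(a, b) at proportion x.
beta_twosided <- function(x, a, b) {
  if (a <= 1 || b <= 1) {
    # monotone density: single tail on the increasing/decreasing side
    p <- if (a <= 1) pbeta(x, a, b) else 1 - pbeta(x, a, b)
    return(min(1, p + (1 - p) * 0))
  }
  mode <- (a - 1) / (a + b - 2)
  ld <- function(z) dbeta(z, a, b, log = TRUE)
  if (abs(x - mode) < 1e-12) return(1)
  if (x < mode) {
    p1 <- pbeta(x, a, b)
    # mirror point on the right of the mode with equal log-density
    lo <- mode; hi <- 1
    if (ld(1 - 1e-12) >= ld(x)) return(min(1, p1 + 1 - pbeta(mode, a, b)))
    x2 <- uniroot(function(z) ld(z) - ld(x), c(lo, hi - 1e-12),
                  tol = 1e-12)$root
    min(1, p1 + 1 - pbeta(x2, a, b))
  } else {
    p1 <- 1 - pbeta(x, a, b)
    lo <- 0; hi <- mode
    if (ld(1e-12) >= ld(x)) return(min(1, p1 + pbeta(mode, a, b)))
    x2 <- uniroot(function(z) ld(z) - ld(x), c(lo + 1e-12, hi),
                  tol = 1e-12)$root
    min(1, p1 + pbeta(x2, a, b))
  }
}

#' Conditional negative-binomial exact test
#'
#' Two-sided exact test of equal means between two groups for each gene.
#' Counts are first equalized to a common library (the geometric mean of the
#' effective library sizes) by per-sample scaling; group pseudo-sums are
#' rounded to integers. Conditional on the total, the p-value is the summed
#' probability of all splits as likely or less likely than the observed one
#' under NB group sums with the supplied dispersion; with dispersion 0 this
#' reduces to the conditional binomial (Poisson) exact test.
#'
#' @param counts count matrix (genes x samples), two-group samples only.
#' @param groups two-level factor of group membership.
#' @param dispersion per-gene dispersion (scalar recycled).
#' @param nf `norm_factors`; default TMM.
#' @return named vector of p-values in `(0, 1]`.
#' @export
nb_exact_test <- function(counts, groups, dispersion, nf = NULL) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("nb_exact_test needs exactly two groups")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (is.null(nf)) nf <- normalization_factors(counts)
  z <- normalized_counts(counts, nf)
  dispersion <- rep_len(dispersion, nrow(counts))
  a <- groups == levels(groups)[1]
  ya <- round(rowSums(z[, a, drop = FALSE]))
  yb <- round(rowSums(z[, !a, drop = FALSE]))
  na <- sum(a); nb <- sum(!a)
  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_pvalue(ya[i], yb[i], na, nb, dispersion[i]), numeric(1))
  names(p) <- rownames(counts)
  pmin(p, 1)
}

#' Negative-binomial Wald test
#'
#' Fits a log-linear NB model with fixed per-gene dispersion and tests the
#' group coefficient by a Wald z statistic. Without a covariate the fit is a
#' fast per-group Newton solve with log effective-library offsets; with a
#' `year` covariate each gene is fitted by [stats::glm()] with the
#' [MASS::negative.binomial()] family (Poisson when dispersion is 0), and the
#' year enters as a fixed effect. Non-converged fits are flagged and given
#' p = 1.
#'
#' @param counts count matrix (genes x samples).
#' @param groups two-level factor; the *second* level is the focal group
#'   whose coefficient is tested (focal vs reference).
#' @param dispersion per-gene dispersion (recycled).
#' @param nf `norm_factors`; default TMM.
#' @param year optional cohort covariate (factor/integer per sample).
#' @return data.frame with `log2_fold_change` (focal vs reference), `p`,
#'   and `converged`.
#' @export
nb_wald_test <- function(counts, groups, dispersion, nf = NULL, year = NULL) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("nb_wald_test needs exactly two groups")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (is.null(nf)) nf <- normalization_factors(counts)
  dispersion <- rep_len(dispersion, nrow(counts))
  offs <- log(nf$eff_lib)
  ref <- groups == levels(groups)[1]
  if (is.null(year)) {
    # genes share sample structure; solve per dispersion-specific group fit
    fit_grp <- function(cols) {
      # phi varies per gene: exploit that the Newton update is elementwise
      y <- counts[, cols, drop = FALSE]
      o <- offs[cols]
      beta <- log((rowSums(y) + 0.5) / sum(exp(o)))
      for (it in 1:30) {
        mu <- exp(outer(beta, o, "+"))
        denom <- 1 + dispersion * mu
        score <- rowSums((y - mu) / denom)
        info <- rowSums(mu * (1 + dispersion * y) / denom^2)
        step <- pmax(pmin(score / pmax(info, 1e-10), 3), -3)
        beta <- beta + step
        if (max(abs(step)) < 1e-10) break
      }
      mu <- exp(outer(beta, o, "+"))
      list(beta = beta, info = rowSums(mu / (1 + dispersion * mu)))
    }
    f_ref <- fit_grp(which(ref))
    f_foc <- fit_grp(which(!ref))
    b <- f_foc$beta - f_ref$beta
    se <- sqrt(1 / pmax(f_foc$info, 1e-10) + 1 / pmax(f_ref$info, 1e-10))
    z <- b / se
    out <- data.frame(log2_fold_change = b / log(2), p = 2 * pnorm(-abs(z)),
                      converged = TRUE, row.names = rownames(counts))
    return(out)
  }
  year <- as.factor(as.character(year))
  gfac <- factor(groups, levels = levels(groups))
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    phi <- dispersion[i]
    fam <- if (phi < 1e-8) poisson() else MASS::negative.binomial(theta = 1 / phi)
    fit <- tryCatch(
      suppressWarnings(glm(counts[i, ] ~ gfac + year, family = fam,
                           offset = offs, control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, 1, 0))
    # dispersion is fixed by the family, so the Wald statistic is a z
    sm <- summary(fit, dispersion = 1)$coefficients
    row <- grep("^gfac", rownames(sm))
    if (length(row) != 1) return(c(NA_real_, 1, 0))
    c(sm[row, "Estimate"] / log(2), sm[row, "Pr(>|z|)"], 1)
  }, numeric(3)))
  data.frame(log2_fold_change = res[, 1], p = pmin(pmax(res[, 2], 0), 1),
             converged = res[, 3] == 1, row.names = rownames(counts))
}
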