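# From-scratch maximum-likelihood estimation for the linear mixed models used
# throughout the pipeline:
#
#   y_i = X_i beta + Z_i u_i + eps_i,   u_i ~ N(0, G),   eps_i ~ N(0, s2 R_i)
#
# with four random structures: RI (random intercept, R = I), RI_AR1 (random
# intercept with AR(1) residual correlation R[j,k] = rho^|j-k| indexed by
# within-patient visit order), RI_RS (random intercept + random slope with
# unstructured 2x2 G), and RI_RS_AR1 (both).
#
# Estimation profiles beta (generalized least squares) and the residual
# variance s2 out of the likelihood and optimizes the remaining variance
# parameters on unconstrained scales (log for variance ratios, Fisher-z for
# correlations) by L-BFGS-B from several dispersed starts. ML (never REML) is
# used so -2LL differences are valid for both fixed- and random-part
# comparisons. Per-group factorizations only; no dense all-observations
# covariance is ever formed.

.STRUCTS <- c("RI", "RI_AR1", "RI_RS", "RI_RS_AR1")

#' Specify a linear mixed model
#'
#' @param outcome Name of the outcome column.
#' @param fixed Character vector of fixed-effect terms (model-formula
#'   language, e.g. `c("phen", "cov", "phen:cov")`); an intercept is always
#'   included.
#' @param random Random structure, one of `"RI"`, `"RI_AR1"`, `"RI_RS"`,
#'   `"RI_RS_AR1"`.
#' @param slope Variable carrying the random slope (required for the `_RS`
#'   structures; defaults to the first fixed term).
#' @param group Grouping (patient) column.
#' @param time Column giving within-group ordering for the AR(1) index.
#' @return An `lmm_spec` list.
#' @export
lmm_spec <- function(outcome, fixed, random = "RI", slope = NULL,
                     group = "patient_id", time = "month_index") {
  random <- match.arg(random, .STRUCTS)
  if (random %in% c("RI_RS", "RI_RS_AR1")) {
    if (is.null(slope) && length(fixed)) slope <- fixed[[1L]]
    if (is.null(slope) || !nzchar(slope)) {
      .stopf("random structure %s needs a slope predictor", random)
    }
  }
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 slope = slope, group = group, time = time,
                 estimation = "ML"),
            class = "lmm_spec")
}

#' Optimizer settings for [fit_lmm()]
#'
#' @param n_starts Number of dispersed starting points (at least 3).
#' @param maxit Max L-BFGS-B iterations per start.
#' @param factr,pgtol L-BFGS-B convergence controls.
#' @return List of control settings.
#' @export
lmm_control <- function(n_starts = 3L, maxit = 200L, factr = 1e5,
                        pgtol = 1e-8) {
  list(n_starts = max(3L, as.integer(n_starts)), maxit = maxit,
       factr = factr, pgtol = pgtol)
}

# ---- data preparation -------------------------------------------------------

.prep_parts <- function(spec, data, for_fit = TRUE) {
  need <- unique(c(spec$outcome, all.vars(stats::reformulate(
    if (length(spec$fixed)) spec$fixed else "1")), spec$group, spec$time,
    spec$slope))
  need <- intersect(need, names(data))
  miss <- setdiff(c(spec$outcome, spec$group, spec$time), names(data))
  if (length(miss)) .stopf("data lacks columns: %s", paste(miss, collapse = ", "))
  d <- data[, need, drop = FALSE]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  ord <- order(d[[spec$group]], d[[spec$time]])
  d <- d[ord, , drop = FALSE]
  fml <- if (length(spec$fixed)) stats::reformulate(spec$fixed) else ~1
  X <- stats::model.matrix(fml, d)
  y <- as.numeric(d[[spec$outcome]])
  n <- length(y)
  p <- ncol(X)
  if (for_fit && n <= p) {
    .stopf("fewer observations (%d) than fixed effects (%d)", n, p)
  }
  g <- factor(d[[spec$group]])
  if (for_fit && nlevels(g) < 2L) .stopf("need at least 2 groups")
  idx <- split(seq_len(n), g)
  xs <- if (!is.null(spec$slope)) as.numeric(d[[spec$slope]]) else NULL
  sx <- t(vapply(idx, function(ii) colSums(X[ii, , drop = FALSE]), numeric(p)))
  if (p == 1L) sx <- matrix(sx, ncol = 1L)
  # per-group blocks cached once so each likelihood evaluation avoids
  # re-indexing; lag matrices feed the AR(1) correlation
  pre <- lapply(idx, function(ii) {
    mi <- length(ii)
    xi <- if (!is.null(xs)) xs[ii] else NULL
    list(Xy = cbind(X[ii, , drop = FALSE], y[ii]),
         xs = xi,
         xx = if (!is.null(xi)) tcrossprod(xi) else NULL,
         xp = if (!is.null(xi)) outer(xi, xi, "+") else NULL,
         lag = abs(outer(seq_len(mi), seq_len(mi), "-")),
         eye = diag(mi),
         m = mi)
  })
  list(X = X, y = y, idx = idx, xs = xs, n = n, p = p,
       m = lengths(idx), XtX = crossprod(X), Xty = crossprod(X, y),
       yty = sum(y^2), sx = sx, sy = vapply(idx, function(ii) sum(y[ii]),
                                            numeric(1)),
       pre = pre, struct = spec$random, data = d)
}

.theta_dim <- function(struct) {
  switch(struct, RI = 1L, RI_AR1 = 2L, RI_RS = 3L, RI_RS_AR1 = 4L)
}

.theta_unpack <- function(theta, struct) {
  g0 <- exp(theta[[1L]])
  out <- list(g0 = g0, g1 = NULL, corr = NULL, rho = 0)
  if (struct %in% c("RI_RS", "RI_RS_AR1")) {
    out$g1 <- exp(theta[[2L]])
    out$corr <- tanh(theta[[3L]])
  }
  if (struct %in% c("RI_AR1", "RI_RS_AR1")) {
    out$rho <- tanh(theta[[length(theta)]])
  }
  out
}

# profile evaluation: beta by GLS, s2 = q/n, all in residual-variance units
.profile_eval <- function(theta, parts) {
  pp <- .theta_unpack(theta, parts$struct)
  p <- parts$p
  if (parts$struct == "RI") {
    k <- pp$g0 / (1 + pp$g0 * parts$m)
    A <- parts$XtX - crossprod(parts$sx, parts$sx * k)
    b <- parts$Xty - colSums(parts$sx * (k * parts$sy))
    yy <- parts$yty - sum(k * parts$sy^2)
    ldet <- sum(log1p(pp$g0 * parts$m))
  } else {
    A <- matrix(0, p, p); b <- numeric(p); yy <- 0; ldet <- 0
    rs <- !is.null(pp$g1)
    cv <- if (rs) pp$corr * sqrt(pp$g0 * pp$g1) else 0
    ok <- tryCatch({
      for (gb in parts$pre) {
        # W = Z G Z' + R assembled from cached theta-independent blocks
        W <- if (pp$rho != 0) pp$rho^gb$lag else gb$eye
        W <- if (rs) W + pp$g0 + cv * gb$xp + pp$g1 * gb$xx else W + pp$g0
        U <- chol(W)
        tXy <- backsolve(U, gb$Xy, transpose = TRUE)
        cp <- crossprod(tXy)
        A <- A + cp[seq_len(p), seq_len(p), drop = FALSE]
        b <- b + cp[seq_len(p), p + 1L]
        yy <- yy + cp[p + 1L, p + 1L]
        ldet <- ldet + 2 * sum(log(diag(U)))
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) return(NULL)
  }
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  beta <- as.numeric(beta)
  q <- yy - sum(b * beta)
  if (!is.finite(q)) return(NULL)
  # exact interpolation (noise-free data) drives q to numerical zero; floor
  # it so the GLS beta is still returned instead of failing
  q <- max(q, parts$n * 1e-280)
  s2 <- q / parts$n
  nll <- 0.5 * (parts$n * log(2 * pi) + parts$n * log(s2) + ldet + parts$n)
  list(nll = nll, beta = beta, sigma2 = s2, A = A, ldet = ldet, q = q)
}

.nll_of <- function(theta, parts) {
  ev <- .profile_eval(theta, parts)
  if (is.null(ev) || !is.finite(ev$nll)) 1e10 else ev$nll
}

# negative loglik over phi = c(log s2, theta) with beta (only) profiled;
# used for the observed information behind Satterthwaite df
.nll_full <- function(phi, parts) {
  s2 <- exp(phi[[1L]])
  ev <- .profile_eval(phi[-1L], parts)
  if (is.null(ev)) return(1e10)
  0.5 * (parts$n * log(2 * pi) + parts$n * log(s2) + ev$ldet + ev$q / s2)
}

.starts_for <- function(parts, n_starts) {
  # variance decomposition of OLS residuals for a data-driven start
  beta0 <- tryCatch(solve(parts$XtX, parts$Xty), error = function(e) NULL)
  r <- if (is.null(beta0)) parts$y - mean(parts$y) else
    parts$y - parts$X %*% beta0
  gm <- vapply(parts$idx, function(ii) mean(r[ii]), numeric(1))
  vb <- max(stats::var(gm), 1e-4)
  vw <- max(mean(vapply(parts$idx, function(ii)
    sum((r[ii] - mean(r[ii]))^2), numeric(1))) / max(mean(parts$m) - 1, 1),
    1e-4)
  lg0 <- log(vb / vw)
  lg1 <- if (!is.null(parts$xs)) {
    log(max(vb / vw, 0.05) / (mean(parts$xs^2) + 1e-12))
  } else NA_real_
  base <- switch(parts$struct,
    RI = list(lg0),
    RI_AR1 = list(c(lg0, atanh(0.2))),
    RI_RS = list(c(lg0, lg1, 0)),
    RI_RS_AR1 = list(c(lg0, lg1, 0, atanh(0.2))))
  disp <- list(c(-1.6, 0, 0, 0), c(1.6, 0.8, 0, -0.35), c(0, -1.6, 0.5, 0.55),
               c(-0.8, 1.6, -0.5, 0.2))
  starts <- list(base[[1L]])
  for (k in seq_len(n_starts - 1L)) {
    s <- base[[1L]] + disp[[1L + (k - 1L) %% length(disp)]][seq_along(base[[1L]])]
    starts[[k + 1L]] <- s
  }
  starts
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Fixed effects are profiled out by generalized least squares; variance
#' parameters are optimized on unconstrained scales (log variances, Fisher-z
#' correlations) by L-BFGS-B from at least three dispersed starts. Failure to
#' converge (optimizer failure or non-positive-definite observed information)
#' is recorded in `converged`, not raised.
#'
#' @param spec An [lmm_spec()].
#' @param data Modelling table (one row per patient-month).
#' @param control An [lmm_control()].
#' @param start Optional warm-start vector for the variance parameters.
#' @return An `lmm_fit`: fixed-effect estimates with SEs, Satterthwaite df,
#'   two-tailed t-test p-values, variance parameters, `-2` log-likelihood,
#'   marginal pseudo-R2 and Cohen f2 (random-intercept fits only), and
#'   convergence status.
#' @export
fit_lmm <- function(spec, data, control = lmm_control(), start = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  parts <- .prep_parts(spec, data)
  dim_t <- .theta_dim(parts$struct)
  lower <- rep(-30, dim_t); upper <- rep(15, dim_t)
  zc <- switch(parts$struct, RI_RS = 3L, RI_RS_AR1 = c(3L, 4L), RI_AR1 = 2L,
               integer(0))
  lower[zc] <- -6; upper[zc] <- 6

  starts <- .starts_for(parts, control$n_starts)
  if (!is.null(start)) starts <- c(list(start), starts)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(stats::optim(s, .nll_of, parts = parts,
                                 method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(maxit = control$maxit,
                                                factr = control$factr,
                                                pgtol = control$pgtol)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
  }
  if (is.null(best)) .stopf("all optimizer starts failed")
  theta <- best$par
  ev <- .profile_eval(theta, parts)
  if (is.null(ev)) .stopf("optimum is numerically degenerate")

  s2 <- ev$sigma2
  pp <- .theta_unpack(theta, parts$struct)
  var_params <- list(sigma2_resid = s2, sigma2_intercept = pp$g0 * s2,
                     sigma2_slope = if (!is.null(pp$g1)) pp$g1 * s2 else NULL,
                     cov_intercept_slope = if (!is.null(pp$g1))
                       pp$corr * sqrt(pp$g0 * pp$g1) * s2 else NULL,
                     rho = if (parts$struct %in% c("RI_AR1", "RI_RS_AR1"))
                       pp$rho else NULL)

  cov_beta <- s2 * tryCatch(solve(ev$A), error = function(e)
    matrix(NA_real_, parts$p, parts$p))
  se <- sqrt(pmax(diag(cov_beta), 0))

  phi <- c(log(s2), theta)
  H <- tryCatch(pracma::hessian(.nll_full, phi, parts = parts),
                error = function(e) NULL)
  Acov <- NULL
  hess_pd <- FALSE
  if (!is.null(H) && all(is.finite(H))) {
    eh <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    if (all(is.finite(eh)) && all(eh > 0)) {
      Acov <- tryCatch(solve(H), error = function(e) NULL)
      hess_pd <- !is.null(Acov)
    }
  }
  converged <- (best$convergence == 0) && hess_pd

  fit <- structure(list(
    spec = spec, beta = stats::setNames(ev$beta, colnames(parts$X)),
    se = stats::setNames(se, colnames(parts$X)),
    var_params = var_params,
    minus2_loglik = 2 * ev$nll,
    converged = converged,
    n_obs = parts$n, n_groups = length(parts$idx),
    theta = theta, phi = phi
  ), class = "lmm_fit")
  attr(fit, "parts") <- parts
  attr(fit, "Acov") <- Acov
  attr(fit, "A") <- ev$A

  dfs <- vapply(seq_len(parts$p), function(j) {
    cvec <- numeric(parts$p); cvec[[j]] <- 1
    satterthwaite_df(fit, cvec, warn = FALSE)
  }, numeric(1))
  fit$satterthwaite_df <- stats::setNames(dfs, colnames(parts$X))
  fit$t_values <- fit$beta / fit$se
  fit$p_values <- 2 * stats::pt(abs(fit$t_values), dfs, lower.tail = FALSE)

  if (parts$struct == "RI") {
    r2 <- marginal_r2_f2(fit)
    fit$Rm <- r2$Rm
    fit$f2 <- r2$f2
  } else {
    fit$Rm <- NA_real_
    fit$f2 <- NA_real_
  }
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s on %s | n=%d, groups=%d, -2LL=%.3f%s\n",
              x$spec$random, x$spec$outcome, x$n_obs, x$n_groups,
              x$minus2_loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$beta, se = x$se, t = x$t_values,
                    df = x$satterthwaite_df, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Marginal Gaussian log-likelihood at explicit parameter values
#'
#' Evaluates the exact marginal log-likelihood sum over groups,
#' `sum_i log N(y_i; X_i beta, V_i)` with `V_i = Z_i G Z_i' + s2 R_i`, using
#' per-group Cholesky factorizations.
#'
#' @param spec An [lmm_spec()].
#' @param data Modelling table.
#' @param var_params List with `sigma2_resid`, `sigma2_intercept`, and (per
#'   structure) `sigma2_slope`, `cov_intercept_slope`, `rho`.
#' @param beta Fixed-effect vector in model-matrix order.
#' @return The log-likelihood (scalar).
#' @export
loglik_lmm <- function(spec, data, var_params, beta) {
  parts <- .prep_parts(spec, data, for_fit = FALSE)
  s2 <- var_params$sigma2_resid
  g0 <- var_params$sigma2_intercept
  rs <- parts$struct %in% c("RI_RS", "RI_RS_AR1")
  ar <- parts$struct %in% c("RI_AR1", "RI_RS_AR1")
  rho <- if (ar) var_params$rho else 0
  G <- if (rs) {
    cv <- var_params$cov_intercept_slope %||% 0
    matrix(c(g0, cv, cv, var_params$sigma2_slope), 2, 2)
  } else matrix(g0, 1, 1)
  if (length(beta) != parts$p) .stopf("beta has length %d, expected %d",
                                      length(beta), parts$p)
  ll <- 0
  for (ii in parts$idx) {
    mi <- length(ii)
    Zi <- if (rs) cbind(1, parts$xs[ii]) else matrix(1, mi, 1)
    R <- if (rho != 0) rho^abs(outer(seq_len(mi), seq_len(mi), "-"))
         else diag(mi)
    V <- Zi %*% G %*% t(Zi) + s2 * R
    U <- tryCatch(chol(V), error = function(e)
      .stopf("marginal covariance is not positive definite"))
    r <- parts$y[ii] - parts$X[ii, , drop = FALSE] %*% beta
    tr <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (mi * log(2 * pi) + 2 * sum(log(diag(U))) + sum(tr^2))
  }
  ll
}

#' Satterthwaite degrees of freedom for a fixed-effect contrast
#'
#' Moment-matching df `2 * Var(c'beta-hat)^2 / Var[Var-hat(c'beta-hat)]`,
#' the denominator obtained by the delta method over the variance parameters
#' using the observed information of the (beta-profiled) likelihood. Clamped
#' to `[1, n_obs - p]`; a singular information matrix falls back to
#' `n_obs - p` with a warning.
#'
#' @param fit An `lmm_fit`.
#' @param contrast Numeric contrast vector over the fixed effects.
#' @param warn Emit the fallback warning (default `TRUE`).
#' @return Positive real degrees of freedom.
#' @export
satterthwaite_df <- function(fit, contrast, warn = TRUE) {
  parts <- attr(fit, "parts")
  Acov <- attr(fit, "Acov")
  p <- parts$p
  cap <- max(parts$n - p, 1)
  fallback <- function(msg) {
    if (warn) warning(msg, call. = FALSE)
    cap
  }
  if (is.null(Acov)) return(fallback(
    "singular variance-parameter information; df set to n_obs - p"))
  varfun <- function(phi) {
    ev <- .profile_eval(phi[-1L], parts)
    if (is.null(ev)) return(NA_real_)
    Ainv_c <- tryCatch(solve(ev$A, contrast), error = function(e) NULL)
    if (is.null(Ainv_c)) return(NA_real_)
    exp(phi[[1L]]) * sum(contrast * Ainv_c)
  }
  V <- varfun(fit$phi)
  if (!is.finite(V) || V <= 0) return(fallback(
    "degenerate contrast variance; df set to n_obs - p"))
  g <- tryCatch(pracma::grad(varfun, fit$phi), error = function(e) NULL)
  if (is.null(g) || any(!is.finite(g))) return(fallback(
    "variance gradient failed; df set to n_obs - p"))
  denom <- as.numeric(t(g) %*% Acov %*% g)
  if (!is.finite(denom) || denom <= 0) return(fallback(
    "non-positive delta-method variance; df set to n_obs - p"))
  min(max(2 * V^2 / denom, 1), cap)
}

#' Two-tailed Wald t-test
#'
#' @param estimate,se Estimate and its standard error (`se > 0`).
#' @param df Degrees of freedom (> 0).
#' @return List with `t` and two-tailed `p`.
#' @export
#' @examples
#' wald_t_test(0.548, 0.172, 469.7)
wald_t_test <- function(estimate, se, df) {
  if (!is.finite(se) || se <= 0) .stopf("wald_t_test: se must be positive")
  if (!is.finite(df) || df <= 0) .stopf("wald_t_test: df must be positive")
  t <- estimate / se
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Marginal pseudo-R2 and Cohen f2 of a random-intercept fit
#'
#' `Rm = var(X beta-hat) / (var(X beta-hat) + s2_intercept + s2_resid)`
#' (Nakagawa-style marginal proportion) and `f2 = Rm / (1 - Rm)`. Defined for
#' the random-intercept structure only: with AR(1) or random-slope parts the
#' residual variance is no longer a scalar and the proportion is not
#' comparable.
#'
#' @param fit A converged random-intercept `lmm_fit`.
#' @return List with `Rm` and `f2`.
#' @export
marginal_r2_f2 <- function(fit) {
  if (fit$spec$random != "RI") {
    .stopf(paste("marginal pseudo-R2 is defined for random-intercept fits",
                 "only: with AR(1) or random-slope parts the residual",
                 "variance is a matrix, not a scalar"))
  }
  parts <- attr(fit, "parts")
  varf <- stats::var(as.numeric(parts$X %*% fit$beta))
  Rm <- varf / (varf + fit$var_params$sigma2_intercept +
                  fit$var_params$sigma2_resid)
  list(Rm = Rm, f2 = Rm / (1 - Rm))
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' `Lambda = max(0, (-2LL_small) - (-2LL_big))`. For the AR(1) parameter the
#' null is chi-square with 1 df; for adding a random slope (a variance on the
#' boundary plus a covariance) the null is the equal-weight mixture
#' `p = 0.5 P(chi2_1 > Lambda) + 0.5 P(chi2_2 > Lambda)`.
#'
#' @param fit_big,fit_small Nested fits on the same rows (small within big).
#' @param null_type `"chi2_1"` or `"mix_half_chi2_1_chi2_2"`.
#' @return An `lrt_result`: `statistic`, `null_type`, `p_value`.
#' @export
#' @examples
#' \dontrun{lrt(fit_ar1, fit_ri, "chi2_1")}
lrt <- function(fit_big, fit_small,
                null_type = c("chi2_1", "mix_half_chi2_1_chi2_2")) {
  null_type <- match.arg(null_type)
  if (fit_big$n_obs != fit_small$n_obs) {
    .stopf("lrt: fits use different numbers of rows (%d vs %d)",
           fit_big$n_obs, fit_small$n_obs)
  }
  lam <- fit_small$minus2_loglik - fit_big$minus2_loglik
  if (lam < -1e-6) {
    .stopf(paste("lrt: the larger model fits worse (Lambda = %.3g);",
                 "refit with more optimizer restarts"), lam)
  }
  lam <- max(lam, 0)
  p <- if (null_type == "chi2_1") {
    stats::pchisq(lam, 1, lower.tail = FALSE)
  } else {
    0.5 * stats::pchisq(lam, 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(lam, 2, lower.tail = FALSE)
  }
  structure(list(statistic = lam, null_type = null_type, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> Lambda = %.4g, null = %s, p = %s\n",
              x$statistic, x$null_type, format_p(x$p_value)))
  invisible(x)
}

# mixture p-value at a bare statistic (report/arithmetic layer)
.mixture_p <- function(lambda) {
  0.5 * stats::pchisq(lambda, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(lambda, 2, lower.tail = FALSE)
}

# Wald F-test for a set of coefficients (multi-level factors in screening);
# denominator df is the mean Satterthwaite df of the involved coefficients
.wald_F <- function(fit, coef_idx) {
  q <- length(coef_idx)
  parts <- attr(fit, "parts")
  covb <- fit$var_params$sigma2_resid *
    solve(attr(fit, "A"))[coef_idx, coef_idx, drop = FALSE]
  b <- fit$beta[coef_idx]
  Fstat <- as.numeric(t(b) %*% solve(covb, b)) / q
  df2 <- mean(fit$satterthwaite_df[coef_idx])
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Serialize a fitted model to a plain list
#'
#' All numeric `lmm_fit` fields in a JSON-ready form (used by the report
#' layer's audit log).
#'
#' @param fit An `lmm_fit`.
#' @return Nested list of plain vectors.
#' @export
fit_to_list <- function(fit) {
  list(spec = unclass(fit$spec),
       beta = as.list(fit$beta), se = as.list(fit$se),
       t_values = as.list(fit$t_values),
       satterthwaite_df = as.list(fit$satterthwaite_df),
       p_values = as.list(fit$p_values),
       var_params = fit$var_params[!vapply(fit$var_params, is.null,
                                           logical(1))],
       minus2_loglik = fit$minus2_loglik, Rm = fit$Rm, f2 = fit$f2,
       converged = fit$converged, n_obs = fit$n_obs,
       n_groups = fit$n_groups)
}
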