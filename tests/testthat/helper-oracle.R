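# Shared fixtures and independent oracles for the mixed-model machinery.

# Dense multivariate-normal log-likelihood oracle: builds the FULL
# block-diagonal marginal covariance over all observations explicitly and
# evaluates the Gaussian density with generic dense linear algebra — an
# independent path from the package's per-group profiled evaluation.
dense_mvn_loglik <- function(data, struct, beta, s2, g0, g1 = NULL,
                             cov01 = NULL, rho = 0, slope_col = "x") {
  d <- data[order(data$patient_id, data$month_index), ]
  n <- nrow(d)
  V <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (d$patient_id[[j]] != d$patient_id[[k]]) next
      v <- g0
      if (!is.null(g1)) {
        xj <- d[[slope_col]][[j]]; xk <- d[[slope_col]][[k]]
        v <- v + cov01 * (xj + xk) + g1 * xj * xk
      }
      lagjk <- abs(sum(d$patient_id[seq_len(j)] == d$patient_id[[j]]) -
                     sum(d$patient_id[seq_len(k)] == d$patient_id[[k]]))
      v <- v + s2 * rho^lagjk
      V[j, k] <- v
    }
  }
  X <- cbind(1, d[[slope_col]])
  r <- d$y - X %*% beta
  ld <- determinant(V, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(V, r)))
}

# small random longitudinal dataset for oracle checks
make_tiny_dataset <- function(seed, n_groups = NULL, n_per = NULL) {
  set.seed(seed)
  if (is.null(n_groups)) n_groups <- sample(2:5, 1)
  if (is.null(n_per)) n_per <- sample(2:6, 1)
  d <- expand.grid(month_index = seq_len(n_per),
                   patient_id = sprintf("g%d", seq_len(n_groups)))
  d$x <- rnorm(nrow(d))
  d$y <- 1 + 0.5 * d$x + rep(rnorm(n_groups), each = n_per) + rnorm(nrow(d))
  d[, c("patient_id", "month_index", "x", "y")]
}

# balanced one-way random-effects data with known ML closed forms
make_balanced_ri <- function(seed, k = 10, m = 5, mu = 2, sb = 1.5, se = 1) {
  set.seed(seed)
  d <- data.frame(patient_id = rep(sprintf("g%02d", seq_len(k)), each = m),
                  month_index = rep(seq_len(m), k))
  d$y <- mu + rep(rnorm(k, 0, sb), each = m) + rnorm(k * m, 0, se)
  d
}

# closed-form ML estimates for the balanced one-way random-intercept model
# (derived from the spectral decomposition of the balanced covariance)
balanced_ri_ml <- function(d) {
  k <- length(unique(d$patient_id))
  m <- nrow(d) / k
  gm <- tapply(d$y, d$patient_id, mean)
  ssw <- sum((d$y - gm[d$patient_id])^2)
  ssb <- m * sum((gm - mean(d$y))^2)
  s2e <- ssw / (nrow(d) - k)
  tau <- ssb / k                       # ML estimate of s2e + m*s2b
  list(mu = mean(d$y), s2e = s2e, s2b = max((tau - s2e) / m, 0))
}

# brute-force two-pass RMSSD for the property test
rmssd_bruteforce <- function(v) {
  if (length(v) < 2) return(NA_real_)
  acc <- 0
  for (i in 2:length(v)) acc <- acc + (v[[i]] - v[[i - 1]])^2
  sqrt(acc / (length(v) - 1))
}

# minimal stand-in carrying just the fields lrt() consumes
fake_fit <- function(m2ll, n = 100L) {
  structure(list(minus2_loglik = m2ll, n_obs = n), class = "lmm_fit")
}

# quick monthly-level cohort -> modelling table
monthly_table <- function(truth) {
  analysis_table_from_bundle(generate_cohort(truth, level = "monthly"))
}

no_missing <- list(window_drop_prob = 0, nonwear_day_prob = 0,
                   month_visit_miss_prob = 0)
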