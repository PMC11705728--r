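# Independent reference implementations used as oracles, deliberately
# written as plain brute-force code distinct from the package's paths.

# Direct log partial likelihood (Breslow ties; equals Efron when untied).
pl_loglik <- function(beta, time, event, X, strata = NULL) {
  X <- as.matrix(X)
  if (is.null(strata)) strata <- rep(1, length(time))
  eta <- drop(X %*% beta)
  ll <- 0
  for (s in unique(strata)) {
    idx <- which(strata == s)
    for (i in idx[event[idx] == 1]) {
      risk <- idx[time[idx] >= time[i]]
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# Nelder-Mead maximization of the direct partial likelihood.
pl_fit <- function(time, event, X, strata = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  opt <- stats::optim(rep(0, p),
                      function(b) -pl_loglik(b, time, event, X, strata),
                      method = if (p == 1) "Brent" else "Nelder-Mead",
                      lower = if (p == 1) -20 else -Inf,
                      upper = if (p == 1) 20 else Inf,
                      control = list(maxit = 5000, reltol = 1e-14))
  opt$par
}

# Brute-force Benjamini-Hochberg by the double-loop definition:
# q_(i) = min_{j >= i} p_(j) * m / j, ties share values, order restored.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force Harrell C: loop over all pairs; usable pairs are orderable
# under censoring (shorter time observed as an event, times untied);
# half-credit for score ties.
cindex_brute <- function(scores, time, event) {
  n <- length(time)
  num <- den <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      shorter <- if (time[i] < time[j]) i else j
      longer <- if (time[i] < time[j]) j else i
      if (event[shorter] != 1) next
      den <- den + 1
      if (scores[shorter] > scores[longer]) num <- num + 1
      else if (scores[shorter] == scores[longer]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Mann-Whitney AUC of scores against binary labels (half-credit ties).
auc_binary <- function(scores, labels) {
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  s <- 0
  for (x in xs) s <- s + sum((x > ys) + 0.5 * (x == ys))
  s / (length(xs) * length(ys))
}

# small random survival fixture for oracle comparisons
random_survival_fixture <- function(n, seed, p = 1, tie_free = TRUE) {
  set.seed(seed)
  X <- matrix(round(rnorm(n * p), 2), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  time <- if (tie_free) sample(seq_len(n)) + runif(n, 0, 0.4) else
    sample(1:4, n, TRUE)
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[1] <- 1
  list(time = time, event = event, X = X)
}

# minimal fitted-model stand-in for score/surface closed-form checks
mock_interaction_fit <- function(coefficients, design, spec,
                                 sample_id = NULL) {
  lp <- drop(design[, names(coefficients), drop = FALSE] %*% coefficients)
  structure(list(terms = names(coefficients), coefficients = coefficients,
                 se = coefficients * 0 + 1, design = design,
                 linear_predictor = lp, spec = spec,
                 highest_term = names(coefficients)[length(coefficients)],
                 sample_id = sample_id %||% seq_len(nrow(design))),
            class = c("cox_interaction", "cox_fit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
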