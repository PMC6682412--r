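# Independent oracles used to verify package computations, plus small
# fixture generators. Everything here is deliberately naive/brute-force
# and independent of the implementation paths it checks.

# Random but valid calibration set.
random_calibration <- function() {
  R_red <- runif(1, 0.2, 2)
  calibration_set(
    R_red = R_red,
    R_ox = R_red * runif(1, 2, 8),
    i488_red = runif(1, 0.5, 2),
    i488_ox = runif(1, 0.2, 2))
}

# Closed-form OLS through the normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- drop(X %*% beta)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Logistic-regression MLE by plain Newton-Raphson on the score equations.
logistic_mle_newton <- function(x, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, x); y <- as.numeric(y)
  b <- c(0, 0)
  for (i in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    g <- drop(t(X) %*% (y - p))
    H <- -crossprod(X, X * (p * (1 - p)))
    step <- solve(H, g)
    b <- b - step
    if (max(abs(step)) < tol) break
  }
  c(beta0 = unname(b[1]), beta1 = unname(b[2]))
}

# Exhaustive optimal partial matching: among all one-to-one matchings
# using pairs with distance <= max_dist, pick maximum cardinality, then
# minimum total distance. Feasible only for small instances.
brute_force_matching <- function(cells_a, cells_b, max_dist) {
  na <- nrow(cells_a); nb <- nrow(cells_b)
  d <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((cells_a$x[i] - cells_b$x[j])^2 + (cells_a$y[i] - cells_b$y[j])^2))
  best <- list(card = -1L, total = Inf)
  recurse <- function(i, used_b, card, total) {
    if (i > na) {
      if (card > best$card ||
          (card == best$card && total < best$total - 1e-12)) {
        best <<- list(card = card, total = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, card, total)  # leave cell i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= max_dist) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, card + 1L, total + d[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nb), 0L, 0)
  best
}

# Tiny event-table fixture with known gating outcome.
make_event_fixture <- function() {
  tibble::tibble(
    event_id = 1:10,
    sample_id = "s1", dose_uM = 80, time_min = 30, replicate = 1,
    i405 = c(200, 300, 150, 5, 2, 400, 250, 3, 500, 1),
    i488 = c(100, 200, 120, 4, 3, 300, 100, 2, 250, 2),
    chl = 800, sytox = 5)
}
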