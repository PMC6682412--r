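# Logistic cell-fate model: death probability as a function of early
# OxD, the derived decision threshold, and classification scoring.

#' Fit the logistic cell-fate model
#'
#' Maximum-likelihood logistic regression of terminal fate (died /
#' survived) on the decision-time OxD:
#' `logit P(death) = beta0 + beta1 * OxD`. The OxD at which the fitted
#' death probability crosses 0.5 is the decision threshold
#' `-beta0 / beta1`. Complete separation (all dead cells above all alive
#' cells) makes the MLE diverge; it is detected and the threshold is
#' then reported as the midpoint between the two class boundaries, with
#' `separation = TRUE`.
#'
#' @param oxd Decision-time OxD fractions.
#' @param died Logical: did the cell die.
#' @param ridge Optional ridge penalty (default 0, plain MLE).
#' @return A `fate_model` list: `beta0`, `beta1`, `threshold_oxd`,
#'   `converged`, `separation`, `n_cells`.
#' @export
fit_logistic <- function(oxd, died, ridge = 0) {
  stopifnot(length(oxd) == length(died))
  ok <- is.finite(oxd) & !is.na(died)
  oxd <- oxd[ok]; died <- as.logical(died[ok])
  n <- length(oxd)
  if (n < 20) stop("need at least 20 cells to fit the fate model")
  if (all(died) || !any(died))
    stop("both fates must be present to fit the fate model")
  separated <- max(oxd[!died]) < min(oxd[died])
  if (separated) {
    boundary <- (max(oxd[!died]) + min(oxd[died])) / 2
    # steep but finite surrogate slope through the midpoint, for
    # downstream probability evaluation
    slope <- 4 / max(min(oxd[died]) - max(oxd[!died]), 1e-6)
    model <- list(beta0 = -slope * boundary, beta1 = slope,
                  threshold_oxd = boundary, converged = TRUE,
                  separation = TRUE, n_cells = n)
    class(model) <- "fate_model"
    return(model)
  }
  if (ridge > 0) {
    # penalized Newton iterations (ridge on beta1 only)
    b <- c(0, 0)
    X <- cbind(1, oxd); y <- as.numeric(died)
    for (it in 1:100) {
      p <- 1 / (1 + exp(-drop(X %*% b)))
      W <- p * (1 - p)
      g <- drop(t(X) %*% (y - p)) - c(0, ridge * b[2])
      Hm <- -crossprod(X, X * W) - diag(c(0, ridge))
      step <- solve(Hm, g)
      b <- b - step
      if (max(abs(step)) < 1e-10) break
    }
    fit <- list(coefficients = b, converged = TRUE)
    co <- b
    conv <- TRUE
  } else {
    fit <- suppressWarnings(
      stats::glm(died ~ oxd, family = stats::binomial()))
    co <- unname(stats::coef(fit))
    conv <- fit$converged
  }
  model <- list(beta0 = co[1], beta1 = co[2],
                threshold_oxd = if (co[2] != 0) -co[1] / co[2] else NA_real_,
                converged = conv, separation = FALSE, n_cells = n)
  class(model) <- "fate_model"
  model
}

#' @export
print.fate_model <- function(x, ...) {
  cat("Logistic cell-fate model (n =", x$n_cells, "cells)\n")
  cat(sprintf("  logit P(death) = %.3f + %.3f * OxD\n", x$beta0, x$beta1))
  cat(sprintf("  decision threshold: %.1f%% OxD%s\n",
              100 * x$threshold_oxd,
              if (x$separation) "  [complete separation: class midpoint]"
              else ""))
  invisible(x)
}

#' OxD decision threshold of a fate model
#'
#' The OxD at which the fitted death probability is 0.5:
#' `-beta0 / beta1`.
#'
#' @param model A `fate_model` (or any list with `beta0`, `beta1`).
#' @return Threshold OxD fraction.
#' @export
decision_threshold <- function(model) {
  if (is.null(model$beta1) || !is.finite(model$beta1) || model$beta1 == 0)
    stop("undefined threshold: beta1 is zero or missing")
  -model$beta0 / model$beta1
}

#' Classify cells by the fitted threshold and score the model
#'
#' Predicts death for cells whose OxD exceeds the model threshold and
#' scores the prediction against the observed fates. False-positive
#' (alive predicted dead) and false-negative (dead predicted alive)
#' rates are reported as fractions of ALL cells, so that
#' `accuracy = 1 - fp_rate - fn_rate` exactly; per-class rates are also
#' returned.
#'
#' @param model A `fate_model`.
#' @param oxd Decision OxD fractions.
#' @param died Logical observed fates.
#' @return A list: `accuracy`, `fp_rate`, `fn_rate` (fractions of all
#'   cells), `fp_rate_class`, `fn_rate_class` (per-class), `confusion`
#'   (2x2 table), `n`.
#' @export
classify_and_score <- function(model, oxd, died) {
  stopifnot(length(oxd) == length(died))
  ok <- is.finite(oxd) & !is.na(died)
  oxd <- oxd[ok]; died <- as.logical(died[ok])
  n <- length(oxd)
  if (n == 0) stop("no cells to score")
  thr <- model$threshold_oxd
  pred <- oxd > thr
  tp <- sum(pred & died); tn <- sum(!pred & !died)
  fp <- sum(pred & !died); fn <- sum(!pred & died)
  fp_rate <- fp / n; fn_rate <- fn / n
  list(accuracy = 1 - fp_rate - fn_rate,
       fp_rate = fp_rate, fn_rate = fn_rate,
       fp_rate_class = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fn_rate_class = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(predicted = c("alive", "dead"),
                                          observed = c("alive", "dead"))),
       n = n)
}

#' Simulate decision OxD and stochastic fate from a logistic law
#'
#' Draws per-cell decision OxD uniformly over `oxd_range` and samples
#' death as a Bernoulli outcome with
#' `P(death) = plogis(slope * (oxd - threshold))`. Used to study
#' threshold recovery by [fit_logistic()] under a known generating law.
#'
#' @param n Number of cells.
#' @param threshold True OxD threshold (default 0.74).
#' @param slope True logistic slope per OxD unit (default 40).
#' @param oxd_range Range of decision OxD values.
#' @param seed Integer seed.
#' @return A tibble with columns `oxd`, `died`.
#' @export
simulate_logistic_fate <- function(n = 250, threshold = 0.74, slope = 40,
                                   oxd_range = c(0.4, 1.0), seed = 1L) {
  with_seed(seed, {
    oxd <- stats::runif(n, oxd_range[1], oxd_range[2])
    p <- stats::plogis(slope * (oxd - threshold))
    tibble::tibble(oxd = oxd, died = stats::runif(n) < p)
  })
}
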