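# Validation statistics: standardized mean differences, per-condition
# patient-overlap tables, concordance, and the univariable logistic
# one-year-mortality model.

#' Standardized mean difference between two groups
#'
#' Binary covariates: `|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b))/2)`.
#' Continuous covariates: `|m_a - m_b| / sqrt((s_a^2 + s_b^2)/2)`. Returns 0
#' when both spreads are zero and the means are equal, and `Inf` (a
#' sentinel) when the pooled spread is zero but the means differ. An SMD
#' below 0.10 is conventionally read as balanced.
#'
#' @param stat_a,stat_b For `type = "binary"`: proportions in `[0, 1]`
#'   (vectorized). For `type = "continuous"`: length-2 vectors
#'   `c(mean, sd)`.
#' @param type `"binary"` or `"continuous"`.
#' @return Non-negative numeric (possibly `Inf`).
#' @export
#' @examples
#' smd(0.5, 0.4)                                   # 0.2020...
#' smd(c(3.75, 3.66), c(3.6, 3.56), "continuous")  # 0.0415...
smd <- function(stat_a, stat_b, type = c("binary", "continuous")) {
  type <- match.arg(type)
  if (type == "binary") {
    if (any(stat_a < 0 | stat_a > 1 | stat_b < 0 | stat_b > 1, na.rm = TRUE)) {
      abort_cci("proportions must lie in [0, 1]", "snomedcci_contract_error")
    }
    num <- abs(stat_a - stat_b)
    den <- sqrt((stat_a * (1 - stat_a) + stat_b * (1 - stat_b)) / 2)
  } else {
    if (length(stat_a) != 2L || length(stat_b) != 2L) {
      abort_cci("continuous stats must be c(mean, sd)", "snomedcci_contract_error")
    }
    if (stat_a[2L] < 0 || stat_b[2L] < 0) {
      abort_cci("sds must be non-negative", "snomedcci_contract_error")
    }
    num <- abs(stat_a[1L] - stat_b[1L])
    den <- sqrt((stat_a[2L]^2 + stat_b[2L]^2) / 2)
  }
  out <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  unname(out)
}

#' Per-condition patient overlap between two algorithms
#'
#' For each condition, partitions the cohort into the 2x2 table of patients
#' flagged by both algorithms, neither, or only one; the four counts sum to
#' the cohort size.
#'
#' @param flags_a,flags_b data.frames from [score_cohort()] (or any frames
#'   with `person_id` plus one logical column per condition) covering the
#'   same persons.
#' @param conditions Condition labels to tabulate; default: every condition
#'   column present in both frames.
#' @return data.frame `condition`, `n_both`, `n_neither`, `n_a_only`,
#'   `n_b_only`.
#' @export
overlap_table <- function(flags_a, flags_b, conditions = NULL) {
  assert_cols(flags_a, "person_id", "flags_a")
  assert_cols(flags_b, "person_id", "flags_b")
  a <- flags_a[order(flags_a$person_id), , drop = FALSE]
  b <- flags_b[order(flags_b$person_id), , drop = FALSE]
  if (nrow(a) != nrow(b) || !identical(a$person_id, b$person_id)) {
    abort_cci("flags_a and flags_b must cover the same persons",
              "snomedcci_contract_error")
  }
  if (is.null(conditions)) {
    is_flag <- function(df) names(df)[vapply(df, is.logical, logical(1))]
    conditions <- intersect(is_flag(a), is_flag(b))
  }
  do.call(rbind, lapply(conditions, function(cond) {
    fa <- a[[cond]]; fb <- b[[cond]]
    data.frame(condition = cond,
               n_both = sum(fa & fb),
               n_neither = sum(!fa & !fb),
               n_a_only = sum(fa & !fb),
               n_b_only = sum(!fa & fb))
  }))
}

#' Concordance statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen case (outcome 1) has a higher
#' score than a randomly chosen control, with ties counting one half —
#' computed via the rank-sum formulation, which equals the all-pairs
#' definition and the trapezoidal AUC exactly.
#'
#' @param scores Numeric predictor.
#' @param outcomes Binary outcome (0/1 or logical).
#' @return c in `[0, 1]`.
#' @export
c_statistic <- function(scores, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  if (length(scores) != length(outcomes)) {
    abort_cci("scores and outcomes differ in length", "snomedcci_contract_error")
  }
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort_cci("c statistic undefined: only one outcome class present",
              "snomedcci_nonestimable_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariable logistic model of one-year mortality on the CCI
#'
#' Fits `outcome ~ score` by maximum likelihood (iteratively reweighted
#' least squares, convergence tolerance 1e-8, at most 25 iterations),
#' computes the c statistic from the fitted probabilities, and a seeded
#' percentile-bootstrap confidence interval for c. Because the logistic link
#' is monotone, c from fitted probabilities equals c computed on the raw
#' scores whenever the fitted slope is positive; the bootstrap therefore
#' resamples patients and recomputes the rank-based c directly.
#'
#' @param scores Numeric predictor (e.g. per-patient CCI).
#' @param outcomes Binary outcome.
#' @param label Algorithm label carried into the result.
#' @param boot_n Bootstrap resamples for the CI (default 2000).
#' @param seed Seed for the bootstrap stream (default 1); the global RNG
#'   state is restored afterwards.
#' @param conf Confidence level (default 0.95).
#' @return list of class `cci_model_performance`: `algorithm`, `intercept`,
#'   `slope`, `c_statistic`, `ci_low`, `ci_high`, `n`, `n_events`,
#'   `iterations`.
#' @export
fit_mortality_model <- function(scores, outcomes, label = "model",
                                boot_n = 2000L, seed = 1L, conf = 0.95) {
  outcomes <- as.integer(as.logical(outcomes))
  if (length(unique(outcomes)) < 2L) {
    abort_cci("model non-estimable: outcome has a single class",
              "snomedcci_nonestimable_error")
  }
  fit <- stats::glm(outcomes ~ scores, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 25L))
  if (!fit$converged) {
    abort_cci(sprintf("IRLS failed to converge within %d iterations", fit$iter),
              "snomedcci_convergence_error")
  }
  coefs <- stats::coef(fit)
  # a constant predictor drops out of the fit; its slope is the stationary 0
  if (is.na(coefs[2L])) coefs[2L] <- 0
  cstat <- c_statistic(stats::fitted(fit), outcomes)
  ci <- c(NA_real_, NA_real_)
  if (boot_n > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    n <- length(scores)
    bc <- vapply(seq_len(boot_n), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcomes[idx])) < 2L) return(NA_real_)
      c_statistic(scores[idx], outcomes[idx])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(bc, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(list(algorithm = label,
                 intercept = unname(coefs[1L]),
                 slope = unname(coefs[2L]),
                 c_statistic = cstat,
                 ci_low = ci[1L], ci_high = ci[2L],
                 n = length(scores), n_events = sum(outcomes),
                 iterations = fit$iter),
            class = "cci_model_performance")
}

#' @export
print.cci_model_performance <- function(x, ...) {
  cat(sprintf("<%s> n=%d, events=%d | intercept %.4f, slope %.4f | c = %.4f (%.3f-%.3f)\n",
              x$algorithm, x$n, x$n_events, x$intercept, x$slope,
              x$c_statistic, x$ci_low, x$ci_high))
  invisible(x)
}

#' Table-1-style balance rows comparing two algorithms
#'
#' Computes per-condition prevalence under each algorithm and the binary
#' SMD, plus a continuous SMD row for the CCI itself.
#'
#' @param results_a,results_b data.frames from [score_cohort()] over the
#'   same persons.
#' @param threshold Imbalance threshold on the SMD (default 0.10).
#' @return data.frame `covariate`, `stat_a`, `stat_b`, `smd`, `imbalanced`.
#' @export
balance_table <- function(results_a, results_b, threshold = 0.10) {
  conds <- intersect(names(results_a)[vapply(results_a, is.logical, logical(1))],
                     names(results_b)[vapply(results_b, is.logical, logical(1))])
  n <- nrow(results_a)
  rows <- lapply(conds, function(cond) {
    pa <- mean(results_a[[cond]]); pb <- mean(results_b[[cond]])
    data.frame(covariate = cond, stat_a = pa, stat_b = pb,
               smd = smd(pa, pb))
  })
  cci_row <- data.frame(
    covariate = "cci",
    stat_a = mean(results_a$score), stat_b = mean(results_b$score),
    smd = smd(c(mean(results_a$score), stats::sd(results_a$score)),
              c(mean(results_b$score), stats::sd(results_b$score)),
              type = "continuous"))
  out <- rbind(cci_row, do.call(rbind, rows))
  out$imbalanced <- out$smd > threshold
  rownames(out) <- NULL
  out
}
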