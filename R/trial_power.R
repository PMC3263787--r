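#' Sample size per group for a continuous endpoint
#'
#' Two-arm 1:1 trial with a normally distributed primary outcome, two-sided
#' test.  The default normal-approximation formula is
#' \deqn{n = 2 (z_{1-\alpha/2} + z_{power})^2 (\sigma/\delta)^2}
#' rounded up.  \code{method = "nct"} instead finds the smallest n whose
#' exact noncentral-t power of the pooled two-sample t-test reaches the
#' target; it typically adds one subject per group at these sizes.
#'
#' @param delta minimal clinically relevant mean difference (points).
#' @param sd outcome standard deviation (points).
#' @param alpha two-sided significance level, in (0, 1).
#' @param power target power, in (0, 1).
#' @param method \code{"normal"} (default) or \code{"nct"}.
#' @return An object of class \code{"sample_size_result"}: list with
#'   \code{n_per_group}, \code{n_total}, \code{n_unrounded}, and the echoed
#'   assumptions.
#' @export
#' @examples
#' n_per_group_continuous(delta = 5, sd = 15)  # 190 per group
n_per_group_continuous <- function(delta, sd, alpha = 0.05, power = 0.90,
                                   method = c("normal", "nct")) {
  method <- match.arg(method)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  if (!(power > 0 && power < 1)) stop("power must lie in (0, 1)",
                                      call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (delta == 0) stop("delta must be non-zero", call. = FALSE)
  n_raw <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 *
    (sd / delta)^2
  n <- ceiling(n_raw)
  if (method == "nct") {
    n <- max(2L, n - 2L)
    while (t_test_power(n, delta, sd, alpha) < power) n <- n + 1L
  }
  structure(list(n_per_group = as.integer(n), n_total = 2L * as.integer(n),
                 n_unrounded = n_raw,
                 assumptions = list(endpoint = "continuous", delta = delta,
                                    sd = sd, alpha = alpha, power = power,
                                    allocation = "1:1", method = method)),
            class = "sample_size_result")
}

# exact power of the pooled two-sample t-test (noncentral t), n per group
t_test_power <- function(n, delta, sd, alpha) {
  df <- 2 * n - 2
  ncp <- abs(delta) / (sd * sqrt(2 / n))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Cohen's d standardized effect size
#'
#' @param delta mean difference.
#' @param sd outcome standard deviation.
#' @return list with \code{d} (full precision) and \code{d_rounded}
#'   (2 decimals, the conventionally reported figure).
#' @export
#' @examples
#' cohens_d(5, 15)
cohens_d <- function(delta, sd) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  d <- delta / sd
  list(d = d, d_rounded = round(d, 2))
}

#' Sample size per group for a binary endpoint
#'
#' Two-proportion comparison (e.g. a combined endpoint of death or
#' neurodevelopmental impairment) with the pooled-variance normal
#' approximation
#' \deqn{n = \frac{(z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{power}\sqrt{p_1 q_1 + p_2 q_2})^2}{(p_1 - p_2)^2}}
#' and optionally the Fleiss continuity correction.
#'
#' @param p_control,p_treated event risks in (0, 1), distinct.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param continuity_correction apply the Fleiss correction.
#' @return A \code{"sample_size_result"} (per-group and total N, echoed
#'   assumptions).
#' @export
#' @examples
#' n_binary(0.25, 0.20)  # 1464 per group uncorrected
n_binary <- function(p_control, p_treated, alpha = 0.05, power = 0.90,
                     continuity_correction = FALSE) {
  for (p in c(p_control, p_treated))
    if (!(p > 0 && p < 1)) stop("risks must lie in (0, 1)", call. = FALSE)
  if (p_control == p_treated) stop("risks must be distinct", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  if (!(power > 0 && power < 1)) stop("power must lie in (0, 1)",
                                      call. = FALSE)
  pbar <- (p_control + p_treated) / 2
  qbar <- 1 - pbar
  num <- (stats::qnorm(1 - alpha / 2) * sqrt(2 * pbar * qbar) +
            stats::qnorm(power) * sqrt(p_control * (1 - p_control) +
                                         p_treated * (1 - p_treated)))^2
  n_raw <- num / (p_control - p_treated)^2
  if (continuity_correction)
    n_raw <- n_raw / 4 *
      (1 + sqrt(1 + 8 / (n_raw * abs(p_control - p_treated))))^2
  n <- ceiling(n_raw)
  structure(list(n_per_group = as.integer(n), n_total = 2L * as.integer(n),
                 n_unrounded = n_raw,
                 assumptions = list(endpoint = "binary",
                                    p_control = p_control,
                                    p_treated = p_treated, alpha = alpha,
                                    power = power,
                                    continuity_correction =
                                      continuity_correction)),
            class = "sample_size_result")
}

#' Inflate a per-group sample size for attrition
#'
#' \code{ceiling(n / (1 - attrition))}.  Any further rounding to an
#' administratively convenient figure is a protocol decision and is never
#' applied silently here.
#'
#' @param n_per_group evaluable subjects needed per group.
#' @param attrition expected fraction lost (e.g. mortality), in [0, 1).
#' @return integer subjects to randomize per group.
#' @export
#' @examples
#' inflate_for_attrition(190, 0.20)  # 238
inflate_for_attrition <- function(n_per_group, attrition) {
  if (attrition < 0 || attrition >= 1)
    stop("attrition must lie in [0, 1)", call. = FALSE)
  as.integer(ceiling(n_per_group / (1 - attrition)))
}

#' Empirical power of the two-sample t-test by trial simulation
#'
#' Simulates complete two-arm trials with normal outcomes (means 0 and
#' \code{delta}, common \code{sd}) and reports the fraction rejected by the
#' two-sided pooled two-sample t-test at level \code{alpha}, with an exact
#' binomial confidence interval.
#'
#' @param n_per_group subjects per arm.
#' @param delta true mean difference.
#' @param sd outcome standard deviation.
#' @param alpha two-sided significance level.
#' @param n_reps number of simulated trials.
#' @param seed integer seed.
#' @param conf_level confidence level of the binomial interval.
#' @return list with \code{power} (proportion rejected), \code{ci}
#'   (two-sided binomial interval), \code{n_rejected}, \code{n_reps},
#'   \code{seed}.
#' @export
#' @examples
#' simulate_power(190, delta = 5, sd = 15, n_reps = 2000, seed = 1)
simulate_power <- function(n_per_group, delta, sd, alpha = 0.05,
                           n_reps = 1e4, seed = 1L, conf_level = 0.95) {
  if (n_per_group < 2) stop("n_per_group must be at least 2", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  set.seed(seed)
  n <- n_per_group
  tc <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  rejected <- 0L
  chunk <- max(1L, floor(2e6 / (2 * n)))
  done <- 0L
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    X <- matrix(stats::rnorm(n * m, 0, sd), n, m)
    Y <- matrix(stats::rnorm(n * m, delta, sd), n, m)
    mx <- colMeans(X); my <- colMeans(Y)
    vx <- (colMeans(X^2) - mx^2) * n / (n - 1)
    vy <- (colMeans(Y^2) - my^2) * n / (n - 1)
    tstat <- (my - mx) / sqrt((vx + vy) / n)
    rejected <- rejected + sum(abs(tstat) > tc)
    done <- done + m
  }
  ci <- stats::binom.test(rejected, n_reps,
                          conf.level = conf_level)$conf.int
  list(power = rejected / n_reps, ci = as.numeric(ci),
       n_rejected = rejected, n_reps = n_reps, seed = seed, alpha = alpha)
}

#' Sample size as a function of effect size
#'
#' @param delta_grid mean differences to tabulate.
#' @param sd,alpha,power,method as in
#'   \code{\link{n_per_group_continuous}}.
#' @return data frame with columns \code{delta}, \code{cohens_d},
#'   \code{n_per_group}, \code{n_total}.
#' @export
#' @examples
#' power_curve(c(2.5, 5, 7.5), sd = 15)
power_curve <- function(delta_grid, sd, alpha = 0.05, power = 0.90,
                        method = "normal") {
  res <- lapply(delta_grid, function(d)
    n_per_group_continuous(d, sd, alpha, power, method))
  data.frame(delta = delta_grid,
             cohens_d = vapply(delta_grid, function(d) cohens_d(d, sd)$d,
                               numeric(1)),
             n_per_group = vapply(res, `[[`, integer(1), "n_per_group"),
             n_total = vapply(res, `[[`, integer(1), "n_total"))
}

#' @export
print.sample_size_result <- function(x, ...) {
  a <- x$assumptions
  if (a$endpoint == "continuous") {
    cat(sprintf(
      "Sample size (continuous endpoint, %s): delta %g, sd %g, alpha %g, power %g\n",
      a$method, a$delta, a$sd, a$alpha, a$power))
  } else {
    cat(sprintf(
      "Sample size (binary endpoint%s): risks %g vs %g, alpha %g, power %g\n",
      if (isTRUE(a$continuity_correction)) ", continuity-corrected" else "",
      a$p_control, a$p_treated, a$alpha, a$power))
  }
  cat(sprintf("  n per group: %d (unrounded %.2f); total: %d\n",
              x$n_per_group, x$n_unrounded, x$n_total))
  invisible(x)
}
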