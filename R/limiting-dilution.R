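# Single-hit Poisson limiting-dilution analysis: a well plated with d
# cells is positive when it received at least one clonogenic cell, so
# P(positive) = 1 - exp(-f * d) where f is the clonogenic frequency per
# cell. The frequency is fitted by maximizing the exact binomial
# log-likelihood in log(f) (complementary log-log link with log-dose
# offset), with a Wald interval on log(f) and a likelihood-ratio test for
# comparing two groups.

#' Construct a limiting-dilution design
#'
#' @param dose cells plated per well at each dilution (positive integers).
#' @param wells replicate wells per dose.
#' @param positive positive (sphere-forming) wells per dose,
#'   `0 <= positive <= wells`.
#' @param group optional group label.
#' @return A data.frame of class `ld_design` with columns `dose`, `wells`,
#'   `positive` and a `group` attribute.
#' @export
ld_design <- function(dose, wells, positive, group = NULL) {
  if (length(dose) < 1L || length(wells) != length(dose) ||
      length(positive) != length(dose)) {
    stop_field("dose", "dose, wells and positive must be equal-length, nonempty")
  }
  if (any(dose <= 0) || any(dose != round(dose))) {
    stop_field("dose", "doses must be positive integers")
  }
  if (any(wells < 1) || any(wells != round(wells))) {
    stop_field("wells", "well counts must be positive integers")
  }
  if (any(positive < 0) || any(positive > wells) ||
      any(positive != round(positive))) {
    stop_field("positive", "positive counts must be integers in [0, wells]")
  }
  out <- data.frame(dose = as.numeric(dose), wells = as.integer(wells),
                    positive = as.integer(positive))
  attr(out, "group") <- group
  class(out) <- c("ld_design", "data.frame")
  out
}

# log-likelihood and derivatives in theta = log(f).
# ll(theta) = sum pos * log(1 - exp(-f d)) - f * d * (wells - pos)
ld_loglik <- function(theta, design) {
  f <- exp(theta)
  x <- f * design$dose
  sum(design$positive * log(-expm1(-x))) - sum(x * (design$wells - design$positive))
}

ld_score <- function(theta, design) {
  x <- exp(theta) * design$dose
  # d/dtheta [pos log(1 - e^-x)] = pos * x / (e^x - 1)
  sum(design$positive * x / expm1(x)) - sum(x * (design$wells - design$positive))
}

ld_hessian <- function(theta, design) {
  x <- exp(theta) * design$dose
  ex <- expm1(x)
  # d/dtheta [x / (e^x - 1)] = x * (e^x - 1 - x e^x) / (e^x - 1)^2
  h <- x * (ex - x * (ex + 1)) / ex^2
  sum(design$positive * h) - sum(x * (design$wells - design$positive))
}

#' Fit the clonogenic frequency of a limiting-dilution assay
#'
#' Maximizes the single-hit binomial likelihood in `log(f)` (bracketed
#' search refined by Newton steps), with a 95% Wald interval on `log(f)`
#' back-transformed and clipped to \[0, 1\]. Boundary designs are flagged:
#' with no positive wells anywhere, `f_hat = 0` and the upper limit is the
#' exact binomial zero-count bound `-log(0.05) / sum(dose * wells)`; with
#' every well positive, `f_hat` sits at the working upper bound of 1 per
#' cell and the lower limit is the exact bound solving
#' `P(all wells positive | f) = 0.05`.
#'
#' @param design an [ld_design()].
#' @return An object of class `clonogenic_estimate`: list with `f_hat`,
#'   `ci_low`, `ci_high` (95%), `log_likelihood`, `boundary_flag`
#'   (`"none"`, `"all_negative"`, `"all_positive"`) and `se_log_f`.
#' @export
fit_frequency <- function(design) {
  if (!inherits(design, "ld_design")) design <- as_ld_design(design)
  tot_pos <- sum(design$positive)
  if (tot_pos == 0L) {
    return(structure(
      list(f_hat = 0, ci_low = 0,
           ci_high = min(1, -log(0.05) / sum(design$dose * design$wells)),
           log_likelihood = 0, boundary_flag = "all_negative",
           se_log_f = NA_real_),
      class = "clonogenic_estimate"))
  }
  if (all(design$positive == design$wells)) {
    # P(all positive | f) = prod (1 - e^(-f d))^wells = 0.05 at the bound
    g <- function(th) {
      sum(design$wells * log(-expm1(-exp(th) * design$dose))) - log(0.05)
    }
    lo <- stats::uniroot(g, c(-40, 5), tol = 1e-12)$root
    return(structure(
      list(f_hat = 1, ci_low = min(1, exp(lo)), ci_high = 1,
           log_likelihood = ld_loglik(0, design),
           boundary_flag = "all_positive", se_log_f = NA_real_),
      class = "clonogenic_estimate"))
  }
  # interior: bracketed maximization in theta = log f, Newton-polished
  opt <- stats::optimize(ld_loglik, interval = c(-30, 0), maximum = TRUE,
                         design = design, tol = 1e-10)
  theta <- opt$maximum
  for (i in 1:5) {
    h <- ld_hessian(theta, design)
    if (!is.finite(h) || h >= 0) break
    step <- ld_score(theta, design) / h
    theta_new <- min(theta - step, 0)
    if (!is.finite(theta_new) || abs(theta_new - theta) < 1e-14) {
      theta <- theta_new
      break
    }
    theta <- theta_new
  }
  h <- ld_hessian(theta, design)
  se <- if (is.finite(h) && h < 0) sqrt(-1 / h) else NA_real_
  zc <- stats::qnorm(0.975)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else exp(theta + c(-1, 1) * zc * se)
  structure(
    list(f_hat = exp(theta),
         ci_low = max(0, min(ci[1], exp(theta))),
         ci_high = min(1, max(ci[2], exp(theta))),
         log_likelihood = ld_loglik(theta, design),
         boundary_flag = "none",
         se_log_f = se),
    class = "clonogenic_estimate"
  )
}

as_ld_design <- function(x) {
  ld_design(x$dose, x$wells, x$positive, group = attr(x, "group"))
}

#' @export
print.clonogenic_estimate <- function(x, ...) {
  cat(sprintf(
    "clonogenic_estimate: f = %.3g per cell (1 in %.0f), 95%% CI [%.3g, %.3g]%s\n",
    x$f_hat, 1 / x$f_hat, x$ci_low, x$ci_high,
    if (x$boundary_flag == "none") "" else paste0(" [", x$boundary_flag, "]")))
  invisible(x)
}

#' Likelihood-ratio comparison of two clonogenic frequencies
#'
#' Fits each design separately and once jointly under a shared frequency;
#' `2 * (ll_a + ll_b - ll_pooled)` is referred to a chi-square with 1
#' degree of freedom.
#'
#' @param a,b [ld_design()] objects.
#' @return List with `lrt_stat`, `df` (1), `p_value`, the per-group fits
#'   `fit_a`, `fit_b`, the pooled fit `fit_pooled`, and `caveat`
#'   (non-`NA` when either group fit sits on a boundary).
#' @export
compare_frequencies <- function(a, b) {
  fa <- fit_frequency(a)
  fb <- fit_frequency(b)
  pooled <- ld_design(c(a$dose, b$dose), c(a$wells, b$wells),
                      c(a$positive, b$positive))
  fp <- fit_frequency(pooled)
  lrt <- max(0, 2 * (fa$log_likelihood + fb$log_likelihood - fp$log_likelihood))
  caveat <- if (fa$boundary_flag != "none" || fb$boundary_flag != "none") {
    "a group fit is on the boundary; the chi-square reference is unreliable"
  } else {
    NA_character_
  }
  list(lrt_stat = lrt, df = 1L,
       p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       fit_a = fa, fit_b = fb, fit_pooled = fp, caveat = caveat)
}
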