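#' Prior parameters for the BCPNN information component
#'
#' The Bayesian confidence propagation neural network (BCPNN) places
#' Dirichlet/beta priors on the joint and marginal reporting probabilities of
#' a drug--event pair. With the conventional choice (Bate et al. 1998) the
#' marginal priors are `Beta(alpha1, alpha - alpha1)` and
#' `Beta(beta1, beta - beta1)` with `alpha1 = beta1 = 1`, `alpha = beta = 2`,
#' and the joint prior `Beta(gamma11, gamma - gamma11)` with `gamma11 = 1` and
#' `gamma` chosen so that the prior expectation of the information component
#' is zero. `gamma` depends on the observed margins and is derived inside
#' [ic_stat()]; it is not a free parameter here.
#'
#' @param alpha,beta Total prior weight for the drug and event margins.
#' @param alpha1,beta1 Prior success weight for the drug and event margins.
#' @param gamma11 Prior success weight for the joint cell.
#' @return An object of class `bcpnn_priors`.
#' @examples
#' bcpnn_priors()
#' @export
bcpnn_priors <- function(alpha = 2, beta = 2, alpha1 = 1, beta1 = 1,
                         gamma11 = 1) {
  vals <- c(alpha = alpha, beta = beta, alpha1 = alpha1, beta1 = beta1,
            gamma11 = gamma11)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all BCPNN prior parameters must be positive finite reals",
         call. = FALSE)
  }
  structure(as.list(vals), class = "bcpnn_priors")
}

check_cells <- function(a, b, c, d) {
  n <- length(a)
  if (length(b) != n || length(c) != n || length(d) != n) {
    stop("cell vectors a, b, c, d must have equal length", call. = FALSE)
  }
  for (x in list(a, b, c, d)) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
      stop("contingency cells must be finite non-negative numbers",
           call. = FALSE)
    }
  }
  invisible(n)
}

# validate and coerce to double in the caller's frame (cell products such
# as (a+b)(c+d)(a+c)(b+d) overflow 32-bit integers at realistic scale)
cells_as_double <- function(env) {
  with(env, check_cells(a, b, c, d))
  for (v in c("a", "b", "c", "d")) assign(v, as.numeric(get(v, env)), env)
  invisible(NULL)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = (a/c)/(b/d)` with `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)` and
#' `CI = exp(ln ROR +/- z * SE)`. Computed in log space. Any zero cell makes
#' the statistic undefined; the row is returned with `NA` values and a reason
#' flag rather than raising.
#'
#' @param a,b,c,d Cells of the 2x2 table(s): `a` target drug with the event,
#'   `b` target drug with other events, `c` other drugs with the event, `d`
#'   other drugs with other events. Vectors are recycled per table, not
#'   across arguments.
#' @param conf Confidence level for the interval (default 0.95).
#' @return A `data.frame` with columns `ror`, `ror_lo`, `ror_hi`, `ror_flag`
#'   (`NA` or `"zero_cell"`).
#' @examples
#' ror_stat(4, 6, 2, 8)
#' @export
ror_stat <- function(a, b, c, d, conf = 0.95) {
  cells_as_double(environment())
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  lr <- ifelse(ok, log(a) + log(d) - log(b) - log(c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ror = exp(lr),
             ror_lo = exp(lr - z * se),
             ror_hi = exp(lr + z * se),
             ror_flag = ifelse(ok, NA_character_, "zero_cell"),
             stringsAsFactors = FALSE)
}

#' Proportional reporting ratio with Wald 95% confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with
#' `SE(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @inheritParams ror_stat
#' @return A `data.frame` with columns `prr`, `prr_lo`, `prr_hi`, `prr_flag`.
#' @examples
#' prr_stat(4, 6, 2, 8)
#' @export
prr_stat <- function(a, b, c, d, conf = 0.95) {
  cells_as_double(environment())
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ok <- a > 0 & c > 0 & b > 0 & d > 0
  lp <- ifelse(ok, log(a) - log(a + b) - log(c) + log(c + d), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  data.frame(prr = exp(lp),
             prr_lo = exp(lp - z * se),
             prr_hi = exp(lp + z * se),
             prr_flag = ifelse(ok, NA_character_, "zero_cell"),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, without continuity
#' correction. Undefined (flagged) when any margin is zero.
#'
#' @inheritParams ror_stat
#' @return A `data.frame` with columns `chi2`, `chi2_flag`.
#' @examples
#' chi2_stat(4, 6, 2, 8)
#' @export
chi2_stat <- function(a, b, c, d) {
  cells_as_double(environment())
  n <- a + b + c + d
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chi2 <- ifelse(ok,
                 n * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)),
                 NA_real_)
  data.frame(chi2 = chi2,
             chi2_flag = ifelse(ok, NA_character_, "zero_margin"),
             stringsAsFactors = FALSE)
}

#' Empirical Bayes geometric mean (crude relative reporting ratio)
#'
#' Point estimate `EBGM = a N / [(a+b)(a+c)]`, the observed-to-expected
#' reporting ratio under independence, with lower signal bound
#' `EBGM05 = exp(ln EBGM - z * SE)` where `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
#' The default multiplier `z = 1.645` gives the fifth percentile; pass
#' `z = 1.96` for a two-sided 95% lower bound. No gamma-Poisson shrinkage is
#' applied: this is the crude ratio, so `ic_stat()` equals `log2(ebgm)`
#' identically.
#'
#' @inheritParams ror_stat
#' @param z Multiplier for the lower bound (default `qnorm(0.95)`-style 1.645).
#' @return A `data.frame` with columns `ebgm`, `ebgm05`, `ebgm_flag`.
#' @examples
#' ebgm_stat(4, 6, 2, 8)
#' @export
ebgm_stat <- function(a, b, c, d, z = 1.645) {
  cells_as_double(environment())
  n <- a + b + c + d
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  le <- ifelse(ok, log(a) + log(n) - log(a + b) - log(a + c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ebgm = exp(le),
             ebgm05 = exp(le - z * se),
             ebgm_flag = ifelse(ok, NA_character_, "zero_cell"),
             stringsAsFactors = FALSE)
}

#' BCPNN information component
#'
#' The point estimate is the crude information component
#' `IC = log2[a N / ((a+b)(a+c))]` (identically `log2(EBGM)`). The lower
#' credibility bound `IC025 = E(IC) - 2 sqrt(V(IC))` uses the Bayesian
#' posterior moments of Bate et al. (1998):
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11}(N+\alpha)(N+\beta) /
#'   [(a+b+\alpha_1)(a+c+\beta_1)]} and
#' \deqn{V(IC) = \frac{1}{(\ln 2)^2}\left[
#'   \frac{N - a + \gamma - \gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
#'   \frac{N - (a+b) + \alpha - \alpha_1}{(a+b+\alpha_1)(1+N+\alpha)} +
#'   \frac{N - (a+c) + \beta - \beta_1}{(a+c+\beta_1)(1+N+\beta)}\right].}
#' The bound is defined for any table with `N > 0`; the point estimate
#' requires `a > 0`.
#'
#' @inheritParams ror_stat
#' @param priors A [bcpnn_priors()] object.
#' @return A `data.frame` with columns `ic`, `ic025`, `ic_flag`.
#' @examples
#' ic_stat(4, 6, 2, 8)
#' @export
ic_stat <- function(a, b, c, d, priors = bcpnn_priors()) {
  cells_as_double(environment())
  stopifnot(inherits(priors, "bcpnn_priors"))
  n <- a + b + c + d
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ic <- ifelse(ok, (log(a) + log(n) - log(a + b) - log(a + c)) / log(2),
               NA_real_)
  p <- priors
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((a + b + p$alpha1) * (a + c + p$beta1))
  eic_ok <- n > 0
  eic <- ifelse(eic_ok,
                log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
                       ((n + gamma) * (a + b + p$alpha1) * (a + c + p$beta1))),
                NA_real_)
  vic <- ifelse(eic_ok,
                ((n - a + gamma - p$gamma11) /
                   ((a + p$gamma11) * (1 + n + gamma)) +
                 (n - (a + b) + p$alpha - p$alpha1) /
                   ((a + b + p$alpha1) * (1 + n + p$alpha)) +
                 (n - (a + c) + p$beta - p$beta1) /
                   ((a + c + p$beta1) * (1 + n + p$beta))) / log(2)^2,
                NA_real_)
  data.frame(ic = ic,
             ic025 = eic - 2 * sqrt(vic),
             ic_flag = ifelse(ok, NA_character_,
                              ifelse(a == 0, "zero_a", "zero_cell")),
             stringsAsFactors = FALSE)
}

#' All five disproportionality statistics for one or more 2x2 tables
#'
#' Composes [ror_stat()], [prr_stat()], [chi2_stat()], [ic_stat()] and
#' [ebgm_stat()]. An optional Haldane--Anscombe continuity correction
#' (`+0.5` to every cell of tables containing a zero) can be switched on;
#' it is off by default so that undefined statistics stay visible as flags.
#'
#' @inheritParams ror_stat
#' @param priors A [bcpnn_priors()] object for the IC bound.
#' @param ebgm_z Multiplier for the EBGM lower bound (default 1.645).
#' @param haldane If `TRUE`, add 0.5 to all four cells of any table with a
#'   zero cell before computing the ratio statistics.
#' @return A `data.frame` with the input cells, `n`, and all statistic
#'   columns.
#' @examples
#' signal_stats(c(4, 10), c(6, 10), c(2, 10), c(8, 10))
#' @export
signal_stats <- function(a, b, c, d, priors = bcpnn_priors(),
                         conf = 0.95, ebgm_z = 1.645, haldane = FALSE) {
  check_cells(a, b, c, d)
  a0 <- a; b0 <- b; c0 <- c; d0 <- d
  if (haldane) {
    zc <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * zc; b <- b + 0.5 * zc
    c <- c + 0.5 * zc; d <- d + 0.5 * zc
  }
  cbind(data.frame(a = a0, b = b0, c = c0, d = d0, n = a0 + b0 + c0 + d0),
        ror_stat(a, b, c, d, conf = conf),
        prr_stat(a, b, c, d, conf = conf),
        chi2_stat(a, b, c, d),
        ic_stat(a, b, c, d, priors = priors),
        ebgm_stat(a, b, c, d, z = ebgm_z))
}
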