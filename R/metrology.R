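#' Instrument uncertainty budget
#'
#' Calibration-derived absolute uncertainties of the measurement chain: the
#' displacement transducer (0.01 mm), the fascicle thickness measurement
#' (0.0025 mm), the load cell (0.0001 g) and TEM lengths from the diffraction
#' grating calibration (0.5 nm).
#'
#' @param delta_x displacement uncertainty, mm.
#' @param delta_d thickness uncertainty, mm.
#' @param delta_P load uncertainty, gram-force.
#' @param delta_D_tem TEM length uncertainty, nm.
#' @return list of class `instrument_budget`.
#' @export
instrument_budget <- function(delta_x = 0.01, delta_d = 0.0025,
                              delta_P = 1e-4, delta_D_tem = 0.5) {
  vals <- c(delta_x, delta_d, delta_P, delta_D_tem)
  if (any(vals < 0)) stop_tm("uncertainties must be non-negative", "domain")
  structure(list(delta_x = delta_x, delta_d = delta_d,
                 delta_P = delta_P, delta_D_tem = delta_D_tem),
            class = "instrument_budget")
}

#' Add uncertainties in quadrature
#'
#' For a quantity formed by addition or subtraction, the combined absolute
#' uncertainty is the root sum of squares of the terms,
#' \eqn{\delta Q = \sqrt{\sum \delta_i^2}}.
#'
#' @param terms non-negative absolute uncertainties.
#' @return combined absolute uncertainty.
#' @export
quad_add <- function(terms) {
  if (any(!is.finite(terms)) || any(terms < 0))
    stop_tm("uncertainty terms must be non-negative", "domain")
  sqrt(sum(terms^2))
}

#' Propagate relative uncertainties through products and quotients
#'
#' For a quantity formed by multiplication or division, the combined
#' uncertainty is \eqn{\delta Q = |Q| \sqrt{\sum (\delta_i / a_i)^2}}. A
#' squared factor contributes its relative term twice, as two independent
#' entries in `rel_terms`.
#'
#' @param Q value of the derived quantity.
#' @param rel_terms non-negative relative uncertainties `delta_a / a`.
#' @return absolute uncertainty of Q, same units as Q.
#' @export
quad_mul <- function(Q, rel_terms) {
  if (any(!is.finite(rel_terms)) || any(rel_terms < 0))
    stop_tm("relative uncertainty terms must be non-negative", "domain")
  abs(Q) * sqrt(sum(rel_terms^2))
}

#' Assemble the per-quantity uncertainty budget
#'
#' Add-in-quadrature propagation of the instrument uncertainties to the
#' derived quantities of the pipeline. Term lists per quantity:
#' \describe{
#'   \item{eps}{\eqn{\varepsilon = x/L_0}; the nominal length enters as an
#'     order of magnitude only, so \eqn{\delta\varepsilon =
#'     \varepsilon\,\delta x / x}.}
#'   \item{A}{\eqn{A = \pi d^2/4}; the squared thickness contributes
#'     \eqn{\delta d/d} twice: \eqn{\delta A = A\sqrt{2}\,\delta d/d}.}
#'   \item{sigma}{\eqn{\sigma = P/A}: terms \eqn{\delta P/P} and
#'     \eqn{\delta A/A}.}
#'   \item{E}{slope \eqn{\sigma/\varepsilon} at yield: terms
#'     \eqn{\delta\sigma/\sigma} and \eqn{\delta\varepsilon/\varepsilon}.}
#'   \item{a_f}{\eqn{a_f = \pi D^2/4}: \eqn{\delta a_f =
#'     a_f\sqrt{2}\,\delta D/D} (same squared-variable convention as A).}
#'   \item{field_area}{width times height of the TEM field of view.}
#'   \item{rho}{\eqn{\rho = \sum a_f / S}: terms
#'     \eqn{\delta(\sum a_f)/\sum a_f} (per-fibril deltas added in
#'     quadrature) and \eqn{\delta S/S}.}
#' }
#'
#' @param x displacement at the point of interest, mm.
#' @param L0 nominal length, mm.
#' @param d fascicle thickness, mm.
#' @param P load, gram-force.
#' @param sigma stress at the point of interest, MPa (measured; used rather
#'   than recomputed from P/A so a reported group mean can be budgeted).
#' @param eps strain at the point of interest (defaults to `x / L0`).
#' @param E stiffness, MPa; optional.
#' @param D fibril diameter, nm; optional.
#' @param n_fibrils,mean_a_f fibril count and mean area for the rho budget;
#'   optional.
#' @param rho area fraction; optional.
#' @param field_width,field_height TEM field of view, nm.
#' @param budget an [instrument_budget()].
#' @return data frame with columns `quantity`, `value`, `delta` (absolute
#'   uncertainty, same units as the value).
#' @export
uncertainty_budget <- function(x, L0, d, P, sigma,
                               eps = x / L0, E = NA_real_,
                               D = NA_real_,
                               n_fibrils = NA_integer_, mean_a_f = NA_real_,
                               rho = NA_real_,
                               field_width = 5000, field_height = 4000,
                               budget = instrument_budget()) {
  for (v in list(x, L0, d, P, sigma))
    if (!is_scalar_number(v) || v <= 0)
      stop_tm("x, L0, d, P and sigma must be positive", "domain")
  rows <- list()
  add <- function(q, value, delta) rows[[length(rows) + 1L]] <<-
    data.frame(quantity = q, value = value, delta = delta,
               stringsAsFactors = FALSE)

  d_eps <- quad_mul(eps, budget$delta_x / x)
  add("eps", eps, d_eps)

  A <- pi * d^2 / 4
  rel_A <- sqrt(2) * budget$delta_d / d
  add("A", A, quad_mul(A, rel_A))

  d_sigma <- quad_mul(sigma, c(budget$delta_P / P, rel_A))
  add("sigma", sigma, d_sigma)

  if (is_scalar_number(E))
    add("E", E, quad_mul(E, c(d_sigma / sigma, d_eps / eps)))

  if (is_scalar_number(D)) {
    a_f <- pi * D^2 / 4
    add("a_f", a_f, quad_mul(a_f, sqrt(2) * budget$delta_D_tem / D))
  }

  S <- field_width * field_height
  d_S <- quad_mul(S, c(budget$delta_D_tem / field_width,
                       budget$delta_D_tem / field_height))
  add("field_area", S, d_S)

  if (is_scalar_number(rho) && is_scalar_number(mean_a_f) &&
      is_scalar_number(n_fibrils)) {
    D_bar <- sqrt(4 * mean_a_f / pi)
    d_af <- quad_mul(mean_a_f, sqrt(2) * budget$delta_D_tem / D_bar)
    sum_af <- n_fibrils * mean_a_f
    d_sum <- quad_add(rep(d_af, n_fibrils))
    add("rho", rho, quad_mul(rho, c(d_sum / sum_af, d_S / S)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo cross-check of quadrature propagation
#'
#' Draws Gaussian perturbations of the inputs with the stated absolute
#' uncertainties, evaluates `fun` on each draw, and reports the empirical SD
#' of the output: a model-free check of the add-in-quadrature deltas.
#'
#' @param fun function taking a named list/vector of input values.
#' @param values named numeric vector of central input values.
#' @param deltas named numeric vector of absolute input uncertainties
#'   (matching `values`).
#' @param n number of draws (default 1e5).
#' @param seed RNG seed.
#' @return list with `sd` (empirical output SD) and `mean`.
#' @export
mc_propagate <- function(fun, values, deltas, n = 1e5, seed = 1) {
  stopifnot(identical(names(values), names(deltas)))
  with_seed(seed, {
    draws <- vapply(seq_along(values), function(i)
      stats::rnorm(n, values[i], deltas[i]), numeric(n))
    colnames(draws) <- names(values)
    out <- apply(draws, 1L, function(r) fun(as.list(r)))
    list(sd = stats::sd(out), mean = mean(out))
  })
}

#' Recover an SD from a printed SEM
#' @param sem standard error of the mean.
#' @param n sample size it was computed from.
#' @return the standard deviation, `sem * sqrt(n)`.
#' @export
sd_from_sem <- function(sem, n) {
  if (any(n < 2)) stop_tm("n must be at least 2", "domain")
  sem * sqrt(n)
}

#' Welch two-sample t-test power
#'
#' Analytic power of the two-sample t test for unequal sample sizes and
#' variances, from the noncentral t distribution with Welch-Satterthwaite
#' degrees of freedom and noncentrality
#' \eqn{|\mu_1-\mu_2| / \sqrt{s_1^2/n_1 + s_2^2/n_2}}.
#'
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (recover from a printed SEM with
#'   [sd_from_sem()]).
#' @param n1,n2 group sample sizes (>= 2).
#' @param alpha significance level (default 0.05).
#' @param sides 1 or 2 (default two-sided).
#' @return power in (0, 1).
#' @export
welch_power <- function(mean1, mean2, sd1, sd2, n1, n2,
                        alpha = 0.05, sides = 2) {
  if (n1 < 2 || n2 < 2) stop_tm("need n >= 2 per group", "domain")
  if (!(alpha > 0 && alpha < 1)) stop_tm("alpha must lie in (0, 1)", "domain")
  if (sd1 < 0 || sd2 < 0) stop_tm("SDs must be non-negative", "domain")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) stop_tm("zero variance in both groups", "domain")
  se <- sqrt(v1 + v2)
  ncp <- abs(mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else if (sides == 1) {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  } else stop_tm("`sides` must be 1 or 2", "domain")
}

#' Monte-Carlo Welch power
#'
#' Simulates Welch two-sample t tests under the specified group means, SDs
#' and sizes, and reports the rejection rate: the simulation oracle for
#' [welch_power()].
#'
#' @inheritParams welch_power
#' @param nrep number of simulated tests (default 2e4).
#' @param seed RNG seed.
#' @return empirical power.
#' @export
welch_power_mc <- function(mean1, mean2, sd1, sd2, n1, n2,
                           alpha = 0.05, sides = 2, nrep = 2e4, seed = 1) {
  with_seed(seed, {
    x1 <- matrix(stats::rnorm(nrep * n1, mean1, sd1), nrow = nrep)
    x2 <- matrix(stats::rnorm(nrep * n2, mean2, sd2), nrow = nrep)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- apply(x1, 1L, stats::var) / n1
    v2 <- apply(x2, 1L, stats::var) / n2
    tstat <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    if (sides == 2) {
      mean(abs(tstat) > stats::qt(1 - alpha / 2, df))
    } else {
      # one-sided in the direction of the true effect
      s <- sign(mean1 - mean2); if (s == 0) s <- 1
      mean(s * tstat > stats::qt(1 - alpha, df))
    }
  })
}
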