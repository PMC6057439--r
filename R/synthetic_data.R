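# Ground-truthed generators for every pipeline stage. Each generator is a
# pure function of its parameter object (seed included) and attaches the
# exact truth it was built from, so recovery can be asserted end to end.

#' Parameters for a synthetic tensile trace
#'
#' The stress-strain shape is a fixed three-piece family whose landmarks are
#' analytically known: a power-law toe \eqn{\sigma = \sigma_Y
#' (\varepsilon/\varepsilon_Y)^m} with exponent \eqn{m = E
#' \varepsilon_Y/\sigma_Y} (so the slope increases monotonically to exactly
#' E at the yield point), a concave quadratic plastic segment joining the
#' yield point to the strength point with slope continuity at yield, and a
#' linear post-peak decay to rupture. Feasibility requires \eqn{m > 1} (the
#' toe is convex) and \eqn{\sigma_U - \sigma_Y \le E(\varepsilon_U -
#' \varepsilon_Y) \le 2(\sigma_U - \sigma_Y)} (the quadratic is concave and
#' peaks no earlier than \eqn{\varepsilon_U}).
#'
#' @param E_true stiffness (maximum slope, at yield), MPa.
#' @param sigmaY_true,epsY_true yield stress (MPa) and strain.
#' @param sigmaU_true,epsU_true strength (MPa) and its strain.
#' @param rupture_eps strain at the end of the record.
#' @param end_stress_frac stress at rupture as a fraction of the strength
#'   (1 gives a flat post-peak plateau).
#' @param slack_mm slack travel before the specimen is taut, mm.
#' @param noise_sd_g SD of Gaussian load noise, gram-force.
#' @param d fascicle diameter, mm.
#' @param L0 nominal specimen length, mm.
#' @param rate crosshead displacement rate, mm/s (0.067 by convention).
#' @param sample_hz sampling rate, Hz.
#' @param seed RNG seed for the load noise.
#' @param disp_gain_mv,disp_offset_mv,load_gain_mv,load_offset_mv affine
#'   maps generating the raw mV channels from the physical columns.
#' @return list of class `trace_params` with the analytic ground truth
#'   attached as `$truth` (landmarks, stiffness, and the segment strain
#'   energy densities u_Y, u_P, u_R, u_F, u_0).
#' @export
trace_params <- function(E_true = 600, sigmaY_true = 20, sigmaU_true = 50,
                         epsY_true = 0.05, epsU_true = 0.11,
                         rupture_eps = 0.15, end_stress_frac = 0.2,
                         slack_mm = 0.5, noise_sd_g = 0.02,
                         d = 0.1, L0 = 5, rate = 0.067, sample_hz = 100,
                         seed = 1L,
                         disp_gain_mv = 400, disp_offset_mv = 120,
                         load_gain_mv = 25, load_offset_mv = -3) {
  if (!(0 < epsY_true && epsY_true < epsU_true && epsU_true < rupture_eps))
    stop_tm("need 0 < epsY < epsU < rupture_eps", "parameter")
  if (!(sigmaY_true > 0 && sigmaU_true > sigmaY_true))
    stop_tm("need 0 < sigmaY < sigmaU", "parameter")
  if (any(c(E_true, d, L0, rate, sample_hz) <= 0) ||
      slack_mm < 0 || noise_sd_g < 0)
    stop_tm("scale parameters must be positive (slack and noise non-negative)",
            "parameter")
  if (!(end_stress_frac > 0 && end_stress_frac <= 1))
    stop_tm("end_stress_frac must lie in (0, 1]", "parameter")
  m <- E_true * epsY_true / sigmaY_true
  if (m <= 1)
    stop_tm("infeasible toe: need E * epsY > sigmaY (slope must rise to E)",
            "parameter")
  Dp <- epsU_true - epsY_true
  rise <- sigmaU_true - sigmaY_true
  if (E_true * Dp < rise || E_true * Dp > 2 * rise)
    stop_tm("infeasible plastic segment: need sigmaU - sigmaY <= E * (epsU - epsY) <= 2 * (sigmaU - sigmaY)",
            "parameter")
  cquad <- (rise - E_true * Dp) / Dp^2   # <= 0: concave cap
  u_Y <- sigmaY_true * epsY_true / (m + 1)
  u_P <- sigmaY_true * Dp + E_true * Dp^2 / 2 + cquad * Dp^3 / 3
  u_R <- sigmaU_true * (1 + end_stress_frac) / 2 * (rupture_eps - epsU_true)
  p <- list(E_true = E_true, sigmaY_true = sigmaY_true,
            sigmaU_true = sigmaU_true, epsY_true = epsY_true,
            epsU_true = epsU_true, rupture_eps = rupture_eps,
            end_stress_frac = end_stress_frac,
            slack_mm = slack_mm, noise_sd_g = noise_sd_g,
            d = d, L0 = L0, rate = rate, sample_hz = sample_hz,
            seed = as.integer(seed),
            disp_gain_mv = disp_gain_mv, disp_offset_mv = disp_offset_mv,
            load_gain_mv = load_gain_mv, load_offset_mv = load_offset_mv,
            m = m, cquad = cquad,
            truth = list(E = E_true, sigma_Y = sigmaY_true, eps_Y = epsY_true,
                         sigma_U = sigmaU_true, eps_U = epsU_true,
                         rupture_eps = rupture_eps,
                         u_Y = u_Y, u_P = u_P, u_R = u_R,
                         u_F = u_P + u_R, u_0 = u_Y + u_P + u_R))
  class(p) <- "trace_params"
  p
}

#' Evaluate the noise-free synthetic stress-strain law
#' @param eps strain values (may be negative: slack region, stress 0).
#' @param p a [trace_params()].
#' @return stress, MPa.
#' @export
true_stress <- function(eps, p) {
  stopifnot(inherits(p, "trace_params"))
  s <- numeric(length(eps))
  toe <- eps > 0 & eps <= p$epsY_true
  s[toe] <- p$sigmaY_true * (eps[toe] / p$epsY_true)^p$m
  pl <- eps > p$epsY_true & eps <= p$epsU_true
  t <- eps[pl] - p$epsY_true
  s[pl] <- p$sigmaY_true + p$E_true * t + p$cquad * t^2
  post <- eps > p$epsU_true
  s[post] <- p$sigmaU_true *
    (1 - (1 - p$end_stress_frac) * (eps[post] - p$epsU_true) /
       (p$rupture_eps - p$epsU_true))
  s
}

#' Simulate a raw mtt-dialect tensile trace
#'
#' Emulates a slack-then-taut load-displacement record: the grip-to-grip
#' displacement advances at the crosshead rate from `L0 - slack_mm`; the
#' specimen is taut once the displacement reaches the nominal length L0, and
#' from there the load follows the analytic stress-strain law of
#' [trace_params()] converted to gram-force through the specimen geometry.
#' Gaussian load noise is added, and the raw mV channels are affine maps of
#' the physical columns.
#'
#' @param p a [trace_params()].
#' @param specimen_id id attached to the trace.
#' @return list with `trace` (an [mtt_trace()]) and `truth` (the analytic
#'   property set from `p$truth`, plus the geometry used).
#' @export
simulate_trace <- function(p = trace_params(), specimen_id = "mtt01_1_t1a") {
  stopifnot(inherits(p, "trace_params"))
  dt <- 1 / p$sample_hz
  total_travel <- p$slack_mm + p$L0 * p$rupture_eps
  n <- floor(total_travel / (p$rate * dt)) + 1L
  t_s <- (seq_len(n) - 1L) * dt
  disp <- (p$L0 - p$slack_mm) + p$rate * t_s
  eps <- (disp - p$L0) / p$L0
  A <- pi * p$d^2 / 4
  g2n <- 9.80665e-3
  load <- true_stress(eps, p) * A / g2n
  load <- with_seed(p$seed, load + stats::rnorm(n, 0, p$noise_sd_g))
  trace <- mtt_trace(time_ms = t_s * 1000,
                     disp_mv = p$disp_gain_mv * disp + p$disp_offset_mv,
                     load_mv = p$load_gain_mv * load + p$load_offset_mv,
                     disp_mm = disp, load_g = load,
                     specimen_id = specimen_id)
  truth <- p$truth
  truth$d <- p$d
  truth$A <- A
  truth$L0 <- p$L0
  list(trace = trace, truth = truth)
}

#' Parameters for a bimodal fibril-diameter population
#'
#' Two-component Gaussian mixture on the scale of the observed fibril
#' subpopulations (small-diameter component near 100 nm, large-diameter
#' component near 250 nm).
#'
#' @param mu1,mu2 component means, nm (`mu1 < mu2`).
#' @param sd1,sd2 component SDs, nm.
#' @param weight1 probability of the first component, in (0, 1).
#' @param n number of fibrils to draw.
#' @param seed RNG seed.
#' @return list of class `mixture_params`.
#' @export
mixture_params <- function(mu1 = 100, mu2 = 250, sd1 = 30, sd2 = 50,
                           weight1 = 0.5, n = 2000L, seed = 1L) {
  if (!(mu1 < mu2)) stop_tm("need mu1 < mu2", "parameter")
  if (!(sd1 > 0 && sd2 > 0)) stop_tm("SDs must be positive", "parameter")
  if (!(weight1 > 0 && weight1 < 1))
    stop_tm("weight1 must lie in (0, 1)", "parameter")
  structure(list(mu1 = mu1, mu2 = mu2, sd1 = sd1, sd2 = sd2,
                 weight1 = weight1, n = as.integer(n), seed = as.integer(seed)),
            class = "mixture_params")
}

#' Simulate fibril diameters from a two-component Gaussian mixture
#'
#' Each draw comes from component 1 with probability `weight1`, else from
#' component 2; non-positive draws are redrawn from the same component.
#' Component assignments are kept, so per-component recovery can be checked
#' directly.
#'
#' @param p a [mixture_params()].
#' @return list with `diameters` (nm), `component` (1/2 per draw) and
#'   `truth` (the generating parameters and realised per-component counts).
#' @export
simulate_diameters <- function(p = mixture_params()) {
  stopifnot(inherits(p, "mixture_params"))
  with_seed(p$seed, {
    comp <- 1L + stats::rbinom(p$n, 1L, 1 - p$weight1)
    mu <- c(p$mu1, p$mu2)[comp]
    sd_ <- c(p$sd1, p$sd2)[comp]
    x <- stats::rnorm(p$n, mu, sd_)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- stats::rnorm(sum(bad), mu[bad], sd_[bad])
    }
    list(diameters = x, component = comp,
         truth = list(mu = c(p$mu1, p$mu2), sd = c(p$sd1, p$sd2),
                      weight = c(p$weight1, 1 - p$weight1),
                      n_component = tabulate(comp, 2L)))
  })
}

#' Parameters for a packed-disc fibril field
#'
#' @param width,height field-of-view dimensions, nm (nominal 5 x 4 um TEM
#'   field).
#' @param target_rho area fraction to reach; must be below 0.91 (disc
#'   packing feasibility), and in practice below about 0.55 for random
#'   sequential placement to terminate within the attempt budget.
#' @param mixture a [mixture_params()] supplying the diameter distribution.
#' @param max_attempts placement attempt budget (default 1e5).
#' @param seed RNG seed.
#' @return list of class `field_params`.
#' @export
field_params <- function(width = 5000, height = 4000, target_rho = 0.5,
                         mixture = mixture_params(), max_attempts = 1e5,
                         seed = 1L) {
  if (!(width > 0 && height > 0))
    stop_tm("field dimensions must be positive", "parameter")
  if (!(target_rho >= 0 && target_rho < 0.91))
    stop_tm("target_rho must lie in [0, 0.91)", "parameter")
  structure(list(width = width, height = height, target_rho = target_rho,
                 mixture = mixture, max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "field_params")
}

# Area of a disc clipped to the axis-aligned field rectangle [0,w] x [0,h],
# by adaptive quadrature of the chord height. Discs fully inside are exact.
circle_rect_area <- function(cx, cy, r, w, h) {
  if (cx - r >= 0 && cx + r <= w && cy - r >= 0 && cy + r <= h)
    return(pi * r^2)
  height_at <- function(x) {
    s <- sqrt(pmax(0, r^2 - (x - cx)^2))
    pmax(0, pmin(h, cy + s) - pmax(0, cy - s))
  }
  lo <- max(0, cx - r)
  hi <- min(w, cx + r)
  if (hi <= lo) return(0)
  # split where the circle crosses the top/bottom field edges (and at the
  # centre), so each piece is smooth for the quadrature
  brk <- c(lo, hi, cx)
  for (edge in c(h - cy, -cy)) {
    if (abs(edge) < r) {
      s <- sqrt(r^2 - edge^2)
      brk <- c(brk, cx - s, cx + s)
    }
  }
  brk <- sort(unique(pmin(hi, pmax(lo, brk))))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    if (brk[i + 1L] - brk[i] < 1e-12) next
    total <- total + stats::integrate(height_at, brk[i], brk[i + 1L],
                                      rel.tol = 1e-10,
                                      subdivisions = 500L)$value
  }
  total
}

#' Simulate a non-overlapping packed-disc fibril field
#'
#' Random sequential placement: diameters are drawn from the mixture,
#' centres uniformly over the field; a candidate overlapping an already
#' placed disc is rejected. Discs crossing the field boundary are clipped
#' and their clipped area counted (they are flagged as boundary
#' part-fibrils). Placement continues until the bookkept area fraction
#' reaches `target_rho` or the attempt budget is exhausted, in which case a
#' feasibility error suggests lowering the target.
#'
#' @param p a [field_params()].
#' @param image_id id attached to the record.
#' @return list with `record` (a [fibril_image_record()] whose
#'   `fibril_areas` are the exact bookkept clipped areas), `diameters`
#'   (full, unclipped, per placed disc) and `truth` (the exact `rho` and the
#'   placement bookkeeping).
#' @export
simulate_field <- function(p = field_params(), image_id = "Scan001") {
  stopifnot(inherits(p, "field_params"))
  S <- p$width * p$height
  with_seed(p$seed, {
    xs <- ys <- rs <- areas <- numeric(0)
    boundary <- logical(0)
    acc_area <- 0
    attempts <- 0L
    while (acc_area / S < p$target_rho && attempts < p$max_attempts) {
      attempts <- attempts + 1L
      # draw a component, then a positive diameter from it
      repeat {
        if (stats::runif(1) < p$mixture$weight1)
          D <- stats::rnorm(1, p$mixture$mu1, p$mixture$sd1)
        else
          D <- stats::rnorm(1, p$mixture$mu2, p$mixture$sd2)
        if (D > 0) break
      }
      r <- D / 2
      cx <- stats::runif(1, 0, p$width)
      cy <- stats::runif(1, 0, p$height)
      if (length(xs) > 0 &&
          any((cx - xs)^2 + (cy - ys)^2 < (r + rs)^2)) next
      a <- circle_rect_area(cx, cy, r, p$width, p$height)
      if (a <= 0) next
      xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r)
      areas <- c(areas, a)
      boundary <- c(boundary, a < pi * r^2 - 1e-9)
      acc_area <- acc_area + a
    }
    if (acc_area / S < p$target_rho)
      stop_tm(sprintf("could not reach target_rho = %.3f within %d attempts (reached %.3f); lower the target",
                      p$target_rho, p$max_attempts, acc_area / S),
              "feasibility")
    record <- fibril_image_record(image_id, areas,
                                  field_width = p$width,
                                  field_height = p$height,
                                  boundary = boundary)
    list(record = record,
         diameters = 2 * rs,
         truth = list(rho = sum(areas) / S, n_discs = length(areas),
                      attempts = attempts))
  })
}
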