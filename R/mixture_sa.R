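#' Simulated-annealing configuration for the mixture fit
#'
#' Mirrors the parameter file of the original fibril-subpopulation program.
#' Proposal ranges for component means and SDs are affine maps of a
#' uniform(0,1) draw, `value = A + B * u`; they are stored here as
#' `[min, max] = [A, A + B]` intervals, one per component.
#'
#' @param lower,upper fibril-diameter limits, nm; proposals are confined to
#'   this interval. Default to the histogram range at fit time when `NULL`.
#' @param n_config maximum configurations explored per temperature step
#'   (NCONFIG, default 100).
#' @param n_succ_limit Metropolis acceptances allowed before moving to the
#'   next temperature step (NSUCCLIMIT, default 10).
#' @param n_trials number of temperature steps (NTRIALS, default 100).
#' @param seed RNG seed (SEED); the fit is a pure function of it.
#' @param temperature initial annealing temperature (default 0.5).
#' @param t_factor temperature reduction factor per step (default 0.9),
#'   in (0, 1).
#' @param ngauss number of Gaussian components; two subpopulations in this
#'   workflow, but general values are accepted for nested-model checks.
#' @param mu_ranges,sd_ranges list of `c(min, max)` proposal intervals, one
#'   per component; derived from the histogram when `NULL` (means span
#'   `[lower, upper]`, SDs span `[bin width / 2, (upper - lower) / 3]`).
#' @param nonneg solve component amplitudes by non-negative least squares
#'   (default); `FALSE` uses plain least squares for fidelity experiments.
#' @return list of class `sa_config`.
#' @export
sa_config <- function(lower = NULL, upper = NULL,
                      n_config = 100L, n_succ_limit = 10L, n_trials = 100L,
                      seed = 1L, temperature = 0.5, t_factor = 0.9,
                      ngauss = 2L, mu_ranges = NULL, sd_ranges = NULL,
                      nonneg = TRUE) {
  if (!(temperature > 0)) stop_tm("initial temperature must be positive", "contract")
  if (!(t_factor > 0 && t_factor < 1))
    stop_tm("temperature reduction factor must lie in (0, 1)", "contract")
  if (!is.null(lower) && !is.null(upper) && !(lower < upper))
    stop_tm("`lower` must be below `upper`", "contract")
  ngauss <- as.integer(ngauss)
  if (ngauss < 1L) stop_tm("ngauss must be at least 1", "contract")
  structure(list(lower = lower, upper = upper,
                 n_config = as.integer(n_config),
                 n_succ_limit = as.integer(n_succ_limit),
                 n_trials = as.integer(n_trials),
                 seed = as.integer(seed),
                 temperature = temperature, t_factor = t_factor,
                 ngauss = ngauss,
                 mu_ranges = mu_ranges, sd_ranges = sd_ranges,
                 nonneg = isTRUE(nonneg)),
            class = "sa_config")
}

#' Read a simulated-annealing parameter file
#'
#' Plain `KEY value...` lines using the original program's keys: NCONFIG,
#' NSUCCLIMIT, NTRIALS, SEED, TEMPERATURE, TFACTR, LOWER, UPPER, NGAUSS,
#' and per-component MUA/MUB, SDA/SDB amplification coefficients (one pair
#' of values per line, components in order). The affine convention
#' `value = A + B * u`, u ~ uniform(0,1), maps to the `[A, A + B]` proposal
#' intervals of [sa_config()].
#'
#' @param path parameter file path.
#' @return an [sa_config()].
#' @export
read_sa_parfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines))])
  lines <- lines[!startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    kv[[toupper(parts[1])]] <- as.numeric(parts[-1])
  }
  need1 <- function(key, default = NULL) {
    if (!is.null(kv[[key]])) kv[[key]][1] else default
  }
  ab_to_range <- function(a, b) c(a, a + b)
  mu_ranges <- sd_ranges <- NULL
  if (!is.null(kv$MUA) && !is.null(kv$MUB))
    mu_ranges <- Map(ab_to_range, kv$MUA, kv$MUB)
  if (!is.null(kv$SDA) && !is.null(kv$SDB))
    sd_ranges <- Map(ab_to_range, kv$SDA, kv$SDB)
  sa_config(lower = need1("LOWER"), upper = need1("UPPER"),
            n_config = need1("NCONFIG", 100), n_succ_limit = need1("NSUCCLIMIT", 10),
            n_trials = need1("NTRIALS", 100), seed = need1("SEED", 1),
            temperature = need1("TEMPERATURE", 0.5),
            t_factor = need1("TFACTR", 0.9),
            ngauss = need1("NGAUSS", 2),
            mu_ranges = mu_ranges, sd_ranges = sd_ranges)
}

#' Unit-amplitude Gaussian component
#'
#' The component shape used by the mixture fit:
#' \eqn{\exp(-(x-\mu)^2 / (2\sigma^2))}, i.e. value 1 at the mean. Component
#' proportions are carried separately as fitted amplitudes.
#'
#' @param x evaluation grid (bin centres), nm.
#' @param mu component mean, nm.
#' @param sigma component SD, nm; must be positive.
#' @return numeric vector of component values on `x`.
#' @export
gaussian_component <- function(x, mu, sigma) {
  if (!(sigma > 0)) stop_tm("sigma must be positive", "domain")
  exp(-((x - mu)^2) / (2 * sigma^2))
}

# Exact NNLS for two columns via KKT case enumeration; falls back to
# pracma's Lawson-Hanson solver for general column counts.
nnls_solve <- function(M, y) {
  k <- ncol(M)
  if (k <= 2L) {
    cand <- list()
    g <- crossprod(M)           # k x k
    b <- crossprod(M, y)
    sol <- tryCatch(solve(g, b), error = function(e) NULL)
    if (!is.null(sol) && all(sol >= 0)) return(as.numeric(sol))
    for (j in seq_len(k)) {
      a <- max(0, b[j] / g[j, j])
      x <- numeric(k); x[j] <- a
      cand[[length(cand) + 1L]] <- x
    }
    cand[[length(cand) + 1L]] <- numeric(k)
    sse <- vapply(cand, function(x) sum((y - M %*% x)^2), numeric(1))
    return(cand[[which.min(sse)]])
  }
  as.numeric(pracma::lsqnonneg(M, y)$x)
}

#' Solve component amplitudes by least squares
#'
#' Given the component profiles evaluated on the bin centres, finds the
#' amplitudes minimising the squared deviation from the target histogram.
#' Amplitudes are proportions and are constrained non-negative by default.
#'
#' @param target normalised frequencies (one per bin).
#' @param components matrix of component values, one column per component.
#' @param nonneg constrain amplitudes to be non-negative (default `TRUE`).
#' @return numeric vector of amplitudes.
#' @export
solve_amplitudes <- function(target, components, nonneg = TRUE) {
  components <- as.matrix(components)
  if (nrow(components) < 2L) stop_tm("need at least 2 bins", "contract")
  if (length(target) != nrow(components))
    stop_tm("target length must match component rows", "contract")
  if (qr(components)$rank < ncol(components))
    stop_tm("component matrix is rank deficient (identical components?)",
            "degenerate_fit")
  if (nonneg) nnls_solve(components, target)
  else as.numeric(qr.solve(components, target))
}

#' Metropolis acceptance rule
#'
#' Accept a proposed configuration if it improves the objective
#' (`delta <= 0`); otherwise accept with probability
#' \eqn{\exp(-\Delta/T)}.
#'
#' @param delta objective change (proposed minus current).
#' @param temperature annealing temperature T > 0.
#' @param u uniform(0,1) draw; supplied for reproducibility, drawn from the
#'   current RNG stream by default.
#' @return logical: accept the proposal?
#' @export
metropolis_accept <- function(delta, temperature, u = stats::runif(1)) {
  if (!(temperature > 0)) stop_tm("temperature must be positive", "domain")
  delta <= 0 || u < exp(-delta / temperature)
}

# SSE between the normalised histogram and the amplitude-solved composite.
# Degenerate component draws (rank deficiency) score Inf so the annealer
# simply never accepts them.
mixture_objective <- function(target, centres, mu, sigma, nonneg = TRUE) {
  M <- vapply(seq_along(mu),
              function(i) gaussian_component(centres, mu[i], sigma[i]),
              numeric(length(centres)))
  amps <- tryCatch(solve_amplitudes(target, M, nonneg = nonneg),
                   error = function(e) NULL)
  if (is.null(amps)) return(list(sse = Inf, amplitudes = rep(NA_real_, length(mu))))
  list(sse = sum((target - as.numeric(M %*% amps))^2), amplitudes = amps)
}

resolve_ranges <- function(h, cfg) {
  lower <- if (is.null(cfg$lower)) h$bin_edges[1] else cfg$lower
  upper <- if (is.null(cfg$upper)) h$bin_edges[length(h$bin_edges)] else cfg$upper
  if (!(lower < upper)) stop_tm("lower limit must be below upper", "configuration")
  w <- diff(h$bin_edges)[1]
  mu_ranges <- cfg$mu_ranges
  if (is.null(mu_ranges))
    mu_ranges <- replicate(cfg$ngauss, c(lower, upper), simplify = FALSE)
  sd_ranges <- cfg$sd_ranges
  if (is.null(sd_ranges))
    sd_ranges <- replicate(cfg$ngauss, c(w / 2, (upper - lower) / 3),
                           simplify = FALSE)
  clip <- function(r) c(max(r[1], lower), min(r[2], upper))
  mu_ranges <- lapply(mu_ranges, clip)
  bad <- vapply(mu_ranges, function(r) !(r[1] <= r[2]), logical(1))
  if (any(bad))
    stop_tm("a mean proposal range lies entirely outside [lower, upper]",
            "configuration")
  sd_ranges <- lapply(sd_ranges, function(r) c(max(r[1], 1e-6), r[2]))
  bad <- vapply(sd_ranges, function(r) !(r[1] <= r[2]), logical(1))
  if (any(bad)) stop_tm("an SD proposal range is empty", "configuration")
  list(lower = lower, upper = upper, mu = mu_ranges, sd = sd_ranges)
}

#' Fit a Gaussian mixture to a diameter histogram by simulated annealing
#'
#' Decomposes the primary diameter-frequency distribution into `ngauss`
#' Gaussian subpopulations. At each of `n_trials` temperature steps, up to
#' `n_config` candidate configurations are proposed by drawing fresh
#' component means and SDs uniformly from their proposal ranges; each
#' candidate's amplitudes are solved by (non-negative) least squares against
#' the normalised histogram and the summed squared residual is the annealing
#' objective. Proposals are accepted by the Metropolis rule; after
#' `n_succ_limit` acceptances the temperature is multiplied by `t_factor`
#' and the next step begins. The best configuration ever seen is returned,
#' with components sorted by increasing mean (so `mu[1]` is the
#' small-diameter subpopulation D1 and `mu[2]` the large-diameter D2).
#'
#' @param h a [fibril_histogram()].
#' @param cfg an [sa_config()].
#' @return object of class `mixture_fit`: `mu`, `sigma`, `amplitude`
#'   (per component, sorted by mean), `objective` (residual SSE),
#'   `trace` (best objective after each temperature step, non-increasing),
#'   `fitted` (composite on the bin centres), `centres`, and the resolved
#'   configuration.
#' @export
sa_fit <- function(h, cfg = sa_config()) {
  stopifnot(inherits(h, "fibril_histogram"), inherits(cfg, "sa_config"))
  centres <- bin_midpoints(h)
  if (length(centres) < 2L) stop_tm("histogram needs at least 2 bins", "contract")
  target <- h$norm_freq
  rng <- resolve_ranges(h, cfg)
  k <- cfg$ngauss

  with_seed(cfg$seed, {
    draw_state <- function() {
      mu <- vapply(rng$mu, function(r) stats::runif(1, r[1], r[2]), numeric(1))
      sd <- vapply(rng$sd, function(r) stats::runif(1, r[1], r[2]), numeric(1))
      list(mu = mu, sd = sd)
    }
    cur <- draw_state()
    cur_obj <- mixture_objective(target, centres, cur$mu, cur$sd, cfg$nonneg)
    best <- list(state = cur, obj = cur_obj)
    temp <- cfg$temperature
    trace <- numeric(cfg$n_trials)
    for (step in seq_len(cfg$n_trials)) {
      nsucc <- 0L
      for (k_cfg in seq_len(cfg$n_config)) {
        prop <- draw_state()
        prop_obj <- mixture_objective(target, centres, prop$mu, prop$sd,
                                      cfg$nonneg)
        delta <- prop_obj$sse - cur_obj$sse
        if (is.finite(delta) && metropolis_accept(delta, temp)) {
          cur <- prop
          cur_obj <- prop_obj
          nsucc <- nsucc + 1L
          if (cur_obj$sse < best$obj$sse) best <- list(state = cur, obj = cur_obj)
        } else if (!is.finite(delta) && prop_obj$sse < cur_obj$sse) {
          # current was Inf (degenerate start): take any finite proposal
          cur <- prop; cur_obj <- prop_obj
          if (cur_obj$sse < best$obj$sse) best <- list(state = cur, obj = cur_obj)
        }
        if (nsucc >= cfg$n_succ_limit) break
      }
      trace[step] <- best$obj$sse
      temp <- temp * cfg$t_factor
    }

    ord <- order(best$state$mu)
    comp <- vapply(seq_len(k),
                   function(i) gaussian_component(centres, best$state$mu[i],
                                                  best$state$sd[i]),
                   numeric(length(centres)))
    fitted <- as.numeric(comp %*% best$obj$amplitudes)
    structure(list(mu = best$state$mu[ord],
                   sigma = best$state$sd[ord],
                   amplitude = best$obj$amplitudes[ord],
                   objective = best$obj$sse,
                   trace = trace,
                   fitted = fitted,
                   centres = centres,
                   target = target,
                   ranges = rng,
                   config = cfg),
              class = "mixture_fit")
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture fit (%d components, SSE = %.3g):\n",
              length(x$mu), x$objective))
  for (i in seq_along(x$mu))
    cat(sprintf("  D%d: mean %.1f nm, SD %.1f nm, amplitude %.3f\n",
                i, x$mu[i], x$sigma[i], x$amplitude[i]))
  invisible(x)
}

#' Refinement run of the annealed mixture fit
#'
#' Re-runs [sa_fit()] with the proposal ranges re-centred on the first run's
#' estimates and their widths multiplied by `shrink` (clipped to the
#' diameter limits), then returns the better of the two fits by objective.
#' The refinement run uses `cfg$seed + 1` so the pair of runs remains a pure
#' function of the original seed.
#'
#' @param first a completed `mixture_fit`.
#' @param h the histogram it was fitted to.
#' @param cfg the original [sa_config()].
#' @param shrink fraction of the original range widths to keep (default
#'   0.25).
#' @return the better `mixture_fit`, with attribute `refined` flagging
#'   whether the refinement run won.
#' @export
refine_fit <- function(first, h, cfg, shrink = 0.25) {
  stopifnot(inherits(first, "mixture_fit"))
  if (!(shrink > 0)) stop_tm("shrink must be positive", "contract")
  rng <- first$ranges
  recentre <- function(centre, r) {
    half <- shrink * (r[2] - r[1]) / 2
    c(centre - half, centre + half)
  }
  # component order in `first` is sorted by mean; ranges follow that order
  cfg2 <- cfg
  cfg2$mu_ranges <- Map(recentre, first$mu, rng$mu)
  cfg2$sd_ranges <- Map(recentre, first$sigma, rng$sd)
  cfg2$sd_ranges <- lapply(cfg2$sd_ranges, function(r) c(max(r[1], 1e-6), r[2]))
  cfg2$lower <- rng$lower
  cfg2$upper <- rng$upper
  cfg2$seed <- cfg$seed + 1L
  second <- sa_fit(h, cfg2)
  if (second$objective <= first$objective) {
    attr(second, "refined") <- TRUE
    second
  } else {
    attr(first, "refined") <- FALSE
    first
  }
}
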