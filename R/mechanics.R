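#' Analysis configuration for the mechanics pipeline
#'
#' Mirrors the inputs of the original trace-analysis program: fascicle
#' diameter, an estimate of the rupture strain, the order of the smoothing
#' polynomial, and whether to zero the trace automatically at 1% of maximum
#' load.
#'
#' @param diameter fascicle diameter d in mm (mean of repeated thickness
#'   measurements). Cross-sectional area is \eqn{A = \pi d^2/4}.
#' @param laststrainpt estimate of the strain at rupture; samples beyond it
#'   are excluded from the rupture segment.
#' @param orderpoly integer 2-7, degree of the polynomial fitted to the
#'   stress-strain data between the origin and the maximum-stress point
#'   before differentiation.
#' @param loadat1percent logical; `TRUE` zeroes the trace at the first sample
#'   whose load reaches `load_cutoff_fraction` of the maximum load. `FALSE`
#'   is the manual fallback for noisy low-load data: supply `start_index`.
#' @param load_cutoff_fraction fraction of maximum load defining the
#'   zero-load point (default 0.01, i.e. 1%).
#' @param start_index caller-chosen origin sample when `loadat1percent` is
#'   `FALSE`.
#' @param gram_force_to_newton conversion constant, N per gram-force
#'   (standard gravity, 9.80665e-3).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(diameter, laststrainpt, orderpoly = 5L,
                            loadat1percent = TRUE,
                            load_cutoff_fraction = 0.01,
                            start_index = NULL,
                            gram_force_to_newton = 9.80665e-3) {
  if (!is_scalar_number(diameter) || diameter <= 0)
    stop_tm("`diameter` must be a positive number (mm)", "contract")
  if (!is_scalar_number(laststrainpt) || laststrainpt <= 0)
    stop_tm("`laststrainpt` must be a positive strain", "contract")
  orderpoly <- as.integer(orderpoly)
  if (!(orderpoly %in% 2:7))
    stop_tm("`orderpoly` must be an integer between 2 and 7", "contract")
  if (!is_scalar_number(load_cutoff_fraction) ||
      load_cutoff_fraction <= 0 || load_cutoff_fraction >= 1)
    stop_tm("`load_cutoff_fraction` must lie in (0, 1)", "contract")
  if (!isTRUE(loadat1percent) && is.null(start_index))
    stop_tm("manual truncation (loadat1percent = FALSE) requires `start_index`",
            "contract")
  structure(list(diameter = diameter, laststrainpt = laststrainpt,
                 orderpoly = orderpoly, loadat1percent = isTRUE(loadat1percent),
                 load_cutoff_fraction = load_cutoff_fraction,
                 start_index = start_index,
                 gram_force_to_newton = gram_force_to_newton),
            class = "analysis_config")
}

#' Fascicle geometry
#'
#' @param d mean fascicle thickness (mm), from repeated measurements along
#'   the specimen axis; the cross section is modelled as circular.
#' @param d_sem standard error of the thickness mean (mm), optional.
#' @param L0 nominal specimen length (mm); usually set by [zero_trace()].
#' @return list of class `fascicle_geometry` with area `A = pi * d^2 / 4`
#'   in mm^2.
#' @export
fascicle_geometry <- function(d, d_sem = NA_real_, L0 = NA_real_) {
  if (!is_scalar_number(d) || d <= 0)
    stop_tm("thickness d must be positive", "geometry")
  if (!is.na(L0) && L0 <= 0) stop_tm("L0 must be positive", "geometry")
  structure(list(d = d, d_sem = d_sem, A = pi * d^2 / 4, L0 = L0),
            class = "fascicle_geometry")
}

#' Zero a raw trace at the load cutoff
#'
#' Removes the slack region of a slack-to-taut tensile record. The maximum
#' load is found, the zero-load point is the first sample whose load reaches
#' `load_cutoff_fraction` of it (default 1%), the nominal length L0 is set to
#' the displacement at that point, earlier samples are discarded, and both
#' displacement and load are offset to zero at the new origin. With
#' `loadat1percent = FALSE` the caller's `start_index` is used instead.
#'
#' @param trace an [mtt_trace()].
#' @param cfg an [analysis_config()].
#' @return list with `disp` (mm, zeroed), `load` (g, zeroed), `L0` (mm) and
#'   `origin_index` into the raw trace.
#' @export
zero_trace <- function(trace, cfg) {
  stopifnot(inherits(trace, "mtt_trace"), inherits(cfg, "analysis_config"))
  load <- trace$load_g
  disp <- trace$disp_mm
  pmax_ <- max(load)
  if (!(pmax_ > 0)) stop_tm("maximum load is not positive", "degenerate_trace")
  if (cfg$loadat1percent) {
    cutoff <- cfg$load_cutoff_fraction * pmax_
    origin <- match(TRUE, load >= cutoff)
    if (is.na(origin))
      stop_tm("no sample reaches the load cutoff", "degenerate_trace")
  } else {
    origin <- as.integer(cfg$start_index)
    if (origin < 1L || origin > length(load))
      stop_tm("start_index outside the trace", "contract")
  }
  L0 <- disp[origin]
  if (!(L0 > 0))
    stop_tm("nominal length L0 is not positive at the zero-load point",
            "geometry")
  idx <- origin:length(load)
  list(disp = disp[idx] - disp[origin],
       load = load[idx] - load[origin],
       L0 = L0, origin_index = origin)
}

#' Convert a zeroed trace to a stress-strain curve
#'
#' Strain is displacement over nominal length, \eqn{\varepsilon = x/L_0};
#' stress is load over cross-sectional area, \eqn{\sigma = P/A}, converted to
#' MPa via the gram-force-to-newton constant (N/mm^2 = MPa).
#'
#' @param zeroed result of [zero_trace()].
#' @param geometry a [fascicle_geometry()], or `NULL` to build one from
#'   `cfg$diameter`.
#' @param cfg an [analysis_config()].
#' @return object of class `stress_strain_curve`: list with `strain`,
#'   `stress` (MPa), `L0`, `A`, and a `landmarks` list (`O`, `p`, `q`, `r`)
#'   filled in by the locator functions.
#' @export
to_stress_strain <- function(zeroed, geometry = NULL, cfg) {
  if (is.null(geometry)) geometry <- fascicle_geometry(cfg$diameter)
  if (!(geometry$A > 0)) stop_tm("zero cross-sectional area", "geometry")
  if (!(zeroed$L0 > 0)) stop_tm("non-positive L0", "geometry")
  strain <- zeroed$disp / zeroed$L0
  stress <- zeroed$load * cfg$gram_force_to_newton / geometry$A
  structure(list(strain = strain, stress = stress,
                 L0 = zeroed$L0, A = geometry$A,
                 landmarks = list(O = 1L, p = NA_integer_,
                                  q = NA_integer_, r = NA_integer_)),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("stress-strain curve: %d samples, max stress %.2f MPa at strain %.4f\n",
              length(x$strain), max(x$stress), x$strain[which.max(x$stress)]))
  invisible(x)
}

# Odd moving-window length for the local polynomial smoother: a fixed
# fraction of the origin-to-peak segment, bounded so the window always
# exceeds the polynomial degree and fits inside the segment.
sg_window <- function(q, orderpoly, frac = 0.2) {
  w <- max(orderpoly + 2L, floor(frac * q))
  if (w %% 2L == 0L) w <- w + 1L
  wmax <- if (q %% 2L == 1L) q else q - 1L
  min(w, wmax)
}

#' Locate the yield point (point of inflexion)
#'
#' The stress-strain samples between the origin and the maximum-stress point
#' q are smoothed by a moving least-squares polynomial of degree `orderpoly`
#' (Savitzky-Golay, window one fifth of the segment), and the derivative
#' d\eqn{\sigma}/d\eqn{\varepsilon} of the smoothed curve is evaluated on
#' the sample grid. The yield point p is where that derivative is maximal;
#' the stiffness E is the maximum slope, and the yield stress and strain are
#' the smoothed stress and the grid strain at p. The local fit is run on the
#' sample index, with the derivative rescaled by the local strain spacing,
#' so unevenly sampled strain grids are handled exactly. Constant-slope ties
#' break to the earliest index; a p on the grid boundary is flagged.
#'
#' @param curve a `stress_strain_curve`.
#' @param orderpoly polynomial degree (2-7).
#' @return list with `p`, `q`, `sigma_Y`, `eps_Y`, `E`, `fitted` (smoothed
#'   stress on the grid up to q) and `boundary` (logical flag).
#' @export
locate_yield <- function(curve, orderpoly = 5L) {
  orderpoly <- as.integer(orderpoly)
  q <- which.max(curve$stress)
  if (q < orderpoly + 2L)
    stop_tm(sprintf("need at least orderpoly + 2 = %d samples before maximum stress, have %d",
                    orderpoly + 2L, q), "numeric")
  x <- curve$strain[1:q]
  y <- curve$stress[1:q]
  if (any(diff(x) <= 0))
    stop_tm("strain grid must be strictly increasing up to the peak for the local polynomial fit",
            "numeric")
  w <- sg_window(q, orderpoly)
  yfit <- signal::sgolayfilt(y, p = orderpoly, n = w, m = 0L)
  # d(sigma)/d(eps) = (d sigma/d index) / (d eps/d index); both from the
  # same local polynomial filter, so uneven grids cancel exactly
  dydi <- signal::sgolayfilt(y, p = orderpoly, n = w, m = 1L)
  dxdi <- signal::sgolayfilt(x, p = orderpoly, n = w, m = 1L)
  dydx <- dydi / dxdi
  dmax <- max(dydx)
  tol <- 1e-8 * max(1, abs(dmax))
  p <- which(dydx >= dmax - tol)[1]  # earliest index on ties
  boundary <- p == 1L || p == q
  if (boundary)
    warn_tm("maximum slope found at the boundary of the origin-to-peak segment",
            "boundary")
  list(p = p, q = q, sigma_Y = yfit[p], eps_Y = x[p], E = dydx[p],
       fitted = yfit, boundary = boundary)
}

#' Locate the rupture point
#'
#' The rupture index r is the last sample whose strain does not exceed the
#' caller's rupture-strain estimate `laststrainpt`, provided that estimate
#' lies beyond the maximum-stress strain; otherwise the final recorded sample
#' is used and a warning raised.
#'
#' @param curve a `stress_strain_curve`.
#' @param laststrainpt estimated rupture strain.
#' @param q index of maximum stress (located first).
#' @return rupture index r (r >= q).
#' @export
locate_rupture <- function(curve, laststrainpt, q = which.max(curve$stress)) {
  n <- length(curve$strain)
  if (laststrainpt <= curve$strain[q]) {
    warn_tm("laststrainpt is below the strain at maximum stress; using the final sample",
            "rupture_fallback")
    return(n)
  }
  r <- max(which(curve$strain <= laststrainpt))
  max(r, q)
}

#' Partition the strain energy density along the curve
#'
#' Strain energy densities (MPa = MJ/m^3) are trapezium-rule integrals of
#' stress over strain: resilience u_Y from the origin to the yield point p,
#' plastic work u_P from p to the maximum-stress point q, rupture work u_R
#' from q to the rupture point r. Segments share their endpoint samples, so
#' u_0 = u_Y + u_P + u_R holds exactly; u_F = u_P + u_R.
#'
#' @param curve a `stress_strain_curve`.
#' @param p,q,r landmark indices with `1 <= p <= q <= r`.
#' @return list with `u_Y`, `u_P`, `u_R`, `u_F`, `u_0`.
#' @export
strain_energy_partition <- function(curve, p, q, r) {
  n <- length(curve$strain)
  if (!(1L <= p && p <= q && q <= r && r <= n))
    stop_tm("landmarks must satisfy O <= p <= q <= r", "contract")
  eps <- curve$strain[1:r]
  sig <- curve$stress[1:r]
  if (any(diff(eps) < 0))
    stop_tm("strain must be non-decreasing over the integrated segment",
            "integration")
  # per-interval trapezoid contributions, summed per segment so the total
  # is exactly the sum of the parts
  contrib <- if (r > 1L) (sig[-1] + sig[-r]) / 2 * diff(eps) else numeric(0)
  seg_sum <- function(a, b) if (b > a) sum(contrib[a:(b - 1L)]) else 0
  u_Y <- seg_sum(1L, p)
  u_P <- seg_sum(p, q)
  u_R <- seg_sum(q, r)
  list(u_Y = u_Y, u_P = u_P, u_R = u_R, u_F = u_P + u_R,
       u_0 = u_Y + u_P + u_R)
}

# Tag stage failures so pipeline callers can see where a trace failed.
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      msg <- paste0("[", stage, "] ", conditionMessage(e))
      cls <- class(e)
      cond <- structure(class = unique(c("tendonmech_stage_error", cls)),
                        list(message = msg, call = NULL, stage = stage))
      stop(cond)
    })
}

#' Derive the full mechanical-property set for one specimen
#'
#' Composes the pipeline: slack removal ([zero_trace()]), unit conversion
#' ([to_stress_strain()]), landmark location ([locate_yield()],
#' [locate_rupture()]) and energy partition ([strain_energy_partition()]).
#' Stage failures are re-thrown with the failing stage named in the message.
#'
#' @param trace an [mtt_trace()].
#' @param cfg an [analysis_config()].
#' @param geometry optional [fascicle_geometry()]; built from `cfg$diameter`
#'   when absent.
#' @return object of class `mechanical_properties`: yield stress/strain
#'   `sigma_Y`/`eps_Y`, stiffness `E` (maximum slope, MPa), strength
#'   `sigma_U` and its strain `eps_U`, energies `u_Y`, `u_P`, `u_R`,
#'   `u_F`, `u_0` (MPa), and the ratios `ratio_Y = u_Y/sigma_Y`,
#'   `ratio_F = u_F/sigma_U`. The processed curve and landmarks are attached.
#' @export
derive_properties <- function(trace, cfg, geometry = NULL) {
  zeroed <- with_stage("zero_trace", zero_trace(trace, cfg))
  curve <- with_stage("to_stress_strain", to_stress_strain(zeroed, geometry, cfg))
  yld <- with_stage("locate_yield", locate_yield(curve, cfg$orderpoly))
  r <- with_stage("locate_rupture",
                  locate_rupture(curve, cfg$laststrainpt, q = yld$q))
  en <- with_stage("strain_energy_partition",
                   strain_energy_partition(curve, yld$p, yld$q, r))
  curve$landmarks <- list(O = 1L, p = yld$p, q = yld$q, r = r)
  sigma_U <- curve$stress[yld$q]
  props <- list(sigma_Y = unname(yld$sigma_Y), eps_Y = unname(yld$eps_Y),
                E = unname(yld$E),
                sigma_U = sigma_U, eps_U = curve$strain[yld$q],
                u_Y = en$u_Y, u_P = en$u_P, u_R = en$u_R,
                u_F = en$u_F, u_0 = en$u_0,
                ratio_Y = en$u_Y / unname(yld$sigma_Y),
                ratio_F = en$u_F / sigma_U,
                specimen_id = attr(trace, "specimen_id"),
                boundary_warning = yld$boundary)
  attr(props, "curve") <- curve
  class(props) <- "mechanical_properties"
  props
}

#' @export
print.mechanical_properties <- function(x, ...) {
  cat(sprintf("mechanical properties (%s):\n", x$specimen_id))
  cat(sprintf("  E = %.1f MPa   sigma_Y = %.2f MPa at eps_Y = %.4f\n",
              x$E, x$sigma_Y, x$eps_Y))
  cat(sprintf("  sigma_U = %.2f MPa at eps_U = %.4f\n", x$sigma_U, x$eps_U))
  cat(sprintf("  u_Y = %.3f  u_P = %.3f  u_R = %.3f  u_F = %.3f  u_0 = %.3f MPa\n",
              x$u_Y, x$u_P, x$u_R, x$u_F, x$u_0))
  invisible(x)
}

#' Turn one property set into a specimen-level sheet row
#'
#' @param props a `mechanical_properties` object.
#' @param age_group,sample,file identifying columns of the deposited layout.
#' @return one-row data frame with the specimen-sheet columns.
#' @export
properties_row <- function(props, age_group, sample,
                           file = props$specimen_id) {
  data.frame(age_group = age_group, sample = sample, file = file,
             sY = props$sigma_Y, eY = props$eps_Y, E = props$E,
             sU = props$sigma_U, eU = props$eps_U,
             uY = props$u_Y, uP = props$u_P, uR = props$u_R,
             uF = props$u_F, u0 = props$u_0,
             uY_sY = props$ratio_Y, uF_sU = props$ratio_F,
             stringsAsFactors = FALSE)
}

#' Aggregate specimen properties to tails and age groups
#'
#' Technical replicates (fascicle segments) are averaged within each tail
#' (mouse), then tail means are averaged within each age group. Group
#' dispersion is the SEM over tails, so n is the number of mice, not the
#' number of specimens; it is missing for single-tail groups.
#'
#' @param records specimen-level data frame with `age_group`, `sample`
#'   columns and the derived-property columns (as from [properties_row()]).
#' @return list with `tail` (per-mouse means) and `age_group` (group means
#'   and SEMs) data frames matching the deposited worksheet layouts.
#' @export
aggregate_properties <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_tm("no specimen records to aggregate", "contract")
  if (!all(c("age_group", "sample") %in% names(records)))
    stop_tm("records need `age_group` and `sample` columns", "contract")
  miss <- setdiff(mean_props, names(records))
  if (length(miss) > 0L)
    stop_tm(paste0("records lack property column(s): ",
                   paste(miss, collapse = ", ")), "contract")

  key <- interaction(records$age_group, records$sample, drop = TRUE)
  tails <- do.call(rbind, lapply(split(records, key), function(d) {
    out <- data.frame(age_group = d$age_group[1], sample = d$sample[1],
                      stringsAsFactors = FALSE)
    for (pp in mean_props) out[[pp]] <- mean(d[[pp]])
    out
  }))
  rownames(tails) <- NULL
  tails <- tails[order(tails$age_group, tails$sample), , drop = FALSE]
  attr(tails, "level") <- "tail"

  groups <- do.call(rbind, lapply(split(tails, tails$age_group), function(d) {
    out <- data.frame(age_group = d$age_group[1], stringsAsFactors = FALSE)
    for (pp in mean_props) out[[paste0("mean_", pp)]] <- mean(d[[pp]])
    for (pp in mean_props) out[[paste0("sem_", pp)]] <- sem(d[[pp]])
    out$n_tails <- nrow(d)
    out
  }))
  rownames(groups) <- NULL
  attr(groups, "level") <- "age_group"
  list(tail = tails, age_group = groups)
}
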