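# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Raw mtt-dialect text body (tab-delimited, 5 columns) from column vectors.
mtt_body <- function(time, dmv, lmv, dmm, lg, header = FALSE) {
  rows <- mapply(function(...) paste(c(...), collapse = "\t"),
                 time, dmv, lmv, dmm, lg)
  if (header)
    rows <- c(paste(c("Time", "Displacement", "Load", "mm", "grams"),
                    collapse = "\t"), rows)
  paste(rows, collapse = "\n")
}

# A clean taut-from-the-start linear-elastic trace: load ramps linearly
# with displacement; useful when closed-form answers are needed.
linear_trace <- function(n = 101, L0 = 5, slope_g_per_mm = 40, d = 0.1) {
  disp <- L0 + seq(0, 1, length.out = n)
  # offset so the first sample already exceeds the 1% cutoff
  load <- slope_g_per_mm * (disp - L0) + 1
  mtt_trace(time_ms = seq(0, by = 10, length.out = n),
            disp_mv = disp * 400, load_mv = load * 25,
            disp_mm = disp, load_g = load, specimen_id = "mtt01_1_t1a")
}

# Specimen-level property data frame with known values for aggregation.
specimen_records <- function(age_groups, samples, values) {
  df <- data.frame(age_group = age_groups, sample = samples,
                   stringsAsFactors = FALSE)
  for (pp in c("sY", "sU", "E", "uY", "uP", "uR", "uF", "u0", "uY_sY", "uF_sU"))
    df[[pp]] <- values
  df
}

# Realistic-scale random tensile parameters with feasible landmarks.
draw_trace_params <- function(seed) {
  set.seed(seed)
  E <- runif(1, 400, 700)
  epsY <- runif(1, 0.04, 0.06)
  sY <- E * epsY / runif(1, 1.3, 1.8)
  Dp <- runif(1, 0.04, 0.07)
  sU <- sY + E * Dp / runif(1, 1.2, 1.8)
  trace_params(E_true = E, sigmaY_true = sY, sigmaU_true = sU,
               epsY_true = epsY, epsU_true = epsY + Dp,
               rupture_eps = epsY + Dp + runif(1, 0.03, 0.05),
               seed = seed)
}
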