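# Reading/writing the tabular artifacts: raw traces, property sheets,
# structural sheets and the run log.

test_that("mtt reader transcribes the five columns and skips a header", {
  body <- "0\t10\t5\t0.0\t0.1\n100\t20\t6\t0.5\t0.2\n200\t30\t9\t1.0\t0.9"
  tr <- read_mtt_trace(body, id = "mtt01_1_t1a")
  expect_s3_class(tr, "mtt_trace")
  expect_equal(tr$disp_mm, c(0, 0.5, 1.0))
  expect_equal(tr$load_g, c(0.1, 0.2, 0.9))
  expect_equal(tr$time_ms, c(0, 100, 200))

  with_header <- paste("Time\tDisplacement\tLoad\tmm\tgrams", body, sep = "\n")
  tr2 <- read_mtt_trace(with_header, id = "mtt01_1_t1a")
  expect_equal(as.data.frame(tr2), as.data.frame(tr))
})

test_that("mtt reader rejects narrow bodies and validates monotonicity", {
  four_cols <- "0\t10\t5\t0.0\n100\t20\t6\t0.5"
  expect_error(read_mtt_trace(four_cols), class = "tendonmech_format")
  # the error names the offending line
  expect_error(read_mtt_trace(four_cols), "line 1")

  expect_error(read_mtt_trace("0\t1\t2\t3\t4"),
               class = "tendonmech_insufficient_data")

  # time must strictly increase; never silently repaired
  bad_time <- "0\t1\t1\t0\t0\n0\t2\t2\t1\t1\n10\t3\t3\t2\t2"
  expect_error(read_mtt_trace(bad_time), class = "tendonmech_format")
  # crosshead travel cannot reverse
  bad_disp <- "0\t1\t1\t2\t0\n10\t2\t2\t1\t1"
  expect_error(read_mtt_trace(bad_disp), class = "tendonmech_format")

  # non-parsable rows are dropped with a warning, not fatal
  messy <- "0\t10\t5\t0.0\t0.1\n100\tx\t6\t0.5\t0.2\n200\t30\t9\t1.0\t0.9"
  expect_warning(tr <- read_mtt_trace(messy), class = "tendonmech_bad_rows")
  expect_equal(nrow(tr), 2L)
})

test_that("mtt write/read round trip is lossless and order-preserving", {
  sim <- simulate_trace(trace_params(seed = 11))
  path <- withr::local_tempfile(fileext = ".txt")
  write_mtt_trace(sim$trace, path)
  back <- read_mtt_trace(path)
  expect_equal(back$disp_mm, sim$trace$disp_mm, tolerance = 1e-9)
  expect_equal(back$load_g, sim$trace$load_g, tolerance = 1e-9)
  expect_equal(back$time_ms, sim$trace$time_ms, tolerance = 1e-9)
  expect_false(is.unsorted(back$time_ms))
})

test_that("specimen ids parse into age group, sample, fascicle and segment", {
  p <- parse_specimen_id("mtt04_2_t13b")
  expect_true(p$parsed)
  expect_equal(p$age_group, "04M")
  expect_equal(p$sample, 2L)
  expect_equal(p$fascicle, 13L)
  expect_equal(p$segment, "b")
  expect_warning(q <- parse_specimen_id("oddname.txt"),
                 class = "tendonmech_malformed_id")
  expect_false(q$parsed)
  expect_equal(q$id, "oddname.txt")
})

test_that("property sheets mirror the deposited layouts and round trip", {
  sim <- simulate_trace(trace_params(seed = 2))
  props <- derive_properties(sim$trace,
                             analysis_config(0.1, laststrainpt = 0.2))
  row <- properties_row(props, age_group = "01M", sample = 1)
  expect_equal(ncol(row), 15L)  # columns A-O of the specimen worksheet
  expect_identical(names(row), property_sheet_columns("specimen"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_property_sheet(row, "specimen", path)
  back <- read_property_sheet(path, "specimen")
  for (nm in setdiff(names(row), c("age_group", "sample", "file")))
    expect_equal(back[[nm]], row[[nm]], tolerance = 1e-9)

  # empty record list gives a header-only sheet
  write_property_sheet(list(), "age_group", path)
  hdr <- read_property_sheet(path, "age_group")
  expect_equal(nrow(hdr), 0L)
  expect_equal(ncol(hdr), 21L)  # group means then SEMs

  # mixed levels are a contract violation
  tails <- row
  attr(tails, "level") <- "tail"
  expect_error(write_property_sheet(tails, "specimen", path),
               class = "tendonmech_contract")
})

test_that("structural sheets round trip and validate frequencies", {
  h1 <- fibril_histogram(c(50, 100, 150, 200), c(2, 6, 2), group_id = "01M")
  expect_equal(h1$norm_freq, c(0.2, 0.6, 0.2))
  h2 <- fibril_histogram(c(50, 100, 150, 200), c(1, 1, 3), group_id = "35M")

  hp <- withr::local_tempfile(fileext = ".csv")
  write_fibril_histogram_sheet(list(`01M` = h1, `35M` = h2), hp)
  tabs <- read_fibril_tables(hist_path = hp)
  expect_equal(tabs$histograms[["01M"]]$freq, h1$freq)
  expect_equal(tabs$histograms[["35M"]]$norm_freq, h2$norm_freq,
               tolerance = 1e-9)
  expect_equal(tabs$histograms[["01M"]]$bin_edges, h1$bin_edges)

  ap <- withr::local_tempfile(fileext = ".csv")
  fr <- data.frame(group = c("01M", "01M", "04M"),
                   image_id = c("Scan001", "Scan002", "Scan079"),
                   rho = c(0.56, 0.58, 0.85))
  write_area_fraction_sheet(fr, ap)
  back <- read_fibril_tables(area_path = ap)$area_fractions
  expect_equal(back$rho[back$group == "01M"], c(0.56, 0.58), tolerance = 1e-9)
  expect_equal(back$rho[back$group == "04M"], 0.85, tolerance = 1e-9)

  # negative frequencies are a data error; all-zero groups honour the config
  expect_error(fibril_histogram(c(0, 10, 20), c(-1, 2)),
               class = "tendonmech_data")
  zp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bin,freq_a,freq_b", "0,0,1", "10,0,3"), zp)
  expect_error(read_fibril_tables(hist_path = zp), class = "tendonmech_data")
  flagged <- read_fibril_tables(hist_path = zp, empty_groups = "flag")
  expect_equal(attr(flagged$histograms, "empty_groups"), "a")
  expect_named(flagged$histograms, "b")
})

test_that("run log lines are appended in order and parse back exactly", {
  lp <- withr::local_tempfile(fileext = ".txt")
  entry <- list(specimen = "mtt01_1_t1a", diameter = 0.1,
                laststrainpt = 0.2, orderpoly = 5L, loadat1percent = "y")
  append_run_log(entry, lp)
  append_run_log(entry, lp)
  lines <- readLines(lp)
  expect_length(lines, 2L)
  for (key in c("diameter", "laststrainpt", "orderpoly", "loadat1percent"))
    expect_match(lines[1], key, fixed = TRUE)

  parsed <- parse_run_log(lp)[[1]]
  expect_equal(parsed$specimen, "mtt01_1_t1a")
  expect_equal(parsed$diameter, 0.1, tolerance = 1e-12)
  expect_equal(parsed$orderpoly, 5)
  expect_equal(parsed$loadat1percent, "y")

  expect_error(append_run_log(list(specimen = "x", diameter = 0.1), lp),
               class = "tendonmech_contract")
})
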