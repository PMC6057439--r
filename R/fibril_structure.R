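#' Equivalent-circle diameter from a fibril cross-sectional area
#'
#' Fibril cross sections are modelled as circular, so area and diameter are
#' the exact inverses \eqn{a_f = \pi D^2/4} and \eqn{D = \sqrt{4 a_f/\pi}}.
#'
#' @param a_f cross-sectional area(s), nm^2; must be positive.
#' @return diameter(s) D, nm.
#' @export
diameter_from_area <- function(a_f) {
  if (any(!is.finite(a_f)) || any(a_f <= 0))
    stop_tm("fibril areas must be positive", "domain")
  sqrt(4 * a_f / pi)
}

#' Fibril cross-sectional area from an equivalent-circle diameter
#' @param D diameter(s), nm; must be positive.
#' @return area(s) a_f = pi D^2 / 4, nm^2.
#' @export
area_from_diameter <- function(D) {
  if (any(!is.finite(D)) || any(D <= 0))
    stop_tm("fibril diameters must be positive", "domain")
  pi * D^2 / 4
}

#' One transmission electron micrograph's traced fibrils
#'
#' @param image_id image identifier, conventionally `ScanNNN`.
#' @param fibril_areas traced cross-sectional areas, nm^2. Part fibrils at
#'   the image boundary contribute their clipped areas.
#' @param field_width,field_height field-of-view dimensions, nm (the nominal
#'   field is 5 x 4 um, i.e. 2e7 nm^2).
#' @param boundary logical vector flagging boundary part-fibrils; these are
#'   counted in the area fraction but excluded from diameter statistics
#'   (a clipped area underestimates the diameter).
#' @return list of class `fibril_image_record` with the area fraction `rho`
#'   precomputed.
#' @export
fibril_image_record <- function(image_id, fibril_areas,
                                field_width = 5000, field_height = 4000,
                                boundary = rep(FALSE, length(fibril_areas))) {
  if (!(field_width > 0) || !(field_height > 0))
    stop_tm("field dimensions must be positive", "domain")
  if (any(fibril_areas < 0)) stop_tm("negative fibril area", "data")
  if (length(boundary) != length(fibril_areas))
    stop_tm("`boundary` must match `fibril_areas` in length", "contract")
  structure(list(image_id = image_id,
                 fibril_areas = as.numeric(fibril_areas),
                 boundary = boundary,
                 field_width = field_width, field_height = field_height,
                 field_area = field_width * field_height,
                 rho = sum(fibril_areas) / (field_width * field_height)),
            class = "fibril_image_record")
}

#' @export
print.fibril_image_record <- function(x, ...) {
  cat(sprintf("fibril image %s: %d fibrils (%d at boundary), field %.0f x %.0f nm, rho = %.4f\n",
              x$image_id, length(x$fibril_areas), sum(x$boundary),
              x$field_width, x$field_height, x$rho))
  invisible(x)
}

#' Fibril area fraction of one image
#'
#' The collagen fibril area fraction is the ratio of the summed traced
#' cross-sectional areas (boundary part-fibrils counted as their clipped
#' areas) to the field-of-view area.
#'
#' @param image a [fibril_image_record()].
#' @return rho, dimensionless.
#' @export
area_fraction <- function(image) {
  stopifnot(inherits(image, "fibril_image_record"))
  if (!(image$field_area > 0)) stop_tm("field area must be positive", "domain")
  if (any(image$fibril_areas < 0)) stop_tm("negative fibril area", "data")
  sum(image$fibril_areas) / image$field_area
}

#' Two-stage randomised image sampling
#'
#' Reproduces the unbiased image-selection protocol: every image in the pool
#' is tagged with a uniform(0,1) draw and the pool is sorted ascending by
#' tag (stable sort, so tied tags preserve input order); the number of images
#' to keep is itself drawn uniformly from the integers 4-11; the first
#' `min(N_c, pool size)` sorted images are returned. A pure function of
#' `(pool, seed)`.
#'
#' @param pool character vector of image ids.
#' @param seed integer seed.
#' @return character vector of selected ids, with attribute `n_target`
#'   (the drawn N_c). Pools smaller than N_c truncate with a warning.
#' @export
sample_images <- function(pool, seed) {
  if (length(pool) == 0L) stop_tm("image pool is empty", "contract")
  with_seed(seed, {
    tags <- stats::runif(length(pool))
    sorted <- pool[order(tags)]        # order() is stable
    n_c <- sample(4:11, 1L)
    if (n_c > length(pool))
      warn_tm(sprintf("pool of %d images truncates the drawn N_c = %d",
                      length(pool), n_c), "truncation")
    sel <- sorted[seq_len(min(n_c, length(pool)))]
    attr(sel, "n_target") <- n_c
    sel
  })
}

#' Diameter-frequency histogram
#'
#' @param bin_edges strictly increasing, contiguous bin edges, nm (length
#'   = number of bins + 1). Bins are right-open `[a, b)`.
#' @param freq non-negative counts per bin.
#' @param group_id optional age-group label.
#' @return list of class `fibril_histogram` with `bin_edges`, `freq`,
#'   `norm_freq` (summing to 1) and `group_id`.
#' @export
fibril_histogram <- function(bin_edges, freq, group_id = NA_character_) {
  if (length(bin_edges) != length(freq) + 1L)
    stop_tm("need one more bin edge than frequency", "contract")
  if (any(diff(bin_edges) <= 0))
    stop_tm("bin edges must be strictly increasing", "contract")
  if (any(freq < 0)) stop_tm("negative frequency", "data")
  total <- sum(freq)
  if (total <= 0) stop_tm("histogram has zero total frequency", "empty_histogram")
  structure(list(bin_edges = as.numeric(bin_edges), freq = as.numeric(freq),
                 norm_freq = as.numeric(freq) / total, group_id = group_id),
            class = "fibril_histogram")
}

#' @export
print.fibril_histogram <- function(x, ...) {
  cat(sprintf("fibril histogram%s: %d bins on [%g, %g) nm, %g fibrils\n",
              if (is.na(x$group_id)) "" else paste0(" (", x$group_id, ")"),
              length(x$freq), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$freq)))
  invisible(x)
}

#' Bin midpoints of a histogram
#' @param h a [fibril_histogram()].
#' @return numeric vector of bin centres, nm.
#' @export
bin_midpoints <- function(h) {
  e <- h$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Build a diameter histogram with fixed-width right-open bins
#'
#' Bins are `[k w, (k+1) w)` from zero up to cover the largest diameter; a
#' diameter on a boundary goes to the bin whose lower edge it equals.
#'
#' @param diameters fibril diameters, nm.
#' @param bin_width bin width w, nm (default 20).
#' @param group_id optional group label.
#' @return a [fibril_histogram()].
#' @export
build_histogram <- function(diameters, bin_width = 20, group_id = NA_character_) {
  if (length(diameters) == 0L)
    stop_tm("no diameters to bin", "empty_histogram")
  if (!(bin_width > 0)) stop_tm("bin width must be positive", "contract")
  if (any(diameters < 0)) stop_tm("negative diameter", "data")
  nbin <- floor(max(diameters) / bin_width) + 1L
  edges <- seq(0, by = bin_width, length.out = nbin + 1L)
  idx <- floor(diameters / bin_width) + 1L   # right-open bins
  freq <- tabulate(idx, nbins = nbin)
  fibril_histogram(edges, freq, group_id = group_id)
}

#' Group-level area-fraction summary
#'
#' Per-group mean of the per-image area fractions and the SEM over images,
#' as in the deposited summary columns. SEM is missing for single-image
#' groups.
#'
#' @param fractions data frame with columns `group` and `rho` (one row per
#'   image), e.g. from [read_fibril_tables()].
#' @return data frame with `group`, `n_images`, `mean_rho`, `sem_rho`.
#' @export
group_area_fraction <- function(fractions) {
  if (!is.data.frame(fractions) || nrow(fractions) == 0L)
    stop_tm("no area fractions to summarise", "contract")
  stopifnot(all(c("group", "rho") %in% names(fractions)))
  out <- do.call(rbind, lapply(split(fractions, fractions$group), function(d) {
    data.frame(group = d$group[1], n_images = nrow(d),
               mean_rho = mean(d$rho), sem_rho = sem(d$rho),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
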