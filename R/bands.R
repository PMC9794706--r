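#' Build a 100-m elevational band system
#'
#' Bands are identified by their elevation marks and are inclusive at both
#' domain ends, so a 200-4800 m domain at 100-m width yields
#' (4800 - 200)/100 + 1 = 47 bands. This is the convention under which a
#' species ranging 1300-1700 m occupies exactly the five bands
#' 1300, 1400, 1500, 1600, 1700.
#'
#' @param domain_min,domain_max domain limits (m); `domain_min <= domain_max`.
#' @param width band width (m), default 100; the span must divide evenly.
#' @return An `elevation_bands` object: the ordered band labels plus domain
#'   metadata.
#' @examples
#' build_bands(200, 4800)          # 47 bands
#' build_bands(0, 500, 100)$labels # 0 100 ... 500
#' @export
build_bands <- function(domain_min, domain_max, width = 100) {
  stopifnot(is.numeric(domain_min), is.numeric(domain_max), is.numeric(width))
  if (width <= 0) stop("band width must be positive")
  if (domain_min > domain_max) stop("domain_min must not exceed domain_max")
  rem <- (domain_max - domain_min) %% width
  if (rem != 0) {
    stop(sprintf("domain span %g is not divisible by width %g (remainder %g)",
                 domain_max - domain_min, width, rem))
  }
  structure(
    list(labels = seq(domain_min, domain_max, by = width),
         domain_min = domain_min, domain_max = domain_max, width = width),
    class = "elevation_bands"
  )
}

#' @export
print.elevation_bands <- function(x, ...) {
  cat(sprintf("<elevation_bands> %d bands of %g m over %g-%g m\n",
              length(x$labels), x$width, x$domain_min, x$domain_max))
  invisible(x)
}

#' @export
length.elevation_bands <- function(x) length(x$labels)

# Snap a range conservatively onto the band system: the lower limit rounds
# down, the upper limit rounds up, then both are clipped to the domain.
# A band touched by the raw range is never dropped.
snap_ranges <- function(ranges, bands) {
  w <- bands$width
  mn <- floor(ranges$min_elev / w) * w
  mx <- ceiling(ranges$max_elev / w) * w
  outside <- mx < bands$domain_min | mn > bands$domain_max
  data.frame(
    species = as.character(ranges$species),
    min_elev = pmax(mn, bands$domain_min),
    max_elev = pmin(mx, bands$domain_max),
    outside = outside,
    stringsAsFactors = FALSE
  )
}

#' Interpolate species ranges into per-band richness
#'
#' Each species is assumed present in every band between its lower and upper
#' elevational limits (range interpolation). Limits are snapped conservatively
#' (min down, max up) to the band marks and clipped to the domain; species
#' whose range lies wholly outside the domain are excluded with a warning.
#'
#' @param ranges a species range table: data frame with columns
#'   `species`, `min_elev`, `max_elev` (see [read_ranges()]).
#' @param bands an [build_bands()] object.
#' @return A `richness_profile`: data frame with columns `band` and
#'   `richness`, one row per band.
#' @examples
#' b <- build_bands(200, 4800)
#' r <- data.frame(species = "Fagus chienii", min_elev = 1300, max_elev = 1700)
#' p <- interpolate_richness(r, b)
#' p$band[p$richness > 0]   # 1300 1400 1500 1600 1700
#' @export
interpolate_richness <- function(ranges, bands) {
  stopifnot(inherits(bands, "elevation_bands"))
  labels <- bands$labels
  if (nrow(ranges) == 0) {
    prof <- data.frame(band = labels, richness = 0L)
    return(structure(prof, class = c("richness_profile", "data.frame"),
                     n_species = 0L))
  }
  if (any(ranges$min_elev > ranges$max_elev)) {
    stop("range table has rows with min_elev > max_elev")
  }
  snapped <- snap_ranges(ranges, bands)
  if (any(snapped$outside)) {
    warning(sprintf(
      "%d species wholly outside the band domain were excluded: %s",
      sum(snapped$outside),
      paste(utils::head(snapped$species[snapped$outside], 5), collapse = ", ")))
    snapped <- snapped[!snapped$outside, , drop = FALSE]
  }
  counts <- vapply(
    labels,
    function(L) sum(snapped$min_elev <= L & snapped$max_elev >= L),
    integer(1)
  )
  structure(data.frame(band = labels, richness = counts),
            class = c("richness_profile", "data.frame"),
            n_species = nrow(snapped))
}

#' @export
print.richness_profile <- function(x, ...) {
  occ <- x$band[x$richness > 0]
  cat(sprintf("<richness_profile> %d bands, %s species\n",
              nrow(x), attr(x, "n_species") %||% "?"))
  if (length(occ)) {
    pk <- profile_summary(x)
    cat(sprintf("  occupied %g-%g m; peak %d at %g m\n",
                min(occ), max(occ), pk$peak_count, pk$peak_band))
  } else {
    cat("  no occupied bands\n")
  }
  invisible(x)
}

#' Fit the richness-elevation polynomial trend
#'
#' Ordinary least squares of band richness on raw powers of elevation.
#' The default degree of 4 accommodates the hump-plus-decline shapes typical
#' of elevational richness profiles; the degree used is always reported.
#'
#' @param profile a [interpolate_richness()] result.
#' @param degree polynomial degree (>= 1); the profile must have more than
#'   `degree + 1` bands.
#' @return A `trend_fit`: degree, coefficients, `r_squared` and the underlying
#'   `lm` fit.
#' @export
fit_polynomial_trend <- function(profile, degree = 4) {
  stopifnot(degree >= 1)
  if (nrow(profile) <= degree + 1) {
    stop("profile must have more than degree + 1 bands")
  }
  if (stats::var(profile$richness) == 0) {
    warning("richness is constant across bands; r_squared defined as 0")
    fit <- stats::lm(richness ~ 1, data = profile)
    return(structure(list(degree = degree,
                          coefficients = stats::coef(fit),
                          r_squared = 0, model = fit),
                     class = "trend_fit"))
  }
  fit <- stats::lm(richness ~ poly(band, degree, raw = TRUE), data = profile)
  structure(
    list(degree = degree,
         coefficients = stats::setNames(stats::coef(fit),
                                        c("(Intercept)",
                                          paste0("elev^", seq_len(degree)))),
         r_squared = summary(fit)$r.squared,
         model = fit),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Polynomial richness-elevation trend (degree %d)\n", x$degree))
  cat(sprintf("  R-squared: %.*f\n", digits, x$r_squared))
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' Summarise a richness profile
#'
#' Peak and minimum bands of the profile. The minimum is taken over occupied
#' bands only; ties for either are broken toward the lowest elevation.
#'
#' @param profile a [interpolate_richness()] result.
#' @return A list with `peak_band`, `peak_count`, `min_band`, `min_count` and
#'   `occupied_domain` (lowest and highest band with nonzero richness).
#'   An all-zero profile yields the empty sentinel `list(empty = TRUE)` with
#'   `NA` fields.
#' @export
profile_summary <- function(profile) {
  occ <- profile$richness > 0
  if (!any(occ)) {
    return(list(empty = TRUE, peak_band = NA_real_, peak_count = NA_integer_,
                min_band = NA_real_, min_count = NA_integer_,
                occupied_domain = c(NA_real_, NA_real_)))
  }
  pk <- which.max(profile$richness)                 # first max = lowest band
  occ_idx <- which(occ)
  mn <- occ_idx[which.min(profile$richness[occ_idx])]
  list(
    empty = FALSE,
    peak_band = profile$band[pk],
    peak_count = profile$richness[pk],
    min_band = profile$band[mn],
    min_count = profile$richness[mn],
    occupied_domain = c(min(profile$band[occ]), max(profile$band[occ]))
  )
}
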