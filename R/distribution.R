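#' Discrete orientation distributions relative to a reference
#'
#' An `orientation_distribution` is a discrete probability distribution over
#' signed orientation offsets (degrees) relative to an absolute reference
#' orientation. Offsets are signed with the package-wide convention: positive
#' is clockwise, negative is counter-clockwise. All experiment stimuli are
#' parameterised by one of these objects.
#'
#' @param support numeric vector of strictly increasing offsets in degrees,
#'   each in (-90, 90].
#' @param mass numeric vector of non-negative probabilities aligned with
#'   `support`; normalised to sum to one.
#' @param reference absolute reference orientation in degrees; wrapped into
#'   \[0, 180).
#' @return an object of class `orientation_distribution` with fields
#'   `support`, `mass`, `reference`.
#' @seealso [build_skewed_gaussian()], [build_skewed_uniform()],
#'   [distribution_stats()]
#' @examples
#' d <- orientation_distribution(c(-10, 0, 10), c(1, 2, 1), reference = 90)
#' distribution_stats(d)
#' @export
orientation_distribution <- function(support, mass, reference = 90) {
  if (length(support) != length(mass)) {
    stop("`support` and `mass` must have the same length", call. = FALSE)
  }
  if (length(support) == 0) {
    stop("`support` must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(support)) || any(!is.finite(mass))) {
    stop("`support` and `mass` must be finite", call. = FALSE)
  }
  if (any(mass < 0)) {
    stop("`mass` must be non-negative", call. = FALSE)
  }
  if (sum(mass) <= 0) {
    stop("`mass` must have positive total", call. = FALSE)
  }
  if (is.unsorted(support, strictly = TRUE)) {
    stop("`support` must be strictly increasing", call. = FALSE)
  }
  if (any(support <= -90) || any(support > 90)) {
    stop("`support` offsets must lie in (-90, 90]", call. = FALSE)
  }
  structure(
    list(
      support = as.numeric(support),
      mass = as.numeric(mass) / sum(mass),
      reference = wrap_orientation(as.numeric(reference)[1])
    ),
    class = "orientation_distribution"
  )
}

#' @export
print.orientation_distribution <- function(x, ...) {
  s <- distribution_stats(x)
  cat("orientation_distribution:", length(x$support), "support points in [",
      min(x$support), ",", max(x$support), "] deg; reference",
      x$reference, "deg\n")
  cat(sprintf("  offsets: mean %.2f, median %.2f, mode %.2f deg\n",
              s[["mean"]], s[["median"]], s[["mode"]]))
  invisible(x)
}

#' @export
as.data.frame.orientation_distribution <- function(x, ...) {
  data.frame(offset_deg = x$support, mass = x$mass,
             orientation_deg = wrap_orientation(x$reference + x$support))
}

#' Specification of a piecewise (skewed) Gaussian orientation distribution
#'
#' Each half of a Gaussian centred on the reference is given its own standard
#' deviation, sampling interval and truncation, producing distributions whose
#' mean, median and mode can be pulled apart. `half_weighting` controls how
#' the two halves share probability mass: `"density-matched"` keeps the
#' density continuous at the mode (half mass proportional to the side SD);
#' `"equal-mass"` gives each half mass 1/2, which pins the median to the mode.
#'
#' @param sigma_ccw,sigma_cw standard deviations (degrees, >= 0) of the
#'   counter-clockwise and clockwise halves. A side with SD 0 contributes a
#'   point mass at 0 only.
#' @param interval_ccw,interval_cw sampling steps in degrees (> 0).
#' @param truncation_ccw,truncation_cw extent of each half in degrees
#'   (> 0, <= 90).
#' @param half_weighting `"density-matched"` or `"equal-mass"`.
#' @return an object of class `skewed_gaussian_spec`.
#' @examples
#' skewed_gaussian_spec(sigma_ccw = 30, sigma_cw = 0)
#' @export
skewed_gaussian_spec <- function(sigma_ccw, sigma_cw,
                                 interval_ccw = 2.5, interval_cw = 2.5,
                                 truncation_ccw = 45, truncation_cw = 45,
                                 half_weighting = c("density-matched",
                                                    "equal-mass")) {
  half_weighting <- match.arg(half_weighting)
  if (sigma_ccw < 0 || sigma_cw < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (sigma_ccw + sigma_cw <= 0) {
    stop("at least one half must have a positive standard deviation",
         call. = FALSE)
  }
  if (interval_ccw <= 0 || interval_cw <= 0) {
    stop("sampling intervals must be > 0", call. = FALSE)
  }
  if (truncation_ccw <= 0 || truncation_cw <= 0 ||
      truncation_ccw > 90 || truncation_cw > 90) {
    stop("truncations must lie in (0, 90]", call. = FALSE)
  }
  if (interval_ccw > truncation_ccw || interval_cw > truncation_cw) {
    stop("sampling interval exceeds the truncation of its half", call. = FALSE)
  }
  if (half_weighting == "equal-mass" && (sigma_ccw == 0 || sigma_cw == 0)) {
    stop("equal-mass weighting is undefined when a half has SD 0",
         call. = FALSE)
  }
  structure(
    list(sigma_ccw = sigma_ccw, sigma_cw = sigma_cw,
         interval_ccw = interval_ccw, interval_cw = interval_cw,
         truncation_ccw = truncation_ccw, truncation_cw = truncation_cw,
         half_weighting = half_weighting),
    class = "skewed_gaussian_spec"
  )
}

#' Specification of a skewed uniform orientation distribution
#'
#' Orientations clockwise and counter-clockwise of the reference are sampled
#' uniformly over ranges of different extents, with each half carrying total
#' mass 1/2, so the junction between the halves is the median by construction.
#'
#' @param range_ccw,range_cw half ranges in degrees (> 0); their sum must not
#'   exceed 180.
#' @param interval sampling step in degrees (> 0).
#' @return an object of class `skewed_uniform_spec`.
#' @examples
#' skewed_uniform_spec(range_ccw = 75, range_cw = 15)
#' @export
skewed_uniform_spec <- function(range_ccw, range_cw, interval = 2.5) {
  if (range_ccw <= 0 || range_cw <= 0) {
    stop("half ranges must be > 0", call. = FALSE)
  }
  if (range_ccw + range_cw > 180) {
    stop("total range must not exceed 180 degrees", call. = FALSE)
  }
  if (interval <= 0) {
    stop("`interval` must be > 0", call. = FALSE)
  }
  if (interval > min(range_ccw, range_cw)) {
    stop("`interval` exceeds the smaller half range", call. = FALSE)
  }
  structure(
    list(range_ccw = range_ccw, range_cw = range_cw, interval = interval),
    class = "skewed_uniform_spec"
  )
}

# Half-Gaussian weights at offsets x (>= 0 magnitudes) for side SD s.
# s == 0 collapses to a point mass at 0.
.half_gauss_weights <- function(x, s) {
  if (s == 0) as.numeric(x == 0) else exp(-x^2 / (2 * s^2))
}

#' Build a piecewise-Gaussian orientation distribution
#'
#' Constructs the discrete distribution described by a
#' [skewed_gaussian_spec()]: the counter-clockwise half is sampled at
#' `interval_ccw` over \[-truncation_ccw, 0\], the clockwise half at
#' `interval_cw` over \[0, truncation_cw\] (the shared 0 offset appears once),
#' and mass at offset x is proportional to exp(-x^2 / (2 sigma_side^2)).
#' Under density-matched weighting the halves receive total mass in proportion
#' sigma_ccw : sigma_cw; under equal-mass weighting each half receives 1/2.
#'
#' A truncation of exactly 90 degrees on the counter-clockwise side would
#' place a support point at -90, which is the same orientation as +90; that
#' point is dropped (its relative weight is below 1e-5 for all experiment
#' parameters).
#'
#' @param spec a [skewed_gaussian_spec()].
#' @param reference absolute reference orientation in degrees.
#' @return an [orientation_distribution()].
#' @examples
#' d <- build_skewed_gaussian(skewed_gaussian_spec(30, 0), reference = 90)
#' distribution_stats(d)
#' @export
build_skewed_gaussian <- function(spec, reference = 90) {
  stopifnot(inherits(spec, "skewed_gaussian_spec"))
  x_ccw <- rev(seq(0, spec$truncation_ccw, by = spec$interval_ccw))
  x_cw <- seq(0, spec$truncation_cw, by = spec$interval_cw)
  x_ccw <- x_ccw[x_ccw < 90]  # -90 is the same orientation as +90
  w_ccw <- .half_gauss_weights(x_ccw, spec$sigma_ccw)
  w_cw <- .half_gauss_weights(x_cw, spec$sigma_cw)
  if (spec$half_weighting == "density-matched") {
    share_ccw <- spec$sigma_ccw / (spec$sigma_ccw + spec$sigma_cw)
    share_cw <- spec$sigma_cw / (spec$sigma_ccw + spec$sigma_cw)
  } else {
    share_ccw <- share_cw <- 0.5
  }
  m_ccw <- if (sum(w_ccw) > 0) share_ccw * w_ccw / sum(w_ccw) else w_ccw
  m_cw <- if (sum(w_cw) > 0) share_cw * w_cw / sum(w_cw) else w_cw
  support <- c(-x_ccw, x_cw)
  mass <- c(m_ccw, m_cw)
  # merge the shared 0 offset (present in both halves); a side with SD 0
  # leaves zero-mass points behind, which are dropped
  agg <- tapply(mass, support, sum)
  keep <- agg > 0
  orientation_distribution(as.numeric(names(agg))[keep],
                           as.numeric(agg)[keep], reference)
}

#' Build a skewed uniform orientation distribution
#'
#' Constructs the discrete distribution described by a
#' [skewed_uniform_spec()]: support sampled at `interval` over
#' \[-range_ccw, 0) and (0, range_cw\] (0 itself carries no mass), each half
#' carrying total mass 1/2 spread uniformly over its points. The junction is
#' therefore the median by construction.
#'
#' @param spec a [skewed_uniform_spec()].
#' @param reference absolute reference orientation in degrees.
#' @return an [orientation_distribution()].
#' @examples
#' d <- build_skewed_uniform(skewed_uniform_spec(75, 15), reference = 90)
#' distribution_stats(d)
#' @export
build_skewed_uniform <- function(spec, reference = 90) {
  stopifnot(inherits(spec, "skewed_uniform_spec"))
  x_ccw <- -rev(seq(spec$interval, spec$range_ccw, by = spec$interval))
  x_cw <- seq(spec$interval, spec$range_cw, by = spec$interval)
  x_ccw <- x_ccw[x_ccw > -90]
  support <- c(x_ccw, x_cw)
  mass <- c(rep(0.5 / length(x_ccw), length(x_ccw)),
            rep(0.5 / length(x_cw), length(x_cw)))
  orientation_distribution(support, mass, reference)
}

#' Central-tendency statistics of an orientation distribution
#'
#' Linear arithmetic on the signed offsets is valid because every support
#' spans less than 180 degrees. The median is the smallest support point whose
#' cumulative mass reaches 0.5; when the cumulative mass hits 0.5 exactly
#' between two support points (as at the junction of an equal-mass skewed
#' uniform) the median is their midpoint, so the junction of a 75/15 uniform
#' is the median exactly. Mode ties are broken in favour of the point nearest
#' 0 (then the smaller offset).
#'
#' @param dist an [orientation_distribution()].
#' @return named numeric vector with elements `mean`, `median`, `mode`
#'   (degrees, signed offsets relative to the reference).
#' @export
distribution_stats <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  m <- sum(dist$support * dist$mass)
  cm <- cumsum(dist$mass)
  i <- which(cm >= 0.5 - 1e-12)[1]
  if (abs(cm[i] - 0.5) <= 1e-12 && i < length(dist$support)) {
    med <- (dist$support[i] + dist$support[i + 1]) / 2
  } else {
    med <- dist$support[i]
  }
  top <- which(dist$mass >= max(dist$mass) - 1e-12)
  mode <- dist$support[top[order(abs(dist$support[top]),
                                 dist$support[top])[1]]]
  c(mean = m, median = med, mode = mode)
}

#' Mirror an orientation distribution about its reference
#'
#' Negates every support offset (swapping the clockwise and counter-clockwise
#' halves) while keeping the reference. For supports strictly inside
#' (-90, 90), every statistic of the mirrored distribution is the negative of
#' the original's. A support point at exactly +90 is its own mirror image
#' (the orthogonal orientation has no side), so it stays at +90 and linear
#' statistics of such distributions are not exactly antisymmetric.
#'
#' @param dist an [orientation_distribution()].
#' @return an [orientation_distribution()].
#' @export
mirror_distribution <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  support <- -dist$support
  support[support == -90] <- 90  # axially identical
  ord <- order(support)
  agg <- tapply(dist$mass[ord], support[ord], sum)
  orientation_distribution(as.numeric(names(agg)), as.numeric(agg),
                           dist$reference)
}

#' Rotate an orientation distribution to a new reference
#'
#' @param dist an [orientation_distribution()].
#' @param by rotation in degrees (positive = clockwise).
#' @return an [orientation_distribution()] with the reference rotated.
#' @export
rotate_distribution <- function(dist, by) {
  stopifnot(inherits(dist, "orientation_distribution"))
  orientation_distribution(dist$support, dist$mass,
                           wrap_orientation(dist$reference + by))
}

#' A point-mass (common-orientation) distribution
#'
#' The standard stimulus in the discrimination task: every line shares the
#' reference orientation.
#'
#' @param reference absolute orientation in degrees.
#' @return an [orientation_distribution()] with all mass at offset 0.
#' @export
point_mass_distribution <- function(reference = 90) {
  orientation_distribution(0, 1, reference)
}
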