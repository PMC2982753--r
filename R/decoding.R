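#' Log-likelihood profile over candidate stimuli
#'
#' For each candidate on the neuron grid, the log likelihood (up to
#' candidate-independent constants) of the observed spike counts:
#' `logL(c) = sum_i n_i * log R_i(c)`, where `R_i(c)` is the mean response of
#' neuron i to candidate c. Two candidate families are supported:
#'
#' * `template = NULL` (default): candidates are single orientations on the
#'   grid, so `R_i(c)` is the floored point-stimulus response `k * S_i(c)`.
#' * `template = <orientation_distribution>`: candidates are translated
#'   copies of the template distribution, centred at each grid orientation -
#'   the likelihood family of an observer who knows the stimulus
#'   distribution up to rotation. On the uniform wrap-around grid the
#'   response matrix is circulant, so its column sums are
#'   candidate-independent and dropping the `-R_i(c)` Poisson term is exact.
#'
#' @param bank a [neuron_bank()].
#' @param spike_counts integer spike counts, one per neuron.
#' @param t stimulus duration in seconds used for the candidate responses.
#' @param template optional [orientation_distribution()] giving the candidate
#'   family (its reference is ignored; candidates are its translates).
#' @param gain gain in (0, 1] applied to `r_max` for the candidate responses.
#' @param include_rate_term if `TRUE`, subtract `sum_i R_i(c)` (the full
#'   Poisson likelihood up to factorials). Identical argmax on the uniform
#'   grid; provided for completeness.
#' @return an object of class `loglik_profile` with fields `candidates`
#'   (degrees), `loglik`, and `flat` (`TRUE` when the profile carries no
#'   information, e.g. for all-zero counts).
#' @export
loglik_profile <- function(bank, spike_counts, t, template = NULL, gain = 1,
                           include_rate_term = FALSE) {
  stopifnot(inherits(bank, "neuron_bank"))
  if (length(spike_counts) != length(bank$preferred)) {
    stop("`spike_counts` must have one entry per neuron", call. = FALSE)
  }
  if (any(spike_counts < 0)) {
    stop("`spike_counts` must be non-negative", call. = FALSE)
  }
  logR <- .log_candidate_response(bank, t, template, gain)
  ll <- as.numeric(spike_counts %*% logR)
  if (include_rate_term) ll <- ll - colSums(exp(logR))
  flat <- sum(spike_counts) == 0 || diff(range(ll)) < 1e-9
  structure(list(candidates = bank$grid, loglik = ll, flat = flat),
            class = "loglik_profile")
}

# neurons x candidates matrix of log mean responses for duration t.
.log_candidate_response <- function(bank, t, template = NULL, gain = 1) {
  k <- bank$r_max * gain * t
  if (is.null(template)) {
    # single-orientation candidates: response = floored point response
    return(log(pmax(k * bank$sens, bank$rate_floor * t)))
  }
  stopifnot(inherits(template, "orientation_distribution"))
  n <- length(bank$preferred)
  if (n != length(bank$grid)) {
    stop("template candidates require one neuron per grid orientation",
         call. = FALSE)
  }
  pr0 <- stimulus_proportions(
    orientation_distribution(template$support, template$mass, reference = 0)
  )
  r0 <- pmax(k * as.numeric(bank$sens %*% pr0), bank$rate_floor * t)
  # circulant: candidate c is the template rotated by c degrees, so neuron i
  # responds to it as neuron i - c responds to the template at 0
  idx <- outer(seq_len(n), seq_len(n) - 1L,
               function(i, c) ((i - 1L - c) %% n) + 1L)
  matrix(log(r0)[idx], nrow = n)
}

#' @export
print.loglik_profile <- function(x, ...) {
  if (x$flat) {
    cat("loglik_profile: flat (degenerate)\n")
  } else {
    cat("loglik_profile: argmax at",
        x$candidates[which.max(x$loglik)], "deg\n")
  }
  invisible(x)
}

#' Decoder estimate container
#'
#' @param estimate orientation estimate in degrees (\[0, 180)); `NA` when
#'   degenerate.
#' @param decoder one of `"ML"`, `"WTA"`, `"VA"`.
#' @param degenerate flag for undefined cases (flat likelihood, all counts
#'   equal, zero resultant). The forced-choice layer resolves degenerate
#'   estimates by a fair coin.
#' @return an object of class `decoder_estimate`.
#' @export
decoder_estimate <- function(estimate, decoder, degenerate = FALSE) {
  if (!degenerate && (is.na(estimate) || estimate < 0 || estimate >= 180)) {
    stop("`estimate` must lie in [0, 180) unless degenerate", call. = FALSE)
  }
  structure(list(estimate = estimate, decoder = decoder,
                 degenerate = degenerate),
            class = "decoder_estimate")
}

#' @export
print.decoder_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("decoder_estimate:", x$decoder, "- degenerate\n")
  } else {
    cat(sprintf("decoder_estimate: %s %.2f deg\n", x$decoder, x$estimate))
  }
  invisible(x)
}

#' Maximum-likelihood read-out
#'
#' The candidate of maximal log likelihood; exact ties are broken uniformly
#' at random (ambient RNG stream). A flat profile yields a degenerate
#' estimate.
#'
#' @param profile a [loglik_profile()].
#' @return a [decoder_estimate()].
#' @export
ml_decode <- function(profile) {
  stopifnot(inherits(profile, "loglik_profile"))
  if (profile$flat) {
    return(decoder_estimate(NA_real_, "ML", degenerate = TRUE))
  }
  top <- which(profile$loglik >= max(profile$loglik) - 1e-9)
  pick <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
  decoder_estimate(profile$candidates[pick], "ML")
}

#' Winner-takes-all read-out
#'
#' The preferred orientation of the neuron with the maximal spike count;
#' ties uniform at random. All counts equal (including all zero) is
#' degenerate.
#'
#' @param bank a [neuron_bank()].
#' @param spike_counts integer spike counts, one per neuron.
#' @return a [decoder_estimate()].
#' @export
wta_decode <- function(bank, spike_counts) {
  stopifnot(inherits(bank, "neuron_bank"))
  if (length(spike_counts) != length(bank$preferred)) {
    stop("`spike_counts` must have one entry per neuron", call. = FALSE)
  }
  if (diff(range(spike_counts)) == 0) {
    return(decoder_estimate(NA_real_, "WTA", degenerate = TRUE))
  }
  top <- which(spike_counts == max(spike_counts))
  pick <- if (length(top) == 1) top else top[sample.int(length(top), 1)]
  decoder_estimate(bank$preferred[pick], "WTA")
}

#' Vector-average read-out
#'
#' The average of the neurons' preferred orientations weighted by their spike
#' counts. Because orientation is axial, the plain weighted vector mean is
#' ill-defined at the 0/180 seam; the read-out is therefore computed as the
#' weighted axial Frechet mean: the orientation m such that, when every
#' preferred orientation is represented by its signed offset in (-90, 90]
#' from m, the count-weighted mean of those offsets is zero. It is found by
#' fixed-point iteration started at the doubled-angle resultant (which is
#' always seam-safe) and is rotation equivariant. When activity is
#' concentrated away from the seam it equals the plain weighted vector
#' average of the preferred orientations.
#'
#' A zero doubled-angle resultant (e.g. all counts equal) is degenerate.
#'
#' @param bank a [neuron_bank()].
#' @param spike_counts numeric spike counts (or mean counts), one per neuron.
#' @return a [decoder_estimate()].
#' @export
va_decode <- function(bank, spike_counts) {
  stopifnot(inherits(bank, "neuron_bank"))
  if (length(spike_counts) != length(bank$preferred)) {
    stop("`spike_counts` must have one entry per neuron", call. = FALSE)
  }
  est <- .va_estimate(bank$preferred, spike_counts)
  if (is.na(est)) {
    return(decoder_estimate(NA_real_, "VA", degenerate = TRUE))
  }
  decoder_estimate(est, "VA")
}

# weighted axial Frechet mean (fixed-point recentred average);
# NA when degenerate
.va_estimate <- function(preferred, w, max_iter = 50L) {
  total <- sum(w)
  if (total <= 0) return(NA_real_)
  two <- preferred * (pi / 90)  # doubled angles in radians
  z2 <- sum(w * exp(1i * two))
  if (Mod(z2) < total * 1e-9) return(NA_real_)
  centre <- (Arg(z2) * 90 / pi) %% 180
  for (i in seq_len(max_iter)) {
    shift <- sum(w * signed_offset(preferred, centre)) / total
    centre <- wrap_orientation(centre + shift)
    if (abs(shift) < 1e-10) break
  }
  centre
}

#' Decode spike counts with a named decoder
#'
#' Convenience dispatcher used by the task layer and the command-line
#' interface.
#'
#' @param bank a [neuron_bank()].
#' @param spike_counts integer spike counts, one per neuron.
#' @param decoder `"ml"`, `"wta"` or `"va"`.
#' @param t duration in seconds (required for `"ml"`).
#' @param template optional candidate template for `"ml"`, see
#'   [loglik_profile()].
#' @param gain gain in (0, 1] for the `"ml"` candidate responses.
#' @return a [decoder_estimate()].
#' @export
decode_counts <- function(bank, spike_counts, decoder = c("va", "wta", "ml"),
                          t = NULL, template = NULL, gain = 1) {
  decoder <- match.arg(decoder)
  switch(decoder,
    va = va_decode(bank, spike_counts),
    wta = wta_decode(bank, spike_counts),
    ml = {
      if (is.null(t)) stop("`t` is required for the ML decoder", call. = FALSE)
      ml_decode(loglik_profile(bank, spike_counts, t, template = template,
                               gain = gain))
    }
  )
}
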