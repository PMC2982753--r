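#' Line-texture stimuli
#'
#' A `texture_stimulus` holds one or more frames of absolute line orientations
#' together with the per-frame duration and Michelson contrast. Only the
#' orientations matter to the model; line positions, luminance profiles and
#' window geometry are not represented.
#'
#' @param frames list of numeric vectors of absolute orientations in degrees
#'   (each wrapped into \[0, 180)). In common-orientation mode a frame may
#'   hold a single shared orientation.
#' @param frame_duration duration of one frame in seconds (> 0).
#' @param contrast Michelson contrast in (0, 1].
#' @return an object of class `texture_stimulus` with fields `frames`,
#'   `n_lines`, `frame_duration`, `contrast`.
#' @seealso [sample_static_texture()], [sample_dynamic_texture()]
#' @export
texture_stimulus <- function(frames, frame_duration = 0.052, contrast = 1) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a non-empty list of orientation vectors",
         call. = FALSE)
  }
  n_lines <- lengths(frames)
  if (any(n_lines == 0)) {
    stop("every frame must contain at least one orientation", call. = FALSE)
  }
  if (length(unique(n_lines)) != 1) {
    stop("every frame must contain the same number of lines", call. = FALSE)
  }
  if (frame_duration <= 0) {
    stop("`frame_duration` must be > 0", call. = FALSE)
  }
  if (contrast <= 0 || contrast > 1) {
    stop("`contrast` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(frames = lapply(frames, wrap_orientation),
         n_lines = n_lines[1],
         frame_duration = frame_duration,
         contrast = contrast),
    class = "texture_stimulus"
  )
}

#' @export
print.texture_stimulus <- function(x, ...) {
  cat("texture_stimulus:", length(x$frames), "frame(s) x", x$n_lines,
      "line(s);", x$frame_duration, "s/frame; contrast", x$contrast, "\n")
  invisible(x)
}

#' Total duration of a texture stimulus
#' @param stimulus a [texture_stimulus()].
#' @return duration in seconds (frames x frame duration).
#' @export
stimulus_duration <- function(stimulus) {
  stopifnot(inherits(stimulus, "texture_stimulus"))
  length(stimulus$frames) * stimulus$frame_duration
}

#' All line orientations of a stimulus, pooled over frames
#' @param stimulus a [texture_stimulus()].
#' @return numeric vector of absolute orientations in degrees.
#' @export
pooled_orientations <- function(stimulus) {
  stopifnot(inherits(stimulus, "texture_stimulus"))
  unlist(stimulus$frames, use.names = FALSE)
}

#' @export
as.data.frame.texture_stimulus <- function(x, ...) {
  data.frame(
    frame = rep(seq_along(x$frames), lengths(x$frames)),
    line = unlist(lapply(lengths(x$frames), seq_len), use.names = FALSE),
    orientation_deg = pooled_orientations(x)
  )
}

#' Sample a static texture from an orientation distribution
#'
#' Draws `n_lines` line orientations i.i.d. (with replacement) from the
#' distribution and maps them through its reference into absolute
#' orientations, producing a single-frame texture. The defaults match the
#' experimental stimuli: 500 lines shown for one 0.052 s frame.
#'
#' @param dist an [orientation_distribution()].
#' @param n_lines number of lines per frame (default 500).
#' @param frame_duration frame duration in seconds (default 0.052).
#' @param contrast Michelson contrast in (0, 1].
#' @return a [texture_stimulus()] with one frame.
#' @examples
#' d <- build_skewed_gaussian(skewed_gaussian_spec(30, 0), reference = 90)
#' set.seed(1)
#' sample_static_texture(d)
#' @export
sample_static_texture <- function(dist, n_lines = 500,
                                  frame_duration = 0.052, contrast = 1) {
  stopifnot(inherits(dist, "orientation_distribution"))
  if (n_lines < 1) stop("`n_lines` must be >= 1", call. = FALSE)
  offs <- .sample_offsets(dist, n_lines)
  texture_stimulus(list(wrap_orientation(dist$reference + offs)),
                   frame_duration = frame_duration, contrast = contrast)
}

#' Sample a dynamic texture from an orientation distribution
#'
#' In `"common-per-frame"` mode (the default) each frame draws one
#' orientation from the distribution, shared by all lines of that frame - the
#' temporal analogue of one orientation per line. In `"per-line"` mode every
#' line of every frame is drawn independently. The defaults match the
#' experimental stimuli: 25 frames at 0.052 s each (1.3 s total).
#'
#' @inheritParams sample_static_texture
#' @param n_frames number of frames (default 25).
#' @param mode `"common-per-frame"` or `"per-line"`.
#' @param n_lines lines per frame; in common-per-frame mode the shared
#'   orientation is stored once per frame.
#' @return a [texture_stimulus()].
#' @export
sample_dynamic_texture <- function(dist, n_frames = 25,
                                   mode = c("common-per-frame", "per-line"),
                                   n_lines = 500, frame_duration = 0.052,
                                   contrast = 1) {
  stopifnot(inherits(dist, "orientation_distribution"))
  mode <- match.arg(mode)
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  if (mode == "common-per-frame") {
    offs <- .sample_offsets(dist, n_frames)
    frames <- as.list(wrap_orientation(dist$reference + offs))
  } else {
    frames <- lapply(seq_len(n_frames), function(i) {
      wrap_orientation(dist$reference + .sample_offsets(dist, n_lines))
    })
  }
  texture_stimulus(frames, frame_duration = frame_duration,
                   contrast = contrast)
}

# i.i.d. draws of signed offsets from a discrete distribution,
# using the ambient RNG stream.
.sample_offsets <- function(dist, n) {
  if (length(dist$support) == 1) {
    rep(dist$support, n)
  } else {
    sample(dist$support, n, replace = TRUE, prob = dist$mass)
  }
}

#' Write a stimulus to CSV
#'
#' Long format with columns `frame`, `line`, `orientation_deg`, for external
#' inspection.
#'
#' @param stimulus a [texture_stimulus()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_stimulus_csv <- function(stimulus, path) {
  utils::write.csv(as.data.frame(stimulus), path, row.names = FALSE)
  invisible(path)
}
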