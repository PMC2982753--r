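#' Serialise distribution specs to and from plain lists
#'
#' Round-trips [skewed_gaussian_spec()] and [skewed_uniform_spec()] objects
#' through plain named lists so they can be written to YAML or JSON configs.
#'
#' @param spec a spec object.
#' @return `spec_to_list()` returns a named list with a `type` field.
#' @export
spec_to_list <- function(spec) {
  if (inherits(spec, "skewed_gaussian_spec")) {
    c(list(type = "skewed_gaussian"), unclass(spec))
  } else if (inherits(spec, "skewed_uniform_spec")) {
    c(list(type = "skewed_uniform"), unclass(spec))
  } else {
    stop("unsupported spec object", call. = FALSE)
  }
}

#' @rdname spec_to_list
#' @param x a named list with a `type` field (`"skewed_gaussian"` or
#'   `"skewed_uniform"`).
#' @return `spec_from_list()` returns the corresponding spec object.
#' @export
spec_from_list <- function(x) {
  if (is.null(x$type)) stop("config is missing field `type`", call. = FALSE)
  if (x$type == "skewed_gaussian") {
    skewed_gaussian_spec(x$sigma_ccw, x$sigma_cw,
                         interval_ccw = x$interval_ccw %||% 2.5,
                         interval_cw = x$interval_cw %||% 2.5,
                         truncation_ccw = x$truncation_ccw %||% 45,
                         truncation_cw = x$truncation_cw %||% 45,
                         half_weighting = x$half_weighting %||%
                           "density-matched")
  } else if (x$type == "skewed_uniform") {
    skewed_uniform_spec(x$range_ccw, x$range_cw,
                        interval = x$interval %||% 2.5)
  } else {
    stop(sprintf("unknown spec type `%s`", x$type), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a plain config file
#'
#' Format chosen by extension: `.yaml`/`.yml` via the yaml package,
#' `.json` via jsonlite.
#'
#' @param x a list to write.
#' @param path file path.
#' @return `read_config()` returns a list; `write_config()` the path,
#'   invisibly.
#' @export
write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("config files must be .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config files must be .yaml, .yml or .json", call. = FALSE)
  }
}

#' Write a population response as CSV
#'
#' Columns `neuron`, `preferred_deg`, `mean_count`, `spike_count`.
#'
#' @param response a [population_response()].
#' @param bank the [neuron_bank()] that produced it.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_response_csv <- function(response, bank, path) {
  stopifnot(inherits(response, "population_response"),
            inherits(bank, "neuron_bank"))
  df <- as.data.frame(response)
  df$preferred_deg <- bank$preferred
  utils::write.csv(df[, c("neuron", "preferred_deg", "mean_count",
                          "spike_count")],
                   path, row.names = FALSE)
  invisible(path)
}
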