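# Plugin registries. Filters, baseline detectors, peak detectors, integrators,
# spectrum-comparison measures and file-format converters are all looked up by
# id in package-level registries so that user code can plug in alternatives.

.registries <- new.env(parent = emptyenv())

registry_get <- function(kind) {
  if (!exists(kind, envir = .registries))
    assign(kind, list(), envir = .registries)
  get(kind, envir = .registries)
}

registry_put <- function(kind, id, entry, overwrite = FALSE) {
  reg <- registry_get(kind)
  if (!overwrite && id %in% names(reg))
    stop(sprintf("%s '%s' is already registered", kind, id))
  reg[[id]] <- entry
  assign(kind, reg, envir = .registries)
  invisible(entry)
}

registry_lookup <- function(kind, id) {
  reg <- registry_get(kind)
  if (!id %in% names(reg))
    stop(sprintf("unknown %s '%s'; registered: %s", sub("s$", "", kind), id,
                 paste(names(reg), collapse = ", ")))
  reg[[id]]
}

#' Register a chromatogram filter
#'
#' Filters operate on a [chromatogram_selection()] and return the modified
#' chromatogram; scans outside the selection window must be left untouched.
#'
#' @param id unique filter id (e.g. `"savitzky-golay"`).
#' @param name human-readable display name.
#' @param fun function `(selection, ...)` returning a `chromatogram`.
#' @param parameters list describing tunable parameters: each element a list
#'   with `name`, `type`, `default` and optionally `bounds`.
#' @return the registered descriptor, invisibly.
#' @export
register_filter <- function(id, name, fun, parameters = list()) {
  stopifnot(is.character(id), nzchar(id), is.function(fun))
  registry_put("filters", id, list(filter_id = id, name = name, fun = fun,
                                   parameters = parameters))
}

#' List registered filters
#'
#' @return data.frame with columns `filter_id` and `name`, in deterministic
#'   (lexicographic) order.
#' @export
list_filters <- function() {
  reg <- registry_get("filters")
  ids <- sort(names(reg))
  data.frame(filter_id = ids,
             name = vapply(reg[ids], `[[`, character(1), "name"),
             row.names = NULL)
}

#' Apply a registered filter by id
#'
#' @param selection a `chromatogram_selection`.
#' @param filter_id id of a registered filter.
#' @param params named list of filter parameters.
#' @return the modified `chromatogram`.
#' @export
apply_filter <- function(selection, filter_id, params = list()) {
  entry <- registry_lookup("filters", filter_id)
  out <- do.call(entry$fun, c(list(selection), params))
  assert_chromatogram_valid(out)
  out
}

#' Register a baseline detector
#' @param id unique detector id.
#' @param name display name.
#' @param fun function `(selection, ...)` returning a per-scan baseline vector.
#' @return the registered descriptor, invisibly.
#' @export
register_baseline_detector <- function(id, name, fun) {
  registry_put("baseline_detectors", id, list(id = id, name = name, fun = fun))
}

#' Register a peak detector
#' @param id unique detector id.
#' @param name display name.
#' @param fun function `(selection, ...)` returning a chromatogram with peaks
#'   attached (areas unset).
#' @return the registered descriptor, invisibly.
#' @export
register_peak_detector <- function(id, name, fun) {
  registry_put("peak_detectors", id, list(id = id, name = name, fun = fun))
}

#' Register a peak integrator
#' @param id unique integrator id.
#' @param name display name.
#' @param fun function `(peak, scan_times)` returning the peak with `area` set.
#' @return the registered descriptor, invisibly.
#' @export
register_integrator <- function(id, name, fun) {
  registry_put("integrators", id, list(id = id, name = name, fun = fun))
}

#' Register a spectrum-comparison measure
#' @param id unique measure id.
#' @param name display name.
#' @param fun function `(a, b)` returning a score in \[0, 1\].
#' @return the registered descriptor, invisibly.
#' @export
register_measure <- function(id, name, fun) {
  registry_put("measures", id, list(id = id, name = name, fun = fun))
}

#' List registered components of one kind
#'
#' @param kind one of `"filters"`, `"baseline_detectors"`, `"peak_detectors"`,
#'   `"integrators"`, `"measures"`, `"formats"`.
#' @return character vector of registered ids in lexicographic order.
#' @export
list_registered <- function(kind = c("filters", "baseline_detectors",
                                     "peak_detectors", "integrators",
                                     "measures", "formats")) {
  kind <- match.arg(kind)
  sort(names(registry_get(kind)))
}

# built-in components are (re-)registered on load
register_builtins <- function() {
  for (kind in c("filters", "baseline_detectors", "peak_detectors",
                 "integrators", "measures", "formats"))
    assign(kind, list(), envir = .registries)

  register_filter("savitzky-golay", "Savitzky-Golay smoothing",
                  filter_savitzky_golay, parameters = list(
    list(name = "window", type = "integer", default = 9L,
         bounds = c(5L, NA)),
    list(name = "poly_order", type = "integer", default = 2L,
         bounds = c(2L, NA))))
  register_filter("remove-background", "Per-ion background removal",
                  filter_remove_background)
  register_filter("mean-normalize", "Mean TIC normalization",
                  filter_mean_normalize, parameters = list(
    list(name = "target", type = "numeric", default = 1000,
         bounds = c(0, Inf))))
  register_filter("subtract-baseline", "Subtract attached baseline",
                  filter_subtract_baseline)

  register_baseline_detector("moving-min", "Moving minimum + smoothing",
                             detect_baseline_moving_min)
  register_peak_detector("first-derivative", "First-derivative detector",
                         detect_peaks_first_derivative)
  register_integrator("trapezoid", "Trapezoidal integrator",
                      integrate_trapezoid)
  register_measure("cosine", "Normalized dot product", cosine_match)
  register_measure("euclidean", "Normalized Euclidean similarity",
                   euclidean_match)
  register_formats()
}

.onLoad <- function(libname, pkgname) {
  register_builtins()
}
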