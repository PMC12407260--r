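#' Read and write clock and model JSON
#'
#' Clock files are the package's single interchange format: JSON with a
#' `schema` field, the per-biomarker `coefficients` (years per unit), the
#' `constant` (years), the `beta1` denominator when known, optional
#' `reference_values`, and a free-text `provenance`. Fitted Gompertz
#' models serialize analogously.
#'
#' @param clock A [bioage_clock].
#' @param path File path.
#' @return `read_clock()` returns a [bioage_clock]; `read_model()` a
#'   [gompertz_ph]; the writers return `path` invisibly.
#' @export
write_clock <- function(clock, path) {
  obj <- list(
    schema = "bioclock/clock/v1",
    provenance = clock$provenance,
    beta1 = clock$beta1,
    constant = clock$constant,
    coefficients = as.list(clock$coefficients),
    reference_values = if (is.null(clock$reference_values)) NULL
                       else as.list(clock$reference_values)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "bioclock/clock/")) {
    stop("not a bioclock clock file (missing schema field): ", path,
         call. = FALSE)
  }
  bioage_clock(
    coefficients = unlist(obj$coefficients),
    constant = obj$constant,
    beta1 = if (is.null(obj$beta1)) NA_real_ else obj$beta1,
    reference_values = if (is.null(obj$reference_values)) NULL
                       else unlist(obj$reference_values),
    provenance = if (is.null(obj$provenance)) "file" else obj$provenance
  )
}

#' @rdname write_clock
#' @param model A [gompertz_ph] model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema = "bioclock/gompertz/v1",
    rate = model$rate, shape = model$shape, beta_age = model$beta_age,
    beta = as.list(model$beta),
    loglik = model$loglik, n = model$n, n_events = model$n_events,
    converged = model$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "bioclock/gompertz/")) {
    stop("not a bioclock model file (missing schema field): ", path,
         call. = FALSE)
  }
  gompertz_ph(
    rate = obj$rate, shape = obj$shape, beta_age = obj$beta_age,
    beta = unlist(obj$beta),
    loglik = if (is.null(obj$loglik)) NA_real_ else obj$loglik,
    n = if (is.null(obj$n)) NA_integer_ else obj$n,
    n_events = if (is.null(obj$n_events)) NA_integer_ else obj$n_events,
    converged = if (is.null(obj$converged)) NA else obj$converged
  )
}

# run metadata sidecar: version, seed, config hash -- written next to every
# CLI artifact so outputs are reproducible from (input, config, seed)
write_run_metadata <- function(dir, command, config, seed) {
  meta <- list(
    tool = "bioclock",
    version = as.character(utils::packageVersion("bioclock")),
    command = command,
    seed = seed,
    config_hash = rlang::hash(config),
    config = config
  )
  jsonlite::write_json(meta, file.path(dir, paste0("run_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(meta)
}
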