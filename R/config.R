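# Layered configuration resolution and run manifests for the command-line
# entry point: defaults < YAML file < explicit overrides, with unknown keys
# rejected.

config_constructors <- function() {
  list(simulate = sim_config, pretrain = pretrain_config,
       finetune = finetune_config)
}

#' Resolve a pipeline configuration
#'
#' Starts from the pipeline's documented defaults, overlays the keys of a
#' YAML file (if given), then explicit overrides (highest precedence), and
#' validates the result through the pipeline's config constructor. Unknown
#' keys are rejected with the list of valid keys; values whose type cannot
#' be reconciled with the default raise an error.
#'
#' @param pipeline `"simulate"`, `"pretrain"` or `"finetune"`.
#' @param file Optional YAML file of overrides.
#' @param overrides Named list of highest-precedence overrides (e.g. parsed
#'   command-line flags).
#' @return A validated config object for the pipeline.
#' @export
resolve_config <- function(pipeline = c("simulate", "pretrain", "finetune"),
                           file = NULL, overrides = list()) {
  pipeline <- match.arg(pipeline)
  ctor <- config_constructors()[[pipeline]]
  defaults <- formals(ctor)
  valid <- names(defaults)
  layers <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    layers$file <- yaml::read_yaml(file) %||% list()
  }
  layers$overrides <- overrides
  merged <- list()
  for (layer in layers) {
    if (length(layer) == 0L) next
    if (is.null(names(layer)) || any(!nzchar(names(layer))))
      stop("config entries must be named")
    bad <- setdiff(names(layer), valid)
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           "; valid keys are: ", paste(valid, collapse = ", "))
    merged[names(layer)] <- layer
  }
  # type reconciliation against evaluated defaults
  ev <- lapply(valid, function(k) tryCatch(eval(defaults[[k]], envir = as.list(merged)),
                                           error = function(e) NULL))
  names(ev) <- valid
  for (k in names(merged)) {
    dft <- ev[[k]]
    v <- merged[[k]]
    if (is.numeric(dft)) {
      if (is.list(v)) v <- unlist(v)
      if (!is.numeric(v)) stop("config key '", k, "' must be numeric")
      if (!is.null(names(dft)) && length(v) == length(dft) && is.null(names(v)))
        names(v) <- names(dft)
      merged[[k]] <- v
    } else if (is.logical(dft) && !is.logical(v)) {
      stop("config key '", k, "' must be logical")
    }
  }
  do.call(ctor, merged)
}

#' Build a run manifest
#'
#' A manifest captures everything needed to re-run an experiment
#' bit-for-bit: the resolved configuration, content fingerprints of the
#' input files, the master seed and the derived seed map, and timestamps.
#'
#' @param config A config object (list).
#' @param inputs Named character vector of input file paths to fingerprint.
#' @param seed Master seed of the run.
#' @param path Optional JSON output path (written before training starts).
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, inputs = character(), seed = NULL, path = NULL) {
  fps <- vapply(inputs, function(f)
    fnv1a32(paste(readLines(f, warn = FALSE), collapse = "\n")), character(1))
  man <- list(config = unclass(config),
              input_fingerprints = as.list(fps),
              master_seed = seed,
              seed_map = if (!is.null(seed)) as.list(seed_everything(seed)),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(utils::packageVersion("claimformer")))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(man))
  }
  man
}
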