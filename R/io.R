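## Spike-event lists and model configuration files ----------------------------

#' Read and write spike-event lists
#'
#' Tab-separated spike-event format, one row per spike, with a header row
#' and columns `time_ms`, `neuron_id`, `pool` (`e` or `i`), `input_index`.
#' On reading, `(neuron_id, input_index)` pairs are mapped to consecutive
#' global input ids; on writing, trains generated by
#' [sample_spike_trains()] use the first innervated neuron as `neuron_id`.
#'
#' @param path file path.
#' @param trains a `"spike_trains"` data frame.
#' @return `read_spike_events()` returns a `"spike_trains"` data frame;
#'   `write_spike_events()` returns `path` invisibly.
#' @examples
#' tr <- sample_spike_trains(betabinomial_pool(3, 10, 0.2), 500, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_spike_events(tr, f)
#' head(read_spike_events(f))
#' @export
read_spike_events <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c(time_ms = "numeric"))
  need <- c("time_ms", "neuron_id", "pool", "input_index")
  if (!all(need %in% names(df)))
    stop("spike-event file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$pool %in% c("e", "i")))
    stop("'pool' must be 'e' or 'i'", call. = FALSE)
  key <- paste(df$neuron_id, df$pool, df$input_index, sep = "/")
  df$input_id <- as.integer(factor(key, levels = unique(key)))
  out <- df[order(df$time_ms, df$input_id),
            c("time_ms", "input_id", "pool", "neuron_id", "input_index")]
  rownames(out) <- NULL
  structure(out, class = c("spike_trains", "data.frame"),
            duration_ms = max(df$time_ms))
}

#' @rdname read_spike_events
#' @export
write_spike_events <- function(trains, path) {
  it <- attr(trains, "input_table")
  neuron_id <- if (!is.null(trains$neuron_id)) trains$neuron_id
    else if (!is.null(it)) {
      first_neuron <- apply(it$weights, 1, function(w) which(w > 0)[1])
      first_neuron[match(trains$input_id, it$id)]
    } else 1L
  input_index <- if (!is.null(trains$input_index)) trains$input_index
    else trains$input_id
  out <- data.frame(time_ms = trains$time_ms, neuron_id = neuron_id,
                    pool = trains$pool, input_index = input_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a synchrony model and neuron parameters from a configuration list
#'
#' Configurations are key-value lists, typically read from YAML or JSON by
#' [read_model_config()].  The `model` block selects a constructor via its
#' `type` field: `"betabinomial_pool"`, `"ensemble"`, `"paired"` (the
#' calibrated two-neuron mixture) or `"shared"`; the remaining fields are
#' passed to the corresponding constructor.  The optional `neuron` block
#' holds [neuron_params()] fields; `seed` is carried through.
#'
#' @param config a named list.
#' @return A list with `model`, `params`, `seed`.
#' @examples
#' cfg <- list(model = list(type = "betabinomial_pool", K = 10, rate_hz = 5,
#'                          rho = 0.1, weight = 0.01),
#'             neuron = list(tau = 15), seed = 7)
#' aoncb_model_from_config(cfg)$model
#' @export
aoncb_model_from_config <- function(config) {
  stopifnot(is.list(config), is.list(config$model))
  mc <- config$model
  type <- mc$type
  mc$type <- NULL
  builder <- switch(type,
    betabinomial_pool = betabinomial_pool,
    ensemble = ensemble_model,
    paired = function(...) {
      args <- list(...)
      tnames <- intersect(names(args),
                          c("rho_e", "rho_i", "rho_ei", "rho_cross_ee",
                            "rho_cross_ii", "rho_cross_ei"))
      do.call(calibrate_mixture,
              c(list(targets = args[tnames]), args[setdiff(names(args), tnames)]))
    },
    shared = shared_input_model,
    stop("unknown model type: ", type, call. = FALSE))
  model <- do.call(builder, mc)
  params <- do.call(neuron_params,
                    if (is.list(config$neuron)) config$neuron else list())
  list(model = model, params = params, seed = config$seed)
}

#' @rdname aoncb_model_from_config
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package", call. = FALSE)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
  aoncb_model_from_config(cfg)
}
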