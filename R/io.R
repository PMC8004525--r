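config_keys <- c(
  "parameters", "life_history", "e", "a", "b", "init", "t_end",
  "seed", "n", "semiwidth", "sweep", "output_dir"
)

#' Read and validate a run configuration
#'
#' Parses a YAML or JSON key-value configuration describing a run. The
#' model rates come either from a `parameters` block (the twelve rates by
#' name) or from a `life_history` block (per-species `lifespan`,
#' `annual_factor`, `capacity`, converted via [derive_params()]); `a`, `b`
#' and `e` at the top level override either. Unknown keys are rejected by
#' name, negative rates are rejected by name, and every defaulted field is
#' recorded in the `defaulted` attribute and messaged. Units are fixed by
#' the schema: years for time, individuals per km^2 for densities.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A list of class `hp_config`: `params` ([hp_params] or `NULL`
#'   when no rates were given), `init`, `t_end`, `seed`, `n`, `semiwidth`,
#'   `sweep`, `output_dir`, with attribute `defaulted`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "hp_io_error")
  }
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key `n` as boolean FALSE; restore it at the
  # two levels where the schema uses it (run size, cottontail mortality)
  fix_n <- function(x) {
    names(x)[names(x) == "FALSE"] <- "n"
    x
  }
  cfg <- fix_n(cfg)
  if (!is.null(cfg$parameters)) cfg$parameters <- fix_n(cfg$parameters)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", toString(unknown)),
      class = "hp_schema_error"
    )
  }
  defaulted <- character(0)
  take <- function(key, default) {
    if (is.null(cfg[[key]])) {
      defaulted <<- c(defaulted, key)
      default
    } else {
      cfg[[key]]
    }
  }
  params <- NULL
  if (!is.null(cfg$parameters)) {
    pb <- cfg$parameters
    bad <- setdiff(names(pb), param_names)
    if (length(bad) > 0) {
      abort(paste0("unknown parameter key(s): ", toString(bad)),
        class = "hp_schema_error"
      )
    }
    neg <- names(pb)[vapply(pb, function(v) is.numeric(v) && v < 0, logical(1))]
    if (length(neg) > 0) {
      abort(paste0("negative rate for key(s): ", toString(neg)),
        class = "hp_schema_error"
      )
    }
    params <- do.call(hp_params, pb)
  } else if (!is.null(cfg$life_history)) {
    lh <- cfg$life_history
    tab <- purrr::imap(lh, function(block, sp) {
      tibble(
        species = sp,
        lifespan = block$lifespan,
        annual_factor = block$annual_factor,
        capacity = block$capacity
      )
    })
    params <- derive_params(dplyr::bind_rows(tab))
  }
  if (!is.null(params)) {
    for (key in c("e", "a", "b")) {
      if (!is.null(cfg[[key]])) params[[key]] <- as.double(cfg[[key]])
    }
    validate_params(params)
  }
  sweep_spec <- cfg$sweep
  if (!is.null(sweep_spec)) {
    need <- c("parameter", "from", "to")
    miss <- setdiff(need, names(sweep_spec))
    if (length(miss) > 0) {
      abort(paste0("sweep block lacks key(s): ", toString(miss)),
        class = "hp_schema_error"
      )
    }
    check_sweep_param(sweep_spec$parameter)
  }
  out <- list(
    params = params,
    init = as_state(unlist(take("init", c(0.4, 1, 3)))),
    t_end = as.double(take("t_end", 500)),
    seed = as.integer(take("seed", 101)),
    n = as.integer(take("n", 500)),
    semiwidth = as.double(take("semiwidth", 0.09)),
    sweep = sweep_spec,
    output_dir = take("output_dir", ".")
  )
  if (length(defaulted) > 0) {
    message("defaulted config fields: ", toString(defaulted))
  }
  attr(out, "defaulted") <- defaulted
  class(out) <- "hp_config"
  out
}

# Render doubles so the written text round-trips to the identical binary
# value when re-read.
format_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

csv_ready <- function(df) {
  atomic <- vapply(df, function(col) is.atomic(col) && !is.complex(col),
    logical(1)
  )
  df <- df[, atomic, drop = FALSE]
  df[] <- lapply(df, function(col) {
    if (is.double(col)) format_full(col) else col
  })
  df
}

jsonable <- function(x) {
  if (is.complex(x)) {
    return(list(re = Re(x), im = Im(x)))
  }
  if (is.data.frame(x)) {
    x <- as.list(x)
  }
  if (is.list(x)) {
    return(lapply(x, jsonable))
  }
  x
}

#' Write run results with a reproducibility manifest
#'
#' Writes each named result to `dir`: plain tabular results (atomic
#' columns) as CSV, structured results (list-columns, complex eigenvalues,
#' nested lists) as JSON. Doubles are written in full precision so a
#' re-read reproduces the in-memory values exactly. A `manifest.json`
#' records the package version, fixed units, per-file content hashes and
#' an overall results hash, so reruns with identical inputs produce an
#' identical manifest.
#'
#' @param results A named list of results (data frames or lists).
#' @param dir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
write_run_outputs <- function(results, dir) {
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("results must be a fully named list", class = "hp_invalid_input")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create output directory ", dir),
      class = "hp_io_error"
    )
  }
  files <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x) &&
      all(vapply(x, function(col) is.atomic(col) && !is.complex(col),
        logical(1)
      ))) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(csv_ready(x), path, row.names = FALSE, quote = FALSE)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(jsonable(x), path,
        auto_unbox = TRUE, digits = NA, null = "null"
      )
    }
    files[[nm]] <- list(
      file = basename(path),
      hash = rlang::hash(results[[nm]])
    )
  }
  manifest <- list(
    package = "hyperpred",
    version = as.character(utils::packageVersion("hyperpred")),
    units = list(time = "years", density = "individuals per km^2"),
    files = files,
    results_hash = rlang::hash(results)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
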