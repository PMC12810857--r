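# Minimal flat-TOML reader: [section] headers, key = value lines with
# numeric, boolean, quoted-string or numeric-array values, '#' comments.
# Covers the package's config and fixture files; not a general TOML parser.
.read_flat_toml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "trigame_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_value <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[", v)) {
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (trimws(inner) == "") return(numeric(0))
      parts <- trimws(strsplit(inner, ",")[[1]])
      return(vapply(parts, function(x) parse_value(x), numeric(1),
                    USE.NAMES = FALSE))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) {
      abort(sprintf("cannot parse TOML value '%s'", v),
            class = "trigame_error_parse")
    }
    num
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[.+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      abort(sprintf("cannot parse TOML line '%s'", raw),
            class = "trigame_error_parse")
    }
    key <- trimws(sub("=.*$", "", line))
    val <- parse_value(sub("^[^=]*=", "", line))
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

#' Read a run configuration from a TOML file
#'
#' The configuration holds a `[parameters]` table with the 17 romanized
#' field names (`ip1`, ..., `bg`), and optionally a `[run]` table with
#' `init` (length-3 array, default `[0.5, 0.5, 0.5]`), `horizon` (default
#' 200), `rel_tol` (1e-8), `abs_tol` (1e-10) and `seed` (0).
#'
#' @param path Path to the TOML file.
#' @return A `run_config` list: `params` (`game_parameters`), `init`
#'   (strategy-state tibble), `horizon`, `rel_tol`, `abs_tol`, `seed`.
#' @export
read_config <- function(path) {
  cfg <- .read_flat_toml(path)
  if (is.null(cfg$parameters)) {
    abort("config is missing the [parameters] block",
          class = "trigame_error_config")
  }
  params <- validate_parameters(cfg$parameters)
  run <- cfg$run %||% list()
  init <- run$init %||% c(0.5, 0.5, 0.5)
  if (length(init) != 3) {
    abort("run.init must have three components", class = "trigame_error_config")
  }
  structure(
    list(
      params = params,
      init = strategy_state(init),
      horizon = run$horizon %||% 200,
      rel_tol = run$rel_tol %||% 1e-8,
      abs_tol = run$abs_tol %||% 1e-10,
      seed = as.integer(run$seed %||% 0)
    ),
    class = "run_config"
  )
}

#' Write a trajectory to CSV (with a JSON metadata sidecar)
#'
#' Writes `time,delta,eta,zeta` at full double precision and a sidecar
#' `<path>.meta.json` recording the parameter set and solver settings, so a
#' run can be reproduced from its outputs alone.
#'
#' @param traj A `game_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj[, c("time", "delta", "eta", "zeta")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,delta,eta,zeta", con)
  if (nrow(df) > 0) {
    writeLines(
      apply(format(df, digits = 17, scientific = TRUE, trim = TRUE), 1,
            paste, collapse = ","),
      con
    )
  }
  meta <- list(
    params = as.list(attr(traj, "params")),
    solver = attr(traj, "solver")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path; the `.meta.json` sidecar is restored when present.
#' @return A `game_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  df <- as_tibble(read.csv(path, colClasses = "numeric"))
  meta_path <- paste0(path, ".meta.json")
  params <- NULL; solver <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$params)) params <- validate_parameters(meta$params)
    solver <- meta$solver
  }
  structure(df, params = params, solver = solver,
            class = c("game_trajectory", class(df)))
}

#' Write a stability report to JSON
#'
#' Serializes the eight classified corner equilibria and the proposition
#' check for a parameter set.
#'
#' @param params A `game_parameters` object.
#' @param path Output JSON path.
#' @param tol Eigenvalue tolerance passed to [stability_analysis()].
#' @return The path, invisibly.
#' @export
report_stability <- function(params, path, tol = 1e-9) {
  st <- stability_analysis(params, tol = tol)
  payload <- list(
    parameters = as.list(params),
    equilibria = st$equilibria,
    propositions = st$propositions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
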