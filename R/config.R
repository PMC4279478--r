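#' Read a model configuration file
#'
#' Parses a minimal TOML-style `key = value` file with `[section]` headers
#' into the package's parameter objects. Recognised sections mirror the
#' constructor names: `[fruit]` (diameter, albedo, emissivity,
#' vapour_conductance), `[scene]` (ground_emissivity, ground_leaf_temp,
#' atm_emissivity_model, atm_emissivity_value), `[illumination]`
#' (sunlit_ratio, reflected_ratio), `[simulation]` (levels as a
#' comma-separated list, time_step, window_start, window_end, apply_window)
#' and `[solver]` (tol, maxiter, closure_tol, slope_at). Unquoted bare words
#' are kept as strings; `#` starts a comment; every key is optional and
#' falls back to the package default.
#'
#' @param path Path to the configuration file.
#' @return A [simulation_config()] assembled from the file.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list()
  current <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      current <- tolower(gsub("^\\[|\\]$", "", ln))
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln, call. = FALSE)
    sections[[current]][[kv[2]]] <- parse_config_value(kv[3])
  }
  build_config_from_sections(sections)
}

parse_config_value <- function(x) {
  x <- trimws(gsub('^"|"$', "", trimws(x)))
  if (grepl(",", x, fixed = TRUE)) {
    return(unlist(lapply(strsplit(x, ",")[[1]], parse_config_value)))
  }
  if (tolower(x) %in% c("true", "false")) return(tolower(x) == "true")
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) n else x
}

build_config_from_sections <- function(s) {
  take <- function(section, defaults) {
    vals <- s[[section]] %||% list()
    keep <- intersect(names(vals), defaults)
    vals[keep]
  }
  fruit <- do.call(fruit_properties,
                   take("fruit", c("diameter", "albedo", "emissivity",
                                   "vapour_conductance")))
  scene <- do.call(scene_properties,
                   take("scene", c("ground_emissivity", "ground_leaf_temp",
                                   "atm_emissivity_model",
                                   "atm_emissivity_value")))
  solver_args <- take("solver", c("tol", "maxiter", "closure_tol", "slope_at"))
  sim_args <- take("simulation", c("levels", "time_step", "window_start",
                                   "window_end", "apply_window"))
  illum <- s[["illumination"]] %||% list()
  args <- c(sim_args,
            list(fruit = fruit, scene = scene,
                 solver = do.call(solver_config, solver_args)))
  if (!is.null(illum$sunlit_ratio) && is.null(args$levels)) {
    args$levels <- illum$sunlit_ratio
  }
  if (!is.null(illum$reflected_ratio)) {
    args$reflected_ratio <- illum$reflected_ratio
  }
  do.call(simulation_config, args)
}
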