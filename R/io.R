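# Export helpers (CSV for curves and trajectories, JSON for fixed points)
# and config parsing for the command-line interface.

#' Write a cycle or ensemble trajectory to CSV
#'
#' @param traj A `cycle_trajectory` or `ensemble_trajectory`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}

#' Write an isocline curve to CSV
#'
#' Columns `variable`, `origin` (`"numeric"`), `branch`, `xbar_1`, `nbar`.
#'
#' @param curve An `isocline_curve`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_isocline_csv <- function(curve, file) {
  df <- as.data.frame(curve)
  df <- cbind(variable = attr(curve, "variable"), origin = "numeric", df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write fixed points to JSON
#'
#' @param fps A `fixed_point_list` (or single `fixed_point`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fixed_points_json <- function(fps, file) {
  if (inherits(fps, "fixed_point")) fps <- list(fps)
  rec <- lapply(fps, function(fp) list(
    nbar = fp$position[["nbar"]],
    xbar_1 = fp$position[["xbar_1"]],
    counts = fp$counts,
    type = fp$type,
    classification = fp$classification,
    eigenvalues = if (is.null(fp$eigenvalues)) NULL else
      list(re = Re(fp$eigenvalues), im = Im(fp$eigenvalues),
           modulus = Mod(fp$eigenvalues))))
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Build a world configuration from a parsed config list
#'
#' Used by the command-line interface; accepts the structure produced by
#' reading a JSON or YAML configuration file.  Required keys: `s0_phi`,
#' `d`, `strains` (list of objects with optional `delta_alpha`,
#' `delta_phi`, `rho`).  Optional: `t_mix` (default 24), `interaction`
#' (object with `kind` and its parameters), `consumption`,
#' `extinction_cutoff`.
#'
#' @param cfg A named list.
#' @return A [world_config()].
#' @export
world_from_config <- function(cfg) {
  for (key in c("s0_phi", "d", "strains"))
    if (is.null(cfg[[key]])) stop("config is missing required key '", key, "'")
  strains <- lapply(cfg$strains, function(s)
    strain_params(delta_alpha = s$delta_alpha %||% 0,
                  delta_phi = s$delta_phi %||% 0,
                  rho = s$rho %||% 0))
  interaction <- "base"
  if (!is.null(cfg$interaction)) {
    ic <- cfg$interaction
    kind <- ic$kind %||% "base"
    interaction <- switch(kind,
      base = "base",
      antibiotics = {
        if (is.null(ic$b0)) stop("config is missing required key 'b0'")
        antibiotic_params(b0 = ic$b0, kappa = ic$kappa %||% 2,
                          gamma = ic$gamma %||% 2)
      },
      pyoverdine = pyoverdine_params(sigma = ic$sigma %||% 2),
      stop("unknown interaction kind '", kind, "'"))
  }
  world_config(strains = strains, s0_phi = cfg$s0_phi,
               t_mix = cfg$t_mix %||% 24, d = cfg$d,
               interaction = interaction,
               consumption = cfg$consumption %||% "clamped",
               extinction_cutoff = cfg$extinction_cutoff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a JSON or YAML configuration file
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format '", ext, "' (use .json or .yaml)")
  }
}
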