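# Config and result I/O: flat YAML/JSON parameter files, trajectory CSV
# export with a JSON metadata sidecar.

#' Read a parameter configuration file
#'
#' Flat key/value YAML or JSON with keys named exactly as the model
#' symbols (see [botc_params()]); unknown keys raise an error naming them.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return `prebotc_params`.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("unsupported config format: .", ext))
  if (!is.list(vals)) vals <- as.list(vals)
  do.call(botc_params, vals)
}

#' Write a parameter configuration file
#'
#' @param p `prebotc_params`.
#' @param path destination (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(p)
  switch(ext,
         yaml = , yml = yaml::write_yaml(vals, path),
         json = jsonlite::write_json(vals, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         stop("unsupported config format: .", ext))
  invisible(path)
}

#' Export a trajectory as CSV with a JSON sidecar
#'
#' @param traj `prebotc_traj`.
#' @param path CSV destination; the metadata sidecar is written next to it
#'   as `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  cfg <- attr(traj, "config")
  p <- attr(traj, "params")
  meta <- list(columns = names(traj), n = nrow(traj),
               params = if (inherits(p, "prebotc_params")) unclass(p) else NULL,
               solver = if (!is.null(cfg))
                 list(rtol = cfg$rtol, atol = cfg$atol, dt_out = cfg$dt_out,
                      t_end = cfg$t_end, transient = cfg$transient))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return `prebotc_traj` (params restored from the sidecar when present).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  p <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$params))
      p <- do.call(botc_params, as.list(meta$params))
  }
  structure(df, params = p, class = c("prebotc_traj", class(df)))
}
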