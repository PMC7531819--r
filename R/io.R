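# Config serialization (YAML) and delimited-text export of fields and
# sweep tables, with provenance headers so every output can be traced
# back to the parameters and seed that produced it.

#' Read and write run configurations as YAML
#'
#' @param path file path.
#' @return `read_config` returns a [wm_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pl <- y$params
  params <- circuit_params(a = pl$a, b = pl$b, d = pl$d, gamma = pl$gamma,
                           tau_S = pl$tau_S, J11 = pl$J11, J22 = pl$J22,
                           J12 = pl$J12, J21 = pl$J21, I0 = pl$I0,
                           I_ext1 = pl$I_ext1, I_ext2 = pl$I_ext2)
  wm_config(params = params,
            J_plus_values = as.numeric(y$J_plus_values),
            J_minus_values = as.numeric(y$J_minus_values),
            grid_n = y$grid_n, D = y$D, dest_radius = y$dest_radius,
            stimulus_amplitude = y$stimulus_amplitude,
            floor_rel = y$floor_rel, seed = y$seed)
}

#' @rdname read_config
#' @param config a [wm_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "wm_config"))
  p <- config$params
  y <- list(schema = "wmflux/config/1",
            params = p[c("a", "b", "d", "gamma", "tau_S", "J11", "J22",
                         "J12", "J21", "I0", "I_ext1", "I_ext2")],
            J_plus_values = config$J_plus_values,
            J_minus_values = config$J_minus_values,
            grid_n = config$grid_n, D = config$D,
            dest_radius = config$dest_radius,
            stimulus_amplitude = config$stimulus_amplitude,
            floor_rel = config$floor_rel, seed = config$seed,
            units = list(currents = "nA", time = "s", rates = "Hz",
                         gamma = "dimensionless", D = "nA^2/s"))
  yaml::write_yaml(y, path)
  invisible(path)
}

provenance_lines <- function(params = NULL, seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("wmflux")),
                  error = function(e) "dev")
  lines <- c(sprintf("# wmflux %s", ver))
  if (!is.null(params))
    lines <- c(lines, sprintf(
      "# params: a=%g b=%g d=%g gamma=%g tau_S=%g J11=%g J22=%g J12=%g J21=%g I0=%g I_ext1=%g I_ext2=%g",
      params$a, params$b, params$d, params$gamma, params$tau_S,
      params$J11, params$J22, params$J12, params$J21, params$I0,
      params$I_ext1, params$I_ext2))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", seed))
  lines
}

#' Export a gridded field as delimited text
#'
#' Long-format CSV (`x`, `y`, `value`) with `#`-prefixed provenance and
#' axis metadata lines, readable by [read_field()].
#'
#' @param Z matrix of cell-center values.
#' @param grid the [grid2d()] it lives on.
#' @param path output path.
#' @param name value-column name.
#' @param params optional [circuit_params()] for the provenance header.
#' @return `path`, invisibly.
#' @export
write_field <- function(Z, grid, path, name = "value", params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_lines(params),
               sprintf("# grid: nx=%d ny=%d xlim=%g,%g ylim=%g,%g frame=%s",
                       grid$nx, grid$ny, grid$xlim[1], grid$xlim[2],
                       grid$ylim[1], grid$ylim[2], grid$frame)), con)
  df <- data.frame(x = rep(grid$xc, times = grid$ny),
                   y = rep(grid$yc, each = grid$nx),
                   value = as.numeric(Z))
  names(df)[3] <- name
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  hdr <- readLines(path, n = 10)
  gl <- grep("^# grid:", hdr, value = TRUE)
  m <- regmatches(gl, gregexpr("-?[0-9.eE+]+", gl))[[1]]
  nx <- as.integer(m[1]); ny <- as.integer(m[2])
  frame <- sub(".*frame=", "", gl)
  grid <- grid2d(nx = nx, ny = ny,
                 xlim = as.numeric(m[3:4]), ylim = as.numeric(m[5:6]),
                 frame = frame)
  df <- utils::read.csv(path, comment.char = "#")
  list(grid = grid, Z = matrix(df[[3]], nx, ny), name = names(df)[3])
}

#' Export a sweep table with provenance headers
#'
#' @param records a `sweep_record` from [run_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(records, path) {
  config <- attr(records, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(
    if (!is.null(config)) config$params else NULL,
    if (!is.null(config)) config$seed else NULL), con)
  utils::write.csv(as.data.frame(records), con, row.names = FALSE)
  invisible(path)
}
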