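# Configuration and tabular I/O.  All unit conversion happens at this
# boundary: files carry field units (mV, pA, mM, Angstrom); everything
# inside the package is SI plus kT for energies and mol/L for
# concentrations.

.config_sections <- list(
  energy = c("Uc", "nf", "z"),
  sites = c("dmu", "D"),
  bath = c("cw", "T", "clamp"),
  geometry = c("radius", "length", "area", "volume", "Lc"),
  io = c("out_dir", "format"),
  seed = NULL)

#' Load a run configuration
#'
#' Reads a YAML configuration with sections `energy` (Uc, nf, z),
#' `sites` (dmu, D), `bath` (cw, T, clamp), `geometry` (radius,
#' length, area, volume, Lc in Angstrom units), `io` and a top-level
#' `seed`.  Missing sections and keys fall back to the fitted NaChBac
#' defaults; unknown sections or keys are rejected.  An empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return an object of class `run_config`: a list with `energy`
#'   ([energy_params()]), `sites` ([site_params()]), `geometry`
#'   ([pore_geometry()]), `bath_defaults` (cw, T, clamp), `io`,
#'   `seed`, and `file_sha` (hex digest of the file bytes, logged for
#'   provenance).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse failure in '", path, "': ", conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config root must be a mapping")
  unknown <- setdiff(names(raw), names(.config_sections))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in setdiff(names(raw), "seed")) {
    bad <- setdiff(names(raw[[sec]]), .config_sections[[sec]])
    if (length(bad) > 0)
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  g <- function(sec, key, default) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) default else v
  }
  energy <- energy_params(Uc = g("energy", "Uc", 10),
                          nf = g("energy", "nf", -2.5),
                          z = g("energy", "z", 1))
  sites <- site_params(dmu = g("sites", "dmu", c(2.3, 3.4, 2.8, 2.4)),
                       D = g("sites", "D", 1.33e-10))
  geometry <- pore_geometry(
    radius = g("geometry", "radius", c(3.06, 2.77, 2.75, 2.77)),
    length = g("geometry", "length", c(3, 4, 3, 2)),
    area = g("geometry", "area", c(116, 126, 90, 78)),
    volume = g("geometry", "volume", c(117, 129, 80, 63)),
    Lc = g("geometry", "Lc", 12))
  bath_defaults <- list(cw = g("bath", "cw", 55.5),
                        T = g("bath", "T", 298.15),
                        clamp = g("bath", "clamp", 1e-4))
  if (bath_defaults$cw <= 0 || bath_defaults$T <= 0 ||
      bath_defaults$clamp <= 0)
    stop("bath cw, T and clamp must be positive")
  structure(list(energy = energy, sites = sites, geometry = geometry,
                 bath_defaults = bath_defaults,
                 io = list(out_dir = g("io", "out_dir", "."),
                           format = g("io", "format", "csv")),
                 seed = if (is.null(raw$seed)) 1L
                        else as.integer(raw$seed),
                 file_sha = .file_digest(path)),
            class = "run_config")
}

# small polynomial rolling digest; provenance logging only, not
# cryptographic
.file_digest <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Save a run configuration
#'
#' Writes a [load_config()]-compatible YAML file; `load_config()` of
#' the result reproduces the configuration.
#'
#' @param config a `run_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(
    list(energy = list(Uc = config$energy$Uc, nf = config$energy$nf,
                       z = config$energy$z),
         sites = list(dmu = config$sites$dmu, D = config$sites$D),
         bath = config$bath_defaults,
         geometry = list(radius = config$geometry$radius,
                         length = config$geometry$length,
                         area = config$geometry$area,
                         volume = config$geometry$volume,
                         Lc = config$geometry$Lc),
         io = config$io,
         seed = config$seed),
    path)
  invisible(path)
}

# file column -> (internal name, scale to internal units)
.table_schemas <- list(
  iv = list(cols = c(voltage_mV = "voltage", current_pA = "current",
                     bath_L_M = "bath_L", bath_R_M = "bath_R"),
            scale = c(voltage_mV = 1e-3, current_pA = 1e-12,
                      bath_L_M = 1, bath_R_M = 1)),
  occupancy = list(cols = c(site = "site", occupancy = "occupancy",
                            se = "se", bath_M = "bath_c"),
                   scale = c(site = 1, occupancy = 1, se = 1,
                             bath_M = 1)),
  wholecell = list(cols = c(bath_Na_mM = "bath_Na",
                            pipette_Na_mM = "pipette_Na",
                            voltage_mV = "voltage",
                            normalized_current = "normalized_current",
                            sem = "sem"),
                   scale = c(bath_Na_mM = 1e-3, pipette_Na_mM = 1e-3,
                             voltage_mV = 1e-3, normalized_current = 1,
                             sem = 1)))

#' Read an experiment table
#'
#' Reads a CSV in one of the package's tabular schemas and converts
#' field units to internal ones (mV to V, pA to A, mM to M) at the
#' boundary.  Row order is preserved.  A header-only file yields an
#' empty table.
#'
#' @param path CSV path.
#' @param schema one of `"iv"` (columns voltage_mV, current_pA,
#'   bath_L_M, bath_R_M), `"occupancy"` (site, occupancy, se, bath_M)
#'   or `"wholecell"` (bath_Na_mM, pipette_Na_mM, voltage_mV,
#'   normalized_current, sem).
#' @return a data.frame in internal units with attribute `schema`.
#' @export
read_table <- function(path, schema = c("iv", "occupancy",
                                        "wholecell")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("table file not found: ", path)
  sch <- .table_schemas[[schema]]
  d <- utils::read.csv(path, colClasses = "character",
                       check.names = FALSE)
  missing_cols <- setdiff(names(sch$cols), names(d))
  if (length(missing_cols) > 0)
    stop("missing column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "))
  out <- list()
  for (fc in names(sch$cols)) {
    v <- suppressWarnings(as.numeric(d[[fc]]))
    bad <- which(is.na(v) & nzchar(trimws(d[[fc]])))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s', row %d of '%s'",
                   fc, bad[1], path))
    out[[sch$cols[[fc]]]] <- v * sch$scale[[fc]]
  }
  out <- as.data.frame(out)
  attr(out, "schema") <- schema
  out
}

#' Write an experiment table
#'
#' Converts a table in internal units back to the field-unit CSV
#' schema (fixed column order, 6 significant digits), so that
#' `write_table()` then [read_table()] round-trips.  Deterministic
#' input gives byte-identical output.
#'
#' @param table a data.frame in internal units (as from
#'   [read_table()] or the pipeline functions).
#' @param path output path.
#' @param schema table schema; defaults to the table's `schema`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, schema = attr(table, "schema")) {
  if (is.null(schema)) stop("'schema' must be given")
  sch <- .table_schemas[[match.arg(schema, names(.table_schemas))]]
  out <- list()
  for (fc in names(sch$cols)) {
    int <- sch$cols[[fc]]
    if (!int %in% names(table))
      stop("table lacks internal column '", int, "'")
    out[[fc]] <- signif(table[[int]] / sch$scale[[fc]], 6)
  }
  out <- as.data.frame(out)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ",
         conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
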