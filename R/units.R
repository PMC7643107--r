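# Unit handling. Everything inside the package is SI (m, s, kg, Pa.s,
# m^3/s, kg/m^3); conversion happens once, at the boundary.

.length_units <- c(m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, cm = 1e-2)
.flow_units <- c("m3/s" = 1, "ml/min" = 1e-6 / 60, "ul/min" = 1e-9 / 60,
                 "l/min" = 1e-3 / 60)
.density_units <- c("kg/m3" = 1, "g/ml" = 1000, "g/cm3" = 1000)
.viscosity_units <- c("Pa.s" = 1, "Pa s" = 1, "mPa.s" = 1e-3, "cP" = 1e-3)

.convert <- function(value, unit, table, what) {
  if (is.null(unit) || !nzchar(unit)) {
    stop("missing unit for ", what, " value", call. = FALSE)
  }
  k <- unname(table[match(unit, names(table))])
  if (length(k) != 1L || is.na(k)) {
    stop("unknown ", what, " unit '", unit, "' (expected one of: ",
         paste(names(table), collapse = ", "), ")", call. = FALSE)
  }
  value * k
}

#' Convert micrometres to metres
#'
#' Convenience converters used throughout examples and the CLI; the core
#' API works in SI units only.
#'
#' @param x numeric value(s) in the source unit.
#' @return numeric value(s) in SI units (m, m^3/s or kg/m^3).
#' @export
um <- function(x) x * 1e-6

#' @rdname um
#' @export
mm <- function(x) x * 1e-3

#' @rdname um
#' @export
ml_min <- function(x) x * 1e-6 / 60

#' @rdname um
#' @export
g_ml <- function(x) x * 1000

#' Parse a quantity string such as "1.7ml/min" or "21um"
#'
#' Accepts an optional space between the number and the unit. Used by the
#' command-line interface; returns the value in SI units.
#'
#' @param s a single string, e.g. `"500um"`, `"5 mm"`, `"1.7ml/min"`,
#'   `"1.05g/ml"`.
#' @param what one of `"length"`, `"flow"`, `"density"`, `"viscosity"`;
#'   selects the unit table.
#' @return numeric scalar in SI units.
#' @export
parse_quantity <- function(s, what = c("length", "flow", "density",
                                       "viscosity")) {
  what <- match.arg(what)
  table <- switch(what, length = .length_units, flow = .flow_units,
                  density = .density_units, viscosity = .viscosity_units)
  m <- regmatches(s, regexec("^\\s*([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3 || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop("cannot parse quantity '", s, "'", call. = FALSE)
  }
  val <- as.numeric(m[2])
  unit <- trimws(m[3])
  if (!nzchar(unit)) return(val)  # already SI
  .convert(val, unit, table, what)
}

# Convert a config entry {value, unit} (or bare number, taken as SI).
.config_quantity <- function(entry, what, field) {
  if (is.numeric(entry)) return(entry)
  if (is.list(entry) && !is.null(entry$value)) {
    table <- switch(what, length = .length_units, flow = .flow_units,
                    density = .density_units, viscosity = .viscosity_units,
                    count = NULL)
    if (is.null(table)) return(entry$value)
    return(tryCatch(.convert(entry$value, entry$unit, table, what),
                    error = function(e) {
                      stop("config field '", field, "': ",
                           conditionMessage(e), call. = FALSE)
                    }))
  }
  stop("config field '", field, "' must be a number or {value, unit} object",
       call. = FALSE)
}
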