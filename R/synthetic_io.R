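# Synthetic particle populations, replicate generators and file/config
# I/O. Populations emulate the experimental materials: monodisperse
# polymer microspheres ("regular") and cryogenically ground powders
# ("irregular") sieved below 100 um and sorted into +/- 2 um size bins,
# with circularity spread uniformly over 0.1-1.

#' Specification of a synthetic particle population
#'
#' @param n number of particles (>= 1).
#' @param nominal_diameter nominal bin centre (um).
#' @param bin_halfwidth half-width of the size bin (um); the measurement
#'   convention is +/- 2 um, the default.
#' @param density particle density (g/ml).
#' @param shape `"regular"` (microspheres, circularity 1) or
#'   `"irregular"` (ground powder, circularity uniform on \[0.1, 1\]).
#' @param diameter_distribution `"uniform_bin"` (uniform on the bin) or
#'   `"fixed"` (all particles exactly nominal; regular beads only).
#' @param seed integer seed; every stochastic draw is reproducible.
#' @param label free-text material label.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n, nominal_diameter, bin_halfwidth = 2,
                            density = 1.05,
                            shape = c("regular", "irregular"),
                            diameter_distribution = c("uniform_bin", "fixed"),
                            seed = 1L, label = shape) {
  shape <- match.arg(shape)
  diameter_distribution <- match.arg(diameter_distribution)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (bin_halfwidth < 0) stop("bin_halfwidth must be >= 0", call. = FALSE)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  if (nominal_diameter - bin_halfwidth <= 0) {
    stop("invalid population spec: size bin extends to non-positive ",
         "diameters", call. = FALSE)
  }
  structure(list(n = as.integer(n), nominal_diameter = nominal_diameter,
                 bin_halfwidth = bin_halfwidth, density = density,
                 shape = shape,
                 diameter_distribution = diameter_distribution,
                 seed = as.integer(seed), label = label[1]),
            class = "population_spec")
}

#' Generate a synthetic particle population
#'
#' Regular populations have circularity 1 and either a fixed diameter or
#' diameters uniform on the +/- bin; irregular populations draw
#' circularity uniform on \[0.1, 1\] and diameters uniform on the bin.
#' Diameters are truncated to (0, 100) um — powders are collected through
#' a 100 um filter. Deterministic given the spec's seed.
#'
#' @param spec a [population_spec()].
#' @return a `particle_population` data frame with columns `diameter_um`,
#'   `density_g_ml`, `circularity`, `label`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  lo <- max(spec$nominal_diameter - spec$bin_halfwidth, .Machine$double.eps)
  hi <- min(spec$nominal_diameter + spec$bin_halfwidth, 100)
  df <- .with_seed(spec$seed, {
    d <- if (spec$diameter_distribution == "fixed") {
      rep(spec$nominal_diameter, spec$n)
    } else {
      stats::runif(spec$n, lo, hi)
    }
    circ <- if (spec$shape == "regular") rep(1, spec$n) else
      stats::runif(spec$n, 0.1, 1)
    data.frame(diameter_um = d, density_g_ml = rep(spec$density, spec$n),
               circularity = circ, label = rep(spec$label, spec$n),
               stringsAsFactors = FALSE)
  })
  class(df) <- c("particle_population", class(df))
  df
}

#' Generate replicated hPRR measurements around a true value
#'
#' Fixture generator for the averaging test: replicates are drawn from
#' Normal(true_hprr, sd) and clipped to \[0, 100\] percent, emulating
#' "mean +/- SD of three independent experiments".
#'
#' @param true_hprr underlying mean hPRR (percent, in \[0, 100\]).
#' @param sd replicate standard deviation (percentage points, >= 0).
#' @param n_replicates number of replicates (>= 2); triplicates typical.
#' @param seed integer seed.
#' @param test_diameter diameter label for the measurement (um).
#' @param outlet outlet index label.
#' @return a [prr_measurement()].
#' @export
generate_prr_replicates <- function(true_hprr, sd, n_replicates = 3L,
                                    seed = 1L, test_diameter = NA_real_,
                                    outlet = NA_integer_) {
  if (true_hprr < 0 || true_hprr > 100) {
    stop("true_hprr must lie in [0, 100]", call. = FALSE)
  }
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n_replicates < 2L) stop("need >= 2 replicates", call. = FALSE)
  reps <- .with_seed(seed, stats::rnorm(n_replicates, true_hprr, sd))
  prr_measurement(test_diameter, pmin(100, pmax(0, reps)), outlet)
}

#' Read / write per-outlet count tables
#'
#' CSV with header `outlet,count`; outlets must be the contiguous block
#' 1..n with no duplicates and non-negative integer counts. Round-trips
#' are lossless.
#'
#' @param path file path.
#' @param n_outlets expected number of outlets; default: infer from file.
#' @return [read_counts()]: an [outlet_counts()]; [write_counts()]: the
#'   path, invisibly.
#' @export
read_counts <- function(path, n_outlets = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path,
                               call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("numeric", "numeric")),
    error = function(e) stop("malformed counts file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(names(df), c("outlet", "count"))) {
    stop("counts file must have exactly the columns 'outlet,count'",
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("counts file is empty", call. = FALSE)
  n <- if (is.null(n_outlets)) nrow(df) else as.integer(n_outlets)
  for (i in seq_len(nrow(df))) {
    o <- df$outlet[i]; cnt <- df$count[i]
    if (is.na(o) || o != round(o) || o < 1 || o > n) {
      stop("counts row ", i, ": outlet ", o, " outside 1..", n,
           call. = FALSE)
    }
    if (is.na(cnt) || cnt < 0 || cnt != round(cnt)) {
      stop("counts row ", i, ": count must be a non-negative integer, got ",
           cnt, call. = FALSE)
    }
  }
  if (anyDuplicated(df$outlet)) {
    stop("duplicate outlet rows: ",
         paste(unique(df$outlet[duplicated(df$outlet)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(df$outlet, seq_len(n))) {
    stop("outlet rows must cover 1..", n, " contiguously; missing: ",
         paste(setdiff(seq_len(n), df$outlet), collapse = ", "),
         call. = FALSE)
  }
  outlet_counts(df$count[order(df$outlet)])
}

#' @param counts an [outlet_counts()] (or coercible vector).
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  if (!inherits(counts, "outlet_counts")) counts <- outlet_counts(counts)
  utils::write.csv(
    data.frame(outlet = seq_along(counts), count = as.integer(counts)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a device/fluid configuration file
#'
#' JSON (default) or YAML document with keys `width`, `height`,
#' `spiral_radius`, `n_loops`, `loop_spacing`, `n_outlets`,
#' `outlet_width` and `fluid: {density, viscosity}`; each numeric value is
#' either a bare SI number or an object `{value, unit}` with explicit unit
#' tags (`um`, `mm`, `m`; `g/ml`, `kg/m3`; `mPa.s`, `Pa.s`). YAML support
#' requires the optional `yaml` package.
#'
#' @param path config file path (`.json`, `.yaml` or `.yml`).
#' @return list with elements `channel` (a [rect_channel()]) and `fluid`
#'   (a [fluid()]).
#' @export
read_device_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  need <- c("width", "height", "spiral_radius", "fluid")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  len <- function(f) .config_quantity(cfg[[f]], "length", f)
  n_outlets <- if (is.null(cfg$n_outlets)) 5L else
    as.integer(.config_quantity(cfg$n_outlets, "count", "n_outlets"))
  width <- len("width")
  channel <- rect_channel(
    width = width, height = len("height"),
    spiral_radius = len("spiral_radius"),
    n_loops = if (is.null(cfg$n_loops)) 10L else
      as.integer(.config_quantity(cfg$n_loops, "count", "n_loops")),
    loop_spacing = if (is.null(cfg$loop_spacing)) um(300) else
      len("loop_spacing"),
    n_outlets = n_outlets,
    outlet_width = if (is.null(cfg$outlet_width)) width / n_outlets else
      len("outlet_width"))
  fl <- fluid(
    density = .config_quantity(cfg$fluid$density, "density",
                               "fluid$density"),
    viscosity = .config_quantity(cfg$fluid$viscosity, "viscosity",
                                 "fluid$viscosity"))
  list(channel = channel, fluid = fl)
}

#' Read / write a particle population CSV
#'
#' Columns `diameter_um,density_g_per_ml,circularity` (the `density_g_ml`
#' spelling is also accepted on read).
#'
#' @param path file path.
#' @return a `particle_population` data frame.
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop("population file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  if ("density_g_per_ml" %in% names(df)) {
    names(df)[names(df) == "density_g_per_ml"] <- "density_g_ml"
  }
  need <- c("diameter_um", "density_g_ml", "circularity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("population file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$diameter_um <= 0) || any(df$density_g_ml <= 0) ||
      any(df$circularity <= 0 | df$circularity > 1)) {
    stop("population file contains out-of-range values", call. = FALSE)
  }
  class(df) <- c("particle_population", class(df))
  df
}

#' @param population a `particle_population` data frame.
#' @rdname read_population
#' @export
write_population <- function(population, path) {
  df <- as.data.frame(population)[, c("diameter_um", "density_g_ml",
                                      "circularity")]
  names(df)[2] <- "density_g_per_ml"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read calibration anchors for the density-coefficient model
#'
#' CSV with header `density_g_per_ml,c`.
#'
#' @param path file path.
#' @return data frame with columns `density_g_per_ml`, `c`.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("anchor file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("density_g_per_ml", "c") %in% names(df))) {
    stop("anchor file must have columns 'density_g_per_ml,c'",
         call. = FALSE)
  }
  df
}
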