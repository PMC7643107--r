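test_that("regular fixed populations are degenerate and deterministic", {
  spec <- population_spec(300, 21, density = 1.05, shape = "regular",
                          diameter_distribution = "fixed", seed = 5)
  pop <- generate_population(spec)
  expect_equal(nrow(pop), 300)
  expect_true(all(pop$diameter_um == 21))
  expect_true(all(pop$circularity == 1))
  expect_identical(generate_population(spec), pop)
})

test_that("irregular populations match the stated uniforms", {
  spec <- population_spec(1e4, 21, density = 1.05, shape = "irregular",
                          seed = 42)
  pop <- generate_population(spec)
  expect_lt(abs(mean(pop$diameter_um) - 21), 0.1)
  expect_true(all(pop$diameter_um > 19 & pop$diameter_um < 23))
  expect_lt(min(pop$circularity), 0.15)
  expect_gt(max(pop$circularity), 0.95)
  # KS against the stated uniforms at alpha = 0.01 (fixed seed)
  expect_gt(stats::ks.test(pop$diameter_um, "punif", 19, 23)$p.value, 0.01)
  expect_gt(stats::ks.test(pop$circularity, "punif", 0.1, 1)$p.value, 0.01)
})

test_that("population spec validation and truncation", {
  expect_error(population_spec(0, 21), "n must")
  expect_error(population_spec(100, 1.5, bin_halfwidth = 2),
               "non-positive")
  # bins never extend past the 100 um filter
  pop <- generate_population(population_spec(2000, 99, bin_halfwidth = 2,
                                             shape = "irregular", seed = 9))
  expect_true(all(pop$diameter_um <= 100))
})

test_that("replicate generator: clipping, degeneracy, sampling distribution", {
  m0 <- generate_prr_replicates(80, 0, 3, seed = 1)
  expect_equal(m0$replicate_hprrs, rep(80, 3))
  mc <- generate_prr_replicates(99, 10, 50, seed = 2)
  expect_true(all(mc$replicate_hprrs <= 100))
  expect_error(generate_prr_replicates(120, 5), "\\[0, 100\\]")
  expect_error(generate_prr_replicates(50, 5, n_replicates = 1), "replicates")
  # mean of replicate means over many seeds stays within 3 SE of the truth
  means <- vapply(1:400, function(s) {
    mean(generate_prr_replicates(91.6, 7.3, 3, seed = s)$replicate_hprrs)
  }, numeric(1))
  se <- 7.3 / sqrt(3 * 400)
  expect_lt(abs(mean(means) - 91.6), 3 * se + 0.2)  # +0.2: clipping bias at 100
})

test_that("counts I/O round-trips and validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  cnt <- outlet_counts(c(3, 0, 524, 476, 12))
  write_counts(cnt, path)
  expect_identical(as.integer(read_counts(path)), as.integer(cnt))
  expect_identical(as.integer(read_counts(path, n_outlets = 5)),
                   as.integer(cnt))

  # outlet index beyond the device
  writeLines(c("outlet,count", "1,5", "2,5", "3,5", "4,5", "6,5"), path)
  expect_error(read_counts(path, n_outlets = 5), "outside 1..5")
  # missing outlet row
  writeLines(c("outlet,count", "1,5", "2,5", "3,5", "5,5"), path)
  expect_error(read_counts(path, n_outlets = 5), "missing")
  # duplicates
  writeLines(c("outlet,count", "1,5", "1,6", "2,1"), path)
  expect_error(read_counts(path), "duplicate")
  # negative / non-integer counts
  writeLines(c("outlet,count", "1,-5", "2,5"), path)
  expect_error(read_counts(path), "row 1")
  # empty file is a schema error, not empty counts
  writeLines("outlet,count", path)
  expect_error(read_counts(path), "empty")
})

test_that("population I/O round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  pop <- generate_population(population_spec(50, 21, shape = "irregular",
                                             seed = 4))
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$diameter_um, pop$diameter_um, tolerance = 1e-12)
  expect_equal(back$density_g_ml, pop$density_g_ml)
  expect_equal(back$circularity, pop$circularity, tolerance = 1e-12)
})

test_that("device config loads with explicit units", {
  cfg <- read_device_config(system.file("extdata", "device.json",
                                        package = "spiralsort"))
  expect_equal(cfg$channel$width, um(500))
  expect_equal(cfg$channel$height, um(220))
  expect_equal(cfg$channel$spiral_radius, mm(5))
  expect_equal(cfg$channel$n_outlets, 5L)
  expect_equal(cfg$fluid$density, 1000)   # g/ml -> kg/m^3
  expect_equal(cfg$fluid$viscosity, 1e-3) # mPa.s -> Pa.s
  # unknown unit is an error, not a silent pass-through
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"width": {"value": 500, "unit": "furlong"},
               "height": {"value": 220, "unit": "um"},
               "spiral_radius": {"value": 5, "unit": "mm"},
               "fluid": {"density": 1000, "viscosity": 0.001}}', bad)
  expect_error(read_device_config(bad), "unknown length unit")
})

test_that("quantity strings parse with units", {
  expect_equal(parse_quantity("1.7ml/min", "flow"), ml_min(1.7))
  expect_equal(parse_quantity("21um", "length"), um(21))
  expect_equal(parse_quantity("5 mm", "length"), mm(5))
  expect_equal(parse_quantity("1.05g/ml", "density"), 1050)
  expect_error(parse_quantity("abc", "length"), "parse")
})

test_that("CLI subcommands run end-to-end", {
  # flow as machine-readable JSON
  out <- capture.output(suppressMessages(
    spiralsort_cli(c("flow", "--flow-rate", "1.7ml/min", "--json"))))
  j <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(j$velocity_m_s, 0.2575758, tolerance = 1e-6)
  expect_equal(j$hydraulic_diameter_um, 305.5556, tolerance = 1e-4)
  expect_equal(j$reynolds, 78.7037, tolerance = 1e-4)

  # TM4 threshold for talc density
  out2 <- capture.output(suppressMessages(
    spiralsort_cli(c("threshold", "--model", "TM4", "--density",
                     "2.75g/ml", "--json"))))
  j2 <- jsonlite::fromJSON(paste(out2, collapse = ""))
  expect_equal(j2$threshold_rounded_um, 26)

  # prr from a counts file
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(outlet_counts(c(0, 0, 524, 476, 0)), path)
  out3 <- capture.output(suppressMessages(
    spiralsort_cli(c("prr", "--counts", path, "--json"))))
  j3 <- jsonlite::fromJSON(paste(out3, collapse = ""))
  expect_equal(j3$hprr_outlet, 3)
  expect_equal(j3$hprr_value, 52.4)

  # simulate + generate round-trip through files
  popf <- withr::local_tempfile(fileext = ".csv")
  cntf <- withr::local_tempfile(fileext = ".csv")
  invisible(capture.output(suppressMessages(spiralsort_cli(c(
    "generate", "--n", "100", "--diameter", "21um", "--density",
    "1.05g/ml", "--bin-halfwidth", "0", "--distribution", "fixed",
    "--seed", "3", "--out", popf, "--json")))))
  out4 <- capture.output(suppressMessages(spiralsort_cli(c(
    "simulate", "--population", popf, "--seed", "3", "--out", cntf,
    "--json"))))
  j4 <- jsonlite::fromJSON(paste(out4, collapse = ""))
  expect_equal(sum(j4$counts), 100)
  expect_equal(as.integer(read_counts(cntf)), j4$counts)
})
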