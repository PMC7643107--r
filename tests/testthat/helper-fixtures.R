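# Shared fixtures: the reference device, water, and replicate builders.

ref_channel <- function() example_channel()

# a triplet with exact mean m and sample SD s
triplet <- function(m, s) c(m - s, m, m + s)

# deterministic hPRR oracle: "focuses like the reference" iff d >= flip.
# Zero-variance replicates make the Welch comparison deterministic.
step_oracle <- function(flip, ref_level = 90, low_level = 50) {
  function(d) {
    prr_measurement(d, rep(if (d >= flip) ref_level else low_level, 3))
  }
}

ref_measurement <- function(level = 90) prr_measurement(21, rep(level, 3))

# independent Welch oracle (closed-form), kept separate from compare_hprr
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = stats::pt(t, df))
}
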