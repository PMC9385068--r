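# Shared fixtures, all built in code.

# Five-point stream exercising every censoring rule: an equal-value run,
# a same-trend run, and a trend turn.
fx_five <- function() device_stream(1:5, c(70, 70, 72, 74, 73))

# Piecewise-linear stream with breakpoints every `spacing` minutes and
# strictly alternating slope signs, so every breakpoint is a salient
# turning point whenever spacing > alpha. Default slopes are dyadic
# rationals, so chord interpolation reproduces the values bit-exactly.
fx_piecewise_linear <- function(n_seg = 6, spacing = 50, start = 80,
                                slopes = NULL) {
  if (is.null(slopes))
    slopes <- rep_len(c(0.5, -0.25, 0.75, -0.5), n_seg)
  t <- seq_len(n_seg * spacing + 1)
  x <- numeric(length(t))
  x[1] <- start
  for (i in 2:length(t)) {
    seg <- ((t[i] - 2) %/% spacing) + 1
    x[i] <- x[i - 1] + slopes[seg]
  }
  device_stream(t, x)
}

# Random stream with no zero-derivative runs (consecutive values distinct).
fx_jitter_stream <- function(n = 80, seed = 1) {
  set.seed(seed)
  x <- cumsum(sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)) + 90
  device_stream(seq_len(n), x)
}
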