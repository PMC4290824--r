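# Internal numeric helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make normalized counts depend on the parity of the integer part.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Floor applied to every p-value before it leaves the package; keeps values
# strictly inside (0, 1] so that downstream logs and rank statistics are
# finite.
P_FLOOR <- 1e-300

# Relative variance inflation applied when a predicted variance does not
# exceed the mean: the negative binomial requires overdispersion.
VAR_EPSILON <- 1e-2

`%||%` <- function(a, b) if (is.null(a)) b else a
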