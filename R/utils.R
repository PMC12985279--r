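# Internal numeric helpers.

# Round half away from zero (commercial rounding).  base::round() rounds
# half to even, which would turn a cohort total landing exactly on .5 EUR
# the wrong way relative to how such tables are conventionally printed.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + sign(x) * 0.5) / m
}

# Convert EUR (<= 2 decimals) to integer cents without binary-float drift.
as_cents <- function(eur) {
  round(eur * 100)
}

cents_to_eur <- function(cents) {
  cents / 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a
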