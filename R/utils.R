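# round half away from zero to `digits` decimals; base round() is
# round-half-even, which does not reproduce printed survey tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# reverse cumulative sum: out[i] = sum(x[i:length(x)])
rev_cumsum <- function(x) rev(cumsum(rev(x)))

check_probability <- function(x, name = "probability") {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0(name, " must lie in [0, 1]"), class = "hlyr_domain_error")
  }
  invisible(x)
}
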