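#' @keywords internal
"_PACKAGE"

# Numerically stable log(1 + exp(x)); never NaN for finite x.
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

expit <- function(x) stats::plogis(x)

# Derive a 32-bit-safe stream seed from a master seed and a counter.
# Deterministic, collision-free for counters < 2^31 / 1 within a run.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %% 2147483647)
}
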