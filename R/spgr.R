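# Spoiled gradient-echo (SPGR) steady-state signal:
#   S = M0 sin(a) (1 - E) / (1 - E cos(a)),  E = exp(-TR * R1)
spgr_signal <- function(m0, r1, tr, alpha_deg) {
  a <- alpha_deg * pi / 180
  E <- exp(-tr * r1)
  m0 * sin(a) * (1 - E) / (1 - E * cos(a))
}

# Invert SPGR for R1 given M0. Returns NA where the signal sits on or above
# the SPGR ceiling (r >= 1) or is non-positive.
spgr_invert_r1 <- function(s, m0, tr, alpha_deg) {
  a <- alpha_deg * pi / 180
  r <- s / (m0 * sin(a))
  E <- (1 - r) / (1 - r * cos(a))
  out <- suppressWarnings(-log(E) / tr)
  out[!is.finite(out) | E <= 0 | E >= 1] <- NA_real_
  out
}
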