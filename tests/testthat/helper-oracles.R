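# Independent, deliberately naive reference implementations used to
# cross-check the vectorised energy kernels.

ref_noe_energy <- function(r, lower, upper, k, rs, fmax) {
  slope <- min(fmax, 2 * k * rs)
  if (r < lower) return(k * (lower - r)^2)
  if (r <= upper) return(0)
  if (r <= upper + rs) return(k * (r - upper)^2)
  k * rs^2 + slope * (r - upper - rs)
}

ref_dihedral_energy <- function(theta, theta0, delta, k) {
  d <- (theta - theta0) %% 360
  if (d > 180) d <- d - 360
  d <- abs(d)
  if (d <= delta) 0 else k * (d - delta)^2
}

ref_mcc <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}
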