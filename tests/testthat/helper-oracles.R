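## Independent statistical oracles.

## exact two-sided Mann-Whitney p by exhaustive enumeration of all
## rank assignments (symmetric null distribution of U)
mw_exact_oracle <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  u_obs <- sum(rank(c(a, b))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(utils::combn(n, n1), 2, function(idx) {
    sum(rank(c(a, b))[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (n - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

## whole-lung APF-weighted AWT of one measured phantom, at the fixed
## 3.5 mm diameter class
tube_awt35 <- function(locs, config = ct_config()) {
  sel <- select_fixed_diameter_locations(locs, config$target_diameter_mm,
                                         config$tol_mm, config$min_apf)
  if (nrow(sel) == 0) return(NA_real_)
  aggregate_lobes(sel)$awt_mm
}
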