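# Shared fixtures: DVHs built in code, brute-force per-voxel oracles.

# random voxel dose list and its DVH (one narrow bin per distinct dose)
random_voxel_dvh <- function(n = 50, max_dose = 70, min_dose = 0.5,
                             bin_width = 0.001) {
  doses <- round(runif(n, min_dose, max_dose), 2)
  doses <- unique(doses)
  list(doses = doses, dvh = dvh_from_doses(doses, bin_width = bin_width))
}

# brute-force oracles on a raw voxel list (equal volumes)
brute_mean <- function(doses) mean(doses)
brute_d_at_v <- function(doses, frac) {
  # largest dose d such that at least frac of voxels receive >= d
  sd <- sort(doses, decreasing = TRUE)
  sd[ceiling(frac * length(sd))]
}
brute_tcp <- function(doses, params) {
  p <- poisson_response(doses, params)
  prod(p^(1 / length(doses)))
}
brute_eud <- function(doses, n_volume) {
  mean(doses^(1 / n_volume))^n_volume
}

# invert the Poisson-LQ response: dose giving probability P
response_inverse <- function(P, params) {
  params$d50_gy * (1 - log(-log2(P)) / (exp(1) * params$gamma))
}

# two-structure plan used across pipeline tests
uniform_ptv <- function(dose = 60, width = 0.2) {
  dvh(c(0, dose - width / 2, dose + width / 2), c(1, 1, 0), "cumulative",
      "ptv")
}

simple_lung <- function(mean_gy = 5, cc = 3000, cap = 40, w = 0.5) {
  e <- seq(0, cap, by = w)
  cum <- exp(-e / mean_gy)
  cum <- pmax((cum - cum[length(cum)]) / (1 - cum[length(cum)]), 0)
  dvh(e, cum, "cumulative", "lung", total_volume_cc = cc)
}
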