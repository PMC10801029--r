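# Shared fixtures, all generated in code.

# A 4D two-compartment DWI volume: one voxel per entry of `fgrid` (arranged
# in the given dims), every voxel sharing the tissue tensor diag(evals).
mixed_signal_volume <- function(fgrid, dims = c(length(fgrid), 1, 1),
                                evals = c(1.7e-3, 0.2e-3, 0.2e-3),
                                gtab = phantom_gradient_table(),
                                S0 = 1000, snr = 0, seed = 1,
                                d_water = 3.0e-3, affine = diag(4)) {
  stopifnot(prod(dims) == length(fgrid))
  b <- gtab$bvals
  g <- gtab$bvecs
  q <- rowSums((g %*% diag(evals)) * g) * b
  att <- exp(-q)
  wat <- exp(-b * d_water)
  S <- S0 * (outer(att, 1 - fgrid) + outer(wat, fgrid))
  if (snr > 0) {
    set.seed(seed)
    sg <- S0 / snr
    S <- sqrt((S + matrix(rnorm(length(S), 0, sg), nrow(S)))^2 +
                matrix(rnorm(length(S), 0, sg), nrow(S))^2)
  }
  image_volume(array(t(S), c(dims, length(b))), affine)
}

# FA of an eigenvalue triple, straight from the definition (test oracle)
fa_of_eigenvalues <- function(lam) {
  md <- mean(lam)
  sqrt(1.5) * sqrt(sum((lam - md)^2)) / sqrt(sum(lam^2))
}

# The full standard-edema benchmark, computed once per test session.
.benchmark_cache <- new.env(parent = emptyenv())
standard_benchmark <- function() {
  if (!is.null(.benchmark_cache$bm)) return(.benchmark_cache$bm)
  ph <- standard_edema_phantom(seed = 7)
  mask <- ph$truth$brain
  tf <- fit_tensor(ph$dwi, ph$gtab, mask)
  maps <- tensor_metrics(tf)
  fit <- suppressMessages(fit_freewater(ph$dwi, ph$gtab, mask))
  cmaps <- corrected_fa(fit$tensor, fit$fw)
  params <- tracking_params(seed = 7)
  seeds <- seeds_from_mask(ph$truth$bundle, params)
  t_unc <- track(tf, maps, seeds, params)
  t_cor <- track(fit$tensor, cmaps, seeds, params, fw_gate = fit$fw)
  fwt <- parameterize_tractogram(t_cor, fit$fw)
  bm <- list(ph = ph, tf = tf, maps = maps, fit = fit, cmaps = cmaps,
             params = params, seeds = seeds, t_unc = t_unc, t_cor = t_cor,
             fwt = fwt)
  .benchmark_cache$bm <- bm
  bm
}

# Printed survey table used for the agreement-identity checks: per item the
# published percent agreement, chance agreement, coefficient and rating.
published_survey_table <- function() {
  data.frame(
    item = c("brain-tumor interface", "false signal CSF",
             "false negative normal brain", "false negative near lesion",
             "grey-white interface", "spatial orientation",
             "tract reduction", "tract displacement",
             "tract infiltration", "surgical pathway"),
    pa = c(0.6364, 0.7084, 0.6924, 0.8533, 0.8035, 0.7395, 0.7603,
           0.8160, 0.6679, 0.8448),
    pe = c(0.6189, 0.5223, 0.5370, 0.4329, 0.4616, 0.3541, 0.4978,
           0.3756, 0.6269, 0.4591),
    ac2 = c(0.05, 0.39, 0.34, 0.74, 0.64, 0.60, 0.52, 0.71, 0.11, 0.71),
    rating = c("poor", "fair", "fair", "substantial", "substantial",
               "moderate", "moderate", "substantial", "poor", "substantial"),
    stringsAsFactors = FALSE)
}
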