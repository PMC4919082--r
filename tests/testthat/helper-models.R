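# Reference parameter sets used throughout the suite: the single-resource
# growth-competition model at three noise levels and the two-resource
# utilisation model.
ref_gbm <- function(sigma1 = 0.5, phi = 10, ...)
  gbm_model(b1 = 0.15, sigma1 = sigma1, mu0 = 0.01, x0 = 0.01,
            xstar = 1.5, phi = phi, ...)

ref_two <- function(kappa = 0.5, phi = 10, ...)
  two_resource_model(b1 = 0.15, b2 = 0.05, sigma1 = 0.6, sigma2 = 0.02,
                     kappa = kappa, mu0 = 0.01, x0 = 0.01, xstar = 1.5,
                     phi = phi, ...)
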