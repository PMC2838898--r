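# Eigenvalue sign-convention guard: a dark ridge on a bright background
# must yield lambda1 > 0 under the package's Gaussian-derivative Hessian.
# Everything in the tracking module builds on this orientation.
local({
  img <- matrix(0.6, 41, 41)
  img[20:21, ] <- 0.3
  h <- hessian_field(img, sigma_h = 1.5)
  stopifnot(h$lambda1[20, 21] > 0, abs(h$lambda2[20, 21]) < h$lambda1[20, 21])
})
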