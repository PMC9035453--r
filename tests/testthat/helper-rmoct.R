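# shared test utilities

# random complex matrix with unit-variance components
cmat <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)),
         n, m)
}

cfrob <- function(x) sqrt(sum(Mod(x)^2))

# random unitary matrix via QR of a complex Gaussian
runitary <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(cmat(n, n)))
}

disk_mask_for_tests <- function(n, centre, radius) {
  outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2, `+`) <= radius^2
}

# small geometry whose scan points coincide exactly with pixel centres:
# 16 x 16 scan on a 32 px grid over the same FOV (scan pitch = 2 px)
aligned_geometry <- function() {
  list(grid = grid_spec(32), scan = scan_grid(16))
}
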