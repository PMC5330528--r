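# Independent numerical oracles and small random fixtures used across the
# suite. Oracles deliberately avoid the package's closed-form code paths.

# Slope-constrained reference shielding by 1-D numerical least squares:
# minimise sum((delta_exp - (s - sigma))^2) over s.
sigma_ref_oracle <- function(sigma, delta_exp) {
  obj <- function(s) sum((delta_exp - (s - sigma))^2)
  stats::optimize(obj, interval = range(sigma + delta_exp) + c(-50, 50),
                  tol = 1e-12)$minimum
}

# Optimal-superposition RMSD by direct numerical minimisation over Euler
# angles (after centroid alignment), independent of the SVD solution.
superpose_oracle <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  euler_rot <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(p) mean(rowSums((b0 %*% t(euler_rot(p)) - a0)^2))
  best <- Inf
  for (start in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                     c(pi, 0, 0), c(0, 0, pi / 2), c(1, 1, 1))) {
    r <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
    best <- min(best, r$value)
  }
  sqrt(best)
}

# Random molecular-free crystal for I/O round trips: triclinic-ish cell,
# a handful of random sites.
random_crystal <- function(seed, n_sites = 6) {
  set.seed(seed)
  cell <- unit_cell(runif(1, 5, 15), runif(1, 5, 15), runif(1, 5, 15),
                    runif(1, 75, 105), runif(1, 75, 105), runif(1, 75, 105))
  sites <- data.frame(
    label = paste0(sample(c("C", "N", "O"), n_sites, replace = TRUE), seq_len(n_sites)),
    element = NA, fx = runif(n_sites), fy = runif(n_sites), fz = runif(n_sites),
    stringsAsFactors = FALSE
  )
  sites$element <- gsub("[0-9]", "", sites$label)
  crystal(cell, sites, name = sprintf("random_%d", seed))
}

# Random rigid motion applied to a coordinate matrix.
random_rigid <- function(x, seed) {
  set.seed(seed)
  ax <- rnorm(3)
  ang <- runif(1, 0, 2 * pi)
  r <- nmrcsp:::rotation_matrix(ax, ang)
  sweep(x %*% t(r), 2, rnorm(3, 0, 5), "+")
}

# A tiny fast campaign configuration for pipeline-level tests.
small_campaign_config <- function(approaches = c("static", "md"), n_decoys = 3,
                                  n_transitions = 1) {
  campaign_config(n_decoys = n_decoys, approaches = approaches,
                  n_transitions = n_transitions)
}
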