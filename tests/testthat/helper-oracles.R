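# Analytic oracles and synthetic fixtures shared across tests.
#
# One-dimensional harmonic ("Gaussian ladder") states are the workhorse:
# u_l(x) = k_l x^2 / 2 sampled exactly with rnorm, so estimator tests compare
# against the closed-form free energy difference (1/2) log(k_j / k_i)
# without any Markov-chain error.

gaussian_ladder_rpm <- function(k_vec, n_per_state, seed = 1) {
  set.seed(seed)
  K <- length(k_vec)
  x <- unlist(lapply(k_vec, function(k) rnorm(n_per_state, 0, 1 / sqrt(k))))
  u <- outer(x^2, k_vec / 2)
  structure(list(u = u, N_k = rep(as.integer(n_per_state), K),
                 origin = rep(seq_len(K), each = n_per_state), diag_dev = 0),
            class = "reduced_potential_matrix")
}

gaussian_ladder_exact <- function(k_vec) 0.5 * log(k_vec[length(k_vec)] / k_vec[1])

# shifted unit harmonic states u_l(x) = (x - m_l)^2 / 2; exact df = 0
shifted_gaussian_rpm <- function(means, n_per_state, seed = 1) {
  set.seed(seed)
  K <- length(means)
  x <- unlist(lapply(means, function(m) rnorm(n_per_state, m, 1)))
  u <- vapply(means, function(m) (x - m)^2 / 2, numeric(length(x)))
  structure(list(u = u, N_k = rep(as.integer(n_per_state), K),
                 origin = rep(seq_len(K), each = n_per_state), diag_dev = 0),
            class = "reduced_potential_matrix")
}

rpm_from_parts <- function(u, N_k) {
  structure(list(u = u, N_k = as.integer(N_k),
                 origin = rep(seq_along(N_k), times = N_k), diag_dev = 0),
            class = "reduced_potential_matrix")
}

# restrict a reduced-potential matrix to a contiguous block of states
rpm_subset <- function(rpm, states) {
  keep <- rpm$origin %in% states
  structure(list(u = rpm$u[keep, states, drop = FALSE],
                 N_k = rpm$N_k[states],
                 origin = match(rpm$origin[keep], states),
                 diag_dev = rpm$diag_dev),
            class = "reduced_potential_matrix")
}

# small diatomic topology used by molecular-crystal tests
diatomic_topology <- function(d = 1.2, sigma_rot = 1L) {
  molecule_topology(c("C", "O"), c(12.011, 15.999),
                    rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
                    bonds = rbind(c(1L, 2L)), bond_k = 300, bond_r0 = d,
                    sigma_rot = sigma_rot, linear = TRUE)
}
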