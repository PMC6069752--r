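#' Sample configurations from one alchemical state
#'
#' Draws configurations from \eqn{\propto e^{-H(\lambda)}} (beta = 1) with
#' either a single-particle-move Metropolis sampler (default; exact for these
#' toy Hamiltonians) or BAOAB-discretized Langevin dynamics. The fixed atom,
#' if any, is never displaced. The Metropolis step size is auto-tuned to
#' 30-50 % acceptance during the equilibration window only — tuning during
#' production would break detailed balance — and the equilibration fraction
#' is discarded.
#'
#' @param model an [energy_model] (the state's Hamiltonian).
#' @param coords0 starting configuration (n x 3).
#' @param n_steps number of MC sweeps (one attempted move per mobile atom) or
#'   Langevin steps, >= 1.
#' @param seed integer seed for the state's private RNG stream; identical
#'   seeds reproduce identical trajectories.
#' @param fixed_atom fixed atom index, or 0 for none.
#' @param mode `"metropolis"` or `"langevin"`.
#' @param step initial Metropolis displacement (Angstrom); tuned during
#'   equilibration.
#' @param equil_frac fraction of steps discarded as equilibration (default
#'   0.1).
#' @param save_every keep every `save_every`-th production configuration.
#' @param dt,gamma Langevin reduced time step and friction.
#' @return an object of class `state_samples`: `frames` (n x 3 x n_frames
#'   array), `energies` (sampling-time totals), `acceptance`, `step`, `seed`.
#' @export
sample_state <- function(model, coords0, n_steps, seed, fixed_atom = 0L,
                         mode = c("metropolis", "langevin"), step = 0.1,
                         equil_frac = 0.1, save_every = 1L, dt = 0.01,
                         gamma = 1) {
  mode <- match.arg(mode)
  stopifnot(n_steps >= 1)
  coords0 <- as.matrix(coords0)
  n_equil <- floor(n_steps * equil_frac)
  res <- if (mode == "metropolis") {
    cpp_mc_sample(coords0, term_list(model), model$box, as.integer(fixed_atom),
                  as.integer(n_steps), as.integer(n_equil), step, TRUE,
                  as.integer(save_every), as.numeric(seed))
  } else {
    cpp_baoab(coords0, term_list(model), model$box, as.integer(fixed_atom),
              as.integer(n_steps), as.integer(n_equil), dt, gamma,
              as.integer(save_every), as.numeric(seed))
  }
  if (mode == "metropolis" && !is.na(res$acceptance) && res$acceptance == 0)
    warning("zero acceptance after tuning: pathological state")
  structure(list(frames = res$frames, energies = res$energies,
                 acceptance = res$acceptance, step = res$step, seed = seed,
                 n_steps = n_steps, mode = mode, model = model,
                 fixed_atom = as.integer(fixed_atom)),
            class = "state_samples")
}

#' @export
print.state_samples <- function(x, ...) {
  cat(sprintf("State samples: %d frames (%s, acceptance %.2f, step %.3g, seed %s)\n",
              dim(x$frames)[3], x$mode,
              if (is.na(x$acceptance)) NA else x$acceptance, x$step,
              format(x$seed)))
  invisible(x)
}

#' Sample every state of an alchemical path
#'
#' Runs [sample_state] for each state model with per-state RNG streams
#' derived from one master seed by fixed offsets, then (optionally)
#' subsamples each state's configurations at its statistical inefficiency so
#' downstream estimators see approximately independent samples.
#'
#' @param states list of [energy_model]s (e.g. from [alchemical_states]).
#' @param coords0 starting configuration for every state.
#' @param n_steps sweeps per state.
#' @param seed master seed; state i uses `seed + 7919 * i`.
#' @param subsample logical; subsample frames by the statistical inefficiency
#'   of the energy series (default TRUE).
#' @param step initial Metropolis displacement; a scalar, or one value per
#'   state (useful when the stiffness varies strongly along the path, e.g.
#'   `step ~ 1/sqrt(k_state)`).
#' @param ... passed to [sample_state].
#' @return an object of class `sample_set`: per-state `state_samples`
#'   (subsampled), sample counts `N_k`, inefficiencies `g`.
#' @export
sample_path <- function(states, coords0, n_steps, seed, subsample = TRUE,
                        step = 0.1, ...) {
  K <- length(states)
  step <- rep_len(step, K)
  samples <- vector("list", K)
  g <- numeric(K)
  for (i in seq_len(K)) {
    s <- sample_state(states[[i]], coords0, n_steps, seed = seed + 7919 * i,
                      step = step[i], ...)
    if (subsample && length(s$energies) >= 2) {
      sub <- subsample_decorrelated(s$energies)
      g[i] <- sub$g
      s$frames <- s$frames[, , sub$indices, drop = FALSE]
      s$energies <- s$energies[sub$indices]
    } else {
      g[i] <- 1
    }
    samples[[i]] <- s
  }
  structure(list(samples = samples, N_k = vapply(samples, function(s)
    dim(s$frames)[3], 0L), g = g, seed = seed),
    class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d states, N_k in [%d, %d], inefficiency g in [%.2f, %.2f]\n",
              length(x$samples), min(x$N_k), max(x$N_k), min(x$g), max(x$g)))
  invisible(x)
}

#' Statistical inefficiency of a time series
#'
#' Estimates \eqn{g = 1 + 2 \sum_t (1 - t/n) \rho_t} from the normalized
#' autocorrelation function, truncating the sum when the autocorrelation
#' first drops below zero. Samples spaced by `ceiling(g)` are approximately
#' independent. A constant series has no information; it is flagged and
#' assigned g = n (one effective sample).
#'
#' @param series numeric vector, length >= 2.
#' @return list with `g`, `n_eff` and `constant` flag.
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 2) stop("series must have length >= 2")
  v <- var(series)
  if (!is.finite(v) || v <= 0) {
    warning("constant series: one effective sample")
    return(list(g = n, n_eff = 1, constant = TRUE))
  }
  x <- series - mean(series)
  # autocovariance via FFT with zero padding (linear, not circular);
  # normalization cancels in rho
  m <- nextn(2 * n)
  ft <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(ft * Conj(ft), inverse = TRUE))[seq_len(n)]
  rho <- ac / ac[1]
  g <- 1
  for (t in seq_len(n - 1)) {
    if (rho[t + 1] <= 0) break
    g <- g + 2 * (1 - t / n) * rho[t + 1]
  }
  list(g = max(1, g), n_eff = n / max(1, g), constant = FALSE)
}

#' Subsample a series at its statistical inefficiency
#'
#' @param series numeric vector (e.g. sampling-time energies).
#' @return list with `indices` (spaced by `ceiling(g)`), `g`, and `n_eff`.
#' @export
subsample_decorrelated <- function(series) {
  si <- statistical_inefficiency(series)
  idx <- seq(1, length(series), by = ceiling(si$g))
  list(indices = idx, g = si$g, n_eff = si$n_eff)
}

#' Cross-evaluate samples in every state's Hamiltonian
#'
#' Builds the reduced-potential matrix \eqn{u_{n,l}}: every sample from every
#' state, re-evaluated under every state's Hamiltonian (k_B T). This is the
#' single input that BAR/MBAR estimation and the overlap diagnostic need.
#' Terms shared between states (everything except coefficients and soft-core
#' lambda) are evaluated once per frame and recombined, so the cost is one
#' energy pass per distinct term rather than per state.
#'
#' @param samples a [sample_set].
#' @param states the list of state [energy_model]s the samples came from.
#' @return an object of class `reduced_potential_matrix`: `u` (N_total x K),
#'   `N_k`, `origin` (state of each pooled row), `diag_dev` (largest
#'   deviation between `u[n, k(n)]` and the sampling-time energy).
#' @export
cross_evaluate <- function(samples, states) {
  stopifnot(inherits(samples, "sample_set"))
  K <- length(states)
  if (length(samples$samples) != K) stop("missing states: samples and states differ in length")
  if (any(samples$N_k < 1)) stop("every state needs at least one sample")
  box <- states[[1]]$box

  # unique terms across states (ignoring coefficients)
  uniq <- list()
  cmat_idx <- vector("list", K)
  coeffs <- vector("list", K)
  for (l in seq_len(K)) {
    tms <- states[[l]]$terms
    idx <- integer(length(tms))
    for (j in seq_along(tms)) {
      t0 <- tms[[j]]
      t0$coeff <- NULL
      t0$name <- NULL
      hit <- 0L
      for (q in seq_along(uniq)) if (identical(uniq[[q]], t0)) { hit <- q; break }
      if (hit == 0L) { uniq[[length(uniq) + 1L]] <- t0; hit <- length(uniq) }
      idx[j] <- hit
    }
    cmat_idx[[l]] <- idx
    coeffs[[l]] <- vapply(tms, `[[`, 1.0, "coeff")
  }
  C <- matrix(0, length(uniq), K)
  for (l in seq_len(K)) {
    for (j in seq_along(cmat_idx[[l]]))
      C[cmat_idx[[l]][j], l] <- C[cmat_idx[[l]][j], l] + coeffs[[l]][j]
  }
  uniq_terms <- lapply(uniq, function(t) { t$coeff <- 1; t })

  # pool frames
  n_atoms <- dim(samples$samples[[1]]$frames)[1]
  Ntot <- sum(samples$N_k)
  frames <- array(0, c(n_atoms, 3, Ntot))
  origin <- integer(Ntot)
  pos <- 0L
  for (k in seq_len(K)) {
    nk <- samples$N_k[k]
    frames[, , pos + seq_len(nk)] <- samples$samples[[k]]$frames
    origin[pos + seq_len(nk)] <- k
    pos <- pos + nk
  }
  E <- cpp_term_energies_frames(frames, uniq_terms, box)
  u <- E %*% C
  if (any(!is.finite(u))) stop("non-finite reduced potentials")

  samp_e <- unlist(lapply(samples$samples, `[[`, "energies"))
  diag_dev <- max(abs(u[cbind(seq_len(Ntot), origin)] - samp_e))
  structure(list(u = u, N_k = as.integer(samples$N_k), origin = origin,
                 diag_dev = diag_dev),
            class = "reduced_potential_matrix")
}

#' @export
print.reduced_potential_matrix <- function(x, ...) {
  cat(sprintf("Reduced potential matrix: %d pooled samples x %d states (diag dev %.2e)\n",
              nrow(x$u), ncol(x$u), x$diag_dev))
  invisible(x)
}

#' Reduced-potential matrix as a padded 3-D array
#'
#' Returns `u[k, l, n]` (sample n drawn in state k, evaluated in state l),
#' padded with NA beyond each state's sample count, with attribute `N_k`.
#'
#' @param rpm a `reduced_potential_matrix`.
#' @return K x K x max(N_k) array.
#' @export
rpm_array <- function(rpm) {
  K <- ncol(rpm$u)
  nmax <- max(rpm$N_k)
  arr <- array(NA_real_, c(K, K, nmax))
  for (k in seq_len(K)) {
    rows <- which(rpm$origin == k)
    for (l in seq_len(K)) arr[k, l, seq_along(rows)] <- rpm$u[rows, l]
  }
  attr(arr, "N_k") <- rpm$N_k
  arr
}

#' Serialize / restore a reduced-potential matrix
#'
#' Long-format CSV (`k`, `l`, `n`, `u`) plus a JSON sidecar carrying sample
#' counts; the pair round-trips through [read_rpm].
#'
#' @param rpm a `reduced_potential_matrix`.
#' @param file CSV path; the sidecar is `<file>.json`.
#' @export
write_rpm <- function(rpm, file) {
  K <- ncol(rpm$u)
  n_within <- unlist(lapply(rpm$N_k, seq_len))
  df <- data.frame(
    k = rep(rpm$origin, times = K),
    l = rep(seq_len(K), each = nrow(rpm$u)),
    n = rep(n_within, times = K),
    u = as.vector(rpm$u)
  )
  write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(list(N_k = rpm$N_k, diag_dev = rpm$diag_dev),
                       paste0(file, ".json"), digits = NA)
  invisible(file)
}

#' @rdname write_rpm
#' @export
read_rpm <- function(file) {
  df <- read.csv(file)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  N_k <- as.integer(side$N_k)
  K <- length(N_k)
  Ntot <- sum(N_k)
  u <- matrix(df$u, nrow = Ntot, ncol = K)
  origin <- df$k[seq_len(Ntot)]
  structure(list(u = u, N_k = N_k, origin = origin,
                 diag_dev = side$diag_dev),
            class = "reduced_potential_matrix")
}
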