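#' Free energy estimate container
#'
#' @param value free energy difference (k_B T).
#' @param se standard error (k_B T, >= 0).
#' @param estimator estimator name.
#' @param n_states number of lambda states used.
#' @param segments optional per-segment breakdown (data.frame with `value`,
#'   `se`).
#' @param diagnostics optional list (overlap report, solver iterations, ...).
#' @return an object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(value, se, estimator, n_states = NA_integer_,
                                 segments = NULL, diagnostics = list()) {
  if (!is.na(se) && se < 0) stop("standard error must be >= 0")
  structure(list(value = value, se = se, estimator = estimator,
                 n_states = n_states, segments = segments,
                 diagnostics = diagnostics),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("dA = %.6g +/- %.3g k_BT  [%s%s]\n", x$value, x$se, x$estimator,
              if (!is.na(x$n_states)) sprintf(", %d states", x$n_states) else ""))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Thermodynamic integration
#'
#' Trapezoidal quadrature of the ensemble-averaged Hamiltonian derivative
#' \eqn{\Delta A = \int_0^1 \langle \partial H / \partial \lambda
#' \rangle_\lambda d\lambda}. The reported error propagates only the
#' statistical errors of the integrand at the sampled lambda values; it says
#' nothing about whether the integrand varies smoothly between them or
#' whether phase space overlap along the path is adequate — sparse-state TI
#' can look precise while being badly wrong, which is why the overlap-aware
#' estimators are preferred for diagnosis.
#'
#' @param lambdas sorted lambda values (>= 2).
#' @param dhdl_means ensemble means of dH/dlambda per state (k_B T).
#' @param dhdl_ses standard errors of those means.
#' @return a [free_energy_estimate].
#' @export
ti_estimate <- function(lambdas, dhdl_means, dhdl_ses = rep(0, length(lambdas))) {
  K <- length(lambdas)
  stopifnot(K >= 2, length(dhdl_means) == K, length(dhdl_ses) == K)
  if (is.unsorted(lambdas, strictly = TRUE)) stop("lambdas must be sorted increasing")
  if (any(!is.finite(dhdl_means))) stop("non-finite integrand")
  h <- diff(lambdas)
  w <- c(h / 2, 0) + c(0, h / 2) # trapezoid weights
  value <- sum(w * dhdl_means)
  se <- sqrt(sum((w * dhdl_ses)^2))
  seg <- data.frame(
    value = h * (dhdl_means[-K] + dhdl_means[-1]) / 2,
    se = h / 2 * sqrt(dhdl_ses[-K]^2 + dhdl_ses[-1]^2)
  )
  free_energy_estimate(value, se, "TI", K, segments = seg)
}

#' Exponential averaging (one-sided free energy perturbation)
#'
#' \eqn{\Delta A = -\ln \langle e^{-\Delta U} \rangle} over samples of the
#' initial state (beta = 1). Exact in the infinite-sample limit but biased
#' and slowly convergent when the target state is poorly represented in the
#' sampled configurations; forward and backward applications that disagree
#' beyond their joint error are the classic symptom.
#'
#' @param dU energy differences H_final - H_initial (k_B T) for initial-state
#'   samples.
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed seed for the bootstrap.
#' @return a [free_energy_estimate].
#' @export
exp_estimate <- function(dU, n_boot = 200, seed = 1L) {
  n <- length(dU)
  if (n < 1) stop("need at least one sample")
  est <- -(logsumexp(-dU) - log(n))
  se <- 0
  if (n > 1 && n_boot > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      d <- dU[sample.int(n, n, replace = TRUE)]
      -(logsumexp(-d) - log(n))
    }, 0)
    se <- sd(bs)
  }
  free_energy_estimate(est, se, "EXP", 2L)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Bennett acceptance ratio (two states)
#'
#' Solves the self-consistent acceptance-ratio equation for the free energy
#' difference between two states from forward and backward energy
#' differences, weighting by the number of statistically independent samples
#' in each state. The root is bracketed and solved to `tol`; absence of a
#' root within any expanded bracket signals catastrophic overlap failure and
#' raises an error rather than returning a silently wrong number.
#'
#' The asymptotic variance is the logistic-information expression
#' \eqn{1 / \sum_n h_n (1 - h_n) - 1/N_F - 1/N_R} with \eqn{h_n} the Fermi
#' weights at the solution.
#'
#' @param dU_f forward differences \eqn{U_1 - U_0} on state-0 samples.
#' @param dU_b backward differences \eqn{U_0 - U_1} on state-1 samples.
#' @param tol convergence tolerance for the root (k_B T).
#' @return a [free_energy_estimate].
#' @export
bar_estimate <- function(dU_f, dU_b, tol = 1e-10) {
  N0 <- length(dU_f); N1 <- length(dU_b)
  if (N0 < 1 || N1 < 1) stop("both directions need samples")
  M <- log(N0 / N1)
  fermi <- function(x) 1 / (1 + exp(x))
  # stationarity of the two-state mixture likelihood:
  # sum over pooled samples of the state-1 posterior weight equals N1
  gfun <- function(d) {
    sum(fermi(M + dU_f - d)) + sum(fermi(M - dU_b - d)) - N1
  }
  lo <- min(-dU_b, dU_f) - 10
  hi <- max(-dU_b, dU_f) + 10
  for (i in 1:60) {
    if (gfun(lo) < 0 && gfun(hi) > 0) break
    lo <- lo - 2^i; hi <- hi + 2^i
    if (i == 60) stop("BAR: no root found; catastrophic overlap failure")
  }
  d <- uniroot(gfun, c(lo, hi), tol = tol)$root
  h <- c(fermi(M + dU_f - d), fermi(M - dU_b - d))
  info <- sum(h * (1 - h))
  v <- 1 / info - 1 / N0 - 1 / N1
  free_energy_estimate(d, sqrt(max(v, 0)), "BAR", 2L)
}

#' Multistate Bennett acceptance ratio
#'
#' Solves the MBAR self-consistent equations for the dimensionless free
#' energies of all states (anchored at `f_1 = 0`) from the cross-evaluated
#' reduced-potential matrix: self-consistent iteration warm-up followed by
#' Newton polishing on the pooled-mixture likelihood, to a tight tolerance so
#' the overlap diagnostics are reproducible. Returns the asymptotic
#' covariance of the free energies and the phase-space overlap matrix.
#'
#' @param rpm a `reduced_potential_matrix` (from [cross_evaluate] or
#'   [read_rpm]), or a plain N x K matrix (then `N_k` is required).
#' @param N_k per-state sample counts when `rpm` is a plain matrix.
#' @param tol convergence tolerance on the free energies (k_B T).
#' @param max_iter iteration cap; non-convergence is reported with the
#'   residual norm.
#' @return an object of class `mbar_result`: `f` (per-state free energies),
#'   `Theta` (asymptotic covariance), `overlap` (an `overlap_matrix`),
#'   `value`/`se` (end-to-end difference `f_K - f_1`), `iterations`,
#'   `converged`, `residual`.
#' @export
mbar_solve <- function(rpm, N_k = NULL, tol = 1e-10, max_iter = 2000L) {
  if (inherits(rpm, "reduced_potential_matrix")) {
    u <- rpm$u; N_k <- rpm$N_k
  } else {
    u <- rpm
    if (is.null(N_k)) stop("N_k required for a plain matrix")
  }
  if (any(N_k < 1)) stop("all states need at least one sample")
  if (any(!is.finite(u))) stop("non-finite reduced potentials")
  K <- ncol(u); Ntot <- nrow(u)
  stopifnot(sum(N_k) == Ntot)
  logN <- log(N_k)

  # log denominator per pooled sample: logsumexp_k(logN_k + f_k - u_nk)
  log_denom <- function(f) {
    M <- sweep(-u, 2, f + logN, "+")
    mx <- do.call(pmax, lapply(seq_len(K), function(j) M[, j]))
    mx + log(rowSums(exp(M - mx)))
  }
  new_f <- function(f, ld) {
    A <- -u - ld
    mx <- vapply(seq_len(K), function(j) max(A[, j]), 0)
    fn <- -(mx + log(colSums(exp(sweep(A, 2, mx)))))
    fn - fn[1]
  }
  grad_norm <- function(f) {
    ld <- log_denom(f)
    W <- exp(sweep(-u, 2, f, "+") - ld)
    max(abs(N_k * (colSums(W) - 1)))
  }
  f <- numeric(K)
  iter <- 0L
  converged <- FALSE
  resid <- Inf
  repeat {
    iter <- iter + 1L
    ld <- log_denom(f)
    # self-consistent update
    f_sc <- new_f(f, ld)
    # Newton step on the pooled likelihood (states 2..K; f_1 anchored)
    W <- exp(sweep(-u, 2, f, "+") - ld) # satisfies sum_k N_k W_nk = 1 at any f
    Wn <- sweep(W, 2, N_k, "*")
    cs <- colSums(W)
    grad <- N_k * (cs - 1)
    H <- -crossprod(Wn) + diag(N_k * cs, K)
    f_nt <- tryCatch({
      step <- solve(H[-1, -1, drop = FALSE], grad[-1])
      fn <- f
      fn[-1] <- fn[-1] - step
      fn
    }, error = function(e) NULL)
    pick <- f_sc
    if (iter > 2 && !is.null(f_nt) && all(is.finite(f_nt))) {
      # adaptive: keep whichever candidate has the smaller gradient norm
      if (grad_norm(f_nt) < grad_norm(f_sc)) pick <- f_nt
    }
    resid <- max(abs(pick - f))
    f <- pick
    if (resid < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  ld <- log_denom(f)
  f <- new_f(f, ld)
  ld <- log_denom(f)
  W <- exp(sweep(-u, 2, f, "+") - ld)
  WtW <- crossprod(W)
  O <- WtW * rep(N_k, each = K) # O_ij = sum_n W_ni W_nj N_j
  Theta <- mbar_covariance(WtW, N_k)
  se_total <- sqrt(max(Theta[1, 1] + Theta[K, K] - 2 * Theta[1, K], 0))
  if (!converged)
    warning(sprintf("MBAR did not converge in %d iterations (residual %.3e)",
                    iter, resid))
  structure(list(
    f = f, Theta = Theta,
    overlap = structure(O, class = "overlap_matrix"),
    value = f[K] - f[1], se = se_total,
    N_k = N_k, iterations = iter, converged = converged, residual = resid
  ), class = "mbar_result")
}

# Asymptotic covariance from the K x K Gram matrix of the weight matrix:
# Theta = V S (I - S V' N V S)^+ S V'  with  W'W = V S^2 V'.
# The inner matrix always has one structural null direction (the common-shift
# gauge of the free energies); only that one is dropped. Additional near-null
# directions arise when the path is disconnected (no phase-space overlap
# across a link) and are inverted, so the reported variance diverges instead
# of being silently truncated to a small number.
mbar_covariance <- function(WtW, N_k) {
  K <- ncol(WtW)
  ev <- eigen((WtW + t(WtW)) / 2, symmetric = TRUE)
  s <- sqrt(pmax(ev$values, 0))
  V <- ev$vectors
  VS <- V %*% diag(s, K)
  inner <- diag(K) - diag(s, K) %*% t(V) %*% (N_k * V) %*% diag(s, K)
  ei <- eigen((inner + t(inner)) / 2, symmetric = TRUE)
  drop_idx <- which.min(abs(ei$values))
  li <- 1 / pmax(abs(ei$values), .Machine$double.xmin) # sign-safe magnitude
  li[drop_idx] <- 0
  pinv <- ei$vectors %*% diag(li, K) %*% t(ei$vectors)
  VS %*% pinv %*% t(VS)
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("MBAR: %d states, dA(1 -> K) = %.6g +/- %.3g k_BT (%s, %d iterations)\n",
              length(x$f), x$value, x$se,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Free energy difference between two states of an MBAR solution
#'
#' @param mbar an `mbar_result`.
#' @param i,j state indices; returns `f_j - f_i` with its standard error.
#' @return a [free_energy_estimate].
#' @export
mbar_difference <- function(mbar, i, j) {
  v <- mbar$f[j] - mbar$f[i]
  se <- sqrt(max(mbar$Theta[i, i] + mbar$Theta[j, j] - 2 * mbar$Theta[i, j], 0))
  free_energy_estimate(v, se, "MBAR", length(mbar$f),
                       diagnostics = list(converged = mbar$converged))
}

#' Phase-space overlap matrix
#'
#' Row-stochastic matrix \eqn{O_{ij} = \sum_n W_{ni} W_{nj} N_j} of
#' probabilities that configurations from state i are representative of state
#' j. Near-zero entries between neighboring states flag path segments whose
#' free energy differences cannot be estimated reliably.
#'
#' @param mbar a converged `mbar_result`.
#' @return the K x K `overlap_matrix`.
#' @export
overlap_matrix <- function(mbar) {
  stopifnot(inherits(mbar, "mbar_result"))
  mbar$overlap
}

#' @export
print.overlap_matrix <- function(x, ...) {
  K <- ncol(x)
  cat(sprintf("Overlap matrix: %d states; min neighbor overlap %.4f; row sums in [%.6f, %.6f]\n",
              K, min(x[cbind(1:(K - 1), 2:K)]), min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

#' Chain segment free energies
#'
#' Sums an ordered list of segment estimates; variances add under the
#' documented assumption that segments come from independent simulations.
#'
#' @param estimates list of [free_energy_estimate]s, ordered along the path.
#' @return a single [free_energy_estimate] with the per-segment breakdown.
#' @export
chain_segments <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "free_energy_estimate")))
  vals <- vapply(estimates, `[[`, 0, "value")
  ses <- vapply(estimates, `[[`, 0, "se")
  free_energy_estimate(sum(vals), sqrt(sum(ses^2)),
                       paste0("chained-", estimates[[1]]$estimator),
                       n_states = sum(vapply(estimates, function(e)
                         if (is.na(e$n_states)) 2L else e$n_states, 0L)),
                       segments = data.frame(value = vals, se = ses))
}

#' Chained BAR along a path
#'
#' Applies [bar_estimate] to every adjacent state pair of a
#' reduced-potential matrix and chains the segments.
#'
#' @param rpm a `reduced_potential_matrix`.
#' @return a [free_energy_estimate].
#' @export
bar_chain <- function(rpm) {
  K <- ncol(rpm$u)
  segs <- lapply(seq_len(K - 1), function(i) {
    si <- rpm$origin == i
    sj <- rpm$origin == i + 1
    bar_estimate(rpm$u[si, i + 1] - rpm$u[si, i],
                 rpm$u[sj, i] - rpm$u[sj, i + 1])
  })
  out <- chain_segments(segs)
  out$estimator <- "chained-BAR"
  out
}

#' Diagnose an alchemical path from its overlap matrix
#'
#' Flags every adjacent state pair whose mutual overlap falls below the
#' threshold. Broken links mean the states on either side share essentially
#' no configurations, so free energy differences across them rest on
#' extrapolation; the remedy is densifying the schedule around the broken
#' region (power-law spacing toward the weak-restraint end usually
#' suffices).
#'
#' The raw row-stochastic entries dilute as 1/K when many states crowd the
#' same region (a dense schedule spreads each row's unit mass over all its
#' near-identical neighbors), so the neighbor check uses the pair-normalized
#' overlap \eqn{O_{i,i+1} / (O_{i,i} + O_{i,i+1})}: near 1/2 for
#' indistinguishable neighbors, near 0 for disconnected ones, independent of
#' how densely the path is discretized.
#'
#' @param overlap an `overlap_matrix`.
#' @param threshold minimum acceptable pair-normalized neighbor overlap
#'   (default 0.03).
#' @return list with `status` (`"pass"`/`"warn"`), `min_neighbor_overlap`
#'   (pair-normalized), `broken_links` (data.frame of failing pairs) and
#'   `suggestion`.
#' @export
diagnose_path <- function(overlap, threshold = 0.03) {
  K <- ncol(overlap)
  i <- seq_len(K - 1)
  dg <- diag(overlap)
  fwd <- overlap[cbind(i, i + 1)] / (dg[i] + overlap[cbind(i, i + 1)])
  bwd <- overlap[cbind(i + 1, i)] / (dg[i + 1] + overlap[cbind(i + 1, i)])
  o <- pmin(fwd, bwd)
  broken <- which(o < threshold)
  list(
    status = if (length(broken) == 0) "pass" else "warn",
    min_neighbor_overlap = min(o),
    broken_links = data.frame(i = broken, j = broken + 1L, overlap = o[broken]),
    suggestion = if (length(broken) == 0) NULL else
      "insufficient phase-space overlap: add intermediate states (denser lambda spacing) around the broken links"
  )
}
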