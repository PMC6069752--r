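#' Assemble the absolute chemical potential of a solid
#'
#' Sums the three legs of the Einstein molecule cycle — the ideal reference
#' free energy, the force-field-on leg, and the restraint-removal leg — plus
#' the molecular symmetry correction, and converts to a per-molecule chemical
#' potential (\eqn{\mu = A / N}) when the inputs are extensive.
#'
#' @param A_EM ideal Einstein molecule free energy (k_B T).
#' @param dA_em_iem free energy of turning on the force field (EM to
#'   interacting EM) (k_B T).
#' @param dA_iem_solid free energy of removing the restraints (interacting EM
#'   to solid) (k_B T).
#' @param N number of molecules.
#' @param sigma_rot proper-rotation symmetry number.
#' @param per_molecule TRUE when the three inputs are already per-molecule
#'   quantities (the symmetry correction is then `-log(sigma_rot)`).
#' @param se_A_EM,se_em_iem,se_iem_solid standard errors of the legs.
#' @return an object of class `solid_free_energy` with `mu` (k_B T per
#'   molecule), `se`, `total`, and the `components`.
#' @export
assemble_solid_mu <- function(A_EM, dA_em_iem, dA_iem_solid, N, sigma_rot = 1L,
                              per_molecule = FALSE, se_A_EM = 0,
                              se_em_iem = 0, se_iem_solid = 0) {
  if (N < 1) stop("N must be >= 1")
  sym <- symmetry_correction(if (per_molecule) 1 else N, sigma_rot)
  total <- A_EM + dA_em_iem + dA_iem_solid + sym
  se_total <- sqrt(se_A_EM^2 + se_em_iem^2 + se_iem_solid^2)
  mu <- if (per_molecule) total else total / N
  se_mu <- if (per_molecule) se_total else se_total / N
  structure(list(
    mu = mu, se = se_mu, total = total, se_total = se_total, N = N,
    per_molecule = per_molecule, sigma_rot = as.integer(sigma_rot),
    components = c(A_EM = A_EM, dA_em_iem = dA_em_iem,
                   dA_iem_solid = dA_iem_solid, symmetry = sym)
  ), class = "solid_free_energy")
}

#' @export
print.solid_free_energy <- function(x, ...) {
  cat(sprintf("Solid chemical potential: mu = %.4f +/- %.3g k_BT per molecule (N = %d)\n",
              x$mu, x$se, x$N))
  cat(sprintf("  components (%s): A_EM %.4f, ff_on %.4f, restraints_off %.4f, symmetry %.4f\n",
              if (x$per_molecule) "per molecule" else "extensive",
              x$components[1], x$components[2], x$components[3], x$components[4]))
  invisible(x)
}

#' Locate the solubility point
#'
#' The solubility is the concentration at which the solution chemical
#' potential equals the solid's. Given a concentration series
#' \eqn{(x, \mu_{solution}(x), \sigma)} and \eqn{\mu_{solid} \pm \sigma},
#' interpolates \eqn{\mu_{solution}} piecewise-linearly in \eqn{\ln x} (the
#' ideal term is logarithmic in composition) and returns the smallest
#' crossing, or a range-relative verdict: `insoluble-in-range` when the
#' solution stays above the solid everywhere sampled, `supersaturated-in-range`
#' when it stays below. The verdict is `confident` when the gap exceeds the
#' joint 3-sigma band at every sampled concentration; extrapolation beyond
#' the sampled interval is never attempted.
#'
#' @param series data.frame with columns `x` (mole fraction, strictly
#'   increasing, >= 2 rows), `mu` (k_B T) and optionally `sigma`.
#' @param mu_solid solid chemical potential (k_B T per molecule).
#' @param se_solid its standard error.
#' @param tol interpolation tolerance on the crossing (in ln x).
#' @return an object of class `solubility_report`.
#' @export
find_solubility <- function(series, mu_solid, se_solid = 0, tol = 1e-6) {
  stopifnot(is.data.frame(series), all(c("x", "mu") %in% names(series)))
  if (nrow(series) < 2) stop("need at least two concentrations")
  if (any(!is.finite(series$mu))) stop("non-finite chemical potentials")
  if (anyDuplicated(series$x)) stop("duplicate concentrations")
  if (is.unsorted(series$x, strictly = TRUE)) stop("x must be strictly increasing")
  if (is.null(series$sigma)) series$sigma <- 0

  lx <- log(series$x)
  gap <- series$mu - mu_solid
  joint3 <- 3 * sqrt(series$sigma^2 + se_solid^2)
  confident <- all(abs(gap) > joint3)

  crossing <- NA_real_
  if (any(gap == 0)) {
    crossing <- series$x[which(gap == 0)[1]] # tie-break: smaller x
  } else {
    s <- sign(gap)
    flip <- which(s[-1] != s[-length(s)])
    if (length(flip) > 0) {
      i <- flip[1]
      fgap <- function(l) {
        w <- (l - lx[i]) / (lx[i + 1] - lx[i])
        (1 - w) * gap[i] + w * gap[i + 1]
      }
      crossing <- exp(uniroot(fgap, c(lx[i], lx[i + 1]), tol = tol)$root)
    }
  }
  verdict <- if (!is.na(crossing)) "crossing"
             else if (all(gap > 0)) "insoluble-in-range"
             else "supersaturated-in-range"
  # statistical error of x*: propagate mu errors through the local slope
  se_x <- NA_real_
  if (!is.na(crossing) && !any(gap == 0)) {
    i <- which(series$x <= crossing)
    i <- if (length(i) > 0) max(i) else 1L
    i <- min(i, nrow(series) - 1L)
    slope <- (series$mu[i + 1] - series$mu[i]) / (lx[i + 1] - lx[i])
    se_mu_here <- sqrt(max(series$sigma[i:(i + 1)])^2 + se_solid^2)
    se_x <- abs(crossing * se_mu_here / slope)
  }
  structure(list(
    mu_solid = mu_solid, se_solid = se_solid, series = series,
    verdict = verdict, x_star = crossing, se_x_star = se_x,
    confident = confident, range = range(series$x)
  ), class = "solubility_report")
}

#' @export
print.solubility_report <- function(x, ...) {
  cat(sprintf("Solubility report over x in [%.3g, %.3g] (mu_solid = %.3f +/- %.2g k_BT):\n",
              x$range[1], x$range[2], x$mu_solid, x$se_solid))
  if (x$verdict == "crossing") {
    cat(sprintf("  crossing at x* = %.6g%s\n", x$x_star,
                if (is.finite(x$se_x_star)) sprintf(" +/- %.2g", x$se_x_star) else ""))
  } else {
    cat(sprintf("  %s%s within the sampled interval\n", x$verdict,
                if (x$confident) " (confident: gap > 3 sigma everywhere)" else ""))
  }
  invisible(x)
}

#' Two-curve chemical potential plot
#'
#' Solution chemical potential versus mole fraction (log axis) with the
#' solid's chemical potential as a horizontal line; the crossing, if any, is
#' marked.
#'
#' @param x a `solubility_report`.
#' @param ... passed to `plot`.
#' @export
plot.solubility_report <- function(x, ...) {
  s <- x$series
  graphics::plot(s$x, s$mu, log = "x", type = "b", pch = 16,
                 xlab = "mole fraction", ylab = expression(mu ~ (k[B] * T)), ...)
  if (!is.null(s$sigma) && any(s$sigma > 0))
    graphics::arrows(s$x, s$mu - s$sigma, s$x, s$mu + s$sigma,
                     angle = 90, code = 3, length = 0.02)
  graphics::abline(h = x$mu_solid, col = "firebrick", lwd = 2)
  if (x$verdict == "crossing")
    graphics::points(x$x_star, x$mu_solid, col = "firebrick", pch = 4, cex = 1.5)
  graphics::legend("topleft", legend = c("solution", "solid"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
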