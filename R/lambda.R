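#' Generate a lambda schedule
#'
#' `linear` gives equally spaced values on `[0, 1]`; `power` gives
#' \eqn{\lambda_i = (i/(K-1))^p}, which concentrates states near
#' \eqn{\lambda = 0}. When a restraint-removal path is parameterized so the
#' restraint coefficient equals \eqn{\lambda}, the power schedule packs states
#' at the weak-restraint end, where configurations decorrelate from the
#' lattice and phase-space overlap is hardest to maintain. The schedule only
#' emits values; the mixing functions of the path decide their meaning.
#'
#' @param kind `"linear"` or `"power"`.
#' @param K number of states (>= 2).
#' @param exponent power-law exponent (>= 1); ignored for `"linear"`.
#' @return numeric vector of K strictly increasing lambda values in `[0, 1]`.
#' @examples
#' make_schedule("power", 5, 4)  # 0, 1/256, 16/256, 81/256, 1
#' @export
make_schedule <- function(kind = c("linear", "power"), K, exponent = 1) {
  kind <- match.arg(kind)
  if (K < 2) stop("K must be at least 2")
  if (exponent < 1) stop("exponent must be >= 1")
  i <- seq(0, K - 1) / (K - 1)
  if (kind == "linear") i else i^exponent
}

#' Define an alchemical path
#'
#' An ordered set of lambda states with the mixing functions of
#' \eqn{H(\lambda) = f(\lambda) H_{initial} + g(\lambda) H_{final}}. The
#' default linear mixing has \eqn{f = 1 - \lambda}, \eqn{g = \lambda}.
#' Lambda values are stored at full floating precision; they are never
#' rounded for matching or serialization.
#'
#' @param lambdas strictly increasing lambda values in `[0, 1]`, endpoints 0
#'   and 1 included.
#' @param segment which leg of the cycle the path represents: `ff_on`
#'   (Einstein molecule to interacting Einstein molecule), `restraints_off`
#'   (interacting Einstein molecule to solid) or `decouple` (solvation).
#' @param f,g mixing functions; defaults `1 - lambda` and `lambda`.
#' @param fp,gp their derivatives (for thermodynamic integration).
#' @return an object of class `lambda_path`.
#' @export
lambda_path <- function(lambdas,
                        segment = c("ff_on", "restraints_off", "decouple"),
                        f = NULL, g = NULL, fp = NULL, gp = NULL) {
  segment <- match.arg(segment)
  lambdas <- as.numeric(lambdas)
  if (any(diff(lambdas) <= 0)) stop("lambda values must be strictly increasing")
  if (any(lambdas < 0 | lambdas > 1)) stop("lambda values must lie in [0, 1]")
  if (abs(lambdas[1]) > 0 || abs(lambdas[length(lambdas)] - 1) > 0)
    stop("path endpoints lambda = 0 and lambda = 1 must be present")
  default <- is.null(f) && is.null(g)
  if (is.null(f)) { f <- function(l) 1 - l; fp <- function(l) rep(-1, length(l)) }
  if (is.null(g)) { g <- function(l) l;     gp <- function(l) rep(1, length(l)) }
  if (is.null(fp) || is.null(gp)) stop("custom mixing functions require fp and gp")
  if (default) {
    stopifnot(f(0) == 1, g(0) == 0, f(1) == 0, g(1) == 1)
  }
  structure(list(lambdas = lambdas, segment = segment,
                 f = f, g = g, fp = fp, gp = gp),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("Lambda path (%s): %d states, lambda in [%g, %g]\n",
              x$segment, length(x$lambdas), min(x$lambdas), max(x$lambdas)))
  invisible(x)
}

#' Mixed Hamiltonian energy and its lambda derivative
#'
#' Evaluates \eqn{H(\lambda) = f(\lambda) H_{initial} + g(\lambda) H_{final}}
#' and the analytic derivative
#' \eqn{\partial H / \partial \lambda = f'(\lambda) H_{initial} +
#' g'(\lambda) H_{final}} for one configuration.
#'
#' @param initial,final [energy_model]s defined on the same coordinates and
#'   box.
#' @param lambda coupling value in `[0, 1]`.
#' @param coords n x 3 configuration.
#' @param path optional [lambda_path] supplying non-default mixing functions.
#' @return list with `energy` and `dhdl` (both k_B T).
#' @export
mixed_energy <- function(initial, final, lambda, coords, path = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (!isTRUE(all.equal(initial$box, final$box)))
    stop("initial and final models must share a box")
  mf <- mixing_funs(path)
  ei <- evaluate_energy(initial, coords)$total
  ef <- evaluate_energy(final, coords)$total
  list(energy = mf$f(lambda) * ei + mf$g(lambda) * ef,
       dhdl = mf$fp(lambda) * ei + mf$gp(lambda) * ef)
}

mixing_funs <- function(path = NULL) {
  if (is.null(path)) {
    list(f = function(l) 1 - l, g = function(l) l,
         fp = function(l) rep(-1, length(l)), gp = function(l) rep(1, length(l)))
  } else {
    path[c("f", "g", "fp", "gp")]
  }
}

#' Build the mixed model at one lambda state
#'
#' Concatenates the terms of both end-state models with coefficients scaled
#' by \eqn{f(\lambda)} and \eqn{g(\lambda)}; the result is an ordinary
#' [energy_model] that can be sampled and re-evaluated.
#'
#' @inheritParams mixed_energy
#' @return an [energy_model].
#' @export
mixed_model <- function(initial, final, lambda, path = NULL) {
  mf <- mixing_funs(path)
  ti <- lapply(initial$terms, function(t) { t$coeff <- t$coeff * mf$f(lambda); t })
  tf <- lapply(final$terms, function(t) { t$coeff <- t$coeff * mf$g(lambda); t })
  energy_model(c(ti, tf), box = initial$box)
}

#' Build all intermediate-state models of a path
#'
#' @inheritParams mixed_energy
#' @param path a [lambda_path].
#' @return list of [energy_model]s, one per lambda state.
#' @export
alchemical_states <- function(initial, final, path) {
  lapply(path$lambdas, function(l) mixed_model(initial, final, l, path))
}
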