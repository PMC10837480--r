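## Internal helpers: angle arithmetic, RNG scoping, box filters.

#' Reduce angles into the nematic fundamental domain [0, pi)
#'
#' Directors are head-tail symmetric, so orientations are only defined
#' modulo pi. All angles stored by the package are reduced with this
#' function.
#'
#' @param theta numeric vector of angles in radians.
#' @return angles in `[0, pi)`.
#' @export
reduce_mod_pi <- function(theta) {
  out <- theta %% pi
  # %% can return pi itself through floating-point roundoff
  out[out >= pi] <- 0
  out
}

## Wrap director increments into (-pi/2, pi/2].
## A difference of two directors is only defined mod pi; the representative
## closest to zero is taken, with an exact +pi/2 jump kept positive so the
## tie-break is deterministic.
wrap_half_pi <- function(d) {
  m <- d %% pi
  m[m > pi / 2 + 1e-12] <- m[m > pi / 2 + 1e-12] - pi
  m
}

## Nematic mean of a set of directors: average in double-angle space.
## Direct angle averaging is wrong across the pi wrap; averaging
## (cos 2theta, sin 2theta) respects head-tail symmetry.
nematic_mean <- function(theta) {
  reduce_mod_pi(0.5 * atan2(mean(sin(2 * theta)), mean(cos(2 * theta))))
}

#' Scalar nematic order parameter of a set of directors
#'
#' S is the largest eigenvalue of the 2D nematic tensor
#' \eqn{Q = \langle 2 \hat u_m \hat u_n - \delta_{mn} \rangle} with
#' \eqn{\hat u = (\cos\theta, \sin\theta)}. In two dimensions Q is traceless
#' and symmetric, so its largest eigenvalue has the closed form
#' \eqn{S = \sqrt{\langle\cos 2\theta\rangle^2 + \langle\sin 2\theta\rangle^2}},
#' which is used here instead of an eigensolver. S = 1 for perfect local
#' alignment and S = 0 for a locally isotropic set.
#'
#' @param theta numeric vector of director angles in radians.
#' @return scalar S in `[0, 1]`.
#' @examples
#' nematic_order(rep(0.7, 10))        # perfectly aligned: 1
#' nematic_order(c(0, pi / 2))        # orthogonal pair: 0
#' @export
nematic_order <- function(theta) {
  sqrt(mean(cos(2 * theta))^2 + mean(sin(2 * theta))^2)
}

## Evaluate an expression with a temporary RNG state seeded by `seed`,
## restoring the caller's .Random.seed afterwards. Every seeded operation
## in the package goes through this so generation is a pure function of
## its config.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Shift a matrix along rows (axis = 1) or columns (axis = 2) by k,
## wrapping periodically or padding with `fill`.
shift_mat <- function(m, k, axis, periodic, fill = 0) {
  n <- dim(m)[axis]
  if (k == 0) return(m)
  if (periodic) {
    idx <- ((seq_len(n) - 1 - k) %% n) + 1
  } else {
    idx <- seq_len(n) - k
    idx[idx < 1 | idx > n] <- NA
  }
  out <- if (axis == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  out[is.na(out)] <- fill
  out
}

## Separable boxcar sum over a (2*hx+1) x (2*hy+1) neighbourhood.
## Non-periodic edges simply sum fewer terms; callers normalise by the
## box-summed count field so edge windows are means over what exists.
box_sum <- function(m, hx, hy, periodic) {
  out <- m
  if (hx > 0) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (k in -hx:hx) acc <- acc + shift_mat(m, k, 1L, periodic)
    out <- acc
  }
  if (hy > 0) {
    acc <- matrix(0, nrow(out), ncol(out))
    for (k in -hy:hy) acc <- acc + shift_mat(out, k, 2L, periodic)
    out <- acc
  }
  out
}

## Minimal-image displacement for periodic boxes.
min_image <- function(d, L) d - L * round(d / L)

stop_nemadef <- function(msg, class) {
  stop(structure(class = c(class, "nemadef_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
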