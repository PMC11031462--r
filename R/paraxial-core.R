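# Paraxial vergence optics in the reduced-angle (n*u) convention.
#
# Sign rules used throughout the package: light travels left to right;
# axial distances are in millimetres, positive rightward; a surface radius
# is positive when its centre of curvature lies to the right of the vertex
# (convex toward the incoming light); vergence is positive for converging
# wavefronts.  Powers are always dioptres.  Lengths cross into metres only
# inside the vergence / matrix arithmetic.

#' Sentinel for a planar refracting surface
#'
#' Passed in place of a numeric radius wherever a surface is flat.  A flat
#' surface has zero power regardless of the index step; an explicit sentinel
#' avoids the float ambiguities of `Inf` radii.
#'
#' @export
FLAT <- "flat"

is_flat <- function(radius) {
  is.character(radius) && length(radius) == 1L && identical(radius, FLAT)
}

#' Wavefront vergence in a medium
#'
#' A vergence couples a wavefront curvature (in dioptres) with the
#' refractive index of the medium the wavefront travels in.  The value may
#' be a vector, which propagates elementwise through [refract()] and
#' [translate()].
#'
#' @param value Wavefront vergence(s) in dpt; positive = converging.
#' @param n Refractive index of the medium (scalar, >= 1).
#' @return An object of class `"vergence"` with fields `value` and `n`.
#' @examples
#' v <- vergence(0)                    # plane wave in air
#' refract(v, 43.44, n_after = 1.376)
#' @export
vergence <- function(value, n = 1) {
  stopifnot(is.numeric(value), is.numeric(n), length(n) == 1L)
  if (!all(is.finite(value))) stop("vergence values must be finite")
  if (n < 1) stop("medium index must be >= 1")
  structure(list(value = as.numeric(value), n = as.numeric(n)),
            class = "vergence")
}

#' @export
print.vergence <- function(x, ...) {
  cat(sprintf("<vergence> %s dpt in n = %.4f\n",
              paste(format(x$value, digits = 6), collapse = ", "), x$n))
  invisible(x)
}

#' Power of a single refracting surface
#'
#' @param n_before,n_after Refractive indices before and after the surface.
#' @param radius Surface radius in mm, or [FLAT] for a planar surface.
#' @return Surface power in dpt: `1000 * (n_after - n_before) / radius`.
#' @examples
#' surface_power(1, 1.3375, 7.77)   # keratometric corneal power, 43.44 dpt
#' surface_power(1.336, 1.376, FLAT)
#' @export
surface_power <- function(n_before, n_after, radius) {
  stopifnot(is.numeric(n_before), is.numeric(n_after))
  if (any(n_before < 1) || any(n_after < 1)) stop("indices must be >= 1")
  if (is_flat(radius)) return(0)
  if (!is.numeric(radius)) stop("radius must be numeric or the FLAT sentinel")
  if (any(radius == 0)) stop("zero radius: use the FLAT sentinel for planar surfaces")
  1000 * (n_after - n_before) / radius
}

#' Refract a vergence at a surface
#'
#' Vergence addition: the outgoing vergence is the incoming vergence plus
#' the surface power, in the medium behind the surface.
#'
#' @param v A [vergence()].
#' @param power Surface power in dpt.
#' @param n_after Index of the medium behind the surface (defaults to the
#'   incoming medium, i.e. a thin element).
#' @export
refract <- function(v, power, n_after = v$n) {
  stopifnot(inherits(v, "vergence"))
  vergence(v$value + power, n_after)
}

#' Translate a vergence along the axis
#'
#' Vergence transfer over a homogeneous gap: `V' = V / (1 - (d/n) V)` with
#' the reduced distance `d/n` in metres.  Exactly invertible:
#' `translate(translate(v, d), -d)` returns `v`.
#'
#' @param v A [vergence()].
#' @param distance Signed axial distance in mm (negative traces backwards).
#' @export
translate <- function(v, distance) {
  stopifnot(inherits(v, "vergence"), is.numeric(distance))
  tau <- distance / 1000 / v$n
  den <- 1 - tau * v$value
  if (any(abs(den) < 1e-12)) {
    stop(sprintf("vergence focus coincides with the target plane at %g mm",
                 distance[which(abs(den) < 1e-12)[1L]]))
  }
  vergence(v$value / den, v$n)
}

# bare-numeric translation used on the vectorised hot path
translate_num <- function(value, distance_mm, n) {
  den <- 1 - (distance_mm / 1000 / n) * value
  if (any(abs(den) < 1e-12)) {
    stop("vergence focus coincides with a translation target plane")
  }
  value / den
}

#' Thick lens specification
#'
#' A single homogeneous lens bounded by two spherical (or flat) surfaces.
#' Models both the cornea (`n_lens` = 1.376 between air and aqueous) and
#' the PIOL (collamer in aqueous humour on both sides).
#'
#' @param r_front,r_back Surface radii in mm (or [FLAT]).
#' @param thickness Central thickness in mm, >= 0.
#' @param n_lens Lens material index; must exceed the surrounding indices.
#' @param n_before,n_after Ambient indices in front of / behind the lens.
#' @return An object of class `"thick_lens"`.
#' @examples
#' cornea <- thick_lens(7.77, 6.40, 0.50, 1.376, n_before = 1, n_after = 1.336)
#' equivalent_power(cornea)
#' @export
thick_lens <- function(r_front, r_back, thickness, n_lens,
                       n_before = 1, n_after = n_before) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L)
  if (thickness < 0) stop("thickness must be >= 0")
  if (n_before < 1 || n_after < 1 || n_lens < 1) stop("indices must be >= 1")
  if (n_lens <= max(n_before, n_after)) {
    stop("n_lens must exceed the surrounding media for the lens materials modelled here")
  }
  for (r in list(r_front, r_back)) {
    if (!is_flat(r) && (!is.numeric(r) || length(r) != 1L || r == 0)) {
      stop("radii must be nonzero scalars or the FLAT sentinel")
    }
  }
  structure(list(r_front = r_front, r_back = r_back, thickness = thickness,
                 n_lens = n_lens, n_before = n_before, n_after = n_after),
            class = "thick_lens")
}

#' Equivalent power of a thick lens (Gullstrand equation)
#'
#' `P = P1 + P2 - (t/n_lens) P1 P2` with the reduced thickness in metres.
#' The labelled power of a PIOL is its equivalent power immersed in aqueous
#' on both sides.
#'
#' @param lens A [thick_lens()].
#' @return Equivalent power in dpt.
#' @export
equivalent_power <- function(lens) {
  stopifnot(inherits(lens, "thick_lens"))
  p1 <- surface_power(lens$n_before, lens$n_lens, lens$r_front)
  p2 <- surface_power(lens$n_lens, lens$n_after, lens$r_back)
  p1 + p2 - (lens$thickness / 1000 / lens$n_lens) * p1 * p2
}

#' Principal plane offsets of a thick lens
#'
#' Offsets (mm, positive rightward) of the object-side principal plane from
#' the front vertex and of the image-side principal plane from the back
#' vertex.  A thin lens of the equivalent power placed at the principal
#' planes reproduces the lens's ray-transfer matrix exactly.
#'
#' @param lens A [thick_lens()].
#' @return Named numeric vector `c(front = ..., back = ...)`.
#' @export
principal_planes <- function(lens) {
  stopifnot(inherits(lens, "thick_lens"))
  m <- system_matrix(lens_elements(lens))
  p <- -m[2, 1]
  if (abs(p) < 1e-9) stop("equivalent power is zero: principal planes undefined")
  c(front = -1000 * lens$n_before * (1 - m[2, 2]) / m[2, 1],
    back  =  1000 * lens$n_after  * (1 - m[1, 1]) / m[2, 1])
}

## ---- optical elements and the ray-transfer-matrix oracle -------------------

#' Optical system elements
#'
#' Building blocks for ordered optical systems: a refracting surface between
#' two media and a homogeneous gap.  A surface is specified either by its
#' geometry (`radius`, power derived from the index step) or directly by a
#' `power` in dpt (e.g. the keratometric thin cornea, whose power comes from
#' the fictitious keratometer index rather than its physical index step).
#'
#' @param n_before,n_after Media in front of / behind the surface.
#' @param radius Surface radius in mm or [FLAT]; exclusive with `power`.
#' @param power Surface power in dpt; exclusive with `radius`.
#' @param distance Gap length in mm (>= 0).
#' @param n Gap medium index.
#' @return A list describing the element, of class `"optical_element"`.
#' @export
elem_surface <- function(n_before, n_after, radius = NULL, power = NULL) {
  if (is.null(power) == is.null(radius)) {
    stop("give exactly one of `radius` or `power`")
  }
  if (is.null(power)) power <- surface_power(n_before, n_after, radius)
  structure(list(kind = "surface", power = power,
                 n_before = n_before, n_after = n_after),
            class = "optical_element")
}

#' @rdname elem_surface
#' @export
elem_gap <- function(distance, n) {
  stopifnot(is.numeric(distance), length(distance) == 1L)
  if (distance < 0) stop("gap length must be >= 0")
  if (n < 1) stop("gap index must be >= 1")
  structure(list(kind = "gap", distance = distance, n = n),
            class = "optical_element")
}

lens_elements <- function(lens) {
  list(elem_surface(lens$n_before, lens$n_lens, radius = lens$r_front),
       elem_gap(lens$thickness, lens$n_lens),
       elem_surface(lens$n_lens, lens$n_after, radius = lens$r_back))
}

#' Ray-transfer matrix of an ordered element sequence
#'
#' Multiplies elementary refraction and translation matrices in the reduced
#' convention (ray state `(y, n*u)`), so every system matrix has unit
#' determinant.  Media must be consistent between adjacent elements.
#'
#' @param elements List of elements from [elem_surface()] / [elem_gap()].
#' @return A 2x2 matrix of class `"system_matrix"` with attributes
#'   `n_before` and `n_after`.
#' @export
system_matrix <- function(elements) {
  m <- diag(2)
  n_cur <- NA_real_
  n_first <- NA_real_
  for (el in elements) {
    stopifnot(inherits(el, "optical_element"))
    if (el$kind == "surface") {
      if (!is.na(n_cur) && abs(el$n_before - n_cur) > 1e-12) {
        stop("inconsistent media between adjacent elements")
      }
      m <- matrix(c(1, -el$power, 0, 1), 2, 2) %*% m
      if (is.na(n_first)) n_first <- el$n_before
      n_cur <- el$n_after
    } else {
      if (!is.na(n_cur) && abs(el$n - n_cur) > 1e-12) {
        stop("inconsistent media between adjacent elements")
      }
      m <- matrix(c(1, 0, el$distance / 1000 / el$n, 1), 2, 2) %*% m
      if (is.na(n_first)) n_first <- el$n
      n_cur <- el$n
    }
  }
  if (abs(det(m) - 1) > 1e-9) stop("system matrix determinant deviates from 1")
  structure(m, class = c("system_matrix", "matrix"),
            n_before = n_first, n_after = n_cur)
}

#' Propagate a vergence through a system matrix
#'
#' Oracle counterpart of stepwise [refract()]/[translate()] propagation.
#' For a matrix `[[A, B], [C, D]]` the output vergence is
#' `(D V - C) / (A - B V)`.
#'
#' @param m A [system_matrix()].
#' @param v A [vergence()] entering the first element.
#' @export
matrix_vergence <- function(m, v) {
  stopifnot(inherits(m, "system_matrix"), inherits(v, "vergence"))
  den <- m[1, 1] - m[1, 2] * v$value
  if (any(abs(den) < 1e-12)) stop("matrix propagation singular at the exit plane")
  vergence((m[2, 2] * v$value - m[2, 1]) / den,
           n = if (is.na(attr(m, "n_after"))) v$n else attr(m, "n_after"))
}

#' Equivalent power of a system matrix
#'
#' @param m A [system_matrix()].
#' @return `-C`, the equivalent power in dpt.
#' @export
matrix_equivalent_power <- function(m) {
  stopifnot(inherits(m, "system_matrix"))
  -m[2, 1]
}

#' Propagate a vergence element by element
#'
#' Forward propagation by vergence addition and transfer, optionally
#' recording the (incoming, outgoing) vergence pair at every refracting
#' surface -- the raw material of the lateral-magnification products.
#'
#' @param elements List of elements from [elem_surface()] / [elem_gap()].
#' @param v Entering [vergence()].
#' @param trace If `TRUE`, also return the per-surface vergence pairs.
#' @return The exit vergence, or (with `trace = TRUE`) a list with fields
#'   `v` and `trace` (data.frame `surface`, `v_in`, `v_out`).
#' @export
propagate_vergence <- function(elements, v, trace = FALSE) {
  stopifnot(inherits(v, "vergence"))
  v_in <- v_out <- numeric(0)
  for (el in elements) {
    stopifnot(inherits(el, "optical_element"))
    if (el$kind == "surface") {
      if (abs(el$n_before - v$n) > 1e-12) {
        stop("inconsistent media between adjacent elements")
      }
      v2 <- refract(v, el$power, el$n_after)
      if (trace) {
        v_in <- c(v_in, v$value)
        v_out <- c(v_out, v2$value)
      }
      v <- v2
    } else {
      if (abs(el$n - v$n) > 1e-12) {
        stop("inconsistent media between adjacent elements")
      }
      v <- translate(v, el$distance)
    }
  }
  if (!trace) return(v)
  list(v = v,
       trace = data.frame(surface = seq_along(v_in), v_in = v_in, v_out = v_out))
}
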