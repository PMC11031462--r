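# Thick meniscus PIOL designs: back-calculation of missing design data via
# the Gullstrand equation, a parameterized surrogate family covering the
# full labelled power schedule, and CSV input/output.
#
# All PIOL powers are equivalent powers with the lens immersed in aqueous
# humour (n = 1.336) on both sides, matching its anatomical position in the
# posterior chamber between iris and crystalline lens.

#' The labelled PIOL power schedule
#'
#' 58 equivalent-power steps: -17.0 (0.5) -3.0 dpt and 3.0 (0.5) 17.0 dpt.
#'
#' @return Numeric vector of length 58, increasing.
#' @export
piol_power_steps <- function() {
  c(seq(-17, -3, by = 0.5), seq(3, 17, by = 0.5))
}

#' Back-calculate the lens refractive index from a complete design
#'
#' Solves the Gullstrand equation for the material index given both radii,
#' the central thickness and the labelled equivalent power.  The equation is
#' quadratic in the index excess over the ambient medium; the physical root
#' (index above ambient) is returned, and re-substitution reproduces the
#' labelled power to machine precision.
#'
#' @param r_front,r_back Surface radii in mm (both positive for a meniscus
#'   with convex front and concave back surface).
#' @param thickness Central thickness in mm.
#' @param power_label Labelled equivalent power in dpt.
#' @param n_ambient Ambient index (aqueous humour by default).
#' @return The lens refractive index.
#' @examples
#' back_calc_index(7.0, 4.3128, 0.2, -10)   # ~1.449, the collamer index
#' @export
back_calc_index <- function(r_front, r_back, thickness, power_label,
                            n_ambient = 1.336) {
  stopifnot(is.numeric(r_front), is.numeric(r_back), is.numeric(thickness),
            is.numeric(power_label))
  if (any(r_front <= 0) || any(r_back <= 0)) {
    stop("meniscus radii must be positive")
  }
  # P*(d + n_amb) = 1000*(1/r1 - 1/r2)*d*(d + n_amb) + 1000*t*d^2/(r1*r2),
  # d = n - n_amb  =>  a d^2 + b d + c = 0
  a <- 1000 * ((1 / r_front - 1 / r_back) + thickness / (r_front * r_back))
  b <- 1000 * (1 / r_front - 1 / r_back) * n_ambient - power_label
  cc <- -power_label * n_ambient
  root_one <- function(a, b, cc) {
    if (abs(a) < 1e-12) {
      if (abs(b) < 1e-12) return(NA_real_)
      return(-cc / b)
    }
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    d <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    d <- d[d > 1e-9]
    if (!length(d)) return(NA_real_)
    min(d)  # smaller physical excess if two admissible roots
  }
  delta <- mapply(root_one, a, b, cc)
  if (any(is.na(delta))) {
    stop("no physical refractive index solves the Gullstrand equation for this design")
  }
  unname(delta + n_ambient)
}

#' Back-calculate the missing back-surface radius
#'
#' Closed-form solution of the Gullstrand equation for the back-surface
#' power given the labelled equivalent power, front radius, thickness and
#' material index, then converted to a radius.  Completing a design this
#' way reproduces the labelled power exactly.
#'
#' @param power_label Labelled equivalent power in dpt.
#' @param n_lens Lens material index.
#' @param r_front Front surface radius in mm.
#' @param thickness Central thickness in mm.
#' @param n_ambient Ambient index (aqueous humour by default).
#' @return Back-surface radius in mm (positive: concave back surface).
#' @examples
#' back_calc_back_radius(-10, 1.449, 7.0, 0.2)   # ~4.313 mm
#' @export
back_calc_back_radius <- function(power_label, n_lens, r_front, thickness,
                                  n_ambient = 1.336) {
  stopifnot(is.numeric(power_label), is.numeric(r_front), is.numeric(thickness))
  if (any(r_front <= 0)) stop("front radius must be positive")
  if (any(n_lens <= n_ambient)) stop("n_lens must exceed the ambient index")
  p1 <- 1000 * (n_lens - n_ambient) / r_front
  p2 <- (power_label - p1) / (1 - (thickness / 1000 / n_lens) * p1)
  bad <- abs(p2) < 1e-9
  if (any(bad)) {
    stop(sprintf("flat back surface at power %g dpt: design degenerates out of the meniscus family",
                 power_label[which(bad)[1L]]))
  }
  r_back <- 1000 * (n_ambient - n_lens) / p2
  bad <- r_back <= 0
  if (any(bad)) {
    stop(sprintf("non-meniscus geometry at power %g dpt (back radius %.4g mm <= 0)",
                 power_label[which(bad)[1L]], r_back[which(bad)[1L]]))
  }
  r_back
}

#' A single PIOL design
#'
#' Constructs and validates one thick meniscus design row: positive radii,
#' positive thickness, and the labelled power reproduced by the equivalent
#' power (in aqueous on both sides) to 1e-6 dpt.
#'
#' @param power_label Labelled equivalent power in dpt.
#' @param r_front,r_back Surface radii in mm.
#' @param thickness Central thickness in mm.
#' @param n_lens Material index.
#' @param n_ambient Ambient index used for verification.
#' @return One-row data.frame with columns `power_dpt`, `r_front_mm`,
#'   `r_back_mm`, `thickness_mm`, `n_lens`.
#' @export
piol_design <- function(power_label, r_front, r_back, thickness, n_lens,
                        n_ambient = 1.336) {
  if (r_front <= 0 || r_back <= 0) stop("meniscus radii must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  p <- equivalent_power(thick_lens(r_front, r_back, thickness, n_lens,
                                   n_before = n_ambient, n_after = n_ambient))
  if (abs(p - power_label) > 1e-6) {
    stop(sprintf("equivalent power %.8f dpt does not match the label %.8f dpt",
                 p, power_label))
  }
  data.frame(power_dpt = power_label, r_front_mm = r_front,
             r_back_mm = r_back, thickness_mm = thickness, n_lens = n_lens)
}

default_r_front <- function(power) 9 - (3 / 17) * power

default_thickness <- function(power) {
  ifelse(power < 0, 0.2, 0.2 + 0.4 * (power - 3) / 14)
}

#' Synthesize a surrogate 58-step design table
#'
#' Builds a complete meniscus design family over the labelled power
#' schedule.  The front-radius schedule decreases smoothly with power
#' within 6--12 mm and the central thickness is ~0.2 mm for all negative
#' powers, growing affinely from 0.2 mm at +3 dpt to 0.6 mm at +17 dpt;
#' each back radius is then back-calculated so that every design reproduces
#' its labelled equivalent power exactly.  The schedules are calibrated so
#' the family shows the behaviour of disclosed collamer-lens designs:
#' negative lenses are thin (thick and thin models nearly agree) and the
#' thin-lens simplification error grows to about half a dioptre at +17 dpt.
#'
#' @param n_lens Material index (default: the collamer consensus 1.4490).
#' @param n_ambient Ambient index.
#' @param r_front_fun,thickness_fun Schedule functions of the labelled
#'   power returning mm; defaults as described above.
#' @return A `piol_design_table`: data.frame with 58 rows and columns
#'   `power_dpt`, `r_front_mm`, `r_back_mm`, `thickness_mm`, `n_lens`;
#'   attribute `provenance = "synthetic"`.
#' @examples
#' tbl <- synth_design_table()
#' range(tbl$r_back_mm)
#' @export
synth_design_table <- function(n_lens = 1.4490, n_ambient = 1.336,
                               r_front_fun = default_r_front,
                               thickness_fun = default_thickness) {
  powers <- piol_power_steps()
  r_front <- r_front_fun(powers)
  thickness <- thickness_fun(powers)
  if (any(r_front <= 0) || any(thickness <= 0)) {
    stop(sprintf("schedule produces non-physical geometry at power %g dpt",
                 powers[which(r_front <= 0 | thickness <= 0)[1L]]))
  }
  r_back <- back_calc_back_radius(powers, n_lens, r_front, thickness, n_ambient)
  tbl <- data.frame(power_dpt = powers, r_front_mm = r_front,
                    r_back_mm = r_back, thickness_mm = thickness,
                    n_lens = n_lens)
  as_design_table(tbl, provenance = "synthetic", n_ambient = n_ambient)
}

as_design_table <- function(tbl, provenance, n_ambient = 1.336) {
  tbl <- tbl[order(tbl$power_dpt), , drop = FALSE]
  rownames(tbl) <- NULL
  validate_design_table(tbl, n_ambient = n_ambient)
  attr(tbl, "provenance") <- provenance
  class(tbl) <- c("piol_design_table", "data.frame")
  tbl
}

#' Validate a PIOL design table
#'
#' Checks the full labelled schedule (58 unique powers), meniscus geometry
#' and the label/equivalent-power identity for every row.
#'
#' @param tbl Data.frame with the design-table columns.
#' @param n_ambient Ambient index for power verification.
#' @param tol Tolerance in dpt on the label identity.
#' @return `tbl`, invisibly; errors on the first violated invariant.
#' @export
validate_design_table <- function(tbl, n_ambient = 1.336, tol = 1e-6) {
  need <- c("power_dpt", "r_front_mm", "r_back_mm", "thickness_mm", "n_lens")
  if (!all(need %in% names(tbl))) {
    stop("design table must have columns ", paste(need, collapse = ", "))
  }
  sched <- piol_power_steps()
  pw <- sort(tbl$power_dpt)
  if (anyDuplicated(tbl$power_dpt)) stop("duplicated power labels in design table")
  if (length(pw) != length(sched) || any(abs(pw - sched) > 1e-9)) {
    stop("design table must cover exactly the 58 labelled power steps")
  }
  if (any(tbl$r_front_mm <= 0) || any(tbl$r_back_mm <= 0)) {
    stop("meniscus radii must be positive for every design")
  }
  if (any(tbl$thickness_mm <= 0)) stop("thickness must be positive for every design")
  p <- design_equivalent_power(tbl, n_ambient)
  off <- abs(p - tbl$power_dpt)
  if (any(off > tol)) {
    i <- which.max(off)
    stop(sprintf("equivalent power deviates from the label by %.3g dpt at %g dpt",
                 off[i], tbl$power_dpt[i]))
  }
  invisible(tbl)
}

# vectorized Gullstrand power of every row, immersed in n_ambient both sides
design_equivalent_power <- function(tbl, n_ambient = 1.336) {
  p1 <- 1000 * (tbl$n_lens - n_ambient) / tbl$r_front_mm
  p2 <- 1000 * (n_ambient - tbl$n_lens) / tbl$r_back_mm
  p1 + p2 - (tbl$thickness_mm / 1000 / tbl$n_lens) * p1 * p2
}

#' Read / write a design-table CSV
#'
#' The CSV carries a header row with columns `power_dpt`, `r_front_mm`,
#' `thickness_mm` and optionally `r_back_mm` and `n_lens` ('.' decimal
#' separator).  Missing material indices are back-calculated from the rows
#' that are fully specified (their mean is applied to all rows, mirroring
#' how a consensus index is derived from complete designs); missing back
#' radii are then completed from the labelled power.  Writing uses 17
#' significant digits so a write/read cycle round-trips exactly.
#'
#' @param path File path.
#' @param n_ambient Ambient index for completion and verification.
#' @return [read_design_csv()]: a `piol_design_table` with provenance
#'   `"loaded"`.  [write_design_csv()]: `path`, invisibly.
#' @export
read_design_csv <- function(path, n_ambient = 1.336) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("power_dpt", "r_front_mm", "thickness_mm")
  if (!all(need %in% names(tbl))) {
    stop("design CSV must have columns ", paste(need, collapse = ", "))
  }
  if (!"r_back_mm" %in% names(tbl)) tbl$r_back_mm <- NA_real_
  if (!"n_lens" %in% names(tbl)) tbl$n_lens <- NA_real_
  bad <- which(tbl$r_front_mm <= 0 | tbl$thickness_mm <= 0 |
                 (!is.na(tbl$r_back_mm) & tbl$r_back_mm <= 0))
  if (length(bad)) {
    stop(sprintf("invalid design geometry in CSV row %d", bad[1L]))
  }
  if (anyNA(tbl$n_lens)) {
    complete <- which(!is.na(tbl$r_back_mm))
    if (!length(complete)) {
      stop(sprintf("CSV row %d: neither r_back_mm nor n_lens derivable",
                   which(is.na(tbl$n_lens))[1L]))
    }
    n_hat <- back_calc_index(tbl$r_front_mm[complete], tbl$r_back_mm[complete],
                             tbl$thickness_mm[complete], tbl$power_dpt[complete],
                             n_ambient)
    tbl$n_lens[is.na(tbl$n_lens)] <- mean(n_hat)
  }
  miss <- which(is.na(tbl$r_back_mm))
  if (length(miss)) {
    tbl$r_back_mm[miss] <- back_calc_back_radius(
      tbl$power_dpt[miss], tbl$n_lens[miss], tbl$r_front_mm[miss],
      tbl$thickness_mm[miss], n_ambient)
  }
  tbl <- tbl[c("power_dpt", "r_front_mm", "r_back_mm", "thickness_mm", "n_lens")]
  as_design_table(tbl, provenance = "loaded", n_ambient = n_ambient)
}

#' @rdname read_design_csv
#' @param tbl A design table.
#' @export
write_design_csv <- function(tbl, path) {
  out <- as.data.frame(tbl)
  for (nm in names(out)) {
    out[[nm]] <- formatC(out[[nm]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
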