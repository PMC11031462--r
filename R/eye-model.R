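# Pre- and postoperative phakic model eye.
#
# Four scenarios combine thick/thin models of the cornea and the PIOL:
#   A thick cornea + thick PIOL      B thin cornea + thick PIOL
#   C thick cornea + thin PIOL       D thin cornea + thin PIOL
# The thin cornea is a single keratometric surface of power
# PC = (n_K - 1)/RC_a at the corneal front vertex with aqueous behind it;
# the thin PIOL is a single surface of the labelled power at SLPOS.  The
# PIOL back surface (thick model) or thin-lens plane sits at
# SLPOS = ACD - vault behind the corneal front vertex.

#' Anterior-segment biometry of one eye
#'
#' @param rc_a,rc_p Corneal front / back surface radii in mm (meridian
#'   averages).
#' @param cct Central corneal thickness in mm.
#' @param aqd Aqueous depth in mm (endothelium to crystalline lens apex).
#' @param lt Crystalline lens thickness in mm.
#' @param n_k Keratometer index used to derive the keratometric power.
#' @return An object of class `"eye_biometry"` with the measured fields
#'   plus the derived `acd = aqd + cct` and `pc = 1000*(n_k - 1)/rc_a`.
#' @examples
#' eye_biometry(7.77, 6.40, 0.50, 3.00, 3.70)
#' @export
eye_biometry <- function(rc_a, rc_p, cct, aqd, lt, n_k = 1.3375) {
  vals <- c(rc_a = rc_a, rc_p = rc_p, cct = cct, aqd = aqd, lt = lt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all biometry lengths must be positive and finite")
  }
  structure(list(rc_a = rc_a, rc_p = rc_p, cct = cct, aqd = aqd, lt = lt,
                 acd = aqd + cct, pc = 1000 * (n_k - 1) / rc_a),
            class = "eye_biometry")
}

#' @export
print.eye_biometry <- function(x, ...) {
  cat(sprintf(paste0("<eye_biometry> RC_a %.4f | RC_p %.4f | CCT %.4f | ",
                     "AQD %.4f | ACD %.4f | LT %.4f mm; PC %.2f dpt\n"),
              x$rc_a, x$rc_p, x$cct, x$aqd, x$acd, x$lt, x$pc))
  invisible(x)
}

#' Scenario configuration
#'
#' @param scenario One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param vault Clearance between PIOL back surface and crystalline lens
#'   front apex, mm.
#' @param vd Back vertex distance (spectacle plane to corneal front
#'   vertex), mm.
#' @param n_c Physical corneal index (Liou--Brennan schematic eye).
#' @param n_k Keratometer index for the thin-cornea scenarios.
#' @param n_a Aqueous humour index.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("A", "B", "C", "D"), vault = 0.4,
                            vd = 12, n_c = 1.376, n_k = 1.3375, n_a = 1.336) {
  scenario <- match.arg(scenario)
  if (vault < 0) stop("vault must be >= 0")
  if (vd <= 0) stop("vertex distance must be positive")
  structure(list(scenario = scenario, vault = vault, vd = vd,
                 n_c = n_c, n_k = n_k, n_a = n_a),
            class = "scenario_config")
}

thick_cornea_scenario <- function(s) s %in% c("A", "C")
thick_piol_scenario <- function(s) s %in% c("A", "B")

# Extract (power label, geometry) from a design row, a design table row
# index, or a bare power for the thin-PIOL scenarios.
piol_fields <- function(piol, thick) {
  if (is.numeric(piol) && length(piol) == 1L) {
    if (thick) stop("thick-PIOL scenarios (A, B) need a full design, not a bare power")
    return(list(power = piol, r_front = NA_real_, r_back = NA_real_,
                thickness = 0, n_lens = NA_real_))
  }
  piol <- as.list(piol)
  need <- c("power_dpt", "r_front_mm", "r_back_mm", "thickness_mm", "n_lens")
  if (!all(need %in% names(piol))) {
    stop("PIOL must be a design row with fields ", paste(need, collapse = ", "),
         " or a bare power (thin scenarios)")
  }
  list(power = piol$power_dpt, r_front = piol$r_front_mm,
       r_back = piol$r_back_mm, thickness = piol$thickness_mm,
       n_lens = piol$n_lens)
}

## ---- vectorised correction core -------------------------------------------

# Single source of truth for REF and delta-M.  All biometry and design
# arguments may be equal-length vectors; `scenario` and the configuration
# scalars are fixed per call.  The element/matrix machinery in
# paraxial-core.R provides the independent oracle for this closed form.
correction_core <- function(rc_a, rc_p, cct, acd, piolp,
                            r_front, r_back, t_piol, n_lens,
                            scenario, vault, vd, n_c, n_k, n_a,
                            want_dm = TRUE) {
  thick_c <- thick_cornea_scenario(scenario)
  thick_p <- thick_piol_scenario(scenario)
  slpos <- acd - vault
  t_eff <- if (thick_p) t_piol else 0
  x_front <- slpos - t_eff  # PIOL front vertex (thick) or lens plane (thin)

  if (thick_c) {
    gap <- x_front - cct
    if (any(gap < 0)) {
      stop("PIOL front vertex lies at or before the corneal back vertex (SLPOS - PIOLT < CCT)")
    }
  } else if (any(x_front < 0)) {
    stop("PIOL front vertex lies in front of the corneal vertex (SLPOS - PIOLT < 0)")
  }

  # forward pass, object at infinity
  if (thick_c) {
    p_ca <- 1000 * (n_c - 1) / rc_a
    p_cp <- 1000 * (n_a - n_c) / rc_p
    s1_out <- p_ca + numeric(length(rc_a))        # surface 1: 0 -> p_ca
    s2_in <- translate_num(s1_out, cct, n_c)
    s2_out <- s2_in + p_cp
    v_at_front <- translate_num(s2_out, x_front - cct, n_a)
  } else {
    pc <- 1000 * (n_k - 1) / rc_a
    s1_out <- pc + numeric(length(rc_a))
    v_at_front <- translate_num(s1_out, x_front, n_a)
  }
  if (thick_p) {
    p1 <- 1000 * (n_lens - n_a) / r_front
    p2 <- 1000 * (n_a - n_lens) / r_back
    sp1_in <- v_at_front
    sp1_out <- sp1_in + p1
    sp2_in <- translate_num(sp1_out, t_piol, n_lens)
    v_slpos <- sp2_in + p2
  } else {
    sp1_in <- v_at_front
    v_slpos <- sp1_in + piolp
  }

  # preoperative back-trace from SLPOS to the spectacle plane
  if (thick_c) {
    b <- translate_num(v_slpos, -(slpos - cct), n_a)
    b <- b - p_cp
    b <- translate_num(b, -cct, n_c)
    b <- b - p_ca
  } else {
    b <- translate_num(v_slpos, -slpos, n_a)
    b <- b - pc
  }
  ref <- translate_num(b, -vd, 1)

  dm <- NULL
  if (want_dm) {
    if (any(ref == 0)) {
      stop("spectacle vergence is zero: magnification change undefined (zero-power correction)")
    }
    # preoperative surfaces: spectacle (in 0 dropped, out ref) + cornea
    c1_in <- translate_num(ref, vd, 1)
    if (thick_c) {
      c1_out <- c1_in + p_ca
      c2_in <- translate_num(c1_out, cct, n_c)
      c2_out <- c2_in + p_cp
      m_pre <- (c1_in * c2_in) / (ref * c1_out * c2_out)
    } else {
      c1_out <- c1_in + pc
      m_pre <- c1_in / (ref * c1_out)
    }
    # postoperative surfaces: cornea (first in 0 dropped) + PIOL
    if (thick_c && thick_p) {
      m_po <- (s2_in * sp1_in * sp2_in) /
        (s1_out * s2_out * sp1_out * v_slpos)
    } else if (thick_c) {
      m_po <- (s2_in * sp1_in) / (s1_out * s2_out * v_slpos)
    } else if (thick_p) {
      m_po <- (sp1_in * sp2_in) / (s1_out * sp1_out * v_slpos)
    } else {
      m_po <- sp1_in / (s1_out * v_slpos)
    }
    if (any(!is.finite(m_pre)) || any(!is.finite(m_po))) {
      stop("zero outgoing vergence at a refracting surface: magnification undefined")
    }
    dm <- 100 * (m_po / m_pre - 1)
  }

  list(ref = ref, delta_m = dm, slpos = slpos, v_slpos = v_slpos)
}

core_from_inputs <- function(eye, piol, cfg, want_dm) {
  stopifnot(inherits(cfg, "scenario_config"))
  pf <- piol_fields(piol, thick_piol_scenario(cfg$scenario))
  correction_core(eye$rc_a, eye$rc_p, eye$cct, eye$aqd + eye$cct, pf$power,
                  pf$r_front, pf$r_back, pf$thickness, pf$n_lens,
                  cfg$scenario, cfg$vault, cfg$vd, cfg$n_c, cfg$n_k, cfg$n_a,
                  want_dm = want_dm)
}

#' Assemble the optical system of one scenario
#'
#' Returns the ordered element sequence (surfaces and gaps) of the
#' postoperative system (corneal front vertex to SLPOS, cornea then PIOL)
#' or of the preoperative system (spectacle plane to SLPOS, thin spectacle
#' lens then cornea then an aqueous gap).  These sequences feed the
#' ray-transfer-matrix oracle and the magnification traces; the closed-form
#' solver in [solve_ref()] is their algebraic equivalent.
#'
#' @param eye An [eye_biometry()].
#' @param piol A design row (scenarios A, B) or a bare power in dpt
#'   (scenarios C, D).
#' @param cfg A [scenario_config()].
#' @param phase `"post"` (with the PIOL) or `"pre"` (spectacle + cornea).
#' @param spectacle_power Thin spectacle power in dpt for the preoperative
#'   system.
#' @return List of optical elements.
#' @export
build_system <- function(eye, piol, cfg, phase = c("post", "pre"),
                         spectacle_power = 0) {
  stopifnot(inherits(eye, "eye_biometry"), inherits(cfg, "scenario_config"))
  phase <- match.arg(phase)
  thick_c <- thick_cornea_scenario(cfg$scenario)
  thick_p <- thick_piol_scenario(cfg$scenario)
  slpos <- eye$acd - cfg$vault

  cornea <- if (thick_c) {
    list(elem_surface(1, cfg$n_c, radius = eye$rc_a),
         elem_gap(eye$cct, cfg$n_c),
         elem_surface(cfg$n_c, cfg$n_a, radius = eye$rc_p))
  } else {
    list(elem_surface(1, cfg$n_a, power = 1000 * (cfg$n_k - 1) / eye$rc_a))
  }
  x_cornea_back <- if (thick_c) eye$cct else 0

  if (phase == "pre") {
    return(c(list(elem_surface(1, 1, power = spectacle_power),
                  elem_gap(cfg$vd, 1)),
             cornea,
             list(elem_gap(slpos - x_cornea_back, cfg$n_a))))
  }

  pf <- piol_fields(piol, thick_p)
  t_eff <- if (thick_p) pf$thickness else 0
  x_front <- slpos - t_eff
  if (x_front < x_cornea_back) {
    stop("PIOL front vertex lies at or before the corneal back vertex (SLPOS - PIOLT < CCT)")
  }
  piol_elems <- if (thick_p) {
    list(elem_surface(cfg$n_a, pf$n_lens, radius = pf$r_front),
         elem_gap(pf$thickness, pf$n_lens),
         elem_surface(pf$n_lens, cfg$n_a, radius = pf$r_back))
  } else {
    list(elem_surface(cfg$n_a, cfg$n_a, power = pf$power))
  }
  c(cornea, list(elem_gap(x_front - x_cornea_back, cfg$n_a)), piol_elems)
}

#' Spectacle-plane refraction correction of a PIOL
#'
#' Forward-propagates a plane wave (object at infinity) through the
#' postoperative system to obtain the vergence just behind the PIOL at the
#' SLPOS plane, then inverts the preoperative trace (cornea only, no PIOL)
#' back to the spectacle plane.  The resulting spectacle vergence is the
#' refraction correction REF produced by implanting the lens.
#'
#' @param eye An [eye_biometry()].
#' @param piol A design row (scenarios A, B) or a bare power (C, D).
#' @param cfg A [scenario_config()].
#' @return An object of class `"correction_result"`: list with `ref` (dpt),
#'   `slpos` (mm), `v_slpos` (dpt), `piolp` (dpt) and `scenario`.
#' @examples
#' eye <- eye_biometry(7.77, 6.40, 0.50, 3.00, 3.70)
#' tbl <- synth_design_table()
#' solve_ref(eye, tbl[tbl$power_dpt == -10, ], scenario_config("A"))
#' @export
solve_ref <- function(eye, piol, cfg) {
  res <- core_from_inputs(eye, piol, cfg, want_dm = FALSE)
  pf <- piol_fields(piol, thick_piol_scenario(cfg$scenario))
  structure(list(ref = res$ref, slpos = res$slpos, v_slpos = res$v_slpos,
                 piolp = pf$power, scenario = cfg$scenario),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result %s> PIOLP %+.1f dpt -> REF %+.3f dpt (V_SLPOS %.3f dpt at %.3f mm)\n",
              x$scenario, x$piolp, x$ref, x$v_slpos, x$slpos))
  invisible(x)
}

#' Relative change in lateral magnification
#'
#' Ratio of the postoperative (cornea + PIOL) to the preoperative
#' (spectacle + cornea) lateral magnification, as the product of the
#' incoming over the outgoing vergence at every refracting surface:
#' `dM = 100 * ((prod V_po / prod V'_po) * (prod V'_pr / prod V_pr) - 1)`.
#' Both states are fully corrected: the preoperative spectacle power equals
#' the REF of the lens.  For the object at infinity the incoming vergence
#' at the first surface is zero in both states and cancels symbolically;
#' the result equals the finite-object-distance limit.
#'
#' @inheritParams solve_ref
#' @return The magnification change in percent; positive = image gain.
#' @export
delta_m <- function(eye, piol, cfg) {
  core_from_inputs(eye, piol, cfg, want_dm = TRUE)$delta_m
}

#' Per-surface vergence trace of both corrected states
#'
#' Element-by-element propagation through the preoperative (spectacle with
#' power REF + cornea) and postoperative (cornea + PIOL) systems, recording
#' the (incoming, outgoing) vergence pair at every refracting surface, and
#' the magnification change computed from those products.  With a finite
#' `object_distance_m` (measured from the corneal front vertex) no
#' cancellation is applied; with the default infinite distance the shared
#' first-surface zero is dropped from both products.  Serves as the
#' independent check of [delta_m()].
#'
#' @inheritParams solve_ref
#' @param object_distance_m Object distance in metres, `Inf` for a plane
#'   wave.
#' @return List with `pre` and `post` trace data.frames, `ref`, and
#'   `delta_m`.
#' @export
magnification_trace <- function(eye, piol, cfg, object_distance_m = Inf) {
  ref <- solve_ref(eye, piol, cfg)$ref
  pre <- build_system(eye, piol, cfg, phase = "pre", spectacle_power = ref)
  post <- build_system(eye, piol, cfg, phase = "post")
  v0_pre <- if (is.finite(object_distance_m)) {
    vergence(-1 / (object_distance_m + cfg$vd / 1000))
  } else {
    vergence(0)
  }
  v0_post <- if (is.finite(object_distance_m)) {
    vergence(-1 / object_distance_m)
  } else {
    vergence(0)
  }
  tr_pre <- propagate_vergence(pre, v0_pre, trace = TRUE)$trace
  tr_post <- propagate_vergence(post, v0_post, trace = TRUE)$trace
  mag <- function(tr, drop_first) {
    num <- if (drop_first) tr$v_in[-1L] else tr$v_in
    prod(num) / prod(tr$v_out)
  }
  sym <- !is.finite(object_distance_m)
  dm <- 100 * (mag(tr_post, sym) / mag(tr_pre, sym) - 1)
  list(pre = tr_pre, post = tr_post, ref = ref, delta_m = dm)
}

#' Evaluate a full design table on one eye
#'
#' Computes REF and the magnification change for every labelled power step.
#'
#' @param eye An [eye_biometry()].
#' @param table A `piol_design_table`.
#' @param cfg A [scenario_config()]; thin-PIOL scenarios use the labelled
#'   powers of the table.
#' @return Data.frame with one row per power step: `power_dpt`, `ref_dpt`,
#'   `delta_m_pct`, `slpos_mm`, `v_slpos_dpt`.
#' @examples
#' eye <- eye_biometry(7.77, 6.40, 0.50, 3.00, 3.70)
#' head(scan_power_range(eye, synth_design_table(), scenario_config("A")))
#' @export
scan_power_range <- function(eye, table, cfg) {
  stopifnot(inherits(eye, "eye_biometry"), inherits(cfg, "scenario_config"))
  validate_design_table(table, n_ambient = cfg$n_a)
  n <- nrow(table)
  res <- correction_core(rep(eye$rc_a, n), rep(eye$rc_p, n), rep(eye$cct, n),
                         rep(eye$acd, n), table$power_dpt,
                         table$r_front_mm, table$r_back_mm,
                         table$thickness_mm, table$n_lens,
                         cfg$scenario, cfg$vault, cfg$vd,
                         cfg$n_c, cfg$n_k, cfg$n_a, want_dm = TRUE)
  data.frame(power_dpt = table$power_dpt, ref_dpt = res$ref,
             delta_m_pct = res$delta_m, slpos_mm = res$slpos,
             v_slpos_dpt = res$v_slpos)
}
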