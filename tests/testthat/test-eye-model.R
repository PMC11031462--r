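tbl <- synth_design_table()

test_that("biometry derives the chamber depth and keratometric power", {
  eye <- clinical_eye()
  expect_equal(eye$acd, 3.50)
  expect_equal(eye$pc, 337.5 / 7.77)
  expect_error(eye_biometry(7.77, -6.4, 0.5, 3, 3.7), "positive")
  expect_error(scenario_config("E"), "arg")
  expect_error(scenario_config("A", vault = -0.1), "vault")
})

test_that("system assembly respects the scenario geometry", {
  eye <- clinical_eye()
  d17 <- design_row(tbl, 17)
  cfgA <- clinical_cfg("A")

  elsA <- build_system(eye, d17, cfgA)
  kinds <- vapply(elsA, `[[`, "", "kind")
  expect_identical(sum(kinds == "surface"), 4L)
  # gap between corneal back vertex and PIOL front vertex = AQD - vault - PIOLT
  gapA <- elsA[[which(kinds == "gap")[2]]]
  expect_equal(gapA$distance, eye$aqd - cfgA$vault - d17$thickness_mm,
               tolerance = 1e-12)

  # scenario D: exactly two refracting elements postoperatively
  elsD <- build_system(eye, 17, clinical_cfg("D"))
  expect_identical(sum(vapply(elsD, `[[`, "", "kind") == "surface"), 2L)

  # B and A share the PIOL elements; the aqueous gaps end at the same plane
  elsB <- build_system(eye, d17, clinical_cfg("B"))
  expect_equal(elsB[-(1:2)], elsA[-(1:4)], ignore_attr = TRUE)
  expect_equal(elsB[[2]]$distance, elsA[[4]]$distance + eye$cct,
               tolerance = 1e-12)

  # thick-PIOL scenarios refuse a bare power; shallow chambers are caught
  expect_error(build_system(eye, 17, cfgA), "full design")
  shallow <- eye_biometry(7.77, 6.40, 0.50, 0.55, 3.70)
  expect_error(build_system(shallow, d17, cfgA), "corneal back vertex")
  expect_error(solve_ref(shallow, d17, cfgA), "corneal back vertex")
})

test_that("a zero-power thin lens leaves the refraction unchanged", {
  res <- solve_ref(clinical_eye(), 0, clinical_cfg("D"))
  expect_equal(res$ref, 0, tolerance = 1e-9)
  res <- solve_ref(clinical_eye(), 0, clinical_cfg("C"))
  expect_equal(res$ref, 0, tolerance = 1e-9)
})

test_that("solving REF is self-consistent and matches the element and matrix oracles", {
  cohort <- random_cohort(25, seed = 71)
  powers <- c(-17, -8.5, -3, 3, 10.5, 17)
  for (i in seq_len(nrow(cohort))) {
    eye <- eye_from_row(cohort[i, ])
    for (sc in c("A", "B", "C", "D")) {
      cfg <- scenario_config(sc)
      for (p in powers) {
        piol <- if (sc %in% c("A", "B")) design_row(tbl, p) else p
        res <- solve_ref(eye, piol, cfg)
        # forward element propagation reproduces the closed-form V_SLPOS
        post <- build_system(eye, piol, cfg, phase = "post")
        expect_equal(propagate_vergence(post, vergence(0))$value, res$v_slpos,
                     tolerance = 1e-9)
        expect_equal(matrix_vergence(system_matrix(post), vergence(0))$value,
                     res$v_slpos, tolerance = 1e-9)
        # re-substituting REF through the preoperative system returns V_SLPOS
        pre <- build_system(eye, piol, cfg, phase = "pre",
                            spectacle_power = res$ref)
        expect_equal(propagate_vergence(pre, vergence(0))$value, res$v_slpos,
                     tolerance = 1e-9)
        expect_equal(res$slpos, eye$acd - cfg$vault, tolerance = 1e-12)
      }
    }
  }
})

test_that("the magnification change matches its finite-object-distance limit", {
  eye <- clinical_eye()
  for (sc in c("A", "B", "C", "D")) {
    cfg <- clinical_cfg(sc)
    for (p in c(-17, -6, 4.5, 17)) {
      piol <- if (sc %in% c("A", "B")) design_row(tbl, p) else p
      dm <- delta_m(eye, piol, cfg)
      tr_inf <- magnification_trace(eye, piol, cfg)
      tr_far <- magnification_trace(eye, piol, cfg, object_distance_m = 1e6)
      expect_equal(tr_inf$delta_m, dm, tolerance = 1e-9)
      expect_equal(tr_far$delta_m, dm, tolerance = 1e-6)
    }
  }
})

test_that("the magnification change vanishes with the correction", {
  dm <- delta_m(clinical_eye(), 1e-4, clinical_cfg("D"))
  expect_lt(abs(dm), 1e-2)
  expect_error(delta_m(clinical_eye(), 0, clinical_cfg("D")), "zero")
})

test_that("myopic lenses magnify and hyperopic lenses minify", {
  s <- scan_power_range(mean_eye(), tbl, scenario_config("A"))
  neg <- s$power_dpt < 0
  expect_true(all(s$ref_dpt[neg] < 0) && all(s$delta_m_pct[neg] > 0))
  expect_true(all(s$ref_dpt[!neg] > 0) && all(s$delta_m_pct[!neg] < 0))
})

test_that("REF increases and the magnification change decreases over the schedule", {
  cohort <- random_cohort(20, seed = 99)
  for (sc in c("A", "B")) {
    cfg <- scenario_config(sc)
    for (i in seq_len(nrow(cohort))) {
      s <- scan_power_range(eye_from_row(cohort[i, ]), tbl, cfg)
      expect_true(all(diff(s$ref_dpt) > 0))
      expect_true(all(diff(s$delta_m_pct) < 0))
    }
  }
})

test_that("the corneal model barely matters but the PIOL model does", {
  eye <- clinical_eye()
  sA <- scan_power_range(eye, tbl, clinical_cfg("A"))
  sB <- scan_power_range(eye, tbl, clinical_cfg("B"))
  sC <- scan_power_range(eye, tbl, clinical_cfg("C"))
  # thin vs thick cornea: sub-0.1 dpt everywhere
  expect_lt(max(abs(sA$ref_dpt - sB$ref_dpt)), 0.1)
  # thin vs thick PIOL: error grows monotonically over the positive branch
  dCA <- abs(sC$ref_dpt - sA$ref_dpt)
  pos <- sA$power_dpt > 0
  expect_true(all(diff(dCA[pos]) > 0))
  expect_gt(max(dCA[pos]), 0.25)
})

test_that("scenario collapse: thick models converge to thin ones as PIOLT -> 0", {
  thin_tbl <- synth_design_table(thickness_fun = function(p) rep(1e-7, length(p)))
  eye <- mean_eye()
  for (p in c(-17, -3, 3, 17)) {
    d <- design_row(thin_tbl, p)
    expect_equal(solve_ref(eye, d, scenario_config("A"))$ref,
                 solve_ref(eye, p, scenario_config("C"))$ref, tolerance = 1e-3)
    expect_equal(solve_ref(eye, d, scenario_config("B"))$ref,
                 solve_ref(eye, p, scenario_config("D"))$ref, tolerance = 1e-3)
  }
})
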