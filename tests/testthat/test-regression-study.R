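small_grid <- function(n_eyes = 10, seed = 21, scenario = "A") {
  cohort <- random_cohort(n_eyes, seed = seed)
  build_grid(cohort, synth_design_table(), scenario_config(scenario))
}

test_that("the simulation grid crosses every eye with every power step", {
  grid <- small_grid(10)
  expect_identical(nrow(grid), 580L)
  expect_identical(unique(table(grid$eye_id)), 58L)
  expect_true(all(is.finite(grid$ref)) && all(is.finite(grid$delta_m)))
  # REF monotone in the lens power within each eye
  for (id in unique(grid$eye_id)) {
    expect_true(all(diff(grid$ref[grid$eye_id == id]) > 0))
  }
  # scenarios A and B differ only in the responses, not the layout
  gridB <- small_grid(10, scenario = "B")
  expect_identical(grid[c("eye_id", "rc_a", "piolp")],
                   gridB[c("eye_id", "rc_a", "piolp")])
  expect_false(isTRUE(all.equal(grid$ref, gridB$ref)))
  expect_error(build_grid(random_cohort(3, 1), synth_design_table(),
                          scenario_config("C")),
               "thick-PIOL")
})

test_that("stepwise selection keeps the constant model under pure noise", {
  grid <- small_grid(6, seed = 31)
  set.seed(8)
  grid$ref <- rnorm(nrow(grid))
  rep0 <- stepwise_fit(grid, "ref", degree = 2)
  expect_identical(rep0$terms$term, "(Intercept)")
  expect_identical(length(rep0$path), 0L)
  expect_equal(rep0$rmse, sqrt(mean((grid$ref - mean(grid$ref))^2)),
               tolerance = 1e-12)
})

test_that("stepwise selection recovers a planted single-predictor model", {
  grid <- small_grid(6, seed = 32)
  set.seed(9)
  grid$ref <- 2 * grid$piolp + rnorm(nrow(grid), sd = 0.01)
  rep1 <- stepwise_fit(grid, "ref", degree = 1)
  expect_identical(setdiff(rep1$terms$term, "(Intercept)"), "piolp")
  expect_equal(rep1$terms$estimate[rep1$terms$term == "piolp"], 2,
               tolerance = 1e-3)
})

test_that("every recorded stepwise decision replays under the add/remove rules", {
  grid <- small_grid(8, seed = 33)
  rep2 <- stepwise_fit(grid, "ref", degree = 2)
  included <- character(0)
  candidates <- sort(c("rc_a", "rc_p", "cct", "acd", "lt", "piolp",
                       paste0(c("rc_a", "rc_p", "cct", "acd", "lt", "piolp"), "_sq")))
  dat <- grid
  for (v in c("rc_a", "rc_p", "cct", "acd", "lt", "piolp")) {
    dat[[paste0(v, "_sq")]] <- dat[[v]]^2
  }
  pval <- function(terms, of) {
    fit <- lm(reformulate(terms, response = "ref"), data = dat)
    summary(fit)$coefficients[of, 4]
  }
  for (step in rep2$path) {
    if (step$action == "add") {
      eligible <- setdiff(candidates, included)
      eligible <- eligible[!grepl("_sq$", eligible) |
                             sub("_sq$", "", eligible) %in% included]
      ps <- vapply(eligible, function(tm) pval(c(included, tm), tm), numeric(1))
      expect_identical(step$term, eligible[which.min(ps)])
      expect_lte(min(ps), 0.01)
      expect_equal(step$p, unname(min(ps)), tolerance = 1e-9)
      included <- c(included, step$term)
    } else {
      expect_gte(step$p, 0.1)
      included <- setdiff(included, step$term)
    }
  }
  expect_setequal(included, setdiff(rep2$terms$term, "(Intercept)"))
  # final model is stable: nothing left to add at p_enter, nothing at p_remove
  left <- setdiff(candidates, included)
  left <- left[!grepl("_sq$", left) | sub("_sq$", "", left) %in% included]
  ps_left <- vapply(left, function(tm) pval(c(included, tm), tm), numeric(1))
  expect_gt(min(ps_left), 0.01)
  ps_in <- vapply(included, function(tm) pval(included, tm), numeric(1))
  expect_lt(max(ps_in), 0.1)
})

test_that("model reports expose exact in-sample performance statistics", {
  grid <- small_grid(5, seed = 34)
  # noiseless linear response: saturated recovery
  grid$ref <- 1 + 0.5 * grid$rc_a - 2 * grid$piolp
  rep3 <- suppressWarnings(fit_terms(grid, "ref", c("rc_a", "piolp")))
  expect_lt(rep3$rmse, 1e-10)
  expect_equal(rep3$adj_r2, 1, tolerance = 1e-9)
  # constant model: RMSE is the n-normalized sample SD
  rep4 <- fit_terms(grid, "ref", character(0))
  expect_equal(rep4$rmse, sqrt(mean((grid$ref - mean(grid$ref))^2)),
               tolerance = 1e-12)
  # evaluate() reproduces the embedded statistics on the same grid
  rep5 <- fit_terms(grid, "delta_m", c("rc_a", "piolp", "piolp_sq"))
  ev <- evaluate_model(rep5, grid)
  expect_equal(ev$rmse, rep5$rmse, tolerance = 1e-10)
  expect_equal(ev$adj_r2, rep5$adj_r2, tolerance = 1e-10)
  expect_equal(ev$f, rep5$f, tolerance = 1e-6)
})

test_that("fitted signs match the optics: REF rises and magnification falls with power", {
  grid <- small_grid(15, seed = 35)
  ref_fit <- fit_terms(grid, "ref", c("rc_a", "acd", "piolp"))
  dm_fit <- fit_terms(grid, "delta_m", c("rc_a", "piolp"))
  expect_gt(ref_fit$terms$estimate[ref_fit$terms$term == "piolp"], 0)
  expect_lt(dm_fit$terms$estimate[dm_fit$terms$term == "piolp"], 0)
})

test_that("the lens-power coefficient is stable across cohort seeds", {
  co <- function(seed) {
    grid <- small_grid(400, seed = seed)
    f <- fit_terms(grid, "ref", c("rc_a", "acd", "piolp"))
    f$terms$estimate[f$terms$term == "piolp"]
  }
  expect_lt(abs(co(101) - co(202)), 0.01)
})

test_that("the full study yields eight deterministic reports with quadratic gains", {
  study <- run_study(n_eyes = 60, seed = 17)
  expect_identical(length(study$reports), 8L)
  expect_true(all(vapply(study$reports, function(r) {
    length(setdiff(r$terms$term, "(Intercept)")) > 0
  }, logical(1))))
  for (sc in c("A", "B")) {
    for (resp in c("ref", "delta_m")) {
      expect_lt(study$reports[[sprintf("%s_%s_deg2", sc, resp)]]$rmse,
                study$reports[[sprintf("%s_%s_deg1", sc, resp)]]$rmse)
    }
  }
  expect_identical(run_study(n_eyes = 60, seed = 17)$reports, study$reports)
})
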