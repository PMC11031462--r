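# Monte-Carlo prediction study: evaluate REF and delta-M over a cohort
# crossed with the full labelled power schedule (thick-PIOL scenarios A
# and B), then fit prediction models by bidirectional p-value stepwise
# selection restricted to first- and second-order terms without
# interactions.

scenario_candidates <- function(scenario) {
  switch(scenario,
         A = c("rc_a", "rc_p", "cct", "acd", "lt", "piolp"),
         B = c("pc", "acd", "lt", "piolp"),
         stop("prediction models are defined for the thick-PIOL scenarios A and B"))
}

#' Simulation grid of REF and delta-M over cohort x power schedule
#'
#' One row per eye and labelled power step, carrying the eye predictors and
#' both responses.  Deterministic given the cohort and design table.
#'
#' @param cohort A `biometry_cohort` (or any data.frame with columns
#'   `rc_a`, `rc_p`, `cct`, `aqd` or `acd`, `lt`, `pc`).
#' @param table A `piol_design_table`.
#' @param cfg A [scenario_config()] for scenario `"A"` or `"B"`.
#' @return Data.frame with `n_eyes * 58` rows: `eye_id`, `rc_a`, `rc_p`,
#'   `cct`, `pc`, `acd`, `lt`, `piolp`, `ref`, `delta_m`, `scenario`.
#' @export
build_grid <- function(cohort, table, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!thick_piol_scenario(cfg$scenario)) {
    stop("prediction models are defined for the thick-PIOL scenarios A and B")
  }
  validate_design_table(table, n_ambient = cfg$n_a)
  if (!"acd" %in% names(cohort)) cohort$acd <- cohort$aqd + cohort$cct
  ne <- nrow(cohort)
  nd <- nrow(table)
  ie <- rep(seq_len(ne), each = nd)
  id <- rep(seq_len(nd), times = ne)
  res <- correction_core(cohort$rc_a[ie], cohort$rc_p[ie], cohort$cct[ie],
                         cohort$acd[ie], table$power_dpt[id],
                         table$r_front_mm[id], table$r_back_mm[id],
                         table$thickness_mm[id], table$n_lens[id],
                         cfg$scenario, cfg$vault, cfg$vd,
                         cfg$n_c, cfg$n_k, cfg$n_a, want_dm = TRUE)
  grid <- data.frame(eye_id = if ("eye_id" %in% names(cohort)) cohort$eye_id[ie] else ie,
                     rc_a = cohort$rc_a[ie], rc_p = cohort$rc_p[ie],
                     cct = cohort$cct[ie], pc = cohort$pc[ie],
                     acd = cohort$acd[ie], lt = cohort$lt[ie],
                     piolp = table$power_dpt[id],
                     ref = res$ref, delta_m = res$delta_m,
                     scenario = cfg$scenario)
  drop <- !is.finite(grid$ref) | !is.finite(grid$delta_m)
  if (any(drop)) {
    warning(sprintf("dropped %d grid rows with failed optical solutions", sum(drop)))
    grid <- grid[!drop, , drop = FALSE]
  }
  grid
}

# add squared-term columns "<name>_sq" for every candidate
with_squares <- function(data, candidates) {
  for (v in candidates) data[[paste0(v, "_sq")]] <- data[[v]]^2
  data
}

term_parent <- function(term) sub("_sq$", "", term)
is_square <- function(term) grepl("_sq$", term)

fit_ols <- function(data, response, terms) {
  fml <- if (length(terms)) {
    stats::reformulate(terms, response = response)
  } else {
    stats::as.formula(paste(response, "~ 1"))
  }
  stats::lm(fml, data = data)
}

term_p_values <- function(fit) {
  cf <- summary(fit)$coefficients
  p <- cf[, 4]
  names(p) <- rownames(cf)
  p
}

#' Bidirectional p-value stepwise model selection
#'
#' Starting from the constant model, repeatedly adds the eligible excluded
#' term with the smallest coefficient p-value (two-sided t-test) if
#' `p <= p_enter`, then removes the included term with the largest p-value
#' while `p >= p_remove`, until the model is stable.  Candidate predictors
#' depend on the scenario (A: RC_a, RC_p, CCT, ACD, LT, PIOLP;
#' B: PC, ACD, LT, PIOLP); `degree = 2` adds the squares of all candidates
#' (no interactions).  Selection is hierarchical: a squared term is
#' eligible only while its linear parent is in the model, and a parent is
#' not removable while its square is present.  Ties in the p-value are
#' broken by lexicographic term order.
#'
#' @param grid A simulation grid from [build_grid()] (or any data.frame
#'   carrying the candidate columns and the response).
#' @param response `"ref"` or `"delta_m"`.
#' @param degree 1 (linear terms) or 2 (linear + quadratic).
#' @param scenario `"A"` or `"B"`; taken from the grid when present.
#' @param p_enter,p_remove Entry / removal thresholds on the coefficient
#'   p-value; `p_enter < p_remove`.
#' @return A `piol_model_report`: list with `terms` (data.frame `term`,
#'   `estimate`, `p_value`, intercept first), `rmse` (n-normalized
#'   in-sample residual RMS), `adj_r2`, `f`, `f_p` (final vs constant
#'   model), `path` (the add/remove decisions), plus metadata.
#' @examples
#' cohort <- sample_cohort(cohort_spec(50, seed = 3))
#' grid <- build_grid(cohort, synth_design_table(), scenario_config("A"))
#' stepwise_fit(grid, "ref", degree = 2)
#' @export
stepwise_fit <- function(grid, response = c("ref", "delta_m"), degree = 1,
                         scenario = NULL, p_enter = 0.01, p_remove = 0.1) {
  response <- match.arg(response)
  stopifnot(degree %in% c(1, 2))
  if (p_enter >= p_remove) stop("p_enter must be smaller than p_remove")
  if (is.null(scenario)) {
    scenario <- unique(as.character(grid$scenario))
    if (length(scenario) != 1L) stop("grid must carry a single scenario tag")
  }
  linear <- scenario_candidates(scenario)
  candidates <- sort(if (degree == 2) c(linear, paste0(linear, "_sq")) else linear)
  data <- with_squares(grid[c(response, linear)], linear)
  if (nrow(data) <= length(candidates) + 2L) {
    stop("too few rows for the candidate set")
  }

  included <- character(0)
  path <- list()
  repeat {
    changed <- FALSE
    # entry step
    eligible <- setdiff(candidates, included)
    eligible <- eligible[!is_square(eligible) | term_parent(eligible) %in% included]
    if (length(eligible)) {
      p_try <- vapply(eligible, function(tm) {
        fit <- fit_ols(data, response, c(included, tm))
        unname(term_p_values(fit)[tm])
      }, numeric(1))
      best <- which.min(p_try)  # candidates pre-sorted: first minimum = lexicographic tie-break
      if (is.finite(p_try[best]) && p_try[best] <= p_enter) {
        included <- c(included, eligible[best])
        path[[length(path) + 1L]] <- list(action = "add",
                                          term = eligible[best],
                                          p = unname(p_try[best]))
        changed <- TRUE
      }
    }
    # removal step
    repeat {
      if (!length(included)) break
      removable <- included[!(included %in% term_parent(included[is_square(included)]))]
      if (!length(removable)) break
      p_cur <- term_p_values(fit_ols(data, response, included))[removable]
      worst <- which.max(p_cur)
      if (is.finite(p_cur[worst]) && p_cur[worst] >= p_remove) {
        tm <- removable[worst]
        included <- setdiff(included, tm)
        path[[length(path) + 1L]] <- list(action = "remove", term = tm,
                                          p = unname(p_cur[worst]))
        changed <- TRUE
      } else break
    }
    if (!changed) break
    if (length(path) > 100L) stop("stepwise selection failed to stabilize")
  }

  fit <- fit_ols(data, response, included)
  report <- model_report(fit, data, response, included, scenario, degree)
  report$path <- path
  report$p_enter <- p_enter
  report$p_remove <- p_remove
  report
}

#' Ordinary least squares with a fixed term set
#'
#' Companion to [stepwise_fit()] for fitting a prescribed model (e.g. the
#' published predictor sets) without selection.
#'
#' @inheritParams stepwise_fit
#' @param terms Character vector of term names; squares as `"<name>_sq"`.
#' @return A `piol_model_report`.
#' @export
fit_terms <- function(grid, response = c("ref", "delta_m"), terms,
                      scenario = NULL) {
  response <- match.arg(response)
  if (is.null(scenario)) {
    scenario <- unique(as.character(grid$scenario))
    if (length(scenario) != 1L) stop("grid must carry a single scenario tag")
  }
  linear <- unique(term_parent(terms))
  data <- with_squares(grid[c(response, linear)], linear)
  fit <- fit_ols(data, response, terms)
  model_report(fit, data, response, terms, scenario,
               degree = if (any(is_square(terms))) 2L else 1L)
}

model_report <- function(fit, data, response, terms, scenario, degree) {
  y <- data[[response]]
  n <- length(y)
  res <- stats::residuals(fit)
  rmse <- sqrt(mean(res^2))
  k <- length(terms)
  if (k) {
    sm <- summary(fit)
    cf <- sm$coefficients
    adj_r2 <- sm$adj.r.squared
    tss <- sum((y - mean(y))^2)
    rss <- sum(res^2)
    f <- ((tss - rss) / k) / (rss / (n - k - 1))
    f_p <- stats::pf(f, k, n - k - 1, lower.tail = FALSE)
  } else {
    cf <- matrix(c(mean(y), stats::sd(y) / sqrt(n), NA, NA), 1, 4,
                 dimnames = list("(Intercept)", NULL))
    adj_r2 <- 0
    f <- NA_real_
    f_p <- NA_real_
  }
  structure(list(terms = data.frame(term = rownames(cf),
                                    estimate = unname(cf[, 1]),
                                    p_value = unname(cf[, 4]),
                                    row.names = NULL),
                 rmse = rmse, adj_r2 = adj_r2, f = f, f_p = f_p,
                 n_rows = n, response = response, scenario = scenario,
                 degree = degree),
            class = "piol_model_report")
}

#' @export
print.piol_model_report <- function(x, digits = 5, ...) {
  cat(sprintf("<piol_model_report> scenario %s, response %s, degree %d, n = %d\n",
              x$scenario, x$response, x$degree, x$n_rows))
  tt <- x$terms
  tt$estimate <- signif(tt$estimate, digits)
  tt$p_value <- signif(tt$p_value, 3)
  print(tt, row.names = FALSE)
  cat(sprintf("RMSE %.4g | adj R^2 %.4g | F %.4g (p %.3g)\n",
              x$rmse, x$adj_r2, x$f, x$f_p))
  invisible(x)
}

#' Evaluate a fitted model report on a grid
#'
#' Applies the report's coefficients to (possibly new) grid rows and
#' recomputes the performance record: residual RMSE, adjusted R-squared and
#' the F statistic against the constant model.
#'
#' @param report A `piol_model_report`.
#' @param grid A data.frame carrying the predictor columns and the response.
#' @return List with `rmse`, `adj_r2`, `f`, `f_p`, `n_rows`.
#' @export
evaluate_model <- function(report, grid) {
  stopifnot(inherits(report, "piol_model_report"))
  terms <- setdiff(report$terms$term, "(Intercept)")
  linear <- unique(term_parent(terms))
  data <- with_squares(grid[c(report$response, linear)], linear)
  x <- cbind(1, as.matrix(data[, terms, drop = FALSE]))
  beta <- report$terms$estimate[match(c("(Intercept)", terms), report$terms$term)]
  y <- data[[report$response]]
  res <- y - drop(x %*% beta)
  n <- length(y)
  k <- length(terms)
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  r2 <- 1 - rss / tss
  list(rmse = sqrt(mean(res^2)),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
       f = if (k) ((tss - rss) / k) / (rss / (n - k - 1)) else NA_real_,
       f_p = if (k) stats::pf(((tss - rss) / k) / (rss / (n - k - 1)),
                              k, n - k - 1, lower.tail = FALSE) else NA_real_,
       n_rows = n)
}

#' Run the full Monte-Carlo prediction study
#'
#' Samples a synthetic cohort, evaluates REF and delta-M over the design
#' table for scenarios A and B, and fits stepwise models for both responses
#' at degree 1 and 2: eight model reports in total.
#'
#' @param n_eyes Cohort size.
#' @param seed Integer seed for the cohort generator.
#' @param table Design table (default: the surrogate family).
#' @param vault,vd Scenario geometry in mm.
#' @param p_enter,p_remove Stepwise thresholds.
#' @return An object of class `"piol_study"`: list of eight
#'   `piol_model_report`s named `<scenario>_<response>_deg<degree>`, plus
#'   `meta` (seed, n_eyes, vault, vd).
#' @export
run_study <- function(n_eyes = 1000, seed = 1L, table = synth_design_table(),
                      vault = 0.4, vd = 12, p_enter = 0.01, p_remove = 0.1) {
  cohort <- sample_cohort(cohort_spec(n_eyes, seed = seed))
  reports <- list()
  for (sc in c("A", "B")) {
    cfg <- scenario_config(sc, vault = vault, vd = vd)
    grid <- build_grid(cohort, table, cfg)
    for (resp in c("ref", "delta_m")) {
      for (deg in 1:2) {
        reports[[sprintf("%s_%s_deg%d", sc, resp, deg)]] <-
          stepwise_fit(grid, resp, degree = deg, scenario = sc,
                       p_enter = p_enter, p_remove = p_remove)
      }
    }
  }
  structure(list(reports = reports,
                 meta = list(seed = seed, n_eyes = n_eyes, vault = vault,
                             vd = vd, p_enter = p_enter, p_remove = p_remove,
                             provenance = attr(table, "provenance"))),
            class = "piol_study")
}

#' @export
print.piol_study <- function(x, ...) {
  cat(sprintf("<piol_study> %d eyes (seed %d), scenarios A/B x {REF, dM} x degree {1, 2}\n",
              x$meta$n_eyes, x$meta$seed))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-16s terms {%s}  RMSE %.4g  adj R^2 %.4g\n", nm,
                paste(setdiff(r$terms$term, "(Intercept)"), collapse = ", "),
                r$rmse, r$adj_r2))
  }
  invisible(x)
}
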