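# Synthetic anterior-segment biometry cohorts and preprocessing of
# Casia-style tomographer exports.
#
# The generator draws (RC_a, RC_p, CCT, AQD, LT) from a truncated
# multivariate normal whose marginal means and SDs default to the
# descriptive statistics of a large (N = 2365) clinical anterior-segment
# OCT cohort, truncated at +/- 3 SD, with the manufacturer's AQD >= 2.8 mm
# implantability filter applied by rejection.  ACD = AQD + CCT holds
# exactly for every synthetic eye and PC is derived keratometrically.

#' Default marginal statistics of the reference cohort
#'
#' Means and standard deviations (mm) of the five sampled biometry
#' parameters, taken from the descriptive statistics of a 2365-eye clinical
#' anterior-segment OCT cohort.
#'
#' @return List with numeric vectors `means` and `sds`, both named
#'   `rc_a`, `rc_p`, `cct`, `aqd`, `lt`.
#' @export
cohort_defaults <- function() {
  list(means = c(rc_a = 7.7633, rc_p = 6.5751, cct = 0.5434,
                 aqd = 3.1256, lt = 3.9217),
       sds = c(rc_a = 0.2854, rc_p = 0.2473, cct = 0.0366,
               aqd = 0.2381, lt = 0.2024))
}

#' The mean-biometry eye of the reference cohort
#'
#' @param n_k Keratometer index.
#' @return An [eye_biometry()] at the default marginal means.
#' @export
mean_eye <- function(n_k = 1.3375) {
  m <- cohort_defaults()$means
  eye_biometry(m[["rc_a"]], m[["rc_p"]], m[["cct"]], m[["aqd"]], m[["lt"]],
               n_k = n_k)
}

default_biometry_corr <- function() {
  nm <- c("rc_a", "rc_p", "cct", "aqd", "lt")
  corr <- diag(5)
  dimnames(corr) <- list(nm, nm)
  corr["rc_a", "rc_p"] <- corr["rc_p", "rc_a"] <- 0.9
  corr["aqd", "lt"] <- corr["lt", "aqd"] <- -0.3
  corr
}

#' Specification of a synthetic biometry cohort
#'
#' @param n_eyes Number of eyes to generate (>= 1).
#' @param means,sds Named marginal means / SDs over
#'   `c("rc_a", "rc_p", "cct", "aqd", "lt")`; defaults from
#'   [cohort_defaults()].
#' @param corr 5x5 correlation matrix (symmetric positive semi-definite,
#'   unit diagonal).  The default couples the two corneal radii (0.9) and
#'   aqueous depth with lens thickness (-0.3); correlations are not
#'   published for the reference cohort, and the downstream responses are
#'   near-deterministic functions of the marginals, so results are
#'   insensitive to this choice.
#' @param aqd_min Inclusive lower implantability bound on AQD, mm.
#' @param seed Integer seed; identical specs yield identical cohorts.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_eyes, means = cohort_defaults()$means,
                        sds = cohort_defaults()$sds,
                        corr = default_biometry_corr(),
                        aqd_min = 2.8, seed = 1L) {
  nm <- c("rc_a", "rc_p", "cct", "aqd", "lt")
  stopifnot(length(n_eyes) == 1L, n_eyes >= 1)
  if (!all(nm %in% names(means)) || !all(nm %in% names(sds))) {
    stop("means and sds must be named over ", paste(nm, collapse = ", "))
  }
  if (any(sds < 0)) stop("marginal SDs must be >= 0")
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)) ||
      any(abs(diag(corr) - 1) > 1e-10)) {
    stop("correlation matrix must be symmetric with unit diagonal")
  }
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("correlation matrix must be positive semi-definite")
  }
  structure(list(n_eyes = as.integer(n_eyes), means = means[nm],
                 sds = sds[nm], corr = corr, aqd_min = aqd_min,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a synthetic biometry cohort
#'
#' Draws from the truncated multivariate normal of the spec (componentwise
#' truncation at mean +/- 3 SD, rejection sampling), applies the AQD filter
#' by rejection, and derives ACD and PC.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of class `"biometry_cohort"` with columns `eye_id`,
#'   `rc_a`, `rc_p`, `cct`, `aqd`, `acd`, `lt`, `pc`.
#' @examples
#' cohort <- sample_cohort(cohort_spec(200, seed = 7))
#' colMeans(cohort[c("rc_a", "aqd")])
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sigma <- diag(spec$sds) %*% spec$corr %*% diag(spec$sds)
  lo <- spec$means - 3 * spec$sds
  hi <- spec$means + 3 * spec$sds
  kept <- matrix(numeric(0), ncol = 5)
  tries <- 0L
  while (nrow(kept) < spec$n_eyes) {
    tries <- tries + 1L
    if (tries > 1000L) stop("rejection rate too high: check spec bounds")
    m <- max(64L, ceiling(1.4 * (spec$n_eyes - nrow(kept))))
    x <- MASS::mvrnorm(m, mu = spec$means, Sigma = sigma)
    if (m == 1L) x <- matrix(x, nrow = 1L)
    inside <- rowSums(sweep(x, 2, lo, `<`) | sweep(x, 2, hi, `>`)) == 0
    ok <- inside & x[, 4] >= spec$aqd_min
    kept <- rbind(kept, x[ok, , drop = FALSE])
  }
  kept <- kept[seq_len(spec$n_eyes), , drop = FALSE]
  out <- data.frame(eye_id = seq_len(spec$n_eyes),
                    rc_a = kept[, 1], rc_p = kept[, 2], cct = kept[, 3],
                    aqd = kept[, 4], acd = kept[, 4] + kept[, 3],
                    lt = kept[, 5], pc = 337.5 / kept[, 1])
  class(out) <- c("biometry_cohort", "data.frame")
  out
}

## ---- ingestion of real tomographer exports --------------------------------

#' Average the two corneal meridians of raw records
#'
#' Converts raw per-meridian records (flat/steep radii of the corneal front
#' and back surfaces) to per-eye biometry: `RC = (RC1 + RC2) / 2` for both
#' surfaces, `ACD = AQD + CCT`, and the keratometric power.
#'
#' @param records Data.frame with columns `RC1a_mm`, `RC2a_mm`, `RC1p_mm`,
#'   `RC2p_mm`, `CCT_mm`, `AQD_mm`, `LT_mm` (plus any identifiers, which
#'   are carried through).
#' @param n_k Keratometer index.
#' @return Data.frame with the identifier columns plus `rc_a`, `rc_p`,
#'   `cct`, `aqd`, `acd`, `lt`, `pc`.
#' @export
average_meridians <- function(records, n_k = 1.3375) {
  need <- c("RC1a_mm", "RC2a_mm", "RC1p_mm", "RC2p_mm",
            "CCT_mm", "AQD_mm", "LT_mm")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  rad <- records[c("RC1a_mm", "RC2a_mm", "RC1p_mm", "RC2p_mm")]
  bad <- which(rowSums(rad <= 0 | !is.finite(as.matrix(rad))) > 0)
  if (length(bad)) {
    stop(sprintf("non-positive meridian radius in record %d", bad[1L]))
  }
  ids <- records[setdiff(names(records), need)]
  out <- data.frame(rc_a = (records$RC1a_mm + records$RC2a_mm) / 2,
                    rc_p = (records$RC1p_mm + records$RC2p_mm) / 2,
                    cct = records$CCT_mm, aqd = records$AQD_mm,
                    acd = records$AQD_mm + records$CCT_mm,
                    lt = records$LT_mm)
  out$pc <- 1000 * (n_k - 1) / out$rc_a
  cbind(ids, out)
}

#' Preprocess raw biometry records for analysis
#'
#' Implements the study selection rules for raw tomographer exports:
#' records without identifiers are rejected; repeat measurements of the
#' same eye (same patient and side) are reduced to the first occurrence;
#' where both eyes of a patient are present one is selected by a seeded
#' random draw and the fellow eye discarded; eyes with an aqueous depth
#' below the implantability bound (AQD < 2.8 mm by default; the bound is
#' inclusive) are removed.  Meridians are averaged afterwards.
#'
#' @param records Data.frame with `patient_id`, `eye` and the meridian
#'   columns of [average_meridians()].
#' @param seed Integer seed for the one-eye selection.
#' @param aqd_min Inclusive lower bound on AQD in mm.
#' @param n_k Keratometer index.
#' @return List with `eyes` (the processed per-eye biometry data.frame) and
#'   `audit` (named counts of records removed by each rule).
#' @export
preprocess_biometry <- function(records, seed = 1L, aqd_min = 2.8,
                                n_k = 1.3375) {
  if (!all(c("patient_id", "eye") %in% names(records))) {
    stop("records must carry patient_id and eye columns")
  }
  n_input <- nrow(records)
  ok_id <- !is.na(records$patient_id) & !is.na(records$eye) &
    nzchar(as.character(records$patient_id)) & nzchar(as.character(records$eye))
  n_missing_id <- sum(!ok_id)
  records <- records[ok_id, , drop = FALSE]

  key <- paste(records$patient_id, records$eye, sep = "\r")
  dup <- duplicated(key)
  n_repeats <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$patient_id),
                        function(idx) {
                          if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
                        }), use.names = FALSE)
  n_fellow <- nrow(records) - length(keep)
  records <- records[sort(keep), , drop = FALSE]

  pass_aqd <- records$AQD_mm >= aqd_min
  n_aqd <- sum(!pass_aqd)
  records <- records[pass_aqd, , drop = FALSE]

  eyes <- average_meridians(records, n_k = n_k)
  rownames(eyes) <- NULL
  list(eyes = eyes,
       audit = c(n_input = n_input, removed_missing_id = n_missing_id,
                 removed_repeat_measurements = n_repeats,
                 removed_fellow_eyes = n_fellow,
                 removed_aqd = n_aqd, n_final = nrow(eyes)))
}

#' Read a raw biometry CSV / write a cohort CSV
#'
#' The ingest CSV carries `patient_id`, `eye`, `RC1a_mm`, `RC2a_mm`,
#' `RC1p_mm`, `RC2p_mm`, `CCT_mm`, `AQD_mm`, `LT_mm`.  The emitted cohort
#' CSV carries `rc_a_mm`, `rc_p_mm`, `cct_mm`, `aqd_mm`, `acd_mm`, `lt_mm`,
#' `pc_dpt`.
#'
#' @param path File path.
#' @return [read_biometry_csv()]: the raw records data.frame.
#'   [write_cohort_csv()]: `path`, invisibly.
#' @export
read_biometry_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "RC1a_mm", "RC2a_mm", "RC1p_mm", "RC2p_mm",
            "CCT_mm", "AQD_mm", "LT_mm")
  if (!all(need %in% names(rec))) {
    stop("biometry CSV must have columns ", paste(need, collapse = ", "))
  }
  rec
}

#' @rdname read_biometry_csv
#' @param cohort A cohort data.frame with columns `rc_a`, `rc_p`, `cct`,
#'   `aqd`, `acd`, `lt`, `pc`.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(rc_a_mm = cohort$rc_a, rc_p_mm = cohort$rc_p,
                    cct_mm = cohort$cct, aqd_mm = cohort$aqd,
                    acd_mm = cohort$acd, lt_mm = cohort$lt,
                    pc_dpt = cohort$pc)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
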