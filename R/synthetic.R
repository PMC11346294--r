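#' Synthetic screening cohorts
#'
#' Generates longitudinal nodule cohorts with the statistical structure
#' the analysis assumes: per-category growth exponents, log-normal
#' baseline volumes calibrated to printed median/IQR summaries,
#' triangular scan-schedule jitter pinned to the reported interval
#' median/IQRs, group-specific attenuation trajectories, a morphology
#' mix, and optional multiplicative volumetry noise. The growth
#' coefficient `alpha` is derived analytically from each nodule's drawn
#' exponent, baseline volume and target fold change, so every noiseless
#' trajectory is increasing, finite, and exactly recoverable by the
#' fitting module.
#'
#' @name synthetic
NULL

# log-normal (meanlog, sdlog) least-squares matched to log quartiles
.lnorm_from_quartiles <- function(q) {
  stopifnot(length(q) == 3, all(diff(q) > 0))
  lq <- log(q)
  c(meanlog = mean(lq), sdlog = (lq[3] - lq[1]) / (2 * stats::qnorm(0.75)))
}

#' Build a cohort-generator specification
#'
#' Defaults emulate a 180-nodule screening cohort: 40 benign / 140
#' malignant; growth-category mixes 20/0/8/1/11 (benign) and
#' 37/1/13/6/83 (malignant) over
#' decelerated/linear/subexponential/exponential/accelerated; baseline
#' volumes log-normal, calibrated to median (IQR) 103.5 (49.5-414.3)
#' mm^3 for benign and 179.3 (64.3-527.2) mm^3 for malignant; follow-up
#' times with median (IQR) 12.2 (6.2-13.9) and 24.3 (14.37-30.8)
#' months; attenuation stable around (-146, -156, -131) HU for benign
#' and increasing around (-314, -291, -233) HU for malignant; malignant
#' morphology 81/28/31 solid/part-solid/non-solid (benign all solid by
#' default, the mix being configurable).
#'
#' @param n_benign,n_malignant Group sizes.
#' @param category_mix_benign,category_mix_malignant Named integer counts
#'   per growth category; must sum to the group size.
#' @param beta_ranges Named list of `(min, max)` exponent sampling
#'   intervals per category.
#' @param beta_margin Offset keeping sampled exponents away from the
#'   category boundaries, so fitted values (recovered to solver
#'   tolerance) classify back into the drawn category.
#' @param v0_quartiles_benign,v0_quartiles_malignant Baseline-volume
#'   `(q25, median, q75)` in mm^3 used to calibrate the log-normal.
#' @param fold_change Named list of `(min, max)` uniform fold-change (at
#'   the second follow-up) ranges per category; all values must exceed 1.
#' @param t1_quartiles,t2_quartiles Scan-time `(q25, median, q75)` in
#'   months for the first and second follow-up.
#' @param min_gap_months Redraw schedule draws with `t2 <= t1 + gap`.
#' @param hu_benign,hu_malignant Mean attenuation (HU) at the three
#'   scans per group.
#' @param hu_between_sd SD of the per-nodule Gaussian attenuation offset
#'   (between-nodule heterogeneity; large in screening data, which is
#'   why baseline HU is an imperfect classifier).
#' @param hu_within_sd SD of the per-scan Gaussian attenuation jitter
#'   within a nodule.
#' @param morphology_mix_malignant,morphology_mix_benign Named counts
#'   (solid/part_solid/non_solid) per group; must sum to the group size.
#' @param volumetry_noise Multiplicative volume noise half-width applied
#'   to generated volumes (0 = noiseless).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_benign = 40, n_malignant = 140,
    category_mix_benign = c(decelerated = 20, linear = 0,
                            subexponential = 8, exponential = 1,
                            accelerated = 11),
    category_mix_malignant = c(decelerated = 37, linear = 1,
                               subexponential = 13, exponential = 6,
                               accelerated = 83),
    beta_ranges = list(decelerated = c(-2.0, -0.1), linear = c(-0.1, 0.1),
                       subexponential = c(0.1, 0.9),
                       exponential = c(0.9, 1.1),
                       accelerated = c(1.1, 2.5)),
    beta_margin = 1e-3,
    v0_quartiles_benign = c(49.5, 103.5, 414.3),
    v0_quartiles_malignant = c(64.3, 179.3, 527.2),
    fold_change = list(decelerated = c(1.2, 1.8), linear = c(1.2, 2.0),
                       subexponential = c(1.3, 2.5),
                       exponential = c(1.5, 3.0), accelerated = c(1.8, 4.0)),
    t1_quartiles = c(6.2, 12.2, 13.9),
    t2_quartiles = c(14.37, 24.3, 30.8),
    min_gap_months = 1,
    hu_benign = c(-146, -156, -131),
    hu_malignant = c(-314, -291, -233),
    hu_between_sd = 150,
    hu_within_sd = 20,
    morphology_mix_malignant = c(solid = 81, part_solid = 28,
                                 non_solid = 31),
    morphology_mix_benign = c(solid = 40, part_solid = 0, non_solid = 0),
    volumetry_noise = 0) {
  spec <- list(
    n_benign = n_benign, n_malignant = n_malignant,
    category_mix_benign = category_mix_benign,
    category_mix_malignant = category_mix_malignant,
    beta_ranges = beta_ranges, beta_margin = beta_margin,
    v0_quartiles_benign = v0_quartiles_benign,
    v0_quartiles_malignant = v0_quartiles_malignant,
    fold_change = fold_change,
    t1_quartiles = t1_quartiles, t2_quartiles = t2_quartiles,
    min_gap_months = min_gap_months,
    hu_benign = hu_benign, hu_malignant = hu_malignant,
    hu_between_sd = hu_between_sd, hu_within_sd = hu_within_sd,
    morphology_mix_malignant = morphology_mix_malignant,
    morphology_mix_benign = morphology_mix_benign,
    volumetry_noise = volumetry_noise)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec A candidate specification list.
#' @export
validate_cohort_spec <- function(spec) {
  cats <- growth_categories()
  for (grp in c("benign", "malignant")) {
    mix <- spec[[paste0("category_mix_", grp)]]
    n <- spec[[paste0("n_", grp)]]
    if (!setequal(names(mix), cats)) {
      stop_validation(sprintf("category_mix_%s must name all five categories.",
                              grp))
    }
    if (sum(mix) != n) {
      stop_validation(sprintf(
        "category_mix_%s sums to %d but n_%s is %d.", grp, sum(mix), grp, n))
    }
    mmix <- spec[[paste0("morphology_mix_", grp)]]
    if (sum(mmix) != n) {
      stop_validation(sprintf(
        "morphology_mix_%s sums to %d but n_%s is %d.", grp, sum(mmix), grp, n))
    }
  }
  for (cat in cats) {
    fc <- spec$fold_change[[cat]]
    if (is.null(fc) || any(fc <= 1)) {
      stop_validation(sprintf(
        "fold_change$%s must be a range with all values > 1.", cat))
    }
    br <- spec$beta_ranges[[cat]]
    if (is.null(br) || length(br) != 2 || br[1] >= br[2]) {
      stop_validation(sprintf("beta_ranges$%s must be an increasing pair.", cat))
    }
  }
  if (spec$volumetry_noise < 0 || spec$volumetry_noise >= 1) {
    stop_validation("volumetry_noise must be in [0, 1).")
  }
  invisible(spec)
}

# alpha making V(t2) = fc * v0 under the growth law with exponent beta
.alpha_for_fold_change <- function(v0, beta, fc, t2) {
  ifelse(abs(1 - beta) < .beta_one_tol,
         log(fc) / t2,
         ((fc * v0)^(1 - beta) - v0^(1 - beta)) / ((1 - beta) * t2))
}

.generate_group <- function(spec, group, id_prefix) {
  n <- spec[[paste0("n_", group)]]
  mix <- spec[[paste0("category_mix_", group)]][growth_categories()]
  categories <- rep(names(mix), times = mix)
  lnorm <- .lnorm_from_quartiles(spec[[paste0("v0_quartiles_", group)]])
  hu_centre <- spec[[paste0("hu_", group)]]
  mmix <- spec[[paste0("morphology_mix_", group)]]
  morphology <- sample(rep(names(mmix), times = mmix))
  q1 <- spec$t1_quartiles; q2 <- spec$t2_quartiles
  purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    cat_i <- categories[i]
    br <- spec$beta_ranges[[cat_i]]
    beta <- runif(1, br[1] + spec$beta_margin, br[2] - spec$beta_margin)
    v0 <- rlnorm(1, lnorm["meanlog"], lnorm["sdlog"])
    repeat {
      t1 <- rtri(1, q1[1] - (q1[2] - q1[1]), q1[2], q1[3] + (q1[3] - q1[2]))
      t2 <- rtri(1, q2[1] - (q2[2] - q2[1]), q2[2], q2[3] + (q2[3] - q2[2]))
      if (t1 > 0 && t2 > t1 + spec$min_gap_months) break
    }
    fc <- runif(1, spec$fold_change[[cat_i]][1], spec$fold_change[[cat_i]][2])
    alpha <- .alpha_for_fold_change(v0, beta, fc, t2)
    times <- c(0, t1, t2)
    vols <- vb_solve_forward(v0, alpha, beta, times)
    if (spec$volumetry_noise > 0) {
      vols <- vols * (1 + runif(3, -spec$volumetry_noise,
                                spec$volumetry_noise))
    }
    hu <- hu_centre + rnorm(1, 0, spec$hu_between_sd) +
      rnorm(3, 0, spec$hu_within_sd)
    tibble::tibble(
      nodule_id = sprintf("%s%03d", id_prefix, i),
      malignancy = group,
      morphology = morphology[i],
      histology = NA_character_,
      stage = NA_character_,
      time_months = times,
      volume_mm3 = vols,
      attenuation_hu = hu,
      beta_true = beta, alpha_true = alpha, fc_true = fc,
      category_true = cat_i)
  }))
}

#' Generate a synthetic cohort
#'
#' @param spec A `cohort_spec` (default [cohort_spec()]).
#' @param seed Integer seed; the same `(spec, seed)` pair always yields
#'   the same cohort.
#' @return A cohort tibble; the per-nodule generating truth (`beta_true`,
#'   `alpha_true`, `fc_true`, `category_true`) is attached as the
#'   `"params"` attribute, and the seed as `"seed"`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' dplyr::count(cohort, malignancy) # 3 rows per nodule
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  validate_cohort_spec(spec)
  set_seed_if_given(seed)
  raw <- dplyr::bind_rows(
    .generate_group(spec, "benign", "B"),
    .generate_group(spec, "malignant", "M"))
  params <- raw |>
    dplyr::distinct(.data$nodule_id, .data$malignancy, .data$beta_true,
                    .data$alpha_true, .data$fc_true, .data$category_true)
  cohort <- as_cohort(raw[.cohort_cols], rebase = FALSE)
  attr(cohort, "params") <- params
  attr(cohort, "seed") <- seed
  cohort
}

#' Named test fixtures
#'
#' Small regenerable cohorts used throughout the test-suite and
#' examples:
#' * `tiny` — six nodules: one exactly solved trajectory per growth
#'   category plus one non-increasing series that the inclusion filter
#'   must reject;
#' * `default` — the full 180-nodule cohort of [cohort_spec()];
#' * `degenerate` — edge cases: a near-flat trajectory, an exact
#'   exponential (`beta = 1`) series, and a strongly accelerated series
#'   close to its blow-up time.
#'
#' @param name One of `"tiny"`, `"default"`, `"degenerate"`.
#' @param seed Seed used where the fixture is stochastic.
#' @return A cohort tibble.
#' @export
generate_fixture <- function(name = c("tiny", "default", "degenerate"),
                             seed = 101) {
  name <- match.arg(name)
  times <- c(0, 12, 24)
  mk <- function(id, mal, morph, v0, alpha, beta, hu) {
    tibble::tibble(nodule_id = id, malignancy = mal, morphology = morph,
                   histology = NA_character_, stage = NA_character_,
                   time_months = times,
                   volume_mm3 = vb_solve_forward(v0, alpha, beta, times),
                   attenuation_hu = hu)
  }
  if (name == "default") {
    return(generate_cohort(cohort_spec(), seed = seed))
  }
  if (name == "tiny") {
    out <- dplyr::bind_rows(
      mk("T_decel", "benign", "solid", 100, 25, -0.5, c(-146, -156, -131)),
      mk("T_linear", "malignant", "solid", 100, 10, 0, c(-314, -291, -233)),
      mk("T_subexp", "benign", "solid", 120, 1.2, 0.5, c(-146, -156, -131)),
      mk("T_exp", "malignant", "part_solid", 150, 0.05, 1, c(-314, -291, -233)),
      mk("T_accel", "malignant", "non_solid", 100, 0.00702, 1.4,
         c(-314, -291, -233)),
      tibble::tibble(nodule_id = "T_shrink", malignancy = "benign",
                     morphology = "solid", histology = NA_character_,
                     stage = NA_character_, time_months = times,
                     volume_mm3 = c(100, 95, 120),
                     attenuation_hu = c(-146, -156, -131)))
    return(as_cohort(out, rebase = FALSE))
  }
  out <- dplyr::bind_rows(
    mk("D_flat", "benign", "solid", 100, 1 / 12, 0, c(-146, -156, -131)),
    mk("D_exp", "malignant", "solid", 100, 0.08, 1, c(-314, -291, -233)),
    # blow-up time ~ 26.6 months, last scan at 24
    mk("D_nearblowup", "malignant", "solid", 100, 0.0075, 1.5,
       c(-314, -291, -233)))
  as_cohort(out, rebase = FALSE)
}

#' Serialize a cohort spec to JSON
#'
#' @param spec A `cohort_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  validate_cohort_spec(spec)
  # named atomic vectors serialize as JSON arrays (names dropped);
  # promote them to lists so the category/morphology names survive
  out <- lapply(unclass(spec), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$category_mix_benign <- unlist(raw$category_mix_benign)
  raw$category_mix_malignant <- unlist(raw$category_mix_malignant)
  raw$morphology_mix_benign <- unlist(raw$morphology_mix_benign)
  raw$morphology_mix_malignant <- unlist(raw$morphology_mix_malignant)
  do.call(cohort_spec, raw)
}
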