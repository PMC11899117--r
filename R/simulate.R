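# Synthetic study generator: cohort flow, serology, and raw spot-level
# array data with the statistical structure the analysis pipeline
# assumes, plus a ground-truth ledger for recovery tests.

# Baseline serology targets: median and quartiles (kU/L for IgE, mg/L
# for IgG4). Log-normal parameters are solved from median and IQR.
.SEROLOGY_TARGETS <- data.frame(
  marker = c("total_ige", "milk_sige", "alac_sige", "blg_sige", "casein_sige",
             "alac_sigg4", "blg_sigg4", "casein_sigg4"),
  median = c(14.35, 0.89, 0.35, 0.39, 0.34, 0.08, 0.16, 0.11),
  q1 = c(7.88, 0.35, 0.17, 0.30, 0.13, 0.01, 0.07, 0.05),
  q3 = c(28.03, 2.64, 0.80, 1.26, 0.72, 0.35, 0.82, 0.26),
  stringsAsFactors = FALSE
)

#' Configuration of the synthetic cohort
#'
#' Defaults emulate the study population: 118 enrolled infants, all
#' allergic at baseline; at each follow-up visit a still-allergic
#' attendee converts to tolerance with the visit's conversion
#' probability (40.7%, 35.4%, 22.2%, 22.2%, 7.1% at visits 2–6) after
#' surviving a constant per-visit withdrawal risk. A withdrawal
#' probability of 0.11 gives ≈29 expected losses and end-of-study
#' expectations close to 76 tolerant / 13 allergic / 29 lost of 118.
#' Baseline serology is drawn from log-normals whose median and IQR
#' match the published baseline table; markers listed in `assocRho`
#' are correlated (on the log scale) with the latent
#' tolerance-propensity variable, giving baseline features a modest,
#' configurable association with later tolerance (default: whole-milk
#' sIgE, rho 0.5, higher sIgE ↔ later tolerance).
#'
#' @param nPatients cohort size (default 118).
#' @param toleranceProb per-visit conversion probabilities among
#'   still-allergic attendees, visits 2–6.
#' @param dropoutProb per-visit withdrawal probability among
#'   still-allergic patients (before assessment).
#' @param propensitySd effect of the latent propensity on the
#'   logit conversion probability.
#' @param assocRho named vector of log-scale correlations between
#'   serology markers and (negative) tolerance propensity.
#' @param serology data.frame of marker/median/q1/q3 targets.
#' @return list of class `"CohortConfig"`.
#' @export
cohortConfig <- function(nPatients = 118L,
                         toleranceProb = c(0.407, 0.354, 0.222, 0.222, 0.071),
                         dropoutProb = 0.11,
                         propensitySd = 0.6,
                         assocRho = c(milk_sige = 0.5),
                         serology = .SEROLOGY_TARGETS) {
  stopifnot(length(toleranceProb) == 5L)
  if (any(toleranceProb < 0 | toleranceProb > 1) ||
      dropoutProb < 0 || dropoutProb > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (nPatients < 2L) stop("nPatients must be >= 2")
  if (any(abs(assocRho) > 1)) stop("assocRho must lie in [-1, 1]")
  structure(list(nPatients = as.integer(nPatients),
                 toleranceProb = toleranceProb, dropoutProb = dropoutProb,
                 propensitySd = propensitySd, assocRho = assocRho,
                 serology = serology),
            class = "CohortConfig")
}

#' Configuration of the planted array effects
#'
#' Defaults form the faithful preset: the four persistent epitope
#' regions are planted as informative (αs1-cas 3, αs1-cas 16–18,
#' κ-cas 29–31, β-lac 37–39; ten peptides in all) with recognition
#' probability 0.95 among allergic patients; no group difference at
#' baseline (`baselineEffect = 0`); from visit 2 on, still-allergic
#' patients bind the three configured caseins more intensely
#' (`postShift` Z units) and more diversely (`diversityInflation`
#' chance per peptide of an extra positive); IgG4 signal is a
#' attenuated copy of the IgE generative scale (`igg4Attenuation`).
#' A patient's planted-epitope recognition is drawn once and persists
#' across visits; after tolerance the planted signal fades by
#' `tolerantFade`. The default recognition probability (0.97) keeps
#' the recognition fraction above the 75% informativeness cut-off with
#' high probability even in the smallest group the study design
#' produces (the ~13 patients still allergic at the last visit, a
#' binomial-tail argument). Setting `recognitionSlope` above 0 links
#' recognition to low tolerance propensity (persistent recognition
#' tracking persistent allergy) — off by default because it would leak
#' a small group difference into the baseline visit, which the
#' faithful preset keeps exactly null.
#'
#' The spot-noise defaults (background location 200, scale 50,
#' null peptide Z spread 0.7, replicate log-normal sd 0.2) put the
#' false-positive floor of null peptides at roughly 5% above Z = 3.
#' The floor is dominated not by the latent spread but by the 4-spot
#' PBS scale re-estimation, whose heavy-tailed reciprocal inflates
#' recovered Z-scores array-wide — the same property a real 4-control
#' array layout has.
#'
#' @param planted data.frame of planted peptides (`protein`, `index`)
#'   or character vector of peptide keys.
#' @param plantedPositivity recognition probability of a planted
#'   peptide among allergic patients (population average).
#' @param plantedRange Z-score range of a recognized planted peptide.
#' @param recognitionSlope logit slope linking recognition to the
#'   latent propensity.
#' @param baselineEffect Z shift at visit 1 for patients still allergic
#'   at the 6-month visit (0 in the faithful preset). Applied to the
#'   planted peptides when `baselineEffectOn = "planted"` (so a shift
#'   of about twice the per-feature Z spread plants a d ≈ 2 effect on
#'   ten features), or to the whole library with `"all"`.
#' @param baselineEffectOn which peptides carry the baseline effect.
#' @param postShift Z intensity shift for allergic patients at visits
#'   ≥ 2 on `shiftProteins`.
#' @param diversityInflation extra per-peptide positivity probability
#'   for allergic patients at visits ≥ 2 on `shiftProteins`.
#' @param shiftProteins proteins carrying the group effect.
#' @param igg4Attenuation multiplicative attenuation of IgG4 Z signal.
#' @param tolerantFade multiplicative fade of planted signal after
#'   tolerance.
#' @param bgMean,bgSd background fluorescence location/scale (a.u.).
#' @param nullZsd spread of null peptide signal on the Z scale.
#' @param repNoiseSd log-normal sd of multiplicative replicate noise.
#' @return list of class `"EffectConfig"`.
#' @export
effectConfig <- function(planted = defaultPlantedPeptides(),
                         plantedPositivity = 0.97,
                         plantedRange = c(6, 10),
                         recognitionSlope = 0,
                         baselineEffect = 0,
                         baselineEffectOn = c("planted", "all"),
                         postShift = 1.5,
                         diversityInflation = 0.08,
                         shiftProteins = c("as1-cas", "b-cas", "k-cas"),
                         igg4Attenuation = 0.5,
                         tolerantFade = 0.3,
                         bgMean = 200, bgSd = 50,
                         nullZsd = 0.7, repNoiseSd = 0.2) {
  if (is.character(planted)) planted <- .splitKey(planted)
  if (!is.null(planted) && nrow(planted)) {
    planted$protein <- .normalizeProtein(planted$protein)
    planted$key <- peptideKey(planted$protein, planted$index)
  }
  stopifnot(plantedPositivity >= 0, plantedPositivity <= 1,
            diversityInflation >= 0, diversityInflation <= 1,
            bgSd > 0, nullZsd >= 0)
  baselineEffectOn <- match.arg(baselineEffectOn)
  structure(list(planted = planted, plantedPositivity = plantedPositivity,
                 plantedRange = plantedRange, recognitionSlope = recognitionSlope,
                 baselineEffect = baselineEffect,
                 baselineEffectOn = baselineEffectOn, postShift = postShift,
                 diversityInflation = diversityInflation,
                 shiftProteins = .normalizeProtein(shiftProteins),
                 igg4Attenuation = igg4Attenuation, tolerantFade = tolerantFade,
                 bgMean = bgMean, bgSd = bgSd, nullZsd = nullZsd,
                 repNoiseSd = repNoiseSd),
            class = "EffectConfig")
}

#' The four persistent epitope regions as planted peptides
#'
#' αs1-cas 3, αs1-cas 16–18, κ-cas 29–31 and β-lac 37–39: ten peptides.
#'
#' @return data.frame with columns `protein`, `index`.
#' @export
defaultPlantedPeptides <- function() {
  data.frame(
    protein = c("as1-cas", rep("as1-cas", 3L), rep("k-cas", 3L), rep("b-lac", 3L)),
    index = c(3L, 16:18, 29:31, 37:39),
    stringsAsFactors = FALSE
  )
}

#' Simulate the cohort: visit outcomes and baseline serology
#'
#' Runs the visit-by-visit process: every patient starts allergic at
#' visit 1; before each follow-up visit a still-allergic patient may
#' withdraw (dropout), otherwise converts to tolerance with the
#' visit's probability, modulated by a per-patient latent propensity.
#' Once tolerant a patient leaves follow-up but remains tolerant under
#' accumulative labelling. Serology is drawn from the configured
#' log-normals, with the configured markers correlated to the
#' propensity.
#'
#' @param config a [cohortConfig()].
#' @param seed integer seed (drawn state is fully reproducible).
#' @return list with elements `cohort` (one row per patient:
#'   `patient_id`, serology columns, `first_tolerant_visit`,
#'   `last_visit`), `labels` (long status table from [visitLabels()])
#'   and `truth` (ground-truth ledger: latent propensities and the
#'   config).
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(as.integer(seed))
  n <- config$nPatients
  id <- sprintf("P%03d", seq_len(n))
  u <- stats::rnorm(n)  # latent tolerance propensity (higher = earlier)

  ft <- rep(NA_integer_, n)   # first tolerant visit
  lv <- rep(6L, n)            # last attended visit
  active <- rep(TRUE, n)      # still allergic and attending
  for (v in 2:6) {
    p <- config$toleranceProb[v - 1L]
    drop <- active & stats::runif(n) < config$dropoutProb
    lv[drop] <- v - 1L
    active[drop] <- FALSE
    pv <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-9), 1 - 1e-9)) +
                          config$propensitySd * u)
    tol <- active & stats::runif(n) < pv
    ft[tol] <- v
    lv[tol] <- v
    active[tol] <- FALSE
  }

  sero <- config$serology
  sdlog <- log(sero$q3 / sero$q1) / (2 * stats::qnorm(0.75))
  vals <- lapply(seq_len(nrow(sero)), function(i) {
    rho <- config$assocRho[sero$marker[i]]
    eps <- if (!is.na(rho) && rho != 0) {
      rho * (-u) + sqrt(1 - rho^2) * stats::rnorm(n)
    } else stats::rnorm(n)
    exp(log(sero$median[i]) + sdlog[i] * eps)
  })
  names(vals) <- sero$marker

  cohort <- data.frame(patient_id = id, vals,
                       first_tolerant_visit = ft, last_visit = lv,
                       stringsAsFactors = FALSE)
  list(cohort = cohort, labels = visitLabels(cohort),
       truth = list(propensity = stats::setNames(u, id), config = config,
                    seed = as.integer(seed)))
}

# Z-scale true signal for one patient-visit-isotype, vectorized over
# the library's peptides.
.trueZ <- function(nz, lib_prot, planted_idx, recognized, status, visit,
                   future_allergic, iso, eff) {
  atten <- if (iso == "IgG4") eff$igg4Attenuation else 1
  z <- stats::rnorm(nz, 0, eff$nullZsd) * atten
  if (length(planted_idx)) {
    on <- planted_idx[recognized]
    if (length(on)) {
      zp <- stats::runif(length(on), eff$plantedRange[1L], eff$plantedRange[2L])
      if (status == "tolerant") zp <- zp * eff$tolerantFade
      z[on] <- zp * atten
    }
  }
  if (visit >= 2L && status == "allergic") {
    hit <- lib_prot %in% eff$shiftProteins
    z[hit] <- z[hit] + eff$postShift * atten
    extra <- hit & stats::runif(nz) < eff$diversityInflation
    z[extra] <- pmax(z[extra], stats::runif(sum(extra), 3.5, 6))
  }
  if (visit == 1L && eff$baselineEffect != 0 && future_allergic) {
    sel <- if (identical(eff$baselineEffectOn, "planted") && length(planted_idx)) {
      planted_idx
    } else seq_len(nz)
    z[sel] <- z[sel] + eff$baselineEffect * atten
  }
  z
}

#' Simulate raw spot-level array data
#'
#' Generates, for every attended patient × visit × isotype, a full
#' array in the CSV spot dialect: 4 PBS negative-control spots drawn
#' from the background distribution and two replicate spots per
#' library peptide, with the planted epitopes, group shifts and IgG4
#' attenuation of the [effectConfig()] applied on the latent Z scale
#' before background and replicate noise.
#'
#' @param sim output of [simulateCohort()].
#' @param effects an [effectConfig()].
#' @param library a [PeptideLibrary-class].
#' @param visits visits to generate (default all attended, 1..6).
#' @param isotypes isotypes to generate.
#' @param seed integer seed.
#' @return data.frame of spot records (the CSV dialect columns), with
#'   the ground-truth recognition matrix in `attr(, "truth")`.
#' @export
simulateArrays <- function(sim, effects = effectConfig(), library,
                           visits = 1:6, isotypes = c("IgE", "IgG4"),
                           seed = 1L) {
  stopifnot(inherits(effects, "EffectConfig"))
  set.seed(as.integer(seed))
  keys <- peptideKeys(library)
  lib_prot <- peptides(library)$protein
  planted_idx <- integer(0)
  if (!is.null(effects$planted) && nrow(effects$planted)) {
    planted_idx <- match(effects$planted$key, keys)
    if (anyNA(planted_idx)) {
      stop("planted peptide(s) absent from library: ",
           paste(effects$planted$key[is.na(planted_idx)], collapse = ", "))
    }
  }
  cohort <- sim$cohort
  u <- sim$truth$propensity[cohort$patient_id]

  # persistent per-patient recognition of planted peptides; probability
  # rises as tolerance propensity falls (recognition tracks persistence)
  recog <- matrix(FALSE, nrow(cohort), length(planted_idx))
  if (length(planted_idx)) {
    p0 <- pmin(pmax(effects$plantedPositivity, 1e-9), 1 - 1e-9)
    p_i <- stats::plogis(stats::qlogis(p0) - effects$recognitionSlope * u)
    recog <- matrix(stats::runif(nrow(cohort) * length(planted_idx)),
                    nrow(cohort)) < p_i
  }

  lab <- sim$labels
  future_allergic <- is.na(cohort$first_tolerant_visit) |
    cohort$first_tolerant_visit > 2L

  nz <- length(keys)
  spot_per_array <- 2L * nz + 4L
  feat_col <- c(rep(keys, 2L), rep("PBS", 4L))
  rep_col <- c(rep(1:2, each = nz), 1:4)
  pid_v <- character(0); visit_v <- integer(0); iso_v <- character(0)
  inten_l <- list()
  for (v in sort(unique(as.integer(visits)))) {
    at <- lab[lab$visit == v, , drop = FALSE]
    at <- at[at$patient_id %in% cohort$patient_id[cohort$last_visit >= v], ,
             drop = FALSE]
    for (i in seq_len(nrow(at))) {
      pid <- at$patient_id[i]
      row <- match(pid, cohort$patient_id)
      for (iso in isotypes) {
        z <- .trueZ(nz, lib_prot, planted_idx, recog[row, ], at$status[i],
                    v, future_allergic[row], iso, effects)
        sig <- effects$bgSd * z *
          exp(stats::rnorm(2L * nz, 0, effects$repNoiseSd))
        inten <- pmax(0, stats::rnorm(2L * nz, effects$bgMean, effects$bgSd) + sig)
        pbs <- stats::rnorm(4L, effects$bgMean, effects$bgSd)
        pid_v <- c(pid_v, pid); visit_v <- c(visit_v, v); iso_v <- c(iso_v, iso)
        inten_l[[length(inten_l) + 1L]] <- c(inten, pbs)
      }
    }
  }
  n_arr <- length(pid_v)
  spots <- data.frame(
    patient_id = rep(pid_v, each = spot_per_array),
    visit = rep(visit_v, each = spot_per_array),
    isotype = rep(iso_v, each = spot_per_array),
    feature_id = rep.int(feat_col, n_arr),
    replicate = rep.int(rep_col, n_arr),
    intensity = unlist(inten_l, use.names = FALSE),
    flag = "ok",
    stringsAsFactors = FALSE
  )
  if (length(planted_idx)) {
    dimnames(recog) <- list(cohort$patient_id, keys[planted_idx])
  }
  attr(spots, "truth") <- list(recognition = recog,
                               planted = keys[planted_idx], effects = effects,
                               seed = as.integer(seed))
  spots
}

#' Simulate a complete study end to end
#'
#' Convenience wrapper: cohort, labels, spot records and ground truth
#' in one call, fully determined by `seed`.
#'
#' @param config a [cohortConfig()].
#' @param effects an [effectConfig()].
#' @param library a [PeptideLibrary-class] (built from the bundled
#'   allergens if missing).
#' @param visits visits for which arrays are generated.
#' @param isotypes isotypes generated.
#' @param seed integer master seed.
#' @return list: `cohort`, `labels`, `spots`, `truth`.
#' @export
simulateStudy <- function(config = cohortConfig(), effects = effectConfig(),
                          library = buildLibrary(), visits = 1:6,
                          isotypes = c("IgE", "IgG4"), seed = 1L) {
  sim <- simulateCohort(config, seed = seed)
  spots <- simulateArrays(sim, effects, library, visits = visits,
                          isotypes = isotypes, seed = as.integer(seed) + 1L)
  list(cohort = sim$cohort, labels = sim$labels, spots = spots,
       truth = c(sim$truth, attr(spots, "truth")))
}

#' Feature table with a planted group effect
#'
#' Direct generator of a model-validation feature table: standard
#' normal features for every patient, with the first `nInformative`
#' features shifted by `effectSize` (in standard deviations, i.e.
#' Cohen's d) for the tolerant group. This plants a known, clean
#' signal on the feature scale — unlike the array-level presets, whose
#' measured effect is diluted by the PBS re-estimation noise of each
#' simulated array — and is the preset used to validate that the
#' trainer recovers strong signal (test AUC near 1) and reports the
#' informative features at the top of the importance ranking.
#'
#' @param nPatients number of patients (default 118).
#' @param nFeatures total features (default 586, the size of the real
#'   table: 8 serology + 289 peptides × 2 isotypes).
#' @param nInformative number of features carrying the effect.
#' @param effectSize group mean difference in feature SD units.
#' @param tolerantFraction fraction of tolerant patients.
#' @param seed integer seed.
#' @return feature data.frame (an `outcome` factor plus numeric
#'   features `f1..fN`; informative features are `f1..fk`).
#' @export
plantedFeatureTable <- function(nPatients = 118L, nFeatures = 586L,
                                nInformative = 10L, effectSize = 2,
                                tolerantFraction = 0.45, seed = 1L) {
  set.seed(as.integer(seed))
  n_tol <- round(nPatients * tolerantFraction)
  y <- factor(c(rep("allergic", nPatients - n_tol), rep("tolerant", n_tol)),
              levels = c("allergic", "tolerant"))
  x <- matrix(stats::rnorm(nPatients * nFeatures), nPatients)
  if (nInformative > 0L) {
    x[y == "tolerant", seq_len(nInformative)] <-
      x[y == "tolerant", seq_len(nInformative)] + effectSize
  }
  colnames(x) <- paste0("f", seq_len(nFeatures))
  rownames(x) <- sprintf("P%03d", seq_len(nPatients))
  data.frame(outcome = y, x)
}

#' Write spot records in the CSV dialect
#'
#' @param spots spot records (e.g. from [simulateArrays()]).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeSpotCSV <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
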