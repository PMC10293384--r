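#' Longitudinal cohort design
#'
#' Parameters of the synthetic three-visit cohort generator. The defaults
#' emulate the structure of a multiple-longitudinal Parkinson's resting-state
#' study: 16 healthy controls (baseline only), 17 early-stage drug-naive
#' (de novo) patients and 44 treated patients followed over BL/FU1/FU2 with
#' monotone dropout; patients carry progressive spectral slowing (lower peak
#' frequency, a delta/theta-ward shift of relative power) and clinical scores
#' are noisy linear functions of the true spectral state.
#'
#' @param n_controls,n_de_novo,n_treated Group sizes. Defaults 16/17/44.
#' @param visits Ordered visit labels. Default `c("BL","FU1","FU2")`;
#'   controls are only seen at the first visit.
#' @param slowing_per_visit Decrease of the patients' true peak frequency per
#'   visit, in Hz. Default 0.5.
#' @param band_shift_per_visit Named per-band additive drift of true relative
#'   power per visit for patients; must sum to 0 so powers keep summing to 1.
#' @param baseline_band_power Named true relative band powers of controls at
#'   baseline; must sum to 1.
#' @param patient_band_shift Named additive baseline offset of patients
#'   relative to controls (sums to 0).
#' @param baseline_peak_frequency Control true peak frequency in Hz.
#'   Default 9.5.
#' @param patient_peak_shift Baseline patient offset in Hz. Default -0.5.
#' @param subject_sd Between-subject SDs: `peak` (Hz), `band_power`,
#'   `camcog`, `updrs`, `aecc` (random intercepts).
#' @param measurement_sd Estimation-noise SDs attached to derived measures in
#'   `mode = "measures"`: `peak` (Hz; about one spectral grid step),
#'   `band_power`, `aecc`.
#' @param dropout_probability Per visit-transition probability that a patient
#'   drops out (missing-at-random given group and visit; once dropped, absent
#'   thereafter). Default 0.25.
#' @param clinical_model Coefficients mapping the true spectral state to
#'   clinical scores: for CAMCOG (global cognition, higher = better) and
#'   UPDRS-III (motor impairment, higher = worse), each with `intercept`,
#'   `peak_frequency` slope (points per Hz) and residual `sigma`.
#' @param covariates Distribution parameters for age, sex, ISCED, baseline
#'   disease duration and LEDD.
#' @param couplings List of [coupling_spec()]s planted in `mode = "signals"`.
#' @param signal Signal-level parameters used in `mode = "signals"`:
#'   `sample_rate`, `epoch_length`, `n_epochs`, `one_over_f_exponent`,
#'   `peak_power_ratio`, `peak_width`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_design`.
#' @seealso [simulate_cohort()]
#' @export
cohort_design <- function(n_controls = 16L, n_de_novo = 17L, n_treated = 44L,
                          visits = c("BL", "FU1", "FU2"),
                          slowing_per_visit = 0.5,
                          band_shift_per_visit = c(delta = 0.0125, theta = 0.0125,
                                                   alpha1 = 0, alpha2 = -0.02,
                                                   beta = -0.005),
                          baseline_band_power = c(delta = 0.20, theta = 0.12,
                                                  alpha1 = 0.12, alpha2 = 0.18,
                                                  beta = 0.38),
                          patient_band_shift = c(delta = 0, theta = 0.03,
                                                 alpha1 = 0, alpha2 = -0.03,
                                                 beta = 0),
                          baseline_peak_frequency = 9.5,
                          patient_peak_shift = -0.5,
                          subject_sd = list(peak = 0.5, band_power = 0.01,
                                            camcog = 2, updrs = 3, aecc = 0.01),
                          measurement_sd = list(peak = 0.1, band_power = 0.01,
                                                aecc = 0.01),
                          dropout_probability = 0.25,
                          clinical_model = list(
                            CAMCOG = c(intercept = 60, peak_frequency = 4, sigma = 3),
                            UPDRS_III = c(intercept = 38, peak_frequency = -2.8, sigma = 4)),
                          covariates = list(age_mean = c(HC = 59, de_novo = 60.6,
                                                         treated = 64.1),
                                            age_sd = 7, p_male = 0.55,
                                            duration_de_novo = c(mean = 0.94, sd = 0.42),
                                            duration_treated = c(mean = 7.1, sd = 3),
                                            ledd_treated = c(mean = 500, sd = 200),
                                            ledd_per_visit = 350, ledd_sd = 50),
                          couplings = list(),
                          signal = list(sample_rate = 312.5, epoch_length = 4096L,
                                        n_epochs = 10L, one_over_f_exponent = 1,
                                        peak_power_ratio = 1, peak_width = 0.75),
                          seed = 1L) {
  counts <- c(n_controls, n_de_novo, n_treated)
  if (any(counts < 0)) stop("group counts must be >= 0", call. = FALSE)
  if (length(visits) < 1L) stop("at least one visit is required", call. = FALSE)
  if (dropout_probability < 0 || dropout_probability > 1)
    stop("dropout_probability must lie in [0, 1]", call. = FALSE)
  bands <- names(canonical_bands())
  for (v in list(band_shift_per_visit, baseline_band_power, patient_band_shift))
    if (!setequal(names(v), bands))
      stop("band vectors must name every canonical band", call. = FALSE)
  if (abs(sum(baseline_band_power) - 1) > 1e-8)
    stop("baseline_band_power must sum to 1", call. = FALSE)
  if (abs(sum(band_shift_per_visit)) > 1e-8 || abs(sum(patient_band_shift)) > 1e-8)
    stop("band power shifts must sum to 0 so powers keep summing to 1",
         call. = FALSE)
  structure(list(n_controls = as.integer(n_controls),
                 n_de_novo = as.integer(n_de_novo),
                 n_treated = as.integer(n_treated), visits = visits,
                 slowing_per_visit = slowing_per_visit,
                 band_shift_per_visit = band_shift_per_visit[bands],
                 baseline_band_power = baseline_band_power[bands],
                 patient_band_shift = patient_band_shift[bands],
                 baseline_peak_frequency = baseline_peak_frequency,
                 patient_peak_shift = patient_peak_shift,
                 subject_sd = subject_sd, measurement_sd = measurement_sd,
                 dropout_probability = dropout_probability,
                 clinical_model = clinical_model, covariates = covariates,
                 couplings = couplings, signal = signal,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a longitudinal cohort
#'
#' Generates the cohort table, per subject-visit ground truth, and either
#' derived measure columns (`mode = "measures"`, the default: ground truth
#' plus calibrated estimation noise, suitable for statistical simulations) or
#' full 90-region recordings built from [simulate_roi_signal()] with any
#' planted couplings (`mode = "signals"`). Dropout is monotone (a subject
#' that misses a visit is absent from all later visits) and
#' missing-at-random; controls appear only at the first visit. Everything is
#' reproducible from `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param mode `"measures"` or `"signals"`.
#' @return A list with components:
#' \describe{
#'   \item{cohort}{data frame, one row per subject-visit, columns exactly
#'     `subject, group, visit, age, sex, ISCED, disease_duration, LEDD,
#'     UPDRS_III, CAMCOG` (age/duration are baseline values carried forward).}
#'   \item{truth}{ground truth per subject-visit: true peak frequency and
#'     relative band powers; the clinical model and couplings as attributes.}
#'   \item{measures}{(`mode = "measures"`) derived cortical/subcortical
#'     measure columns per subject-visit.}
#'   \item{recordings}{(`mode = "signals"`) named list of [roi_recording()]s,
#'     one per subject-visit.}
#' }
#' @export
simulate_cohort <- function(design, mode = c("measures", "signals")) {
  stopifnot(inherits(design, "cohort_design"))
  mode <- match.arg(mode)
  if (mode == "signals" && length(design$couplings))
    for (cs in design$couplings)
      stopifnot(inherits(cs, "coupling_spec"))
  set.seed(design$seed)
  bands <- names(canonical_bands())
  groups <- rep(c("HC", "de_novo", "treated"),
                times = c(design$n_controls, design$n_de_novo, design$n_treated))
  n_sub <- length(groups)
  if (n_sub == 0L) stop("empty cohort design", call. = FALSE)
  subj <- sprintf("S%03d", seq_len(n_sub))
  cov <- design$covariates
  age <- round(stats::rnorm(n_sub, cov$age_mean[groups], cov$age_sd), 1)
  sex <- sample(c("M", "F"), n_sub, replace = TRUE,
                prob = c(cov$p_male, 1 - cov$p_male))
  isced <- sample(1:6, n_sub, replace = TRUE,
                  prob = c(0.02, 0.30, 0.20, 0.05, 0.40, 0.03))
  duration <- numeric(n_sub)
  duration[groups == "de_novo"] <-
    pmax(0.1, stats::rnorm(sum(groups == "de_novo"),
                           cov$duration_de_novo["mean"], cov$duration_de_novo["sd"]))
  duration[groups == "treated"] <-
    pmax(0.5, stats::rnorm(sum(groups == "treated"),
                           cov$duration_treated["mean"], cov$duration_treated["sd"]))
  ledd0 <- numeric(n_sub)
  ledd0[groups == "treated"] <-
    pmax(0, stats::rnorm(sum(groups == "treated"),
                         cov$ledd_treated["mean"], cov$ledd_treated["sd"]))
  peak_trait <- stats::rnorm(n_sub, 0, design$subject_sd$peak)
  band_trait <- matrix(stats::rnorm(n_sub * 5L, 0, design$subject_sd$band_power),
                       n_sub, 5L, dimnames = list(NULL, bands))
  band_trait <- band_trait - rowMeans(band_trait) # keep powers summing to 1
  camcog_int <- stats::rnorm(n_sub, 0, design$subject_sd$camcog)
  updrs_int <- stats::rnorm(n_sub, 0, design$subject_sd$updrs)
  aecc_trait <- stats::rnorm(n_sub, 0, design$subject_sd$aecc)

  n_vis <- length(design$visits)
  present <- matrix(FALSE, n_sub, n_vis)
  present[, 1L] <- TRUE
  if (n_vis > 1L) {
    for (v in 2L:n_vis) {
      stay <- stats::runif(n_sub) >= design$dropout_probability
      present[, v] <- present[, v - 1L] & stay & groups != "HC"
    }
  }

  rows <- which(present, arr.ind = TRUE)
  rows <- rows[order(rows[, 1L], rows[, 2L]), , drop = FALSE]
  i <- rows[, 1L]
  vnum <- rows[, 2L] - 1L # 0-based visit index
  patient <- groups[i] != "HC"

  peak_true <- design$baseline_peak_frequency + peak_trait[i] +
    ifelse(patient, design$patient_peak_shift, 0) -
    ifelse(patient, design$slowing_per_visit * vnum, 0)
  peak_true <- pmin(pmax(peak_true, 4.05), 12.95)
  bp_true <- matrix(design$baseline_band_power, nrow = length(i), ncol = 5L,
                    byrow = TRUE, dimnames = list(NULL, bands))
  bp_true <- bp_true + band_trait[i, , drop = FALSE] +
    outer(as.numeric(patient), design$patient_band_shift) +
    outer(as.numeric(patient) * vnum, design$band_shift_per_visit)
  if (any(bp_true < 0.005)) { # guard rail for extreme designs
    bp_true <- pmax(bp_true, 0.005)
    bp_true <- bp_true / rowSums(bp_true)
  }

  cm <- design$clinical_model
  camcog <- cm$CAMCOG["intercept"] + cm$CAMCOG["peak_frequency"] * peak_true +
    camcog_int[i] + stats::rnorm(length(i), 0, cm$CAMCOG["sigma"])
  updrs <- ifelse(patient,
                  cm$UPDRS_III["intercept"] +
                    cm$UPDRS_III["peak_frequency"] * peak_true + updrs_int[i] +
                    stats::rnorm(length(i), 0, cm$UPDRS_III["sigma"]),
                  NA_real_)
  ledd <- ifelse(patient,
                 pmax(0, ledd0[i] + cov$ledd_per_visit * vnum +
                        stats::rnorm(length(i), 0, cov$ledd_sd)),
                 0)
  ledd[groups[i] == "de_novo" & vnum == 0L] <- 0 # drug-naive at baseline

  cohort <- data.frame(subject = subj[i], group = groups[i],
                       visit = design$visits[vnum + 1L], age = age[i],
                       sex = sex[i], ISCED = isced[i],
                       disease_duration = round(duration[i], 2),
                       LEDD = round(ledd), UPDRS_III = round(updrs, 1),
                       CAMCOG = round(camcog, 1), stringsAsFactors = FALSE)

  truth <- data.frame(subject = subj[i], visit = design$visits[vnum + 1L],
                      peak_frequency = peak_true, stringsAsFactors = FALSE)
  truth[paste0("rp_", bands)] <- bp_true
  attr(truth, "clinical_model") <- design$clinical_model
  attr(truth, "couplings") <- design$couplings

  out <- list(cohort = cohort, truth = truth)
  if (mode == "measures") {
    ms <- design$measurement_sd
    measures <- data.frame(subject = truth$subject, visit = truth$visit,
                           stringsAsFactors = FALSE)
    for (loc in c("cortical", "subcortical")) {
      measures[[paste0("peak_frequency_", loc)]] <-
        pmin(pmax(peak_true + stats::rnorm(length(i), 0, ms$peak), 4), 13)
      for (b in bands)
        measures[[paste0("rp_", b, "_", loc)]] <-
          bp_true[, b] + stats::rnorm(length(i), 0, ms$band_power)
      for (b in bands)
        measures[[paste0("aecc_", b, "_", loc)]] <-
          0.5 + aecc_trait[i] + stats::rnorm(length(i), 0, ms$aecc)
    }
    out$measures <- measures
  } else {
    sg <- design$signal
    n_samples <- sg$n_epochs * sg$epoch_length
    dur <- n_samples / sg$sample_rate
    recs <- vector("list", length(i))
    for (k in seq_along(i)) {
      sp <- signal_spec(one_over_f_exponent = sg$one_over_f_exponent,
                        peak_frequency = peak_true[k],
                        peak_power_ratio = sg$peak_power_ratio,
                        peak_width = sg$peak_width,
                        sample_rate = sg$sample_rate, duration = dur)
      sp$band_power_tilts <- band_tilts_for_targets(sp, bp_true[k, ])
      data <- matrix(0, 90L, n_samples)
      for (r in 1:90) data[r, ] <- simulate_roi_signal(sp)
      for (cs in design$couplings) {
        pr <- cs$region_pair
        cp <- plant_envelope_coupling(data[pr[1L], ], data[pr[2L], ], cs,
                                      sg$sample_rate)
        data[pr[1L], ] <- cp$x
        data[pr[2L], ] <- cp$y
      }
      recs[[k]] <- roi_recording(data, sg$sample_rate, subject = subj[i[k]],
                                 visit = design$visits[vnum[k] + 1L])
    }
    names(recs) <- paste(subj[i], design$visits[vnum + 1L], sep = "_")
    out$recordings <- recs
  }
  out
}

#' Merge cohort and measure tables for modelling
#'
#' Joins the clinical cohort table with the derived measure columns by
#' subject and visit, and adds the `recording_system` indicator (CTF for
#' BL/FU1, Elekta for the second follow-up) used as a covariate in the
#' clinical-association models.
#'
#' @param cohort Cohort data frame from [simulate_cohort()].
#' @param measures Measure data frame keyed by `subject`, `visit`.
#' @return Merged data frame, one row per subject-visit.
#' @export
assemble_analysis_table <- function(cohort, measures) {
  out <- merge(cohort, measures, by = c("subject", "visit"), sort = FALSE)
  out$recording_system <- ifelse(out$visit == "FU2", "Elekta", "CTF")
  out[order(out$subject, match(out$visit, c("BL", "FU1", "FU2"))), ]
}

#' Simulate subject-level connectivity matrices
#'
#' Parametric generator of per-subject AEC-c adjacency matrices used for
#' permutation-test calibration and power studies: each off-diagonal entry is
#' the no-coupling value 0.5 plus a subject-level offset and independent
#' edge noise, with optional planted effects added to selected edges. The
#' default noise scales were measured once from this package's signal-level
#' null pipeline (AEC-c of independent white-noise pairs averaged over 10
#' epochs of 4096 samples); use [measure_coupling_aecc()] to translate a
#' generator coupling strength into a planted edge shift.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Matrix dimension. Default 90.
#' @param null_mean No-coupling AEC-c level. Default 0.5.
#' @param edge_sd SD of independent per-edge noise. Default 0.021.
#' @param subject_sd SD of the per-subject global offset. Default 0.01.
#' @param planted Optional data frame with columns `i`, `j`, `delta`: edge
#'   `(i, j)` gets `delta` added for every subject.
#' @param seed Optional integer seed.
#' @return List of `n_subjects` symmetric matrices with NA diagonals.
#' @export
simulate_connectivity_cohort <- function(n_subjects, n_regions = 90L,
                                         null_mean = 0.5, edge_sd = 0.021,
                                         subject_sd = 0.01, planted = NULL,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(matrix(0, n_regions, n_regions))
  n_edges <- sum(ut)
  lapply(seq_len(n_subjects), function(s) {
    m <- matrix(NA_real_, n_regions, n_regions)
    m[ut] <- null_mean + stats::rnorm(1, 0, subject_sd) +
      stats::rnorm(n_edges, 0, edge_sd)
    if (!is.null(planted))
      for (k in seq_len(nrow(planted)))
        m[min(planted$i[k], planted$j[k]), max(planted$i[k], planted$j[k])] <-
          m[min(planted$i[k], planted$j[k]), max(planted$i[k], planted$j[k])] +
          planted$delta[k]
    m[ut] <- pmin(pmax(m[ut], 0), 1)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  })
}
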