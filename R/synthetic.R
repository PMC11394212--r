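#' Synthetic whole-blood BAT cytometry generator
#'
#' Generates event tables with the statistical structure the analysis
#' assumes — a rare basophil population (FcERIa-high, SSC-low, CD32+,
#' CD123+, HLA-DR-negative) among lymphocytes, monocytes, neutrophils,
#' dendritic cells, debris, thrombocytes and doublets — with retained
#' ground-truth labels. Marker intensities are Gaussian on the arcsinh
#' scale (log-normal-like raw values); basophil FcERIa and CD32 share a
#' latent factor (positive correlation), activated (CD63-high) basophils
#' have CD32 shifted down and anticorrelated with CD63, and allergic
#' donors carry a baseline CD32 downshift.
#'
#' @name synthetic_data
NULL

default_pop_params <- function() {
  # per population: fraction; FSC-A linear (mean, sd); all other markers
  # Gaussian on the asinh(x/150) scale (mean, sd)
  list(
    basophil    = list(frac = 0.005, fsc_a = c(90000, 8000),  ssc = c(2.3, 0.25),
                       fcer1a = c(5.0, 0.35), cd32 = c(3.5, 0.35), cd63 = c(0.8, 0.40),
                       cd123 = c(3.5, 0.40), hla_dr = c(0.5, 0.40)),
    lymphocyte  = list(frac = 0.280, fsc_a = c(80000, 9000),  ssc = c(2.5, 0.30),
                       fcer1a = c(0.8, 0.50), cd32 = c(1.2, 0.60), cd63 = c(0.5, 0.40),
                       cd123 = c(0.5, 0.40), hla_dr = c(2.0, 1.00)),
    monocyte    = list(frac = 0.070, fsc_a = c(120000, 10000), ssc = c(3.4, 0.25),
                       fcer1a = c(1.5, 0.45), cd32 = c(4.2, 0.40), cd63 = c(0.6, 0.40),
                       cd123 = c(1.5, 0.40), hla_dr = c(4.0, 0.40)),
    neutrophil  = list(frac = 0.550, fsc_a = c(110000, 10000), ssc = c(4.3, 0.30),
                       fcer1a = c(1.2, 0.50), cd32 = c(3.2, 0.40), cd63 = c(0.5, 0.40),
                       cd123 = c(0.5, 0.40), hla_dr = c(0.8, 0.40)),
    dc          = list(frac = 0.004, fsc_a = c(100000, 9000), ssc = c(2.9, 0.30),
                       fcer1a = c(2.8, 0.40), cd32 = c(2.5, 0.50), cd63 = c(0.6, 0.40),
                       cd123 = c(2.5, 0.50), hla_dr = c(4.5, 0.40)),
    debris      = list(frac = 0.051, fsc_a = c(8000, 3000),   ssc = c(1.0, 0.50),
                       fcer1a = c(0.5, 0.50), cd32 = c(0.5, 0.50), cd63 = c(0.5, 0.50),
                       cd123 = c(0.3, 0.40), hla_dr = c(0.5, 0.40)),
    thrombocyte = list(frac = 0.040, fsc_a = c(15000, 4000),  ssc = c(1.2, 0.40),
                       fcer1a = c(0.8, 0.50), cd32 = c(1.5, 0.50), cd63 = c(0.5, 0.40),
                       cd123 = c(0.3, 0.40), hla_dr = c(0.5, 0.40))
  )
}

#' Synthetic donor profile
#'
#' @param allergic is the donor allergic (baseline CD32 downshift on
#'   basophils)?
#' @param responder does the donor's IgE pathway respond to anti-IgE
#'   stimulation? Non-responders activate at most marginally in the
#'   positive control.
#' @param pop_params population fractions and marker distributions; see
#'   `binbat:::default_pop_params()`. Fractions must sum to 1.
#' @param p_act named activation fractions per condition (fraction of
#'   basophils whose CD63 is drawn from the activated high component).
#'   Defaults: UNSTIM 0 — the ~1% of unstimulated basophils that the
#'   calibration convention counts as CD63+ are resting-tail false
#'   positives, which is what makes the calibrated threshold a
#'   false-positive floor rather than a cut through the activated
#'   component; POS_CTRL 0.4 (responder) / 0.02 (non-responder);
#'   ALLERGEN 0.3 for allergic responders, 0.01 otherwise.
#' @param rho_fcer1a_cd32 basophil FcERIa/CD32 latent correlation
#'   (default 0.6).
#' @param cd63_activated CD63 high-component (mean, sd) on the asinh
#'   scale (default `c(5, 0.4)`; at least 4 scale units above resting).
#' @param cd32_activation_shift CD32 downshift of activated basophils
#'   (default 0.4 transformed units).
#' @param cd32_allergic_shift baseline basophil CD32 downshift of
#'   allergic donors (default 0.3).
#' @param doublet_rate fraction of events synthesized as doublets
#'   (default 0.02).
#' @param fluor_cofactor arcsinh cofactor linking the transformed-scale
#'   parameters to raw intensities (default 150).
#' @param donor_id donor identifier.
#' @return a `synthetic_profile`.
#' @export
synthetic_profile <- function(allergic = FALSE, responder = TRUE,
                              pop_params = default_pop_params(),
                              p_act = NULL,
                              rho_fcer1a_cd32 = 0.6,
                              cd63_activated = c(5.0, 0.4),
                              cd32_activation_shift = 0.4,
                              cd32_allergic_shift = 0.3,
                              doublet_rate = 0.02,
                              fluor_cofactor = 150,
                              donor_id = "D1") {
  fr <- vapply(pop_params, function(p) p$frac, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    stop_binbat("binbat_config_error", "population fractions must sum to 1")
  for (p in pop_params) {
    sds <- vapply(setdiff(names(p), "frac"), function(m) p[[m]][2], numeric(1))
    if (any(sds <= 0)) stop_binbat("binbat_config_error", "marker scales must be > 0")
  }
  defaults <- list(
    UNSTIM = 0,
    POS_CTRL = if (responder) 0.40 else 0.02,
    ALLERGEN = if (allergic && responder) 0.30 else 0.01)
  p_act <- utils::modifyList(defaults, as.list(p_act %||% list()))
  if (any(unlist(p_act) < 0 | unlist(p_act) > 1))
    stop_binbat("binbat_config_error", "activation fractions must lie in [0, 1]")
  if (rho_fcer1a_cd32 < -1 || rho_fcer1a_cd32 > 1)
    stop_binbat("binbat_config_error", "rho_fcer1a_cd32 must lie in [-1, 1]")
  structure(list(
    allergic = allergic, responder = responder, pop_params = pop_params,
    p_act = p_act, rho_fcer1a_cd32 = rho_fcer1a_cd32,
    cd63_activated = cd63_activated,
    cd32_activation_shift = cd32_activation_shift,
    cd32_allergic_shift = cd32_allergic_shift,
    doublet_rate = doublet_rate, fluor_cofactor = fluor_cofactor,
    donor_id = donor_id
  ), class = "synthetic_profile")
}

#' Default channel map for synthetic samples
#' @return a [channel_map] matching the generator's channel names.
#' @export
default_channel_map <- function() {
  channel_map(FSC_A = "FSC-A", FSC_H = "FSC-H", SSC = "SSC-A",
              FCER1A = "FceRIa-A", CD63 = "CD63-A", CD32 = "CD32-A",
              CD123 = "CD123-A", HLA_DR = "HLA-DR-A")
}

#' Generate one synthetic whole-blood sample
#'
#' Draws population labels multinomially, marker values from the
#' profile's per-population distributions, applies the
#' condition-dependent activation model to basophils, and synthesizes
#' doublets by merging random event pairs (FSC-A summed, FSC-H max,
#' fluorescence summed). Raw (untransformed) intensities are returned;
#' the analysis pipeline transforms them.
#'
#' @param profile a [synthetic_profile()].
#' @param condition `"UNSTIM"`, `"POS_CTRL"` or `"ALLERGEN"`.
#' @param n_events total events to generate (>= 1000).
#' @param seed integer seed.
#' @return list with `events` (raw `event_table`) and `truth`
#'   (data.frame `population`, `activated`).
#' @export
generate_sample <- function(profile, condition, n_events, seed) {
  condition <- match.arg(condition, c("UNSTIM", "POS_CTRL", "ALLERGEN"))
  if (n_events < 1000) stop_binbat("binbat_config_error", "n_events must be >= 1000")
  set.seed(as.integer(seed))
  pp <- profile$pop_params
  pops <- names(pp)
  frac <- vapply(pp, function(p) p$frac, numeric(1))
  lab <- sample(pops, n_events, replace = TRUE, prob = frac)
  cf <- profile$fluor_cofactor
  draw <- function(param_name) {
    v <- numeric(n_events)
    for (p in pops) {
      i <- lab == p
      prm <- pp[[p]][[param_name]]
      v[i] <- stats::rnorm(sum(i), prm[1], prm[2])
    }
    v
  }
  ssc_t <- draw("ssc"); fce_t <- draw("fcer1a"); cd32_t <- draw("cd32")
  cd63_t <- draw("cd63"); cd123_t <- draw("cd123"); hla_t <- draw("hla_dr")
  fsc_a <- numeric(n_events)
  for (p in pops) {
    i <- lab == p
    fsc_a[i] <- stats::rnorm(sum(i), pp[[p]]$fsc_a[1], pp[[p]]$fsc_a[2])
  }
  fsc_a <- pmax(fsc_a, 1)
  fsc_h <- pmax(0.82 * fsc_a + stats::rnorm(n_events, 0, 3000), 1)

  # basophils: correlated (FcERIa, CD32) via a shared latent factor,
  # allergic baseline downshift, condition-dependent activation
  ib <- which(lab == "basophil")
  activated <- rep(FALSE, n_events)
  if (length(ib)) {
    nb <- length(ib)
    rho <- profile$rho_fcer1a_cd32
    u <- stats::rnorm(nb); e1 <- stats::rnorm(nb); e2 <- stats::rnorm(nb)
    a <- sqrt(abs(rho)); b <- sqrt(1 - abs(rho))
    z1 <- a * u + b * e1
    z2 <- sign(rho) * a * u + b * e2
    fce_t[ib] <- pp$basophil$fcer1a[1] + pp$basophil$fcer1a[2] * z1
    cd32_t[ib] <- pp$basophil$cd32[1] + pp$basophil$cd32[2] * z2
    if (profile$allergic) cd32_t[ib] <- cd32_t[ib] - profile$cd32_allergic_shift
    p_act <- profile$p_act[[condition]]
    act <- stats::runif(nb) < p_act
    if (any(act)) {
      z63 <- stats::rnorm(sum(act))
      cd63_t[ib[act]] <- profile$cd63_activated[1] + profile$cd63_activated[2] * z63
      # activated cells: CD32 shifted down, anticorrelated with CD63
      cd32_t[ib[act]] <- cd32_t[ib[act]] - profile$cd32_activation_shift - 0.25 * z63
      activated[ib[act]] <- TRUE
    }
  }

  to_raw <- function(v) pmax(sinh(v) * cf, 0)
  mat <- cbind(
    "FSC-A" = fsc_a, "FSC-H" = fsc_h, "SSC-A" = to_raw(ssc_t),
    "FceRIa-A" = to_raw(fce_t), "CD63-A" = to_raw(cd63_t),
    "CD32-A" = to_raw(cd32_t), "CD123-A" = to_raw(cd123_t),
    "HLA-DR-A" = to_raw(hla_t))

  # doublets: merge a random partner into selected rows
  n_dbl <- round(profile$doublet_rate * n_events)
  if (n_dbl > 0) {
    tgt <- sample.int(n_events, n_dbl)
    prt <- sample.int(n_events, n_dbl, replace = TRUE)
    mat[tgt, "FSC-A"] <- mat[tgt, "FSC-A"] + mat[prt, "FSC-A"]
    mat[tgt, "FSC-H"] <- pmax(mat[tgt, "FSC-H"], mat[prt, "FSC-H"])
    for (ch in c("SSC-A", "FceRIa-A", "CD63-A", "CD32-A", "CD123-A", "HLA-DR-A"))
      mat[tgt, ch] <- mat[tgt, ch] + mat[prt, ch]
    lab[tgt] <- "doublet"
    activated[tgt] <- FALSE
  }

  list(
    events = event_table(mat, colnames(mat), transformed = FALSE,
                         meta = list(synthetic = TRUE, condition = condition, seed = seed)),
    truth = data.frame(population = lab, activated = activated,
                       stringsAsFactors = FALSE))
}

#' Generate a full experiment (one donor, several conditions)
#'
#' One sample per condition from a shared donor profile, with per-sample
#' seeds derived deterministically from the master seed (two calls with
#' the same master seed are identical).
#'
#' @param profile a [synthetic_profile()].
#' @param conditions character vector including `"UNSTIM"`.
#' @param n_events events per sample.
#' @param seed master seed.
#' @param allergen_name name attached to ALLERGEN samples.
#' @return list of per-sample lists `events`, `meta` ([sample_meta]),
#'   `truth`.
#' @export
generate_experiment <- function(profile, conditions = c("UNSTIM", "POS_CTRL", "ALLERGEN"),
                                n_events = 50000, seed = 1,
                                allergen_name = "allergen1") {
  if (!"UNSTIM" %in% conditions)
    stop_binbat("binbat_config_error", "conditions must include UNSTIM")
  out <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    s <- generate_sample(profile, cond, n_events, derive_seed(seed, i))
    out[[i]] <- list(
      events = s$events,
      meta = sample_meta(profile$donor_id, cond,
                         allergen_name = if (cond == "ALLERGEN") allergen_name else NULL),
      truth = s$truth)
  }
  out
}

#' Generate a paired cohort of experiments
#'
#' For each experiment, one allergic and one non-allergic donor profile
#' differing by the baseline CD32 shift, measured in the same
#' conditions. Supports the cohort-statistics tests
#' ([classify_experiments()], [wilcoxon_matched_pairs()]).
#'
#' @param n_experiments number of experiments (>= 1).
#' @param base_profile profile template (non-allergic side).
#' @param cd32_allergic_shift CD32 downshift of the allergic donors
#'   (default taken from `base_profile`).
#' @param conditions conditions per donor (default `"UNSTIM"` only).
#' @param n_events events per sample.
#' @param seed master seed.
#' @return list of experiments, each with `experiment_id`,
#'   `non_allergic` and `allergic` (outputs of [generate_experiment()]).
#' @export
generate_cohort <- function(n_experiments, base_profile = synthetic_profile(),
                            cd32_allergic_shift = base_profile$cd32_allergic_shift,
                            conditions = "UNSTIM", n_events = 20000, seed = 1) {
  if (n_experiments < 1) stop_binbat("binbat_config_error", "n_experiments must be >= 1")
  lapply(seq_len(n_experiments), function(e) {
    prof_na <- base_profile
    prof_na$allergic <- FALSE
    prof_na$donor_id <- sprintf("E%03d_NA", e)
    prof_al <- base_profile
    prof_al$allergic <- TRUE
    prof_al$cd32_allergic_shift <- cd32_allergic_shift
    prof_al$donor_id <- sprintf("E%03d_AL", e)
    list(
      experiment_id = sprintf("E%03d", e),
      non_allergic = generate_experiment(prof_na, conditions, n_events,
                                         seed = derive_seed(seed, 2L * e)),
      allergic = generate_experiment(prof_al, conditions, n_events,
                                     seed = derive_seed(seed, 2L * e + 1L)))
  })
}
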