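#' Configuration of the synthetic-claims generator
#'
#' Defines a population of hospitals partitioned into behavior groups that
#' differ in their disease-DRG mix, with a configurable minority of planted
#' deviants: "cautious upcoders" that relabel a fraction `delta` of their
#' borderline non-CC episodes to the paired with-complications (CC) DRG, and
#' "complex-casemix" providers that honestly treat sicker patients. Defaults
#' emulate the structure of a regional three-year heart-failure extract at
#' desk scale: 183 hospitals, 6 behavior groups, ~10 planted deviants,
#' ~40k events.
#'
#' @param n_hospitals Number of providers (default 183).
#' @param n_groups Behavior groups (default 6).
#' @param group_sizes Optional integer vector summing to `n_hospitals`;
#'   default near-equal split.
#' @param n_upcoders,n_complex Planted deviants of each type (defaults 8, 2).
#' @param n_pairs Number of CC/non-CC paired disease DRGs (default 25, so the
#'   feature matrix has 50 mix components plus 8 scalar indexes).
#' @param signature_size Disjoint signature pairs per group (default 4;
#'   requires `signature_size * n_groups <= n_pairs`).
#' @param signature_mass Mix mass a group concentrates on its signature pairs
#'   (default 0.7); the rest is spread uniformly.
#' @param dirichlet_conc Dirichlet concentration of hospital-level mix
#'   variation around the group mix (default 500; together with the episode
#'   volume this puts between-group separation on signature components at
#'   roughly 4 within-group standard deviations).
#' @param cc_base Baseline probability that an episode is coded CC (0.3).
#' @param cc_sd Hospital-level SD of the CC propensity around `cc_base`
#'   (default 0.05): real providers are overdispersed in their coding shares,
#'   and this heterogeneity is what makes the planted relabeling "cautious"
#'   rather than glaring.
#' @param delta Upcoder relabeling probability for non-CC episodes (0.4).
#' @param cc_premium Relative tariff premium of a CC DRG (0.35).
#' @param mean_patients Mean patients per hospital (Poisson, floored at 1).
#' @param hf_extra_rate Poisson rate of disease episodes beyond the first per
#'   patient (0.5).
#' @param other_rate Poisson rate of non-disease hospitalizations per patient
#'   (0.8) — the denominator of the specialization index.
#' @param age_mean,age_sd,age_min Patient age model: Normal, clipped below at
#'   `age_min` (78, 10, 18).
#' @param complex_ci_mult Comorbidity-prevalence multiplier of
#'   complex-casemix providers (3, a tertiary-referral casemix).
#' @param upcoder_ci_mult Same multiplier for upcoders; the default 1 makes
#'   upcoders differ from their group only through the relabeling and its
#'   cost consequence.
#' @param window_start,window_end Observation window
#'   (2013-01-01 .. 2015-12-31).
#' @param private_share Probability a hospital is private (0.4).
#' @param seed Integer seed; the whole draw is reproducible.
#' @return Object of class `sim_config`.
#' @export
simConfig <- function(n_hospitals = 183L, n_groups = 6L, group_sizes = NULL,
                      n_upcoders = 8L, n_complex = 2L,
                      n_pairs = 25L, signature_size = 4L,
                      signature_mass = 0.7, dirichlet_conc = 500,
                      cc_base = 0.3, cc_sd = 0.05, delta = 0.4,
                      cc_premium = 0.35,
                      mean_patients = 100, hf_extra_rate = 0.5,
                      other_rate = 0.8,
                      age_mean = 78, age_sd = 10, age_min = 18,
                      complex_ci_mult = 3, upcoder_ci_mult = 1,
                      window_start = "2013-01-01", window_end = "2015-12-31",
                      private_share = 0.4, seed = 1L) {
  if (n_groups > n_hospitals) stop("more behavior groups than hospitals")
  if (is.null(group_sizes)) {
    group_sizes <- diff(round(seq(0, n_hospitals, length.out = n_groups + 1)))
  }
  if (sum(group_sizes) != n_hospitals) {
    stop("group_sizes must sum to n_hospitals")
  }
  if (n_upcoders + n_complex > n_hospitals) stop("more deviants than hospitals")
  if (signature_size * n_groups > n_pairs) {
    stop("signature pairs must be disjoint: signature_size * n_groups <= n_pairs")
  }
  stopifnot(delta >= 0, delta <= 1, cc_base > 0, cc_base < 1, cc_sd >= 0,
            dirichlet_conc > 0, mean_patients > 0, cc_premium >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_hospitals, "hospitals /", x$n_groups, "groups /",
      x$n_upcoders, "upcoders +", x$n_complex, "complex; delta =", x$delta, "\n")
  invisible(x)
}

pair_drg <- function(j, cc) paste0("D", sprintf("%02d", j), ifelse(cc, "C", ""))

#' Cohort configuration matching the generator's coding system
#'
#' @param config A [simConfig()].
#' @return A [cohortConfig()] whose disease prefix, DRG family and CC subset
#'   match [simulateHdc()] output.
#' @export
simCohortConfig <- function(config) {
  j <- seq_len(config$n_pairs)
  cohortConfig(
    disease_codes = "428",
    drg_family = c(pair_drg(j, FALSE), pair_drg(j, TRUE)),
    cc_drg_codes = pair_drg(j, TRUE),
    window_start = config$window_start, window_end = config$window_end
  )
}

# group-level mean mix over DRG pairs
group_mixes <- function(config) {
  m <- matrix(
    (1 - config$signature_mass) / (config$n_pairs - config$signature_size),
    nrow = config$n_groups, ncol = config$n_pairs
  )
  for (g in seq_len(config$n_groups)) {
    sig <- (g - 1L) * config$signature_size + seq_len(config$signature_size)
    m[g, sig] <- config$signature_mass / config$signature_size
  }
  m
}

rdirichlet_row <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x <- alpha  # pathological underflow guard
  x / sum(x)
}

# condition pool for patient comorbidity draws: baseline prevalences for the
# shipped score's conditions (index disease excluded; its code is the primary
# diagnosis of every disease episode)
condition_pool <- function(weights) {
  prevalence <- c(
    hypertension = 0.50, cardiac_arrhythmia = 0.25,
    chronic_pulmonary_disease = 0.20, complicated_diabetes = 0.15,
    deficiency_anemia = 0.12, fluid_electrolyte_disorders = 0.12,
    renal_failure = 0.10, dementia = 0.08, peripheral_vascular_disorder = 0.08,
    any_tumor = 0.06, liver_disease = 0.05,
    pulmonary_circulation_disorders = 0.05, coagulopathy = 0.04,
    weight_loss = 0.04, alcohol_abuse = 0.04, psychosis = 0.03,
    hemiplegia = 0.03, metastatic_cancer = 0.02, hiv_aids = 0.005
  )
  keep <- intersect(names(prevalence), names(weights$entries))
  list(
    names = keep,
    prevalence = prevalence[keep],
    code = vapply(weights$entries[keep], function(e) e$prefixes[[1L]], ""),
    weight = vapply(weights$entries[keep], function(e) e$weight, integer(1))
  )
}

#' Simulate synthetic hospital discharge charts with ground truth
#'
#' Draws a full HDC table from the model in [simConfig()]: hospitals carry a
#' group-specific Dirichlet-perturbed mix over disease-DRG pairs; patients
#' carry age-dependent chronic conditions; length of stay is lognormal with
#' location increasing in comorbidity; cost combines a pair-specific tariff,
#' the CC premium and a sublinear length-of-stay factor with lognormal noise.
#' Upcoder hospitals relabel each non-CC disease episode to its CC pair with
#' probability `delta`; with `delta = 0` (or default multipliers) they are
#' distributionally identical to their group.
#'
#' @param config A [simConfig()].
#' @param weights A [readWeightTable()]; the generator draws patient
#'   conditions from its entries so that [scoreHdc()] recovers the planted
#'   comorbidity exactly.
#' @return List: `records` (canonical HDC tibble), `truth` (tibble
#'   `hospital_id`, `group`, `deviant_type`, `ownership`), `config`.
#' @export
simulateHdc <- function(config = simConfig(), weights = readWeightTable()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ws <- as.Date(config$window_start); we <- as.Date(config$window_end)
  window_days <- as.integer(we - ws)

  # hospitals ---------------------------------------------------------------
  hid <- sprintf("H%03d", seq_len(config$n_hospitals))
  group <- rep(seq_len(config$n_groups), times = config$group_sizes)
  deviant <- rep("none", config$n_hospitals)
  dev_idx <- sample(config$n_hospitals, config$n_upcoders + config$n_complex)
  deviant[dev_idx[seq_len(config$n_upcoders)]] <- "upcoder"
  if (config$n_complex > 0) {
    deviant[dev_idx[config$n_upcoders + seq_len(config$n_complex)]] <- "complex"
  }
  ownership <- ifelse(stats::runif(config$n_hospitals) < config$private_share,
                      "private", "public")
  m <- group_mixes(config)
  mix <- t(vapply(seq_len(config$n_hospitals), function(h) {
    rdirichlet_row(config$dirichlet_conc * m[group[h], ])
  }, numeric(config$n_pairs)))
  ci_mult <- ifelse(deviant == "complex", config$complex_ci_mult,
                    ifelse(deviant == "upcoder", config$upcoder_ci_mult, 1))
  delta_h <- ifelse(deviant == "upcoder", config$delta, 0)
  # hospital-level CC propensity; linear jitter keeps E[pct_cc] = cc_base
  cc_h <- pmin(0.95, pmax(0.05,
                          stats::rnorm(config$n_hospitals, config$cc_base,
                                       config$cc_sd)))

  # patients ----------------------------------------------------------------
  n_pat <- pmax(1L, stats::rpois(config$n_hospitals, config$mean_patients))
  pat_hosp <- rep.int(seq_len(config$n_hospitals), n_pat)
  n_patients <- length(pat_hosp)
  pat_id <- sprintf("P%06d", seq_len(n_patients))
  age0 <- pmax(config$age_min,
               round(stats::rnorm(n_patients, config$age_mean, config$age_sd)))
  pool <- condition_pool(weights)
  sev <- exp(0.02 * (age0 - config$age_mean)) * ci_mult[pat_hosp]
  has_cond <- matrix(
    stats::runif(n_patients * length(pool$names)) <
      pmin(0.95, outer(sev, pool$prevalence)),
    nrow = n_patients
  )
  cond_codes <- apply(has_cond, 1, function(z) paste(pool$code[z], collapse = ";"))
  ci_chronic <- as.integer(has_cond %*% pool$weight)

  # events ------------------------------------------------------------------
  n_hf <- 1L + stats::rpois(n_patients, config$hf_extra_rate)
  n_oth <- stats::rpois(n_patients, config$other_rate)
  ev_pat <- c(rep.int(seq_len(n_patients), n_hf),
              rep.int(seq_len(n_patients), n_oth))
  is_hf <- rep(c(TRUE, FALSE), c(sum(n_hf), sum(n_oth)))
  n_events <- length(ev_pat)
  ev_hosp <- pat_hosp[ev_pat]

  admission <- ws + sample.int(window_days - 30L, n_events, replace = TRUE)
  age_at <- age0[ev_pat] +
    as.integer(format(admission, "%Y")) - as.integer(format(ws, "%Y"))

  # disease-episode DRG: pair from the hospital mix, CC coin, upcoder relabel
  pair <- integer(n_events)
  hf_idx <- which(is_hf)
  for (h in unique(ev_hosp[hf_idx])) {
    idx <- hf_idx[ev_hosp[hf_idx] == h]
    pair[idx] <- sample.int(config$n_pairs, length(idx), replace = TRUE,
                            prob = mix[h, ])
  }
  cc <- logical(n_events)
  cc[hf_idx] <- stats::runif(length(hf_idx)) < cc_h[ev_hosp[hf_idx]]
  relabel <- is_hf & !cc & stats::runif(n_events) < delta_h[ev_hosp]
  cc <- cc | relabel

  drg <- character(n_events)
  drg[hf_idx] <- pair_drg(pair[hf_idx], cc[hf_idx])
  n_oth_ev <- n_events - length(hf_idx)
  drg[!is_hf] <- paste0("OTH", sample.int(5L, n_oth_ev, replace = TRUE))

  # comorbidity as scoreHdc will see it: chronic conditions on every event,
  # plus the index-disease weight on disease episodes (primary code 4280)
  hf_weight <- weights$entries[["congestive_heart_failure"]]$weight %||% 0L
  ci_event <- ci_chronic[ev_pat] + ifelse(is_hf, hf_weight, 0L)

  los <- round(stats::rlnorm(n_events,
                             meanlog = log(3) + 0.10 * pmax(ci_event, 0) +
                               0.10 * cc,
                             sdlog = 0.45))
  discharge <- admission + los

  tariff <- 2500 + 180 * seq_len(config$n_pairs)
  base_cost <- numeric(n_events)
  base_cost[hf_idx] <- tariff[pair[hf_idx]]
  base_cost[!is_hf] <- 1800 + 150 * as.integer(substring(drg[!is_hf], 4))
  cost <- round(base_cost * (1 + config$cc_premium * cc) *
                  (los_denominator(los) / 4)^0.8 *
                  stats::rlnorm(n_events, 0, 0.12), 2)

  primary <- ifelse(is_hf, "4280",
                    sample(c("486", "5990", "71590", "7802", "78650"),
                           n_events, replace = TRUE))
  dx <- ifelse(nzchar(cond_codes[ev_pat]),
               paste(primary, cond_codes[ev_pat], sep = ";"), primary)

  ord <- order(ev_hosp, ev_pat, admission)
  records <- tibble::tibble(
    event_id = sprintf("E%06d", seq_len(n_events)),
    patient_id = pat_id[ev_pat],
    hospital_id = hid[ev_hosp],
    admission_date = admission,
    discharge_date = discharge,
    age = as.integer(age_at),
    diagnosis_codes = dx,
    procedure_codes = ifelse(is_hf, "8952", ""),
    drg_code = drg,
    cost = cost,
    ownership = ownership[ev_hosp]
  )[ord, ]

  truth <- tibble::tibble(hospital_id = hid, group = group,
                          deviant_type = deviant, ownership = ownership)
  list(records = records, truth = truth, config = config)
}

#' Closed-form expected hospital features under the generator
#'
#' Expectations used as oracles in recovery tests: the CC share of an
#' upcoder is `cc_base + delta * (1 - cc_base)`; the expected mix component
#' of pair j splits the group's pair mass by the CC share; the expected
#' specialization follows from the per-patient episode rates.
#'
#' @param config A [simConfig()].
#' @return List: `pct_cc` (named: honest, upcoder), `specialization`,
#'   `r` (list of matrices `honest` and `upcoder`, groups x DRG codes).
#' @export
expectedProfiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cc_honest <- config$cc_base
  cc_up <- config$cc_base + config$delta * (1 - config$cc_base)
  m <- group_mixes(config)
  j <- seq_len(config$n_pairs)
  r_of <- function(cc_share) {
    r <- cbind(m * (1 - cc_share), m * cc_share)
    colnames(r) <- c(pair_drg(j, FALSE), pair_drg(j, TRUE))
    rownames(r) <- paste0("group", seq_len(config$n_groups))
    r
  }
  list(
    pct_cc = c(honest = cc_honest, upcoder = cc_up),
    specialization = (1 + config$hf_extra_rate) /
      (1 + config$hf_extra_rate + config$other_rate),
    r = list(honest = r_of(cc_honest), upcoder = r_of(cc_up))
  )
}
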