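#' Describe one cell population of a tube
#'
#' A population is one Gaussian component of the per-tube event mixture,
#' in the already-transformed channel space the classifiers consume
#' (forward scatter linear, side scatter and fluorescence on log scale).
#'
#' @param weight Mixture weight in (0, 1].
#' @param mean Numeric 7-vector of channel means, canonical order.
#' @param cov 7x7 symmetric positive-definite covariance, or a 7-vector of
#'   standard deviations (taken as a diagonal covariance).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(weight, mean, cov) {
  stopifnot(length(mean) == 7L, weight > 0, weight <= 1)
  if (is.vector(cov)) {
    stopifnot(length(cov) == 7L, all(cov > 0))
    cov <- diag(cov^2)
  }
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) ||
      inherits(try(chol(cov), silent = TRUE), "try-error")) {
    stop("population covariance must be symmetric positive-definite",
         call. = FALSE)
  }
  structure(list(weight = weight, mean = as.numeric(mean), cov = cov),
            class = "population_spec")
}

# Two baseline leukocyte-like populations shared by both classes, used for
# every tube: a low-side-scatter lymphocyte-like cloud and a granulocyte-
# like cloud with higher scatter and CD45.  Channel units: FS in linear
# scatter units, SS and FL1..FL5 in log10 intensity decades.
.default_base_populations <- function() {
  lymph <- population_spec(
    weight = 0.6,
    mean = c(400, 1.8, 1.4, 1.5, 2.6, 1.5, 1.6),
    cov = c(80, 0.30, 0.40, 0.40, 0.30, 0.45, 0.40))
  gran <- population_spec(
    weight = 0.4,
    mean = c(550, 2.6, 1.9, 2.0, 2.2, 2.0, 2.1),
    cov = c(90, 0.30, 0.50, 0.50, 0.35, 0.50, 0.50))
  lapply(1:7, function(t) list(lymph, gran))
}

# Blast population: the lymphocyte-like population shifted on the marker
# channels where AML blasts separate (CD13-PE/CD16-PC5 in tube 4,
# CD34-PC5/CD38-PC7 in tube 6) and with reduced side scatter.  `shift` is
# in units of the channel standard deviation.
.default_blast_populations <- function(base, shift) {
  shifted_channels <- list(`4` = c(4L, 6L), `6` = c(6L, 7L))
  lapply(1:7, function(t) {
    pop <- base[[t]][[1L]]
    mu <- pop$mean
    sd <- sqrt(diag(pop$cov))
    mu[2L] <- mu[2L] - 1.0 * sd[2L] * (shift / 3)    # hypogranular: lower SS
    ch <- shifted_channels[[as.character(t)]]
    if (!is.null(ch)) {
      mu[ch] <- mu[ch] + shift * sd[ch]
    }
    population_spec(1, mu, pop$cov)
  })
}

#' Specify a synthetic multi-tube cohort
#'
#' Patients are simulated per tube from Gaussian mixtures of cell
#' populations.  Healthy and AML patients share the base populations; AML
#' patients additionally carry a blast population whose per-patient
#' prevalence is drawn from `blast_fraction_range`.  A per-patient random
#' mean shift (one 7-vector added to every population mean of every tube)
#' makes patients within a class non-identically distributed, as real
#' cohorts are.
#'
#' The default event-count range matches the per-tube counts of the
#' DREAM6/FlowCAP2 challenge data (6764 to 49370 events); tests and
#' examples typically scale this down.
#'
#' @param n_aml,n_healthy Patient counts per class (at least one of them
#'   positive).
#' @param events_range Integer interval from which each tube's event count
#'   is drawn uniformly; within `[2, 1e6]`.
#' @param blast_fraction_range Interval in `[0, 1]` for the AML blast
#'   prevalence; `c(0, 0)` disables the blast population.
#' @param blast_shift Blast marker shift in channel standard deviations
#'   (default 3); 0 makes the blast population identical to the base
#'   lymphocyte-like population.
#' @param patient_effect_sd Standard deviation (channel units) of the
#'   per-patient mean shift; 0 disables it.
#' @param base_populations Per tube, a list of `population_spec`s with
#'   weights summing to 1 (shared between classes).
#' @param blast_populations Per tube, a single `population_spec` (its
#'   weight field is ignored; prevalence comes from
#'   `blast_fraction_range`).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_aml, n_healthy,
                        events_range = c(6764L, 49370L),
                        blast_fraction_range = c(0.2, 0.5),
                        blast_shift = 3,
                        patient_effect_sd = 0.1,
                        base_populations = NULL,
                        blast_populations = NULL) {
  if (n_aml < 0 || n_healthy < 0 || n_aml + n_healthy == 0) {
    stop("need at least one patient in the cohort", call. = FALSE)
  }
  events_range <- as.integer(round(events_range))
  if (length(events_range) != 2L || events_range[1] < 2L ||
      events_range[2] > 1e6 || events_range[1] > events_range[2]) {
    stop("events_range must be an integer interval within [2, 1e6]",
         call. = FALSE)
  }
  if (length(blast_fraction_range) != 2L ||
      any(blast_fraction_range < 0) || any(blast_fraction_range > 1) ||
      blast_fraction_range[1] > blast_fraction_range[2]) {
    stop("blast_fraction_range must be an interval within [0, 1]",
         call. = FALSE)
  }
  if (is.null(base_populations)) {
    base_populations <- .default_base_populations()
  }
  stopifnot(length(base_populations) == 7L)
  for (t in 1:7) {
    w <- sum(vapply(base_populations[[t]], `[[`, numeric(1), "weight"))
    if (abs(w - 1) > 1e-8) {
      stop("base population weights of tube ", t, " must sum to 1",
           call. = FALSE)
    }
  }
  if (is.null(blast_populations)) {
    blast_populations <- .default_blast_populations(base_populations,
                                                    blast_shift)
  }
  stopifnot(length(blast_populations) == 7L)
  structure(
    list(n_aml = as.integer(n_aml), n_healthy = as.integer(n_healthy),
         events_range = events_range,
         blast_fraction_range = blast_fraction_range,
         blast_shift = blast_shift,
         patient_effect_sd = patient_effect_sd,
         base_populations = base_populations,
         blast_populations = blast_populations),
    class = "cohort_spec")
}

#' Challenge-sized cohort preset
#'
#' The class sizes (43 AML-positive, 316 healthy) and per-tube event-count
#' range (6764-49370) of the DREAM6/FlowCAP2 AML cohort.
#'
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_spec_challenge <- function(...) {
  cohort_spec(n_aml = 43L, n_healthy = 316L, ...)
}

# Sample one tube: mixture of populations with given weights.
.simulate_tube <- function(pops, weights, n_events, patient_shift) {
  counts <- as.vector(stats::rmultinom(1L, n_events, weights))
  out <- matrix(0, nrow = n_events, ncol = 7L)
  at <- 1L
  for (k in seq_along(pops)) {
    if (counts[k] == 0L) next
    mu <- pops[[k]]$mean + patient_shift
    draw <- MASS::mvrnorm(counts[k], mu = mu, Sigma = pops[[k]]$cov)
    out[at:(at + counts[k] - 1L), ] <- draw
    at <- at + counts[k]
  }
  event_matrix(out[sample.int(n_events), , drop = FALSE])
}

#' Simulate a single patient
#'
#' Draws from the current RNG stream; wrap in `set.seed()` (or use
#' [simulate_cohort()]) for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param label 1 for AML, 0 for healthy.
#' @param patient_id Identifier for the sample.
#' @return A [patient_sample()] with 7 tubes.
#' @export
simulate_patient <- function(spec, label, patient_id = "sim") {
  stopifnot(inherits(spec, "cohort_spec"), label %in% c(0, 1))
  shift <- if (spec$patient_effect_sd > 0) {
    stats::rnorm(7L, 0, spec$patient_effect_sd)
  } else {
    numeric(7L)
  }
  blast_w <- if (label == 1) {
    stats::runif(1L, spec$blast_fraction_range[1],
                 spec$blast_fraction_range[2])
  } else {
    0
  }
  tubes <- lapply(1:7, function(t) {
    base <- spec$base_populations[[t]]
    w <- vapply(base, `[[`, numeric(1), "weight")
    pops <- base
    if (blast_w > 0) {
      pops <- c(list(spec$blast_populations[[t]]), base)
      w <- c(blast_w, w * (1 - blast_w))
    }
    n_ev <- spec$events_range[1] +
      sample.int(spec$events_range[2] - spec$events_range[1] + 1L, 1L) - 1L
    .simulate_tube(pops, w, n_ev, shift)
  })
  names(tubes) <- as.character(1:7)
  patient_sample(patient_id, label, tubes)
}

#' Simulate a cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; all randomness of the cohort flows from it.
#' @param dir Optional directory: if given, per-tube CSVs and a manifest
#'   are written there via [write_cohort()].
#' @return An `aml_cohort` with `spec$n_aml + spec$n_healthy` patients;
#'   AML patients come first (ids `aml_001`, ..., `healthy_001`, ...).
#' @export
simulate_cohort <- function(spec, seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  patients <- vector("list", spec$n_aml + spec$n_healthy)
  for (i in seq_len(spec$n_aml)) {
    patients[[i]] <- simulate_patient(spec, 1,
                                      sprintf("aml_%03d", i))
  }
  for (i in seq_len(spec$n_healthy)) {
    patients[[spec$n_aml + i]] <- simulate_patient(spec, 0,
                                                   sprintf("healthy_%03d", i))
  }
  cohort <- as_cohort(patients)
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
  }
  cohort
}
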