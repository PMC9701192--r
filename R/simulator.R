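# Synthetic-experiment generator. Emulates the statistical structure of
# SMR-style single-cell mass data: a right-skewed (lognormal) baseline mass
# distribution, contamination by permeable cells, aggregates and debris,
# mechanism-of-action drug effects, responding-fraction mixtures, and slow
# time-linear phenotypic drift over a measurement session.

#' Specification of a synthetic cell population
#'
#' The baseline single-cell buoyant mass is lognormal with a given mean and
#' coefficient of variation (defaults 60 pg, CV 0.35 — calibrated so that
#' the 500- and 2500-cell baseline-noise levels of the mass-response signal
#' match typical measured populations). Contaminating particle classes are
#' drawn from `class_weights`: permeable cells are intact draws scaled by
#' `permeable_mass_factor`, aggregates are sums of 2-3 intact draws, and
#' debris follows its own light lognormal. An additive Gaussian measurement
#' noise term (default SD 0.5 pg, the sensor's mass precision) is applied to
#' every particle, floored at a small positive mass.
#'
#' @param mean_mass baseline mean intact-cell mass in pg (default 60).
#' @param cv baseline coefficient of variation (default 0.35).
#' @param class_weights named fractions over
#'   `c(intact, permeable, aggregate, debris)` summing to 1.
#' @param permeable_mass_factor mass retained by permeable cells relative to
#'   intact (default 0.5).
#' @param aggregate_multiplicity integer vector of cells per aggregate
#'   (default `2:3`, drawn uniformly).
#' @param debris_mean,debris_cv debris mass distribution (defaults 8 pg,
#'   CV 0.8).
#' @param noise_sd additive measurement-noise SD in pg (default 0.5; set 0
#'   to disable).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(mean_mass = 60, cv = 0.35,
                            class_weights = c(intact = 1, permeable = 0,
                                              aggregate = 0, debris = 0),
                            permeable_mass_factor = 0.5,
                            aggregate_multiplicity = 2:3,
                            debris_mean = 8, debris_cv = 0.8,
                            noise_sd = 0.5) {
  w <- rep(0, 4); names(w) <- c("intact", "permeable", "aggregate", "debris")
  if (is.null(names(class_weights)) && length(class_weights) == 4)
    names(class_weights) <- names(w)
  bad <- setdiff(names(class_weights), names(w))
  if (length(bad) > 0) stop("unknown class weight(s): ", paste(bad, collapse = ", "))
  w[names(class_weights)] <- class_weights
  if (abs(sum(w) - 1) > 1e-8) stop("class weights must sum to 1")
  if (any(w < 0)) stop("class weights must be non-negative")
  stopifnot(mean_mass > 0, cv > 0, permeable_mass_factor > 0,
            all(aggregate_multiplicity >= 2), debris_mean > 0, debris_cv > 0,
            noise_sd >= 0)
  structure(list(mean_mass = mean_mass, cv = cv, class_weights = w,
                 permeable_mass_factor = permeable_mass_factor,
                 aggregate_multiplicity = as.integer(aggregate_multiplicity),
                 debris_mean = debris_mean, debris_cv = debris_cv,
                 noise_sd = noise_sd),
            class = "simulation_spec")
}

# lognormal parameterized by arithmetic mean and CV
.lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# draw n baseline (intact) masses, with measurement noise
.draw_baseline <- function(spec, n) {
  p <- .lnorm_pars(spec$mean_mass, spec$cv)
  m <- rlnorm(n, p["meanlog"], p["sdlog"])
  if (spec$noise_sd > 0) m <- m + stats::rnorm(n, 0, spec$noise_sd)
  pmax(m, 0.05)
}

#' Simulate a particle population
#'
#' Draws `n` particles with true class labels from the spec's class weights
#' and class-specific mass distributions. Under the defaults the class mean
#' masses are ordered aggregate > intact > permeable > debris, the ordering
#' seen in image-classified measurements.
#'
#' @param spec a [simulation_spec()].
#' @param n number of particles.
#' @param seed integer seed.
#' @param condition_id,role,t_meas,instrument_id metadata stamped onto each
#'   record.
#' @return A validated record `data.frame` (see [mass_records()]).
#' @export
simulate_population <- function(spec = simulation_spec(), n, seed = NULL,
                                condition_id = "sim", role = "test",
                                t_meas = 0, instrument_id = "SIM-01") {
  stopifnot(inherits(spec, "simulation_spec"), n >= 1)
  with_seed(seed, {
    classes <- sample(names(spec$class_weights), n, replace = TRUE,
                      prob = spec$class_weights)
    mass <- numeric(n)

    is_int <- classes == "intact"
    mass[is_int] <- .draw_baseline(spec, sum(is_int))

    is_perm <- classes == "permeable"
    mass[is_perm] <- .draw_baseline(spec, sum(is_perm)) *
      spec$permeable_mass_factor

    is_agg <- classes == "aggregate"
    n_agg <- sum(is_agg)
    if (n_agg > 0) {
      k <- if (length(spec$aggregate_multiplicity) == 1)
        rep(spec$aggregate_multiplicity, n_agg)
      else sample(spec$aggregate_multiplicity, n_agg, replace = TRUE)
      draws <- .draw_baseline(spec, sum(k))
      mass[is_agg] <- as.numeric(
        rowsum(draws, rep.int(seq_len(n_agg), k)))
    }

    is_deb <- classes == "debris"
    if (any(is_deb)) {
      p <- .lnorm_pars(spec$debris_mean, spec$debris_cv)
      d <- rlnorm(sum(is_deb), p["meanlog"], p["sdlog"])
      if (spec$noise_sd > 0) d <- d + stats::rnorm(sum(is_deb), 0, spec$noise_sd)
      mass[is_deb] <- pmax(d, 0.05)
    }

    mass_records(mass, classes, condition_id, role, t_meas, instrument_id)
  })
}

#' Mechanism-of-action effect on a cell population
#'
#' Parameterizes the characteristic mass-distribution signatures of the
#' three broad drug-response categories: cell-cycle arrest (the distribution
#' consolidates around the newborn-cell mass for G1 arrest, or around the
#' pre-division mass for G2 arrest: a mean rescale plus CV shrink),
#' metabolic disruption (a catabolic or anabolic pure mean skew), and loss
#' of structural integrity (an affected fraction of cells shifts to a
#' minimally overlapping low-mass permeable mode). `uniform_shift` rescales
#' every mass by `1 + shift` and is the calibration effect whose mass
#' response equals `|shift|` exactly.
#'
#' @param kind one of `"g1_arrest"`, `"g2_arrest"`, `"catabolic"`,
#'   `"anabolic"`, `"membrane_loss"`, `"uniform_shift"`.
#' @param scale mean mass scale factor; defaults per kind: 0.75 (g1), 1.4
#'   (g2), 0.90 (catabolic), 1.10 (anabolic), 0.35 (membrane-loss secondary
#'   mode).
#' @param spread CV shrink factor for arrest kinds (default 0.6).
#' @param fraction affected fraction for `membrane_loss` (default 0.4).
#' @param shift relative shift for `uniform_shift` (default 0.10).
#' @return An object of class `moa_effect`.
#' @export
moa_effect <- function(kind = c("g1_arrest", "g2_arrest", "catabolic",
                                "anabolic", "membrane_loss", "uniform_shift"),
                       scale = NULL, spread = NULL, fraction = NULL,
                       shift = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    g1_arrest = list(scale = 0.75, spread = 0.6),
    g2_arrest = list(scale = 1.4, spread = 0.6),
    catabolic = list(scale = 0.90),
    anabolic = list(scale = 1.10),
    membrane_loss = list(scale = 0.35, fraction = 0.4),
    uniform_shift = list(shift = 0.10))
  eff <- list(kind = kind,
              scale = scale %||% defaults$scale,
              spread = spread %||% defaults$spread,
              fraction = fraction %||% defaults$fraction,
              shift = shift %||% defaults$shift)
  if (!is.null(eff$scale) && eff$scale <= 0) stop("scale must be positive")
  if (!is.null(eff$spread) && eff$spread <= 0) stop("spread must be positive")
  if (!is.null(eff$fraction) &&
      (eff$fraction < 0 || eff$fraction > 1))
    stop("fraction must lie in [0, 1]")
  structure(eff, class = "moa_effect")
}

#' Apply a mechanism-of-action effect to cell records
#'
#' Transforms the masses (and for membrane loss, the class labels) of a
#' record table in place. Arrest effects rescale the distribution in log
#' space so the mean multiplies by `scale` and the CV by `spread`; metabolic
#' skews multiply every mass by `scale`; membrane loss relabels a random
#' `fraction` of cells as permeable at `scale` times their mass;
#' `uniform_shift` multiplies all masses by `1 + shift`.
#'
#' @param records record `data.frame` of cells (effects act on cells, not
#'   debris; typically the output of [simulate_population()] with intact
#'   cells).
#' @param effect a [moa_effect()].
#' @param seed integer seed (used by `membrane_loss`).
#' @return The transformed record `data.frame`.
#' @export
apply_moa <- function(records, effect, seed = NULL) {
  stopifnot(is.data.frame(records), inherits(effect, "moa_effect"))
  m <- records$mass_pg
  out <- records
  if (effect$kind %in% c("g1_arrest", "g2_arrest")) {
    lm <- log(m)
    mu <- mean(lm); s2 <- var(lm)
    if (s2 <= 0) {
      out$mass_pg <- m * effect$scale
    } else {
      # target log-variance so that CV multiplies by `spread`
      s2_new <- log(1 + effect$spread^2 * (exp(s2) - 1))
      mu_new <- mu + log(effect$scale) + (s2 - s2_new) / 2
      out$mass_pg <- exp(mu_new + (lm - mu) * sqrt(s2_new / s2))
    }
  } else if (effect$kind %in% c("catabolic", "anabolic")) {
    out$mass_pg <- m * effect$scale
  } else if (effect$kind == "membrane_loss") {
    out <- with_seed(seed, {
      hit <- runif(nrow(records)) < effect$fraction
      records$mass_pg[hit] <- records$mass_pg[hit] * effect$scale
      records$particle_class[hit] <- "permeable"
      records
    })
  } else { # uniform_shift
    out$mass_pg <- m * (1 + effect$shift)
  }
  out
}

#' Mix populations at defined fractions
#'
#' Draws the stated proportions from each population to emulate a specimen
#' in which only a fraction of cells responds to treatment.
#'
#' @param pops list of record `data.frame`s.
#' @param fractions numeric fractions summing to 1, one per population.
#' @param n total number of records to draw (default: combined size of the
#'   inputs). Draws are without replacement when a population is large
#'   enough, otherwise with replacement.
#' @param seed integer seed.
#' @return A record `data.frame` of `n` rows.
#' @export
mix_populations <- function(pops, fractions, n = NULL, seed = NULL) {
  stopifnot(is.list(pops), length(pops) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (is.null(n)) n <- sum(vapply(pops, nrow, integer(1)))
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) { # assign the remainder to the largest fractional parts
    frac_part <- fractions * n - counts
    counts[order(frac_part, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac_part, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    parts <- Map(function(pop, k) {
      if (k == 0) return(pop[0, , drop = FALSE])
      pop[sample.int(nrow(pop), k, replace = k > nrow(pop)), , drop = FALSE]
    }, pops, counts)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full reference/test/control experiment
#'
#' Generates one measurement session with the standard structure: the
#' vehicle-treated reference is measured at t = 0, the test conditions at
#' evenly staggered times, and the vehicle-treated control replicate at the
#' session end. All conditions share the baseline spec; each test condition
#' optionally receives a mechanism-of-action effect (vehicle conditions
#' never do). Phenotypic drift is applied multiplicatively and linearly in
#' time as `mass * (1 - drift_rate * t_hours)`.
#'
#' @param spec a [simulation_spec()].
#' @param effects named list, one entry per test condition: a [moa_effect()]
#'   or `NULL` for a no-effect condition. Names become condition ids.
#' @param drift_rate fractional mass loss per hour (default 0).
#' @param n_per_condition cells measured per condition (default 2500).
#' @param session_h session duration in hours; the control is measured at
#'   this time (default 3).
#' @param seed integer master seed.
#' @param instrument_id instrument label.
#' @return A record `data.frame` for the whole session, in the standard
#'   measurement-table format so the full pipeline runs on it unchanged
#'   (group with [build_experiment()] or feed to [run_pipeline()]).
#' @export
simulate_experiment <- function(spec = simulation_spec(), effects,
                                drift_rate = 0, n_per_condition = 2500,
                                session_h = 3, seed = NULL,
                                instrument_id = "SIM-01") {
  stopifnot(inherits(spec, "simulation_spec"))
  if (length(effects) < 1) stop("at least one test condition is required")
  if (is.null(names(effects)) || any(names(effects) == ""))
    stop("effects must be a named list (names are condition ids)")
  k <- length(effects)
  test_t <- session_h * seq_len(k) / (k + 1)
  seeds <- spawn_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1),
                       2L * k + 2L)

  drift <- function(rec, t_h) {
    f <- 1 - drift_rate * t_h
    if (f <= 0) stop("drift rate produces non-positive masses at t = ",
                     t_h, " h")
    rec$mass_pg <- rec$mass_pg * f
    rec
  }

  ref <- simulate_population(spec, n_per_condition, seeds[1],
                             condition_id = "REFERENCE", role = "reference",
                             t_meas = 0, instrument_id = instrument_id)
  ctl <- drift(simulate_population(spec, n_per_condition, seeds[2],
                                   condition_id = "CONTROL", role = "control",
                                   t_meas = session_h * 3600,
                                   instrument_id = instrument_id),
               session_h)

  tests <- lapply(seq_len(k), function(i) {
    rec <- simulate_population(spec, n_per_condition, seeds[2 + i],
                               condition_id = names(effects)[i],
                               role = "test", t_meas = test_t[i] * 3600,
                               instrument_id = instrument_id)
    if (!is.null(effects[[i]]))
      rec <- apply_moa(rec, effects[[i]], seed = seeds[2 + k + i])
    drift(rec, test_t[i])
  })

  out <- do.call(rbind, c(list(ref), tests, list(ctl)))
  rownames(out) <- NULL
  out
}

#' Baseline-noise scan over cell counts
#'
#' For each sample size `n`, draws `reps` independent pairs of `n`-cell
#' samples from the baseline population and records the mean and standard
#' deviation of the pairwise mass response: the noise floor of the signal as
#' a function of how many cells are measured. The mean decreases roughly as
#' \eqn{n^{-1/2}}.
#'
#' @param spec a [simulation_spec()] (its intact baseline is sampled).
#' @param n_values sample sizes to scan.
#' @param reps pairs per sample size (default 1000).
#' @param seed integer seed.
#' @return A `data.frame` with columns `n`, `mean_response`, `sd_response`,
#'   `reps` (responses as fractions).
#' @export
noise_vs_n_scan <- function(spec = simulation_spec(),
                            n_values = c(500, 2500), reps = 1000,
                            seed = NULL) {
  stopifnot(reps >= 2)
  with_seed(seed, {
    rows <- lapply(n_values, function(n) {
      vals <- vapply(seq_len(reps), function(i) {
        .mr_sorted(sort(.draw_baseline(spec, n)),
                   sort(.draw_baseline(spec, n)))
      }, numeric(1))
      data.frame(n = n, mean_response = mean(vals), sd_response = sd(vals),
                 reps = reps)
    })
    do.call(rbind, rows)
  })
}
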