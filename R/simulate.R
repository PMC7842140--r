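#' Specification of one strain arm of a virtual cohort
#'
#' @param strain Strain label.
#' @param params Generating \code{\link{dvr_params}} for the strain.
#' @param doses Irradiation dose levels in Gy (excluding the sham 0 Gy arm).
#' @param n_per_dose Animals per irradiated dose group.
#' @param n_control Sham-irradiated (0 Gy) control animals.
#' @return A list of class \code{dvr_strain_spec}.
#' @export
strain_spec <- function(strain, params, doses, n_per_dose = 3L,
                        n_control = 1L) {
  validate_params(params)
  stopifnot(length(doses) >= 1L, all(doses > 0), n_per_dose >= 1L,
            n_control >= 0L)
  structure(list(strain = strain, params = params, doses = sort(doses),
                 n_per_dose = as.integer(n_per_dose),
                 n_control = as.integer(n_control)),
            class = "dvr_strain_spec")
}

#' Virtual-cohort simulation configuration
#'
#' Defaults reproduce the layout of the two-strain proton-irradiation MRI
#' follow-up study the model was built for: a radiosensitive strain
#' (C3H/He) irradiated at 40/60/80 Gy and a radioresistant strain (C57BL/6)
#' at 45/65/85 Gy, three animals per dose group plus one sham-irradiated
#' control per strain (10 mice per strain, 20 in total); a pre-irradiation
#' scan at week -1, biweekly scans starting in week 1 or 2, scan interval
#' widened to 5 weeks after 3 months, follow-up capped at 26 weeks.
#'
#' @param strains List of \code{\link{strain_spec}} objects.
#' @param first_scan_weeks Choice set for the first post-irradiation scan
#'   week; drawn per animal.
#' @param biweekly_interval Early scan interval (weeks).
#' @param late_interval Scan interval after \code{late_start} (weeks).
#' @param late_start Week from which the late interval applies.
#' @param max_followup Follow-up horizon (weeks); censoring time.
#' @param sigma_log10 SD of multiplicative lognormal measurement noise on
#'   the log10 volume scale (dimensionless).
#' @param detection_threshold Minimum CE volume (ul) registered as onset.
#' @param sacrifice_threshold CE volume (ul) at which an animal is removed
#'   for health deterioration (simplified surrogate for the study's
#'   composite health score).
#' @param brain_volume_cap Physical upper bound on lesion volume (ul);
#'   simulated volumes are clipped here with a warning.
#' @param seed Integer seed; cohorts are deterministic given the seed.
#' @return A list of class \code{dvr_sim_config}.
#' @examples
#' cfg <- sim_config(seed = 1)
#' @export
sim_config <- function(strains = default_strains(),
                       first_scan_weeks = c(1, 2),
                       biweekly_interval = 2,
                       late_interval = 5,
                       late_start = 13,
                       max_followup = 26,
                       sigma_log10 = 0.1,
                       detection_threshold = 1,
                       sacrifice_threshold = 60,
                       brain_volume_cap = 491,
                       seed = 1L) {
  stopifnot(max_followup > late_start, late_start > 0,
            biweekly_interval > 0, late_interval > 0,
            detection_threshold > 0,
            sacrifice_threshold > detection_threshold,
            sigma_log10 >= 0, brain_volume_cap > 0,
            all(first_scan_weeks > 0))
  if (!is.list(strains) || !all(vapply(strains, inherits, TRUE,
                                       "dvr_strain_spec")))
    stop("strains must be a list of strain_spec objects", call. = FALSE)
  structure(list(strains = strains,
                 first_scan_weeks = first_scan_weeks,
                 biweekly_interval = biweekly_interval,
                 late_interval = late_interval,
                 late_start = late_start,
                 max_followup = max_followup,
                 sigma_log10 = sigma_log10,
                 detection_threshold = detection_threshold,
                 sacrifice_threshold = sacrifice_threshold,
                 brain_volume_cap = brain_volume_cap,
                 seed = as.integer(seed)),
            class = "dvr_sim_config")
}

#' @rdname sim_config
#' @export
default_strains <- function() {
  list(
    strain_spec("C3H/He", reference_params("C3H/He"), c(40, 60, 80)),
    strain_spec("C57BL/6", reference_params("C57BL/6"), c(45, 65, 85))
  )
}

#' MRI scan schedule for one animal
#'
#' Builds the ordered scan-week list: a pre-irradiation scan at week -1,
#' then biweekly scans from a first scan week drawn from
#' \code{first_scan_weeks}, switching to the late interval once the schedule
#' reaches \code{late_start}, with a terminal scan at the follow-up horizon.
#'
#' @param config A \code{\link{sim_config}}.
#' @param first_week Optional fixed first scan week (otherwise drawn from
#'   the configured choice set using the current RNG state).
#' @return Numeric vector of scan weeks, starting at -1.
#' @examples
#' build_schedule(sim_config(), first_week = 1)
#' @export
build_schedule <- function(config, first_week = NULL) {
  stopifnot(inherits(config, "dvr_sim_config"))
  if (is.null(first_week))
    first_week <- config$first_scan_weeks[
      sample.int(length(config$first_scan_weeks), 1L)]
  weeks <- -1
  t <- first_week
  while (t <= config$max_followup) {
    weeks <- c(weeks, t)
    step <- if (t >= config$late_start) config$late_interval
            else config$biweekly_interval
    t <- t + step
  }
  if (max(weeks) < config$max_followup)
    weeks <- c(weeks, config$max_followup)
  weeks
}

# Stable per-mouse sub-seed so adding or removing animals from a config
# never reshuffles the trajectories of existing ones.
mouse_seed <- function(seed, mouse_id) {
  h <- 0
  for (k in utf8ToInt(mouse_id)) h <- (h * 131 + k) %% 2147483629
  as.integer((h + as.numeric(seed) * 7919) %% 2147483629)
}

#' Simulate one animal's lesion trajectory
#'
#' Draws a scan schedule, places the latent lesion onset at
#' \code{\link{onset_time}} (no lesion ever for sham animals or doses at or
#' below D0), and generates CE volumes from the growth law with
#' multiplicative lognormal noise at every scan at or after onset. The
#' observed onset is the first scan whose volume reaches the detection
#' threshold. The animal is sacrificed (event = 1) at the first scan whose
#' volume reaches the sacrifice threshold -- that scan is retained as the
#' terminal diagnostic measurement -- and otherwise censored at the
#' follow-up horizon (event = 0).
#'
#' @param dose Dose in Gy (0 for sham controls).
#' @param params Generating \code{\link{dvr_params}}.
#' @param config A \code{\link{sim_config}}.
#' @param mouse_id Animal identifier.
#' @param strain Strain label (defaults to the params label).
#' @return A list of class \code{dvr_mouse}: \code{mouse_id}, \code{strain},
#'   \code{dose}, \code{scan_weeks}, \code{volumes} (ul, 0 = no CE),
#'   \code{observed_onset} (NA if never detected), \code{last_week},
#'   \code{event}.
#' @export
simulate_mouse <- function(dose, params, config, mouse_id = "m1",
                           strain = params$strain) {
  validate_params(params)
  stopifnot(inherits(config, "dvr_sim_config"), dose >= 0)
  weeks <- build_schedule(config)
  latent_onset <- if (dose <= max(params$D0, 0) || dose == 0) Inf
                  else onset_time(dose, params)
  vols <- numeric(length(weeks))
  post <- weeks >= 0 & weeks >= latent_onset
  if (any(post)) {
    mu <- predict_volume(dose, weeks[post], params, warn_pre_onset = FALSE)
    eps <- stats::rnorm(sum(post), 0, config$sigma_log10)
    vols[post] <- mu * 10^eps
  }
  det <- which(vols >= config$detection_threshold)
  observed_onset <- if (length(det)) weeks[det[1]] else NA_real_
  sac <- which(vols >= config$sacrifice_threshold)
  if (length(sac)) {
    keep <- seq_len(sac[1])
    weeks <- weeks[keep]; vols <- vols[keep]
    event <- 1L
  } else {
    event <- 0L
  }
  if (any(vols > config$brain_volume_cap)) {
    warning("simulated CE volume exceeded the brain-volume cap (",
            config$brain_volume_cap, " ul) and was clipped", call. = FALSE)
    vols <- pmin(vols, config$brain_volume_cap)
  }
  structure(list(mouse_id = mouse_id, strain = strain, dose = dose,
                 scan_weeks = weeks, volumes = vols,
                 observed_onset = observed_onset,
                 last_week = max(weeks), event = event),
            class = "dvr_mouse")
}

#' Simulate a full virtual cohort
#'
#' Generates every animal of every strain arm of the configuration. The
#' cohort is deterministic for a given seed; each animal runs on its own
#' RNG sub-stream derived from a stable hash of its identifier, so changing
#' the cohort composition does not reshuffle existing animals.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{dvr_cohort} holding the
#'   \code{\link{simulate_mouse}} trajectories and the config.
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 42))
#' length(coh$mice)  # 20 with the default layout
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "dvr_sim_config"))
  mice <- list()
  for (sp in config$strains) {
    tag <- gsub("[^A-Za-z0-9]+", "", sp$strain)
    doses <- c(rep(sp$doses, each = sp$n_per_dose),
               rep(0, sp$n_control))
    idx <- stats::ave(doses, doses, FUN = seq_along)
    for (i in seq_along(doses)) {
      id <- sprintf("%s_%03dGy_%d", tag, doses[i], idx[i])
      old <- .Random.seed_save()
      set.seed(mouse_seed(config$seed, id))
      mice[[id]] <- simulate_mouse(doses[i], sp$params, config,
                                   mouse_id = id, strain = sp$strain)
      .Random.seed_restore(old)
    }
  }
  structure(list(mice = mice, config = config), class = "dvr_cohort")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.dvr_cohort <- function(x, ...) {
  tab <- cohort_table(x)
  cat(sprintf("Virtual cohort: %d mice, %d scans, seed %d\n",
              length(x$mice), nrow(tab), x$config$seed))
  invisible(x)
}

#' Long-format scan table of a simulated cohort
#'
#' @param cohort A \code{dvr_cohort}.
#' @return Data frame with columns \code{mouse_id}, \code{strain},
#'   \code{dose_gy}, \code{scan_week}, \code{ce_volume_ul}.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "dvr_cohort"))
  do.call(rbind, lapply(cohort$mice, function(m) {
    data.frame(mouse_id = m$mouse_id, strain = m$strain, dose_gy = m$dose,
               scan_week = m$scan_weeks, ce_volume_ul = m$volumes,
               row.names = NULL)
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' Per-animal survival table of a simulated cohort
#'
#' @param cohort A \code{dvr_cohort}.
#' @return Data frame with columns \code{mouse_id}, \code{strain},
#'   \code{dose_gy}, \code{last_week}, \code{event} (1 = sacrificed for
#'   health deterioration, 0 = censored at follow-up end).
#' @export
survival_table <- function(cohort) {
  stopifnot(inherits(cohort, "dvr_cohort"))
  tab <- do.call(rbind, lapply(cohort$mice, function(m) {
    data.frame(mouse_id = m$mouse_id, strain = m$strain, dose_gy = m$dose,
               last_week = m$last_week, event = m$event, row.names = NULL)
  }))
  rownames(tab) <- NULL
  tab
}

#' Observed onset observations from a cohort scan table
#'
#' One row per irradiated animal whose lesion was ever detected: the first
#' scan week with CE volume at or above the detection threshold.
#'
#' @param table Long-format scan table (see \code{\link{cohort_table}} /
#'   \code{\link{read_cohort}}).
#' @param detection_threshold Detection limit in ul.
#' @return Data frame with columns \code{mouse_id}, \code{dose},
#'   \code{onset_week}.
#' @export
onset_observations <- function(table, detection_threshold = 1) {
  table <- as.data.frame(table)
  out <- lapply(split(table, table$mouse_id), function(d) {
    if (d$dose_gy[1] <= 0) return(NULL)
    hit <- d$scan_week[d$ce_volume_ul >= detection_threshold]
    if (!length(hit)) return(NULL)
    data.frame(mouse_id = d$mouse_id[1], dose = d$dose_gy[1],
               onset_week = min(hit))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Post-onset volume points eligible for the growth-law fit
#'
#' Only scans with positive CE volume at or after the animal's observed
#' onset enter the volume fit; pre-onset and zero-volume scans are excluded
#' and sham controls contribute no points.
#'
#' @inheritParams onset_observations
#' @return Data frame with columns \code{mouse_id}, \code{dose}, \code{t},
#'   \code{volume} suitable for \code{\link{fit_volume_model}}.
#' @export
volume_points <- function(table, detection_threshold = 1) {
  table <- as.data.frame(table)
  ons <- onset_observations(table, detection_threshold)
  if (is.null(ons) || nrow(ons) == 0L)
    return(data.frame(mouse_id = character(0), dose = numeric(0),
                      t = numeric(0), volume = numeric(0)))
  out <- lapply(seq_len(nrow(ons)), function(i) {
    d <- table[table$mouse_id == ons$mouse_id[i], ]
    d <- d[d$scan_week >= ons$onset_week[i] & d$ce_volume_ul > 0, ]
    data.frame(mouse_id = d$mouse_id, dose = d$dose_gy, t = d$scan_week,
               volume = d$ce_volume_ul)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
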