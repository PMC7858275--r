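# Trial design and generator parameter objects --------------------------------

#' Define the layout of a feeding trial
#'
#' Captures the experimental design of a box-replicated larval feeding trial:
#' which diets are run, how many replicate boxes per diet, how many larvae are
#' seeded per box, the feeding schedule and the observation days. The default
#' reproduces the canonical design of the study this package models: three
#' diets (chicken feed control CFD, canteen food waste FWD, oil-separator
#' waste OWD) with four boxes of 200 larvae each, fed every second day from
#' day 0 to day 18 and observed every second day up to diet-specific
#' termination days.
#'
#' @param diets Character vector of diet labels.
#' @param boxes_per_diet Number of replicate boxes per diet (>= 1).
#' @param larvae_per_box Larvae seeded per box (>= 1).
#' @param feed_interval_days Days between feeding events (>= 1).
#' @param feed_start_day,feed_end_day First and last possible feeding day.
#' @param observation_days Integer vector of days on which boxes are weighed
#'   and counted; must be non-decreasing and within `[0, max(end_day)]`.
#' @param end_day_per_diet Named integer vector mapping each diet to its
#'   termination day.
#' @return An object of class `trial_design` (a validated list).
#' @examples
#' d <- trial_design()
#' d$boxes_per_diet * d$larvae_per_box * length(d$diets)  # total larvae
#' @export
trial_design <- function(diets = c("CFD", "FWD", "OWD"),
                         boxes_per_diet = 4L,
                         larvae_per_box = 200L,
                         feed_interval_days = 2L,
                         feed_start_day = 0L,
                         feed_end_day = 18L,
                         observation_days = seq(0L, 20L, by = 2L),
                         end_day_per_diet = c(CFD = 18L, FWD = 20L, OWD = 12L)) {
  stopifnot(length(diets) >= 1L, !anyDuplicated(diets))
  if (boxes_per_diet < 1L) stop("boxes_per_diet must be >= 1")
  if (larvae_per_box < 1L) stop("larvae_per_box must be >= 1")
  if (feed_interval_days < 1L) stop("feed_interval_days must be >= 1")
  if (is.unsorted(observation_days))
    stop("observation_days must be non-decreasing")
  if (!all(diets %in% names(end_day_per_diet)))
    stop("end_day_per_diet must name every diet")
  end_max <- max(end_day_per_diet[diets])
  if (any(observation_days < 0) || any(observation_days > end_max))
    stop("observation days must lie within [0, max end day]")
  structure(list(
    diets = diets,
    boxes_per_diet = as.integer(boxes_per_diet),
    larvae_per_box = as.integer(larvae_per_box),
    feed_interval_days = as.integer(feed_interval_days),
    feed_start_day = as.integer(feed_start_day),
    feed_end_day = as.integer(feed_end_day),
    observation_days = as.integer(observation_days),
    end_day_per_diet = end_day_per_diet[diets]
  ), class = "trial_design")
}

#' Growth, mortality and mass-budget parameters for one diet
#'
#' Parameterizes the per-larva growth trajectory (logistic rise in fresh mass
#' to `peak_mass_mg`, then a linear relative decline as larvae approach the
#' (pre-)pupal stage), a piecewise-constant mortality hazard that switches on
#' after `mortality_lag_day`, a daily pupation probability after
#' `pupation_start_day`, and the feeding energetics (assimilation efficiency
#' and a dry-matter ingestion capacity per unit larval dry biomass).
#'
#' @param peak_mass_mg Peak fresh mass per larva (mg).
#' @param growth_rate_r Logistic growth rate (per day).
#' @param midpoint_day Day at which the logistic reaches half of peak.
#' @param post_peak_loss_frac_per_day Relative fresh-mass loss per day after
#'   the peak, in `[0, 1)`.
#' @param dry_matter_frac Dry matter as a fraction of fresh mass, in (0, 1).
#' @param vs_of_dry_frac Volatile solids as a fraction of dry mass, in (0, 1).
#' @param mortality_lag_day Day before which the hazard is zero.
#' @param mortality_hazard Constant hazard (per day, >= 0) after the lag.
#' @param pupation_start_day First day pupation can occur.
#' @param pupation_daily_prob Per-larva daily pupation probability in `[0, 1]`.
#' @param assimilation_eff Fraction of ingested dry mass assimilated, in (0, 1);
#'   egesta are the complementary `1 - assimilation_eff` fraction.
#' @param ingestion_capacity Maximum dry-mass intake per mg larval dry biomass
#'   per day.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(peak_mass_mg = 206,
                          growth_rate_r = 0.55,
                          midpoint_day = 6,
                          post_peak_loss_frac_per_day = 0.033,
                          dry_matter_frac = 0.36,
                          vs_of_dry_frac = 0.95,
                          mortality_lag_day = 5,
                          mortality_hazard = 0,
                          pupation_start_day = 12,
                          pupation_daily_prob = 0.25,
                          assimilation_eff = 0.45,
                          ingestion_capacity = 2.5) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(peak_mass_mg > 0, "peak_mass_mg must be positive")
  chk(post_peak_loss_frac_per_day >= 0 && post_peak_loss_frac_per_day < 1,
      "post_peak_loss_frac_per_day must be in [0, 1)")
  chk(dry_matter_frac > 0 && dry_matter_frac < 1,
      "dry_matter_frac must be in (0, 1)")
  chk(vs_of_dry_frac > 0 && vs_of_dry_frac < 1,
      "vs_of_dry_frac must be in (0, 1)")
  chk(mortality_hazard >= 0, "mortality_hazard must be >= 0")
  chk(pupation_daily_prob >= 0 && pupation_daily_prob <= 1,
      "pupation_daily_prob must be in [0, 1]")
  chk(assimilation_eff > 0 && assimilation_eff < 1,
      "assimilation_eff must be in (0, 1)")
  chk(ingestion_capacity > 0, "ingestion_capacity must be positive")
  structure(as.list(environment())[setdiff(names(formals()), "chk")],
            class = "growth_params")
}

#' Default per-diet growth parameters
#'
#' Diet-specific parameter sets emulating the study conditions: CFD and FWD
#' support similar logistic growth to ~184 and ~206 mg fresh peak mass with a
#' post-peak decline of about 1.2 and 3.3 % per day respectively and no
#' mortality; OWD strongly inhibits growth (peak ~22 mg) and carries a hazard
#' after day 5 calibrated so that cumulative mortality reaches ~96 % by day 12.
#'
#' @return Named list of [growth_params()] objects for diets CFD, FWD, OWD.
#' @export
default_diet_params <- function() {
  list(
    CFD = growth_params(peak_mass_mg = 184, growth_rate_r = 0.55,
                        midpoint_day = 5.5,
                        post_peak_loss_frac_per_day = 0.012,
                        dry_matter_frac = 0.37,
                        assimilation_eff = 0.48,
                        pupation_start_day = 12, pupation_daily_prob = 0.3),
    FWD = growth_params(peak_mass_mg = 206, growth_rate_r = 0.55,
                        midpoint_day = 6,
                        post_peak_loss_frac_per_day = 0.0345,
                        dry_matter_frac = 0.35,
                        assimilation_eff = 0.25,
                        pupation_start_day = 12, pupation_daily_prob = 0.25),
    OWD = growth_params(peak_mass_mg = 22, growth_rate_r = 0.45,
                        midpoint_day = 4,
                        post_peak_loss_frac_per_day = 0,
                        dry_matter_frac = 0.36,
                        assimilation_eff = 0.1,
                        ingestion_capacity = 0.3,
                        mortality_lag_day = 5,
                        mortality_hazard = log(25) / 7,
                        pupation_start_day = Inf, pupation_daily_prob = 0)
  )
}

#' Specify a synthetic 16S community with one succession taxon
#'
#' Describes a Dirichlet-multinomial community in which one designated taxon
#' ("bloom" taxon, emulating the *Morganella* take-over seen in food-waste-fed
#' larvae) follows a logistic succession in expected relative abundance from
#' `succession_start_frac` to `succession_end_frac` between the first and last
#' sampled day, while the remaining taxa share the residual mass in
#' proportion to `baseline_concentrations`.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param baseline_concentrations Positive Dirichlet concentration parameters,
#'   recycled to length `n_taxa`.
#' @param succession_taxon_index Index of the bloom taxon, or `NA` for a
#'   static (no-succession) community.
#' @param succession_start_frac,succession_end_frac Expected relative
#'   abundance of the bloom taxon at the start/end day, each in (0, 1) and
#'   ordered start < end for a bloom.
#' @param succession_rate Logistic rate of the succession (per day).
#' @param succession_day_range Days over which the logistic runs (length 2).
#' @param resident_frac Expected relative abundance of the bloom taxon in
#'   samples outside the succession (its low resident level in control
#'   guts and substrates).
#' @param dispersion Dirichlet precision: expected composition is multiplied
#'   by this factor to give the concentration vector; larger values mean less
#'   compositional noise. `Inf` disables Dirichlet perturbation.
#' @param depth_mean,depth_shape Mean and gamma shape of the (gamma-mixed
#'   Poisson, i.e. negative-binomial-like) library-size distribution.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_taxa = 60,
                           baseline_concentrations = NULL,
                           succession_taxon_index = 1L,
                           succession_start_frac = 0.01,
                           succession_end_frac = 0.88,
                           succession_rate = 0.5,
                           succession_day_range = c(2, 20),
                           resident_frac = 0.002,
                           dispersion = 200,
                           depth_mean = 5000,
                           depth_shape = 8) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (is.null(baseline_concentrations))
    baseline_concentrations <- 5 / seq_len(n_taxa)  # power-law-ish baseline
  baseline_concentrations <- rep_len(baseline_concentrations, n_taxa)
  if (any(baseline_concentrations <= 0))
    stop("baseline_concentrations must be positive")
  if (!is.na(succession_taxon_index)) {
    stopifnot(succession_taxon_index >= 1, succession_taxon_index <= n_taxa)
    if (!(succession_start_frac > 0 && succession_end_frac < 1 &&
          succession_start_frac < succession_end_frac))
      stop("succession fractions must satisfy 0 < start < end < 1")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (depth_mean <= 0 || depth_shape <= 0)
    stop("depth parameters must be positive")
  structure(as.list(environment()), class = "community_spec")
}
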