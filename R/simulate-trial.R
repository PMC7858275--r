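# Feeding-trial simulator with mass-budget ground truth -----------------------

# Per-larva fresh mass trajectory: logistic rise to the peak, then a linear
# relative decline (pre-pupal mass loss). The peak day is where the logistic
# reaches 99% of its asymptote.
larval_mass_curve <- function(t, p) {
  peak_day <- p$midpoint_day + log(99) / p$growth_rate_r
  logi <- p$peak_mass_mg / (1 + exp(-p$growth_rate_r * (t - p$midpoint_day)))
  m_peak <- p$peak_mass_mg / (1 + exp(-p$growth_rate_r *
                                        (peak_day - p$midpoint_day)))
  post <- m_peak * pmax(1 - p$post_peak_loss_frac_per_day * (t - peak_day),
                        0.05)
  ifelse(t <= peak_day, logi, post)
}

#' Simulate a complete larval feeding trial
#'
#' Generates per-box observation tables (counts, pupae, mean fresh/dry/VS
#' masses), a feeding log, an end-of-trial residue table and a pupae table,
#' together with the generator's hidden truth (daily dry-mass budget per box
#' and the exact bioconversion indices implied by it). Larvae grow along a
#' deterministic diet-specific mass curve; mortality is a piecewise-constant
#' hazard realized as daily binomial deaths; pupation is a daily Bernoulli
#' event after the diet's pupation start day. Feeding deposits dry substrate
#' into a per-box pool; each day the live biomass ingests
#' `min(capacity x live dry biomass, pool)`, of which the assimilated
#' fraction is retained and the remainder becomes egesta.
#'
#' @param design A [trial_design()].
#' @param params Named list of [growth_params()], one per diet.
#' @param seed Integer master seed; all stochastic streams derive from it.
#' @param ration_mg_per_larva_day Named fresh-mass ration per larva per day.
#' @param ration_dry_frac Named dry-matter fraction of each diet as fed.
#' @param obs_noise_cv Multiplicative observation noise (coefficient of
#'   variation) on reported mean masses; 0 gives noise-free observables.
#' @param pupal_mass_frac Fresh-mass fraction retained at the larva-to-pupa
#'   transition.
#' @return A list of class `bsfl_trial` with elements `observations`,
#'   `feeding_log`, `residues`, `pupae` (data frames) and `truth` (per-box
#'   daily budgets, per-box `mass_budget` objects and true index values).
#' @seealso [build_mass_budget()], [compute_indices()]
#' @export
simulate_trial <- function(design = trial_design(),
                           params = default_diet_params(),
                           seed = 1L,
                           ration_mg_per_larva_day = c(CFD = 100, FWD = 170,
                                                       OWD = 70),
                           ration_dry_frac = c(CFD = 0.40, FWD = 0.25,
                                               OWD = 0.45),
                           obs_noise_cv = 0.02,
                           pupal_mass_frac = 0.92) {
  stopifnot(inherits(design, "trial_design"))
  if (!all(design$diets %in% names(params)))
    stop("params must name every diet in the design")
  if (is.unsorted(design$observation_days))
    stop("observation days must be monotone non-decreasing")

  feed_days <- schedule_feedings(design$feed_start_day, design$feed_end_day,
                                 design$feed_interval_days)$days
  obs <- list(); flog <- list(); resid <- list(); pup <- list()
  truth_daily <- list(); truth_budget <- list()

  for (diet in design$diets) {
    p <- params[[diet]]
    end_day <- design$end_day_per_diet[[diet]]
    days <- 0:end_day
    m_fresh <- larval_mass_curve(days, p)          # per-larva fresh mg
    m_dry <- m_fresh * p$dry_matter_frac
    obs_days <- design$observation_days[design$observation_days <= end_day]

    for (b in seq_len(design$boxes_per_diet)) {
      box <- sprintf("%s_B%d", diet, b)
      n_alive <- design$larvae_per_box
      pool <- 0; egesta <- 0; ingested_tot <- 0; offered_tot <- 0
      pup_dry <- 0; pup_n <- 0
      daily <- data.frame(day = days, offered_dry = 0, ingested_dry = 0,
                          egesta_dry = 0, pool_dry = 0, alive = 0L,
                          pupae = 0L, biomass_dry = 0, pup_dry_cum = 0)
      pup_events <- list()
      for (i in seq_along(days)) {
        t <- days[i]
        # feeding
        if (t %in% feed_days && t <= end_day) {
          off <- ration_mg_per_larva_day[[diet]] * design$feed_interval_days *
            n_alive * ration_dry_frac[[diet]]
          pool <- pool + off
          offered_tot <- offered_tot + off
          daily$offered_dry[i] <- off
          flog[[length(flog) + 1L]] <- data.frame(
            box = box, diet = diet, day = t,
            offered_fresh_mg = ration_mg_per_larva_day[[diet]] *
              design$feed_interval_days * n_alive,
            dry_frac = ration_dry_frac[[diet]])
        }
        # ingestion on live dry biomass
        live_dry <- n_alive * m_dry[i]
        ing <- min(p$ingestion_capacity * live_dry, pool)
        pool <- pool - ing
        ingested_tot <- ingested_tot + ing
        egesta <- egesta + (1 - p$assimilation_eff) * ing
        daily$ingested_dry[i] <- ing
        daily$egesta_dry[i] <- (1 - p$assimilation_eff) * ing
        # pupation then mortality (end of day)
        n_pup_new <- 0L
        if (t >= p$pupation_start_day && n_alive > 0L &&
            p$pupation_daily_prob > 0) {
          n_pup_new <- with_stream_seed(seed, paste0("pupation/", box, "/", t),
                                        rbinom(1L, n_alive,
                                               p$pupation_daily_prob))
          if (n_pup_new > 0L) {
            pd <- n_pup_new * m_dry[i] * pupal_mass_frac
            pup_dry <- pup_dry + pd
            pup_n <- pup_n + n_pup_new
            n_alive <- n_alive - n_pup_new
            pup_events[[length(pup_events) + 1L]] <- data.frame(
              box = box, diet = diet, day = t, n_pupae_new = n_pup_new,
              mean_pupal_fresh_mg = m_fresh[i] * pupal_mass_frac,
              mean_pupal_dry_mg = m_dry[i] * pupal_mass_frac)
          }
        }
        if (t > p$mortality_lag_day && p$mortality_hazard > 0 && n_alive > 0L) {
          pdie <- 1 - exp(-p$mortality_hazard)
          n_die <- with_stream_seed(seed, paste0("mortality/", box, "/", t),
                                    rbinom(1L, n_alive, pdie))
          n_alive <- n_alive - n_die   # dead larvae leave the biomass
        }
        daily$alive[i] <- n_alive
        daily$pupae[i] <- pup_n
        daily$biomass_dry[i] <- n_alive * m_dry[i]
        daily$pool_dry[i] <- pool
        daily$pup_dry_cum[i] <- pup_dry
      }

      # observations (reported means carry optional multiplicative noise)
      noise <- function(x, stream) {
        if (obs_noise_cv <= 0) return(x)
        z <- with_stream_seed(seed, stream, rnorm(length(x)))
        x * pmax(1 + obs_noise_cv * z, 0.01)
      }
      oi <- match(obs_days, days)
      mf <- noise(m_fresh[oi], paste0("obs_fresh/", box))
      md <- pmin(noise(m_dry[oi], paste0("obs_dry/", box)), mf * 0.999)
      obs[[length(obs) + 1L]] <- data.frame(
        box = box, diet = diet, day = obs_days,
        n_alive = daily$alive[oi], n_pupae = daily$pupae[oi],
        mean_fresh_mg = mf, mean_dry_mg = md,
        mean_vs_mg = md * p$vs_of_dry_frac)
      resid[[length(resid) + 1L]] <- data.frame(
        box = box, diet = diet, day = end_day,
        residue_dry_mg = pool + egesta,
        uneaten_dry_mg = pool, egesta_dry_mg = egesta)
      if (length(pup_events))
        pup[[length(pup) + 1L]] <- do.call(rbind, pup_events)

      # ground-truth budget on the same conventions the estimators use
      live_obs <- daily$biomass_dry[oi]
      A <- trapezoid_mean(obs_days, live_obs)
      budget <- mass_budget(
        I_offered_dry = offered_tot,
        R_residue_dry = pool + egesta,
        E_ingested_dry = ingested_tot,
        R_egesta_dry = egesta,
        B_gain_dry = daily$biomass_dry[length(days)] + pup_dry -
          daily$biomass_dry[1L],
        A_mean_biomass = A,
        T_days = end_day,
        L_initial_fresh = m_fresh[1L],
        L_end_fresh = m_fresh[length(days)])
      truth_daily[[box]] <- daily
      truth_budget[[box]] <- budget
    }
  }

  truth <- list(daily = truth_daily, budgets = truth_budget,
                indices = lapply(truth_budget, compute_indices),
                params = params)
  structure(list(observations = do.call(rbind, obs),
                 feeding_log = do.call(rbind, flog),
                 residues = do.call(rbind, resid),
                 pupae = if (length(pup)) do.call(rbind, pup) else
                   data.frame(box = character(), diet = character(),
                              day = integer(), n_pupae_new = integer(),
                              mean_pupal_fresh_mg = double(),
                              mean_pupal_dry_mg = double()),
                 truth = truth, design = design, seed = seed),
            class = "bsfl_trial")
}

# time-average of a piecewise-linear trajectory over [t1, tn]
trapezoid_mean <- function(t, y) {
  if (length(t) < 2L) return(y[1L])
  dt <- diff(t)
  sum((y[-length(y)] + y[-1L]) / 2 * dt) / (t[length(t)] - t[1L])
}

# Substrate physicochemistry ---------------------------------------------------

#' Default physicochemical profile specification
#'
#' Per-substrate means for the 15 measured variables in the fresh ("-S") and
#' post-process residue ("-R") state, encoding the characteristic shifts of
#' larval processing: ammonium rises 20-fold in chicken-feed residue and
#' 30-fold in food-waste residue, protein rises 10-fold in all residues, and
#' the initially acidic food waste (pH 4.5) neutralizes. The pine-humus
#' litter (HUM) is a near-inert reference with no residue state.
#'
#' @param sd_frac Relative standard deviation applied to every mean.
#' @return Data frame with columns `diet`, `variable`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`.
#' @export
default_substrate_spec <- function(sd_frac = 0.05) {
  v <- function(diet, variable, pre, post)
    data.frame(diet = diet, variable = variable, pre_mean = pre,
               pre_sd = sd_frac * abs(pre), post_mean = post,
               post_sd = sd_frac * abs(post))
  rbind(
    v("CFD", "pH", 5.8, 8.0),      v("FWD", "pH", 4.5, 7.5),
    v("OWD", "pH", 4.8, 5.0),      v("HUM", "pH", 6.0, NA),
    v("CFD", "DM", 40, 35),        v("FWD", "DM", 25, 30),
    v("OWD", "DM", 50, 52),        v("HUM", "DM", 90, NA),
    v("CFD", "VS", 90, 80),        v("FWD", "VS", 92, 85),
    v("OWD", "VS", 96, 95),        v("HUM", "VS", 97, NA),
    v("CFD", "Ctot", 42, 38),      v("FWD", "Ctot", 45, 40),
    v("OWD", "Ctot", 60, 59),      v("HUM", "Ctot", 50, NA),
    v("CFD", "Ntot", 2.8, 4.5),    v("FWD", "Ntot", 2.5, 5.0),
    v("OWD", "Ntot", 1.0, 1.2),    v("HUM", "Ntot", 0.4, NA),
    v("CFD", "NH4", 120, 2400),    v("FWD", "NH4", 110, 3300),
    v("OWD", "NH4", 100, 400),     v("HUM", "NH4", 10, NA),
    v("CFD", "COD", 320, 220),     v("FWD", "COD", 250, 180),
    v("OWD", "COD", 300, 290),     v("HUM", "COD", 40, NA),
    v("CFD", "protein", 12, 120),  v("FWD", "protein", 10, 100),
    v("OWD", "protein", 4, 40),    v("HUM", "protein", 1, NA),
    v("CFD", "sugars", 80, 20),    v("FWD", "sugars", 120, 30),
    v("OWD", "sugars", 20, 15),    v("HUM", "sugars", 2, NA),
    v("CFD", "fat", 30, 25),       v("FWD", "fat", 60, 40),
    v("OWD", "fat", 400, 380),     v("HUM", "fat", 5, NA),
    v("CFD", "lactate", 45, 5),    v("FWD", "lactate", 8, 4),
    v("OWD", "lactate", 10, 9),    v("HUM", "lactate", 0.5, NA),
    v("CFD", "formate", 12, 2),    v("FWD", "formate", 2, 1),
    v("OWD", "formate", 3, 3),     v("HUM", "formate", 0.2, NA),
    v("CFD", "acetate", 10, 8),    v("FWD", "acetate", 6, 15),
    v("OWD", "acetate", 8, 9),     v("HUM", "acetate", 0.5, NA),
    v("CFD", "butyrate", 2, 3),    v("FWD", "butyrate", 1, 18),
    v("OWD", "butyrate", 4, 5),    v("HUM", "butyrate", 0.1, NA),
    v("CFD", "valerate", 1, 2),    v("FWD", "valerate", 0.5, 14),
    v("OWD", "valerate", 2, 3),    v("HUM", "valerate", 0.1, NA))
}

#' Simulate replicated physicochemical sample profiles
#'
#' Draws normal replicates around the specified pre-process ("-S", fresh)
#' and post-process ("-R", residue) means for each substrate. Substrates
#' whose `post_mean` is `NA` throughout (e.g. the pine-humus litter) only
#' yield fresh samples. Non-pH variables are truncated at zero.
#'
#' @param spec Data frame as returned by [default_substrate_spec()].
#' @param n_fresh,n_residue Replicates per fresh / residue sample group.
#' @param seed Integer seed.
#' @return Data frame: `sample_id`, `group` (e.g. "FWD-R"), `diet`, `phase`
#'   plus one numeric column per variable.
#' @export
simulate_substrate_profiles <- function(spec = default_substrate_spec(),
                                        n_fresh = 3L, n_residue = 4L,
                                        seed = 1L) {
  need <- c("diet", "variable", "pre_mean", "pre_sd", "post_mean", "post_sd")
  if (!all(need %in% names(spec))) stop("spec missing columns")
  if (any(c(spec$pre_sd, spec$post_sd) < 0, na.rm = TRUE))
    stop("negative sd in substrate spec")
  rows <- list()
  for (diet in unique(spec$diet)) {
    sd_ <- spec[spec$diet == diet, ]
    phases <- if (all(is.na(sd_$post_mean))) "S" else c("S", "R")
    for (phase in phases) {
      n <- if (phase == "S") n_fresh else n_residue
      mu <- if (phase == "S") sd_$pre_mean else sd_$post_mean
      sg <- if (phase == "S") sd_$pre_sd else sd_$post_sd
      for (r in seq_len(n)) {
        vals <- with_stream_seed(seed,
                                 paste("chem", diet, phase, r, sep = "/"),
                                 rnorm(length(mu), mu, sg))
        vals <- ifelse(sd_$variable == "pH", vals, pmax(vals, 0))
        row <- as.data.frame(as.list(setNames(vals, sd_$variable)))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(sample_id = sprintf("%s-%s_%d", diet, phase, r),
                     group = sprintf("%s-%s", diet, phase),
                     diet = diet, phase = phase), row)
      }
    }
  }
  do.call(rbind, rows)
}
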