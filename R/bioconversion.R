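# Waldbauer-family bioconversion indices --------------------------------------

#' Feeding schedule for a trial
#'
#' @param start_day,end_day First and last possible feeding day (end >= start).
#' @param interval_days Days between feedings (>= 1).
#' @return List with `days` (integer vector) and `n_events`.
#' @examples
#' schedule_feedings(0, 18, 2)$n_events  # ten feeding events
#' @export
schedule_feedings <- function(start_day, end_day, interval_days) {
  if (interval_days < 1) stop("interval_days must be >= 1")
  if (end_day < start_day) stop("end_day must be >= start_day")
  days <- seq(from = start_day, to = end_day, by = interval_days)
  list(days = as.integer(days), n_events = length(days))
}

#' Construct a per-box dry-mass budget
#'
#' Bundles the quantities feeding the bioconversion indices. Two distinct
#' residue quantities coexist deliberately: `R_residue_dry` is the total
#' post-process residue (uneaten substrate plus egesta) used in substrate
#' reduction and the waste reduction index, while `R_egesta_dry` is the
#' egesta alone, used in approximate digestibility and the efficiency of
#' conversion of digested food. The printed index values of the study are
#' only mutually consistent if the two bases differ, so both are carried.
#'
#' @param I_offered_dry Total substrate offered, dry basis (mg).
#' @param R_residue_dry Total residue (uneaten + egesta), dry (mg).
#' @param E_ingested_dry Feed ingested, dry (mg).
#' @param R_egesta_dry Egesta, dry (mg).
#' @param B_gain_dry Larval biomass gained (live + pupated), dry (mg).
#' @param A_mean_biomass Time-averaged live larval dry biomass (mg).
#' @param T_days Duration of the feeding period (days, > 0).
#' @param L_initial_fresh,L_end_fresh Per-larva fresh mass at start/end (mg).
#' @return Object of class `mass_budget`.
#' @export
mass_budget <- function(I_offered_dry, R_residue_dry, E_ingested_dry,
                        R_egesta_dry, B_gain_dry, A_mean_biomass, T_days,
                        L_initial_fresh = NA_real_, L_end_fresh = NA_real_) {
  masses <- c(I_offered_dry, R_residue_dry, E_ingested_dry, R_egesta_dry,
              A_mean_biomass)
  if (any(masses < -1e-9)) stop("masses must be non-negative")
  if (E_ingested_dry > I_offered_dry * (1 + 1e-9))
    stop("ingested mass cannot exceed offered mass")
  if (R_egesta_dry > E_ingested_dry * (1 + 1e-9))
    stop("egesta cannot exceed ingested mass")
  if (T_days <= 0) stop("T_days must be positive")
  structure(list(I_offered_dry = I_offered_dry,
                 R_residue_dry = R_residue_dry,
                 E_ingested_dry = E_ingested_dry,
                 R_egesta_dry = R_egesta_dry,
                 B_gain_dry = B_gain_dry,
                 A_mean_biomass = A_mean_biomass,
                 T_days = T_days,
                 L_initial_fresh = L_initial_fresh,
                 L_end_fresh = L_end_fresh,
                 D_fraction = if (I_offered_dry > 0)
                   (I_offered_dry - R_residue_dry) / I_offered_dry
                 else NA_real_),
            class = "mass_budget")
}

#' Assemble a mass budget from trial tables
#'
#' Builds a [mass_budget()] for one box from the observation, feeding-log and
#' residue tables written by the trial simulator (or supplied by a user).
#' Offered mass is the sum of fresh offerings times their dry fraction.
#' Ingested mass and egesta are taken from residue-table columns
#' (`uneaten_dry_mg`, `egesta_dry_mg`) when present; otherwise ingestion is
#' estimated as offered minus total residue and egesta is unavailable (the
#' digestibility-based indices are then flagged undefined). Mean biomass `A`
#' is the trapezoidal time-average of live dry biomass over the observation
#' days, the Waldbauer "mean weight during the feeding period" generalized
#' to unevenly spaced observations. Biomass gain `B` counts live plus
#' pupated dry mass at the end day minus the initial live dry mass.
#'
#' @param observations Observation table (`box`, `day`, `n_alive`,
#'   `mean_fresh_mg`, `mean_dry_mg`, ...).
#' @param feeding_log Feeding log (`box`, `day`, `offered_fresh_mg`,
#'   `dry_frac`).
#' @param residues Residue table (`box`, `day`, `residue_dry_mg` and
#'   optionally `uneaten_dry_mg`, `egesta_dry_mg`).
#' @param box Box identifier to assemble.
#' @param pupae Optional pupae table (`box`, `day`, `n_pupae_new`,
#'   `mean_pupal_dry_mg`); pupated biomass is credited to `B` when given.
#' @return A [mass_budget()].
#' @export
build_mass_budget <- function(observations, feeding_log, residues, box,
                              pupae = NULL) {
  ob <- observations[observations$box == box, , drop = FALSE]
  ob <- ob[order(ob$day), , drop = FALSE]
  if (nrow(ob) < 2L) stop("need at least two observation days for box ", box)
  fl <- feeding_log[feeding_log$box == box, , drop = FALSE]
  rs <- residues[residues$box == box, , drop = FALSE]
  if (nrow(rs) < 1L) stop("missing residue row for box ", box)
  end_day <- max(ob$day)
  T_days <- end_day - min(ob$day)
  if (T_days <= 0) stop("zero trial duration for box ", box)

  I <- if (nrow(fl)) sum(fl$offered_fresh_mg * fl$dry_frac) else 0
  R_res <- rs$residue_dry_mg[which.max(rs$day)]
  if (all(c("uneaten_dry_mg", "egesta_dry_mg") %in% names(rs))) {
    E <- I - rs$uneaten_dry_mg[which.max(rs$day)]
    R_eg <- rs$egesta_dry_mg[which.max(rs$day)]
  } else {
    E <- max(I - R_res, 0)
    R_eg <- NA_real_
  }
  live_dry <- ob$n_alive * ob$mean_dry_mg
  pup_dry_end <- 0
  if (!is.null(pupae) && nrow(pupae)) {
    pp <- pupae[pupae$box == box & pupae$day <= end_day, , drop = FALSE]
    if (nrow(pp)) pup_dry_end <- sum(pp$n_pupae_new * pp$mean_pupal_dry_mg)
  }
  B <- live_dry[length(live_dry)] + pup_dry_end - live_dry[1L]
  A <- trapezoid_mean(ob$day, live_dry)
  mass_budget(I_offered_dry = I, R_residue_dry = R_res,
              E_ingested_dry = E, R_egesta_dry = R_eg, B_gain_dry = B,
              A_mean_biomass = A, T_days = T_days,
              L_initial_fresh = ob$mean_fresh_mg[1L],
              L_end_fresh = ob$mean_fresh_mg[nrow(ob)])
}

#' Compute the seven bioconversion indices from a mass budget
#'
#' Growth rate `GR = (L_end - L_initial) / T` (fresh mass, mg/day);
#' substrate reduction `SR = (I - R) / I x 100` with R the total residue;
#' consumption index `CI = E / (T x A)`; waste reduction index
#' `WRI = D / T x 100` with `D = (I - R) / I`; approximate digestibility
#' `AD = (E - R) / E x 100` with R the egesta; efficiency of conversion of
#' ingested food `ECI = B / E x 100`; and of digested food
#' `ECD = B / (E - R) x 100`. Any division by zero (or an unavailable
#' egesta mass) yields `NA` with a named entry in `flags` rather than an
#' error.
#'
#' @param budget A [mass_budget()].
#' @return Object of class `bioconversion_indices`: list with `GR`, `SR`,
#'   `CI`, `WRI`, `AD`, `ECI`, `ECD` and a character vector `flags`.
#' @examples
#' b <- mass_budget(I_offered_dry = 100, R_residue_dry = 14.7,
#'                  E_ingested_dry = 100, R_egesta_dry = 17.3,
#'                  B_gain_dry = 9.6, A_mean_biomass = 10, T_days = 20)
#' compute_indices(b)$SR   # 85.3
#' @export
compute_indices <- function(budget) {
  stopifnot(inherits(budget, "mass_budget"))
  flags <- character()
  b <- budget
  GR <- if (!is.na(b$L_end_fresh) && !is.na(b$L_initial_fresh))
    (b$L_end_fresh - b$L_initial_fresh) / b$T_days else NA_real_
  if (is.na(GR)) flags <- c(flags, GR = "fresh endpoint masses unavailable")
  if (b$I_offered_dry > 0) {
    SR <- (b$I_offered_dry - b$R_residue_dry) / b$I_offered_dry * 100
    WRI <- SR / b$T_days
  } else {
    SR <- WRI <- NA_real_
    flags <- c(flags, SR = "no substrate offered", WRI = "no substrate offered")
  }
  if (b$A_mean_biomass > 0) {
    CI <- b$E_ingested_dry / (b$T_days * b$A_mean_biomass)
  } else {
    CI <- NA_real_
    flags <- c(flags, CI = "zero mean biomass")
  }
  if (is.na(b$R_egesta_dry)) {
    AD <- ECD <- NA_real_
    flags <- c(flags, AD = "egesta mass unavailable",
               ECD = "egesta mass unavailable")
  } else if (b$E_ingested_dry > 0) {
    AD <- (b$E_ingested_dry - b$R_egesta_dry) / b$E_ingested_dry * 100
    assim <- b$E_ingested_dry - b$R_egesta_dry
    if (assim > 0) {
      ECD <- b$B_gain_dry / assim * 100
    } else {
      ECD <- NA_real_
      flags <- c(flags, ECD = "zero assimilated mass")
    }
  } else {
    AD <- ECD <- NA_real_
    flags <- c(flags, AD = "nothing ingested", ECD = "nothing ingested")
  }
  if (b$E_ingested_dry > 0) {
    ECI <- b$B_gain_dry / b$E_ingested_dry * 100
  } else {
    ECI <- NA_real_
    flags <- c(flags, ECI = "nothing ingested")
  }
  structure(list(GR = GR, SR = SR, CI = CI, WRI = WRI, AD = AD, ECI = ECI,
                 ECD = ECD, flags = flags),
            class = "bioconversion_indices")
}

#' Endpoint biomass and development summary per diet
#'
#' Per-diet means and standard deviations over replicate boxes of the
#' endpoint larval masses (fresh, dry, water = fresh - dry, volatile
#' solids, in g per larva), mortality, pupation rate and development time,
#' mirroring a classical endpoint-characterization table.
#'
#' @param observations Observation table (see [simulate_trial()]).
#' @param pupae Pupae table with `n_pupae_new`, `mean_pupal_fresh_mg`,
#'   `mean_pupal_dry_mg`.
#' @param hatch_offset_days Age of larvae at trial start (days), added to the
#'   pupation day to report development time post-hatching.
#' @return Data frame, one row per diet and statistic.
#' @export
endpoint_summary <- function(observations, pupae = NULL,
                             hatch_offset_days = 6) {
  if (any(observations$mean_dry_mg > observations$mean_fresh_mg))
    stop("dry mass exceeds fresh mass: physically impossible observation")
  out <- list()
  for (diet in unique(observations$diet)) {
    ob <- observations[observations$diet == diet, , drop = FALSE]
    end_day <- max(ob$day)
    per_box <- do.call(rbind, lapply(split(ob, ob$box), function(d) {
      e <- d[d$day == end_day, , drop = FALSE]
      if (!nrow(e)) return(NULL)
      n0 <- d$n_alive[which.min(d$day)] + d$n_pupae[which.min(d$day)]
      data.frame(fresh_g = e$mean_fresh_mg / 1000,
                 dry_g = e$mean_dry_mg / 1000,
                 water_g = (e$mean_fresh_mg - e$mean_dry_mg) / 1000,
                 vs_g = e$mean_vs_mg / 1000,
                 mortality_pct = 100 * (1 - (e$n_alive + e$n_pupae) / n0),
                 pupation_rate_pct = 100 * e$n_pupae / n0)
    }))
    dev_time <- NA_real_; dev_sd <- NA_real_
    pup_fresh <- NA_real_; pup_fresh_sd <- NA_real_
    pup_dry <- NA_real_; pup_dry_sd <- NA_real_
    if (!is.null(pupae)) {
      pp <- pupae[pupae$diet == diet, , drop = FALSE]
      if (nrow(pp)) {
        w <- pp$n_pupae_new
        dev_time <- sum(w * (pp$day + hatch_offset_days)) / sum(w)
        dev_sd <- sqrt(sum(w * (pp$day + hatch_offset_days - dev_time)^2) /
                         max(sum(w) - 1, 1))
        pup_fresh <- sum(w * pp$mean_pupal_fresh_mg) / sum(w) / 1000
        pup_dry <- sum(w * pp$mean_pupal_dry_mg) / sum(w) / 1000
        pup_fresh_sd <- sqrt(sum(w * (pp$mean_pupal_fresh_mg / 1000 -
                                        pup_fresh)^2) / max(sum(w) - 1, 1))
        pup_dry_sd <- sqrt(sum(w * (pp$mean_pupal_dry_mg / 1000 -
                                      pup_dry)^2) / max(sum(w) - 1, 1))
      }
    }
    sd_or_na <- function(x) if (length(x) >= 2L) sd(x) else NA_real_
    out[[diet]] <- data.frame(
      diet = diet, n_boxes = nrow(per_box),
      fresh_g = mean(per_box$fresh_g), fresh_g_sd = sd_or_na(per_box$fresh_g),
      water_g = mean(per_box$water_g), water_g_sd = sd_or_na(per_box$water_g),
      dry_g = mean(per_box$dry_g), dry_g_sd = sd_or_na(per_box$dry_g),
      vs_g = mean(per_box$vs_g), vs_g_sd = sd_or_na(per_box$vs_g),
      mortality_pct = mean(per_box$mortality_pct),
      mortality_pct_sd = sd_or_na(per_box$mortality_pct),
      pupation_rate_pct = mean(per_box$pupation_rate_pct),
      pupation_rate_pct_sd = sd_or_na(per_box$pupation_rate_pct),
      dev_time_days = dev_time, dev_time_days_sd = dev_sd,
      pupal_fresh_g = pup_fresh, pupal_fresh_g_sd = pup_fresh_sd,
      pupal_dry_g = pup_dry, pupal_dry_g_sd = pup_dry_sd)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
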