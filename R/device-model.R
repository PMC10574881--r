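# Closed-form device arithmetic and the real-time alarm engine.

#' Full-scale input range
#'
#' The differential dynamic range of the front end is `+/- v_ref / gain`,
#' i.e. a total span of `2 * v_ref / gain` volts (so +/-2.4 V at unity gain
#' with the 2.4 V reference).
#'
#' @param spec A [device_spec()].
#' @return The total differential span in volts; halve it for the +/- limit.
#' @examples
#' full_scale_range(device_spec()) / 2  # 2.4 V
#' @export
full_scale_range <- function(spec = device_spec()) {
  2 * spec$v_ref / spec$gain
}

#' ADC resolution (LSB voltage)
#'
#' @param spec A [device_spec()].
#' @return Volts per least-significant bit:
#'   `(2 * v_ref / gain) / (2^n_bits - 1)`, about 286.10 nV at gain 1.
#' @export
adc_resolution <- function(spec = device_spec()) {
  full_scale_range(spec) / (2^spec$n_bits - 1)
}

#' Power budget of the monitor
#'
#' Worst-case constant consumption assumed for the battery-life projection:
#' 50 mA at 3.3 V, fed from a 3000 mAh / 3.7 V lithium cell of which 70% is
#' usable before the low-voltage protection circuit cuts off.
#'
#' @param supply_current_ma,supply_voltage_v Device-side consumption.
#' @param battery_capacity_mah,battery_voltage_v Battery ratings.
#' @param usable_fraction Fraction of the theoretical charge deliverable
#'   above the cutoff voltage, in (0, 1].
#' @return An object of class `power_budget`.
#' @export
power_budget <- function(supply_current_ma = 50, supply_voltage_v = 3.3,
                         battery_capacity_mah = 3000, battery_voltage_v = 3.7,
                         usable_fraction = 0.70) {
  vals <- c(supply_current_ma, supply_voltage_v, battery_capacity_mah,
            battery_voltage_v, usable_fraction)
  if (any(vals <= 0) || usable_fraction > 1) {
    stop("all budget values must be positive and usable_fraction in (0, 1]",
         call. = FALSE)
  }
  structure(list(supply_current_ma = supply_current_ma,
                 supply_voltage_v = supply_voltage_v,
                 battery_capacity_mah = battery_capacity_mah,
                 battery_voltage_v = battery_voltage_v,
                 usable_fraction = usable_fraction),
            class = "power_budget")
}

#' Battery-life projection
#'
#' Theoretical hours are battery energy over device power,
#' `(capacity * battery_voltage) / (current * supply_voltage)` - 67.27 h for
#' the default budget - and usable hours apply the usable charge fraction
#' (47.09 h at 70%).
#'
#' @param budget A [power_budget()].
#' @return List with `theoretical_h` and `usable_h`.
#' @examples
#' battery_life_h(power_budget())
#' @export
battery_life_h <- function(budget = power_budget()) {
  p_d <- budget$supply_current_ma * budget$supply_voltage_v     # mW
  p_b <- budget$battery_capacity_mah * budget$battery_voltage_v # mWh
  th <- p_b / p_d
  list(theoretical_h = th, usable_h = budget$usable_fraction * th)
}

ELECTRODES <- c("RL", "LL", "LA", "RA", "V2")

#' Decode the electrode lead-off status word
#'
#' The front end reports electrode contact together with every digitized
#' sample as a bit field, one bit per electrode (RL, LL, LA, RA, V2 from the
#' least significant bit); a set bit means the electrode is faulty. The
#' mapping is direct, with no hysteresis.
#'
#' @param status_word Non-negative integer(s) below 32.
#' @return A named logical vector (or matrix for several words) of
#'   per-electrode fault flags.
#' @examples
#' leadoff_from_status(0b00001)  # RL fault only
#' @export
leadoff_from_status <- function(status_word) {
  if (any(status_word < 0 | status_word > 31 | status_word != round(status_word))) {
    stop("`status_word` must be an integer in [0, 31]", call. = FALSE)
  }
  out <- vapply(0:4, function(b) bitwAnd(as.integer(status_word), bitwShiftL(1L, b)) != 0L,
                logical(length(status_word)))
  if (length(status_word) == 1L) {
    out <- as.vector(out)
    names(out) <- ELECTRODES
  } else {
    colnames(out) <- ELECTRODES
  }
  out
}

#' Alarm engine state
#'
#' The monitor raises visual alarms for electrode faults, a disconnected
#' microSD card, a full card, an out-of-range heart rate (below 60 or above
#' 100 bpm) and a low battery; all but the low battery also sound the
#' buzzer. The heart-rate alarm is debounced: it raises only after
#' `hr_debounce` consecutive out-of-range updates, so a single ectopic beat
#' does not sound the alarm.
#'
#' @param hr_debounce Consecutive out-of-range beats required.
#' @param hr_range Acceptable heart-rate band in bpm.
#' @return An object of class `alarm_state` with logical fields
#'   `electrode_fault` (per electrode), `sd_disconnected`, `sd_full`,
#'   `hr_out_of_range`, `low_battery`, `buzzer_on`.
#' @export
alarm_state <- function(hr_debounce = 3L, hr_range = c(60, 100)) {
  structure(
    list(electrode_fault = stats::setNames(rep(FALSE, 5L), ELECTRODES),
         sd_disconnected = FALSE, sd_full = FALSE,
         hr_out_of_range = FALSE, low_battery = FALSE, buzzer_on = FALSE,
         hr_oor_count = 0L, hr_debounce = as.integer(hr_debounce),
         hr_range = hr_range),
    class = "alarm_state"
  )
}

#' Update the alarm engine
#'
#' Pure function of the inputs except for the heart-rate debounce counter
#' carried in the state. The buzzer sounds iff any electrode is faulty, the
#' microSD card is disconnected during acquisition, the card is full, or the
#' (debounced) heart rate is out of range; a low battery raises only the
#' visual alarm.
#'
#' @param state An [alarm_state()].
#' @param electrode_status Status word (see [leadoff_from_status()]) or a
#'   named logical vector of per-electrode faults.
#' @param sd_connected,sd_full,battery_low Logical device status inputs.
#' @param hr_bpm Latest heart rate of the selected lead, or `NA` if no beat
#'   has been measured yet.
#' @param acquiring Whether a recording acquisition is in progress (an SD
#'   disconnect only sounds the buzzer during acquisition).
#' @return The updated `alarm_state`.
#' @examples
#' st <- alarm_state()
#' st <- update_alarms(st, hr_bpm = 59)
#' st <- update_alarms(st, hr_bpm = 59)
#' st <- update_alarms(st, hr_bpm = 59)
#' st$buzzer_on
#' @export
update_alarms <- function(state, electrode_status = 0L, sd_connected = TRUE,
                          sd_full = FALSE, hr_bpm = NA_real_,
                          battery_low = FALSE, acquiring = TRUE) {
  stopifnot(inherits(state, "alarm_state"))
  if (is.numeric(electrode_status)) {
    electrode_status <- leadoff_from_status(electrode_status)
  }
  state$electrode_fault[] <- electrode_status[ELECTRODES]
  state$sd_disconnected <- !sd_connected
  state$sd_full <- isTRUE(sd_full)
  state$low_battery <- isTRUE(battery_low)

  oor <- !is.na(hr_bpm) && (hr_bpm < state$hr_range[1] || hr_bpm > state$hr_range[2])
  state$hr_oor_count <- if (oor) state$hr_oor_count + 1L else 0L
  state$hr_out_of_range <- state$hr_oor_count >= state$hr_debounce

  state$buzzer_on <- any(state$electrode_fault) ||
    (state$sd_disconnected && acquiring) ||
    state$sd_full || state$hr_out_of_range
  state
}
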