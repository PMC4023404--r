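#' Substrate buffering strengths
#'
#' The buffering strength of a compartment is the total substrate
#' concentration divided by the Michaelis constant of the ERK-substrate
#' interaction, `K_m = (k_off + k_cat) / k_on`:
#' `B_c = (Sc_tot / phi_c) / K_m,c` and `B_n = (Sn_tot / phi_n) / K_m,n`.
#' A compartment with buffering strength well above 1 sequesters most of its
#' free active ERK while unphosphorylated substrate remains.
#'
#' @param params an [erk_params()] object.
#' @return Named numeric vector `c(B_c, B_n)`.
#' @export
#' @examples
#' buffering_strengths(theta_ref())
buffering_strengths <- function(params) {
  b_for <- function(S_tot, phi, k_on, k_off, k_cat) {
    if (S_tot == 0) return(0)
    if (k_on == 0) {
      abort("k_on = 0 with positive substrate: buffering strength undefined")
    }
    (S_tot / phi) / ((k_off + k_cat) / k_on)
  }
  c(B_c = b_for(params$Sc_tot, 1 - params$phi_n,
                params$k_on_c, params$k_off_c, params$k_cat_c),
    B_n = b_for(params$Sn_tot, params$phi_n,
                params$k_on_n, params$k_off_n, params$k_cat_n))
}

#' Classify ensemble members by buffering mode
#'
#' Labels each accepted parameter set by which compartment provides the
#' dominant substrate buffering, following the two fitting modes seen in the
#' buffering-strength scatter: `nuclear_dominant` (B_c < 1 <= B_n),
#' `cytosolic_dominant` (B_c >= 1 and B_n < B_c), `unbuffered`
#' (B_c = B_n = 0), and `mixed` otherwise.  The B = 1 boundary is
#' configurable.
#'
#' @param ensemble an `erk_ensemble` from [ensemble_walk()], or a tibble with
#'   one log10-parameter column per free parameter.
#' @param boundary buffering-strength threshold separating "minimal" from
#'   "significant" buffering.
#' @return A tibble of class `erk_buffering`: one row per member with `B_c`,
#'   `B_n`, and `mode`.
#' @export
classify_modes <- function(ensemble, boundary = 1) {
  params <- ensemble_params(ensemble)
  bs <- purrr::map(params, buffering_strengths)
  out <- tibble(
    member = seq_along(bs),
    B_c = purrr::map_dbl(bs, "B_c"),
    B_n = purrr::map_dbl(bs, "B_n")
  )
  out$mode <- dplyr::case_when(
    out$B_c == 0 & out$B_n == 0 ~ "unbuffered",
    out$B_c < boundary & out$B_n >= boundary ~ "nuclear_dominant",
    out$B_c >= boundary & out$B_n < out$B_c ~ "cytosolic_dominant",
    TRUE ~ "mixed"
  )
  class(out) <- c("erk_buffering", class(out))
  out
}

#' ERK species breakdown per compartment
#'
#' Partitions total cellular ERK into the eight labeled pools used in the
#' buffering analysis: cytosolic unphosphorylated (`c`), mono- (`cp`) and
#' diphosphorylated (`cpp`), substrate-bound (`cs`), and their nuclear
#' counterparts (`n`, `np`, `npp`, `ns`).  Importin-bound nuclear diphospho
#' ERK (importin/combined variants) is counted in `npp`.  Fractions sum to 1
#' at every time point.
#'
#' @param traj an `erk_trajectory`.
#' @return A long tibble with columns `time_min`, `species`, `fraction`.
#' @export
species_breakdown <- function(traj) {
  wide <- tibble(
    time_min = traj$time_min,
    c   = traj$E0c, cp  = traj$E1c, cpp = traj$E2c, cs  = traj$EBc,
    n   = traj$E0n, np  = traj$E1n, npp = traj$E2n + traj$EIn, ns = traj$EBn
  )
  tidyr::pivot_longer(wide, -"time_min",
                      names_to = "species", values_to = "fraction")
}

# parameter sets of an ensemble as a list of erk_params
ensemble_params <- function(ensemble) {
  if (inherits(ensemble, "erk_params")) return(list(ensemble))
  fixed <- attr(ensemble, "fixed_params")
  free <- attr(ensemble, "free_names")
  if (is.null(fixed) || is.null(free)) {
    abort("ensemble lacks fixed_params/free_names attributes")
  }
  purrr::map(seq_len(nrow(ensemble)), function(i) {
    vals <- as.list(10^unlist(ensemble[i, free]))
    erk_params(.values = modifyList(unclass(fixed), vals))
  })
}

#' Prediction battery over an ensemble
#'
#' Simulates a set of protocols for every ensemble member (or a single
#' parameter set) and summarizes each requested readout as the pointwise
#' ensemble mean and standard deviation, plus half-decay times for protocols
#' with an inhibitor event.  Members whose simulation fails are dropped and
#' counted, never imputed.
#'
#' @param x an `erk_ensemble` or a single [erk_params()] object.
#' @param protocols named list of [erk_protocol()] objects.
#' @param readouts readout ids to report.
#' @param dt output sampling interval (min).
#' @param obs observation parameters.
#' @return A list of class `erk_predictions` with elements `traces` (tibble:
#'   protocol, readout, time_min, mean, sd, n), `t_half` (tibble: protocol,
#'   readout, member, t_half), and `n_failed`.
#' @export
run_predictions <- function(x, protocols,
                            readouts = c("nucloc", "ekar_nuc", "ekar_cyt",
                                         "ppERK_blot"),
                            dt = 1, obs = obs_params()) {
  params <- ensemble_params(x)
  traces <- list()
  thalf <- list()
  n_failed <- 0L
  for (pn in names(protocols)) {
    proto <- protocols[[pn]]
    grid <- seq(0, proto$t_end, by = dt)
    per_member <- purrr::map(seq_along(params), function(i) {
      tryCatch({
        tr <- erk_simulate(params[[i]], proto, t_grid = grid)
        ob <- erk_observe(tr, obs = obs, readouts = readouts)
        ob$member <- i
        ob
      }, error = function(e) NULL)
    })
    failed <- purrr::map_lgl(per_member, is.null)
    n_failed <- n_failed + sum(failed)
    ob_all <- dplyr::bind_rows(per_member[!failed])
    ob_all$protocol <- pn
    traces[[pn]] <- ob_all |>
      dplyr::group_by(.data$protocol, .data$readout, .data$time_min) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n = dplyr::n(), .groups = "drop")
    t_i <- proto$u0126_time
    if (!is.na(t_i)) {
      thalf[[pn]] <- ob_all |>
        dplyr::group_by(.data$readout, .data$member) |>
        dplyr::summarise(
          t_half = t_half(dplyr::pick("time_min", "value"), t_i, 1),
          .groups = "drop") |>
        dplyr::mutate(protocol = pn, .before = 1)
    }
  }
  structure(list(traces = dplyr::bind_rows(traces),
                 t_half = dplyr::bind_rows(thalf),
                 n_failed = n_failed),
            class = "erk_predictions")
}

#' @export
print.erk_predictions <- function(x, ...) {
  cat("<erk_predictions>\n")
  cat("traces:", nrow(x$traces), "rows;",
      dplyr::n_distinct(x$traces$protocol), "protocol(s)\n")
  if (nrow(x$t_half)) {
    s <- x$t_half |>
      dplyr::group_by(.data$protocol, .data$readout) |>
      dplyr::summarise(mean_t_half = mean(.data$t_half, na.rm = TRUE),
                       sd_t_half = sd(.data$t_half, na.rm = TRUE),
                       .groups = "drop")
    print(s)
  }
  if (x$n_failed) cat("members dropped (simulation failure):", x$n_failed, "\n")
  invisible(x)
}

#' Default prediction protocols
#'
#' The dose step-up (half-maximal input for 30 min, then maximal) and the
#' inhibition-timing battery (MEK inhibitor at 5, 10, 20, and 46 min after a
#' maximal step).
#'
#' @param t_end simulation end (min).
#' @return Named list of [erk_protocol()] objects.
#' @export
prediction_protocols <- function(t_end = 75) {
  c(list(dose_step = protocol_dose_step(S1 = 0.5, S2 = 1, t_step = 30,
                                        t_end = t_end)),
    setNames(
      lapply(c(5, 10, 20, 46), function(ti)
        protocol_u0126(t_inhibit = ti, t_end = ti + 29)),
      paste0("u0126_", c(5, 10, 20, 46), "min")
    ))
}
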