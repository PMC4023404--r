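#' Observation-model parameters
#'
#' Parameters of the maps from model state to experimental readouts.  The
#' FRET-reporter readouts (EKAR) track free diphospho ERK in the target
#' compartment through an affine map with basal offset `rho_c`/`rho_n`
#' followed by normalization to the pre-stimulus value; `rho_e` plays the
#' same role for the substrate-phosphorylation readouts.  `s_d` are
#' arbitrary-unit gains for blot/mass-spectrometry readouts (one per dataset;
#' at fitting time the gain is profiled out analytically, so the default of 1
#' only affects displayed units).
#'
#' @param rho_c,rho_n basal-signal offsets for the cytosolic/nuclear EKAR
#'   readouts (concentration units, total-ERK equivalents); must be > 0.
#' @param rho_e basal offset for substrate-phosphorylation readouts.
#' @param s_d arbitrary-unit gain for blot/MS readouts.
#' @return An object of class `erk_obs_params`.
#' @export
obs_params <- function(rho_c = 0.25, rho_n = 0.25, rho_e = 0.1, s_d = 1) {
  stopifnot(rho_c > 0, rho_n > 0, rho_e > 0, s_d > 0)
  structure(list(rho_c = rho_c, rho_n = rho_n, rho_e = rho_e, s_d = s_d),
            class = "erk_obs_params")
}

# readout ids understood by erk_observe()
.erk_readouts <- c("ppMEK_blot", "ppERK_blot", "ms_ppERK", "ms_pERK",
                   "nucloc", "ekar_cyt", "ekar_nuc", "sub_c_phos", "sub_n_phos")

# readouts reported in arbitrary units (gain profiled out at fitting time);
# the others are self-normalized to their pre-stimulus value
.arb_unit_readouts <- c("ppMEK_blot", "ppERK_blot", "ms_ppERK", "ms_pERK")

#' Map a trajectory to experimental readouts
#'
#' Computes the model counterparts of the measured readouts:
#' \describe{
#'   \item{ppMEK_blot}{`s_d * M2` (dual-phospho-specific MEK antibody).}
#'   \item{ppERK_blot, ms_ppERK}{`s_d * (E2c + EBc + E2n + EBn + EIn)` --
#'     whole-cell diphospho ERK includes free and substrate-bound pools.}
#'   \item{ms_pERK}{`s_d * (E1c + E1n)` (mono-phospho ERK).}
#'   \item{nucloc}{mean nuclear ERK concentration over mean whole-cell ERK
#'     concentration (= 1 by construction), normalized to its pre-stimulus
#'     value.}
#'   \item{ekar_cyt, ekar_nuc}{affine map of free diphospho ERK concentration
#'     in the compartment, normalized to the pre-stimulus value.}
#'   \item{sub_c_phos, sub_n_phos}{affine map of phosphorylated substrate,
#'     normalized to the pre-stimulus value.}
#' }
#' All self-normalized readouts equal 1 at t = 0 exactly.
#'
#' @param traj an `erk_trajectory` from [erk_simulate()]; must include t = 0.
#' @param obs an [obs_params()] object.
#' @param readouts character vector of readout ids to compute.
#' @return A tibble with columns `readout`, `time_min`, `value`.
#' @export
#' @examples
#' tr <- erk_simulate(theta_ref(), protocol_step(S = 1, t_end = 20))
#' erk_observe(tr, readouts = "nucloc")
erk_observe <- function(traj, obs = obs_params(), readouts = .erk_readouts) {
  readouts <- match.arg(readouts, .erk_readouts, several.ok = TRUE)
  if (!any(traj$time_min == 0)) {
    abort("trajectory must include the pre-stimulus point t = 0")
  }
  p <- attr(traj, "params")
  phi_n <- p$phi_n
  phi_c <- 1 - phi_n
  i0 <- which(traj$time_min == 0)[1]

  norm0 <- function(x, label) {
    if (x[i0] <= 0) {
      abort(paste0("zero pre-stimulus denominator for ", label,
                   " (S_basal = 0 with k_pass = 0?)"))
    }
    x / x[i0]
  }

  vals <- list()
  for (r in readouts) {
    v <- switch(r,
      ppMEK_blot = obs$s_d * traj$M2,
      ppERK_blot = ,
      ms_ppERK   = obs$s_d * (traj$E2c + traj$EBc + traj$E2n + traj$EBn + traj$EIn),
      ms_pERK    = obs$s_d * (traj$E1c + traj$E1n),
      nucloc     = norm0((traj$E0n + traj$E1n + traj$E2n + traj$EBn + traj$EIn) / phi_n,
                         "nucloc"),
      ekar_cyt   = norm0(obs$rho_c + traj$E2c / phi_c, "ekar_cyt"),
      ekar_nuc   = norm0(obs$rho_n + traj$E2n / phi_n, "ekar_nuc"),
      sub_c_phos = norm0(obs$rho_e + traj$Pc, "sub_c_phos"),
      sub_n_phos = norm0(obs$rho_e + traj$Pn, "sub_n_phos")
    )
    vals[[r]] <- tibble(readout = r, time_min = traj$time_min, value = v)
  }
  dplyr::bind_rows(vals)
}

#' Half-decay time after inhibition
#'
#' The decay statistic used for inhibitor experiments: the elapsed time after
#' inhibitor addition at which the readout first crosses halfway between the
#' value just prior to inhibition and the pre-stimulus baseline, located by
#' linear interpolation between the bracketing samples.
#'
#' @param trace a tibble with columns `time_min` and `value` (a single
#'   readout), sampled at/after `t_inhibit`.
#' @param t_inhibit inhibitor addition time (min).
#' @param baseline pre-stimulus baseline value (1 for self-normalized
#'   readouts).
#' @return Elapsed time in min, or `NA_real_` (with attribute
#'   `no_decay = TRUE`) if the trace never reaches the half level.
#' @export
#' @examples
#' tr <- tibble::tibble(time_min = c(46, 48, 50), value = c(2.0, 1.6, 1.2))
#' t_half(tr, t_inhibit = 46, baseline = 1)   # 2.5 min
t_half <- function(trace, t_inhibit, baseline = 1) {
  stopifnot(all(c("time_min", "value") %in% names(trace)))
  trace <- trace[order(trace$time_min), ]
  pre_idx <- which(trace$time_min <= t_inhibit)
  if (!length(pre_idx)) abort("trace has no sample at or before t_inhibit")
  pre <- trace$value[max(pre_idx)]
  if (pre <= baseline) {
    abort("value just prior to inhibition must exceed the baseline")
  }
  half <- (pre + baseline) / 2
  post <- trace[trace$time_min >= t_inhibit, ]
  below <- which(post$value <= half)
  if (!length(below)) {
    return(structure(NA_real_, no_decay = TRUE))
  }
  j <- below[1]
  if (j == 1) return(post$time_min[1] - t_inhibit)
  t1 <- post$time_min[j - 1]; y1 <- post$value[j - 1]
  t2 <- post$time_min[j];     y2 <- post$value[j]
  tc <- t1 + (y1 - half) / (y1 - y2) * (t2 - t1)
  tc - t_inhibit
}
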