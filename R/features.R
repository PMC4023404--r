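#' Kinetic feature summary of a parameter set
#'
#' Simulates the standard stimulation and inhibition protocols and extracts
#' the scalar kinetic features used to characterize the model response:
#' timing and degree of adaptation of nuclear localization and whole-cell
#' phosphorylation, rise time of free nuclear ERK activity, and half-decay
#' times after MEK inhibition imposed early (10 min) versus at quasi-steady
#' state (46 min).
#'
#' @param params an [erk_params()] object.
#' @param obs observation parameters.
#' @param dt_thalf sampling interval (min) for the inhibition traces used by
#'   the half-decay statistic.
#' @return Named numeric vector with elements:
#' \describe{
#'   \item{nucloc_peak_t}{time (min) of the nuclear-localization maximum
#'     after a maximal step (0.5-min output grid).}
#'   \item{nucloc_peak, nucloc_adapt}{peak value and fractional decay of the
#'     peak-above-baseline by 75 min.}
#'   \item{ekar_nuc_t90}{time (min) for nuclear ERK activity to first reach
#'     90% of its 60-min value above baseline.}
#'   \item{ekar_nuc_60, ekar_nuc_adapt}{60-min value and fractional
#'     adaptation of the nuclear activity readout.}
#'   \item{ekar_cyt_peak_t, ekar_cyt_decay}{cytosolic activity peak time and
#'     fractional decay of its peak-above-baseline.}
#'   \item{ppMEK_peak_t, ppERK_peak_t, ppERK_adapt}{blot readout timing and
#'     adaptation.}
#'   \item{th46_nucloc, th46_ekar_nuc, th46_ekar_cyt}{half-decay times (min)
#'     after MEK inhibition at 46 min.}
#'   \item{th10_nucloc, th10_ekar_nuc}{half-decay times after inhibition at
#'     10 min.}
#'   \item{th_ratio_nucloc}{th10_nucloc / th46_nucloc.}
#'   \item{B_c, B_n}{substrate buffering strengths.}
#' }
#' @export
#' @examples
#' \donttest{
#' kinetic_features(theta_ref())[c("nucloc_peak_t", "ekar_nuc_t90")]
#' }
kinetic_features <- function(params, obs = obs_params(), dt_thalf = 1) {
  tr <- erk_simulate(params, protocol_step(S = 1, t_end = 75),
                     t_grid = seq(0, 75, by = 0.5))
  ob <- erk_observe(tr, obs = obs,
                    readouts = c("nucloc", "ekar_nuc", "ekar_cyt",
                                 "ppMEK_blot", "ppERK_blot"))
  g <- function(r) ob[ob$readout == r, ]
  nl <- g("nucloc"); en <- g("ekar_nuc"); ec <- g("ekar_cyt")
  pm <- g("ppMEK_blot"); pe <- g("ppERK_blot")

  v60 <- en$value[en$time_min == 60]
  t90 <- en$time_min[which(en$value >= 1 + 0.9 * (v60 - 1))[1]]
  i_end <- which(nl$time_min == 75)

  th <- function(t_i, readouts) {
    tr2 <- erk_simulate(params, protocol_u0126(t_inhibit = t_i, t_end = t_i + 29),
                        t_grid = seq(0, t_i + 29, by = dt_thalf))
    ob2 <- erk_observe(tr2, obs = obs, readouts = readouts)
    vapply(readouts, function(r)
      t_half(ob2[ob2$readout == r, ], t_inhibit = t_i, baseline = 1),
      numeric(1))
  }
  th46 <- th(46, c("nucloc", "ekar_nuc", "ekar_cyt"))
  th10 <- th(10, c("nucloc", "ekar_nuc"))
  bs <- buffering_strengths(params)

  c(nucloc_peak_t  = nl$time_min[which.max(nl$value)],
    nucloc_peak    = max(nl$value),
    nucloc_adapt   = (max(nl$value) - nl$value[i_end]) / (max(nl$value) - 1),
    ekar_nuc_t90   = t90,
    ekar_nuc_60    = v60,
    ekar_nuc_adapt = (max(en$value) - v60) / (max(en$value) - 1),
    ekar_cyt_peak_t = ec$time_min[which.max(ec$value)],
    ekar_cyt_decay = (max(ec$value) - ec$value[i_end]) / (max(ec$value) - 1),
    ppMEK_peak_t   = pm$time_min[which.max(pm$value)],
    ppERK_peak_t   = pe$time_min[which.max(pe$value)],
    ppERK_adapt    = 1 - pe$value[nrow(pe)] / max(pe$value),
    th46_nucloc    = unname(th46["nucloc"]),
    th46_ekar_nuc  = unname(th46["ekar_nuc"]),
    th46_ekar_cyt  = unname(th46["ekar_cyt"]),
    th10_nucloc    = unname(th10["nucloc"]),
    th10_ekar_nuc  = unname(th10["ekar_nuc"]),
    th_ratio_nucloc = unname(th10["nucloc"] / th46["nucloc"]),
    B_c = unname(bs["B_c"]),
    B_n = unname(bs["B_n"]))
}
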