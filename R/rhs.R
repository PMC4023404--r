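#' Model right-hand side (reference R implementation)
#'
#' Time derivative of the model state.  This pure-R implementation mirrors the
#' compiled version used by the adaptive integrator and is kept as an
#' independent reference: the steady-state Newton solve and the fixed-step
#' RK4 oracle both use it, so agreement between [erk_simulate()] and
#' [erk_simulate_rk4()] cross-checks the two code paths.
#'
#' State components (amounts; ERK and substrate pools as fractions of total
#' cellular ERK): MEK phospho-forms `M0, M1, M2`; feedback desensitization
#' `D`; free cytosolic ERK `E0c, E1c, E2c` and substrate-bound `EBc`; free
#' nuclear ERK `E0n, E1n, E2n`, substrate-bound `EBn`, importin-bound `EIn`;
#' phosphorylated substrate `Pc, Pn`.
#'
#' @param t time (min); unused except for signature compatibility.
#' @param state named numeric state vector (see [initial_state()]).
#' @param params an [erk_params()] object.
#' @param u input strength in effect.
#' @param inh 1 normally, 0 after U0126 (zeroes ERK phosphorylation fluxes).
#' @param pho 1 normally, 0 after okadaic acid (zeroes ERK- and
#'   substrate-dephosphorylation fluxes).
#' @param variant model variant tag.
#' @param m2_clamp clamped active-MEK level (constant-MEK variant only).
#' @return Named numeric vector of time derivatives.
#' @export
erk_rhs <- function(t, state, params, u, inh = 1, pho = 1, variant = "full",
                    m2_clamp = 0) {
  p <- .variant_params(params, variant)
  s <- as.list(state)
  phi_c <- 1 - p$phi_n

  free_Sc <- p$Sc_tot - s$Pc - s$EBc
  free_Sn <- p$Sn_tot - s$Pn - s$EBn
  if (free_Sc < -1e-8 || free_Sn < -1e-8) {
    abort("invariant violation: negative free-substrate pool")
  }

  M2_eff <- if (.variant_constmek(variant)) m2_clamp else s$M2
  fb <- if (p$fb_mode > 0.5) 1 / (1 + (s$E2c / p$fb_K)^p$fb_h) else 1 - s$D
  v  <- p$a_M * u * fb
  p1 <- inh * p$a_E1 * M2_eff
  p2 <- inh * p$a_E2 * M2_eff
  b_c <- p$k_on_c * s$E2c * free_Sc / phi_c
  b_n <- p$k_on_n * s$E2n * free_Sn / p$phi_n

  flux_nuc <- (p$k_in + p$k_pass) * s$E2c
  importin <- .variant_importin(variant)
  J_nuc_in <- if (importin) p$k_rel * s$EIn else flux_nuc

  d <- c(
    M0 = -v * s$M0 + p$d_M * s$M1,
    M1 =  v * s$M0 - v * s$M1 - p$d_M * s$M1 + p$d_M * s$M2,
    M2 =  v * s$M1 - p$d_M * s$M2,
    D  = if (p$fb_mode > 0.5) 0 else p$k_fb * s$E2c * (1 - s$D) - p$k_rec * s$D,
    E0c = -p1 * s$E0c + pho * p$d_c1 * s$E1c - p$k_pass * s$E0c + p$k_out * s$E0n,
    E1c =  p1 * s$E0c - p2 * s$E1c - pho * p$d_c1 * s$E1c + pho * p$d_c2 * s$E2c -
           p$k_pass * s$E1c + p$k_out * s$E1n,
    E2c =  p2 * s$E1c - pho * p$d_c2 * s$E2c - flux_nuc + p$k_out * s$E2n -
           b_c + p$k_off_c * s$EBc + p$k_cat_c * s$EBc,
    EBc =  b_c - p$k_off_c * s$EBc - p$k_cat_c * s$EBc,
    E0n =  p$k_pass * s$E0c + pho * p$d_n1 * s$E1n - p$k_out * s$E0n,
    E1n =  p$k_pass * s$E1c - pho * p$d_n1 * s$E1n + pho * p$d_n2 * s$E2n -
           p$k_out * s$E1n,
    E2n =  J_nuc_in - pho * p$d_n2 * s$E2n - p$k_out * s$E2n -
           b_n + p$k_off_n * s$EBn + p$k_cat_n * s$EBn,
    EBn =  b_n - p$k_off_n * s$EBn - p$k_cat_n * s$EBn,
    EIn =  if (importin) flux_nuc - p$k_rel * s$EIn else 0,
    Pc  =  p$k_cat_c * s$EBc - pho * p$k_sdp_c * s$Pc,
    Pn  =  p$k_cat_n * s$EBn - pho * p$k_sdp_n * s$Pn
  )
  if (.variant_constmek(variant)) d[c("M0", "M1", "M2", "D")] <- 0
  d
}
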