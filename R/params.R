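#' @useDynLib erkshuttle
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort .data `%||%`
#' @importFrom stats approx optim rnorm runif sd setNames median qchisq quantile
#' @importFrom utils modifyList
NULL

# names of kinetic/geometry parameters, in the order expected by the compiled
# right-hand side (src/erk_rhs.c); the remaining slots (u, inh, pho, importin,
# const_mek, m2_clamp) are appended per protocol segment at simulation time.
.erk_parm_order <- c(
  "a_M", "d_M", "k_fb", "k_rec", "a_E1", "a_E2",
  "d_c1", "d_c2", "d_n1", "d_n2",
  "k_in", "k_pass", "k_out",
  "k_on_c", "k_off_c", "k_cat_c", "k_sdp_c",
  "k_on_n", "k_off_n", "k_cat_n", "k_sdp_n",
  "Sc_tot", "Sn_tot", "phi_n", "k_rel",
  "fb_mode", "fb_K", "fb_h"
)

.erk_state_names <- c(
  "M0", "M1", "M2", "D",
  "E0c", "E1c", "E2c", "EBc",
  "E0n", "E1n", "E2n", "EBn", "EIn",
  "Pc", "Pn"
)

.erk_variants <- c("full", "control", "importin", "combined", "constant_mek")

#' Kinetic model parameters
#'
#' Constructs the full parameter set of the compartmental ERK model: two-site
#' MEK and ERK phosphorylation in the cytosol, ERK-driven desensitization of
#' MEK phosphorylation (negative feedback), nucleocytoplasmic shuttling
#' (facilitated import of free diphospho ERK, passive shuttling of all free
#' states, phospho-independent export), and reversible anchoring of diphospho
#' ERK by one dominant substrate per compartment, which protects bound ERK
#' from phosphatases.
#'
#' All rates are first-order coefficients in 1/min except the association
#' coefficients `k_on_c`, `k_on_n` (per concentration per min, concentrations
#' in total-ERK-equivalent amounts per unit compartment volume).  ERK and
#' substrate pools are amounts as fractions of total cellular ERK; `phi_n` is
#' the nuclear volume fraction.
#'
#' @param ... named parameter values overriding the defaults.
#' @param .values optional named list of overrides (merged after `...`).
#' @return An object of class `erk_params` (named list).
#' @export
#' @examples
#' p <- erk_params(Sn_tot = 0.4)
#' p$Sn_tot
erk_params <- function(..., .values = NULL) {
  defaults <- list(
    a_M = 1, d_M = 0.5,
    k_fb = 10, k_rec = 0.05,
    a_E1 = 4, a_E2 = 4,
    d_c1 = 1.5, d_c2 = 1.5, d_n1 = 1.5, d_n2 = 1,
    k_in = 1.5, k_pass = 0.15, k_out = 2,
    k_on_c = 1, k_off_c = 5, k_cat_c = 5, k_sdp_c = 5,
    k_on_n = 34.4, k_off_n = 4, k_cat_n = 0.3, k_sdp_n = 0.02,
    Sc_tot = 0.05, Sn_tot = 0.5,
    phi_n = 0.2, k_rel = 10,
    fb_mode = 0, fb_K = 0.05, fb_h = 2,
    M2_const = 0.25, S_basal = 0.02
  )
  over <- c(list(...), .values)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    defaults <- modifyList(defaults, over)
  }
  p <- structure(defaults, class = "erk_params")
  validate_erk_params(p)
  p
}

#' @export
print.erk_params <- function(x, ...) {
  cat("<erk_params>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model: non-negative rates and
#' pool sizes, nuclear volume fraction strictly inside (0, 1).
#'
#' @param p an `erk_params` object.
#' @return `p`, invisibly; aborts with a message naming the offending field.
#' @export
validate_erk_params <- function(p) {
  vals <- unlist(unclass(p))
  need <- c(.erk_parm_order, "M2_const", "S_basal")
  miss <- setdiff(need, names(vals))
  if (length(miss)) abort(paste0("missing parameter(s): ", paste(miss, collapse = ", ")))
  neg <- names(vals)[vals < 0 | !is.finite(vals)]
  if (length(neg)) abort(paste0("parameters must be finite and >= 0: ", paste(neg, collapse = ", ")))
  if (p$phi_n <= 0 || p$phi_n >= 1) abort("phi_n must satisfy 0 < phi_n < 1")
  if (!p$fb_mode %in% c(0, 1)) abort("fb_mode must be 0 (dynamic) or 1 (instantaneous Hill)")
  if (p$fb_K <= 0) abort("fb_K must be > 0")
  invisible(p)
}

# numeric vector for the compiled rhs, given segment context
.parm_vector <- function(p, u, inh = 1, pho = 1, importin = FALSE,
                         const_mek = FALSE, m2_clamp = 0) {
  c(unlist(p[.erk_parm_order], use.names = FALSE),
    u, inh, pho, as.numeric(importin), as.numeric(const_mek), m2_clamp)
}

# apply variant conventions to a parameter set (control: no substrate)
.variant_params <- function(p, variant) {
  variant <- match.arg(variant, .erk_variants)
  if (variant == "control") {
    p$Sc_tot <- 0
    p$Sn_tot <- 0
  }
  p
}

.variant_importin <- function(variant) variant %in% c("importin", "combined")
.variant_constmek <- function(variant) variant == "constant_mek"

#' Serialize parameters or a protocol to YAML or JSON
#'
#' Flat-key serialization; the format is chosen from the file extension
#' (`.yml`/`.yaml` or `.json`).
#'
#' @param x an `erk_params` or `erk_protocol` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
erk_write <- function(x, path) {
  obj <- if (inherits(x, "erk_protocol")) {
    list(kind = "erk_protocol",
         t_start = x$segments$t_start, S = x$segments$S,
         u0126_time = x$u0126_time, okadaic_time = x$okadaic_time,
         t_end = x$t_end, variant = x$variant,
         u0126_factor = x$u0126_factor, okadaic_factor = x$okadaic_factor)
  } else {
    c(list(kind = "erk_params"), unclass(x))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Read parameters or a protocol written by [erk_write()]
#'
#' @param path file path (`.yml`/`.yaml` or `.json`).
#' @return An `erk_params` or `erk_protocol` object, per the file's `kind`.
#' @export
erk_read <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  kind <- obj$kind %||% "erk_params"
  obj$kind <- NULL
  if (kind == "erk_protocol") {
    erk_protocol(
      segments = tibble(t_start = unlist(obj$t_start), S = unlist(obj$S)),
      u0126_time = obj$u0126_time, okadaic_time = obj$okadaic_time,
      t_end = obj$t_end, variant = obj$variant,
      u0126_factor = obj$u0126_factor %||% 0,
      okadaic_factor = obj$okadaic_factor %||% 0
    )
  } else {
    erk_params(.values = obj)
  }
}

#' Packaged reference parameter set
#'
#' The frozen reference parameter set used throughout the package to generate
#' synthetic data and to anchor the acceptance checks.  It was calibrated once
#' (script in `inst/scripts/derive_theta_ref.R`) so that the full model
#' reproduces the qualitative kinetic features of PDGF-stimulated fibroblasts:
#' a nuclear-localization peak within 10 min followed by strong adaptation,
#' fast near-complete adaptation of whole-cell diphospho ERK, an early
#' (4-5 min) cytosolic ERK-activity peak with modest decay, slow (~20 min)
#' non-adapting accumulation of free nuclear ERK activity, sub-2-min decay of
#' ERK activity after MEK inhibition at quasi-steady state, and roughly
#' 3-4-fold slower decay when inhibition is imposed at 10 min.  Nuclear
#' substrate buffering strength is in the nuclear-dominant regime
#' (B_n ~ 20, B_c < 1).
#'
#' @return An `erk_params` object.
#' @export
#' @examples
#' buffering_strengths(theta_ref())
theta_ref <- function() {
  erk_params(.values = .theta_ref_values)
}
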