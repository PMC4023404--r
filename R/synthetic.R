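#' Experimental design description
#'
#' A design bundles everything needed to emulate one experiment: the
#' stimulation/inhibition protocol, the readouts measured, the sampling grid,
#' the replicate count, and the noise model.  Population readouts (blot, mass
#' spectrometry) receive multiplicative lognormal measurement noise;
#' single-cell imaging readouts additionally draw per-cell parameter jitter
#' on amplitude-like parameters before simulation, emulating cell-to-cell
#' variability.
#'
#' @param id experiment identifier.
#' @param protocol an [erk_protocol()].
#' @param readouts readout ids measured in this experiment.
#' @param t_grid sampling times (min); must include 0.
#' @param n_rep replicate (or cell) count, >= 1.
#' @param noise_cv multiplicative measurement noise CV (>= 0).
#' @param jitter_cv per-cell parameter jitter CV (single-cell designs).
#' @param kind `"population"` or `"single_cell"`.
#' @param role `"fit"` for designs entering the cost function, `"predict"`
#'   for held-out prediction experiments.
#' @return An object of class `erk_design`.
#' @export
erk_design <- function(id, protocol, readouts, t_grid, n_rep,
                       noise_cv = 0.2, jitter_cv = 0,
                       kind = c("population", "single_cell"),
                       role = c("fit", "predict")) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  readouts <- match.arg(readouts, .erk_readouts, several.ok = TRUE)
  stopifnot(n_rep >= 1, noise_cv >= 0, jitter_cv >= 0)
  if (!0 %in% t_grid) abort("design time grid must include the pre-stimulus point t = 0")
  structure(list(id = id, protocol = protocol, readouts = readouts,
                 t_grid = sort(unique(t_grid)), n_rep = as.integer(n_rep),
                 noise_cv = noise_cv, jitter_cv = jitter_cv,
                 kind = kind, role = role),
            class = "erk_design")
}

#' Default experiment designs
#'
#' The packaged set of designs emulating the fitted experiments (quantitative
#' immunoblot and mass-spectrometry timecourses of MEK/ERK phosphorylation,
#' single-cell nuclear localization and cytosolic/nuclear ERK activity
#' traces, and MEK inhibition at quasi-steady state) plus the held-out
#' prediction experiments (dose step-up, MEK inhibition at 10 and 46 min).
#'
#' @return Named list of [erk_design()] objects; the `role` field separates
#'   fitted from prediction designs.
#' @export
#' @examples
#' names(default_designs())
#' default_designs()$blot$n_rep
default_designs <- function() {
  blot_grid <- c(0, 2, 5, 10, 15, 30, 45, 60, 90, 120)
  img_grid <- seq(0, 75, by = 2)
  step1_120 <- protocol_step(S = 1, t_end = 120)
  step1_75 <- protocol_step(S = 1, t_end = 75)
  u46 <- protocol_u0126(t_inhibit = 46, t_end = 75)
  list(
    blot = erk_design("blot", step1_120, c("ppMEK_blot", "ppERK_blot"),
                      blot_grid, n_rep = 3, noise_cv = 0.2),
    ms = erk_design("ms", step1_120, c("ms_ppERK", "ms_pERK"),
                    blot_grid, n_rep = 3, noise_cv = 0.2),
    gfp_nucloc = erk_design("gfp_nucloc", step1_75, "nucloc", img_grid,
                            n_rep = 10, noise_cv = 0.05, jitter_cv = 0.15,
                            kind = "single_cell"),
    imaging_cyt = erk_design("imaging_cyt", step1_75,
                             c("nucloc", "ekar_cyt"), img_grid,
                             n_rep = 8, noise_cv = 0.05, jitter_cv = 0.15,
                             kind = "single_cell"),
    imaging_nuc = erk_design("imaging_nuc", step1_75,
                             c("nucloc", "ekar_nuc"), img_grid,
                             n_rep = 6, noise_cv = 0.05, jitter_cv = 0.15,
                             kind = "single_cell"),
    u0126_cyt = erk_design("u0126_cyt", u46, "ekar_cyt", img_grid,
                           n_rep = 10, noise_cv = 0.05, jitter_cv = 0.15,
                           kind = "single_cell"),
    u0126_nuc = erk_design("u0126_nuc", u46, "ekar_nuc", img_grid,
                           n_rep = 9, noise_cv = 0.05, jitter_cv = 0.15,
                           kind = "single_cell"),
    dose_step = erk_design("dose_step", protocol_dose_step(t_end = 75),
                           c("nucloc", "ekar_cyt"), img_grid,
                           n_rep = 8, noise_cv = 0.05, jitter_cv = 0.15,
                           kind = "single_cell", role = "predict"),
    u0126_early = erk_design("u0126_early",
                             protocol_u0126(t_inhibit = 10, t_end = 39),
                             c("nucloc", "ekar_nuc"), seq(0, 39, by = 2),
                             n_rep = 10, noise_cv = 0.05, jitter_cv = 0.15,
                             kind = "single_cell", role = "predict"),
    u0126_late = erk_design("u0126_late", u46, c("nucloc", "ekar_nuc"),
                            img_grid, n_rep = 9, noise_cv = 0.05,
                            jitter_cv = 0.15, kind = "single_cell",
                            role = "predict")
  )
}

# parameters receiving per-cell lognormal jitter in single-cell designs
.jitter_params <- c("a_M", "a_E1", "a_E2", "Sn_tot", "Sc_tot")

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# mean-one multiplicative lognormal factors with coefficient of variation cv
.lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic dataset for one design
#'
#' Simulates the design's protocol at the generating parameter set and adds
#' the design's noise: population readouts get multiplicative lognormal
#' measurement noise; single-cell readouts simulate each cell with lognormal
#' jitter on the amplitude-like parameters (`a_M`, `a_E1`, `a_E2`, `Sn_tot`,
#' `Sc_tot`) plus measurement noise, and each self-normalized trace is
#' renormalized to its own t = 0 value after noise injection (as in per-cell
#' normalization of imaging data).  Deterministic given `seed`.
#'
#' @param theta generating [erk_params()] (defaults to [theta_ref()]).
#' @param design an [erk_design()].
#' @param seed integer seed (recorded in the output's metadata).
#' @param obs observation parameters.
#' @return A tibble of class `erk_dataset` with columns `experiment_id`,
#'   `readout`, `time_min`, `replicate`, `value`, `sigma`, and attributes
#'   `design`, `seed`, `theta_hash`.
#' @export
#' @examples
#' d <- generate_dataset(theta_ref(), default_designs()$blot, seed = 1)
#' head(d)
generate_dataset <- function(theta = theta_ref(), design, seed, obs = obs_params()) {
  stopifnot(inherits(design, "erk_design"))
  if (missing(seed) || is.null(seed)) abort("a seed is required for dataset generation")
  norm_readouts <- setdiff(design$readouts, .arb_unit_readouts)

  rows <- .with_seed(seed, {
    if (design$kind == "population") {
      tr <- erk_simulate(theta, design$protocol, t_grid = design$t_grid)
      truth <- erk_observe(tr, obs = obs, readouts = design$readouts)
      purrr::map(seq_len(design$n_rep), function(r) {
        v <- truth$value * .lnorm_factor(nrow(truth), design$noise_cv)
        tibble(readout = truth$readout, time_min = truth$time_min,
               replicate = r, value = v)
      })
    } else {
      purrr::map(seq_len(design$n_rep), function(r) {
        th <- theta
        fac <- .lnorm_factor(length(.jitter_params), design$jitter_cv)
        for (i in seq_along(.jitter_params)) {
          th[[.jitter_params[i]]] <- th[[.jitter_params[i]]] * fac[i]
        }
        tr <- erk_simulate(th, design$protocol, t_grid = design$t_grid)
        cell <- erk_observe(tr, obs = obs, readouts = design$readouts)
        cell$value <- cell$value * .lnorm_factor(nrow(cell), design$noise_cv)
        # per-cell renormalization of self-normalized readouts
        cell <- cell |>
          dplyr::group_by(.data$readout) |>
          dplyr::mutate(value = ifelse(.data$readout %in% norm_readouts,
                                       .data$value / .data$value[.data$time_min == 0],
                                       .data$value)) |>
          dplyr::ungroup()
        tibble(readout = cell$readout, time_min = cell$time_min,
               replicate = r, value = cell$value)
      })
    }
  })

  cv_eff <- sqrt(design$noise_cv^2 + design$jitter_cv^2)
  out <- dplyr::bind_rows(rows)
  out <- tibble(experiment_id = design$id, out,
                sigma = pmax(cv_eff, 0.02) * pmax(abs(out$value), 0.05))
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  attr(out, "theta_hash") <- rlang::hash(unclass(theta))
  class(out) <- c("erk_dataset", class(out))
  out
}

#' Generate the packaged multi-experiment dataset
#'
#' Applies [generate_dataset()] to every design (default: the fitted designs
#' from [default_designs()]), with per-design seeds derived from `seed`.
#'
#' @param theta generating parameter set.
#' @param designs named list of designs.
#' @param seed integer master seed.
#' @param obs observation parameters.
#' @return An `erk_dataset` tibble spanning all designs, with attribute
#'   `designs` (the named design list) and `seed`.
#' @export
generate_datasets <- function(theta = theta_ref(), designs = NULL, seed,
                              obs = obs_params()) {
  if (is.null(designs)) {
    designs <- purrr::keep(default_designs(), ~ .x$role == "fit")
  }
  sets <- purrr::imap(designs, function(d, nm) {
    generate_dataset(theta, d, seed = seed + match(nm, names(designs)), obs = obs)
  })
  out <- dplyr::bind_rows(sets)
  attr(out, "designs") <- designs
  attr(out, "seed") <- seed
  attr(out, "theta_hash") <- rlang::hash(unclass(theta))
  class(out) <- c("erk_dataset", class(out))
  out
}

#' Write / read a dataset as CSV with a JSON metadata sidecar
#'
#' The CSV holds the observation rows; the sidecar (`<path>.meta.json`)
#' records the seed, the generating-parameter hash, and each design
#' (protocol, grids, replicate counts, noise model) so a dataset file is
#' self-describing.
#'
#' @param dataset an `erk_dataset`.
#' @param path CSV file path.
#' @return `path` (write) or an `erk_dataset` (read).
#' @export
write_dataset_csv <- function(dataset, path) {
  readr::write_csv(as_tibble(as.data.frame(dataset)), path)
  designs <- attr(dataset, "designs")
  if (is.null(designs) && !is.null(attr(dataset, "design"))) {
    designs <- list(attr(dataset, "design"))
    names(designs) <- designs[[1]]$id
  }
  meta <- list(
    seed = attr(dataset, "seed"),
    theta_hash = attr(dataset, "theta_hash"),
    designs = purrr::map(designs, function(d) {
      list(id = d$id, readouts = d$readouts, t_grid = d$t_grid,
           n_rep = d$n_rep, noise_cv = d$noise_cv, jitter_cv = d$jitter_cv,
           kind = d$kind, role = d$role,
           protocol = list(t_start = d$protocol$segments$t_start,
                           S = d$protocol$segments$S,
                           u0126_time = d$protocol$u0126_time,
                           okadaic_time = d$protocol$okadaic_time,
                           t_end = d$protocol$t_end,
                           variant = d$protocol$variant))
    })
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    designs <- purrr::map(meta$designs, function(m) {
      proto <- erk_protocol(
        segments = tibble(t_start = unlist(m$protocol$t_start),
                          S = unlist(m$protocol$S)),
        u0126_time = m$protocol$u0126_time %||% NA_real_,
        okadaic_time = m$protocol$okadaic_time %||% NA_real_,
        t_end = m$protocol$t_end, variant = m$protocol$variant)
      erk_design(m$id, proto, unlist(m$readouts), unlist(m$t_grid), m$n_rep,
                 m$noise_cv, m$jitter_cv, m$kind, m$role)
    })
    attr(out, "designs") <- designs
    attr(out, "seed") <- meta$seed
    attr(out, "theta_hash") <- meta$theta_hash
  }
  class(out) <- c("erk_dataset", class(out))
  out
}
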