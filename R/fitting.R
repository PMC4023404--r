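# default free-parameter sets per variant (fitted in log10 space)
.free_defaults <- function(variant = "full") {
  base <- c("a_M", "d_M", "k_fb", "k_rec", "a_E1", "a_E2",
            "d_c1", "d_c2", "d_n1", "d_n2", "k_in", "k_pass", "k_out")
  subs <- c("k_on_c", "k_off_c", "k_cat_c", "k_sdp_c",
            "k_on_n", "k_off_n", "k_cat_n", "k_sdp_n", "Sc_tot", "Sn_tot")
  switch(variant,
    control = base,
    importin = ,
    combined = c(base, subs, "k_rel"),
    constant_mek = c(setdiff(base, c("a_M", "d_M", "k_fb", "k_rec")),
                     "M2_const", subs),
    c(base, subs))
}

#' Fitting configuration
#'
#' Defines the weighted least-squares cost and the ensemble algorithm
#' settings: which parameters are free (sampled in log10 space), per-dataset
#' weights, the scale-factor policy (arbitrary-unit readouts get the
#' closed-form optimal gain; self-normalized readouts use gain 1), the
#' acceptance threshold rule `J <= J_min * (1 + epsilon)`, and the proposal
#' step width in log10 units.
#'
#' @param free character vector of free parameter names (default depends on
#'   `variant`).
#' @param weights named numeric vector of per-dataset weights (dataset =
#'   experiment/readout pair, names `"<experiment_id>.<readout>"`); unnamed
#'   datasets get weight 1.
#' @param epsilon ensemble acceptance tolerance (> 0).
#' @param step proposal step width, log10 units (scalar or named per free
#'   parameter).
#' @param variant model variant to fit.
#' @return An object of class `erk_cost_spec`.
#' @export
cost_spec <- function(free = NULL, weights = NULL, epsilon = 0.25,
                      step = 0.03, variant = "full") {
  variant <- match.arg(variant, .erk_variants)
  free <- free %||% .free_defaults(variant)
  stopifnot(epsilon > 0, all(step > 0))
  if (!is.null(weights)) stopifnot(all(weights > 0))
  structure(list(free = free, weights = weights, epsilon = epsilon,
                 step = step, variant = variant),
            class = "erk_cost_spec")
}

# simulate each unique protocol in the designs once, at the union grid of its
# experiments; returns model predictions aligned to the dataset rows
.model_values <- function(params, dataset, designs, variant) {
  key_of <- function(proto) rlang::hash(proto[c("segments", "u0126_time",
                                                "okadaic_time", "t_end")])
  ids <- unique(dataset$experiment_id)
  designs <- designs[purrr::map_chr(designs, "id") %in% ids]
  keys <- purrr::map_chr(designs, ~ key_of(.x$protocol))
  preds <- vector("list", length(designs))
  names(preds) <- purrr::map_chr(designs, "id")
  for (k in unique(keys)) {
    group <- designs[keys == k]
    grid <- sort(unique(c(0, unlist(purrr::map(group, "t_grid")))))
    t_end <- max(purrr::map_dbl(group, ~ .x$protocol$t_end))
    proto <- group[[which.max(purrr::map_dbl(group, ~ .x$protocol$t_end))]]$protocol
    tr <- erk_simulate(params, proto, t_grid = grid[grid <= t_end],
                       variant = variant)
    for (d in group) {
      preds[[d$id]] <- erk_observe(tr, readouts = d$readouts) |>
        dplyr::filter(.data$time_min %in% d$t_grid) |>
        dplyr::rename(model = "value")
    }
  }
  dplyr::bind_rows(preds, .id = "experiment_id")
}

#' Weighted least-squares cost across datasets
#'
#' `J = sum_d w_d sum_i (s_d m_i - y_i)^2 / sigma_i^2`, where `m_i` is the
#' model readout at the data time, and the gain `s_d` is, for arbitrary-unit
#' readouts (blot/MS), the closed-form optimum
#' `s_d* = sum(y m / sigma^2) / sum(m^2 / sigma^2)`, and 1 for
#' self-normalized readouts.  A simulation failure at the proposed parameter
#' set yields `Inf` (the proposal is rejected).
#'
#' @param params an [erk_params()] object.
#' @param dataset an `erk_dataset` (attributes may carry the designs).
#' @param designs named list of [erk_design()]s; defaults to the dataset's
#'   `designs` attribute.
#' @param spec an [cost_spec()] object.
#' @return Non-negative number (possibly `Inf`).
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(theta_ref(), default_designs()$blot, seed = 1)
#' erk_cost(theta_ref(), ds, designs = list(blot = default_designs()$blot))
#' }
erk_cost <- function(params, dataset, designs = NULL, spec = cost_spec()) {
  designs <- designs %||% attr(dataset, "designs")
  if (is.null(designs)) abort("designs must be supplied (or attached to the dataset)")
  pred <- tryCatch(
    .model_values(params, dataset, designs, spec$variant),
    error = function(e) NULL
  )
  if (is.null(pred)) return(Inf)
  df <- dplyr::inner_join(as_tibble(as.data.frame(dataset)), pred,
                          by = c("experiment_id", "readout", "time_min"))
  if (nrow(df) < nrow(dataset)) abort("dataset rows missing model predictions")
  groups <- df |> dplyr::group_by(.data$experiment_id, .data$readout)
  contrib <- groups |>
    dplyr::summarise(
      s_d = if (.data$readout[1] %in% .arb_unit_readouts) {
        sum(.data$value * .data$model / .data$sigma^2) /
          sum(.data$model^2 / .data$sigma^2)
      } else 1,
      J = sum((s_d * .data$model - .data$value)^2 / .data$sigma^2),
      .groups = "drop"
    )
  w <- rep(1, nrow(contrib))
  if (!is.null(spec$weights)) {
    nm <- paste(contrib$experiment_id, contrib$readout, sep = ".")
    w[nm %in% names(spec$weights)] <- spec$weights[nm[nm %in% names(spec$weights)]]
  }
  sum(w * contrib$J)
}

# pack/unpack free parameters <-> log10 vector
.pack <- function(params, free) log10(unlist(params[free], use.names = TRUE))
.unpack <- function(x, free, template) {
  for (i in seq_along(free)) template[[free[i]]] <- unname(10^x[i])
  template
}

# Metropolis annealing on an arbitrary cost closure over a numeric vector;
# the public fit_anneal() wraps this around the model cost in log10 space
.anneal_core <- function(J_fun, x0, step, seed, n_iter, t0, cooling) {
  .with_seed(seed, {
    cur_x <- x0
    cur_J <- J_fun(x0)
    best_x <- cur_x; best_J <- cur_J
    temp <- t0
    n_fail <- 0L
    trace <- matrix(NA_real_, n_iter, 3,
                    dimnames = list(NULL, c("iter", "cost", "temp")))
    for (k in seq_len(n_iter)) {
      prop <- cur_x + rnorm(length(cur_x), 0, step)
      Jp <- J_fun(prop)
      if (!is.finite(Jp)) n_fail <- n_fail + 1L
      if (is.finite(Jp) &&
          (Jp <= cur_J || runif(1) < exp(-(Jp - cur_J) / temp))) {
        cur_x <- prop; cur_J <- Jp
        if (Jp < best_J) { best_x <- prop; best_J <- Jp }
      }
      trace[k, ] <- c(k, cur_J, temp)
      temp <- temp * cooling
    }
    list(best_x = best_x, best_J = best_J, trace = as_tibble(as.data.frame(trace)),
         n_fail = n_fail)
  })
}

# hard-threshold acceptance random walk on an arbitrary cost closure
.threshold_walk_core <- function(J_fun, x0, J0, step, threshold, n, seed,
                                 max_proposals) {
  .with_seed(seed, {
    cur_x <- x0
    cur_J <- J0
    k <- length(x0)
    rows <- matrix(NA_real_, nrow = n, ncol = k + 2,
                   dimnames = list(NULL, c(names(x0) %||% paste0("x", 1:k),
                                           "cost", "proposal")))
    n_acc <- 0L
    n_prop <- 0L
    while (n_acc < n && n_prop < max_proposals) {
      n_prop <- n_prop + 1L
      prop <- cur_x + rnorm(k, 0, step)
      Jp <- J_fun(prop)
      if (is.finite(Jp) && Jp <= threshold) {
        cur_x <- prop; cur_J <- Jp
        n_acc <- n_acc + 1L
        rows[n_acc, ] <- c(prop, Jp, n_prop)
      }
      if (n_prop == 200L && n_acc < 2L) {
        abort("acceptance rate < 1% in calibration phase; reduce step widths")
      }
    }
    if (n_acc < n) {
      abort(sprintf("collected only %d of %d sets in %d proposals", n_acc, n, n_prop))
    }
    list(rows = rows, acceptance_rate = n_acc / n_prop)
  })
}

#' Simulated-annealing fit
#'
#' Metropolis annealing in log10-parameter space with a geometric temperature
#' schedule: proposals are drawn from normal distributions centered on the
#' current values; downhill moves are always accepted, uphill moves with
#' probability `exp(-dJ / T)`; `T` is multiplied by `cooling` each iteration.
#' Deterministic given `seed`.
#'
#' @param dataset,designs,spec as in [erk_cost()].
#' @param seed integer seed.
#' @param init starting [erk_params()] (must be simulable).
#' @param n_iter number of annealing iterations.
#' @param t0 initial temperature; default `max(J0, 1) / 10`.
#' @param cooling geometric cooling factor in (0, 1).
#' @return List with `par` (best `erk_params`), `J_min`, `trace` (tibble of
#'   iteration, cost, temperature), `n_fail` (failed simulations).
#' @export
fit_anneal <- function(dataset, designs = NULL, spec = cost_spec(), seed,
                       init, n_iter = 500, t0 = NULL, cooling = 0.95) {
  designs <- designs %||% attr(dataset, "designs")
  if (missing(seed) || is.null(seed)) abort("a seed is required for annealing")
  J <- function(x) erk_cost(.unpack(x, spec$free, init), dataset, designs, spec)
  x0 <- .pack(init, spec$free)
  J0 <- erk_cost(init, dataset, designs, spec)
  if (!is.finite(J0)) abort("initial parameter set is not simulable")
  step <- if (length(spec$step) == 1) rep(spec$step, length(x0)) else
    spec$step[spec$free]
  res <- .anneal_core(J, x0, step, seed = seed, n_iter = n_iter,
                      t0 = t0 %||% (max(J0, 1) / 10), cooling = cooling)
  if (res$n_fail == n_iter) {
    abort(paste0("all ", n_iter, " proposals failed to simulate; ",
                 "check parameter scales and step widths"))
  }
  list(par = .unpack(res$best_x, spec$free, init), J_min = min(res$best_J, J0),
       trace = res$trace, n_fail = res$n_fail)
}

#' Threshold-acceptance ensemble walk
#'
#' Random walk in log10-parameter space collecting an ensemble of parameter
#' sets that all fit the data almost equally well: a proposal drawn from
#' normal distributions centered on the current accepted set is accepted iff
#' its cost satisfies `J <= J_min * (1 + epsilon)`; every accepted move is
#' recorded (no thinning).  Deterministic given `seed`.  Aborts if the
#' acceptance rate over the first 200 proposals falls below 1% (advising
#' smaller steps).
#'
#' @param dataset,designs,spec as in [erk_cost()].
#' @param seed integer seed.
#' @param start starting [erk_params()]; its cost must be within threshold.
#' @param n number of accepted sets to collect.
#' @param J_min reference minimum cost; defaults to the cost at `start`.
#' @param max_proposals proposal budget before giving up.
#' @return A tibble of class `erk_ensemble`: one row per accepted set
#'   (log10 free-parameter columns, `cost`, `proposal` index), with
#'   attributes `seed`, `J_min`, `threshold`, `acceptance_rate`, `free_names`,
#'   `fixed_params`, `spec`.
#' @export
ensemble_walk <- function(dataset, designs = NULL, spec = cost_spec(), seed,
                          start, n = 300, J_min = NULL,
                          max_proposals = 100 * n) {
  designs <- designs %||% attr(dataset, "designs")
  if (missing(seed) || is.null(seed)) abort("a seed is required for the ensemble walk")
  J <- function(th) erk_cost(th, dataset, designs, spec)
  J_start <- J(start)
  J_min <- J_min %||% J_start
  threshold <- J_min * (1 + spec$epsilon)
  if (J_start > threshold) {
    abort(sprintf("cost at start (%.4g) exceeds the acceptance threshold (%.4g)",
                  J_start, threshold))
  }
  free <- spec$free
  step <- if (length(spec$step) == 1) rep(spec$step, length(free)) else
    spec$step[free]
  Jx <- function(x) erk_cost(.unpack(x, free, start), dataset, designs, spec)
  res <- .threshold_walk_core(Jx, .pack(start, free), J_start, step, threshold,
                              n, seed, max_proposals)
  out <- as_tibble(as.data.frame(res$rows))
  attr(out, "seed") <- seed
  attr(out, "J_min") <- J_min
  attr(out, "threshold") <- threshold
  attr(out, "acceptance_rate") <- res$acceptance_rate
  attr(out, "free_names") <- free
  attr(out, "fixed_params") <- start
  attr(out, "spec") <- spec
  class(out) <- c("erk_ensemble", class(out))
  out
}

#' Save / load an ensemble (CSV plus JSON run metadata)
#'
#' @param ensemble an `erk_ensemble`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `path` (write) or an `erk_ensemble` (read).
#' @export
write_ensemble_csv <- function(ensemble, path) {
  readr::write_csv(as_tibble(as.data.frame(ensemble)), path)
  spec <- attr(ensemble, "spec")
  meta <- list(seed = attr(ensemble, "seed"), J_min = attr(ensemble, "J_min"),
               threshold = attr(ensemble, "threshold"),
               acceptance_rate = attr(ensemble, "acceptance_rate"),
               free_names = attr(ensemble, "free_names"),
               fixed_params = unclass(attr(ensemble, "fixed_params")),
               epsilon = spec$epsilon, step = spec$step, variant = spec$variant)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  attr(out, "seed") <- meta$seed
  attr(out, "J_min") <- meta$J_min
  attr(out, "threshold") <- meta$threshold
  attr(out, "acceptance_rate") <- meta$acceptance_rate
  attr(out, "free_names") <- meta$free_names
  attr(out, "fixed_params") <- erk_params(.values = as.list(meta$fixed_params))
  attr(out, "spec") <- cost_spec(free = meta$free_names, epsilon = meta$epsilon,
                                 step = meta$step, variant = meta$variant)
  class(out) <- c("erk_ensemble", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble: per-parameter posterior-style summary
#'
#' @param x an `erk_ensemble`.
#' @param ... unused.
#' @return Tibble with one row per free parameter: ensemble median and
#'   quantiles on the natural scale.
#' @method tidy erk_ensemble
#' @export
tidy.erk_ensemble <- function(x, ...) {
  free <- attr(x, "free_names")
  purrr::map_dfr(free, function(nm) {
    v <- 10^x[[nm]]
    tibble(parameter = nm, median = median(v),
           q05 = unname(quantile(v, 0.05)), q95 = unname(quantile(v, 0.95)))
  })
}

#' Ensemble run summary
#'
#' @param x an `erk_ensemble`.
#' @param ... unused.
#' @return One-row tibble: size, minimum/threshold cost, acceptance rate,
#'   seed.
#' @method glance erk_ensemble
#' @export
glance.erk_ensemble <- function(x, ...) {
  tibble(n = nrow(x), J_min = attr(x, "J_min"),
         threshold = attr(x, "threshold"),
         acceptance_rate = attr(x, "acceptance_rate"),
         seed = attr(x, "seed"))
}
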