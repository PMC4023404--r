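# Shared fixtures, built once per test run and memoized.  The ensemble fit is
# the expensive piece (annealing + threshold walk on the packaged synthetic
# dataset); several test files share it.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_theta <- function() theta_ref()

fx_dataset <- function() {
  fixture("dataset", function() generate_datasets(theta_ref(), seed = 101))
}

fx_fit <- function() {
  fixture("fit", function() {
    fit_anneal(fx_dataset(), spec = cost_spec(), seed = 1101,
               init = theta_ref(), n_iter = 200)
  })
}

fx_ensemble <- function() {
  fixture("ensemble", function() {
    fit <- fx_fit()
    ensemble_walk(fx_dataset(), spec = cost_spec(), seed = 2101,
                  start = fit$par, J_min = fit$J_min, n = 250)
  })
}

fx_ref_trajectory <- function() {
  fixture("ref_trajectory", function() {
    erk_simulate(theta_ref(), protocol_step(S = 1, t_end = 75),
                 t_grid = seq(0, 75, by = 0.5))
  })
}

fx_features <- function() {
  fixture("features", function() kinetic_features(theta_ref()))
}

# modest random parameter sets around the defaults, for property tests
random_params <- function(n, seed = 99, sd_log10 = 0.15) {
  set.seed(seed)
  base <- erk_params()
  vary <- c("a_M", "d_M", "k_fb", "k_rec", "a_E1", "a_E2", "d_c1", "d_c2",
            "d_n1", "d_n2", "k_in", "k_pass", "k_out", "k_on_c", "k_off_c",
            "k_cat_c", "k_sdp_c", "k_on_n", "k_off_n", "k_cat_n", "k_sdp_n",
            "Sc_tot", "Sn_tot")
  lapply(seq_len(n), function(i) {
    v <- unclass(base)
    for (nm in vary) v[[nm]] <- v[[nm]] * 10^rnorm(1, 0, sd_log10)
    erk_params(.values = v)
  })
}

erk_pool_names <- c("E0c", "E1c", "E2c", "EBc", "E0n", "E1n", "E2n", "EBn", "EIn")

# bare data.frame content, dropping bespoke attributes, for round-trip checks
df_data <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names")]
  as.data.frame(x)
}
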