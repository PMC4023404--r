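noise_free_dataset <- function() {
  fixture("noise_free_dataset", function() {
    designs <- purrr::map(purrr::keep(default_designs(), ~ .x$role == "fit"),
                          function(d) { d$noise_cv <- 0; d$jitter_cv <- 0; d })
    generate_datasets(theta_ref(), designs = designs, seed = 1)
  })
}

test_that("cost is zero at the generating truth on noise-free data", {
  J <- erk_cost(theta_ref(), noise_free_dataset(), spec = cost_spec())
  expect_lt(J, 1e-12)
})

test_that("cost increases for single-parameter perturbations away from truth", {
  ds <- noise_free_dataset()
  spec <- cost_spec()
  for (nm in c("k_out", "a_E1", "Sn_tot", "d_M")) {
    for (fac in c(10^-0.05, 10^0.05)) {
      p <- theta_ref()
      p[[nm]] <- p[[nm]] * fac
      expect_gt(erk_cost(p, ds, spec = spec), 1e-3,
                label = paste("J with", nm, "scaled by", round(fac, 3)))
    }
  }
})

test_that("analytic scale factor matches a brute-force grid search", {
  ds <- fx_dataset()
  blot <- ds[ds$experiment_id == "blot" & ds$readout == "ppERK_blot", ]
  d <- attr(ds, "designs")$blot
  tr <- erk_simulate(theta_ref(), d$protocol, t_grid = d$t_grid)
  m <- erk_observe(tr, readouts = "ppERK_blot")
  joined <- dplyr::left_join(as.data.frame(blot), m,
                             by = c("readout", "time_min"),
                             suffix = c("", "_m"))
  y <- joined$value; mm <- joined$value_m; sg <- joined$sigma
  s_star <- sum(y * mm / sg^2) / sum(mm^2 / sg^2)
  grid <- seq(0.2 * s_star, 5 * s_star, length.out = 10000)
  J_of <- vapply(grid, function(s) sum((s * mm - y)^2 / sg^2), numeric(1))
  expect_lt(abs(grid[which.min(J_of)] - s_star), diff(grid[1:2]) * 1.5)
})

test_that("annealing recovers the minimum of a quadratic toy cost", {
  Jq <- function(x) sum((x - c(1.3, -0.7))^2)
  r <- erkshuttle:::.anneal_core(Jq, c(0, 0), step = c(0.1, 0.1), seed = 1,
                                 n_iter = 3000, t0 = 0.5, cooling = 0.998)
  expect_lt(max(abs(r$best_x - c(1.3, -0.7))), 1e-2)
})

test_that("annealing from truth on noise-free data returns J_min ~ 0", {
  fit <- fit_anneal(noise_free_dataset(), spec = cost_spec(), seed = 4,
                    init = theta_ref(), n_iter = 20)
  expect_lt(fit$J_min, 1e-12)
})

test_that("annealed cost on noisy data is within 20% of the truth cost", {
  ds <- fx_dataset()
  Jt <- erk_cost(theta_ref(), ds, spec = cost_spec())
  fit <- fx_fit()
  expect_lt(abs(fit$J_min - Jt), 0.2 * Jt)
  expect_lte(fit$J_min, Jt)   # started at truth, so it can only improve
})

test_that("hard-threshold walk matches the analytic region of a linear-Gaussian toy", {
  set.seed(5)
  y <- rnorm(20, 2, 0.3)
  sig <- 0.3
  Jl <- function(x) sum((x - y)^2 / sig^2)
  xhat <- mean(y)
  J_min <- Jl(xhat)
  eps <- 0.25
  threshold <- J_min * (1 + eps)
  half_width <- sqrt(eps * J_min * sig^2 / length(y))
  w <- erkshuttle:::.threshold_walk_core(Jl, xhat, J_min, step = half_width / 8,
                                         threshold = threshold, n = 5000,
                                         seed = 2, max_proposals = 1e6)
  xs <- w$rows[, 1]
  # hard threshold: no accepted point lies outside the analytic region
  expect_equal(sum(vapply(xs, Jl, numeric(1)) > threshold), 0)
  # spread of accepted sets approaches the analytic interval width
  expect_lt(abs((max(xs) - min(xs)) / (2 * half_width) - 1), 0.1)
})

test_that("ensemble walk is reproducible and respects its threshold", {
  ds <- fx_dataset()
  a <- ensemble_walk(ds, spec = cost_spec(), seed = 31, start = theta_ref(),
                     n = 20)
  b <- ensemble_walk(ds, spec = cost_spec(), seed = 31, start = theta_ref(),
                     n = 20)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$cost <= attr(a, "threshold")))
  c <- ensemble_walk(ds, spec = cost_spec(), seed = 32, start = theta_ref(),
                     n = 20)
  expect_false(identical(a$cost, c$cost))
})

test_that("walk refuses a start outside the threshold and oversized steps", {
  ds <- fx_dataset()
  bad <- theta_ref(); bad$k_out <- bad$k_out * 5
  expect_error(ensemble_walk(ds, spec = cost_spec(), seed = 1, start = bad,
                             J_min = erk_cost(theta_ref(), ds, spec = cost_spec()),
                             n = 5),
               "threshold")
  expect_error(ensemble_walk(ds, spec = cost_spec(step = 1.5), seed = 1,
                             start = theta_ref(), n = 50),
               "acceptance rate")
})

test_that("ensemble recovers composite kinetic quantities from synthetic data", {
  ens <- fx_ensemble()
  expect_gte(nrow(ens), 250)
  expect_true(all(ens$cost <= attr(ens, "threshold")))

  truth <- theta_ref()
  bs_true <- buffering_strengths(truth)
  modes <- classify_modes(ens)
  # nuclear buffering strength: ensemble median within a factor of 2
  expect_lt(abs(log(median(modes$B_n) / bs_true[["B_n"]])), log(2))
  # other composite quantities within a factor of 3
  expect_lt(abs(log(median(modes$B_c) / bs_true[["B_c"]])), log(3))
  for (nm in c("k_out", "d_M")) {
    med <- median(10^ens[[nm]])
    expect_lt(abs(log(med / truth[[nm]])), log(3), label = nm)
  }
})

test_that("tidy and glance summarize an ensemble", {
  ens <- fx_ensemble()
  td <- tidy(ens)
  expect_true(all(c("parameter", "median", "q05", "q95") %in% names(td)))
  expect_equal(nrow(td), length(attr(ens, "free_names")))
  expect_true(all(td$q05 <= td$median & td$median <= td$q95))
  gl <- glance(ens)
  expect_equal(gl$n, nrow(ens))
  expect_gt(gl$acceptance_rate, 0.05)
  expect_lt(gl$J_min, gl$threshold)
})

test_that("ensemble CSV round-trips with metadata", {
  ens <- fx_ensemble()
  f <- file.path(tempdir(), "ens.csv")
  write_ensemble_csv(ens, f)
  back <- read_ensemble_csv(f)
  expect_equal(df_data(back), df_data(ens), tolerance = 1e-12)
  expect_equal(attr(back, "threshold"), attr(ens, "threshold"))
  expect_equal(attr(back, "free_names"), attr(ens, "free_names"))
})
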