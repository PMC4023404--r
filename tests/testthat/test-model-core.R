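test_that("pre-stimulus steady state satisfies flux-balance limits", {
  # no basal input, passive shuttling on: only unphosphorylated ERK remains,
  # partitioned by the passive import/export balance
  p <- erk_params(S_basal = 0)
  s <- initial_state(p)
  expect_equal(unname(s[c("M2", "E2c", "E2n", "EBc", "EBn", "Pc", "Pn")]),
               rep(0, 7), tolerance = 1e-12)
  expect_equal(s[["E0n"]] / s[["E0c"]], p$k_pass / p$k_out, tolerance = 1e-9)

  # no basal input, no passive shuttling: all ERK cytosolic, unphosphorylated
  s2 <- initial_state(erk_params(S_basal = 0, k_pass = 0))
  expect_equal(s2[["E0c"]], 1, tolerance = 1e-12)
  expect_equal(sum(abs(s2)) - s2[["E0c"]] - s2[["M0"]], 0, tolerance = 1e-12)
})

test_that("steady state matches the long-time integration oracle", {
  p <- theta_ref()
  s <- initial_state(p)
  # oracle: long-time integration from the passive-balance state; the horizon
  # must cover the slowest relaxation mode (basal substrate dephosphorylation,
  # time constant 1/k_sdp_n ~ 7e3 min), so integrate ~30 time constants
  y0 <- setNames(numeric(15), names(s))
  y0["M0"] <- 1
  y0["E0c"] <- 1 / (1 + p$k_pass / p$k_out)
  y0["E0n"] <- 1 - y0["E0c"]
  t_end <- 30 / min(p$k_sdp_n, p$k_sdp_c, p$k_rec, p$d_M)
  proto <- erk_protocol(tibble::tibble(t_start = 0, S = p$S_basal),
                        t_end = t_end)
  tr <- erk_simulate(p, proto, t_grid = c(0, t_end), y0 = y0)
  oracle <- unlist(tr[nrow(tr), names(s)])
  expect_lt(max(abs(s - oracle)), 1e-6)
  # residual of the rhs at the returned state
  expect_lt(max(abs(erk_rhs(0, s, p, u = p$S_basal))), 1e-10)
})

test_that("rhs conserves total ERK and MEK and reduces to the control model", {
  p <- theta_ref()
  s <- initial_state(p)
  s["E2c"] <- 0.05; s["E2n"] <- 0.02; s["E0c"] <- s["E0c"] - 0.07
  d <- erk_rhs(0, s, p, u = 1)
  expect_equal(sum(d[erk_pool_names]), 0, tolerance = 1e-14)
  expect_equal(sum(d[c("M0", "M1", "M2")]), 0, tolerance = 1e-14)

  # zero substrate pools: full rhs equals control rhs componentwise
  p0 <- erk_params(.values = modifyList(unclass(p), list(Sc_tot = 0, Sn_tot = 0)))
  s0 <- s
  s0[c("EBc", "EBn", "Pc", "Pn")] <- 0
  s0["E0c"] <- 1 - sum(s0[setdiff(erk_pool_names, "E0c")])
  expect_equal(erk_rhs(0, s0, p0, u = 1, variant = "full"),
               erk_rhs(0, s0, p0, u = 1, variant = "control"))
})

test_that("rhs matches hand arithmetic for a single active rate", {
  parm_names <- erkshuttle:::.erk_parm_order
  zero <- as.list(setNames(rep(0, length(parm_names)), parm_names))
  zero$phi_n <- 0.2
  zero$fb_K <- 0.05   # validation requires a positive Hill constant
  zero$d_c2 <- 1
  p <- erk_params(.values = c(zero, list(M2_const = 0, S_basal = 0)))
  s <- setNames(numeric(15), names(initial_state(theta_ref())))
  s["E2c"] <- 0.5
  d <- erk_rhs(0, s, p, u = 0)
  expect_equal(d[["E2c"]], -0.5)
  expect_equal(d[["E1c"]], 0.5)
  expect_equal(sum(abs(d)) - abs(d[["E2c"]]) - abs(d[["E1c"]]), 0)
})

test_that("two-site MEK cascade reaches the analytic plateau without feedback", {
  # v/d_M = 1 gives M2 = r^2/(1+r+r^2) = 1/3
  p <- erk_params(k_fb = 0, a_M = 1, d_M = 1, S_basal = 0)
  tr <- erk_simulate(p, protocol_step(S = 1, t_end = 300), t_grid = c(0, 300))
  expect_equal(tr$M2[2], 1 / 3, tolerance = 1e-6)
})

test_that("adaptive integrator agrees with the fixed-step RK4 oracle", {
  p <- theta_ref()
  grid <- seq(0, 30, by = 5)
  proto <- protocol_step(S = 1, t_end = 30)
  ad <- erk_simulate(p, proto, t_grid = grid)
  rk <- erk_simulate_rk4(p, proto, t_grid = grid, dt = 0.001)
  err <- max(abs(as.matrix(ad[, -1]) - as.matrix(rk[, -1])))
  expect_lt(err, 1e-6)
})

test_that("conservation and non-negativity hold across random parameter sets", {
  for (p in random_params(8)) {
    tr <- erk_simulate(p, protocol_step(S = 1, t_end = 75))
    erk_tot <- rowSums(tr[, erk_pool_names])
    mek_tot <- rowSums(tr[, c("M0", "M1", "M2")])
    sub_c <- tr$EBc + tr$Pc
    sub_n <- tr$EBn + tr$Pn
    expect_lt(max(abs(erk_tot - 1)), 1e-7)
    expect_lt(max(abs(mek_tot - 1)), 1e-7)
    expect_lt(max(sub_c) - p$Sc_tot, 1e-7)
    expect_lt(max(sub_n) - p$Sn_tot, 1e-7)
    expect_gt(min(as.matrix(tr[, -1])), -1e-9)
  }
})

test_that("events restart cleanly and inhibitors act instantaneously", {
  p <- theta_ref()
  tr <- erk_simulate(p, protocol_u0126(t_inhibit = 20, t_end = 40),
                     t_grid = seq(0, 40, 0.5))
  # after U0126 the whole-cell diphospho pool only decays
  pp <- tr$E2c + tr$EBc + tr$E2n + tr$EBn
  post <- pp[tr$time_min >= 20]
  expect_true(all(diff(post) <= 1e-9))

  # okadaic acid: total phospho-ERK is non-decreasing once phosphatases stop
  tr2 <- erk_simulate(p, protocol_okadaic(t_inhibit = 20, t_end = 40),
                      t_grid = seq(0, 40, 0.5))
  tot <- tr2$E1c + tr2$E2c + tr2$EBc + tr2$E1n + tr2$E2n + tr2$EBn + tr2$EIn
  expect_true(all(diff(tot[tr2$time_min >= 20]) >= -1e-9))
})

test_that("variant reductions: control limit and fast importin release", {
  p <- theta_ref()
  grid <- seq(0, 60, 1)
  p0 <- erk_params(.values = modifyList(unclass(p), list(Sc_tot = 0, Sn_tot = 0)))
  proto_full <- protocol_step(S = 1, t_end = 60, variant = "full")
  proto_ctrl <- protocol_step(S = 1, t_end = 60, variant = "control")
  tr_full <- erk_simulate(p0, proto_full, t_grid = grid)
  tr_ctrl <- erk_simulate(p0, proto_ctrl, t_grid = grid)
  expect_equal(df_data(tr_full), df_data(tr_ctrl), tolerance = 1e-10)

  # importin variant approaches the control model as release becomes fast
  p_imp <- erk_params(.values = modifyList(unclass(p0), list(k_rel = 1e4)))
  tr_imp <- erk_simulate(p_imp, protocol_step(S = 1, t_end = 60,
                                              variant = "importin"),
                         t_grid = grid)
  rel_err <- max(abs(tr_imp$E2n - tr_ctrl$E2n)) / max(tr_ctrl$E2n)
  expect_lt(rel_err, 0.01)
})

test_that("constant-MEK variant clamps MEK and keeps it inert", {
  p <- theta_ref()
  tr <- erk_simulate(p, protocol_step(S = 1, t_end = 40,
                                      variant = "constant_mek"),
                     t_grid = seq(0, 40, 2))
  expect_true(all(abs(tr$M2 - p$M2_const) < 1e-12))
  # ERK still responds
  expect_gt(max(tr$E2c), 100 * tr$E2c[1])
})

test_that("nuclear buffering delays availability of free nuclear ERK", {
  p <- theta_ref()
  km <- (p$k_off_n + p$k_cat_n) / p$k_on_n
  t90 <- sapply(c(0, 1, 5, 20, 50), function(B) {
    pb <- erk_params(.values = modifyList(unclass(p),
                                          list(Sn_tot = B * p$phi_n * km)))
    tr <- erk_simulate(pb, protocol_step(S = 1, t_end = 75),
                       t_grid = seq(0, 75, 0.5))
    target <- tr$E2n[tr$time_min == 60] * 0.9
    tr$time_min[which(tr$E2n >= target)[1]]
  })
  expect_true(all(diff(t90) >= 0))
})

test_that("parameter and protocol serialization round-trips", {
  p <- theta_ref()
  for (ext in c("yml", "json")) {
    f <- file.path(tempdir(), paste0("theta.", ext))
    erk_write(p, f)
    expect_equal(unclass(erk_read(f)), unclass(p), tolerance = 1e-12)
  }
  proto <- protocol_dose_step()
  f <- file.path(tempdir(), "proto.yml")
  erk_write(proto, f)
  back <- erk_read(f)
  expect_equal(back$segments, proto$segments)
  expect_equal(back$t_end, proto$t_end)

  # invalid protocols are rejected
  expect_error(erk_protocol(tibble::tibble(t_start = c(5, 10), S = c(1, 1))),
               "t = 0")
  expect_error(erk_protocol(u0126_time = 100, t_end = 75), "event times")
  expect_error(protocol_step(variant = "bogus"))
})

test_that("trajectory CSV export keeps all state columns", {
  tr <- erk_simulate(theta_ref(), protocol_step(S = 1, t_end = 10),
                     t_grid = seq(0, 10, 2))
  f <- file.path(tempdir(), "traj.csv")
  write_trajectory_csv(tr, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(back), c("time_min", names(initial_state(theta_ref()))))
  expect_equal(back$E2n, tr$E2n, tolerance = 1e-12)
})

test_that("partial inhibition and instantaneous-feedback options behave sensibly", {
  p <- theta_ref()
  grid <- seq(0, 75, 1)
  full_block <- erk_observe(erk_simulate(p, protocol_u0126(46, t_end = 75),
                                         t_grid = grid),
                            readouts = "ekar_nuc")
  partial <- erk_protocol(tibble::tibble(t_start = 0, S = 1),
                          u0126_time = 46, t_end = 75, u0126_factor = 0.5)
  half_block <- erk_observe(erk_simulate(p, partial, t_grid = grid),
                            readouts = "ekar_nuc")
  # a 50% residual flux leaves the activity well above the fully blocked trace
  v_full <- full_block$value[full_block$time_min == 75]
  v_half <- half_block$value[half_block$time_min == 75]
  expect_lt(v_full, 1.1)
  expect_gt(v_half, v_full + 0.2)

  # instantaneous Hill feedback: MEK still adapts, desensitization state inert
  ph <- erk_params(.values = modifyList(unclass(p),
                                        list(fb_mode = 1, fb_K = 0.05, fb_h = 2)))
  tr <- erk_simulate(ph, protocol_step(S = 1, t_end = 75), t_grid = grid)
  expect_equal(max(abs(tr$D - tr$D[1])), 0)
  # undelayed feedback still adapts MEK, though less sharply than the
  # desensitization-state form
  m2 <- tr$M2
  expect_gt(max(m2), 1.3 * m2[length(m2)])
  # R rhs agrees with the conservation structure in this mode too
  s <- unlist(tr[20, -1])
  dR <- erk_rhs(0, s, ph, u = 1)
  expect_equal(sum(dR[erk_pool_names]), 0, tolerance = 1e-12)
  expect_equal(dR[["D"]], 0)
})
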