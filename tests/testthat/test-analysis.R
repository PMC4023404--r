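test_that("buffering strengths follow the K_m definition", {
  p <- erk_params(k_off_n = 15, k_cat_n = 5, k_on_n = 10,
                  Sn_tot = 2 * 0.2, phi_n = 0.2)
  expect_equal(unname(buffering_strengths(p)["B_n"]), 1)

  p0 <- erk_params(Sc_tot = 0)
  expect_equal(unname(buffering_strengths(p0)["B_c"]), 0)

  bad <- erk_params(k_on_c = 0, Sc_tot = 0.1)
  expect_error(buffering_strengths(bad), "undefined")
})

test_that("mode classification follows the boundary rule and is order-invariant", {
  mk <- function(B_c, B_n) {
    p <- theta_ref()
    p$Sc_tot <- B_c * (1 - p$phi_n) * (p$k_off_c + p$k_cat_c) / p$k_on_c
    p$Sn_tot <- B_n * p$phi_n * (p$k_off_n + p$k_cat_n) / p$k_on_n
    p
  }
  fake_ens <- function(params_list) {
    free <- c("Sc_tot", "Sn_tot")
    out <- tibble::tibble(
      Sc_tot = log10(purrr::map_dbl(params_list, "Sc_tot")),
      Sn_tot = log10(purrr::map_dbl(params_list, "Sn_tot")),
      cost = 0, proposal = seq_along(params_list))
    attr(out, "free_names") <- free
    attr(out, "fixed_params") <- theta_ref()
    class(out) <- c("erk_ensemble", class(out))
    out
  }
  sets <- list(mk(0.1, 20), mk(5, 0.5), mk(2, 2), mk(0, 0))
  cm <- classify_modes(fake_ens(sets))
  expect_equal(cm$mode, c("nuclear_dominant", "cytosolic_dominant",
                          "mixed", "unbuffered"))
  cm_rev <- classify_modes(fake_ens(rev(sets)))
  expect_equal(cm_rev$mode, rev(cm$mode))

  # invariant to joint rescaling that leaves B_c, B_n unchanged
  p <- mk(0.1, 20)
  p2 <- p
  for (nm in c("k_on_n", "k_off_n", "k_cat_n")) p2[[nm]] <- p2[[nm]] * 7
  expect_equal(buffering_strengths(p)["B_n"], buffering_strengths(p2)["B_n"],
               tolerance = 1e-12)
})

test_that("species breakdown partitions total ERK into the eight pools", {
  tr <- fx_ref_trajectory()
  br <- species_breakdown(tr)
  sums <- br |>
    dplyr::group_by(time_min) |>
    dplyr::summarise(total = sum(fraction))
  expect_lt(max(abs(sums$total - 1)), 1e-7)

  # control variant holds no substrate-bound ERK
  tr0 <- erk_simulate(theta_ref(), protocol_step(S = 1, t_end = 30,
                                                 variant = "control"),
                      t_grid = seq(0, 30, 5))
  br0 <- species_breakdown(tr0)
  expect_equal(max(abs(br0$fraction[br0$species %in% c("cs", "ns")])), 0)

  # early after stimulation most nuclear diphospho ERK is substrate-bound;
  # the ratio reverses once the substrate pool is phosphorylated
  wide <- tidyr::pivot_wider(br, names_from = "species", values_from = "fraction")
  early <- wide[wide$time_min == 5, ]
  late <- wide[wide$time_min == 70, ]
  expect_gt(early$ns, early$npp)
  expect_lt(late$ns, late$npp)
})

test_that("prediction battery reproduces the inhibition-timing hierarchy", {
  pr <- fixture("pred_theta", function() {
    run_predictions(theta_ref(), prediction_protocols(),
                    readouts = c("nucloc", "ekar_nuc", "ekar_cyt"), dt = 1)
  })
  expect_equal(pr$n_failed, 0)
  th <- pr$t_half
  get <- function(proto, r) th$t_half[th$protocol == proto & th$readout == r]
  # early inhibition decays slower than late, for localization and activity
  expect_gt(get("u0126_10min", "nucloc"), get("u0126_46min", "nucloc"))
  expect_gt(get("u0126_10min", "ekar_nuc"), get("u0126_46min", "ekar_nuc"))
  # the t-half hierarchy is monotone in inhibition time
  tt <- vapply(c("u0126_5min", "u0126_10min", "u0126_20min", "u0126_46min"),
               function(pr_) get(pr_, "nucloc"), numeric(1))
  expect_true(all(diff(tt) <= 0))

  # mean traces lie within the member envelope trivially for one member;
  # check the ensemble version on a small ensemble
  ens <- fx_ensemble()
  sub <- ens[1:25, ]
  for (a in names(attributes(ens))[!names(attributes(ens)) %in%
                                   c("row.names", "names", "class")]) {
    attr(sub, a) <- attr(ens, a)
  }
  class(sub) <- class(ens)
  pr2 <- run_predictions(sub, prediction_protocols()["u0126_46min"],
                         readouts = "nucloc", dt = 2)
  expect_true(all(pr2$traces$sd >= 0))
  expect_equal(unique(pr2$traces$n), 25)
})

test_that("dose step-up raises cytosolic activity but not nuclear localization", {
  tr <- erk_simulate(theta_ref(), protocol_dose_step(), t_grid = seq(0, 75, 1))
  ob <- erk_observe(tr, readouts = c("nucloc", "ekar_cyt"))
  v <- function(r, t) ob$value[ob$readout == r & ob$time_min == t]
  incr_nucloc <- (v("nucloc", 60) - v("nucloc", 30)) / v("nucloc", 30)
  incr_ekar <- (v("ekar_cyt", 60) - v("ekar_cyt", 30)) / v("ekar_cyt", 30)
  expect_gt(incr_ekar, 0.1)
  expect_lt(incr_nucloc, incr_ekar / 2)
})

test_that("nuclear activity decays to baseline after late MEK inhibition", {
  tr <- erk_simulate(theta_ref(), protocol_u0126(46, t_end = 90),
                     t_grid = seq(0, 90, 1))
  ob <- erk_observe(tr, readouts = "ekar_nuc")
  expect_lt(ob$value[ob$time_min == 90], 1.05)
  expect_gt(max(ob$value), 2)
})
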