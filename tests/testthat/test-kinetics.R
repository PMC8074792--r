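test_that("tumbling bins average constant signals and count events", {
  tab <- event_table(cbind(AF532 = rep(5, 9)), channels("AF532"),
                     time_s = 1:9)
  tr <- bin_time_series(tab)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$AF532, 5)
  expect_equal(tr$n, 9L)
  expect_error(bin_time_series(event_table(cbind(A = 1), channels("A"))),
               "no time information")
})

test_that("uniform Poisson arrivals fill tumbling bins evenly", {
  set.seed(19)
  n <- 10000
  t <- sort(runif(n, 0, 100))
  tab <- event_table(cbind(AF532 = rep(1, n)), channels("AF532"), time_s = t)
  tr <- bin_time_series(tab, window_s = 10)
  expect_equal(nrow(tr), 10L)
  expect_equal(sum(tr$n), n)
  # each bin within the 99% Poisson band around 1000
  band <- qpois(c(0.005, 0.995), 1000)
  expect_true(all(tr$n >= band[1] & tr$n <= band[2]))
})

test_that("tumbling and sliding windows both track a linear signal", {
  set.seed(23)
  t <- sort(runif(20000, 0, 100))
  tab <- event_table(cbind(S = 2 * t + 1), channels("S"), time_s = t)
  tum <- bin_time_series(tab, "S", window_s = 10, mode = "tumbling")
  expect_equal(tum$S, 2 * tum$bin_center_s + 1, tolerance = 0.02)
  sli <- bin_time_series(tab, "S", window_s = 10, mode = "sliding", step_s = 1)
  expect_equal(sli$S, 2 * sli$bin_center_s + 1, tolerance = 0.02)
})

test_that("normalization divides each channel by its own first window", {
  tab <- event_table(cbind(A = c(2, 2, 4, 6), B = c(10, 10, 10, 10)),
                     channels(c("A", "B")), time_s = c(1, 5, 15, 25))
  tr <- normalize_trace(bin_time_series(tab))
  expect_equal(tr$A, c(1, 2, 3))
  expect_equal(tr$B, c(1, 1, 1))
  bad <- event_table(cbind(A = c(0, 1)), channels("A"), time_s = c(1, 15))
  expect_error(normalize_trace(bin_time_series(bad)), "cannot normalize")
})

test_that("ratio traces are 1 for identical traces and drop empty bins", {
  tab <- event_table(cbind(NF = c(1, 2, 3), AF532 = c(1, 2, 3)),
                     channels(c("NF", "AF532")), time_s = c(5, 15, 25))
  nf <- normalize_trace(bin_time_series(tab, "NF"))
  af <- normalize_trace(bin_time_series(tab, "AF532"))
  ratio <- escape_ratio_trace(nf, af)
  expect_equal(ratio$ratio, rep(1, 3))
  expect_error(escape_ratio_trace(nf, bin_time_series(tab, "AF532")),
               "normalized")
})

test_that("closed-form model matches a numeric ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- two_compartment_params(U_max = 10, k_u = 0.02, k_e = 0.002,
                              q = 0.05, baseline = 1)
  t_grid <- seq(0, 1200, by = 0.1)
  closed <- simulate_two_compartment(p, t_grid)
  ode <- deSolve::ode(
    y = c(C = 0), times = t_grid,
    func = function(t, y, parms) {
      u <- p$U_max * (1 - exp(-p$k_u * t))
      list(p$k_e * (u - y[1]))
    }, parms = NULL, method = "rk4"
  )
  expect_lt(max(abs(closed$C - ode[, "C"])), 1e-6 * p$U_max)

  # confluent case k_u == k_e against the same oracle
  pc <- two_compartment_params(U_max = 5, k_u = 0.01, k_e = 0.01, q = 0.2)
  closed2 <- simulate_two_compartment(pc, t_grid)
  ode2 <- deSolve::ode(
    y = c(C = 0), times = t_grid,
    func = function(t, y, parms) {
      u <- pc$U_max * (1 - exp(-pc$k_u * t))
      list(pc$k_e * (u - y[1]))
    }, parms = NULL, method = "rk4"
  )
  expect_lt(max(abs(closed2$C - ode2[, "C"])), 1e-6 * pc$U_max)
})

test_that("model limiting cases behave as the kinetic scheme dictates", {
  t <- seq(0, 2000, by = 10)
  # no escape: C = 0 and the quenchable signal is q*U + baseline
  p0 <- two_compartment_params(k_e = 1e-12, q = 0.1, baseline = 2)
  m0 <- simulate_two_compartment(p0, t)
  expect_equal(m0$C, rep(0, length(t)), tolerance = 1e-6)
  expect_equal(m0$F_NF, 0.1 * m0$U + 2, tolerance = 1e-6)
  # no quenching: the two signals coincide
  p1 <- two_compartment_params(q = 1)
  m1 <- simulate_two_compartment(p1, t)
  expect_equal(m1$F_NF, m1$F_AF)
  # long-time asymptote: C -> U_max, baseline-free ratio -> 1
  p2 <- two_compartment_params(U_max = 10, k_u = 0.02, k_e = 0.005, q = 0.05,
                               baseline = 0)
  m2 <- simulate_two_compartment(p2, 5e4)
  expect_equal(m2$C, 10, tolerance = 1e-4)
  expect_equal(m2$F_NF / m2$F_AF, 1, tolerance = 1e-4)
})

test_that("the uptake signal saturates early and the quenchable one lags", {
  p <- two_compartment_params()
  t <- seq(0, 1200, by = 1)
  m <- simulate_two_compartment(p, t)
  expect_true(all(diff(m$F_AF) >= 0))
  # default rates put 95% of the AF plateau between 100 and 300 s
  t95 <- t[which(m$U >= 0.95 * p$U_max)[1]]
  expect_gt(t95, 100); expect_lt(t95, 300)
  # NF reaches half its dynamic range later than AF for q < 1, k_e < k_u
  half_time <- function(y) t[which(y - y[1] >= (max(y) - y[1]) / 2)[1]]
  expect_gt(half_time(m$F_NF), half_time(m$F_AF))
})

test_that("escape ratio declines early and rises late for strong quenching", {
  kin <- two_compartment_params(q = 0.05, k_u = 0.02, k_e = 0.002)
  tr <- simulated_ratio_trace(seed = 71, kin = kin)$ratio
  early <- tr$ratio[tr$bin_center_s <= 100]
  late <- tr$ratio[tr$bin_center_s >= 600]
  expect_lt(min(early), 0.8)                   # early dip below the start
  expect_gt(tail(late, 1), max(early))         # followed by a gradual rise
  # q = 1 degeneracy: labeling alone cannot move the ratio
  kin1 <- two_compartment_params(q = 1)
  cfg <- sim_config(seed = 72, kinetics = kin1, dye_sigma = 0, meas_cv = 0)
  ev <- simulate_uptake_events(cfg, duration_s = 700)
  af <- normalize_trace(bin_time_series(ev, "AF532"))
  nf <- normalize_trace(bin_time_series(ev, "NF"))
  expect_equal(escape_ratio_trace(nf, af)$ratio,
               rep(1, nrow(af)), tolerance = 1e-12)
})

test_that("noiseless event streams reproduce the closed-form curves", {
  kin <- two_compartment_params()
  cfg <- sim_config(seed = 73, kinetics = kin, dye_sigma = 0, meas_cv = 0,
                    dapi_fraction = 0, event_rate_hz = 50)
  ev <- simulate_uptake_events(cfg, duration_s = 600)
  tr <- bin_time_series(ev, c("AF532", "NF"))
  m <- simulate_two_compartment(kin, tr$bin_center_s)
  # per-cell load is exactly 100 with all noise off; discretization error only
  expect_equal(tr$AF532 / 100, m$F_AF, tolerance = 0.01)
  expect_equal(tr$NF / 100, m$F_NF, tolerance = 0.01)
})

test_that("two-compartment fitting recovers parameters", {
  p <- two_compartment_params(U_max = 10, k_u = 0.02, k_e = 0.002, q = 0.05)
  tc <- seq(5, 995, by = 10)
  af <- model_trace(p, tc, "F_AF")
  nf <- model_trace(p, tc, "F_NF")
  fit <- fit_two_compartment(af, nf)
  expect_equal(fit$params$k_u, p$k_u, tolerance = 0.01)
  expect_equal(fit$params$k_e, p$k_e, tolerance = 0.01)
  expect_equal(fit$params$q, p$q, tolerance = 0.01)
  expect_equal(fit$params$U_max, p$U_max, tolerance = 0.01)

  # flat traces are rejected as unidentifiable
  flat <- model_trace(p, tc, "F_AF"); flat$AF532 <- rep(1, length(tc))
  flat_nf <- model_trace(p, tc, "F_NF"); flat_nf$NF <- rep(1, length(tc))
  expect_error(fit_two_compartment(flat, flat_nf), "unidentifiable")
})

test_that("k_e is recovered within 15% from five noisy replicate streams", {
  kin <- two_compartment_params()
  reps <- lapply(81:85, function(s) simulated_ratio_trace(s, kin))
  # average the five replicate normalized traces, then fit
  mean_trace <- function(key) {
    tmpl <- reps[[1]][[key]]
    ch <- setdiff(names(tmpl), c("bin_center_s", "n"))[1]
    vals <- rowMeans(sapply(reps, function(r) r[[key]][[ch]]))
    tmpl[[ch]] <- vals
    tmpl
  }
  fit <- fit_two_compartment(mean_trace("af"), mean_trace("nf"))
  expect_lt(abs(fit$params$k_e - kin$k_e) / kin$k_e, 0.15)
})

test_that("endpoint comparison flags only truly different groups", {
  kin <- two_compartment_params()
  ctrl <- lapply(91:93, function(s) simulated_ratio_trace(s, kin)$ratio)
  # identical-group null: no significant pairs
  null_res <- endpoint_compare(list(a = ctrl, b = ctrl), t_eval = 900)
  expect_false(any(null_res$tukey$significant))
  # two-group Tukey p equals the two-sample studentized-range result
  kin_hi <- two_compartment_params(k_e = kin$k_e * 1.5)
  enh <- lapply(94:96, function(s) simulated_ratio_trace(s, kin_hi)$ratio)
  res <- endpoint_compare(list(control = ctrl, enhanced = enh), t_eval = 900)
  gd <- split(res$values$value, res$values$group)
  tt <- t.test(gd[[1]], gd[[2]], var.equal = TRUE)
  expect_equal(res$tukey$p_adj, tt$p.value, tolerance = 1e-3)
  expect_error(endpoint_compare(list(a = ctrl, b = ctrl), t_eval = 5000),
               "outside")
})
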