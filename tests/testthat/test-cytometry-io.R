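test_that("CSV round trip is lossless and preserves time stamps", {
  tab <- tiny_event_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(tab, path)
  back <- read_events(path)
  expect_identical(unname(back$events), unname(tab$events))
  expect_equal(channel_names(back), channel_names(tab))

  # empty table round trip
  empty <- event_table(matrix(numeric(0), 0, 2), channels(c("A", "B")))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events(empty, p2)
  expect_equal(nrow(read_events(p2)$events), 0L)

  # timed table: the time column is persisted and recovered
  timed <- event_table(matrix(1:6, 3, 2), channels(c("A", "B")),
                       time_s = c(0.5, 1.25, 9))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_events(timed, p3)
  expect_equal(read_events(p3)$time_s, c(0.5, 1.25, 9))

  # large table: bit-exact CSV round trip
  big <- event_table(matrix(rlnorm(2e4 * 3, 5, 1), ncol = 3),
                     channels(c("X", "Y", "Z")))
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_events(big, p4)
  expect_equal(max(abs(read_events(p4)$events - big$events)), 0)
})

test_that("CSV parsing errors are informative", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), p)  # header row is numeric -> no channel names
  expect_error(read_events(p), "header")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,x"), p2)
  expect_error(read_events(p2), "non-numeric column")
})

test_that("non-finite events are dropped at read time with a count", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,2", "NA,3", "4,5"), p)
  expect_message(tab <- read_events(p), "dropped 1")
  expect_equal(nrow(tab$events), 2L)
  expect_equal(attr(tab, "n_dropped"), 1L)
})

test_that("FCS round trip preserves intensities to float32 precision", {
  tab <- event_table(matrix(rlnorm(500 * 4, 6, 1), ncol = 4),
                     channels(c("FSC", "SSC", "FL1", "FL2")),
                     time_s = sort(runif(500, 0, 100)))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(tab, path)
  back <- read_events(path)
  expect_equal(channel_names(back), channel_names(tab))
  # float32 has ~7 significant digits
  expect_lt(max(abs(back$events - tab$events) / pmax(tab$events, 1)), 1e-6)
  expect_lt(max(abs(back$time_s - tab$time_s)), 1e-3)
})

test_that("a 20,000-event synthetic FCS file is recovered in full", {
  cfg <- sim_config(seed = 11, n_cells = 20000)
  tab <- simulate_f66_population(cfg)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(tab, path)
  back <- read_events(path)
  expect_equal(nrow(back$events), 20000L)
  expect_equal(channel_names(back), channel_names(tab))
})

test_that("compensation solves observed = true . S and leaves scatter alone", {
  s <- spillover_matrix(rbind(c(1, 0.1), c(0, 1)), c("FL1", "FL2"))
  tab <- event_table(cbind(FSC = 500, FL1 = 100, FL2 = 20),
                     channels(c("FSC", "FL1", "FL2")))
  comp <- apply_compensation(tab, s)
  expect_equal(unname(comp$events[1, c("FL1", "FL2")]), c(100, 10))
  expect_equal(comp$events[, "FSC"], tab$events[, "FSC"])

  # identity spillover is a no-op
  id <- spillover_matrix(diag(2), c("FL1", "FL2"))
  expect_equal(apply_compensation(tab, id)$events, tab$events)

  # simulate with known spillover, compensate, recover the truth
  set.seed(42)
  true_sig <- matrix(rlnorm(1000 * 2, 5, 0.5), ncol = 2,
                     dimnames = list(NULL, c("FL1", "FL2")))
  s2 <- spillover_matrix(rbind(c(1, 0.25), c(0.08, 1)), c("FL1", "FL2"))
  observed <- true_sig %*% s2
  obs_tab <- event_table(observed, channels(c("FL1", "FL2")))
  rec <- apply_compensation(obs_tab, s2)$events
  expect_lt(median(abs(rec - true_sig) / true_sig), 1e-10)

  # compensation then re-mixing recovers the observed columns
  remixed <- rec %*% s2
  expect_lt(max(abs(remixed - observed) / observed), 1e-10)
})

test_that("compensation rejects bad spillover matrices", {
  tab <- event_table(cbind(FL1 = 1, FL2 = 2), channels(c("FL1", "FL2")))
  expect_error(spillover_matrix(rbind(c(1, 1), c(1, 1)), c("FL1", "FL2")),
               "singular")
  expect_error(apply_compensation(tab, spillover_matrix(diag(2), c("FL1", "FLX"))),
               "FL2")
  expect_error(spillover_matrix(rbind(c(2, 0), c(0, 1)), c("FL1", "FL2")),
               "diagonal")
})

test_that("gates keep boundary events, are idempotent and report counts", {
  tab <- event_table(cbind(A = c(0, 1, 2, 3, 4), B = c(0, 10, 20, 30, 40)),
                     channels(c("A", "B"), roles = "fluorescence"))
  # rectangle covering the whole range keeps everything
  g_all <- gate_rectangle(c("A", "B"), c(0, 4), c(0, 40))
  expect_equal(nrow(apply_gate(tab, g_all)$events), 5L)
  # closed boundary: threshold at an exact data value keeps it
  g_below <- gate_threshold("A", 2, "below")
  kept <- apply_gate(tab, g_below)
  expect_equal(kept$events[, "A"], c(A1 = 0, A2 = 1, A3 = 2), ignore_attr = TRUE)
  expect_equal(attr(kept, "gating_report")$n_kept, 3L)
  # idempotence
  again <- apply_gate(kept, g_below)
  expect_equal(again$events, kept$events)
  # missing channel errors
  expect_error(apply_gate(tab, gate_threshold("Z", 1)), "Z")
})

test_that("threshold gate recovers a constructed split exactly", {
  set.seed(5)
  lo <- runif(400, 0, 9)
  hi <- runif(600, 11, 20)
  tab <- event_table(cbind(DAPI = sample(c(lo, hi))),
                     channels("DAPI", roles = "fluorescence"))
  kept <- apply_gate(tab, gate_threshold("DAPI", 10, "below"))
  expect_equal(nrow(kept$events), 400L)
})

test_that("polygon gates include boundaries and survive degeneracy", {
  tab <- event_table(cbind(X = c(0.5, 0.5, 2, 0, 1), Y = c(0.5, 0, 2, 0, 0)),
                     channels(c("X", "Y"), roles = "fluorescence"))
  tri <- gate_polygon(c("X", "Y"), rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  kept <- apply_gate(tab, tri)
  # interior point, edge point, two vertices are kept; far point is not
  expect_equal(unname(kept$events[, "X"]), c(0.5, 0.5, 0, 1))
  # collinear polygon (zero area): boundary-only, no crash
  flat <- gate_polygon(c("X", "Y"), rbind(c(0, 0), c(1, 0), c(2, 0)))
  kept2 <- apply_gate(tab, flat)
  expect_true(all(kept2$events[, "Y"] == 0))
})

test_that("viability quadrant fractions sum to one and match construction", {
  # four events, one per quadrant
  tab <- event_table(cbind(Sytox = c(1, 10, 1, 10), Annexin = c(1, 1, 10, 10)),
                     channels(c("Sytox", "Annexin"), roles = "fluorescence"))
  fr <- viability_fractions(tab, "Sytox", "Annexin", c(5, 5))
  expect_equal(as.numeric(fr), rep(0.25, 4))
  expect_lt(abs(sum(fr) - 1), 1e-12)

  # all-negative sample: living fraction 1
  neg <- event_table(cbind(Sytox = rep(1, 10), Annexin = rep(1, 10)),
                     channels(c("Sytox", "Annexin"), roles = "fluorescence"))
  expect_equal(viability_fractions(neg, "Sytox", "Annexin", c(5, 5))[["living"]], 1)

  # constructed 85% double-negative mixture, n = 20,000: within binomial 99% CI
  cfg <- sim_config(seed = 21, n_cells = 20000, live_fraction = 0.85,
                    apoptotic_fraction = 0.08, necrotic_fraction = 0.05)
  pop <- simulate_f66_population(cfg)
  thr <- attr(pop, "truth")$thresholds
  fr2 <- viability_fractions(pop, "SytoxGreen", "AnnexinV", thr)
  ci_half <- 2.576 * sqrt(0.85 * 0.15 / 20000)
  expect_lt(abs(fr2[["living"]] - 0.85), ci_half)
  expect_lt(abs(sum(fr2) - 1), 1e-12)

  expect_error(viability_fractions(
    event_table(matrix(numeric(0), 0, 2),
                channels(c("A", "B"), roles = "fluorescence")),
    "A", "B", c(1, 1)), "empty")
})
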