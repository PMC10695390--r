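spot <- function(k, n, vol = 2, cleared = FALSE) {
  data.frame(dilution_exponent = k, plaques = ifelse(cleared, NA, n),
             volume_uL = vol, lawn_cleared = cleared)
}

test_that("titers come from the least-diluted countable spot", {
  expect_equal(titer_from_spots(spot(0, 10))$value, 5e3)  # 10 / 0.002 mL
  t2 <- titer_from_spots(rbind(spot(0, 0, cleared = TRUE), spot(5, 20)))
  expect_equal(t2$value, 20 / (0.002 * 1e-5))  # 1e9 PFU/mL
  expect_equal(t2$dilution_used, 5)
  # countable window prefers the least-diluted in-range spot
  t3 <- titer_from_spots(rbind(spot(0, 0, cleared = TRUE), spot(1, 200),
                               spot(2, 25), spot(3, 2)))
  expect_equal(t3$dilution_used, 2)
  expect_equal(t3$value, 25 / (0.002 * 1e-2))
})

test_that("all-zero series yield a detection-limit bound; cleared errors", {
  b <- titer_from_spots(rbind(spot(0, 0), spot(1, 0), spot(2, 0)))
  expect_true(b$censored)
  expect_equal(b$value, 500)  # one plaque in 2 uL undiluted
  expect_error(titer_from_spots(spot(0, 0, cleared = TRUE)),
               "too concentrated")
  # counts present but outside the countable window: least-diluted
  # positive spot is used and flagged
  f <- titer_from_spots(rbind(spot(0, 2), spot(1, 1)))
  expect_false(f$censored)
  expect_equal(f$value, 2 / 0.002)
  expect_match(f$note, "outside")
})

test_that("EOP is the target/control titer ratio with censoring carried", {
  expect_equal(compute_eop(1e6, 1e6)$value, 1.0)
  expect_equal(compute_eop(1e4, 1e9)$value, 1e-5)
  b <- titer_from_spots(rbind(spot(0, 0), spot(1, 0)))
  e <- compute_eop(b, 2.5e9)
  expect_true(e$censored)
  expect_equal(e$value, 2e-7)  # "<2.0E-7"
  ctrl <- structure(list(value = 500, censored = TRUE), class = "titer_estimate")
  expect_error(compute_eop(1e4, ctrl), "invalid")
})

test_that("EOP is invariant to rescaling both titers", {
  set.seed(406)
  for (i in 1:20) {
    tt <- runif(1, 1e2, 1e9); ct <- runif(1, 1e2, 1e9)
    c0 <- compute_eop(tt, ct)$value
    s <- runif(1, 1e-3, 1e3)
    expect_equal(compute_eop(tt * s, ct * s)$value, c0)
  }
})

test_that("aggregation and classification follow the 3-log rule", {
  r <- aggregate_and_classify(c(1.0, 1.0))
  expect_equal(r$eop_mean, 1.0)
  expect_equal(r$eop_sd, 0.0)
  expect_equal(r$call, "NE")
  cens <- replicate(3, structure(list(value = 2e-7, censored = TRUE),
                                 class = "eop_value"), simplify = FALSE)
  rc <- aggregate_and_classify(cens)
  expect_true(rc$censored)
  expect_equal(rc$call, "E")
  expect_equal(aggregate_and_classify(c(5e-3, 5e-3))$call, "intermediate")
  expect_equal(aggregate_and_classify(c(2e-2, 2e-2))$call, "NE")
  # sample sd (n-1)
  r2 <- aggregate_and_classify(c(1e-4, 3e-4))
  expect_equal(r2$eop_sd, sd(c(1e-4, 3e-4)))
  # contradictory censored bound triggers a warning, uncensored values win
  mixed <- list(structure(list(value = 1e-6, censored = TRUE),
                          class = "eop_value"),
                structure(list(value = 0.5, censored = FALSE),
                          class = "eop_value"))
  expect_warning(rm1 <- aggregate_and_classify(mixed), "contradict")
  expect_equal(rm1$eop_mean, 0.5)
})

test_that("classification is monotone in the threshold", {
  set.seed(407)
  eops <- 10^runif(50, -8, 1)
  for (v in eops) {
    t1 <- aggregate_and_classify(v, threshold = 1e-3)$call
    t2 <- aggregate_and_classify(v, threshold = 1e-2)$call
    # raising the threshold never converts an E to NE
    if (t1 == "E") expect_true(t2 %in% c("E", "intermediate") || t2 == "E")
    if (t1 == "E") expect_false(t2 == "NE" && v <= 1e-3)
  }
  expect_equal(aggregate_and_classify(5e-3, threshold = 1e-2)$call, "E")
})

test_that("simulated counts recover a known EOP within Monte-Carlo error", {
  spec <- simulation_spec(seed = 51, true_eop = c(target = 1e-5),
                          n_replicates = 200)
  counts <- simulate_spot_counts(spec)
  # per-replicate EOP estimates for the standard-error check
  est <- replicate_eops(counts, "target")
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1e-5), 3 * se)
  tab <- analyze_spot_table(counts)
  expect_equal(tab$call[tab$locus_tag == "target"], "E")
})

test_that("a true EOP far below the detection limit reports a bound", {
  spec <- simulation_spec(seed = 53, true_eop = c(deep = 1e-9),
                          control_titer = 1e9, n_replicates = 3)
  counts <- simulate_spot_counts(spec)
  tab <- analyze_spot_table(counts)
  expect_true(tab$censored[tab$locus_tag == "deep"])
  expect_equal(tab$call[tab$locus_tag == "deep"], "E")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_eop_table(tab, tf)
  rendered <- read.delim(tf, stringsAsFactors = FALSE)
  expect_match(rendered$EOP_average[rendered$locus_tag == "deep"], "^<")
})

test_that("fixture call tallies count E/NE/NT columns", {
  tl <- tally_calls(c("E", "NE", "E", "", NA, "NT"))
  expect_equal(unname(tl["E"]), 2L)
  expect_equal(unname(tl["NE"]), 1L)
  expect_equal(unname(tl["NT"]), 3L)
})
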