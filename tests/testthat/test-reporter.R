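# Shared builder: a plate with one experiment/vehicle pair plus medium wells.
flat_reporter_plate <- function(od_exp = 0.24, gfp_exp = 250,
                                od_veh = 0.24, gfp_veh = 150,
                                od_med = 0.04, gfp_med = 50,
                                times = seq(0, 120, by = 5)) {
  n <- length(times)
  od <- rbind(rep(od_exp, n), rep(od_veh, n), rep(od_med, n), rep(od_med, n))
  gfp <- rbind(rep(gfp_exp, n), rep(gfp_veh, n), rep(gfp_med, n), rep(gfp_med, n))
  wells <- data.frame(
    well = c("E1", "V1", "M1", "M0"),
    orf = c("ORF1", "ORF1", NA, NA),
    stress_category = c("general", "general", NA, NA),
    dose_mgL = c(10, 0, 10, 0),
    role = c("experiment", "vehicle-control", "medium-control", "medium-control"),
    replicate = 1)
  reporter_plate(times, od, gfp, wells)
}

test_that("medium-control correction subtracts matched backgrounds", {
  plate <- flat_reporter_plate()
  corr <- correct_signals(plate)
  expect_equal(unname(corr$od["E1", ]), rep(0.20, length(plate$times)))
  expect_equal(unname(corr$gfp["E1", ]), rep(200, length(plate$times)))
  expect_false(corr$wells$floored[corr$wells$well == "E1"])

  # sample equal to medium control floors at epsilon and flags
  deg <- flat_reporter_plate(od_exp = 0.04, gfp_exp = 50)
  cd <- correct_signals(deg)
  expect_true(cd$wells$floored[cd$wells$well == "E1"])
  expect_true(all(cd$od["E1", ] > 0))

  # randomized drift equals the element-wise oracle
  set.seed(30)
  times <- seq(0, 120, by = 5)
  n <- length(times)
  od_drift <- 0.04 + 0.005 * sin(times / 20)
  gfp_drift <- 50 + 3 * cos(times / 15)
  od_s <- runif(n, 0.2, 0.5); gfp_s <- runif(n, 150, 400)
  od <- rbind(od_s, od_drift, od_drift)
  gfp <- rbind(gfp_s, gfp_drift, gfp_drift)
  wells <- data.frame(well = c("E1", "M1", "M2"), orf = c("o", NA, NA),
                      stress_category = NA, dose_mgL = c(10, 10, 10),
                      role = c("experiment", "medium-control", "medium-control"),
                      replicate = 1)
  corr2 <- correct_signals(reporter_plate(times, od, gfp, wells))
  expect_equal(unname(corr2$od["E1", ]), od_s - od_drift)
  expect_equal(unname(corr2$gfp["E1", ]), gfp_s - gfp_drift)

  # missing medium control errors
  no_med <- flat_reporter_plate()
  no_med$wells$role[3:4] <- "experiment"
  no_med$wells$orf[3:4] <- "ORFX"
  expect_error(correct_signals(no_med), "medium-control")
})

test_that("expression level and induction are pointwise ratios", {
  expect_equal(expression_level(rep(200, 5), rep(0.2, 5)), rep(1000, 5))
  set.seed(31)
  g <- runif(25, 100, 500); o <- runif(25, 0.1, 0.6)
  expect_equal(expression_level(g, o), g / o)
  expect_equal(expression_level(2 * g, 2 * o), g / o)
  expect_error(expression_level(g, o[-1]), "shape")

  expect_equal(induction_series(g / o, g / o), rep(1, 25))
  expect_equal(induction_series(2 * g / o, g / o), rep(2, 25))
  expect_error(induction_series(1:3, 1:4), "time grids")
})

test_that("plate normalization divides by internal-control medians", {
  P <- matrix(runif(40, 500, 1500), 4, 10)
  Pn <- plate_normalize(P, 3:4)
  ref <- apply(P[3:4, ], 2, median)
  expect_equal(Pn, sweep(P, 2, ref, "/"))

  ones <- matrix(1, 2, 10)
  expect_equal(plate_normalize(rbind(P[1:2, ], ones), 3:4)[1:2, ], P[1:2, ])
  expect_warning(plate_normalize(P, integer()), "skipped")

  # a plate-wide multiplicative factor cancels between two plates
  factor <- 1.3
  Pn1 <- plate_normalize(P, 3:4)
  Pn2 <- plate_normalize(P * factor, 3:4)
  expect_equal(Pn1, Pn2, tolerance = 1e-9)
})

test_that("PELI is the time-average of induction with trapezoid quadrature", {
  times <- seq(0, 120, by = 5)
  expect_equal(peli(rep(1, length(times)), times), 1)
  I_lin <- 1 + 2 * times / 120
  expect_equal(peli(I_lin, times), 2)

  set.seed(32)
  I_rand <- runif(25, 0.5, 3)
  expect_equal(peli(I_rand, times),
               pracma::trapz(times, I_rand) / 120, tolerance = 1e-12)
  # linearity: peli(a I + b) = a peli(I) + b
  expect_equal(peli(3 * I_rand + 0.5, times), 3 * peli(I_rand, times) + 0.5)
  expect_error(peli(1, 0), "2 time points")
})

test_that("replicate aggregation and activation calls follow the cutoff", {
  ag <- aggregate_and_call(c(1.6, 1.7, 1.8))
  expect_equal(ag$mean, 1.7)
  expect_true(ag$activated)
  expect_false(aggregate_and_call(c(1.0, 1.0, 1.0))$activated)
  single <- aggregate_and_call(1.2)
  expect_true(single$single_replicate)
  expect_equal(single$sd, 0)

  # activation count nonincreasing in the cutoff
  set.seed(33)
  pelis <- runif(50, 0.5, 3)
  counts <- sapply(c(1, 1.5, 2, 2.5),
                   function(cut) sum(pelis > cut))
  expect_true(all(diff(counts) <= 0))
})

test_that("vehicle-vs-vehicle analysis is exactly null through the pipeline", {
  orfs <- data.frame(orf = c("ORF1", "ORF2"), category = "general")
  sim <- simulate_reporter_plate(
    reporter_sim_config(orfs, I_star = 1, sigma_od = 0, sigma_gfp = 0, seed = 1))
  res <- peli_analysis(sim$plate)
  expect_equal(unname(res$induction), matrix(1, nrow(res$induction), ncol(res$induction)))
  expect_equal(res$records$peli_mean, rep(1, 2))
  expect_false(any(res$records$activated))
  hm <- heatmap_export(list("10" = res$induction[c("E_ORF1_10_r1", "E_ORF2_10_r1"), ]),
                       c(E_ORF1_10_r1 = "general", E_ORF2_10_r1 = "general"))
  expect_true(all(hm == 0))
})

test_that("heat-map export is elementwise ln grouped by category", {
  set.seed(34)
  I1 <- matrix(runif(6, 0.5, 3), 2, 3, dimnames = list(c("b_orf", "a_orf"), NULL))
  cats <- c(b_orf = "catZ", a_orf = "catA")
  hm <- heatmap_export(list(d10 = I1), cats, category_order = c("catA", "catZ"))
  expect_equal(rownames(hm), c("a_orf", "b_orf"))
  expect_equal(unname(hm["b_orf", ]), unname(log(I1["b_orf", ])))
  expect_equal(attr(hm, "row_category"), c("catA", "catZ"))
  one <- matrix(exp(1), 1, 4, dimnames = list("o", NULL))
  expect_equal(unname(heatmap_export(list(d = one), c(o = "c"))[1, ]), rep(1, 4))
})

test_that("rank profiles sort by PELI with lexicographic tie-breaks", {
  rec <- data.frame(orf = c("B", "A"), dose_mgL = 10, peli_mean = c(1, 2),
                    peli_sd = 0, n_rep = 3, activated = FALSE, category = "c")
  rp <- rank_profile(rec)
  expect_equal(rp$orf, c("A", "B"))

  ties <- data.frame(orf = c("C", "A", "B"), dose_mgL = 10, peli_mean = 1,
                     peli_sd = 0, n_rep = 3, activated = FALSE, category = "c")
  expect_equal(rank_profile(ties)$orf, c("A", "B", "C"))

  set.seed(35)
  rnd <- data.frame(orf = paste0("O", 1:20), dose_mgL = 10,
                    peli_mean = runif(20), peli_sd = 0, n_rep = 3,
                    activated = FALSE, category = "c")
  expect_equal(rank_profile(rnd)$orf, rnd$orf[order(-rnd$peli_mean, rnd$orf)])
})
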