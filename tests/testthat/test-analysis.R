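# Transfer functions, resonance picking, crossovers, condition matrix.

make_tf <- function(f, mag, phase = 0) {
  structure(tibble::tibble(frequency_hz = f,
                           ratio = 10^(mag / 20) * exp(2i * pi * phase),
                           magnitude_db = mag,
                           phase_cycles = rep_len(phase, length(f))),
            class = c("ear_tf", "tbl_df", "tbl", "data.frame"),
            node = "X3", kind = "relative", condition = "synthetic")
}

test_that("transfer kinds follow their closed forms", {
  f <- default_grid(100, 10000, 64)
  fit <- fitted_quiet()
  resp <- solve_response(fit, stim_bc(1), f)
  # doubled node motion: relative ratio 1 (0 dB, zero phase)
  fake <- resp
  fake$velocity_m_s[fake$node == "X3"] <- 2 * fake$velocity_m_s[fake$node == "X0"]
  attributes(fake) <- attributes(resp)
  tf <- transfer(fake, "X3", "relative")
  expect_equal(tf$ratio, rep(1 + 0i, 64))
  expect_equal(tf$magnitude_db, rep(0, 64))
  expect_equal(tf$phase_cycles, rep(0, 64))
  # identical node motion: exact zero ratio, floored magnitude
  fake$velocity_m_s[fake$node == "X3"] <- fake$velocity_m_s[fake$node == "X0"]
  attributes(fake) <- attributes(resp)
  tf0 <- transfer(fake, "X3", "relative")
  expect_true(all(tf0$magnitude_db == -300))
})

test_that("absolute = relative + 1 pointwise in the complex plane", {
  f <- default_grid(100, 10000, 128)
  for (cond in list("normal", "malleus_glued", c("is_joint_cut", "cochlea_drained"))) {
    p <- apply_perturbation(fitted_quiet(), cond)
    resp <- solve_response(p, stim_bc(1), f)
    for (nd in c("X3", "X5")) {
      rel <- transfer(resp, nd, "relative")
      abs_ <- transfer(resp, nd, "absolute")
      expect_equal(abs_$ratio, rel$ratio + 1, tolerance = 1e-14)
    }
  }
})

test_that("transfer guards its inputs", {
  f <- default_grid(100, 1000, 16)
  resp <- solve_response(fitted_quiet(), stim_bc(1), f)
  expect_error(transfer(resp, "X1"), "measurement site")
  expect_s3_class(transfer(resp, "X1", allow_any_node = TRUE), "ear_tf")
  expect_error(transfer(resp, "X3", "ac"), "stim_ac")
  ac <- solve_response(fitted_quiet(), stim_ac(1), f)
  expect_s3_class(transfer(ac, "X3", "ac"), "ear_tf")
})

test_that("resonance picking recovers a one-DOF oscillator peak", {
  # |1 / (k - m w^2 + i c w)| with m = 1 kg, k = (2 pi 1000)^2 N/m peaks at
  # f0 sqrt(1 - 2 zeta^2); zeta = 0.05 puts it at 997.5 Hz
  m <- 1; f0 <- 1000; k <- (2 * pi * f0)^2; zeta <- 0.05
  c_ <- 2 * zeta * sqrt(k * m)
  f <- default_grid(100, 10000, 512)
  w <- 2 * pi * f
  mag <- 20 * log10(Mod(1 / (k - m * w^2 + 1i * c_ * w)))
  res <- find_resonances(make_tf(f, mag))
  pk <- res[res$type == "peak", ]
  expect_equal(nrow(pk), 1)
  expect_equal(pk$f_hz, f0 * sqrt(1 - 2 * zeta^2), tolerance = 0.01)
})

test_that("monotone curves yield no extrema and small grids are rejected", {
  f <- default_grid(100, 10000, 64)
  res <- find_resonances(make_tf(f, seq(-40, 0, length.out = 64)))
  expect_equal(nrow(res), 0)
  expect_error(find_resonances(make_tf(f[1:8], rep(0, 8))), "16")
})

test_that("crossovers are exact on data linear in log-frequency", {
  f <- default_grid(100, 10000, 128)
  a <- make_tf(f, 3 * (log10(f) - log10(400)))  # crosses zero at 400 Hz
  b <- make_tf(f, rep(0, 128))
  expect_equal(crossover(a, b), 400, tolerance = 1e-9)
  expect_length(crossover(a, a), 0)
  expect_error(crossover(a, make_tf(f[-1], rep(0, 127))), "same frequency grid")
})

test_that("the condition matrix has the full 12-curve protocol with both kinds", {
  cm <- run_condition_matrix(frequencies = default_grid(100, 10000, 128))
  expect_equal(nrow(cm), 24)
  curves <- unique(paste(cm$site, cm$condition))
  expect_length(curves, 12)
  expect_equal(sum(cm$site == "umbo"), 10)
  expect_equal(sum(cm$site == "stapes"), 14)
  td <- tidy(cm)
  expect_named(td, c("condition", "site", "node", "kind", "frequency_hz",
                     "magnitude_db", "phase_cycles"))
  expect_equal(nrow(td), 24 * 128)
})

test_that("perturbations move the curves in the measured directions", {
  f <- default_grid()
  cm <- run_condition_matrix(frequencies = f)
  g <- function(site, cond) {
    cm$tf[cm$site == site & cm$condition == cond & cm$kind == "relative"][[1]]
  }
  # separating the IS joint hardly affects the umbo: mean change ~1 dB on a
  # curve spanning >40 dB, worst-case a few dB near the resonance
  d_cut <- abs(g("umbo", "is_joint_cut")$magnitude_db -
               g("umbo", "normal")$magnitude_db)
  expect_lt(mean(d_cut), 2)
  expect_lt(max(d_cut), 5)
  # gluing the stapes suppresses its motion at every grid frequency
  expect_true(all(g("stapes", "stapes_glued")$magnitude_db <
                  g("stapes", "normal")$magnitude_db))
  # mass on the eardrum lowers the first umbo resonance
  pk <- function(tf) {
    r <- find_resonances(tf)
    r$f_hz[r$type == "peak"][1]
  }
  expect_lt(pk(g("umbo", "mass_100mg_umbo")), pk(g("umbo", "normal")))
  # draining the cochlea lowers the stapes curve at 1 kHz and raises it at 8 kHz
  at <- function(tf, f0) tf$magnitude_db[which.min(abs(tf$frequency_hz - f0))]
  expect_lt(at(g("stapes", "cochlea_drained"), 1000), at(g("stapes", "normal"), 1000))
  expect_gt(at(g("stapes", "cochlea_drained"), 8000), at(g("stapes", "normal"), 8000))
})

test_that("unadjusted adopted parameter sets rise below 1 kHz and plateau above", {
  f <- default_grid(100, 10000, 256)
  for (nm in c("feng_gan_2004", "rosowski_merchant_1995")) {
    p <- builtin_params(nm, quiet = TRUE)
    resp <- suppressMessages(solve_response(p, stim_bc(1), f))
    for (nd in c("X3", "X5")) {
      y <- transfer(resp, nd, "relative")$magnitude_db
      low <- y[f >= 100 & f <= 800]
      expect_true(all(diff(low) > 0), label = paste(nm, nd, "monotone rise"))
      rise <- max(y[f <= 1000]) - min(y[f <= 1000])
      plateau_variation <- sum(abs(diff(y[f >= 3000])))
      expect_lt(plateau_variation, rise)
    }
  }
})

test_that("glance summarises a transfer function", {
  resp <- solve_response(fitted_quiet(), stim_bc(1), default_grid())
  gl <- glance(transfer(resp, "X3"))
  expect_equal(gl$node, "X3")
  expect_equal(gl$n_freq, 512)
  expect_equal(gl$first_peak_hz, 2230, tolerance = 0.01)
})

test_that("autoplot produces ggplot objects", {
  resp <- solve_response(fitted_quiet(), stim_bc(1), default_grid(100, 10000, 64))
  expect_s3_class(ggplot2::autoplot(transfer(resp, "X3")), "ggplot")
  cm <- run_condition_matrix(frequencies = default_grid(100, 10000, 32))
  expect_s3_class(ggplot2::autoplot(cm), "ggplot")
})
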