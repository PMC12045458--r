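# Built-in parameter sets, perturbation rules, and config-file round trips.

test_that("built-in sets carry the published values", {
  fit <- fitted_quiet()
  expect_equal(fit$M2, 1.35e-5)
  expect_equal(fit$K2, 20001)
  expect_equal(fit$M0, 5)
  expect_equal(fit$K9, 300)   # round-window stiffness
  expect_equal(fit$K6, 2500)
  fg <- builtin_params("feng_gan_2004", quiet = TRUE)
  expect_equal(fg$K2, 20001)
  expect_equal(fg$M2, 2.7e-6)
  expect_equal(fg$C1, 7e-5)
  rm_ <- builtin_params("rosowski_merchant_1995", quiet = TRUE)
  expect_equal(rm_$K1, 276.92)
  expect_equal(rm_$M5, 3e-6)
})

test_that("unknown set names fail listing the valid ones", {
  expect_error(builtin_params("bogus"), "fitted.*feng_gan_2004")
  expect_error(builtin_params("bogus"), "rosowski_merchant_1995")
})

test_that("absent source entries are substituted and logged", {
  op <- builtin_params("oconnor_puria_2008", quiet = TRUE)
  expect_equal(op$M1, 1.55e-6)  # canal air mass taken from Feng & Gan
  expect_equal(op$K2, 0)
  expect_equal(op$K1, 0)
  expect_equal(op$C1, 0.189)
  expect_gt(length(attr(op, "substitutions")), 0)
  expect_message(builtin_params("oconnor_puria_2008"), "substituted")
})

test_that("the fused incudomalleolar joint is a large constant and results are insensitive to it", {
  r1 <- builtin_params("rosowski_merchant_1995", quiet = TRUE)
  r2 <- builtin_params("rosowski_merchant_1995", fused_scale = 1e7, quiet = TRUE)
  expect_equal(r2$Kmi_t / r1$Kmi_t, 10)
  f <- default_grid(100, 10000, 64)
  t1 <- transfer(suppressMessages(solve_response(r1, stim_bc(1), f)), "X5")
  t2 <- transfer(suppressMessages(solve_response(r2, stim_bc(1), f)), "X5")
  expect_lt(max(abs(t1$magnitude_db - t2$magnitude_db)), 1e-3)
})

test_that("named perturbations apply the protocol's edits", {
  fit <- fitted_quiet()
  expect_equal(apply_perturbation(fit, "stapes_glued")$K8, 5e4)
  expect_equal(apply_perturbation(fit, "malleus_glued")$Km_t, 0.8)
  loaded <- apply_perturbation(fit, "mass_100mg_umbo")
  expect_equal(loaded$M2, 1.35e-5 + 1e-4)
  expect_equal(loaded$C1, 0.4)
  drained <- apply_perturbation(fit, c("is_joint_cut", "cochlea_drained"))
  expect_equal(drained$C9, 0)
  expect_equal(drained$K9, 0)
  expect_equal(drained$M6, 0)
  lit <- apply_perturbation(fit, "cochlea_drained", drain_fluid_mass = FALSE)
  expect_equal(lit$M6, fit$M6)
})

test_that("both joint-cut variants are available and behave as documented", {
  fit <- fitted_quiet()
  k6 <- apply_perturbation(fit, "is_joint_cut")  # default variant
  expect_equal(k6$K6, 0)
  expect_equal(k6$C6, 0)
  expect_equal(k6$K8, fit$K8)
  k8 <- apply_perturbation(fit, "is_joint_cut", isjc_variant = "k8")  # printed rule
  expect_equal(k8$K8, 0)
  expect_equal(k8$C6, 0)
  expect_equal(k8$K6, fit$K6)
})

test_that("perturbations are pure and composable", {
  fit <- fitted_quiet()
  before <- unclass(fit)
  out <- apply_perturbation(fit, c("is_joint_cut", "mass_on_stapes"),
                            mass_kg = 20e-6, isjc_variant = "k8")
  expect_identical(unclass(fit), before)          # input untouched
  expect_equal(out$K8, 0)
  expect_equal(out$C6, 0)
  expect_equal(out$M5, 1.78e-6 + 2e-5)
  expect_identical(apply_perturbation(fit, "normal"), fit)
})

test_that("invalid edits are rejected", {
  fit <- fitted_quiet()
  expect_error(apply_perturbation(fit, "no_such_condition"), "valid conditions")
  expect_error(apply_perturbation(fit, list(list(field = "K99", action = "set", value = 1))),
               "unknown field")
  expect_error(apply_perturbation(fit, list(list(field = "M5", action = "add", value = -1))),
               "non-negative")
})

test_that("parameter files round-trip and support a base set", {
  dir <- withr::local_tempdir()
  for (nm in builtin_param_names()) {
    p0 <- builtin_params(nm, quiet = TRUE)
    path <- file.path(dir, paste0(nm, ".yml"))
    write_params(p0, path)
    p1 <- read_params(path)
    expect_equal(unclass(p1)[param_fields()], unclass(p0)[param_fields()])
  }
  # partial file on a declared base
  path <- file.path(dir, "heavy_tm.yml")
  writeLines(c("base: fitted", "M2: 2.0e-5"), path)
  p <- read_params(path)
  expect_equal(p$M2, 2e-5)
  expect_equal(p$K2, 20001)
  # missing fields with no base, and negative values, are rejected
  writeLines("M2: 1.0e-5", file.path(dir, "incomplete.yml"))
  expect_error(read_params(file.path(dir, "incomplete.yml")), "missing field")
  writeLines(c("base: fitted", "M2: -1"), file.path(dir, "neg.yml"))
  expect_error(read_params(file.path(dir, "neg.yml")), "negative")
})

test_that("parameter ratio report flags undefined ratios and recovers the eardrum factor", {
  fit <- fitted_quiet()
  fg <- builtin_params("feng_gan_2004", quiet = TRUE)
  rep <- parameter_ratio_report(fit, fg)
  expect_equal(rep$ratio[rep$field == "M2"], 5)
  expect_false(rep$defined[rep$field == "Km_t"])  # absent from the reference
  expect_true(is.na(rep$ratio[rep$field == "Km_t"]))
  self <- parameter_ratio_report(fit, fit)
  expect_true(all(self$ratio[self$defined] == 1))
})

test_that("every coupling symbol used by the assembly maps to one parameter field", {
  # jitter one field at a time: each must change at least one matrix entry,
  # i.e. no field is silently unused by the assembly
  fit <- fitted_quiet()
  mats0 <- assemble_matrices(fit)
  flat0 <- c(mats0$M, mats0$C, mats0$K)
  for (f in setdiff(param_fields(), "A_canal")) {
    vals <- unclass(fit)[param_fields()]
    vals[[f]] <- vals[[f]] * 2 + 1e-12
    p <- do.call(ear_params, c(list(name = "jitter"), vals))
    m <- assemble_matrices(p)
    expect_false(all(c(m$M, m$C, m$K) == flat0), label = paste("field", f))
  }
})
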