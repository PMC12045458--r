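# Model parameters: field registry, built-in sets, config-file I/O.

# One row per mechanical element of the six-node network. Torsional
# quantities carry the `_t` suffix so that translational (N/m, N s/m) and
# torsional (N m/rad, N m s/rad) units are never mixed in one field.
param_info <- function() {
  tibble::tribble(
    ~field,    ~unit,        ~description,
    "M0",      "kg",         "mass of the skull (rigid-body reference)",
    "M1",      "kg",         "mass of air in the ear canal",
    "M2",      "kg",         "mass of the tympanic membrane",
    "M5",      "kg",         "mass of the stapes",
    "M6",      "kg",         "mass of the cochlear fluid (moves with the stapes)",
    "I3",      "kg m^2",     "moment of inertia of the malleus about its rotation axis",
    "I4",      "kg m^2",     "moment of inertia of the incus about its rotation axis",
    "L3",      "m",          "malleus lever length, rotation axis to umbo",
    "L4",      "m",          "incus lever length, rotation axis to lenticular tip",
    "K1",      "N/m",        "tympanic membrane to skull stiffness",
    "C1",      "N s/m",      "tympanic membrane to skull damping",
    "K2",      "N/m",        "ear-canal air to tympanic membrane coupling stiffness",
    "C2",      "N s/m",      "ear-canal air to tympanic membrane coupling damping",
    "K3",      "N/m",        "tympanic membrane to malleus (umbo) coupling stiffness",
    "C3",      "N s/m",      "tympanic membrane to malleus (umbo) coupling damping",
    "Km_t",    "N m/rad",    "malleus suspension torsional stiffness",
    "Cm_t",    "N m s/rad",  "malleus suspension torsional damping",
    "Kmi_t",   "N m/rad",    "incudomalleolar joint torsional stiffness",
    "Cmi_t",   "N m s/rad",  "incudomalleolar joint torsional damping",
    "Ki_t",    "N m/rad",    "incus suspension torsional stiffness",
    "Ci_t",    "N m s/rad",  "incus suspension torsional damping",
    "K6",      "N/m",        "incudostapedial joint stiffness",
    "C6",      "N s/m",      "incudostapedial joint damping",
    "K8",      "N/m",        "stapedial annular ligament stiffness",
    "C8",      "N s/m",      "stapedial annular ligament damping",
    "K9",      "N/m",        "round-window membrane stiffness",
    "C9",      "N s/m",      "cochlear fluid damping (resistance)",
    "A_canal", "m^2",        "ear-canal cross-sectional area (AC stimulation only)"
  )
}

param_fields <- function() param_info()$field

# Fields that divide or otherwise must stay strictly positive. Everything
# else may be zeroed, either by a perturbation or by an absent ("n/a")
# entry of an adopted parameter set.
.strictly_positive <- c("M0", "I3", "I4", "L3", "L4")

#' Construct and validate a middle-ear parameter set
#'
#' Bundles every mass, moment of inertia, lever length, stiffness and
#' damping of the lumped-element middle-ear model into a validated record.
#' Use [builtin_params()] for the shipped literature sets and
#' [read_params()] to load a set from a YAML file.
#'
#' @param name Identifier for the set.
#' @param ... Named numeric fields; the full list with units is returned by
#'   [param_info()]. All fields are SI. All values must be finite and
#'   non-negative; `M0`, `I3`, `I4`, `L3` and `L4` must be strictly
#'   positive.
#' @param substitutions Character vector recording value substitutions made
#'   while assembling the set (kept as an attribute, surfaced by the
#'   command-line tools).
#'
#' @return An `ear_params` object (a named list of doubles with a `name`).
#' @seealso [builtin_params()], [apply_perturbation()], [tidy.ear_params()]
#' @export
ear_params <- function(name, ..., substitutions = character()) {
  vals <- list(...)
  fields <- param_fields()
  missing <- setdiff(fields, names(vals))
  if (length(missing) > 0) {
    abort(paste0("missing parameter field(s): ", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(vals), fields)
  if (length(extra) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(extra, collapse = ", ")))
  }
  p <- lapply(vals[fields], function(x) as.numeric(x)[1])
  p <- structure(p, name = as.character(name)[1],
                 substitutions = substitutions, class = "ear_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  for (f in param_fields()) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("parameter ", f, " must be a single finite number"))
    }
    if (v < 0) abort(paste0("parameter ", f, " is negative (", v, ")"))
  }
  for (f in .strictly_positive) {
    if (p[[f]] <= 0) abort(paste0("parameter ", f, " must be strictly positive"))
  }
  if (p$M5 + p$M6 <= 0) abort("M5 + M6 must be strictly positive")
  invisible(p)
}

#' @export
print.ear_params <- function(x, ...) {
  cat("<ear_params> ", attr(x, "name"), "\n", sep = "")
  print(tidy(x), n = Inf)
  subs <- attr(x, "substitutions")
  if (length(subs) > 0) cat("substitutions:\n", paste0("  - ", subs, "\n"), sep = "")
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x An `ear_params` object.
#' @param ... Unused.
#' @return A tibble with columns `field`, `value`, `unit`, `description`.
#' @export
tidy.ear_params <- function(x, ...) {
  info <- param_info()
  info$value <- vapply(info$field, function(f) x[[f]], numeric(1))
  info[, c("field", "value", "unit", "description")]
}

# -------------------------------------------------------------------------
# Built-in parameter sets.
#
# The fitted set is the model's own parameterisation; the other three are
# the literature air-conduction parameterisations it was seeded from
# (converted to this model's node variables with the malleus length
# Lm = 6.28e-3 m, incus length Li = 4.83e-3 m, footplate area
# Afp = 3.2e-6 m^2 and tympanic-membrane area Atm = 6e-5 m^2, e.g.
# I3 = M3 * Lm^2 and torsional Km_t = Km * Lm^2).
#
# Entries absent from a source model ("n/a") are zero except:
#   * the ear-canal air mass M1, which is substituted from Feng & Gan so
#     that the canal node exists in every simulation;
#   * the skull mass, absent from all three sources, filled with the fitted
#     5 kg (it only sets the rigid-body reference motion);
#   * the fused (rigid) incudomalleolar joint of Rosowski & Merchant, which
#     is represented by a large finite stiffness/damping, `fused_scale`
#     times the fitted joint values. Results are insensitive to the exact
#     factor (see the package tests).
# -------------------------------------------------------------------------

.L_MALLEUS <- 6.28e-3
.L_INCUS <- 4.83e-3

.fitted <- list(
  M0 = 5, M1 = 1.55e-6, M2 = 1.35e-5, M5 = 1.78e-6, M6 = 3.1875e-6,
  I3 = 7.9e-11, I4 = 5e-11, L3 = .L_MALLEUS, L4 = .L_INCUS,
  K1 = 2000, C1 = 0.1, K2 = 20001, C2 = 0.5, K3 = 10000, C3 = 0.1,
  Km_t = 1e-4, Cm_t = 2.405e-7, Kmi_t = 1, Cmi_t = 1e-5,
  Ki_t = 2.3e-5, Ci_t = 2.335e-8,
  K6 = 2500, C6 = 0.05, K8 = 1000, C8 = 0.04,
  K9 = 300, C9 = 0.16, A_canal = 4e-5
)

.feng_gan <- list(
  M0 = 5, M1 = 1.55e-6, M2 = 2.7e-6, M5 = 1.78e-6, M6 = 2.55e-5,
  I3 = 1.58e-10, I4 = 9.33e-11, L3 = .L_MALLEUS, L4 = .L_INCUS,
  K1 = 1175, C1 = 7e-5, K2 = 20001, C2 = 0.5, K3 = 94740, C3 = 1.74,
  Km_t = 0, Cm_t = 4.81e-6, Kmi_t = 30.33, Cmi_t = 1.09e-5,
  Ki_t = 0, Ci_t = 4.67e-7,
  K6 = 167, C6 = 2.8e-4, K8 = 623, C8 = 4e-5,
  K9 = 0, C9 = 0.2, A_canal = 4e-5
)

.oconnor_puria <- list(
  M0 = 5, M1 = 1.55e-6, M2 = 0, M5 = 3.5e-6, M6 = 0,
  I3 = 1.28e-10, I4 = 1.7e-10, L3 = .L_MALLEUS, L4 = .L_INCUS,
  K1 = 0, C1 = 0.189, K2 = 0, C2 = 0, K3 = 0, C3 = 0.189,
  Km_t = 0.02, Cm_t = 0.14, Kmi_t = 0.0443, Cmi_t = 1.38e-6,
  Ki_t = 0, Ci_t = 0,
  K6 = 1e4, C6 = 3.04e-2, K8 = 798.63, C8 = 0.0986,
  K9 = 295.80, C9 = 0.1962, A_canal = 4e-5
)

.rosowski_merchant <- list(
  M0 = 5, M1 = 1.55e-6, M2 = 2.7e-6, M5 = 3e-6, M6 = 2.46e-5,
  I3 = 1.56e-10, I4 = 9.21e-11, L3 = .L_MALLEUS, L4 = .L_INCUS,
  K1 = 276.92, C1 = 0.0432, K2 = 0, C2 = 0, K3 = 909.09, C3 = 0.043,
  Km_t = 0, Cm_t = 1.42e-7, Kmi_t = NA, Cmi_t = NA,  # fused joint, filled below
  Ki_t = 0, Ci_t = 8.4e-8,
  K6 = 2041, C6 = 3.6, K8 = 1089, C8 = 0,
  K9 = 0, C9 = 0.2048, A_canal = 4e-5
)

.builtin_names <- c("fitted", "feng_gan_2004", "oconnor_puria_2008",
                    "rosowski_merchant_1995")

#' Built-in middle-ear parameter sets
#'
#' Returns one of the four shipped parameter sets: the model's own fitted
#' set, or one of the three literature air-conduction parameterisations
#' used to seed it (Feng & Gan 2004, O'Connor & Puria 2008, Rosowski &
#' Merchant 1995).
#'
#' For the literature sets, values their source models do not contain are
#' filled in: the ear-canal air mass is taken from Feng & Gan, the skull
#' mass from the fitted set, absent stiffness/damping elements are zero,
#' and the rigid ("fused") incudomalleolar joint of Rosowski & Merchant is
#' represented by a large finite stiffness and damping, `fused_scale`
#' times the fitted joint values. Each substitution is recorded in the
#' returned object and, unless `quiet = TRUE`, reported as a message.
#'
#' @param name One of `"fitted"`, `"feng_gan_2004"`,
#'   `"oconnor_puria_2008"`, `"rosowski_merchant_1995"`.
#' @param fused_scale Multiplier on the fitted incudomalleolar joint values
#'   used to represent a fused joint. Default `1e6`.
#' @param quiet Suppress substitution messages.
#' @return An [ear_params] object.
#' @examples
#' builtin_params("fitted")$M2  # 1.35e-5 kg
#' @export
builtin_params <- function(name, fused_scale = 1e6, quiet = FALSE) {
  if (length(name) != 1 || !name %in% .builtin_names) {
    abort(paste0("unknown parameter set ", deparse(name), "; valid sets: ",
                 paste(.builtin_names, collapse = ", ")))
  }
  subs <- character()
  vals <- switch(name,
    fitted = .fitted,
    feng_gan_2004 = {
      subs <- "skull mass M0 absent from Feng & Gan; using fitted 5 kg"
      .feng_gan
    },
    oconnor_puria_2008 = {
      subs <- c(
        "ear-canal air mass M1 absent from O'Connor & Puria; substituted from Feng & Gan (1.55e-6 kg)",
        "skull mass M0 absent from O'Connor & Puria; using fitted 5 kg",
        "tympanic-membrane mass M2 and cochlear-fluid mass M6 absent; set to 0",
        "absent stiffness/damping elements (K1, K2, C2, K3, Ki_t, Ci_t) set to 0"
      )
      .oconnor_puria
    },
    rosowski_merchant_1995 = {
      v <- .rosowski_merchant
      v$Kmi_t <- fused_scale * .fitted$Kmi_t
      v$Cmi_t <- fused_scale * .fitted$Cmi_t
      subs <- c(
        "ear-canal air mass M1 absent from Rosowski & Merchant; substituted from Feng & Gan (1.55e-6 kg)",
        "skull mass M0 absent from Rosowski & Merchant; using fitted 5 kg",
        paste0("fused incudomalleolar joint represented by Kmi_t = ", v$Kmi_t,
               " N m/rad, Cmi_t = ", v$Cmi_t, " N m s/rad (fused_scale = ",
               fused_scale, ")"),
        "absent stiffness elements (K2, C2, K9) set to 0"
      )
      v
    }
  )
  if (!quiet && length(subs) > 0) {
    inform(c(paste0("parameter set ", name, ": substituted values"),
             setNames(subs, rep("*", length(subs)))))
  }
  do.call(ear_params, c(list(name = name), vals, list(substitutions = subs)))
}

#' @rdname builtin_params
#' @export
builtin_param_names <- function() .builtin_names

# -------------------------------------------------------------------------
# Config-file I/O (YAML, keys named exactly as the ear_params fields)
# -------------------------------------------------------------------------

#' Read or write a parameter set as a YAML file
#'
#' The file holds `field: value` pairs in SI units, keyed exactly as the
#' [ear_params] fields, plus an optional `name:`. A `base:` key naming a
#' built-in set allows partial files: unlisted fields are filled from the
#' base set. Writing then re-reading any set reproduces it exactly.
#'
#' @param path File path.
#' @param quiet Passed to [builtin_params()] when a `base:` set is loaded.
#' @return `read_params()` returns an [ear_params]; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path, quiet = TRUE) {
  raw <- yaml::read_yaml(path)
  base_name <- raw[["base"]]
  nm <- raw[["name"]] %||% base_name %||%
    sub("\\.[^.]*$", "", basename(path))
  raw$base <- NULL
  raw$name <- NULL
  extra <- setdiff(names(raw), param_fields())
  if (length(extra) > 0) {
    abort(paste0("unknown field(s) in ", path, ": ", paste(extra, collapse = ", ")))
  }
  if (!is.null(base_name)) {
    base <- builtin_params(base_name, quiet = quiet)
    vals <- unclass(base)[param_fields()]
    vals[names(raw)] <- raw
  } else {
    missing <- setdiff(param_fields(), names(raw))
    if (length(missing) > 0) {
      abort(paste0("missing field(s) in ", path, " (no base set declared): ",
                   paste(missing, collapse = ", ")))
    }
    vals <- raw
  }
  do.call(ear_params, c(list(name = nm), vals))
}

#' @rdname read_params
#' @param params An [ear_params] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ear_params"))
  out <- c(list(name = attr(params, "name")),
           lapply(unclass(params)[param_fields()], identity))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
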