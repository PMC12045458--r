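# Virtual experimental ear conditions and parameter edits.

.conditions <- c("normal", "stapes_glued", "malleus_glued", "mass_100mg_umbo",
                 "is_joint_cut", "mass_on_stapes", "cochlea_drained")

#' Named experimental ear conditions
#'
#' The seven ear conditions of the bone-conduction measurement protocol the
#' model reproduces. `mass_on_stapes` and `cochlea_drained` were performed
#' (and are simulated) after the incudostapedial joint was separated; use
#' e.g. `c("is_joint_cut", "cochlea_drained")` with [apply_perturbation()]
#' to compose them.
#'
#' @return Character vector of condition names.
#' @export
ear_conditions <- function() .conditions

#' Perturbation specification for an ear condition
#'
#' Expands a named condition into its parameter edits. Each edit is a
#' `(field, action, value)` triple with `action` either `"set"` or
#' `"add"`.
#'
#' * `normal` - no edits.
#' * `stapes_glued` - stapedial annular ligament stiffened: `K8 := 5e4`.
#' * `malleus_glued` - malleus head fixed: torsional `Km_t := 0.8`.
#' * `mass_100mg_umbo` - 100 mg added to the eardrum mass (`M2 += 1e-4`)
#'   with eardrum damping raised to `C1 := 0.4`.
#' * `is_joint_cut` - incudostapedial joint separated. The default
#'   (`isjc_variant = "k6"`) removes the joint itself, `K6 := 0, C6 := 0`.
#'   The measurement protocol's table prints `K8 := 0, C6 := 0` instead
#'   (which leaves the joint stiffness active and does not reproduce the
#'   described loss of the 2 kHz stapes resonance); that literal rule is
#'   available as `isjc_variant = "k8"`. Neither is applied silently: the
#'   variant in force is recorded in the perturbation name.
#' * `mass_on_stapes` - `mass_kg` added to the stapes mass (default 20 mg;
#'   the protocol also exercises 7.5 mg).
#' * `cochlea_drained` - the cochlea emptied of fluid. Removes the fluid
#'   resistance and round-window load (`C9 := 0, K9 := 0`) and, by default,
#'   the entrained fluid mass (`M6 := 0`, `drain_fluid_mass = TRUE`);
#'   `drain_fluid_mass = FALSE` gives the literal `C9/K9`-only rule, which
#'   does not reproduce the observed low-frequency suppression.
#'
#' @param name A condition name from [ear_conditions()].
#' @param mass_kg Added mass for `mass_on_stapes`, kg.
#' @param isjc_variant `"k6"` (default) or `"k8"`, see above.
#' @param drain_fluid_mass Whether `cochlea_drained` also zeroes `M6`.
#' @return A `perturbation` object: list with `name` and `edits`.
#' @export
perturbation <- function(name, mass_kg = 20e-6,
                         isjc_variant = c("k6", "k8"),
                         drain_fluid_mass = TRUE) {
  if (length(name) != 1 || !name %in% .conditions) {
    abort(paste0("unknown ear condition ", deparse(name), "; valid conditions: ",
                 paste(.conditions, collapse = ", ")))
  }
  isjc_variant <- match.arg(isjc_variant)
  edit <- function(field, action, value) list(field = field, action = action, value = value)
  edits <- switch(name,
    normal = list(),
    stapes_glued = list(edit("K8", "set", 5e4)),
    malleus_glued = list(edit("Km_t", "set", 0.8)),
    mass_100mg_umbo = list(edit("M2", "add", 1e-4), edit("C1", "set", 0.4)),
    is_joint_cut = if (isjc_variant == "k6") {
      list(edit("K6", "set", 0), edit("C6", "set", 0))
    } else {
      list(edit("K8", "set", 0), edit("C6", "set", 0))
    },
    mass_on_stapes = list(edit("M5", "add", mass_kg)),
    cochlea_drained = c(
      list(edit("C9", "set", 0), edit("K9", "set", 0)),
      if (drain_fluid_mass) list(edit("M6", "set", 0))
    )
  )
  label <- name
  if (name == "is_joint_cut" && isjc_variant == "k8") label <- "is_joint_cut[k8]"
  if (name == "mass_on_stapes") label <- sprintf("mass_on_stapes[%gmg]", mass_kg * 1e6)
  if (name == "cochlea_drained" && !drain_fluid_mass) label <- "cochlea_drained[keep_M6]"
  structure(list(name = label, condition = name, edits = edits),
            class = "perturbation")
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation> ", x$name, "\n", sep = "")
  for (e in x$edits) cat(sprintf("  %s %s %g\n", e$field, e$action, e$value))
  invisible(x)
}

#' Apply a perturbation to a parameter set
#'
#' Pure function: returns an edited copy, the input is unchanged.
#' Perturbations compose; pass several condition names (or `perturbation`
#' objects) to apply them in order, e.g. the post-separation conditions
#' `c("is_joint_cut", "mass_on_stapes")`.
#'
#' @param params An [ear_params] object.
#' @param spec A condition name, a character vector of names applied in
#'   order, a [perturbation] object, or a list of explicit edits (each a
#'   `list(field =, action = "set"|"add", value =)`).
#' @inheritParams perturbation
#' @return A new [ear_params] whose name records the perturbation chain.
#' @examples
#' fit <- builtin_params("fitted")
#' apply_perturbation(fit, "stapes_glued")$K8  # 5e4
#' @export
apply_perturbation <- function(params, spec, mass_kg = 20e-6,
                               isjc_variant = c("k6", "k8"),
                               drain_fluid_mass = TRUE) {
  stopifnot(inherits(params, "ear_params"))
  isjc_variant <- match.arg(isjc_variant)
  if (is.character(spec)) {
    out <- params
    for (nm in spec) {
      out <- apply_perturbation(out, perturbation(nm, mass_kg = mass_kg,
                                                  isjc_variant = isjc_variant,
                                                  drain_fluid_mass = drain_fluid_mass))
    }
    return(out)
  }
  if (inherits(spec, "perturbation")) {
    label <- spec$name
    edits <- spec$edits
  } else if (is.list(spec)) {
    label <- "custom"
    edits <- spec
  } else {
    abort("spec must be a condition name, perturbation object, or list of edits")
  }
  vals <- unclass(params)[param_fields()]
  for (e in edits) {
    if (is.null(e$field) || !e$field %in% param_fields()) {
      abort(paste0("perturbation edit refers to unknown field ",
                   deparse(e$field %||% "<missing>")))
    }
    new <- switch(e$action,
      set = e$value,
      add = vals[[e$field]] + e$value,
      abort(paste0("unknown edit action ", deparse(e$action)))
    )
    if (!is.finite(new) || new < 0) {
      abort(paste0("perturbation would set ", e$field, " to ", new,
                   " (must be finite and non-negative)"))
    }
    vals[[e$field]] <- new
  }
  nm <- attr(params, "name")
  new_name <- if (label == "normal") nm else paste(nm, label, sep = " + ")
  do.call(ear_params, c(list(name = new_name), vals,
                        list(substitutions = attr(params, "substitutions"))))
}

#' Ratio of two parameter sets, field by field
#'
#' Compares a fitted parameter set with a reference set, reporting the
#' ratio `fitted / reference` for every field. Ratios with a zero
#' reference are undefined and returned as `NA` with `defined = FALSE`
#' (zero here means the element is absent from the reference model, not
#' that the ratio diverges).
#'
#' @param fitted,reference [ear_params] objects.
#' @return A tibble with columns `field`, `fitted`, `reference`, `ratio`,
#'   `defined`.
#' @examples
#' parameter_ratio_report(builtin_params("fitted", quiet = TRUE),
#'                        builtin_params("feng_gan_2004", quiet = TRUE))
#' @export
parameter_ratio_report <- function(fitted, reference) {
  stopifnot(inherits(fitted, "ear_params"), inherits(reference, "ear_params"))
  f <- vapply(param_fields(), function(x) fitted[[x]], numeric(1))
  r <- vapply(param_fields(), function(x) reference[[x]], numeric(1))
  tibble(field = param_fields(), fitted = unname(f), reference = unname(r),
         ratio = unname(ifelse(r == 0, NA_real_, f / r)),
         defined = unname(r != 0))
}
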