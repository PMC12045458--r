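# Transfer functions, resonance features, and the full condition matrix.

#' Velocity transfer function of a node
#'
#' Computes the complex velocity ratio of a node against the skull
#' (promontory) reference, or against the ear-canal pressure for AC runs:
#'
#' * `kind = "relative"`: `(Vnode - Vprom) / Vprom` - the differential
#'   motion that actually drives the cochlea in bone conduction;
#' * `kind = "absolute"`: `Vnode / Vprom`; satisfies
#'   `absolute = relative + 1` pointwise in the complex plane;
#' * `kind = "ac"`: `Vnode / Pec`, node velocity per ear-canal pressure
#'   (m/s/Pa), only defined for AC stimulation.
#'
#' Magnitude is `20 log10 |ratio|` (exact zeros floored at `floor_db`);
#' phase is unwrapped along increasing frequency and reported in cycles.
#' No smoothing is applied.
#'
#' @param resp An `ear_response` from [solve_response()].
#' @param node `"X3"` (umbo) or `"X5"` (stapes); other nodes only with
#'   `allow_any_node = TRUE`.
#' @param kind `"relative"`, `"absolute"` or `"ac"`.
#' @param condition Optional label carried along (defaults to the
#'   parameter-set name).
#' @param allow_any_node Allow nodes other than the two measurement sites.
#' @param floor_db Magnitude floor for exact-zero ratios, dB.
#' @return An `ear_tf` tibble: `frequency_hz`, `ratio` (complex),
#'   `magnitude_db`, `phase_cycles`; node/kind/condition as attributes.
#' @export
transfer <- function(resp, node = c("X3", "X5"),
                     kind = c("relative", "absolute", "ac"),
                     condition = NULL, allow_any_node = FALSE,
                     floor_db = -300) {
  stopifnot(inherits(resp, "ear_response"))
  kind <- match.arg(kind)
  if (length(node) != 1 && identical(node, c("X3", "X5"))) node <- "X3"
  if (!node %in% .nodes) {
    abort(paste0("node must be one of ", paste(.nodes, collapse = ", ")))
  }
  if (!allow_any_node && !node %in% c("X3", "X5")) {
    abort(paste0("node ", node, " is not a measurement site (umbo X3 or stapes X5); ",
                 "use allow_any_node = TRUE to extract it anyway"))
  }
  stim <- attr(resp, "stimulus")
  freq <- unique(resp$frequency_hz)
  vn <- resp$velocity_m_s[resp$node == node]
  if (kind == "ac") {
    if (is.null(stim) || stim$mode != "AC") {
      abort('kind = "ac" needs a response driven by stim_ac()')
    }
    if (stim$amplitude == 0) abort("AC transfer undefined for zero pressure")
    ratio <- vn / stim$amplitude
  } else {
    v0 <- resp$velocity_m_s[resp$node == "X0"]
    if (any(v0 == 0)) {
      abort(sprintf("reference (skull) velocity is zero at f = %g Hz; %s",
                    freq[which(v0 == 0)[1]],
                    "the relative transfer function is undefined"))
    }
    ratio <- if (kind == "relative") (vn - v0) / v0 else vn / v0
  }
  mag <- Mod(ratio)
  magnitude_db <- ifelse(mag == 0, floor_db, 20 * log10(mag))
  phase_cycles <- as.numeric(signal::unwrap(Arg(ratio))) / (2 * pi)
  condition <- condition %||% attr(attr(resp, "params"), "name")
  structure(tibble::new_tibble(
    tibble(frequency_hz = freq, ratio = ratio,
           magnitude_db = magnitude_db, phase_cycles = phase_cycles),
    class = "ear_tf"),
    node = node, kind = kind, condition = condition, stimulus = stim)
}

#' @export
print.ear_tf <- function(x, ...) {
  cat(sprintf("<ear_tf> node %s, kind %s, condition %s (%d frequencies)\n",
              attr(x, "node"), attr(x, "kind"), attr(x, "condition"), nrow(x)))
  NextMethod()
}

#' One-line summary of a transfer function
#'
#' @param x An `ear_tf`.
#' @param ... Unused.
#' @return One-row tibble: node, kind, condition, grid span, and the first
#'   resonance peak (if any).
#' @export
glance.ear_tf <- function(x, ...) {
  res <- find_resonances(x)
  pk <- res[res$type == "peak", ]
  tibble(node = attr(x, "node"), kind = attr(x, "kind"),
         condition = attr(x, "condition"), n_freq = nrow(x),
         fmin_hz = min(x$frequency_hz), fmax_hz = max(x$frequency_hz),
         first_peak_hz = if (nrow(pk) > 0) pk$f_hz[1] else NA_real_,
         first_peak_db = if (nrow(pk) > 0) pk$mag_db[1] else NA_real_)
}

# Strict local maxima of y with a topographic-prominence threshold.
# Prominence of a peak: drop to the highest of the two key saddles (the
# minimum between the peak and the nearest higher ground on each side;
# the boundary counts as higher ground at its own level).
.find_peaks <- function(x, y, prominence = 0.5, refine = TRUE) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) == -2) + 1L
  out <- tibble(f_hz = numeric(), mag_db = numeric(), prominence_db = numeric())
  for (i in idx) {
    left <- if (any(y[seq_len(i - 1)] > y[i])) {
      j <- max(which(y[seq_len(i - 1)] > y[i]))
      min(y[j:i])
    } else min(y[1:i])
    right <- if (any(y[(i + 1):n] > y[i])) {
      j <- i + min(which(y[(i + 1):n] > y[i]))
      min(y[i:j])
    } else min(y[i:n])
    prom <- y[i] - max(left, right)
    if (prom < prominence) next
    f0 <- x[i]; m0 <- y[i]
    if (refine && i > 1 && i < n) {
      # quadratic through the three surrounding samples, in log-frequency
      lx <- log10(x[(i - 1):(i + 1)])
      ly <- y[(i - 1):(i + 1)]
      denom <- (ly[1] - 2 * ly[2] + ly[3])
      if (denom < 0) {
        delta <- 0.5 * (ly[1] - ly[3]) / denom
        delta <- max(min(delta, 1), -1)
        h <- (lx[3] - lx[1]) / 2
        f0 <- 10^(lx[2] + delta * h)
        m0 <- ly[2] - 0.25 * (ly[1] - ly[3]) * delta
      }
    }
    out <- dplyr::bind_rows(out, tibble(f_hz = f0, mag_db = m0, prominence_db = prom))
  }
  out
}

#' Locate resonance peaks and dips of a transfer function
#'
#' Strict local extrema of the magnitude curve with topographic prominence
#' of at least `prominence_db` (default 0.5 dB, low enough to catch the
#' shallow resonance of a mass-loaded stapes while ignoring grid-level
#' ripple). Peak locations are refined by a quadratic fit through the
#' three surrounding samples in log-frequency.
#'
#' @param tf An `ear_tf` (or any tibble with `frequency_hz` and
#'   `magnitude_db`), on a grid of at least 16 points.
#' @param prominence_db Minimum prominence, dB.
#' @param refine Apply quadratic interpolation to extremum locations.
#' @return An `ear_resonances` tibble: `type` (`"peak"`/`"dip"`), `f_hz`,
#'   `mag_db`, `prominence_db`, sorted by frequency within type. Empty
#'   tibble if the curve is monotone.
#' @export
find_resonances <- function(tf, prominence_db = 0.5, refine = TRUE) {
  stopifnot(is.data.frame(tf), all(c("frequency_hz", "magnitude_db") %in% names(tf)))
  if (nrow(tf) < 16) abort("find_resonances needs a grid of at least 16 points")
  x <- tf$frequency_hz; y <- tf$magnitude_db
  peaks <- .find_peaks(x, y, prominence_db, refine)
  dips <- .find_peaks(x, -y, prominence_db, refine)
  dips$mag_db <- -dips$mag_db
  out <- dplyr::bind_rows(
    dplyr::mutate(peaks, type = "peak"),
    dplyr::mutate(dips, type = "dip")
  )[, c("type", "f_hz", "mag_db", "prominence_db")]
  out <- dplyr::arrange(out, .data$type == "dip", .data$f_hz)
  structure(tibble::new_tibble(out, class = "ear_resonances"),
            node = attr(tf, "node"), kind = attr(tf, "kind"),
            condition = attr(tf, "condition"))
}

#' Crossover frequencies between two transfer-function magnitudes
#'
#' Frequencies where `magnitude_db(a) - magnitude_db(b)` changes sign,
#' located by linear interpolation (in log-frequency) between the
#' bracketing samples. Both inputs must share the same grid.
#'
#' @param tf_a,tf_b `ear_tf` objects on identical frequency grids.
#' @param fmin Discard crossovers below this frequency, Hz. The magnitude
#'   difference at very low frequency sits at floor level where its sign
#'   is not meaningful; feature reporting conventionally uses the first
#'   crossover above 200 Hz.
#' @return Numeric vector of crossover frequencies, Hz, sorted ascending
#'   (possibly empty).
#' @export
crossover <- function(tf_a, tf_b, fmin = 0) {
  stopifnot(is.data.frame(tf_a), is.data.frame(tf_b))
  fa <- tf_a$frequency_hz; fb <- tf_b$frequency_hz
  if (length(fa) != length(fb) || any(abs(fa - fb) > 1e-9 * pmax(fa, 1))) {
    abort("crossover needs both transfer functions on the same frequency grid")
  }
  d <- tf_a$magnitude_db - tf_b$magnitude_db
  lx <- log10(fa)
  n <- length(d)
  out <- numeric()
  for (i in seq_len(n - 1)) {
    if (d[i] * d[i + 1] < 0) {
      t <- d[i] / (d[i] - d[i + 1])
      out <- c(out, 10^(lx[i] + t * (lx[i + 1] - lx[i])))
    } else if (d[i] == 0 && i > 1) {
      # an exact zero counts only when the curves actually change sides
      before <- d[max(which(d[seq_len(i - 1)] != 0), 0)]
      after_idx <- which(d[(i + 1):n] != 0)
      after <- if (length(after_idx) > 0) d[i + after_idx[1]] else 0
      if (length(before) > 0 && before * after < 0) out <- c(out, fa[i])
    }
  }
  sort(unique(out[out >= fmin]))
}

#' Run the full virtual-experiment condition matrix
#'
#' Simulates every (measurement site, ear condition) cell of the
#' bone-conduction protocol: umbo (X3) under normal, stapes-glued,
#' malleus-glued, 100 mg-on-umbo and IS-joint-cut conditions, and stapes
#' (X5) under those five plus the two post-separation conditions (mass on
#' stapes, cochlea drained) - 12 condition curves, each returned as both
#' the relative and the absolute velocity ratio, with resonance reports.
#' The post-separation conditions are composed after the joint cut, as in
#' the experiments.
#'
#' @param base An [ear_params] object, default the fitted set.
#' @param frequencies Frequency grid, Hz.
#' @param stimulus An `ear_stimulus`, default 1 N bone-conduction force.
#' @param stapes_mass_kg Mass added in the `mass_on_stapes` condition, kg
#'   (20 mg by default; 7.5 mg is the documented alternative).
#' @inheritParams perturbation
#' @param prominence_db Passed to [find_resonances()].
#' @return A `condition_matrix` tibble with one row per (site, condition,
#'   kind): columns `site` (`"umbo"`/`"stapes"`), `node`, `condition`,
#'   `kind`, and list-columns `tf` (`ear_tf`) and `resonances`.
#' @export
run_condition_matrix <- function(base = builtin_params("fitted", quiet = TRUE),
                                 frequencies = default_grid(),
                                 stimulus = stim_bc(),
                                 stapes_mass_kg = 20e-6,
                                 isjc_variant = c("k6", "k8"),
                                 drain_fluid_mass = TRUE,
                                 prominence_db = 0.5) {
  stopifnot(inherits(base, "ear_params"))
  isjc_variant <- match.arg(isjc_variant)
  shared <- c("normal", "stapes_glued", "malleus_glued", "mass_100mg_umbo",
              "is_joint_cut")
  cells <- dplyr::bind_rows(
    tibble(site = "umbo", node = "X3", condition = shared),
    tibble(site = "stapes", node = "X5",
           condition = c(shared, "mass_on_stapes", "cochlea_drained"))
  )
  chain_for <- function(cond) {
    if (cond %in% c("mass_on_stapes", "cochlea_drained")) c("is_joint_cut", cond) else cond
  }
  # one solve per distinct condition, shared between sites and kinds
  conds <- unique(cells$condition)
  responses <- setNames(lapply(conds, function(cond) {
    p <- apply_perturbation(base, chain_for(cond), mass_kg = stapes_mass_kg,
                            isjc_variant = isjc_variant,
                            drain_fluid_mass = drain_fluid_mass)
    solve_response(p, stimulus, frequencies)
  }), conds)
  out <- tidyr::expand_grid(cells, kind = c("relative", "absolute"))
  out$tf <- purrr::pmap(out, function(site, node, condition, kind) {
    transfer(responses[[condition]], node = node, kind = kind,
             condition = condition)
  })
  out$resonances <- purrr::map(out$tf, find_resonances,
                               prominence_db = prominence_db)
  structure(tibble::new_tibble(out, class = "condition_matrix"),
            params = base, stimulus = stimulus,
            isjc_variant = isjc_variant, drain_fluid_mass = drain_fluid_mass,
            stapes_mass_kg = stapes_mass_kg)
}

#' Flatten a condition matrix into a long tibble of curves
#'
#' @param x A `condition_matrix` from [run_condition_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `condition`, `site`, `node`, `kind`,
#'   `frequency_hz`, `magnitude_db`, `phase_cycles`.
#' @export
tidy.condition_matrix <- function(x, ...) {
  purrr::pmap_dfr(x[, c("site", "node", "condition", "kind", "tf")],
    function(site, node, condition, kind, tf) {
      tibble(condition = condition, site = site, node = node, kind = kind,
             frequency_hz = tf$frequency_hz,
             magnitude_db = tf$magnitude_db,
             phase_cycles = tf$phase_cycles)
    })
}

#' Resonance reports of a condition matrix as JSON-ready list
#'
#' @param x A `condition_matrix`.
#' @param kind Which transfer kind to report.
#' @return A list (one element per condition curve) with the peaks, dips
#'   and crossovers against the normal curve, suitable for
#'   [jsonlite::write_json()].
#' @export
resonance_report <- function(x, kind = "relative") {
  stopifnot(inherits(x, "condition_matrix"))
  sub <- x[x$kind == kind, ]
  normals <- split(sub[sub$condition == "normal", ], sub$site[sub$condition == "normal"])
  purrr::pmap(sub[, c("site", "node", "condition", "tf", "resonances")],
    function(site, node, condition, tf, resonances) {
      peaks <- resonances[resonances$type == "peak", ]
      dips <- resonances[resonances$type == "dip", ]
      xo <- if (condition != "normal") {
        crossover(tf, normals[[site]]$tf[[1]], fmin = 200)
      } else numeric()
      list(condition = condition, site = site, node = node, kind = kind,
           peaks = purrr::map2(peaks$f_hz, peaks$mag_db,
                               ~list(f_hz = .x, mag_db = .y)),
           dips = purrr::map2(dips$f_hz, dips$mag_db,
                              ~list(f_hz = .x, mag_db = .y)),
           crossovers_vs_normal = as.list(xo))
    })
}
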