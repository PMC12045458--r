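# Assembly of the 6x6 mass/damping/stiffness matrices.
#
# Node order (fixed): X0 skull, X1 ear-canal air, X2 tympanic membrane,
# X3 umbo (malleus tip), X4 incus tip, X5 stapes + cochlear fluid.
# Displacements are horizontal, positive in a common direction; the
# malleus and incus are hinged pendulums whose tip motions are linearised
# as theta3 = (X3 - X0)/L3 and theta4 = (X4 - X0)/L4.
#
# The skull row keeps only its inertia (M0 * a0 = F0): the reaction forces
# of the suspended elements on the skull are negligible against M0, which
# is why column X0 carries coupling terms while row X0 does not - the
# matrices are deliberately not symmetric across that row.

.nodes <- c("X0", "X1", "X2", "X3", "X4", "X5")

#' Node labels of the middle-ear model
#' @return Character vector `c("X0", ..., "X5")`.
#' @export
ear_nodes <- function() .nodes

# Shared stencil for [K] and [C]: the two matrices have identical structure
# with damping constants in place of stiffnesses.
.coupling_matrix <- function(k1, k2, k3, km, kmi, ki, k6, k8, k9, L3, L4) {
  A <- matrix(0, 6, 6, dimnames = list(.nodes, .nodes))
  # X1: canal air against the eardrum
  A[2, 2] <- k2; A[2, 3] <- -k2
  # X2: eardrum against skull, canal air, and malleus tip
  A[3, 1] <- -k1; A[3, 2] <- -k2; A[3, 3] <- k1 + k2 + k3; A[3, 4] <- -k3
  # X3: malleus torque balance divided by L3, torsional terms mapped to
  # translations via theta3 = (X3 - X0)/L3, theta4 = (X4 - X0)/L4
  A[4, 1] <- kmi / (L3 * L4) - (km + kmi) / L3^2
  A[4, 3] <- -k3
  A[4, 4] <- k3 + (km + kmi) / L3^2
  A[4, 5] <- -kmi / (L3 * L4)
  # X4: incus torque balance divided by L4
  A[5, 1] <- kmi / (L3 * L4) - (ki + kmi) / L4^2
  A[5, 4] <- -kmi / (L3 * L4)
  A[5, 5] <- k6 + (ki + kmi) / L4^2
  A[5, 6] <- -k6
  # X5: stapes + fluid against the incus tip and the skull
  A[6, 1] <- -(k8 + k9); A[6, 5] <- -k6; A[6, 6] <- k6 + k8 + k9
  A
}

#' Assemble the system matrices of the middle-ear model
#'
#' Builds the 6x6 real mass, damping and stiffness matrices `M`, `C`, `K`
#' of the harmonic system `(-w^2 M + i w C + K) X = F` from a parameter
#' set, in the fixed node order [ear_nodes()].
#'
#' @param params An [ear_params] object.
#' @return An `ear_matrices` object: list with `M`, `C`, `K` (dimnamed
#'   6x6 matrices), `nodes`, and the originating `params`.
#' @examples
#' m <- assemble_matrices(builtin_params("fitted"))
#' m$K["X1", "X1"]  # 20001 N/m
#' @export
assemble_matrices <- function(params) {
  stopifnot(inherits(params, "ear_params"))
  validate_params(params)
  p <- params
  M <- matrix(0, 6, 6, dimnames = list(.nodes, .nodes))
  M[1, 1] <- p$M0
  M[2, 2] <- p$M1
  M[3, 3] <- p$M2
  M[4, 1] <- -p$I3 / p$L3^2; M[4, 4] <- p$I3 / p$L3^2
  M[5, 1] <- -p$I4 / p$L4^2; M[5, 5] <- p$I4 / p$L4^2
  M[6, 6] <- p$M5 + p$M6
  K <- .coupling_matrix(p$K1, p$K2, p$K3, p$Km_t, p$Kmi_t, p$Ki_t,
                        p$K6, p$K8, p$K9, p$L3, p$L4)
  C <- .coupling_matrix(p$C1, p$C2, p$C3, p$Cm_t, p$Cmi_t, p$Ci_t,
                        p$C6, p$C8, p$C9, p$L3, p$L4)
  structure(list(M = M, C = C, K = K, nodes = .nodes, params = params),
            class = "ear_matrices")
}

#' @export
print.ear_matrices <- function(x, ...) {
  cat("<ear_matrices> for parameter set ", attr(x$params, "name"),
      "\nnodes: ", paste(x$nodes, collapse = " "), "\n", sep = "")
  for (nm in c("M", "C", "K")) {
    cat("\n[", nm, "]\n", sep = "")
    print(signif(x[[nm]], 4))
  }
  invisible(x)
}

#' Tidy system matrices into a long tibble
#'
#' @param x An `ear_matrices` object.
#' @param ... Unused.
#' @return A tibble with columns `matrix` (`"M"`, `"C"`, `"K"`), `row`,
#'   `col` (node names) and `value`; zero entries included.
#' @export
tidy.ear_matrices <- function(x, ...) {
  purrr::map_dfr(c("M", "C", "K"), function(nm) {
    tibble(matrix = nm,
           row = rep(x$nodes, times = 6),
           col = rep(x$nodes, each = 6),
           value = as.vector(x[[nm]]))
  })
}

#' Export system matrices to CSV
#'
#' Writes one CSV per matrix (`M.csv`, `C.csv`, `K.csv`) into `dir`, with
#' the node names as header row and first column.
#'
#' @param mats An `ear_matrices` object.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_matrices_csv <- function(mats, dir) {
  stopifnot(inherits(mats, "ear_matrices"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(c("M", "C", "K"), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    df <- tibble::as_tibble(mats[[nm]], rownames = "node")
    readr::write_csv(df, path)
    path
  }, character(1))
  invisible(paths)
}
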