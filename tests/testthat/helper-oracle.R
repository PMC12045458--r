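# Independent transcription of the governing equations, used as the oracle
# for the assembled matrices and the frequency-domain solver.
#
# Each nodal force is written directly from the Newton (sum F = m a) or
# torque (sum tau = I alpha) balance, with the pendulum substitution
# theta3 = (X3 - X0)/L3, theta4 = (X4 - X0)/L4 carried out numerically -
# not from the rearranged matrix rows the package assembles.

oracle_force <- function(p, w, X) {
  Xd <- 1i * w * X
  Xdd <- -w^2 * X
  th3 <- (X[4] - X[1]) / p$L3; thd3 <- (Xd[4] - Xd[1]) / p$L3
  thdd3 <- (Xdd[4] - Xdd[1]) / p$L3
  th4 <- (X[5] - X[1]) / p$L4; thd4 <- (Xd[5] - Xd[1]) / p$L4
  thdd4 <- (Xdd[5] - Xdd[1]) / p$L4
  F0 <- p$M0 * Xdd[1]
  F1 <- p$M1 * Xdd[2] - (p$C2 * (Xd[3] - Xd[2]) + p$K2 * (X[3] - X[2]))
  F2 <- p$M2 * Xdd[3] -
    (p$C3 * (Xd[4] - Xd[3]) + p$K3 * (X[4] - X[3]) +
     p$C2 * (Xd[2] - Xd[3]) + p$K2 * (X[2] - X[3]) +
     p$C1 * (Xd[1] - Xd[3]) + p$K1 * (X[1] - X[3]))
  F3 <- (p$I3 * thdd3 -
         (p$Cmi_t * (thd4 - thd3) - p$Cm_t * thd3 +
          p$C3 * (Xd[3] - Xd[4]) * p$L3 +
          p$Kmi_t * (th4 - th3) - p$Km_t * th3 +
          p$K3 * (X[3] - X[4]) * p$L3)) / p$L3
  F4 <- (p$I4 * thdd4 -
         (p$Cmi_t * (thd3 - thd4) - p$Ci_t * thd4 +
          p$C6 * (Xd[6] - Xd[5]) * p$L4 +
          p$Kmi_t * (th3 - th4) - p$Ki_t * th4 +
          p$K6 * (X[6] - X[5]) * p$L4)) / p$L4
  F5 <- (p$M5 + p$M6) * Xdd[6] -
    (p$C6 * (Xd[5] - Xd[6]) + p$K6 * (X[5] - X[6]) +
     (p$C8 + p$C9) * (Xd[1] - Xd[6]) + (p$K8 + p$K9) * (X[1] - X[6]))
  c(F0, F1, F2, F3, F4, F5)
}

# Solve the system through the oracle alone: build the dynamic matrix
# column-by-column by pushing unit displacements through oracle_force.
oracle_solve <- function(p, w, fvec) {
  A <- matrix(complex(real = 0), 6, 6)
  for (j in 1:6) {
    e <- complex(real = numeric(6)); e[j] <- 1 + 0i
    A[, j] <- oracle_force(p, w, e)
  }
  solve(A, fvec)
}

# Random but physically sensible parameter set: fitted values jittered by
# up to a factor of ~3 either way (log-uniform), zeros left at zero.
random_params <- function() {
  base <- builtin_params("fitted", quiet = TRUE)
  vals <- lapply(setNames(param_fields(), param_fields()),
                 function(f) base[[f]] * exp(runif(1, -1, 1)))
  do.call(ear_params, c(list(name = "random"), vals))
}

random_state <- function() {
  complex(real = rnorm(6), imaginary = rnorm(6))
}

fitted_quiet <- function() builtin_params("fitted", quiet = TRUE)
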