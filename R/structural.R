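#' Structural two-compartment parameters
#'
#' Clearance parameterization of the two-compartment disposition model:
#' elimination clearance `CL` and intercompartmental clearance `Q` (L/h),
#' central and peripheral distribution volumes `V1`, `V2` (L).  `Q = 0`
#' degenerates gracefully to a one-compartment model.
#'
#' @param CL,V1,Q,V2 parameter values (scalars).
#' @return named list of class `pk_params`.
#' @export
pk_params <- function(CL, V1, Q, V2) {
  if (any(!is.finite(c(CL, V1, Q, V2)))) stop("parameters must be finite")
  if (CL <= 0 || V1 <= 0 || V2 <= 0) stop("CL, V1, V2 must be positive")
  if (Q < 0) stop("Q must be non-negative")
  structure(list(CL = CL, V1 = V1, Q = Q, V2 = V2), class = "pk_params")
}

#' Micro rate constants and hybrid disposition eigenvalues
#'
#' Converts the clearance parameterization to micro constants
#' `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2` and the hybrid rate constants
#' `lambda1 >= lambda2 > 0`, the roots of
#' `lambda^2 - (k10+k12+k21) lambda + k10 k21 = 0`.  `lambda2` is the
#' terminal disposition rate constant (lambda_z).
#'
#' @param p a [pk_params()].
#' @return list with `k10`, `k12`, `k21`, `lambda1`, `lambda2`.
#' @export
micro_from_macro <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  k10 <- p$CL / p$V1
  k12 <- p$Q / p$V1
  k21 <- if (p$V2 > 0) p$Q / p$V2 else 0
  s <- k10 + k12 + k21
  pr <- k10 * k21
  sq <- sqrt(max(s^2 - 4 * pr, 0))
  l1 <- (s + sq) / 2
  # compute the small root as product/large root to avoid cancellation
  l2 <- if (l1 > 0 && pr > 0) pr / l1 else (s - sq) / 2
  list(k10 = k10, k12 = k12, k21 = k21, lambda1 = l1, lambda2 = l2)
}

#' Dosing regimen constructor
#'
#' @param amt dose amounts (mg), recycled against `time`.
#' @param time infusion start times (h).
#' @param dur infusion durations (h), recycled.
#' @return data.frame with columns `time`, `amt`, `dur`, class `pk_regimen`.
#' @export
pk_regimen <- function(amt, time, dur = 0.5) {
  r <- data.frame(time = time, amt = amt, dur = dur)
  if (any(r$amt <= 0) || any(r$dur <= 0)) stop("amounts and durations must be positive")
  if (any(r$time < 0)) stop("dose times must be non-negative")
  r <- r[order(r$time), , drop = FALSE]
  class(r) <- c("pk_regimen", "data.frame")
  r
}

#' Study dosing regimen (loading dose plus maintenance doses)
#'
#' The regimen used throughout: a loading infusion followed by maintenance
#' infusions every `interval` hours, all of duration `dur`.
#'
#' @param n_doses total number of doses (loading dose included).
#' @param loading,maintenance dose amounts in mg.
#' @param interval dosing interval in h.
#' @param dur infusion duration in h.
#' @export
study_regimen <- function(n_doses, loading = 200, maintenance = 100,
                          interval = 12, dur = 0.5) {
  stopifnot(n_doses >= 1)
  pk_regimen(amt = c(loading, rep(maintenance, n_doses - 1L)),
             time = interval * (seq_len(n_doses) - 1L), dur = dur)
}

#' Central-compartment concentration under zero-order infusions
#'
#' Analytic biexponential solution of the two-compartment model for
#' zero-order infusion input, summed over doses by superposition (the system
#' is linear); with mg amounts and L volumes the result is mg/L = ug/ml.
#' Parameters may differ by occasion (`p` given as a list with one
#' [pk_params()] per occasion and `occ_breaks` marking occasion start
#' times); compartment amounts are continuous across the switch.
#'
#' @param t time(s) in hours at which to evaluate.
#' @param regimen a [pk_regimen()].
#' @param p a [pk_params()], or a list of them (one per occasion, occasions
#'   delimited by the dose times).
#' @return numeric vector of concentrations (0 before the first dose).
#' @export
pk_concentration <- function(t, regimen, p) {
  stopifnot(inherits(regimen, "pk_regimen"))
  if (inherits(p, "pk_params")) p <- list(p)
  K <- length(p)
  pk_profile_cpp(as.numeric(t), regimen$time, regimen$amt, regimen$dur,
                 vapply(p, `[[`, 0, "CL"), vapply(p, `[[`, 0, "V1"),
                 vapply(p, `[[`, 0, "Q"), vapply(p, `[[`, 0, "V2"))
}

#' Secondary pharmacokinetic metrics
#'
#' Derived quantities of the two-compartment model: steady-state volume
#' `Vss = V1 + V2`, terminal rate constant `lambda_z` (the slow hybrid
#' eigenvalue), terminal half-life `ln 2 / lambda_z`, the terminal-phase
#' accumulation ratio for repeated dosing every `tau` hours,
#' `1 / (1 - exp(-lambda_z tau))`, and the steady-state AUC over one
#' interval, `dose / CL`.
#'
#' @param p a [pk_params()].
#' @param tau dosing interval (h).
#' @param maintenance_dose maintenance dose (mg).
#' @return list with `Vss` (L), `lambda_z` (1/h), `terminal_half_life` (h),
#'   `accumulation_ratio`, `auc_tau_ss` (mg h/L).
#' @export
secondary_metrics <- function(p, tau = 12, maintenance_dose = 100) {
  stopifnot(tau > 0)
  m <- micro_from_macro(p)
  lz <- m$lambda2
  list(Vss = p$V1 + p$V2,
       lambda_z = lz,
       terminal_half_life = log(2) / lz,
       accumulation_ratio = 1 / (1 - exp(-lz * tau)),
       auc_tau_ss = maintenance_dose / p$CL)
}
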