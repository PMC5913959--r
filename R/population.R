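#' Population parameter set
#'
#' Hierarchical model parameters: typical values `theta` for CL, V1, Q, V2;
#' diagonal interindividual variances `omega2` (log scale) for CL, V1, V2;
#' diagonal interoccasion variances `pi2` (log scale) for CL and V2; and the
#' combined residual error `sigma_add` (additive SD, ug/ml) and
#' `sigma2_prop` (proportional variance).  A variance set to 0 means the
#' corresponding random effect is absent (fixed); no IIV is carried on Q.
#'
#' An individual-occasion parameter is
#' `P_{i,k} = theta_P exp(eta_{P,i}) exp(kappa_{P,i,k})`, with
#' `eta ~ N(0, omega2)` per subject and `kappa ~ N(0, pi2)` per
#' subject-occasion; the residual model is
#' `y = f (1 + eps_prop) + eps_add`.
#'
#' @param theta_CL,theta_V1,theta_Q,theta_V2 typical values (L/h, L).
#' @param omega2_CL,omega2_V1,omega2_V2 IIV variances (log scale).
#' @param pi2_CL,pi2_V2 IOV variances (log scale).
#' @param sigma_add additive residual SD (ug/ml).
#' @param sigma2_prop proportional residual variance.
#' @return list of class `pk_pop_params`.
#' @export
pop_params <- function(theta_CL, theta_V1, theta_Q, theta_V2,
                       omega2_CL = 0, omega2_V1 = 0, omega2_V2 = 0,
                       pi2_CL = 0, pi2_V2 = 0,
                       sigma_add = 0, sigma2_prop = 0) {
  th <- c(CL = theta_CL, V1 = theta_V1, Q = theta_Q, V2 = theta_V2)
  if (any(th <= 0)) stop("typical values must be positive")
  om <- c(CL = omega2_CL, V1 = omega2_V1, V2 = omega2_V2)
  pi2 <- c(CL = pi2_CL, V2 = pi2_V2)
  if (any(c(om, pi2) < 0)) stop("variances must be non-negative")
  if (sigma_add < 0 || sigma2_prop < 0) stop("residual terms must be non-negative")
  structure(list(theta = th, omega2 = om, pi2 = pi2,
                 sigma_add = sigma_add, sigma2_prop = sigma2_prop),
            class = "pk_pop_params")
}

#' Reference population parameters for high-dose tigecycline in sepsis
#'
#' The final-model estimates for the 200 mg / 100 mg q12h regimen in adult
#' sepsis and septic-shock patients: CL 22.1 L/h, V1 162 L, Q 69.4 L/h,
#' V2 87.9 L; IIV 17.3/19.2/38.7 %CV on CL/V1/V2; IOV 14.4/20.8 %CV on
#' CL/V2; residual error 0.021 ug/ml additive SD plus 13 %CV proportional.
#' Percent CVs are converted to log-scale variances with [cv_to_variance()].
#'
#' @return a [pop_params()] object.
#' @export
tigecycline_pop_params <- function() {
  pop_params(theta_CL = 22.1, theta_V1 = 162, theta_Q = 69.4, theta_V2 = 87.9,
             omega2_CL = cv_to_variance(17.3),
             omega2_V1 = cv_to_variance(19.2),
             omega2_V2 = cv_to_variance(38.7),
             pi2_CL = cv_to_variance(14.4),
             pi2_V2 = cv_to_variance(20.8),
             sigma_add = 0.021, sigma2_prop = 0.13^2)
}

#' @export
print.pk_pop_params <- function(x, ...) {
  cat("<pk_pop_params>\n  theta:", paste(names(x$theta),
      signif(x$theta, 4), sep = "=", collapse = " "), "\n")
  cat("  omega2:", paste(names(x$omega2), signif(x$omega2, 4), sep = "=",
      collapse = " "),
      sprintf(" (CV%%: %s)", paste(signif(variance_to_cv(x$omega2), 3),
                                   collapse = "/")), "\n")
  cat("  pi2:  ", paste(names(x$pi2), signif(x$pi2, 4), sep = "=",
      collapse = " "), "\n")
  cat("  sigma_add:", signif(x$sigma_add, 4),
      " sigma2_prop:", signif(x$sigma2_prop, 4), "\n")
  invisible(x)
}

#' Convert percent CV to a log-scale variance, and back
#'
#' Log-normal convention: a log-scale variance `w2` corresponds to
#' `CV = 100 sqrt(exp(w2) - 1)` percent, so `w2 = log(1 + (cv/100)^2)`.
#' The two functions are exact inverses.
#'
#' @param cv_percent coefficient of variation in percent.
#' @param w2 log-scale variance.
#' @return the converted value (vectorized).
#' @export
cv_to_variance <- function(cv_percent) {
  stopifnot(all(cv_percent >= 0))
  log(1 + (cv_percent / 100)^2)
}

#' @rdname cv_to_variance
#' @export
variance_to_cv <- function(w2) {
  stopifnot(all(w2 >= 0))
  100 * sqrt(exp(w2) - 1)
}

#' Individual-occasion structural parameters
#'
#' Applies the log-normal hierarchy: `CL = theta_CL e^{eta_CL} e^{kappa_CL}`,
#' `V1 = theta_V1 e^{eta_V1}`, `Q = theta_Q`,
#' `V2 = theta_V2 e^{eta_V2} e^{kappa_V2}`.
#'
#' @param pop a [pop_params()].
#' @param eta named vector with any of `CL`, `V1`, `V2` (missing = 0).
#' @param kappa named vector with any of `CL`, `V2` (missing = 0).
#' @return a [pk_params()].
#' @export
individual_params <- function(pop, eta = c(), kappa = c()) {
  g <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  pk_params(CL = pop$theta[["CL"]] * exp(g(eta, "CL") + g(kappa, "CL")),
            V1 = pop$theta[["V1"]] * exp(g(eta, "V1")),
            Q  = pop$theta[["Q"]],
            V2 = pop$theta[["V2"]] * exp(g(eta, "V2") + g(kappa, "V2")))
}

# ---- internal fast path -----------------------------------------------------

# Per-subject working structure used by prediction, simulation, estimation.
# b-vector layout (full): (eta_CL, eta_V1, eta_V2, kappa_CL[1..K], kappa_V2[1..K])
prep_subjects <- function(x, include_blq = FALSE) {
  ev <- x$events
  lapply(unique(ev$subject), function(id) {
    s <- ev[ev$subject == id, , drop = FALSE]
    d <- s[s$evid == 1, , drop = FALSE]
    o <- s[s$evid == 0, , drop = FALSE]
    keep <- if (include_blq) rep(TRUE, nrow(o)) else !o$blq
    K <- nrow(d)
    list(id = id, dose_t = d$time, amt = d$amt, dur = d$dur, K = K,
         obs_t = o$time[keep], y = o$dv[keep],
         obs_all_t = o$time, obs_keep = keep)
  })
}

# predicted concentrations at sub$obs_t for full b vector
predict_subject <- function(sub, pop, b) {
  K <- sub$K
  eta <- b[1:3]
  kCL <- b[3 + seq_len(K)]
  kV2 <- b[3 + K + seq_len(K)]
  pk_profile_cpp(sub$obs_t, sub$dose_t, sub$amt, sub$dur,
                 pop$theta[["CL"]] * exp(eta[1] + kCL),
                 rep(pop$theta[["V1"]] * exp(eta[2]), K),
                 rep(pop$theta[["Q"]], K),
                 pop$theta[["V2"]] * exp(eta[3] + kV2))
}

#' Model-predicted concentrations for a dataset
#'
#' Evaluates the structural model at every observation record.  With
#' `effects = NULL` all random effects are zero and the result is the
#' population (typical-value) prediction; otherwise `effects` supplies
#' per-subject `eta` and per-subject-occasion `kappa` values and parameters
#' change at occasion boundaries with compartment amounts carried
#' continuously across the switch.
#'
#' @param pop a [pop_params()].
#' @param x a [pk_dataset()] with occasions assigned.
#' @param effects `NULL`, or list with `eta` (matrix n_subjects x 3, columns
#'   CL/V1/V2, rownames = subject ids) and `kappa` (named list per subject of
#'   K x 2 matrices, columns CL/V2).
#' @return data.frame `subject`, `time`, `occ`, `pred` for all (non-dose)
#'   observation rows, BLQ included.
#' @export
predict_pk <- function(pop, x, effects = NULL) {
  if (any(x$events$evid == 0 & is.na(x$events$occ)))
    stop("occasions must be assigned before prediction (assign_occasions)")
  subs <- prep_subjects(x, include_blq = TRUE)
  out <- lapply(subs, function(sub) {
    b <- rep(0, 3 + 2 * sub$K)
    if (!is.null(effects)) {
      id <- as.character(sub$id)
      b[1:3] <- effects$eta[id, c("CL", "V1", "V2")]
      kap <- effects$kappa[[id]]
      if (!is.null(kap)) {
        b[3 + seq_len(sub$K)] <- kap[, "CL"]
        b[3 + sub$K + seq_len(sub$K)] <- kap[, "V2"]
      }
    }
    sub$obs_t <- sub$obs_all_t
    data.frame(subject = sub$id, time = sub$obs_all_t,
               pred = predict_subject(sub, pop, b))
  })
  res <- do.call(rbind, out)
  obs <- x$events[x$events$evid == 0, c("subject", "time", "occ")]
  res$occ <- obs$occ
  res[c("subject", "time", "occ", "pred")]
}

#' Simulate observations under the population model
#'
#' Draws subject-level `eta ~ N(0, omega2)` and occasion-level
#' `kappa ~ N(0, pi2)`, evaluates the structural model along each subject's
#' regimen, and adds combined residual error
#' `y = f (1 + eps_prop) + eps_add`.  Simulated concentrations below the
#' assay quantification limit are flagged `blq` (and thereby excluded from
#' fitting by default); negative values are retained (possible under the
#' additive error) unless `truncate = TRUE`.
#'
#' @param pop a [pop_params()].
#' @param x a [pk_dataset()] skeleton (observation rows present, `dv` ignored).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param loq quantification limit in ug/ml used for the `blq` flag.
#' @param truncate clamp negative simulated concentrations to 0.
#' @param eta_shift optional matrix (subjects x CL/V1/V2, rownames = subject
#'   ids) added to the drawn `eta`, e.g. a planted covariate effect.
#' @return the dataset with simulated `dv`; the drawn effects in
#'   `attr(, "effects")`.
#' @export
simulate_pk <- function(pop, x, seed = NULL, loq = 0.078, truncate = FALSE,
                        eta_shift = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(x$events$evid == 0 & is.na(x$events$occ))) x <- assign_occasions(x)
  subs <- prep_subjects(x, include_blq = TRUE)
  ids <- vapply(subs, function(s) as.character(s$id), "")
  eta <- matrix(0, length(subs), 3, dimnames = list(ids, c("CL", "V1", "V2")))
  for (j in colnames(eta)) if (pop$omega2[[j]] > 0)
    eta[, j] <- rnorm(nrow(eta), 0, sqrt(pop$omega2[[j]]))
  if (!is.null(eta_shift))
    eta <- eta + eta_shift[rownames(eta), colnames(eta)]
  kappa <- list()
  ev <- x$events
  for (sub in subs) {
    id <- as.character(sub$id)
    kap <- matrix(0, sub$K, 2, dimnames = list(NULL, c("CL", "V2")))
    for (j in colnames(kap)) if (pop$pi2[[j]] > 0)
      kap[, j] <- rnorm(sub$K, 0, sqrt(pop$pi2[[j]]))
    kappa[[id]] <- kap
    b <- c(eta[id, ], kap[, "CL"], kap[, "V2"])
    sub$obs_t <- sub$obs_all_t
    f <- predict_subject(sub, pop, b)
    n <- length(f)
    y <- f * (1 + rnorm(n, 0, sqrt(pop$sigma2_prop))) +
      rnorm(n, 0, pop$sigma_add)
    if (truncate) y <- pmax(y, 0)
    i <- which(ev$subject == sub$id & ev$evid == 0)
    ev$dv[i] <- y
    ev$blq[i] <- y < loq
  }
  x$events <- ev
  x$n_observations <- sum(ev$evid == 0)
  attr(x, "effects") <- list(eta = eta, kappa = kappa)
  x
}

#' Write or read population parameters as a flat config file
#'
#' Flat YAML mapping with keys `theta_CL, theta_V1, theta_Q, theta_V2,
#' omega2_CL, omega2_V1, omega2_V2, pi2_CL, pi2_V2, sigma_add, sigma2_prop`.
#'
#' @param pop a [pop_params()].
#' @param path file path.
#' @return `write_pop_params` returns `path` invisibly; `read_pop_params`
#'   the [pop_params()].
#' @export
write_pop_params <- function(pop, path) {
  vals <- as.list(pop_to_flat(pop))
  yaml::write_yaml(vals, path, precision = 17)
  invisible(path)
}

#' @rdname write_pop_params
#' @export
read_pop_params <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pop_params, vals[intersect(names(vals), names(formals(pop_params)))])
}

pop_to_flat <- function(pop) {
  c(theta_CL = pop$theta[["CL"]], theta_V1 = pop$theta[["V1"]],
    theta_Q = pop$theta[["Q"]], theta_V2 = pop$theta[["V2"]],
    omega2_CL = pop$omega2[["CL"]], omega2_V1 = pop$omega2[["V1"]],
    omega2_V2 = pop$omega2[["V2"]],
    pi2_CL = pop$pi2[["CL"]], pi2_V2 = pop$pi2[["V2"]],
    sigma_add = pop$sigma_add, sigma2_prop = pop$sigma2_prop)
}
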