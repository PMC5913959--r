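# Marginal-likelihood machinery: per-subject conditional (empirical Bayes)
# modes, a Laplace/FOCE-I approximation to -2 log marginal likelihood, and
# the outer quasi-Newton fit over log-transformed population parameters.

.par_names <- c("theta_CL", "theta_V1", "theta_Q", "theta_V2",
                "omega2_CL", "omega2_V1", "omega2_V2",
                "pi2_CL", "pi2_V2", "sigma_add", "sigma2_prop")

# Active random-effect layout for one subject given the variances:
# list(idx = indices into the full b vector, var = prior variances)
active_layout <- function(pop, K) {
  idx <- integer(0); v <- numeric(0)
  for (j in 1:3) {
    nm <- c("CL", "V1", "V2")[j]
    if (pop$omega2[[nm]] > 0) { idx <- c(idx, j); v <- c(v, pop$omega2[[nm]]) }
  }
  if (pop$pi2[["CL"]] > 0) {
    idx <- c(idx, 3 + seq_len(K)); v <- c(v, rep(pop$pi2[["CL"]], K))
  }
  if (pop$pi2[["V2"]] > 0) {
    idx <- c(idx, 3 + K + seq_len(K)); v <- c(v, rep(pop$pi2[["V2"]], K))
  }
  list(idx = idx, var = v)
}

# Penalized -2 log joint (up to the prior normalizing constant) for one
# subject as a function of the active random effects; residual variance is
# evaluated at the conditional prediction (eta-eps interaction).
subject_objective <- function(sub, pop, lay) {
  nb <- 3 + 2 * sub$K
  s2p <- pop$sigma2_prop; sa2 <- pop$sigma_add^2
  y <- sub$y
  function(ba) {
    b <- numeric(nb); b[lay$idx] <- ba
    f <- predict_subject(sub, pop, b)
    v <- pmax(f * f * s2p + sa2, 1e-12)
    sum(log(2 * pi * v) + (y - f)^2 / v) + sum(ba * ba / lay$var)
  }
}

# Conditional-mode search plus Laplace contribution for one prepared
# subject, delegated to the compiled damped Gauss-Newton kernel (exact
# gradient including the interaction terms; Gauss-Newton curvature with
# Levenberg damping).  Warm starts from the previous outer iteration make
# later calls converge in one or two steps.
inner_mode_sub <- function(sub, pop, lay = active_layout(pop, sub$K),
                           start = NULL, want_jac = FALSE) {
  res <- subject_laplace_cpp(
    sub, list(thCL = pop$theta[["CL"]], thV1 = pop$theta[["V1"]],
              thQ = pop$theta[["Q"]], thV2 = pop$theta[["V2"]],
              s2p = pop$sigma2_prop, sa2 = pop$sigma_add^2),
    as.integer(lay$idx - 1L), lay$var,
    if (is.null(start)) numeric(0) else start,
    want_jac = want_jac)
  res$b <- as.numeric(res$b)
  res
}

#' Conditional mode of one subject's random effects
#'
#' Minimizes the penalized deviance `-2 log p(y | eta, kappa) - 2 log p(eta)
#' - 2 log p(kappa)` over the subject's active random effects.  The
#' observation variance is evaluated at the conditional prediction
#' (`f^2 sigma2_prop + sigma_add^2`), i.e. with eta-eps interaction.  With
#' no observations the mode is exactly zero (the prior mode).
#'
#' @param pop a [pop_params()].
#' @param x a [pk_dataset()].
#' @param subject_id subject identifier in `x`.
#' @return list with `eta` (named CL/V1/V2), `kappa` (K x 2 matrix),
#'   `curvature` (Gauss-Newton Hessian over active effects), `converged`.
#' @export
inner_mode <- function(pop, x, subject_id) {
  subs <- prep_subjects(x)
  i <- match(as.character(subject_id),
             vapply(subs, function(s) as.character(s$id), ""))
  if (is.na(i)) stop("unknown subject: ", subject_id)
  sub <- subs[[i]]
  lay <- active_layout(pop, sub$K)
  m <- inner_mode_sub(sub, pop, lay, want_jac = TRUE)
  b <- numeric(3 + 2 * sub$K); b[lay$idx] <- m$b
  curv <- NULL
  if (length(lay$idx) && length(sub$y)) {
    v <- pmax(m$f^2 * pop$sigma2_prop + pop$sigma_add^2, 1e-12)
    curv <- crossprod(m$J / sqrt(v)) + diag(1 / lay$var, length(lay$idx))
  }
  list(eta = setNames(b[1:3], c("CL", "V1", "V2")),
       kappa = matrix(c(b[3 + seq_len(sub$K)], b[3 + sub$K + seq_len(sub$K)]),
                      ncol = 2, dimnames = list(NULL, c("CL", "V2"))),
       curvature = curv, converged = m$converged)
}

#' Approximate -2 log marginal likelihood (objective function value)
#'
#' Sums the Laplace approximation over subjects, each expanded about its
#' conditional mode with a Gauss-Newton (linearized) curvature and residual
#' variance evaluated at the conditional prediction: the FOCE-with-
#' interaction flavor of the marginal deviance.  Deterministic given the
#' dataset and parameters.  Observations flagged below the quantification
#' limit are excluded.
#'
#' @param pop a [pop_params()].
#' @param x a [pk_dataset()] (occasions assigned).
#' @return the objective value (scalar); subjects whose curvature needed
#'   regularization are counted in `attr(, "n_flagged")`.
#' @export
marginal_ofv <- function(pop, x) {
  subs <- prep_subjects(x)
  tot <- 0; nfl <- 0L
  for (sub in subs) {
    m <- inner_mode_sub(sub, pop, active_layout(pop, sub$K))
    tot <- tot + m$ofv
    nfl <- nfl + m$flagged
  }
  structure(tot, n_flagged = nfl)
}

# internal: ofv over prepared subjects with warm-started modes in `cache`,
# evaluated in one compiled pass over the population
ofv_internal <- function(pop, subs, cache = NULL) {
  idxs <- lapply(subs, function(s)
    as.integer(active_layout(pop, s$K)$idx - 1L))
  pvars <- lapply(subs, function(s) active_layout(pop, s$K)$var)
  starts <- if (!is.null(cache)) cache$modes else vector("list", length(subs))
  res <- population_ofv_cpp(
    subs, list(thCL = pop$theta[["CL"]], thV1 = pop$theta[["V1"]],
               thQ = pop$theta[["Q"]], thV2 = pop$theta[["V2"]],
               s2p = pop$sigma2_prop, sa2 = pop$sigma_add^2),
    idxs, pvars, starts)
  if (!is.null(cache)) cache$modes <- res$modes
  res$total
}

#' Chi-square threshold for the likelihood-ratio test on the OFV scale
#'
#' The difference in objective function value between nested models is
#' asymptotically chi-square; a drop of 3.84 for one extra parameter
#' corresponds to p < 0.05.
#'
#' @param df number of additional parameters.
#' @param alpha significance level.
#' @return required OFV difference.
#' @export
lrt_threshold <- function(df = 1, alpha = 0.05) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  qchisq(1 - alpha, df = df)
}

# pop <-> log-scale vector -----------------------------------------------

pop_from_flat <- function(v) {
  pop_params(theta_CL = v[["theta_CL"]], theta_V1 = v[["theta_V1"]],
             theta_Q = v[["theta_Q"]], theta_V2 = v[["theta_V2"]],
             omega2_CL = v[["omega2_CL"]], omega2_V1 = v[["omega2_V1"]],
             omega2_V2 = v[["omega2_V2"]],
             pi2_CL = v[["pi2_CL"]], pi2_V2 = v[["pi2_V2"]],
             sigma_add = v[["sigma_add"]], sigma2_prop = v[["sigma2_prop"]])
}

#' Default initial estimates for the outer optimization
#'
#' Literature-flavored starting values: CL 20 L/h, V1 100 L, Q 50 L/h,
#' V2 100 L, 20 %CV on all variabilities, additive error 0.02 ug/ml and
#' 15 %CV proportional error.
#'
#' @return a [pop_params()].
#' @export
default_init <- function() {
  pop_params(theta_CL = 20, theta_V1 = 100, theta_Q = 50, theta_V2 = 100,
             omega2_CL = cv_to_variance(20), omega2_V1 = cv_to_variance(20),
             omega2_V2 = cv_to_variance(20),
             pi2_CL = cv_to_variance(20), pi2_V2 = cv_to_variance(20),
             sigma_add = 0.02, sigma2_prop = 0.15^2)
}

#' Fit the population model by approximate marginal maximum likelihood
#'
#' Outer quasi-Newton minimization of [marginal_ofv()] over log-transformed
#' typical values, variances and residual terms (positivity by
#' construction), with per-subject conditional modes warm-started across
#' iterations.  Relative standard errors come from the inverse Hessian of
#' the outer objective; the nonparametric bootstrap
#' ([bootstrap_pk()]) is the confirmatory uncertainty method.
#'
#' @param x a [pk_dataset()] with occasions assigned.
#' @param init initial [pop_params()]; defaults to [default_init()].
#' @param fixed character vector of parameter names (from `theta_CL, ...,
#'   sigma2_prop`) held at their initial values.  A variance fixed at 0
#'   removes the corresponding random effect.
#' @param options list: `outer_rel_tol` (1e-6), `max_iter` (150),
#'   `n_starts` (1; >1 adds jittered restarts), `seed` (jitter seed),
#'   `compute_se` (TRUE), `jitter_sd` (0.2 on the log scale).
#' @return object of class `pk_fit`: `estimates` ([pop_params()]), `ofv`,
#'   `rse_percent`, `se_log`, `vcov_log`, `ebe` (`eta` matrix, `kappa`
#'   list), `convergence`, `fixed`, `init`, `dataset`.
#' @export
fit_pk <- function(x, init = default_init(), fixed = character(),
                   options = list()) {
  opt <- modifyList(list(outer_rel_tol = 1e-6, max_iter = 150, n_starts = 1,
                         seed = 1L, compute_se = TRUE, jitter_sd = 0.2),
                    options)
  stopifnot(all(fixed %in% .par_names))
  subs <- prep_subjects(x)
  flat0 <- pop_to_flat(init)
  free <- setdiff(.par_names, fixed)
  # a parameter fixed at 0 stays 0 (its random effect is absent);
  # free parameters are optimized as logs
  zero_fixed <- names(flat0)[flat0 == 0]
  free <- setdiff(free, zero_fixed)
  lx0 <- log(flat0[free])

  cache <- new.env(parent = emptyenv())
  cache$modes <- vector("list", length(subs))
  nev <- 0L
  outer_obj <- function(lx) {
    nev <<- nev + 1L
    flat <- flat0
    flat[free] <- exp(lx)
    val <- ofv_internal(pop_from_flat(flat), subs, cache)
    cache$last_lx <- lx
    cache$last_val <- val
    val
  }
  # explicit forward-difference gradient: the inner-mode tolerance leaves
  # noise on the objective well above machine precision, so the step must
  # be large enough for the difference quotient to see the true slope
  gstep <- 1e-5
  outer_grad <- function(lx) {
    base <- if (!is.null(cache$last_lx) && isTRUE(all(cache$last_lx == lx)))
      cache$last_val else outer_obj(lx)
    vapply(seq_along(lx), function(j) {
      lxp <- lx
      lxp[j] <- lxp[j] + gstep
      (outer_obj(lxp) - base) / gstep
    }, 0)
  }

  starts <- list(lx0)
  if (opt$n_starts > 1) {
    set.seed(opt$seed)
    for (k in seq_len(opt$n_starts - 1))
      starts[[k + 1]] <- lx0 + rnorm(length(lx0), 0, opt$jitter_sd)
  }
  best <- NULL
  for (st in starts) {
    op <- nlminb(st, outer_obj, gradient = outer_grad,
                 lower = rep(log(1e-8), length(st)),
                 upper = rep(log(1e8), length(st)),
                 control = list(iter.max = opt$max_iter,
                                eval.max = 10 * opt$max_iter,
                                rel.tol = opt$outer_rel_tol))
    # quasi-Newton restarts from the candidate optimum until the OFV
    # reaches a fixed point: nlminb can declare relative convergence while
    # a restart (with a fresh curvature model and cold inner modes) still
    # descends, and at a true optimum a restart cannot move the objective.
    # The inner-mode cache is cleared so each restart is independent of the
    # previous trajectory.
    op$convergence <- 1L
    for (polish in 1:12) {
      cache$modes <- vector("list", length(subs))
      op2 <- nlminb(op$par, outer_obj, gradient = outer_grad,
                    lower = rep(log(1e-8), length(st)),
                    upper = rep(log(1e8), length(st)),
                    control = list(iter.max = opt$max_iter,
                                   eval.max = 10 * opt$max_iter,
                                   rel.tol = opt$outer_rel_tol))
      delta <- op$objective - op2$objective
      if (op2$objective <= op$objective) op <- op2
      if (abs(delta) < 1e-3) { op$convergence <- 0L; break } # fixed point
    }
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  flat <- flat0; flat[free] <- exp(best$par)
  pop <- pop_from_flat(flat)

  se_log <- rep(NA_real_, length(free)); names(se_log) <- free
  vcov_log <- NULL
  if (isTRUE(opt$compute_se)) {
    H <- tryCatch(optimHess(best$par, outer_obj), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(diag(vc) > 0)) {
        vcov_log <- vc
        dimnames(vcov_log) <- list(free, free)
        se_log <- sqrt(diag(vc)); names(se_log) <- free
      }
    }
  }
  rse <- 100 * se_log # delta method: SE of log == relative SE

  # EBEs at the optimum
  ids <- vapply(subs, function(s) as.character(s$id), "")
  eta <- matrix(0, length(subs), 3, dimnames = list(ids, c("CL", "V1", "V2")))
  kappa <- list()
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    lay <- active_layout(pop, sub$K)
    m <- inner_mode_sub(sub, pop, lay, cache$modes[[i]])
    b <- numeric(3 + 2 * sub$K); b[lay$idx] <- m$b
    eta[i, ] <- b[1:3]
    kappa[[ids[i]]] <- matrix(c(b[3 + seq_len(sub$K)],
                                b[3 + sub$K + seq_len(sub$K)]),
                              ncol = 2, dimnames = list(NULL, c("CL", "V2")))
  }

  structure(list(estimates = pop, ofv = best$objective,
                 rse_percent = rse, se_log = se_log, vcov_log = vcov_log,
                 ebe = list(eta = eta, kappa = kappa),
                 convergence = list(status = if (best$convergence == 0)
                                      "converged" else "failed",
                                    iterations = best$iterations,
                                    evaluations = nev,
                                    message = best$message),
                 fixed = union(fixed, zero_fixed), init = init, dataset = x),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> ", x$convergence$status, ", OFV = ",
      format(x$ofv, digits = 8), "\n", sep = "")
  flat <- pop_to_flat(x$estimates)
  rse <- x$rse_percent[match(names(flat), names(x$rse_percent))]
  tab <- data.frame(estimate = signif(flat, 4),
                    `RSE%` = signif(rse, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}
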