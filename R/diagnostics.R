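# Model evaluation: conditional weighted residuals, outlier flagging,
# shrinkage, visual predictive check, nonparametric bootstrap and
# empirical-Bayes covariate screening.

#' Conditional weighted residuals (CWRES)
#'
#' FOCE-linearized residuals: with `J` the Jacobian of the prediction with
#' respect to the random effects at the conditional mode `b*`, the
#' linearized population mean is `E = f(b*) - J b*` and the marginal
#' covariance `V = J O J' + diag(f(b*)^2 sigma2_prop + sigma_add^2)` (`O`
#' the prior covariance of the effects).  CWRES is `V^{-1/2} (y - E)` using
#' the symmetric matrix square root; under a correct model it is
#' approximately standard normal.
#'
#' @param fit a [fit_pk()] result.
#' @param x dataset; defaults to the fitted one.
#' @return data.frame `subject`, `time`, `occ`, `dv`, `ipred` (conditional
#'   prediction), `cwres`, for the non-BLQ observations used in fitting.
#' @export
cwres <- function(fit, x = fit$dataset) {
  pop <- fit$estimates
  subs <- prep_subjects(x)
  out <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    if (!length(sub$y)) next
    lay <- active_layout(pop, sub$K)
    m <- inner_mode_sub(sub, pop, lay, want_jac = TRUE)
    d <- length(lay$idx)
    if (d == 0) {
      f <- predict_subject(sub, pop, numeric(3 + 2 * sub$K))
      v <- pmax(f^2 * pop$sigma2_prop + pop$sigma_add^2, 1e-12)
      w <- (sub$y - f) / sqrt(v)
      ip <- f
    } else {
      v <- pmax(m$f^2 * pop$sigma2_prop + pop$sigma_add^2, 1e-12)
      E <- m$f - drop(m$J %*% m$b)
      V <- m$J %*% (lay$var * t(m$J)) + diag(v, length(v))
      ei <- eigen(V, symmetric = TRUE)
      ev <- pmax(ei$values, 1e-10)
      Vinvsqrt <- ei$vectors %*% (t(ei$vectors) / sqrt(ev))
      w <- drop(Vinvsqrt %*% (sub$y - E))
      ip <- m$f
    }
    out[[i]] <- data.frame(subject = sub$id, time = sub$obs_t,
                           dv = sub$y, ipred = ip, cwres = w)
  }
  res <- do.call(rbind, out)
  obs <- x$events[x$events$evid == 0 & !x$events$blq,
                  c("subject", "time", "occ")]
  res$occ <- obs$occ[match(paste(res$subject, res$time),
                           paste(obs$subject, obs$time))]
  res[c("subject", "time", "occ", "dv", "ipred", "cwres")]
}

#' Flag outlying observations by CWRES magnitude
#'
#' @param residuals data.frame from [cwres()] (or a numeric vector).
#' @param threshold absolute CWRES above which an observation is flagged.
#' @return the input with a logical `flagged` column (or logical vector).
#' @export
flag_outliers <- function(residuals, threshold = 5) {
  if (is.numeric(residuals)) return(abs(residuals) > threshold)
  residuals$flagged <- abs(residuals$cwres) > threshold
  residuals
}

#' Remove flagged observations from a dataset
#'
#' Drops the observation records matched by `subject`/`time` in the flagged
#' rows, supporting the flag-and-refit step of model building.
#'
#' @param x a [pk_dataset()].
#' @param flagged data.frame with columns `subject`, `time` (e.g. the
#'   flagged rows of [flag_outliers()] output).
#' @return the reduced dataset.
#' @export
drop_observations <- function(x, flagged) {
  ev <- x$events
  drop <- ev$evid == 0 &
    paste(ev$subject, ev$time) %in% paste(flagged$subject, flagged$time)
  pk_dataset(ev[!drop, , drop = FALSE], x$covariates)
}

#' Empirical-Bayes shrinkage
#'
#' `100 (1 - SD(EBE) / sqrt(variance))` per random effect.  For the
#' occasion-level effects the statistic is computed per occasion over the
#' subjects contributing to that occasion, which is why sparse late
#' occasions shrink towards 100%.
#'
#' @param fit a [fit_pk()] result.
#' @return data.frame `effect`, `occasion` (NA for subject-level effects),
#'   `n`, `shrinkage_percent` (NA where the variance is zero/fixed).
#' @export
shrinkage <- function(fit) {
  pop <- fit$estimates
  rows <- list()
  for (nm in colnames(fit$ebe$eta)) {
    v <- pop$omega2[[nm]]
    rows[[paste0("eta_", nm)]] <- data.frame(
      effect = paste0("eta_", nm), occasion = NA_integer_,
      n = nrow(fit$ebe$eta),
      shrinkage_percent = if (v > 0)
        shrinkage_pct(fit$ebe$eta[, nm], v) else NA_real_)
  }
  Kmax <- max(vapply(fit$ebe$kappa, nrow, 0L))
  for (nm in c("CL", "V2")) {
    v <- pop$pi2[[nm]]
    for (k in seq_len(Kmax)) {
      kk <- unlist(lapply(fit$ebe$kappa,
                          function(m) if (nrow(m) >= k) m[k, nm] else NULL))
      rows[[paste0("kappa_", nm, "_", k)]] <- data.frame(
        effect = paste0("kappa_", nm), occasion = k, n = length(kk),
        shrinkage_percent = if (v > 0 && length(kk) > 1)
          shrinkage_pct(kk, v) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname shrinkage
#' @param ebe numeric vector of empirical Bayes estimates.
#' @param variance the population variance of the effect.
#' @export
shrinkage_pct <- function(ebe, variance) {
  if (variance <= 0) return(NA_real_)
  100 * (1 - sd(ebe) / sqrt(variance))
}

# time after most recent dose for each observation row of a dataset
time_after_dose <- function(x) {
  ev <- x$events
  tad <- rep(NA_real_, nrow(ev))
  for (id in unique(ev$subject)) {
    i <- which(ev$subject == id)
    dt <- sort(ev$time[i][ev$evid[i] == 1])
    last <- findInterval(ev$time[i], dt)
    prev <- dt[pmax(last, 1L)]
    tad[i] <- ev$time[i] - prev
    # a sample drawn exactly at a dose time is the previous interval's trough
    at_dose <- which(tad[i] == 0 & last > 1L)
    tad[i][at_dose] <- ev$time[i][at_dose] - dt[last[at_dose] - 1L]
  }
  tad[ev$evid == 0]
}

#' Visual predictive check
#'
#' Simulates `nsim` replicate datasets from the fitted model on the original
#' design, bins observations by nominal time after the most recent dose
#' (pooling dosing occasions), and compares the observed 5th/50th/95th
#' percentiles per bin with the central 90% interval of the same percentile
#' across simulated replicates.
#'
#' @param fit a [fit_pk()] result.
#' @param x dataset; defaults to the fitted one.
#' @param nsim number of replicate simulations.
#' @param seed RNG seed.
#' @param probs percentiles summarized per bin.
#' @param conf width of the simulation interval around each percentile.
#' @return object of class `pk_vpc`: data.frame with one row per (bin,
#'   percentile): `tad`, `n`, `prob`, `observed`, `sim_lo`, `sim_med`,
#'   `sim_hi`, plus `inside` (observed within the band).
#' @export
vpc <- function(fit, x = fit$dataset, nsim = 1000, seed = 1L,
                probs = c(0.05, 0.5, 0.95), conf = 0.9) {
  set.seed(seed)
  pop <- fit$estimates
  keep <- !x$events$blq[x$events$evid == 0]
  tad <- round(time_after_dose(x), 6)[keep]
  y <- x$events$dv[x$events$evid == 0][keep]
  bins <- sort(unique(tad))
  obs_q <- vapply(bins, function(b) quantile(y[tad == b], probs, names = FALSE),
                  numeric(length(probs)))
  simq <- array(NA_real_, c(length(probs), length(bins), nsim))
  for (r in seq_len(nsim)) {
    xs <- simulate_pk(pop, x, seed = NULL)
    ys <- xs$events$dv[xs$events$evid == 0][keep]
    simq[, , r] <- vapply(bins, function(b)
      quantile(ys[tad == b], probs, names = FALSE), numeric(length(probs)))
  }
  a <- (1 - conf) / 2
  rows <- list()
  for (j in seq_along(bins)) for (i in seq_along(probs)) {
    qs <- quantile(simq[i, j, ], c(a, 0.5, 1 - a), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      tad = bins[j], n = sum(tad == bins[j]), prob = probs[i],
      observed = obs_q[i, j], sim_lo = qs[1], sim_med = qs[2], sim_hi = qs[3],
      inside = obs_q[i, j] >= qs[1] & obs_q[i, j] <= qs[3])
  }
  structure(do.call(rbind, rows), class = c("pk_vpc", "data.frame"),
            nsim = nsim, conf = conf)
}

#' @export
plot.pk_vpc <- function(x, log_y = FALSE, ...) {
  probs <- unique(x$prob)
  cols <- grDevices::hcl.colors(length(probs), "Dark 3")
  plot(NA, xlim = range(x$tad), ylim = range(c(x$sim_lo, x$sim_hi, x$observed)),
       xlab = "time after dose (h)", ylab = "concentration (ug/ml)",
       log = if (log_y) "y" else "", ...)
  for (i in seq_along(probs)) {
    d <- x[x$prob == probs[i], ]
    graphics::polygon(c(d$tad, rev(d$tad)), c(d$sim_lo, rev(d$sim_hi)),
                      col = grDevices::adjustcolor(cols[i], 0.3), border = NA)
    graphics::lines(d$tad, d$observed, col = cols[i], lwd = 2)
    graphics::points(d$tad, d$observed, col = cols[i], pch = 16)
  }
  invisible(x)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples whole subjects with replacement (the subject is the
#' exchangeable unit; all of a subject's occasions travel together), refits
#' each resampled dataset, and summarizes each parameter by the median and
#' percentile confidence interval over the successful fits.
#'
#' @param x a [pk_dataset()].
#' @param init initial values for the refits (typically the point
#'   estimates).
#' @param n number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @param fixed,options passed to [fit_pk()]; by default refits skip the
#'   standard-error Hessian and use a slightly looser outer tolerance.
#' @return object of class `pk_bootstrap`: `summary` data.frame
#'   (`parameter`, `median`, `lo`, `hi`), `estimates` matrix (n_ok x
#'   parameters), `n_requested`, `n_failed`.
#' @export
bootstrap_pk <- function(x, init = default_init(), n = 1000, seed = 1L,
                         conf = 0.9, fixed = character(), options = list()) {
  if (x$n_subjects < 2) stop("bootstrap needs at least 2 subjects")
  set.seed(seed)
  opt <- modifyList(list(compute_se = FALSE, outer_rel_tol = 1e-5,
                         max_iter = 80), options)
  ids <- unique(x$events$subject)
  res <- list(); nfail <- 0L
  for (r in seq_len(n)) {
    take <- sample(ids, length(ids), replace = TRUE)
    ev <- list(); cv <- list()
    for (j in seq_along(take)) {
      e <- x$events[x$events$subject == take[j], , drop = FALSE]
      e$subject <- sprintf("B%03d", j)
      ev[[j]] <- e
      if (!is.null(x$covariates)) {
        cc <- x$covariates[x$covariates$subject == take[j], , drop = FALSE]
        cc$subject <- sprintf("B%03d", j)
        cv[[j]] <- cc
      }
    }
    xb <- pk_dataset(do.call(rbind, ev),
                     if (length(cv)) do.call(rbind, cv) else NULL)
    ft <- tryCatch(fit_pk(xb, init = init, fixed = fixed, options = opt),
                   error = function(e) NULL)
    if (is.null(ft) || ft$convergence$status != "converged") {
      nfail <- nfail + 1L
      next
    }
    res[[length(res) + 1]] <- pop_to_flat(ft$estimates)
  }
  if (!length(res)) stop("all bootstrap fits failed")
  est <- do.call(rbind, res)
  a <- (1 - conf) / 2
  sm <- data.frame(parameter = colnames(est),
                   median = apply(est, 2, median),
                   lo = apply(est, 2, quantile, a),
                   hi = apply(est, 2, quantile, 1 - a))
  rownames(sm) <- NULL
  structure(list(summary = sm, estimates = est,
                 n_requested = n, n_failed = nfail),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat("<pk_bootstrap> ", nrow(x$estimates), "successful /", x$n_requested,
      "requested (", x$n_failed, "failed )\n")
  print(transform(x$summary, median = signif(median, 4),
                  lo = signif(lo, 4), hi = signif(hi, 4)))
  invisible(x)
}

# ---- covariate screening ----------------------------------------------------

# leave-one-out variance explained by a monotone (isotonic) fit, max over
# both directions, clamped to [0, 1]
iso_loo_r2 <- function(x, y) {
  n <- length(y)
  if (n < 5 || length(unique(x)) < 3) return(NA_real_)
  pred_dir <- function(sgn) {
    pr <- numeric(n)
    for (i in seq_len(n)) {
      fit <- isoreg(x[-i], sgn * y[-i])
      # isoreg returns yf along the sorted abscissa.  Step interpolation:
      # the isotonic fit is a step function, and a rank-based predictor
      # keeps the statistic invariant to monotone covariate rescaling
      pr[i] <- sgn * approx(sort(fit$x), fit$yf, xout = x[i], rule = 2,
                            method = "constant", f = 0.5, ties = mean)$y
    }
    pr
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(NA_real_)
  r2 <- vapply(c(1, -1), function(s) 1 - sum((y - pred_dir(s))^2) / sst, 0)
  min(max(max(r2), 0), 1)
}

# leave-one-out variance explained by group means (categorical covariates)
group_loo_r2 <- function(g, y) {
  n <- length(y)
  pr <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(g == g[i])[-match(i, which(g == g[i]))]
    pr[i] <- if (length(same)) mean(y[same]) else mean(y[-i])
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(NA_real_)
  min(max(1 - sum((y - pr)^2) / sst, 0), 1)
}

#' Screen empirical Bayes estimates against covariates
#'
#' Pairs each subject-level effect (eta on CL, V1, V2) with the
#' time-independent covariates, derived size descriptors (DuBois body
#' surface area, BMI) and per-subject medians of the time-dependent
#' covariates; and each occasion-level effect (kappa on CL, V2) with the
#' time-dependent covariates evaluated at the occasion start.  For every
#' pair it reports the Spearman rank correlation, a lowess trend, and the
#' fraction of effect variance explained by a monotone relationship
#' (leave-one-out isotonic regression; grouped means for categorical
#' covariates).  A pair is a covariate candidate when that fraction reaches
#' `criterion` — the level at which including the covariate would cut the
#' unexplained variability enough to matter clinically.
#'
#' @param fit a [fit_pk()] result.
#' @param x dataset with covariates; defaults to the fitted one.
#' @param criterion variance-explained threshold for flagging (0.20).
#' @return object of class `pk_screen`: `table` data.frame (`effect`,
#'   `covariate`, `n`, `rho`, `var_explained`, `candidate`, `note`) and
#'   `pairs`, a named list of data.frames (`x`, `y`, and lowess `trend` for
#'   continuous covariates).
#' @export
covariate_screen <- function(fit, x = fit$dataset, criterion = 0.20) {
  cov <- x$covariates
  if (is.null(cov)) stop("dataset has no covariates")
  pop <- fit$estimates
  base <- cov[!duplicated(cov$subject), , drop = FALSE]
  ids <- rownames(fit$ebe$eta)
  base <- base[match(ids, as.character(base$subject)), , drop = FALSE]

  subj_cov <- list()
  for (v in intersect(c("age", "weight", "height", "albumin"), names(base)))
    subj_cov[[v]] <- base[[v]]
  if (all(c("weight", "height") %in% names(base))) {
    subj_cov$bsa <- 0.007184 * base$weight^0.425 * base$height^0.725
    subj_cov$bmi <- base$weight / (base$height / 100)^2
  }
  for (v in intersect(.cov_time_dependent, names(cov))) {
    subj_cov[[paste0("median_", v)]] <- vapply(ids, function(id) {
      vi <- cov[[v]][as.character(cov$subject) == id]
      median(vi, na.rm = TRUE)
    }, 0)
  }
  subj_cat <- list()
  for (v in intersect(.cov_categorical, names(base)))
    subj_cat[[v]] <- as.character(base[[v]])

  rows <- list(); pairs <- list()
  add_pair <- function(effect, covariate, xx, yy, categorical) {
    key <- paste(effect, covariate, sep = "~")
    ok <- complete.cases(xx, yy)
    xx <- xx[ok]; yy <- yy[ok]
    if (length(unique(xx)) < 2) {
      rows[[key]] <<- data.frame(effect = effect, covariate = covariate,
                                 n = length(yy), rho = NA_real_,
                                 var_explained = NA_real_, candidate = FALSE,
                                 note = "constant covariate: skipped")
      return()
    }
    if (categorical) {
      ve <- group_loo_r2(xx, yy)
      rho <- NA_real_
      pairs[[key]] <<- data.frame(x = xx, y = yy)
    } else {
      ve <- iso_loo_r2(xx, yy)
      rho <- suppressWarnings(cor(xx, yy, method = "spearman"))
      tr <- stats::lowess(xx, yy)
      pairs[[key]] <<- data.frame(x = xx, y = yy,
                                  trend = approx(tr$x, tr$y, xout = xx,
                                                 rule = 2, ties = mean)$y)
    }
    rows[[key]] <<- data.frame(effect = effect, covariate = covariate,
                               n = length(yy), rho = rho, var_explained = ve,
                               candidate = isTRUE(ve >= criterion), note = "")
  }

  for (p in c("CL", "V1", "V2")) {
    if (pop$omega2[[p]] <= 0) next
    eff <- paste0("eta_", p)
    yy <- fit$ebe$eta[, p]
    for (v in names(subj_cov)) add_pair(eff, v, subj_cov[[v]], yy, FALSE)
    for (v in names(subj_cat)) add_pair(eff, v, subj_cat[[v]], yy, TRUE)
  }

  # occasion-level: kappa against the covariate value at occasion start
  ev <- x$events
  for (p in c("CL", "V2")) {
    if (pop$pi2[[p]] <= 0) next
    eff <- paste0("kappa_", p)
    kap_id <- c(); kap_t <- c(); kap_y <- c()
    for (id in ids) {
      km <- fit$ebe$kappa[[id]]
      if (is.null(km)) next
      dt <- sort(ev$time[ev$subject == id & ev$evid == 1])
      kap_id <- c(kap_id, rep(id, nrow(km)))
      kap_t <- c(kap_t, dt[seq_len(nrow(km))])
      kap_y <- c(kap_y, km[, p])
    }
    for (v in intersect(.cov_time_dependent, names(cov))) {
      xx <- covariate_at(x, v, kap_id, kap_t)
      add_pair(eff, v, xx, kap_y, FALSE)
    }
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, pairs = pairs, criterion = criterion),
            class = "pk_screen")
}

#' @export
print.pk_screen <- function(x, ...) {
  cat("<pk_screen> ", nrow(x$table), " effect-covariate pairs, ",
      sum(x$table$candidate, na.rm = TRUE), " candidate(s) at the ",
      100 * x$criterion, "% variance-explained criterion\n", sep = "")
  tab <- x$table
  tab$rho <- signif(tab$rho, 2)
  tab$var_explained <- signif(tab$var_explained, 2)
  print(tab[order(-replace(tab$var_explained, is.na(tab$var_explained), -1)),
            ][seq_len(min(10, nrow(tab))), ])
  invisible(x)
}
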