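# Synthetic study generator emulating the high-dose tigecycline study
# design: 37 ICU subjects, 200 mg loading dose then 100 mg every 12 h as
# 30-min infusions, 2-8 doses per subject, arterial samples 0.5, 2, 4, 8
# and 12 h after each dose, covariates matching the published population
# summary.  All structure needed by the analysis is generated in code.

#' Study design specification
#'
#' @param n_subjects number of subjects.
#' @param loading_dose,maintenance_dose mg.
#' @param interval dosing interval (h).
#' @param infusion_duration infusion length (h).
#' @param doses_min,doses_max per-subject dose count range.
#' @param dose_weights sampling weights over `doses_min:doses_max`
#'   (uniform by default).
#' @param sample_offsets sampling times after each dose (h).
#' @param missingness fraction of planned samples dropped at random.  With
#'   uniform 2-8 doses the expected total is 37 x 5 x 5 = 925 observations,
#'   already within a few percent of the study's 942, so the default is 0.
#' @return list of class `study_design_spec`.
#' @export
study_design_spec <- function(n_subjects = 37, loading_dose = 200,
                              maintenance_dose = 100, interval = 12,
                              infusion_duration = 0.5,
                              doses_min = 2, doses_max = 8,
                              dose_weights = NULL,
                              sample_offsets = c(0.5, 2, 4, 8, 12),
                              missingness = 0) {
  stopifnot(doses_min >= 2, doses_max <= 8, doses_min <= doses_max,
            all(sample_offsets > 0), all(sample_offsets <= interval),
            missingness >= 0, missingness < 1)
  structure(list(n_subjects = n_subjects, loading_dose = loading_dose,
                 maintenance_dose = maintenance_dose, interval = interval,
                 infusion_duration = infusion_duration,
                 doses_min = doses_min, doses_max = doses_max,
                 dose_weights = dose_weights,
                 sample_offsets = sample_offsets,
                 missingness = missingness),
            class = "study_design_spec")
}

#' Covariate distribution specification
#'
#' Continuous covariates are drawn from Beta distributions rescaled to the
#' published (min, median, max) of the study population — the Beta respects
#' the observed bounds and its shapes are chosen so the median matches.
#' Categorical covariates use the published counts.  Time-dependent
#' covariates evolve across days by a bounded random walk on the logit of
#' the range-scaled value.
#'
#' @param continuous named list of `c(min, median, max)` triples.
#' @param categorical named list of named count vectors.
#' @param concentration Beta shape total `a + b` (larger = tighter).
#' @param rw_sd daily random-walk SD on the logit scale for time-dependent
#'   covariates.
#' @param n_days number of daily covariate records per subject.
#' @return list of class `covariate_spec`.
#' @export
covariate_spec <- function(
    continuous = list(age = c(25, 61, 79), weight = c(50, 80, 129),
                      height = c(158, 175, 190),
                      dialysis_volume = c(14.2, 23.8, 40.0),
                      uf_speed = c(0.34, 1.54, 6.6), elwi = c(5, 9, 41),
                      cardiac_output = c(2.55, 7.49, 15.8),
                      sofa = c(2, 13, 21), pct = c(0.16, 8.22, 122),
                      albumin = c(1.5, 2.2, 3.6)),
    categorical = list(sex = c(male = 26, female = 11),
                       ecmo = c(no = 35, yes = 2),
                       crrt = c(no = 6, yes = 30, sdt = 1)),
    concentration = 6, rw_sd = 0.25, n_days = 4) {
  structure(list(continuous = continuous, categorical = categorical,
                 concentration = concentration, rw_sd = rw_sd,
                 n_days = n_days),
            class = "covariate_spec")
}

#' Generate the dosing and sampling skeleton of a study
#'
#' Draws each subject's dose count, places doses every `interval` hours
#' starting at 0, plans samples at the nominal offsets after every dose,
#' thins them by the missingness fraction, and assigns dosing-interval
#' occasions.  Concentrations are left missing.
#'
#' @param spec a [study_design_spec()].
#' @param seed integer seed (`NULL`: use current RNG state).
#' @return a [pk_dataset()] skeleton.
#' @export
generate_design <- function(spec = study_design_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- spec$doses_min:spec$doses_max
  rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    nd <- if (length(counts) == 1) counts else
      sample(counts, 1, prob = spec$dose_weights)
    dose_t <- spec$interval * (seq_len(nd) - 1)
    doses <- data.frame(subject = i, time = dose_t, evid = 1L,
                        amt = c(spec$loading_dose,
                                rep(spec$maintenance_dose, nd - 1)),
                        dur = spec$infusion_duration, dv = NA_real_)
    obs_t <- as.vector(outer(spec$sample_offsets, dose_t, `+`))
    if (spec$missingness > 0)
      obs_t <- obs_t[runif(length(obs_t)) >= spec$missingness]
    obs <- data.frame(subject = i, time = sort(obs_t), evid = 0L,
                      amt = NA_real_, dur = NA_real_, dv = NA_real_)
    rows[[i]] <- rbind(doses, obs)
  }
  assign_occasions(pk_dataset(do.call(rbind, rows)))
}

# shape parameters of a Beta whose median sits at m in (0,1)
beta_shapes <- function(m, conc) {
  a <- m * (conc - 2 / 3) + 1 / 3
  c(a = a, b = conc - a)
}

#' Generate a study covariate table
#'
#' @param spec a [covariate_spec()].
#' @param n number of subjects.
#' @param seed integer seed (`NULL`: use current RNG state).
#' @return data.frame with one row per subject per day (`time` in hours),
#'   time-independent covariates repeated, time-dependent covariates
#'   evolving by the bounded random walk.
#' @export
generate_covariates <- function(spec = covariate_spec(), n = 37,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- data.frame(subject = seq_len(n))
  for (v in names(spec$continuous)) {
    tri <- spec$continuous[[v]]
    m <- (tri[2] - tri[1]) / (tri[3] - tri[1])
    sh <- beta_shapes(m, spec$concentration)
    base[[v]] <- tri[1] + (tri[3] - tri[1]) * rbeta(n, sh["a"], sh["b"])
  }
  base$sofa <- round(base$sofa)
  for (v in names(spec$categorical)) {
    cnt <- spec$categorical[[v]]
    base[[v]] <- sample(names(cnt), n, replace = TRUE, prob = cnt / sum(cnt))
  }
  days <- seq_len(spec$n_days) - 1
  out <- base[rep(seq_len(n), each = length(days)), , drop = FALSE]
  out <- cbind(subject = out$subject, time = 24 * rep(days, n),
               out[setdiff(names(out), "subject")])
  for (v in intersect(.cov_time_dependent, names(spec$continuous))) {
    tri <- spec$continuous[[v]]
    z <- stats::qlogis(pmin(pmax((out[[v]] - tri[1]) / (tri[3] - tri[1]),
                                 1e-3), 1 - 1e-3))
    day <- out$time / 24
    # per subject-day independent increments, cumulated
    inc <- matrix(rnorm(n * spec$n_days, 0, spec$rw_sd), n, spec$n_days)
    inc[, 1] <- 0
    walk <- t(apply(inc, 1, cumsum))
    z <- z + walk[cbind(out$subject, day + 1)]
    out[[v]] <- tri[1] + (tri[3] - tri[1]) * stats::plogis(z)
  }
  out$sofa <- round(out$sofa)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Composes the design skeleton, the covariate table and forward simulation
#' from the population model into an analysis-ready dataset.  Covariates
#' are generated independently of the PK parameters (the null design) unless
#' an effect is planted for screen power testing.
#'
#' @param design_spec a [study_design_spec()].
#' @param cov_spec a [covariate_spec()].
#' @param truth generating [pop_params()]; defaults to the reference
#'   tigecycline parameter set.
#' @param seed integer seed covering design, covariates and residual noise.
#' @param plant optional planted covariate effect, a list
#'   `list(param, covariate, power)`: the subject's log effect on `param`
#'   is shifted by `power * log(cov / median(cov))`.
#' @return a [pk_dataset()] with simulated concentrations; generating truth,
#'   seed and drawn effects are attached as attributes `truth`, `seed`,
#'   `effects`.
#' @export
generate_study <- function(design_spec = study_design_spec(),
                           cov_spec = covariate_spec(),
                           truth = tigecycline_pop_params(),
                           seed = 1L, plant = NULL) {
  set.seed(seed)
  x <- generate_design(design_spec, seed = NULL)
  cov <- generate_covariates(cov_spec, n = design_spec$n_subjects, seed = NULL)
  x <- pk_dataset(x$events, cov)
  eta_shift <- NULL
  if (!is.null(plant)) {
    base <- cov[!duplicated(cov$subject), ]
    val <- base[[plant$covariate]]
    ids <- as.character(base$subject)
    eta_shift <- matrix(0, length(ids), 3,
                        dimnames = list(ids, c("CL", "V1", "V2")))
    eta_shift[, plant$param] <- plant$power * log(val / median(val))
  }
  x <- simulate_pk(truth, x, seed = NULL, eta_shift = eta_shift)
  attr(x, "truth") <- truth
  attr(x, "seed") <- seed
  x
}
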