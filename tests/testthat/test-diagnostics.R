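test_that("CWRES is near zero for noise-free data at the true parameters", {
  pop0 <- pop_params(22.1, 162, 69.4, 87.9) # no noise, no random effects
  x <- generate_study(study_design_spec(n_subjects = 4), truth = pop0,
                      seed = 21)
  ft <- structure(list(estimates = pop0, dataset = x), class = "pk_fit")
  r <- cwres(ft)
  expect_lt(max(abs(r$cwres)), 1e-4)
})

test_that("a grossly corrupted observation dominates the CWRES", {
  sf <- study_fit()
  x <- sf$x
  iobs <- which(x$events$evid == 0 & !x$events$blq)[57]
  x$events$dv[iobs] <- x$events$dv[iobs] * 10
  r <- cwres(sf$fit, x)
  worst <- which.max(abs(r$cwres))
  expect_equal(r$subject[worst], x$events$subject[iobs])
  expect_equal(r$time[worst], x$events$time[iobs])
  expect_gt(abs(r$cwres[worst]), 5)
  fl <- flag_outliers(r)
  expect_equal(sum(fl$flagged), 1)
  # and the flagged row can be dropped for a refit
  x2 <- drop_observations(x, fl[fl$flagged, ])
  expect_equal(x2$n_observations, x$n_observations - 1)
})

test_that("flagging thresholds behave at the extremes", {
  r <- data.frame(subject = 1, time = 1:5, cwres = c(-6, -1, 0.3, 1, 6))
  expect_equal(sum(flag_outliers(r, 5)$flagged), 2)
  expect_equal(sum(flag_outliers(r, 0)$flagged), 5)
  expect_identical(flag_outliers(c(0.1, 7), 5), c(FALSE, TRUE))
})

test_that("shrinkage identities: exact draws give ~0%, collapsed EBEs 100%", {
  set.seed(4)
  w2 <- 0.04
  draws <- rnorm(5000, 0, sqrt(w2))
  expect_equal(shrinkage_pct(draws, w2), 0, tolerance = 3)
  expect_equal(shrinkage_pct(rep(0, 100), w2), 100)
  expect_true(is.na(shrinkage_pct(draws, 0)))
})

test_that("occasion effects shrink towards zero as observations are removed", {
  # nested-design property: with the population parameters held fixed,
  # thinning an occasion to a single sample must pull its kappa EBEs
  # further towards the prior mode, i.e. increase shrinkage
  sf <- study_fit()
  sh <- shrinkage(sf$fit)
  kcl <- sh[sh$effect == "kappa_CL", ]
  expect_true(all(diff(kcl$n) <= 0)) # monotone dropout by design
  expect_true(all(kcl$shrinkage_percent <= 100))

  ev <- sf$x$events
  thin <- ev$evid == 0 & !is.na(ev$occ) & ev$occ >= 5 &
    !(ev$time %% 12 %in% c(0.5)) # keep one sample per late occasion
  x2 <- pk_dataset(ev[!thin, , drop = FALSE], sf$x$covariates)
  pop <- sf$fit$estimates
  kap_full <- c(); kap_thin <- c()
  for (id in rownames(sf$fit$ebe$eta)) {
    kf <- sf$fit$ebe$kappa[[id]]
    kt <- inner_mode(pop, x2, id)$kappa
    if (nrow(kf) >= 5) {
      kap_full <- c(kap_full, kf[5:nrow(kf), "CL"])
      kap_thin <- c(kap_thin, kt[5:nrow(kt), "CL"])
    }
  }
  expect_gt(length(kap_full), 10)
  expect_lt(sd(kap_thin), sd(kap_full))
  expect_gt(shrinkage_pct(kap_thin, pop$pi2[["CL"]]),
            shrinkage_pct(kap_full, pop$pi2[["CL"]]))
})

test_that("VPC with nsim = 1 collapses to that replicate and is seeded", {
  sf <- study_fit()
  v1 <- vpc(sf$fit, nsim = 1, seed = 12)
  expect_true(all(v1$sim_lo == v1$sim_med & v1$sim_med == v1$sim_hi))
  v2 <- vpc(sf$fit, nsim = 15, seed = 7)
  v3 <- vpc(sf$fit, nsim = 15, seed = 7)
  expect_identical(as.data.frame(v2), as.data.frame(v3))
  expect_true(all(v2$sim_lo <= v2$sim_med & v2$sim_med <= v2$sim_hi))
  # bins are the nominal sampling offsets
  expect_setequal(unique(v2$tad), c(0.5, 2, 4, 8, 12))
})

test_that("bootstrap smoke: two resamples on a small study", {
  x <- small_study(seed = 55, n_subjects = 6)
  ft <- fit_pk(x, options = list(compute_se = FALSE, seed = 1))
  b <- bootstrap_pk(x, init = ft$estimates, n = 2, seed = 2)
  expect_equal(b$n_requested, 2)
  expect_equal(nrow(b$estimates) + b$n_failed, 2)
  expect_gt(nrow(b$estimates), 0)
  expect_true(all(b$summary$lo <= b$summary$median &
                    b$summary$median <= b$summary$hi))
})

test_that("a degenerate resample of one subject equals replicated weighting", {
  # all-identical resampled subjects: the fit objective is n times the
  # single-subject objective, so the optimum coincides
  x <- small_study(seed = 77, n_subjects = 3)
  one <- pk_dataset(x$events[x$events$subject == 2, , drop = FALSE])
  dup <- do.call(rbind, lapply(1:3, function(j) {
    e <- one$events; e$subject <- j * 1000; e
  }))
  xdup <- pk_dataset(dup)
  pop <- tigecycline_pop_params()
  expect_equal(as.numeric(marginal_ofv(pop, xdup)),
               3 * as.numeric(marginal_ofv(pop, one)), tolerance = 1e-9)
})

test_that("constant covariates are skipped by the screen", {
  sf <- study_fit()
  x <- sf$x
  x$covariates$age <- 50 # constant across subjects
  sc <- covariate_screen(sf$fit, x)
  row <- sc$table[sc$table$effect == "eta_CL" & sc$table$covariate == "age", ]
  expect_match(row$note, "skipped")
  expect_false(isTRUE(row$candidate))
})

test_that("screen output covers the full default pair set", {
  sf <- study_fit()
  sc <- covariate_screen(sf$fit)
  expect_setequal(unique(sc$table$effect),
                  c("eta_CL", "eta_V1", "eta_V2", "kappa_CL", "kappa_V2"))
  cl_covs <- sc$table$covariate[sc$table$effect == "eta_CL"]
  expect_true(all(c("age", "weight", "height", "sex", "ecmo", "crrt",
                    "bsa", "bmi", "median_sofa") %in% cl_covs))
  kcl_covs <- sc$table$covariate[sc$table$effect == "kappa_CL"]
  expect_setequal(kcl_covs, c("dialysis_volume", "uf_speed", "elwi",
                              "cardiac_output", "sofa", "pct"))
  expect_true(all(sc$table$var_explained >= 0 | is.na(sc$table$var_explained)))
  expect_true(all(sc$table$var_explained <= 1 | is.na(sc$table$var_explained)))
})

test_that("monotone variance explained is invariant to covariate rescaling", {
  set.seed(31)
  x <- runif(37, 50, 130)
  y <- 0.02 * x + rnorm(37, 0, 0.5)
  r1 <- tigepk:::iso_loo_r2(x, y)
  r2 <- tigepk:::iso_loo_r2(log(x), y) # monotone transform
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_equal(suppressWarnings(cor(x, y, method = "spearman")),
               suppressWarnings(cor(log(x), y, method = "spearman")))
})
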