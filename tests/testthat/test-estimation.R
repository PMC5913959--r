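# A one-eta toy problem used for the oracle comparisons: one subject, one
# dose, a handful of observations, IIV on CL only.
toy_problem <- function(n_obs = 4, seed = 5, omega2_CL = 0.09,
                        sigma2_prop = 0.04, sigma_add = 0.01) {
  set.seed(seed)
  pop <- pop_params(22.1, 162, 69.4, 87.9, omega2_CL = omega2_CL,
                    sigma_add = sigma_add, sigma2_prop = sigma2_prop)
  ev <- data.frame(subject = 1, time = c(0, c(0.5, 2, 8, 12)[seq_len(n_obs)]),
                   evid = c(1L, rep(0L, n_obs)),
                   amt = c(200, rep(NA, n_obs)),
                   dur = c(0.5, rep(NA, n_obs)), dv = NA_real_)
  x <- simulate_pk(pop, assign_occasions(pk_dataset(ev)), seed = seed + 1)
  list(pop = pop, x = x)
}

# Exact -2 log marginal likelihood by adaptive quadrature over the single
# eta dimension.
quadrature_ofv <- function(pop, x) {
  sub <- tigepk:::prep_subjects(x)[[1]]
  w2 <- pop$omega2[["CL"]]
  lik <- function(eta) {
    vapply(eta, function(e) {
      b <- numeric(3 + 2 * sub$K); b[1] <- e
      f <- tigepk:::predict_subject(sub, pop, b)
      v <- f^2 * pop$sigma2_prop + pop$sigma_add^2
      prod(stats::dnorm(sub$y, f, sqrt(v))) * stats::dnorm(e, 0, sqrt(w2))
    }, 0)
  }
  L <- integrate(lik, -10 * sqrt(w2), 10 * sqrt(w2), rel.tol = 1e-12)$value
  -2 * log(L)
}

test_that("a subject with no observations has its mode at zero", {
  pop <- tigecycline_pop_params()
  ev <- data.frame(subject = c(1, 1, 2, 2, 2),
                   time = c(0, 12, 0, 0.5, 2),
                   evid = c(1L, 1L, 1L, 0L, 0L),
                   amt = c(200, 100, 200, NA, NA),
                   dur = c(0.5, 0.5, 0.5, NA, NA),
                   dv = c(NA, NA, NA, 1.2, 0.9))
  x <- assign_occasions(pk_dataset(ev))
  m <- inner_mode(pop, x, 1)
  expect_equal(unname(m$eta), c(0, 0, 0))
  expect_equal(unname(m$kappa), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_true(m$converged)
})

test_that("the conditional mode minimizes the penalized deviance (1-D oracle)", {
  tp <- toy_problem()
  sub <- tigepk:::prep_subjects(tp$x)[[1]]
  lay <- tigepk:::active_layout(tp$pop, sub$K)
  expect_equal(length(lay$idx), 1L) # only eta_CL active
  obj <- tigepk:::subject_objective(sub, tp$pop, lay)
  oracle <- optimize(function(e) obj(e), c(-3, 3), tol = 1e-12)
  m <- tigepk:::inner_mode_sub(sub, tp$pop, lay)
  expect_equal(m$b, oracle$minimum, tolerance = 1e-5)
  expect_equal(m$h, oracle$objective, tolerance = 1e-8)
})

test_that("near-interpolation limit: tiny noise pins the mode to the data", {
  # one observation, one free eta; sigma -> 0 forces f(theta e^eta) = y
  pop <- pop_params(22.1, 162, 69.4, 87.9, omega2_CL = 1,
                    sigma_add = 1e-6, sigma2_prop = 1e-10)
  ev <- data.frame(subject = 1, time = c(0, 12), evid = c(1L, 0L),
                   amt = c(200, NA), dur = c(0.5, NA), dv = c(NA, NA))
  x <- assign_occasions(pk_dataset(ev))
  # target: concentration actually attainable, from a perturbed clearance
  x$events$dv[2] <- predict_pk(pop, x, effects = list(
    eta = matrix(c(0.3, 0, 0), 1, dimnames = list("1", c("CL", "V1", "V2"))),
    kappa = list()))$pred
  m <- inner_mode(pop, x, 1)
  expect_equal(m$eta[["CL"]], 0.3, tolerance = 1e-3)
})

test_that("Laplace OFV matches adaptive quadrature on the 1-eta toy problem", {
  for (seed in c(5, 11, 27)) {
    tp <- toy_problem(seed = seed)
    expect_equal(as.numeric(marginal_ofv(tp$pop, tp$x)),
                 quadrature_ofv(tp$pop, tp$x), tolerance = 0.5)
  }
})

test_that("duplicating every subject exactly doubles the OFV", {
  x <- small_study(seed = 13, n_subjects = 4)
  pop <- tigecycline_pop_params()
  o1 <- as.numeric(marginal_ofv(pop, x))
  ev2 <- x$events
  ev2$subject <- ev2$subject + 100
  xdup <- pk_dataset(rbind(x$events, ev2))
  expect_equal(as.numeric(marginal_ofv(pop, xdup)), 2 * o1,
               tolerance = 1e-10)
})

test_that("with all variances zero the OFV is the ELS deviance", {
  x <- small_study(seed = 19, n_subjects = 4)
  pop <- pop_params(22.1, 162, 69.4, 87.9, sigma_add = 0.021,
                    sigma2_prop = 0.0169)
  pr <- predict_pk(pop, x)
  keep <- !x$events$blq[x$events$evid == 0]
  y <- x$events$dv[x$events$evid == 0][keep]
  f <- pr$pred[keep]
  v <- f^2 * pop$sigma2_prop + pop$sigma_add^2
  expect_equal(as.numeric(marginal_ofv(pop, x)),
               sum(log(2 * pi * v) + (y - f)^2 / v), tolerance = 1e-8)
})

test_that("chi-square OFV thresholds for the likelihood-ratio test", {
  expect_equal(lrt_threshold(1, 0.05), 3.84, tolerance = 1e-3)
  expect_equal(lrt_threshold(2, 0.05), qchisq(0.95, 2))
  expect_equal(lrt_threshold(2, 0.05), 5.99, tolerance = 1e-3)
  expect_equal(lrt_threshold(1, 0.9999), 0, tolerance = 0.01)
  expect_error(lrt_threshold(0, 0.05))
})

test_that("noise-free data identify the typical values to within 0.1%", {
  x <- generate_study(study_design_spec(n_subjects = 6),
                      truth = pop_params(22.1, 162, 69.4, 87.9,
                                         sigma_add = 1e-5,
                                         sigma2_prop = 1e-10),
                      seed = 3)
  init <- pop_params(20, 140, 60, 80, sigma_add = 1e-4, sigma2_prop = 1e-8)
  ft <- fit_pk(x, init = init,
               fixed = c("sigma_add", "sigma2_prop"),
               options = list(compute_se = FALSE, seed = 1,
                              outer_rel_tol = 1e-12, max_iter = 500))
  flat <- flat_estimates(ft)
  expect_equal(flat[["theta_CL"]], 22.1, tolerance = 1e-3)
  expect_equal(flat[["theta_V1"]], 162, tolerance = 1e-3)
  expect_equal(flat[["theta_Q"]], 69.4, tolerance = 1e-3)
  expect_equal(flat[["theta_V2"]], 87.9, tolerance = 1e-3)
})

test_that("refitting from the optimum moves the OFV by less than 1e-3", {
  sf <- study_fit()
  ft2 <- fit_pk(sf$x, init = sf$fit$estimates,
                options = list(compute_se = FALSE, seed = 1))
  expect_lt(abs(ft2$ofv - sf$fit$ofv), 1e-3)
  expect_equal(ft2$convergence$status, "converged")
})

test_that("the full-design fit converges with plausible uncertainty", {
  sf <- study_fit()
  expect_equal(sf$fit$convergence$status, "converged")
  rse <- sf$fit$rse_percent
  expect_true(all(is.finite(rse)))
  expect_true(all(rse > 0))
  # clearance is the best-determined parameter in this design
  expect_lt(rse[["theta_CL"]], 15)
  ofv_at_truth <- as.numeric(marginal_ofv(tigecycline_pop_params(), sf$x))
  expect_lt(sf$fit$ofv, ofv_at_truth + 1e-6)
})
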