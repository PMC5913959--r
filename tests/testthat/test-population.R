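truth <- tigecycline_pop_params()

test_that("individual parameters apply the log-normal hierarchy", {
  p0 <- individual_params(truth)
  expect_equal(unlist(p0[c("CL", "V1", "Q", "V2")]),
               c(CL = 22.1, V1 = 162, Q = 69.4, V2 = 87.9))
  # e^{ln 2} doubles clearance
  p2 <- individual_params(truth, eta = c(CL = log(2)))
  expect_equal(p2$CL, 44.2)
  # opposite eta and kappa on V2 cancel exactly
  p3 <- individual_params(truth, eta = c(V2 = 0.1), kappa = c(V2 = -0.1))
  expect_equal(p3$V2, 87.9)
  # Q carries no random effect
  p4 <- individual_params(truth, eta = c(CL = 1, V1 = 1, V2 = 1),
                          kappa = c(CL = 1, V2 = 1))
  expect_equal(p4$Q, 69.4)
})

test_that("percent CV and log-scale variance convert exactly both ways", {
  expect_equal(cv_to_variance(0), 0)
  expect_equal(cv_to_variance(17.3), log(1 + 0.173^2))
  expect_equal(cv_to_variance(17.3), 0.0295, tolerance = 1e-3)
  cvs <- c(0, 5, 17.3, 38.7, 150)
  expect_equal(variance_to_cv(cv_to_variance(cvs)), cvs, tolerance = 1e-12)
})

test_that("prediction with zero effects equals the typical profile", {
  x <- small_study(seed = 5, n_subjects = 4)
  pr <- predict_pk(truth, x)
  for (id in unique(pr$subject)) {
    ev <- x$events[x$events$subject == id, ]
    reg <- pk_regimen(ev$amt[ev$evid == 1], ev$time[ev$evid == 1],
                      ev$dur[ev$evid == 1])
    direct <- pk_concentration(pr$time[pr$subject == id], reg,
                               pk_params(22.1, 162, 69.4, 87.9))
    expect_equal(pr$pred[pr$subject == id], direct, tolerance = 1e-12)
  }
})

test_that("occasion-varying parameters keep compartment amounts continuous", {
  # piecewise-parameter trajectory vs ODE integration with parameter
  # switches at occasion boundaries
  reg <- study_regimen(4)
  set.seed(9)
  plist <- lapply(1:4, function(k)
    pk_params(22.1 * exp(rnorm(1, 0, 0.2)), 162, 69.4,
              87.9 * exp(rnorm(1, 0, 0.3))))
  tt <- sort(c(as.vector(outer(c(0.5, 2, 4, 8, 12), 12 * (0:3), `+`)),
               11.999, 12.001, 36.5))
  cc <- pk_concentration(tt, reg, plist)
  rate_fun <- function(t) sum(ifelse(reg$time <= t & t < reg$time + reg$dur,
                                     reg$amt / reg$dur, 0))
  deriv <- function(t, A, parms) {
    pp <- plist[[max(findInterval(t, 12 * (0:3)), 1)]]
    k10 <- pp$CL / pp$V1; k12 <- pp$Q / pp$V1; k21 <- pp$Q / pp$V2
    list(c(rate_fun(t) - (k10 + k12) * A[1] + k21 * A[2],
           k12 * A[1] - k21 * A[2]))
  }
  out <- deSolve::ode(c(0, 0), sort(unique(c(0, tt, reg$time,
                                             reg$time + reg$dur,
                                             12 * (0:3)))),
                      deriv, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  f <- approx(out[, 1], out[, 2], xout = tt)$y
  oo <- f / vapply(pmax(findInterval(tt, 12 * (0:3)), 1),
                   function(i) plist[[i]]$V1, 0)
  expect_lt(max(abs(cc - oo) / pmax(abs(oo), 1e-10)), 1e-6)
})

test_that("noise-free simulation reproduces typical predictions exactly", {
  x <- small_study(seed = 3, n_subjects = 3)
  pop0 <- pop_params(22.1, 162, 69.4, 87.9) # all variances zero
  xs <- simulate_pk(pop0, x, seed = 1)
  pr <- predict_pk(pop0, x)
  expect_equal(xs$events$dv[xs$events$evid == 0], pr$pred, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  x <- small_study(seed = 3, n_subjects = 3)
  a <- simulate_pk(truth, x, seed = 99)
  b <- simulate_pk(truth, x, seed = 99)
  expect_identical(a$events$dv, b$events$dv)
  expect_identical(attr(a, "effects"), attr(b, "effects"))
})

test_that("simulated between-subject CV of CL matches the IIV variance", {
  # single-observation design for many subjects: eta moments via effects
  n <- 4000
  ev <- data.frame(subject = rep(1:n, each = 2),
                   time = rep(c(0, 2), n),
                   evid = rep(c(1L, 0L), n),
                   amt = rep(c(100, NA), n),
                   dur = rep(c(0.5, NA), n),
                   dv = NA_real_)
  x <- assign_occasions(pk_dataset(ev))
  xs <- simulate_pk(truth, x, seed = 17)
  eff <- attr(xs, "effects")
  cl <- 22.1 * exp(eff$eta[, "CL"])
  expect_lt(abs(100 * sd(cl) / mean(cl) - 17.3), 0.035 * 17.3)
  expect_lt(abs(mean(eff$eta[, "CL"])),
            3 * sqrt(truth$omega2[["CL"]] / n))
  expect_lt(abs(var(eff$eta[, "V2"]) - truth$omega2[["V2"]]),
            3 * truth$omega2[["V2"]] * sqrt(2 / (n - 1)))
})

test_that("residual variance at a fixed prediction is f^2 s2p + sa2", {
  # one subject observed many times at the same instant: f constant
  ev <- data.frame(subject = 1, time = c(0, rep(2, 3000)),
                   evid = c(1L, rep(0L, 3000)),
                   amt = c(200, rep(NA, 3000)), dur = c(0.5, rep(NA, 3000)),
                   dv = NA_real_)
  pop0 <- pop_params(22.1, 162, 69.4, 87.9, sigma_add = 0.021,
                     sigma2_prop = 0.13^2)
  xs <- simulate_pk(pop0, assign_occasions(pk_dataset(ev)), seed = 23)
  y <- xs$events$dv[xs$events$evid == 0]
  f <- predict_pk(pop0, xs)$pred[1]
  v_expect <- f^2 * 0.13^2 + 0.021^2
  expect_lt(abs(var(y) - v_expect), 3 * v_expect * sqrt(2 / 2999))
  expect_lt(abs(mean(y) - f), 3 * sqrt(v_expect / 3000))
})

test_that("below-LOQ simulated values are flagged and excluded from fitting", {
  x <- small_study(seed = 31, n_subjects = 6)
  blq <- x$events$blq[x$events$evid == 0]
  dv <- x$events$dv[x$events$evid == 0]
  expect_true(all(dv[blq] < 0.078))
  subs <- tigepk:::prep_subjects(x)
  expect_equal(sum(vapply(subs, function(s) length(s$y), 0L)),
               sum(!blq))
})

test_that("prediction is invariant to subject relabeling/ordering", {
  x <- small_study(seed = 8, n_subjects = 5)
  ev <- x$events
  ev$subject <- 6 - ev$subject # reverse the processing order
  x2 <- pk_dataset(ev, x$covariates)
  p1 <- predict_pk(truth, x)
  p2 <- predict_pk(truth, x2)
  for (id in 1:5) {
    a <- p1[p1$subject == id, ]
    b <- p2[p2$subject == 6 - id, ]
    expect_equal(a$pred[order(a$time)], b$pred[order(b$time)],
                 tolerance = 1e-12)
  }
})

test_that("population parameters round trip through the flat config file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pop_params(truth, path)
  back <- read_pop_params(path)
  expect_equal(tigepk:::pop_to_flat(back), tigepk:::pop_to_flat(truth),
               tolerance = 1e-15)
})
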