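# Shared fixtures.  Expensive objects (full-study fits) are built lazily and
# cached for the duration of the test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fix)) assign(name, builder(), envir = .fix)
  get(name, envir = .fix)
}

# 2 subjects, 1 dose + 2 observations each
toy_events <- function() {
  data.frame(
    subject = c(1, 1, 1, 2, 2, 2),
    time = c(0, 0.5, 2, 0, 0.5, 4),
    evid = c(1L, 0L, 0L, 1L, 0L, 0L),
    amt = c(200, NA, NA, 200, NA, NA),
    dur = c(0.5, NA, NA, 0.5, NA, NA),
    dv = c(NA, 1.1, 0.6, NA, 1.0, 0.4))
}

toy_dataset <- function() assign_occasions(pk_dataset(toy_events()))

# reduced synthetic study for cheap unit tests
small_study <- function(seed = 42, n_subjects = 8) {
  generate_study(study_design_spec(n_subjects = n_subjects),
                 truth = tigecycline_pop_params(), seed = seed)
}

# one full-design study and its fit, shared by the diagnostic tests
study_fit <- function() fixture("study_fit", function() {
  x <- generate_study(seed = 201)
  list(x = x, fit = fit_pk(x, options = list(seed = 1)))
})

# five replicate studies fitted from the default initials (recovery tests)
replicate_fits <- function() fixture("replicate_fits", function() {
  lapply(1:5, function(r) {
    x <- generate_study(seed = 300 + r)
    fit_pk(x, options = list(seed = 1))
  })
})

flat_estimates <- function(fit) tigepk:::pop_to_flat(fit$estimates)
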