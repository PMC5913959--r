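#' @useDynLib tigepk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd var rnorm runif rbeta optimHess
#'   nlminb qchisq setNames qnorm cor pnorm approx isoreg complete.cases
#'   aggregate
#' @importFrom utils read.csv write.csv modifyList
NULL

# Covariate layout shared by the generator, the reader and the screen.
.cov_continuous <- c("age", "weight", "height", "dialysis_volume", "uf_speed",
                     "elwi", "cardiac_output", "sofa", "pct", "albumin")
.cov_categorical <- c("sex", "ecmo", "crrt")
.cov_time_dependent <- c("dialysis_volume", "uf_speed", "elwi",
                         "cardiac_output", "sofa", "pct")
.cov_all <- c(.cov_continuous, .cov_categorical)

#' Event dataset for population PK analysis
#'
#' Container for NONMEM-style event records: zero-order infusion doses
#' (`evid = 1`), plasma concentration observations (`evid = 0`) and optional
#' covariate records, all on a common within-subject clock measured in hours
#' since the subject's first dose.  Concentrations are in ug/ml (equivalently
#' mg/L), amounts in mg, durations in hours.
#'
#' @param events data.frame with columns `subject`, `time`, `evid` (1 dose /
#'   0 observation), `amt` (mg, doses), `dur` (h, doses), `dv` (ug/ml,
#'   observations), and optionally `occ` (occasion index) and `blq`
#'   (below-quantification flag).
#' @param covariates optional data.frame keyed by `subject` and `time` with
#'   any of the covariate columns (age, weight, height, sex, ecmo, crrt,
#'   dialysis_volume, uf_speed, elwi, cardiac_output, sofa, pct, albumin).
#'   Time-dependent covariates are carried forward between measurement times.
#' @param validate run [validate_pk_dataset()] on the result.
#' @return An object of class `pk_dataset`: list with elements `events`,
#'   `covariates`, `n_subjects`, `n_observations`.
#' @export
pk_dataset <- function(events, covariates = NULL, validate = TRUE) {
  stopifnot(is.data.frame(events),
            all(c("subject", "time", "evid") %in% names(events)))
  if (is.null(events$amt)) events$amt <- NA_real_
  if (is.null(events$dur)) events$dur <- NA_real_
  if (is.null(events$dv))  events$dv  <- NA_real_
  if (is.null(events$occ)) events$occ <- NA_integer_
  if (is.null(events$blq)) events$blq <- FALSE
  events$blq[is.na(events$blq)] <- FALSE
  # stable sort: time within subject, doses before observations at a tie so
  # that a trough drawn at a dose time follows the new occasion's bookkeeping
  events <- events[order(events$subject, events$time, -events$evid), ,
                   drop = FALSE]
  rownames(events) <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (is.null(covariates$time)) covariates$time <- 0
    covariates <- covariates[order(covariates$subject, covariates$time), ,
                             drop = FALSE]
    rownames(covariates) <- NULL
  }
  x <- structure(list(events = events, covariates = covariates,
                      n_subjects = length(unique(events$subject)),
                      n_observations = sum(events$evid == 0)),
                 class = "pk_dataset")
  if (validate) validate_pk_dataset(x)
  x
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("<pk_dataset> ", x$n_subjects, " subjects, ",
      x$n_observations, " observations, ",
      sum(x$events$evid == 1), " doses\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ",
        paste(intersect(.cov_all, names(x$covariates)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Validate an event dataset
#'
#' Checks the structural invariants the downstream stages rely on: positive
#' dose amounts and durations, non-negative times and concentrations, time
#' order within subject, every observation preceded (or met) by a dose, and
#' per-subject occasion labels that are contiguous from 1 and at most 8.
#'
#' @param x a [pk_dataset()].
#' @return `x` invisibly; errors describe the offending subjects/rows.
#' @export
validate_pk_dataset <- function(x) {
  ev <- x$events
  doses <- ev[ev$evid == 1, ]
  if (any(is.na(doses$amt)) || any(doses$amt <= 0))
    stop("dose amounts must be positive")
  if (any(is.na(doses$dur)) || any(doses$dur <= 0))
    stop("infusion durations must be positive")
  if (any(ev$time < 0)) stop("event times must be non-negative")
  for (id in unique(ev$subject)) {
    s <- ev[ev$subject == id, ]
    if (is.unsorted(s$time)) stop("non-monotone time for subject ", id)
    dt <- s$time[s$evid == 1]
    if (length(dt) == 0) stop("subject ", id, " has no dose records")
    ot <- s$time[s$evid == 0]
    if (length(ot) && min(ot) < min(dt))
      stop("subject ", id, " has an observation before any dose")
    occ <- s$occ[!is.na(s$occ)]
    if (length(occ)) {
      u <- sort(unique(occ))
      if (u[1] != 1L || any(diff(u) != 1L) || max(u) > 8L)
        stop("subject ", id,
             ": occasion indices must be contiguous from 1 and at most 8")
    }
  }
  invisible(x)
}

#' Label events with dosing-interval occasions
#'
#' An occasion is a dosing interval: occasion k spans from the time of the
#' k-th dose (inclusive) to the time of the (k+1)-th dose (exclusive); the
#' final occasion is open-ended.  An observation falling exactly on a dose
#' time therefore belongs to the new occasion.  The labelling is recomputed
#' from the dose records, so the operation is idempotent.
#'
#' @param x a [pk_dataset()].
#' @return the dataset with the `occ` column filled in.
#' @export
assign_occasions <- function(x) {
  ev <- x$events
  for (id in unique(ev$subject)) {
    i <- which(ev$subject == id)
    dt <- sort(ev$time[i][ev$evid[i] == 1])
    ev$occ[i] <- findInterval(ev$time[i], dt)
  }
  ev$occ[ev$occ < 1L] <- NA_integer_
  x$events <- ev
  validate_pk_dataset(x)
  x
}

#' Summarize covariates as medians, ranges and counts
#'
#' Continuous covariates are summarized by the median and range of the
#' per-subject values (baseline value for time-dependent covariates);
#' categorical covariates by level counts, mirroring the usual Table-1
#' presentation of a study population.
#'
#' @param x a [pk_dataset()] with covariates.
#' @return data.frame with columns `covariate`, `type`, `median`, `min`,
#'   `max`, `counts`.
#' @export
summarize_covariates <- function(x) {
  cov <- x$covariates
  if (is.null(cov) || nrow(cov) == 0) stop("dataset has no covariates")
  base <- cov[!duplicated(cov$subject), , drop = FALSE] # baseline row
  rows <- list()
  for (v in intersect(.cov_continuous, names(base))) {
    val <- base[[v]]
    if (all(is.na(val))) {
      rows[[v]] <- data.frame(covariate = v, type = "continuous",
                              median = NA_real_, min = NA_real_,
                              max = NA_real_, counts = "missing")
    } else {
      rows[[v]] <- data.frame(covariate = v, type = "continuous",
                              median = median(val, na.rm = TRUE),
                              min = min(val, na.rm = TRUE),
                              max = max(val, na.rm = TRUE), counts = "")
    }
  }
  for (v in intersect(.cov_categorical, names(base))) {
    tb <- table(base[[v]])
    rows[[v]] <- data.frame(covariate = v, type = "categorical",
                            median = NA_real_, min = NA_real_, max = NA_real_,
                            counts = paste(names(tb), as.integer(tb),
                                           sep = ":", collapse = " "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- delimited I/O (NONMEM-conventional layout) -----------------------------

.num_cols <- c("TIME", "AMT", "DUR", "RATE", "DV", .cov_continuous)

#' Write an event dataset as delimited text
#'
#' Single-file NONMEM-conventional layout: one row per event with columns
#' `ID, TIME, EVID, AMT, DUR, RATE, DV, OCC, BLQ` plus covariate columns.
#' Dose rows have `EVID = 1` (with `RATE = AMT/DUR`), observations
#' `EVID = 0`, and covariate measurement records `EVID = 2`.  Missing values
#' are written as `.`; numbers are written with full precision so that a
#' write/read cycle is exact.
#'
#' @param x a [pk_dataset()].
#' @param path output file.
#' @param sep field separator (comma by default).
#' @return `path` invisibly.
#' @export
write_pk_dataset <- function(x, path, sep = ",") {
  ev <- x$events
  main <- data.frame(ID = ev$subject, TIME = ev$time, EVID = ev$evid,
                     AMT = ev$amt, DUR = ev$dur,
                     RATE = ifelse(ev$evid == 1, ev$amt / ev$dur, NA_real_),
                     DV = ev$dv, OCC = ev$occ,
                     BLQ = as.integer(ev$blq))
  cov <- x$covariates
  covnames <- intersect(.cov_all, names(cov))
  for (v in covnames) main[[v]] <- NA
  if (!is.null(cov) && nrow(cov)) {
    crow <- data.frame(ID = cov$subject, TIME = cov$time, EVID = 2L,
                       AMT = NA_real_, DUR = NA_real_, RATE = NA_real_,
                       DV = NA_real_, OCC = NA_integer_, BLQ = NA_integer_)
    for (v in covnames) crow[[v]] <- cov[[v]]
    main <- rbind(main, crow)
    main <- main[order(main$ID, main$TIME, main$EVID != 2, -main$EVID), ]
  }
  fmt <- function(v) {
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    v <- as.character(v)
    v[v %in% c("NA", "nan")] <- "."
    v[is.na(v)] <- "."
    v
  }
  out <- vapply(main, fmt, character(nrow(main)))
  lines <- c(paste(colnames(main), collapse = sep),
             apply(out, 1, paste, collapse = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an event dataset from delimited text
#'
#' Reads the layout written by [write_pk_dataset()].  `ID`, `TIME`, `EVID`
#' and `DV` are mandatory; a dose row needs `AMT` and either `DUR` or `RATE`
#' (`DUR` is derived as `AMT/RATE` when absent).  Rows that cannot be
#' interpreted are reported with their line numbers.
#'
#' @param path input file.
#' @param sep field separator.
#' @param validate run [validate_pk_dataset()] after reading.
#' @return a [pk_dataset()].
#' @export
read_pk_dataset <- function(path, sep = ",", validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, na.strings = c(".", "", "NA"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ID", "TIME", "EVID", "DV")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (v in intersect(.num_cols, names(raw))) raw[[v]] <- as.numeric(raw[[v]])
  raw$EVID <- as.integer(raw$EVID)
  bad <- which(is.na(raw$TIME) | is.na(raw$EVID) |
                 (raw$EVID == 1 & (is.na(raw$AMT) | raw$AMT <= 0)))
  if (length(bad))
    stop("malformed rows at line(s) ", paste(bad + 1L, collapse = ", "),
         " (header is line 1)")
  isev <- raw$EVID %in% c(0L, 1L)
  ev <- raw[isev, , drop = FALSE]
  dur <- if ("DUR" %in% names(ev)) ev$DUR else NA_real_
  if ("RATE" %in% names(ev)) {
    fill <- is.na(dur) & ev$EVID == 1 & !is.na(ev$RATE) & ev$RATE > 0
    dur[fill] <- ev$AMT[fill] / ev$RATE[fill]
  }
  events <- data.frame(subject = ev$ID, time = ev$TIME, evid = ev$EVID,
                       amt = if ("AMT" %in% names(ev)) ev$AMT else NA_real_,
                       dur = dur, dv = ev$DV,
                       occ = if ("OCC" %in% names(ev)) as.integer(ev$OCC)
                             else NA_integer_,
                       blq = if ("BLQ" %in% names(ev)) !is.na(ev$BLQ) & ev$BLQ == 1
                             else FALSE)
  covariates <- NULL
  covnames <- intersect(.cov_all, names(raw))
  if (any(raw$EVID == 2L) && length(covnames)) {
    cr <- raw[raw$EVID == 2L, , drop = FALSE]
    covariates <- data.frame(subject = cr$ID, time = cr$TIME)
    for (v in covnames) covariates[[v]] <- cr[[v]]
  }
  pk_dataset(events, covariates, validate = validate)
}

# Covariate value for given subjects at given times, last observation
# carried forward from the covariate measurement grid.
covariate_at <- function(x, name, subjects, times) {
  cov <- x$covariates
  out <- rep(NA_real_, length(subjects))
  if (is.null(cov) || !(name %in% names(cov))) return(out)
  for (id in unique(subjects)) {
    i <- which(subjects == id)
    ci <- cov[cov$subject == id & !is.na(cov[[name]]), , drop = FALSE]
    if (!nrow(ci)) next
    idx <- findInterval(times[i], ci$time)
    idx[idx < 1L] <- 1L # before first measurement: carry backward
    val <- ci[[name]][idx]
    out[i] <- if (is.numeric(val)) val else as.numeric(factor(val))
  }
  out
}
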