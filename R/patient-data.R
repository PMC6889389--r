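#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a patient record
#'
#' @param patientId character identifier.
#' @param doseTimes,doses dose days (ascending) and doses in mg.
#' @param obsTimes,leukocyte,crp visit days (ascending), leukocyte counts
#'   (1e9 cells/L, `NA` allowed) and CRP (mg/L, `NA` allowed).
#' @param bsaTimes,bsa BSA recording days and values (m^2).  A single value
#'   is treated as constant over the treatment.
#' @return a validated [PatientRecord-class].
#' @export
#' @examples
#' rec <- PatientRecord("p1",
#'   doseTimes = 0:20, doses = rep(50, 21),
#'   obsTimes = c(0, 7, 14), leukocyte = c(5.1, 4.2, 3.0),
#'   crp = c(NA, 4, 12), bsaTimes = 0, bsa = 1.0)
#' rec
PatientRecord <- function(patientId, doseTimes = numeric(), doses = numeric(),
                          obsTimes = numeric(), leukocyte = numeric(),
                          crp = rep(NA_real_, length(obsTimes)),
                          bsaTimes = 0, bsa) {
  new("PatientRecord", patientId = as.character(patientId),
      doseTimes = as.numeric(doseTimes), doses = as.numeric(doses),
      obsTimes = as.numeric(obsTimes), leukocyte = as.numeric(leukocyte),
      crp = as.numeric(crp), bsaTimes = as.numeric(bsaTimes),
      bsa = as.numeric(bsa))
}

#' @rdname PatientRecord-accessors
#' @name PatientRecord-accessors
#' @title Accessors for PatientRecord and fit objects
#' @param x the object.
#' @aliases patientId doseTimes doses obsTimes leukocyte crp bsaTimes bsa
#'   treatmentSpan
NULL

setMethod("patientId", "PatientRecord", function(x) x@patientId)
setMethod("doseTimes", "PatientRecord", function(x) x@doseTimes)
setMethod("doses", "PatientRecord", function(x) x@doses)
setMethod("obsTimes", "PatientRecord", function(x) x@obsTimes)
setMethod("leukocyte", "PatientRecord", function(x) x@leukocyte)
setMethod("crp", "PatientRecord", function(x) x@crp)
setMethod("bsaTimes", "PatientRecord", function(x) x@bsaTimes)
setMethod("bsa", "PatientRecord", function(x) x@bsa)

#' @rdname PatientRecord-accessors
setMethod("treatmentSpan", "PatientRecord", function(x) {
  allT <- c(x@doseTimes, x@obsTimes, x@bsaTimes)
  diff(range(allT))
})

## ---------------------------------------------------------------------------
## CSV I/O
##
## Schema (one file per patient, RFC-4180): columns
##   patient_id, time, dose, leukocyte, crp, bsa
## Each row is one day/time point; empty cells mean "not recorded".  Rows
## with a non-empty `dose` form the dosing series, rows with a non-empty
## `leukocyte` and/or `crp` form the visit series, rows with non-empty `bsa`
## the BSA series.  The paper's supplementary tables are converted to this
## layout by a trivial column mapping.
## ---------------------------------------------------------------------------

#' Read a patient CSV file
#'
#' Parses one patient file in the package's CSV schema (columns
#' `patient_id`, `time`, `dose`, `leukocyte`, `crp`, `bsa`; empty cells are
#' missing values, never zeros) into a validated [PatientRecord-class].
#' Column names can be remapped through `dialect` for externally produced
#' files.
#'
#' @param path CSV file path.
#' @param dialect named list remapping schema names to file column names,
#'   e.g. `list(leukocyte = "wbc")`.
#' @return a [PatientRecord-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' rec <- PatientRecord("p1", doseTimes = 0:6, doses = rep(25, 7),
#'   obsTimes = c(0, 7), leukocyte = c(5, 4), bsaTimes = 0, bsa = 1)
#' writePatientCsv(rec, f)
#' readPatientCsv(f)
readPatientCsv <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e)))
  cols <- c(patient_id = "patient_id", time = "time", dose = "dose",
            leukocyte = "leukocyte", crp = "crp", bsa = "bsa")
  cols[names(dialect)] <- unlist(dialect)
  missingCols <- setdiff(unname(cols[c("time")]), names(df))
  if (length(missingCols))
    stop("'", path, "': required column(s) missing: ",
         paste(missingCols, collapse = ", "))
  getCol <- function(key) {
    cn <- cols[[key]]
    if (cn %in% names(df)) df[[cn]] else rep(NA_real_, nrow(df))
  }
  num <- function(key) {
    x <- getCol(key)
    if (is.character(x)) {
      bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
      if (length(bad))
        stop("'", path, "': non-numeric value in column '", cols[[key]],
             "', row ", bad[1] + 1L)
      x <- suppressWarnings(as.numeric(x))
    }
    as.numeric(x)
  }
  tm <- num("time")
  if (any(is.na(tm)))
    stop("'", path, "': missing time in row ",
         which(is.na(tm))[1] + 1L)
  dose <- num("dose"); leuk <- num("leukocyte")
  crpv <- num("crp"); bsav <- num("bsa")
  pid <- getCol("patient_id")
  pid <- if (all(is.na(pid))) sub("\\.csv$", "", basename(path))
         else as.character(pid[!is.na(pid)][1])
  obsSel <- !is.na(leuk) | !is.na(crpv)
  rec <- tryCatch(
    PatientRecord(pid,
      doseTimes = tm[!is.na(dose)], doses = dose[!is.na(dose)],
      obsTimes = tm[obsSel], leukocyte = leuk[obsSel], crp = crpv[obsSel],
      bsaTimes = tm[!is.na(bsav)], bsa = bsav[!is.na(bsav)]),
    error = function(e) stop("'", path, "' failed validation: ",
                             conditionMessage(e)))
  rec
}

#' Write a patient record in the package CSV schema
#'
#' Inverse of [readPatientCsv()]: the round trip preserves all values and
#' missingness patterns exactly (up to CSV formatting).
#'
#' @param record a [PatientRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePatientCsv <- function(record, path) {
  stopifnot(is(record, "PatientRecord"))
  tm <- sort(unique(c(record@doseTimes, record@obsTimes, record@bsaTimes)))
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 15,
                                                  format = "g"))
  lookup <- function(keys, vals) {
    out <- rep(NA_real_, length(tm))
    out[match(keys, tm)] <- vals
    out
  }
  df <- data.frame(
    patient_id = record@patientId,
    time = fmt(tm),
    dose = fmt(lookup(record@doseTimes, record@doses)),
    leukocyte = fmt(lookup(record@obsTimes, record@leukocyte)),
    crp = fmt(lookup(record@obsTimes, record@crp)),
    bsa = fmt(lookup(record@bsaTimes, record@bsa)),
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a directory of patient CSV files as a cohort
#'
#' @param dir directory containing one CSV per patient.
#' @param pattern file pattern, default `"\\.csv$"`.
#' @param dialect passed to [readPatientCsv()].
#' @return named list of [PatientRecord-class] objects.
#' @export
readCohort <- function(dir, pattern = "\\.csv$", dialect = list()) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no patient CSV files found in ", dir)
  recs <- lapply(files, readPatientCsv, dialect = dialect)
  names(recs) <- vapply(recs, patientId, character(1))
  recs
}

#' Write a cohort as one CSV per patient
#'
#' @param records list of [PatientRecord-class] objects.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
writeCohort <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(records, function(r) {
    p <- file.path(dir, paste0(patientId(r), ".csv"))
    writePatientCsv(r, p)
    p
  }, character(1))
  invisible(paths)
}

## ---------------------------------------------------------------------------
## BSA and dose input
## ---------------------------------------------------------------------------

#' Mosteller body surface area
#'
#' `sqrt(height_cm * weight_kg / 3600)` in m^2.
#'
#' @param height height in cm (> 0).
#' @param weight weight in kg (> 0).
#' @return BSA in m^2.
#' @export
#' @examples
#' mostellerBsa(100, 36)  # 1.0
mostellerBsa <- function(height, weight) {
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive")
  sqrt(height * weight / 3600)
}

#' BSA at arbitrary times by interpolation
#'
#' Piecewise-linear interpolation of the record's BSA series, clamped at the
#' endpoints (no extrapolation beyond the recorded range).
#'
#' @param record a [PatientRecord-class].
#' @param t numeric vector of days.
#' @return BSA in m^2 at each `t`.
#' @export
bsaAt <- function(record, t) {
  bt <- bsaTimes(record); bv <- bsa(record)
  if (length(bv) == 1L) return(rep(bv, length(t)))
  stats::approx(bt, bv, xout = t, rule = 2, ties = "ordered")$y
}

#' BSA series from a user-supplied median growth table
#'
#' Optional helper replicating the growth-curve interpolation used to track
#' BSA over a long treatment when only baseline height/weight are recorded:
#' given a median growth table (columns `age_days`, `height_cm`,
#' `weight_kg`; e.g. national reference curves averaged over sexes), the
#' child's recorded baseline values are carried along the table's increments
#' and converted to BSA with the Mosteller formula.  No reference table is
#' bundled.
#'
#' @param growthTable data.frame with columns `age_days`, `height_cm`,
#'   `weight_kg`, ascending in age.
#' @param ageAtStart age in days at the start of maintenance therapy.
#' @param height0,weight0 recorded baseline height (cm) and weight (kg).
#' @param times days since start at which BSA is wanted.
#' @return numeric BSA series at `times`.
#' @export
bsaFromGrowthTable <- function(growthTable, ageAtStart, height0, weight0,
                               times) {
  stopifnot(all(c("age_days", "height_cm", "weight_kg") %in%
                  names(growthTable)))
  h <- function(a) stats::approx(growthTable$age_days, growthTable$height_cm,
                                 xout = a, rule = 2)$y
  w <- function(a) stats::approx(growthTable$age_days, growthTable$weight_kg,
                                 xout = a, rule = 2)$y
  ages <- ageAtStart + times
  mostellerBsa(height0 + h(ages) - h(ageAtStart),
               weight0 + w(ages) - w(ageAtStart))
}

#' BSA-normalised dose input d(t)
#'
#' The drug input of the state-space models: the last 6-MP dose administered
#' within the window `(t - tDur, t]` (default 24 h), normalised by the
#' patient's interpolated BSA at `t`; zero if no dose falls in the window.
#' Piecewise constant in `t` and scaling as 1/BSA.
#'
#' @param record a [PatientRecord-class].
#' @param t numeric vector of days.
#' @param tDur window length in days (default 1).
#' @return dose in mg/m^2 at each `t`.
#' @export
#' @examples
#' rec <- PatientRecord("p", doseTimes = 10, doses = 50,
#'   obsTimes = c(0, 14), leukocyte = c(5, 4), bsaTimes = 0, bsa = 1)
#' doseInput(rec, c(10.5, 11.5))  # 50, 0
doseInput <- function(record, t, tDur = 1) {
  stopifnot(tDur > 0)
  dtm <- doseTimes(record); dv <- doses(record)
  out <- numeric(length(t))
  if (length(dtm)) {
    # index of the last dose time <= t
    idx <- findInterval(t, dtm)
    hit <- idx >= 1L
    hit[hit] <- dtm[idx[hit]] > t[hit] - tDur  # within the window
    out[hit] <- dv[idx[hit]]
  }
  out / bsaAt(record, t)
}

#' Restrict a record to data up to a time
#'
#' Keeps observations with `obsTimes <= tMax` and doses with
#' `doseTimes <= tMax`; the BSA series is kept in full (it is a known
#' covariate, not an outcome).  Used to build the expanding training sets of
#' the cross-validation harness.
#'
#' @param record a [PatientRecord-class].
#' @param tMax cut-off day (inclusive).
#' @return a [PatientRecord-class].
#' @export
truncateRecord <- function(record, tMax) {
  keepO <- obsTimes(record) <= tMax
  keepD <- doseTimes(record) <= tMax
  PatientRecord(patientId(record),
    doseTimes = doseTimes(record)[keepD], doses = doses(record)[keepD],
    obsTimes = obsTimes(record)[keepO],
    leukocyte = leukocyte(record)[keepO], crp = crp(record)[keepO],
    bsaTimes = bsaTimes(record), bsa = bsa(record))
}
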