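## INI dialect: '#' and ';' comments, optional [section] headers,
## case-insensitive keys, key = value pairs.
.read_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("[#;].*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "" || grepl("^\\[.*\\]$", ln)) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0)
      stop(sprintf("parse error: line %d is not 'key = value': %s",
                   i, lines[i]), call. = FALSE)
    key <- tolower(trimws(substr(ln, 1, eq - 1)))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    out[[key]] <- list(value = val, line = i)
  }
  out
}

.config_defaults <- function() list(
  useinterpolation = 0,
  interpolationmethod = "trilinear",
  interpolation2d = 0,
  targetspacing = 2,          # mm, isotropic unless per-axis keys are set
  targetspacingx = NA_real_,
  targetspacingy = NA_real_,
  targetspacingz = NA_real_,
  maskinterpolationthreshold = 0.5,
  resegmentimage = 0,
  minintensity = -Inf,
  maxintensity = Inf,
  excludeoutliers = 0,
  outliersigma = 3,
  discretizationmethod = "FBN",
  nrbins = 64,
  binwidth = 1,
  discretizeivhseparately = 0,
  ivhdiscretizationmethod = "FBN",
  ivhnrbins = 1000,
  ivhbinwidth = 1,
  thresholdforvoi = 0.5,
  petscaling = "SUV",
  scalingfactor = NA_real_,
  ngldmalpha = 0,
  smoothiterations = 40
)

.config_numeric_keys <- c(
  "useinterpolation", "interpolation2d", "targetspacing", "targetspacingx",
  "targetspacingy", "targetspacingz", "maskinterpolationthreshold",
  "resegmentimage", "minintensity", "maxintensity", "excludeoutliers",
  "outliersigma", "nrbins", "binwidth", "discretizeivhseparately",
  "ivhnrbins", "ivhbinwidth", "thresholdforvoi", "scalingfactor",
  "ngldmalpha", "smoothiterations")

#' Parse an INI configuration file into a resolved run configuration
#'
#' Every recognised key receives its documented default when absent;
#' unknown keys are rejected naming the offending key, and malformed
#' numeric values are rejected naming the key and line. The provenance of
#' every resolved value (`"default"` or `"file:<line>"`) is kept in the
#' `"provenance"` attribute.
#'
#' @param path INI file; missing file is an error.
#' @return A named list of class `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop("file error: configuration file ", path, " not found",
         call. = FALSE)
  raw <- .read_ini(path)
  cfg <- .config_defaults()
  prov <- stats::setNames(rep("default", length(cfg)), names(cfg))
  for (key in names(raw)) {
    if (!key %in% names(cfg))
      stop("parse error: unknown configuration key '", key, "'",
           call. = FALSE)
    v <- raw[[key]]$value
    if (key %in% .config_numeric_keys) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num) && !tolower(v) %in% c("inf", "-inf", "nan"))
        stop(sprintf(
          "parse error: key '%s' (line %d) has non-numeric value '%s'",
          key, raw[[key]]$line, v), call. = FALSE)
      cfg[[key]] <- num
    } else {
      cfg[[key]] <- v
    }
    prov[[key]] <- sprintf("file:%d", raw[[key]]$line)
  }
  cfg$discretizationmethod <- toupper(cfg$discretizationmethod)
  cfg$ivhdiscretizationmethod <- toupper(cfg$ivhdiscretizationmethod)
  cfg$petscaling <- toupper(cfg$petscaling)
  if (!cfg$discretizationmethod %in% c("FBN", "FBS"))
    stop("parse error: DiscretizationMethod must be FBN or FBS",
         call. = FALSE)
  if (!cfg$petscaling %in% c("SUV", "SUL", "SCALE", "NONE"))
    stop("parse error: PETScaling must be SUV, SUL, SCALE or NONE",
         call. = FALSE)
  attr(cfg, "provenance") <- prov
  attr(cfg, "source") <- path
  class(cfg) <- "run_config"
  cfg
}

#' Default run configuration (no configuration file)
#' @return A `run_config` with every key at its default.
#' @export
default_config <- function() {
  cfg <- .config_defaults()
  attr(cfg, "provenance") <- stats::setNames(rep("default", length(cfg)),
                                             names(cfg))
  class(cfg) <- "run_config"
  cfg
}

.feature_groups <- c("Morphology", "LocalIntensity", "Statistics",
                     "IntensityVolume", "IntensityHistogram", "GLCM",
                     "GLRLM", "GLSZM", "GLDZM", "NGTDM", "NGLDM")

#' Parse a feature-output definition file
#'
#' INI file with one 0/1 flag per feature group (`Morphology`,
#' `LocalIntensity`, `Statistics`, `IntensityVolume`,
#' `IntensityHistogram`, `GLCM`, `GLRLM`, `GLSZM`, `GLDZM`, `NGTDM`,
#' `NGLDM`). Groups absent from the file stay selected; with no file at
#' all every group is calculated.
#'
#' @param path INI file, or `NULL` to select every group.
#' @return Named logical vector over the group names.
#' @export
parse_feature_selection <- function(path = NULL) {
  sel <- stats::setNames(rep(TRUE, length(.feature_groups)),
                         .feature_groups)
  if (is.null(path)) return(sel)
  if (!file.exists(path))
    stop("file error: feature definition file ", path, " not found",
         call. = FALSE)
  raw <- .read_ini(path)
  lut <- stats::setNames(.feature_groups, tolower(.feature_groups))
  for (key in names(raw)) {
    if (!key %in% names(lut))
      stop("parse error: unknown feature group '", key, "'",
           call. = FALSE)
    sel[[lut[[key]]]] <- !identical(trimws(raw[[key]]$value), "0")
  }
  sel
}

#' Parse a PET patient-information INI file
#'
#' Keys: `PatientWeight` (kg), `PatientHeight` (cm), `PatientSex` (M/F),
#' `InjectedActivity` (Bq), `InjectionTime` and `ScanStartTime`
#' (`YYYY-MM-DD HH:MM:SS` or seconds), `HalfLife` (s), `ScalingFactor`,
#' `ActivityDecayCorrected` (0/1).
#'
#' @param path INI file.
#' @return A [patient_info()].
#' @export
parse_patient_info <- function(path) {
  if (!file.exists(path))
    stop("file error: patient info file ", path, " not found",
         call. = FALSE)
  raw <- .read_ini(path)
  g <- function(key, default = NA_real_) {
    if (is.null(raw[[key]])) return(default)
    raw[[key]]$value
  }
  parse_time <- function(v) {
    if (is.na(suppressWarnings(as.numeric(v)))) {
      t <- as.POSIXct(v, tz = "UTC",
                      tryFormats = c("%Y-%m-%d %H:%M:%S", "%H:%M:%S"))
      as.numeric(t)
    } else as.numeric(v)
  }
  sf <- suppressWarnings(as.numeric(g("scalingfactor")))
  patient_info(
    weight = as.numeric(g("patientweight")),
    height = as.numeric(g("patientheight")),
    sex = toupper(g("patientsex", "M")),
    injected_activity = as.numeric(g("injectedactivity")),
    injection_time = if (!is.null(raw[["injectiontime"]]))
      parse_time(raw[["injectiontime"]]$value) else NA_real_,
    scan_start_time = if (!is.null(raw[["scanstarttime"]]))
      parse_time(raw[["scanstarttime"]]$value) else NA_real_,
    half_life = as.numeric(g("halflife", 6586.2)),
    scaling_override = if (is.na(sf)) NULL else sf,
    activity_decay_corrected =
      identical(trimws(g("activitydecaycorrected", "0")), "1"))
}
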