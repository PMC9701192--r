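#' @importFrom stats median quantile sd qnorm pnorm rlnorm runif var
#' @importFrom utils read.csv write.csv write.table
NULL

#' Particle classes recognized by the pipeline
#'
#' Every measured event carries a particle-class label, normally produced by
#' an image classifier running inline with the mass sensor: `intact` and
#' `permeable` single cells are accepted for analysis, while `aggregate` and
#' `debris` events are rejected. Labels the classifier cannot place map to
#' `unclassified`.
#' @export
PARTICLE_CLASSES <- c("intact", "permeable", "aggregate", "debris",
                      "unclassified")

#' Condition roles in a mass-response experiment
#'
#' A session measures a vehicle-treated `reference` population first, the
#' drug-treated `test` conditions next, and a vehicle-treated `control`
#' replicate last; the reference-to-control distance quantifies phenotypic
#' drift over the session.
#' @export
CONDITION_ROLES <- c("reference", "control", "test")

#' Default column schema for measurement tables
#'
#' Maps canonical field names to the column names expected in a delimited
#' measurement table. Users can override any entry via the `schema` argument
#' of [load_measurements()].
#' @export
default_schema <- function() {
  c(mass          = "mass_pg",
    particle_class = "particle_class",
    condition_id  = "condition_id",
    role          = "role",
    t_meas        = "t_meas_s",
    instrument_id = "instrument_id")
}

canonical_record_columns <- c("mass_pg", "particle_class", "condition_id",
                              "role", "t_meas_s", "instrument_id")

#' Construct a table of validated mass records
#'
#' A mass record is one particle's buoyant mass (picograms) together with its
#' particle-class label, condition identifier, condition role and measurement
#' time. This constructor validates and canonicalizes a data frame of such
#' records.
#'
#' @param mass numeric, buoyant mass in pg; must be finite and positive.
#' @param particle_class character, one of [PARTICLE_CLASSES]; unknown labels
#'   become `"unclassified"` with a warning.
#' @param condition_id character condition identifier.
#' @param role character, one of [CONDITION_ROLES]; missing/NA roles default
#'   to `"test"` with a warning.
#' @param t_meas numeric, seconds since the start of the measurement session
#'   (non-negative).
#' @param instrument_id optional character instrument identifier.
#' @return A `data.frame` with columns `mass_pg`, `particle_class`,
#'   `condition_id`, `role`, `t_meas_s`, `instrument_id`.
#' @export
mass_records <- function(mass, particle_class = "intact",
                         condition_id = "cond", role = "test",
                         t_meas = 0, instrument_id = NA_character_) {
  df <- data.frame(mass_pg = as.numeric(mass),
                   particle_class = as.character(particle_class),
                   condition_id = as.character(condition_id),
                   role = as.character(role),
                   t_meas_s = as.numeric(t_meas),
                   instrument_id = as.character(instrument_id),
                   stringsAsFactors = FALSE)
  validate_records(df)
}

# Validate a canonical record data.frame. Rows failing hard invariants are
# dropped with a message; label problems are repaired with a warning.
validate_records <- function(df, quiet = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(canonical_record_columns, names(df))
  if ("instrument_id" %in% missing_cols) {
    df$instrument_id <- NA_character_
    missing_cols <- setdiff(missing_cols, "instrument_id")
  }
  if (length(missing_cols) > 0)
    stop("measurement table is missing required columns: ",
         paste(missing_cols, collapse = ", "))

  unknown <- !(df$particle_class %in% PARTICLE_CLASSES) | is.na(df$particle_class)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unknown particle class mapped to 'unclassified'")
    df$particle_class[unknown] <- "unclassified"
  }
  no_role <- is.na(df$role) | !(df$role %in% CONDITION_ROLES)
  if (any(no_role)) {
    warning(sum(no_role), " record(s) with missing/unknown role defaulted to 'test'")
    df$role[no_role] <- "test"
  }

  bad_mass <- !is.finite(df$mass_pg) | df$mass_pg <= 0
  bad_t <- !is.finite(df$t_meas_s) | df$t_meas_s < 0
  bad <- bad_mass | bad_t
  if (any(bad)) {
    if (!quiet)
      message("rejected ", sum(bad), " record(s): ",
              sum(bad_mass), " invalid mass, ", sum(bad_t & !bad_mass),
              " invalid measurement time")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df <- df[, canonical_record_columns]
  attr(df, "n_rejected") <- sum(bad)
  df
}

#' Read a measurement table from a delimited text file
#'
#' Reads one record per particle from a comma- (default) or tab-delimited
#' file with a header row, applies the column schema, and validates every
#' row. Rows with non-numeric, non-positive or non-finite mass, or negative
#' measurement time, are rejected and counted (see attribute `n_rejected`).
#'
#' @param path path to the delimited file.
#' @param schema named character vector mapping canonical field names
#'   (`mass`, `particle_class`, `condition_id`, `role`, `t_meas`,
#'   `instrument_id`) to the column names in the file; defaults to
#'   [default_schema()]. Partial overrides are merged with the default.
#' @param sep field separator; `NULL` (default) sniffs comma versus tab from
#'   the header line.
#' @return A validated record `data.frame` (see [mass_records()]), with
#'   attribute `n_rejected` giving the count of dropped rows.
#' @export
load_measurements <- function(path, schema = default_schema(), sep = NULL) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  full <- default_schema()
  full[names(schema)] <- schema
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  required <- full[c("mass", "particle_class", "condition_id", "role")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0)
    stop("measurement table is missing required columns: ",
         paste(missing_cols, collapse = ", "))

  df <- data.frame(
    mass_pg = suppressWarnings(as.numeric(raw[[full[["mass"]]]])),
    particle_class = as.character(raw[[full[["particle_class"]]]]),
    condition_id = as.character(raw[[full[["condition_id"]]]]),
    role = as.character(raw[[full[["role"]]]]),
    t_meas_s = if (full[["t_meas"]] %in% names(raw))
      suppressWarnings(as.numeric(raw[[full[["t_meas"]]]])) else 0,
    instrument_id = if (full[["instrument_id"]] %in% names(raw))
      as.character(raw[[full[["instrument_id"]]]]) else NA_character_,
    stringsAsFactors = FALSE)
  validate_records(df)
}

#' Write a measurement table
#'
#' Inverse of [load_measurements()] under the default schema; round-trips
#' mass values at full precision.
#'
#' @param records validated record `data.frame`.
#' @param path output file path; `.tsv` extension writes tab-delimited.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- records[, canonical_record_columns]
  # full-precision masses so that write/read is lossless
  df$mass_pg <- format(df$mass_pg, digits = 17, trim = TRUE, scientific = FALSE)
  df$t_meas_s <- format(df$t_meas_s, digits = 17, trim = TRUE, scientific = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a condition sample
#'
#' The ordered single-cell mass sample for one condition/role: the unit on
#' which the mass-response statistic operates. Masses are stored sorted
#' ascending (the order-statistic pairing of the statistic requires it).
#'
#' @param masses numeric vector of positive masses (pg).
#' @param condition_id condition identifier.
#' @param role one of [CONDITION_ROLES].
#' @param curated logical, whether particle-class filtering was applied.
#' @return An object of class `condition_sample`.
#' @export
condition_sample <- function(masses, condition_id = "cond", role = "test",
                             curated = FALSE) {
  masses <- as.numeric(masses)
  if (length(masses) == 0) stop("empty mass sample for condition '", condition_id, "'")
  if (any(!is.finite(masses) | masses <= 0))
    stop("condition '", condition_id, "' contains non-finite or non-positive masses")
  structure(list(condition_id = as.character(condition_id),
                 role = match.arg(role, CONDITION_ROLES),
                 masses = sort(masses),
                 n = length(masses),
                 curated = isTRUE(curated)),
            class = "condition_sample")
}

#' @export
print.condition_sample <- function(x, ...) {
  cat(sprintf("<condition_sample> %s (%s): n=%d, mean=%.2f pg%s\n",
              x$condition_id, x$role, x$n, mean(x$masses),
              if (x$curated) ", curated" else ""))
  invisible(x)
}

# Coerce numeric vectors or condition_samples to a sorted mass vector.
as_masses <- function(x) {
  if (inherits(x, "condition_sample")) return(x$masses)
  x <- as.numeric(x)
  if (is.unsorted(x)) x <- sort(x)
  x
}

#' Group mass records into an experiment set
#'
#' Groups records by condition into [condition_sample()] objects and checks
#' the reference/control/test structure: exactly one condition with role
#' `reference` (measured first) and one with role `control` (measured last).
#' A violation of the measurement-time ordering produces a warning, not an
#' error. Grouping is invariant to the order of input rows.
#'
#' @param records validated record `data.frame`.
#' @param curated logical flag carried onto each sample.
#' @return An object of class `experiment_set` with elements `reference`,
#'   `control`, `tests` (named list) and `metadata`.
#' @export
build_experiment <- function(records, curated = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  ref_ids <- unique(records$condition_id[records$role == "reference"])
  ctl_ids <- unique(records$condition_id[records$role == "control"])
  if (length(ref_ids) != 1)
    stop("experiment must contain exactly one reference condition (found ",
         length(ref_ids), ")")
  if (length(ctl_ids) != 1)
    stop("experiment must contain exactly one control condition (found ",
         length(ctl_ids), ")")

  mk <- function(id) {
    rows <- records[records$condition_id == id, , drop = FALSE]
    if (nrow(rows) == 0) stop("empty condition: ", id)
    condition_sample(rows$mass_pg, id, rows$role[1], curated = curated)
  }
  test_ids <- setdiff(unique(records$condition_id), c(ref_ids, ctl_ids))
  tests <- lapply(test_ids, mk)
  names(tests) <- test_ids

  t_of <- function(id) median(records$t_meas_s[records$condition_id == id])
  t_all <- vapply(unique(records$condition_id), t_of, numeric(1))
  if (t_of(ref_ids) > min(t_all) || t_of(ctl_ids) < max(t_all))
    warning("measurement times violate the reference-first / control-last design")

  structure(list(reference = mk(ref_ids),
                 control = mk(ctl_ids),
                 tests = tests,
                 metadata = list(
                   instrument_id = unique(stats::na.omit(records$instrument_id)),
                   t_range_s = range(records$t_meas_s))),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("<experiment_set> reference '%s' (n=%d), control '%s' (n=%d), %d test condition(s)\n",
              x$reference$condition_id, x$reference$n,
              x$control$condition_id, x$control$n, length(x$tests)))
  invisible(x)
}

#' Inference configuration
#'
#' Parameters of the mass-response test. Defaults follow the method's
#' standard operating values: a 3% limit of decision (three sigma of the
#' 500-cell resampling distance), 2500 cells per distribution, 5000 bootstrap
#' replicates for confidence intervals, 999 outer test replicates with 19
#' inner replicates for the standard error, a 90% confidence level, and a
#' 10% control-drift limit beyond which a run is inconclusive.
#'
#' @param theta0 limit of decision, as a fraction (default 0.03).
#' @param alpha significance level (default 0.05).
#' @param N cells per distribution used for inference; larger samples are
#'   subsampled to `N` without replacement (default 2500).
#' @param R_ci bootstrap replicates for confidence intervals (default 5000).
#' @param R_test outer replicates of the bootstrap-t test (default 999).
#' @param r_inner inner replicates used to estimate each standard error
#'   (default 19).
#' @param ci_level confidence level, a fraction (default 0.90; 0.95 is the
#'   common alternative).
#' @param drift_limit control-drift fraction above which every call is
#'   inconclusive (default 0.10).
#' @param min_n smallest sample size not flagged as low-n (default 100).
#' @param seed integer master seed; `NULL` leaves the RNG stream untouched.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(theta0 = 0.03, alpha = 0.05, N = 2500,
                             R_ci = 5000, R_test = 999, r_inner = 19,
                             ci_level = 0.90, drift_limit = 0.10,
                             min_n = 100, seed = NULL) {
  cfg <- list(theta0 = theta0, alpha = alpha, N = as.integer(N),
              R_ci = as.integer(R_ci), R_test = as.integer(R_test),
              r_inner = as.integer(r_inner), ci_level = ci_level,
              drift_limit = drift_limit, min_n = as.integer(min_n),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$theta0 > 0, cfg$theta0 < 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$R_test >= 1, cfg$r_inner >= 2,
            cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$drift_limit > 0, cfg$N >= 1)
  structure(cfg, class = "inference_config")
}

#' Read an inference configuration from JSON
#'
#' Unknown fields are ignored with a warning; missing fields take defaults.
#'
#' @param path JSON file with fields of [inference_config()].
#' @return An `inference_config` object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(inference_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    warning("ignoring unknown config fields: ", paste(extra, collapse = ", "))
  do.call(inference_config, raw[intersect(names(raw), known)])
}

#' Write test results as a machine-readable report
#'
#' Emits a JSON report (one record per condition with signal, confidence
#' interval, p-value, call, sample sizes and a config echo) and a flat CSV
#' twin next to it.
#'
#' @param results a list of `test_result` objects (see [bootstrap_t_test()]).
#' @param path output path prefix; `<path>.json` and `<path>.csv` are
#'   written.
#' @param config the `inference_config` used, echoed in the report.
#' @return Invisibly, a character vector with the two file paths.
#' @export
write_report <- function(results, path, config = NULL) {
  if (inherits(results, "test_result")) results <- list(results)
  if (length(results) == 0) stop("no results to report")
  tab <- do.call(rbind, lapply(results, as.data.frame))
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  payload <- list(results = tab,
                  config = if (is.null(config)) NULL else unclass(config),
                  package_version = as.character(utils::packageVersion("massresponse")))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  write.csv(tab, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

#' Re-read a report written by [write_report()]
#'
#' @param path the path prefix or the `.json` file itself.
#' @return A `data.frame` of per-condition results, with the config echo in
#'   attribute `config`.
#' @export
read_report <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- payload$results
  attr(out, "config") <- payload$config
  out
}
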