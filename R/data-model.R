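# Domain types and CSV I/O. All tables are plain CSV, one dialect:
# comma-separated, "." decimal, header row, empty cell or "NA" for missing.

#' Serial-dilution design
#'
#' Describes the tenfold dilution series used in the two-step MPN assay:
#' `soil_mass_g_wet` grams of wet sample suspended in `diluent_ml` mL of
#' water form the primary suspension; `inoculum_ml` of each tenfold dilution
#' is inoculated into `tubes_per_level` replicate tubes per level. Dilution
#' level `n` corresponds to a `dilution_base^-n` dilution of the primary
#' suspension, so with the defaults (3 g in 27 mL, 1 mL inoculum) a level-`n`
#' tube receives `10^-(n+1)` g wet sample.
#'
#' @param soil_mass_g_wet Grams of wet sample in the primary suspension.
#' @param diluent_ml Millilitres of diluent added to it.
#' @param inoculum_ml Millilitres of dilution transferred per tube.
#' @param tubes_per_level Replicate tubes at each dilution level.
#' @param level_exponents Strictly increasing integer dilution exponents.
#' @param dilution_base Dilution factor between consecutive levels.
#' @return An object of class `dilution_design`.
#' @examples
#' dilution_design()
#' @export
dilution_design <- function(soil_mass_g_wet = 3, diluent_ml = 27,
                            inoculum_ml = 1, tubes_per_level = 3,
                            level_exponents = 2:10, dilution_base = 10) {
  stopifnot(soil_mass_g_wet > 0, diluent_ml > 0, inoculum_ml > 0,
            tubes_per_level >= 1, dilution_base > 1)
  level_exponents <- as.integer(level_exponents)
  if (length(level_exponents) < 1 || any(diff(level_exponents) <= 0))
    stop("level_exponents must be strictly increasing", call. = FALSE)
  structure(list(soil_mass_g_wet = soil_mass_g_wet, diluent_ml = diluent_ml,
                 inoculum_ml = inoculum_ml,
                 tubes_per_level = as.integer(tubes_per_level),
                 level_exponents = level_exponents,
                 dilution_base = dilution_base),
            class = "dilution_design")
}

#' @export
print.dilution_design <- function(x, ...) {
  cat(sprintf("Dilution design: %g g wet in %g mL, %g mL inoculum, %d tubes/level, base %g, levels %s\n",
              x$soil_mass_g_wet, x$diluent_ml, x$inoculum_ml,
              x$tubes_per_level, x$dilution_base,
              paste(range(x$level_exponents), collapse = "..")))
  invisible(x)
}

#' Sample metadata
#'
#' Physicochemical description of one environmental sample. Soil-like samples
#' (forest soil, volcanic ash, scoria) carry the wet mass used in the rate
#' assay and a water content so results can be expressed per gram dry weight;
#' water samples carry the assay volume and are expressed per mL.
#'
#' @param sample_id Sample identifier.
#' @param sample_type One of `"forest_soil"`, `"volcanic_ash"`, `"scoria"`,
#'   `"pond_water"`, `"other"`.
#' @param water_content Fraction of wet weight that is water, in `[0, 1)`.
#'   Required for soil-like samples.
#' @param pH Sample pH.
#' @param toc Total organic carbon, percent of dry weight.
#' @param mass_used_g_wet Wet grams used in the rate-constant assay
#'   (soil-like samples only).
#' @param volume_ml Millilitres used in the rate-constant assay (water
#'   samples only).
#' @return An object of class `sample_metadata`.
#' @examples
#' sample_metadata("KS-13", "forest_soil", water_content = 0.297,
#'                 pH = 5.28, toc = 4.8, mass_used_g_wet = 4)
#' @export
sample_metadata <- function(sample_id, sample_type, water_content = NA_real_,
                            pH = NA_real_, toc = NA_real_,
                            mass_used_g_wet = NULL, volume_ml = NULL) {
  sample_type <- match.arg(sample_type, c("forest_soil", "volcanic_ash",
                                          "scoria", "pond_water", "other"))
  is_water <- sample_type == "pond_water"
  if (is_water) {
    if (!is.null(mass_used_g_wet))
      stop("water samples take volume_ml, not mass_used_g_wet", call. = FALSE)
    if (!is.null(volume_ml) && volume_ml <= 0)
      stop("volume_ml must be positive", call. = FALSE)
  } else {
    if (!is.null(volume_ml))
      stop("soil-like samples take mass_used_g_wet, not volume_ml", call. = FALSE)
    if (!is.null(mass_used_g_wet) && mass_used_g_wet <= 0)
      stop("mass_used_g_wet must be positive", call. = FALSE)
    if (!is.na(water_content) && (water_content < 0 || water_content >= 1))
      stop("water_content must be in [0, 1)", call. = FALSE)
  }
  if (!is.na(pH) && (pH <= 0 || pH >= 14))
    stop("pH must be in (0, 14)", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 sample_type = sample_type,
                 water_content = water_content, pH = pH, toc = toc,
                 mass_used_g_wet = mass_used_g_wet, volume_ml = volume_ml),
            class = "sample_metadata")
}

#' Run configuration for the two-step assay
#'
#' Collects the assay constants: the degradation-ratio threshold that calls a
#' culture COS-positive, the initial COS concentration, assay duration, the
#' gas chromatograph detection limit (ppmv) below which residual COS is
#' censored, the measurement days of the first step, the dilution design, and
#' the two chemical-hydrolysis anchor points used to calibrate the abiotic
#' baseline.
#'
#' @param positivity_threshold_pct Degradation ratio (percent) at or above
#'   which a culture is called COS-positive. Comparison is inclusive.
#' @param cos_initial_ppmv Initial COS concentration in the sealed tube.
#' @param assay_duration_h Duration of the degradation assay in hours.
#' @param detection_limit_ppmv GC detection limit for COS.
#' @param measurement_days Days of the first-step incubation on which
#'   degradation is assayed.
#' @param design A [dilution_design()].
#' @param hydrolysis_anchors Data frame with columns `pH` and `fraction`:
#'   observed chemical-only 24-h degradation fractions at two pH values.
#' @return An object of class `run_config`.
#' @examples
#' run_config()
#' @export
run_config <- function(positivity_threshold_pct = 40, cos_initial_ppmv = 30,
                       assay_duration_h = 24, detection_limit_ppmv = 1.97,
                       measurement_days = c(4, 11, 18, 40),
                       design = dilution_design(),
                       hydrolysis_anchors = data.frame(
                         pH = c(7.0, 7.5), fraction = c(0.26, 0.32))) {
  if (positivity_threshold_pct <= 0 || positivity_threshold_pct > 100)
    stop("positivity_threshold_pct must be in (0, 100]", call. = FALSE)
  if (assay_duration_h <= 0) stop("assay_duration_h must be > 0", call. = FALSE)
  stopifnot(inherits(design, "dilution_design"))
  structure(list(positivity_threshold_pct = positivity_threshold_pct,
                 cos_initial_ppmv = cos_initial_ppmv,
                 assay_duration_h = assay_duration_h,
                 detection_limit_ppmv = detection_limit_ppmv,
                 measurement_days = measurement_days,
                 design = design,
                 hydrolysis_anchors = hydrolysis_anchors),
            class = "run_config")
}

tube_table_cols <- c("sample_id", "level_exponent", "replicate", "day",
                     "turbid", "degradation_ratio_pct", "residual_ppmv",
                     "initial_ppmv")

#' Read a tube observation table
#'
#' Reads a `tubes.csv` file: one row per tube and measurement day with
#' columns `sample_id,level_exponent,replicate,day,turbid,
#' degradation_ratio_pct,residual_ppmv,initial_ppmv` (an optional
#' `below_detection` column, as written by the simulator, is preserved).
#' Empty cells and `NA` denote missing measurements — the published tables'
#' em-dash — and are kept distinct from zero. Degradation ratios above 100%
#' up to 120% are retained with a warning (measurement overshoot); values
#' outside `[0, 120]` are rejected.
#'
#' @param path Path to the CSV file.
#' @param design A [dilution_design()] used to validate level exponents and
#'   replicate indices; `NULL` skips design validation.
#' @return A data frame of tube observations (class `tube_table`), with an
#'   attribute `overshoot_rows` listing rows whose ratio exceeded 100.
#' @examples
#' tab <- read_tube_table(cosmpn_example("tubes_ks13.csv"), dilution_design())
#' nrow(tab)  # 108 tube x day records
#' @export
read_tube_table <- function(path, design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  miss <- setdiff(tube_table_cols, names(x))
  if (length(miss))
    stop("tube table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("level_exponent", "replicate", "day", "turbid",
                "degradation_ratio_pct", "residual_ppmv", "initial_ppmv")) {
    v <- x[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop(sprintf("malformed value in column '%s' at data row %d: '%s'",
                     col, bad[1], v[bad[1]]), call. = FALSE)
      x[[col]] <- vn
    }
  }
  if (nrow(x) == 0) {
    class(x) <- c("tube_table", class(x))
    return(x)
  }
  r <- x$degradation_ratio_pct
  out_of_range <- which(!is.na(r) & (r < 0 | r > 120))
  if (length(out_of_range))
    stop(sprintf("degradation ratio outside [0, 120] at data row %d: %g",
                 out_of_range[1], r[out_of_range[1]]), call. = FALSE)
  overshoot <- which(!is.na(r) & r > 100)
  if (length(overshoot))
    warning(length(overshoot),
            " degradation ratio(s) above 100% retained as measurement overshoot",
            call. = FALSE)
  if (any(!is.na(x$residual_ppmv))) {
    i <- which(!is.na(x$residual_ppmv))
    if (any(is.na(x$initial_ppmv[i])))
      stop("residual_ppmv present without initial_ppmv", call. = FALSE)
    if (any(x$residual_ppmv[i] > x$initial_ppmv[i] * 1.2))
      stop("residual_ppmv exceeds initial_ppmv beyond tolerance", call. = FALSE)
  }
  if (!is.null(design)) {
    stopifnot(inherits(design, "dilution_design"))
    bad_lvl <- which(!x$level_exponent %in% design$level_exponents)
    if (length(bad_lvl))
      stop(sprintf("unknown level exponent %g at data row %d",
                   x$level_exponent[bad_lvl[1]], bad_lvl[1]), call. = FALSE)
    bad_rep <- which(x$replicate < 1 | x$replicate > design$tubes_per_level)
    if (length(bad_rep))
      stop(sprintf("replicate index out of range at data row %d", bad_rep[1]),
           call. = FALSE)
  }
  attr(x, "overshoot_rows") <- overshoot
  class(x) <- c("tube_table", class(x))
  x
}

# Full-precision numeric formatting so that write -> read round-trips doubles
# exactly. %.17g is the shortest guaranteed-lossless decimal form.
fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) NA_character_ else sprintf("%.17g", z)
  }, character(1))
  out
}

#' Write MPN estimates to CSV
#'
#' Serializes estimates produced by [estimate_sample()] (or a data frame from
#' [estimates_table()]) to `estimates.csv` with columns
#' `sample_id,target,pattern,levels,lambda,mpn_per_g_dry,ci_low,ci_high,status`.
#' Numeric fields are written at full double precision so a read-back
#' reproduces them exactly; estimates without a finite upper bound carry the
#' `above_range` sentinel in the status column.
#'
#' @param estimates A list of `mpn_estimate` objects, or the data frame
#'   returned by [estimates_table()]. An empty list writes a header-only file.
#' @param path Output path.
#' @return The path, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(estimates, path) {
  df <- if (is.data.frame(estimates)) estimates else estimates_table(estimates)
  out <- df
  for (col in c("lambda", "mpn_per_g_dry", "ci_low", "ci_high"))
    out[[col]] <- fmt_num(df[[col]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to ", path, call. = FALSE)
  invisible(path)
}

#' Read back an estimates CSV written by [write_results()]
#' @param path Path to the CSV file.
#' @return A data frame with one row per estimate.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"),
                       colClasses = c(sample_id = "character"))
  for (col in c("lambda", "mpn_per_g_dry", "ci_low", "ci_high"))
    x[[col]] <- as.numeric(x[[col]])
  x
}

#' Flatten a list of MPN estimates into a data frame
#' @param estimates List of `mpn_estimate` objects.
#' @return A data frame with columns `sample_id,target,pattern,levels,lambda,
#'   mpn_per_g_dry,ci_low,ci_high,status`.
#' @export
estimates_table <- function(estimates) {
  if (inherits(estimates, "mpn_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0) {
    return(data.frame(sample_id = character(), target = character(),
                      pattern = character(), levels = character(),
                      lambda = numeric(), mpn_per_g_dry = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(sample_id = e$sample_id, target = e$target,
               pattern = paste(e$pattern, collapse = "-"),
               levels = paste(e$selected_levels, collapse = "-"),
               lambda = e$lambda_per_ref_tube,
               mpn_per_g_dry = e$mpn_per_g_dry,
               ci_low = e$ci_low, ci_high = e$ci_high,
               status = e$status, stringsAsFactors = FALSE)
  }))
}

#' Read a sample metadata table
#'
#' Reads `samples.csv` with columns
#' `sample_id,sample_type,water_content_pct_wet,pH,toc_pct,rate_constant`
#' (water content as percent of wet weight, as customarily tabulated) and an
#' optional `mass_used_g_wet` / `volume_ml` pair; the assay defaults of 4 g
#' wet for soil-like samples and 10 mL for water samples are filled in when
#' absent.
#'
#' @param path Path to the CSV file.
#' @return A named list of [sample_metadata()] objects, with the per-sample
#'   `rate_constant` attached as attribute `rate_constants` (a named vector).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  need <- c("sample_id", "sample_type", "water_content_pct_wet", "pH",
            "toc_pct", "rate_constant")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    water <- identical(row$sample_type, "pond_water")
    mass <- if (!water) {
      if (!is.null(x$mass_used_g_wet) && !is.na(row$mass_used_g_wet))
        row$mass_used_g_wet else 4
    } else NULL
    vol <- if (water) {
      if (!is.null(x$volume_ml) && !is.na(row$volume_ml))
        row$volume_ml else 10
    } else NULL
    sample_metadata(row$sample_id, row$sample_type,
                    water_content = if (is.na(row$water_content_pct_wet))
                      NA_real_ else row$water_content_pct_wet / 100,
                    pH = row$pH, toc = row$toc_pct,
                    mass_used_g_wet = mass, volume_ml = vol)
  })
  names(out) <- x$sample_id
  attr(out, "rate_constants") <- stats::setNames(x$rate_constant, x$sample_id)
  out
}

#' Read COS concentration time courses
#'
#' Reads `timecourse.csv` with columns
#' `series_id,time_h,cos_ppmv,below_detection` and returns one
#' `cos_timecourse` per series.
#'
#' @param path Path to the CSV file.
#' @return A named list of [cos_timecourse()] objects.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  need <- c("series_id", "time_h", "cos_ppmv", "below_detection")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("time course table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  split_x <- split(x, x$series_id)
  out <- lapply(split_x, function(s) {
    s <- s[order(s$time_h), ]
    cos_timecourse(s$time_h, s$cos_ppmv, as.logical(s$below_detection))
  })
  out[unique(x$series_id)]
}

#' COS concentration time course
#'
#' Headspace COS concentrations measured over time in one sealed tube, with a
#' per-point censoring flag for readings at or below the GC detection limit.
#'
#' @param times_h Strictly increasing, non-negative measurement times (h).
#' @param concentrations_ppmv COS concentrations (ppmv), same length.
#' @param below_detection Logical flags marking censored points.
#' @return An object of class `cos_timecourse`.
#' @examples
#' cos_timecourse(c(0, 4, 8, 24), 30 * exp(-0.1 * c(0, 4, 8, 24)))
#' @export
cos_timecourse <- function(times_h, concentrations_ppmv,
                           below_detection = rep(FALSE, length(times_h))) {
  stopifnot(length(times_h) == length(concentrations_ppmv),
            length(times_h) == length(below_detection))
  if (any(times_h < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(times_h) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(concentrations_ppmv < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(times_h = as.numeric(times_h),
                 concentrations_ppmv = as.numeric(concentrations_ppmv),
                 below_detection = as.logical(below_detection)),
            class = "cos_timecourse")
}

#' Read a flat key/value run configuration file
#'
#' Parses a plain-text configuration of `key = value` lines (`#` comments and
#' blank lines ignored). Keys match the [run_config()] and [dilution_design()]
#' field names; list-valued keys (`measurement_days`, `level_exponents`,
#' densities for the simulator) take comma-separated values.
#'
#' @param path Path to the configuration file.
#' @return A named list of parsed values (numeric where possible).
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (any(is.na(num))) parts else num
  }
  out
}

#' Build a [run_config()] from a parsed configuration list
#' @param cfg Named list as returned by [read_config_file()].
#' @return A [run_config()].
#' @export
config_to_run_config <- function(cfg) {
  design_args <- cfg[intersect(names(cfg),
                               c("soil_mass_g_wet", "diluent_ml", "inoculum_ml",
                                 "tubes_per_level", "level_exponents",
                                 "dilution_base"))]
  design <- do.call(dilution_design, design_args)
  rc_args <- cfg[intersect(names(cfg),
                           c("positivity_threshold_pct", "cos_initial_ppmv",
                             "assay_duration_h", "detection_limit_ppmv",
                             "measurement_days"))]
  rc_args$design <- design
  if (!is.null(cfg$hydrolysis_anchor_ph) && !is.null(cfg$hydrolysis_anchor_fraction))
    rc_args$hydrolysis_anchors <- data.frame(pH = cfg$hydrolysis_anchor_ph,
                                             fraction = cfg$hydrolysis_anchor_fraction)
  do.call(run_config, rc_args)
}
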