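# End-to-end orchestration: recordings -> individuals, sightings ->
# aggregations with habitat attributes, and the four analysis blocks.

period_of_month <- function(month) {
  ifelse(month %in% 1:3, 1L, ifelse(month %in% 4:5, 2L, NA_integer_))
}

#' Process one recording into individual estimates and behaviours
#'
#' High-pass filter, click detection, train segmentation and classification,
#' per-click envelope IPI measurement, IPI-space clustering into putative
#' individuals and per-individual summaries. Hunting/socialising come from
#' the acoustic ethogram; moving/resting only from the visual notes.
#'
#' @param audio An [audio_segment()] (or a WAV path).
#' @param visual_notes Character visual behaviour notes for the aggregation.
#' @param calf_confirmed Visual calf confirmation, admitting sub-floor IPIs.
#' @param cutoff_hz High-pass cutoff.
#' @param ipi_tol_ms Individual-discrimination linkage tolerance (ms).
#' @param detect_args List of extra arguments to [detect_clicks()].
#' @return List: `individuals` (data frame of accepted estimates),
#'   `trains`, `behaviours`, `clicks` (detections with per-click IPI),
#'   `n_rejected`.
#' @export
analyze_recording <- function(audio, visual_notes = character(0),
                              calf_confirmed = FALSE, cutoff_hz = 1000,
                              ipi_tol_ms = 0.15, detect_args = list()) {
  if (is.character(audio)) audio <- read_wav(audio)
  hp <- highpass(audio, cutoff_hz)
  det <- do.call(detect_clicks, c(list(hp), detect_args))
  trains <- segment_trains(det)
  beh <- infer_behaviours(trains, visual_notes)
  ipi <- rep(NA_real_, nrow(det))
  for (i in seq_len(nrow(det))) {
    m <- estimate_ipi_envelope(hp, det$time_s[i])
    ipi[i] <- m$ipi_ms
  }
  det$ipi_ms <- ipi
  groups <- cluster_individuals(ipi, tol_ms = ipi_tol_ms)
  est <- lapply(groups, function(idx)
    summarize_individual(ipi[idx], calf_confirmed = calf_confirmed))
  accepted <- vapply(est, function(e) e$accepted, logical(1))
  individuals <- do.call(rbind, lapply(est[accepted], function(e) data.frame(
    ipi_mean_ms = e$ipi_mean_ms, ipi_sd_ms = e$ipi_sd_ms,
    n_measurements = e$n_measurements, length_m = e$length_m,
    class_label = e$class_label, calf_confirmed = e$calf_confirmed,
    flags = paste(e$flags, collapse = ";"), stringsAsFactors = FALSE
  )))
  if (is.null(individuals)) individuals <- data.frame()
  list(individuals = individuals, trains = trains, behaviours = beh,
       clicks = det, n_rejected = sum(!accepted))
}

#' Social-structure analysis block
#'
#' Composition profile by aggregation size (mean and SD of member lengths,
#' averaged within each aggregation-size category), Poisson GLM of
#' aggregation size on immature presence with overdispersion and Type-II
#' deviance checks, and the pooled t-test of the non-immature mean length
#' (member lengths below 9 m removed before averaging) against immature
#' presence.
#'
#' @param individuals Data frame with `aggregation_id`, `length_m`.
#' @param aggregations Data frame with `aggregation_id`, `size`,
#'   `has_immature`.
#' @return List: `profile`, `size_glm`, `size_overdispersion`,
#'   `size_effect`, `nonimmature_length_test`, `notes`.
#' @export
social_structure_analysis <- function(individuals, aggregations) {
  notes <- character(0)
  per_agg <- do.call(rbind, lapply(split(individuals, individuals$aggregation_id),
    function(d) data.frame(
      aggregation_id = d$aggregation_id[1], n = nrow(d),
      mean_length_m = mean(d$length_m), sd_length_m = stats::sd(d$length_m),
      nonimm_mean_length_m = if (any(d$length_m >= 9)) mean(d$length_m[d$length_m >= 9])
                             else NA_real_,
      stringsAsFactors = FALSE)))
  profile <- do.call(rbind, lapply(split(per_agg, per_agg$n), function(d)
    data.frame(aggregation_size = d$n[1], n_aggregations = nrow(d),
               mean_of_mean_length_m = mean(d$mean_length_m),
               mean_of_sd_length_m = mean(d$sd_length_m, na.rm = TRUE))))
  rownames(profile) <- NULL
  out <- list(profile = profile)
  agg <- merge(aggregations, per_agg, by = "aggregation_id", all.x = TRUE)
  if (length(unique(agg$has_immature)) < 2 || any(table(agg$has_immature) < 2)) {
    notes <- c(notes, "immature presence contrast skipped: fewer than 2 aggregations per level")
  } else {
    fit <- poisson_glm(agg$size, factor(agg$has_immature))
    out$size_glm <- fit
    out$size_overdispersion <- overdispersion_check(fit)
    out$size_effect <- type2_deviance_test(fit)
    ok <- !is.na(agg$nonimm_mean_length_m)
    if (sum(ok) >= 4 && length(unique(agg$has_immature[ok])) == 2 &&
        all(table(agg$has_immature[ok]) >= 2)) {
      out$nonimmature_length_test <-
        two_sample_lm(agg$nonimm_mean_length_m[ok], factor(agg$has_immature[ok]))
    } else {
      notes <- c(notes, "non-immature length contrast skipped: insufficient aggregations")
    }
  }
  out$notes <- notes
  out
}

#' Spatial-distribution analysis block
#'
#' The topography battery: Pearson correlation of bathymetry with distance
#' to coast, correlations of aggregation size and mean individual length
#' with bathymetry and slope, permutation linear models of bathymetry and
#' slope across sperm whale classes, and t-tests of bathymetry and slope on
#' immature presence. Undefined slopes are dropped from the slope analyses
#' only.
#'
#' @param aggregations Data frame with `size`, `mean_length_m`,
#'   `has_immature`, `depth_m`, `dist_coast_m`, `slope_pct`.
#' @param individuals Optional data frame with `aggregation_id`,
#'   `class_label` (enables the class contrasts).
#' @param B,seed Permutation settings.
#' @return Named list of `stat_result`s (entries skipped where data do not
#'   permit them, with a note).
#' @export
spatial_distribution_analysis <- function(aggregations, individuals = NULL,
                                          B = 1000, seed = 1) {
  out <- list(notes = character(0))
  a <- aggregations
  try_add <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e$message)
    if (is.character(res)) {
      out$notes <<- c(out$notes, paste0(name, " skipped: ", res))
    } else {
      out[[name]] <<- res
    }
  }
  try_add("bathy_coast_cor", pearson_cor(a$depth_m, a$dist_coast_m))
  try_add("size_bathy_cor", pearson_cor(a$size, a$depth_m))
  try_add("meanlength_bathy_cor", pearson_cor(a$mean_length_m, a$depth_m))
  sl_ok <- is.finite(a$slope_pct)
  try_add("size_slope_cor", pearson_cor(a$size[sl_ok], a$slope_pct[sl_ok]))
  try_add("meanlength_slope_cor", pearson_cor(a$mean_length_m[sl_ok], a$slope_pct[sl_ok]))
  if (length(unique(a$has_immature)) == 2) {
    try_add("immature_bathy_test", two_sample_lm(a$depth_m, factor(a$has_immature)))
    try_add("immature_slope_test",
            two_sample_lm(a$slope_pct[sl_ok], factor(a$has_immature[sl_ok])))
  }
  if (!is.null(individuals) && "class_label" %in% names(individuals)) {
    ind <- merge(individuals, a[, c("aggregation_id", "depth_m", "slope_pct")],
                 by = "aggregation_id")
    if (length(unique(ind$class_label)) >= 2) {
      try_add("class_bathy_perm",
              lm_permutation_test(ind$depth_m, factor(ind$class_label), B, seed))
      cs <- is.finite(ind$slope_pct)
      try_add("class_slope_perm",
              lm_permutation_test(ind$slope_pct[cs], factor(ind$class_label[cs]),
                                  B, seed + 1L))
    }
  }
  out
}

#' Habitat-use analysis block
#'
#' Behaviour-versus-bathymetry linear model with Holm-corrected pairwise
#' contrasts and a Shapiro-Wilk residual check, and a behaviour-versus-slope
#' permutation linear model. Behaviours with fewer than two records are
#' dropped with a warning; undefined slopes are dropped from the slope test
#' only.
#'
#' @param records Data frame with one row per behaviour occurrence:
#'   `behaviour`, `depth_m`, `slope_pct`.
#' @param B,seed Permutation settings.
#' @return List: `bathy_lm` (overall F `stat_result`), `bathy_normality`,
#'   `bathy_pairwise` (a `pairwise_matrix`), `slope_perm`, `notes`.
#' @export
habitat_use_analysis <- function(records, B = 1000, seed = 1) {
  beh <- factor(records$behaviour)
  tab <- table(beh)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    warning("dropping behaviour(s) with n < 2: ", paste(drop, collapse = ", "),
            call. = FALSE)
    records <- records[!records$behaviour %in% drop, , drop = FALSE]
    beh <- droplevels(factor(records$behaviour))
  }
  if (nlevels(beh) < 2) {
    stop("habitat-use analysis needs at least two behaviours with n >= 2",
         call. = FALSE)
  }
  notes <- character(0)
  fit <- stats::lm(depth_m ~ behaviour, data = records)
  fs <- summary(fit)$fstatistic
  bathy_lm <- stat_result("behaviour_bathymetry_lm", statistic = unname(fs[1]),
                          df = unname(fs[2:3]),
                          p_value = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  bathy_normality <- normality_check(stats::residuals(fit))
  bathy_pairwise <- pairwise_behaviour_test(records$depth_m, beh)
  sl_ok <- is.finite(records$slope_pct)
  slope_perm <- NULL
  if (sum(sl_ok) >= 5 && nlevels(droplevels(beh[sl_ok])) >= 2) {
    slope_perm <- lm_permutation_test(records$slope_pct[sl_ok],
                                      droplevels(beh[sl_ok]), B, seed)
  } else {
    notes <- c(notes, "slope permutation test skipped: insufficient defined slopes")
  }
  list(bathy_lm = bathy_lm, bathy_normality = bathy_normality,
       bathy_pairwise = bathy_pairwise, slope_perm = slope_perm, notes = notes)
}

#' Temporal-variation analysis block
#'
#' Individual length against the two-period calendar split (January-March
#' versus April-May, the dry season and the male-departure season), a
#' Poisson GLM of aggregation size over months with overdispersion and
#' Type-II checks, and permutation linear models of bathymetry and slope
#' over months.
#'
#' @param individuals Data frame with `length_m`, `period`.
#' @param aggregations Data frame with `size`, `month`, `depth_m`,
#'   `slope_pct`.
#' @param B,seed Permutation settings.
#' @return Named list of results plus `notes` for skipped contrasts.
#' @export
temporal_analysis <- function(individuals, aggregations, B = 1000, seed = 1) {
  out <- list(notes = character(0))
  pr <- factor(individuals$period)
  if (nlevels(droplevels(pr)) == 2 && all(table(droplevels(pr)) >= 2)) {
    out$length_period_test <- two_sample_lm(individuals$length_m, pr)
  } else {
    out$notes <- c(out$notes, "period contrast skipped: records span a single period")
  }
  mo <- factor(aggregations$month)
  if (nlevels(droplevels(mo)) >= 2) {
    fit <- poisson_glm(aggregations$size, droplevels(mo))
    out$size_month_glm <- fit
    out$size_month_overdispersion <- tryCatch(overdispersion_check(fit),
      error = function(e) {
        out$notes <<- c(out$notes, paste("overdispersion check skipped:", e$message))
        NULL
      })
    out$size_month_effect <- type2_deviance_test(fit)
    if ("depth_m" %in% names(aggregations) && all(is.finite(aggregations$depth_m))) {
      out$bathy_month_perm <- lm_permutation_test(aggregations$depth_m,
                                                  droplevels(mo), B, seed)
      sl_ok <- is.finite(aggregations$slope_pct)
      if (sum(sl_ok) >= 5 && nlevels(droplevels(mo[sl_ok])) >= 2) {
        out$slope_month_perm <- lm_permutation_test(
          aggregations$slope_pct[sl_ok], droplevels(mo[sl_ok]), B, seed + 1L)
      }
    }
  } else {
    out$notes <- c(out$notes, "month contrasts skipped: single month")
  }
  out
}

summary_quantiles <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(n = length(x), mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
             min = min(x), max = max(x))
}

#' Run the full acoustic-to-habitat analysis
#'
#' Orchestrates the whole chain on either a synthetic scene or user-supplied
#' files: click detection and IPI sizing per recording, the 1 km aggregation
#' rule on the sightings, habitat attribute extraction, and the four
#' statistical blocks (social structure, spatial distribution, habitat use,
#' temporal variation). Fully reproducible for a fixed config: every seed is
#' derived from `config$seed` and recorded in the report provenance.
#'
#' @param config A list. Either `simulate = list(...)` (arguments passed to
#'   [synth_survey()]; `n_aggregations` at minimum) or `inputs = list(
#'   sightings = , audio_manifest = , bathymetry = , coastline = )` with
#'   file paths (sightings/manifest CSV, ESRI ASCII grid, GeoJSON
#'   polyline). Optional: `seed` (default 1), `out_dir`, `B` (permutations,
#'   default 1000), `ipi_tol_ms`, `cutoff_hz`.
#' @return An `analysis_report` list: `summary_stats`, `individuals`,
#'   `aggregations`, `records`, the four analysis blocks, `notes`,
#'   `provenance`. Tables are also written as CSVs under `out_dir`.
#' @export
run_full_analysis <- function(config) {
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% file.path(tempdir(), "cachalot_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  B <- config$B %||% 1000L
  notes <- character(0)

  # --- inputs ----------------------------------------------------------------
  grid <- NULL; coastline <- NULL; scene <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim_args$out_dir <- sim_args$out_dir %||% file.path(out_dir, "scene")
    scene <- do.call(synth_survey, sim_args)
    grid <- scene$grid; coastline <- scene$coastline
    sightings <- scene$sightings
    manifest <- scene$audio_manifest
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    missing_in <- setdiff(c("sightings"), names(inp))
    if (length(missing_in)) {
      stop("missing inputs: ", paste(missing_in, collapse = ", "), call. = FALSE)
    }
    sightings <- utils::read.csv(inp$sightings, stringsAsFactors = FALSE)
    manifest <- if (!is.null(inp$audio_manifest))
      utils::read.csv(inp$audio_manifest, stringsAsFactors = FALSE) else data.frame()
    if (!is.null(inp$bathymetry)) grid <- read_esri_ascii(inp$bathymetry)
    if (!is.null(inp$coastline)) coastline <- read_coastline_geojson(inp$coastline)
  } else {
    stop("config must contain either `simulate` or `inputs`", call. = FALSE)
  }
  if (is.null(grid)) {
    notes <- c(notes, "no bathymetry supplied: habitat, spatial and temporal-topography blocks skipped")
  }
  if (!"date" %in% names(sightings) && "datetime" %in% names(sightings)) {
    sightings$date <- substr(sightings$datetime, 1, 10)
  }

  # --- aggregation clustering ------------------------------------------------
  no_gps <- !is.finite(sightings$lat) | !is.finite(sightings$lon)
  if (any(no_gps)) {
    notes <- c(notes, sprintf("%d sighting(s) without GPS excluded", sum(no_gps)))
    sightings <- sightings[!no_gps, , drop = FALSE]
  }
  clustered <- cluster_aggregations(sightings)
  agg_ids <- unique(clustered$aggregation_id)

  # --- per-recording acoustics ----------------------------------------------
  individuals <- list(); agg_rows <- list()
  for (aid in agg_ids) {
    rows <- clustered[clustered$aggregation_id == aid, , drop = FALSE]
    lat_c <- mean(rows$lat); lon_c <- mean(rows$lon)
    date <- rows$date[1]
    vnotes <- unique(c(rows$visual_behaviours, rows$notes))
    vnotes <- vnotes[nzchar(vnotes %||% "")]
    calf <- any(grepl("calf", tolower(paste(rows$notes, collapse = " "))))
    # recordings made at this aggregation: same date, within the 1 km rule
    rec <- if (nrow(manifest)) {
      m <- manifest[manifest$date == date & !is.na(manifest$wav), , drop = FALSE]
      if (nrow(m)) {
        d <- haversine(rep(lat_c, nrow(m)), rep(lon_c, nrow(m)), m$lat, m$lon)
        m[d <= 1000, , drop = FALSE]
      } else m
    } else data.frame()
    beh_ac <- character(0)
    ind <- data.frame()
    if (nrow(rec)) {
      res_list <- lapply(rec$wav, function(w)
        analyze_recording(w, visual_notes = vnotes, calf_confirmed = calf,
                          cutoff_hz = config$cutoff_hz %||% 1000,
                          ipi_tol_ms = config$ipi_tol_ms %||% 0.15))
      ind <- do.call(rbind, lapply(res_list, `[[`, "individuals"))
      beh_ac <- unique(unlist(lapply(res_list, function(r) r$behaviours$behaviours)))
    }
    beh_vis <- intersect(c("moving", "resting"),
                         tolower(trimws(unlist(strsplit(paste(vnotes, collapse = ";"), ";")))))
    behaviours <- sort(unique(c(setdiff(beh_ac, c("moving", "resting")), beh_vis)))
    if (nrow(ind)) {
      ind$aggregation_id <- aid
      individuals[[length(individuals) + 1L]] <- ind
    }
    hab <- if (!is.null(grid)) habitat_point(grid, coastline, lat_c, lon_c)
           else data.frame(depth_m = NA_real_, dist_coast_m = NA_real_,
                           slope_pct = NA_real_, slope_class = "undefined")
    month <- as.integer(substr(date, 6, 7))
    agg_rows[[length(agg_rows) + 1L]] <- cbind(
      data.frame(aggregation_id = aid, date = date, month = month,
                 period = period_of_month(month), lat = lat_c, lon = lon_c,
                 size = nrow(ind),
                 mean_length_m = if (nrow(ind)) mean(ind$length_m) else NA_real_,
                 has_immature = nrow(ind) > 0 && any(ind$class_label == "immature"),
                 behaviours = paste(behaviours, collapse = ";"),
                 stringsAsFactors = FALSE),
      hab)
  }
  individuals <- if (length(individuals)) do.call(rbind, individuals) else data.frame()
  aggregations <- do.call(rbind, agg_rows)
  rownames(aggregations) <- NULL
  if (nrow(individuals)) {
    individuals <- merge(individuals,
                         aggregations[, c("aggregation_id", "date", "month", "period")],
                         by = "aggregation_id")
  }

  # one record per (aggregation, behaviour) for the habitat-use block
  records <- do.call(rbind, lapply(seq_len(nrow(aggregations)), function(i) {
    b <- strsplit(aggregations$behaviours[i], ";")[[1]]
    b <- b[nzchar(b)]
    if (!length(b)) return(NULL)
    data.frame(aggregation_id = aggregations$aggregation_id[i], behaviour = b,
               depth_m = aggregations$depth_m[i],
               slope_pct = aggregations$slope_pct[i],
               month = aggregations$month[i], stringsAsFactors = FALSE)
  }))
  if (is.null(records)) records <- data.frame()

  # --- summary statistics ----------------------------------------------------
  summary_stats <- list()
  if (nrow(individuals)) {
    summary_stats$ipi_ms <- summary_quantiles(individuals$ipi_mean_ms)
    summary_stats$length_m <- summary_quantiles(individuals$length_m)
  }
  acoustic <- aggregations$size > 0
  if (any(acoustic)) {
    summary_stats$aggregation_size <- summary_quantiles(aggregations$size[acoustic])
  }

  # --- analysis blocks -------------------------------------------------------
  report <- list(summary_stats = summary_stats, individuals = individuals,
                 aggregations = aggregations, records = records)
  if (nrow(individuals) && sum(acoustic) >= 3) {
    report$social <- tryCatch(
      social_structure_analysis(individuals, aggregations[acoustic, ]),
      error = function(e) {notes <<- c(notes, paste("social block skipped:", e$message)); NULL})
  }
  if (!is.null(grid)) {
    report$spatial <- tryCatch(
      spatial_distribution_analysis(aggregations[acoustic, , drop = FALSE],
                                    individuals, B = B, seed = seed + 10L),
      error = function(e) {notes <<- c(notes, paste("spatial block skipped:", e$message)); NULL})
    report$habitat <- tryCatch(
      habitat_use_analysis(records, B = B, seed = seed + 20L),
      error = function(e) {notes <<- c(notes, paste("habitat block skipped:", e$message)); NULL})
  }
  report$temporal <- tryCatch(
    temporal_analysis(individuals, aggregations, B = B, seed = seed + 30L),
    error = function(e) {notes <<- c(notes, paste("temporal block skipped:", e$message)); NULL})
  report$notes <- notes
  report$provenance <- list(
    seed = seed, B = B, config = config,
    package_version = as.character(utils::packageVersion("cachalot")),
    r_version = R.version.string, timestamp_utc = NA
  )

  # --- outputs ---------------------------------------------------------------
  if (nrow(individuals)) {
    utils::write.csv(individuals, file.path(out_dir, "individuals.csv"), row.names = FALSE)
  }
  utils::write.csv(aggregations, file.path(out_dir, "aggregations.csv"), row.names = FALSE)
  if (nrow(records)) {
    utils::write.csv(records, file.path(out_dir, "behaviour_records.csv"), row.names = FALSE)
  }
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  aggregations: %d (acoustically characterised: %d)\n",
              nrow(x$aggregations), sum(x$aggregations$size > 0)))
  cat(sprintf("  individuals:  %d\n", nrow(x$individuals)))
  if (!is.null(x$summary_stats$ipi_ms)) {
    s <- x$summary_stats$ipi_ms
    cat(sprintf("  IPI (ms): median %.2f, Q1 %.2f, Q3 %.2f, mean %.2f\n",
                s$median, s$q1, s$q3, s$mean))
    s <- x$summary_stats$length_m
    cat(sprintf("  AS (m):   median %.1f, Q1 %.1f, Q3 %.1f, mean %.1f\n",
                s$median, s$q1, s$q3, s$mean))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
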