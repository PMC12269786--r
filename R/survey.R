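# Whole-survey scene generation with retained ground truth.

#' Composition rules for a synthetic survey
#'
#' Defaults encode the study conditions of a five-month small-boat survey on
#' a steep island margin: 19 aggregations totalling 74 acoustically
#' characterised individuals (27 adult males, 31 females/juvenile males,
#' 16 immatures), aggregation sizes 1-9 with median 4, one visually
#' confirmed calf at IPI 1.90 ms, positions between the 1,000 and 2,000 m
#' isobaths, hunting placed deeper than other behaviours, and clean
#' (noise-free) 96 kHz recordings of regular click trains (ICI 0.5-2 s) with
#' buzzes on hunting aggregations and codas on the two socialising ones.
#'
#' Within each aggregation, true IPIs are drawn inside per-class windows
#' kept 0.15 ms clear of the 2.9 / 5.0 ms class boundaries and separated by
#' at least `min_ipi_sep_ms`, so acoustic individual discrimination is
#' well-posed (the field protocol likewise relies on distinguishable IPIs).
#'
#' @param class_counts Named counts for `adult_male`,
#'   `female_or_juvenile_male`, `immature`.
#' @param sizes Aggregation sizes; must sum to `sum(class_counts)`. `NULL`
#'   uses the default 19-aggregation size distribution (or resamples it for
#'   other aggregation counts).
#' @param include_calf Include one visually confirmed calf at IPI 1.90 ms
#'   (below the 2 ms floor) among the immatures.
#' @param isobath_range_m Depth band containing all positions.
#' @param hunting_depth_m,other_depth_m Placement depth bands by behaviour.
#' @param n_socialising Number of aggregations with codas.
#' @param p_hunting Probability an aggregation is hunting (buzzes present).
#' @param ici_s Regular-train ICI range (s).
#' @param n_clicks Clicks per individual (>= the 10-measurement protocol).
#' @param snr_db Ambient SNR of the rendered audio; `Inf` = clean.
#' @param sample_rate Audio sample rate (Hz).
#' @param min_ipi_sep_ms Minimum true-IPI separation within an aggregation.
#' @return A `survey_composition` list.
#' @export
survey_composition <- function(class_counts = c(adult_male = 27,
                                                female_or_juvenile_male = 31,
                                                immature = 16),
                               sizes = NULL,
                               include_calf = TRUE,
                               isobath_range_m = c(1000, 2000),
                               hunting_depth_m = c(1500, 2000),
                               other_depth_m = c(1000, 1400),
                               n_socialising = 2,
                               p_hunting = 0.75,
                               ici_s = c(0.5, 2),
                               n_clicks = 12,
                               snr_db = Inf,
                               sample_rate = 96000,
                               min_ipi_sep_ms = 0.3) {
  structure(as.list(environment()), class = "survey_composition")
}

default_sizes_19 <- c(1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 5, 5, 5, 6, 7, 9)

# Per-class true-IPI windows, kept clear of the 2.9/5.0 ms boundaries so
# clean-audio recovery assigns every individual its true class.
class_ipi_windows <- function(sep) {
  list(immature = c(2.0 + sep / 2, 2.9 - sep / 2),
       female_or_juvenile_male = c(2.9 + sep / 2, 5.0 - sep / 2),
       adult_male = c(5.0 + sep / 2, 7.75))
}

# k uniform draws in [lo, hi] with pairwise gaps >= g (spacing transform).
spaced_uniform <- function(k, lo, hi, g) {
  if (k == 0L) return(numeric(0))
  slack <- hi - lo - (k - 1) * g
  if (slack < 0) stop("IPI window too narrow for ", k, " individuals", call. = FALSE)
  sort(stats::runif(k, 0, slack)) + lo + (seq_len(k) - 1) * g
}

# Spread class labels evenly through the individual sequence so consecutive
# chunks (aggregations) get a balanced class mixture.
interleave_classes <- function(class_counts) {
  ranks <- unlist(lapply(names(class_counts), function(cl) {
    k <- class_counts[[cl]]
    if (k == 0) return(NULL)
    stats::setNames((seq_len(k) - 0.5) / k, rep(cl, k))
  }))
  names(ranks)[order(ranks)]
}

#' Generate a complete synthetic survey scene
#'
#' Builds (or accepts) a bathymetry grid, places aggregations between the
#' configured isobaths with hunting aggregations deeper, assigns individuals
#' with known true IPIs/lengths/classes, renders one clean multipulse-click
#' WAV per aggregation (individual trains time-multiplexed, plus buzzes for
#' hunting and a coda for socialising aggregations), and writes sighting and
#' manifest CSVs. The full truth is retained so every downstream stage can
#' be scored.
#'
#' @param n_aggregations Number of aggregations (0 gives empty manifests).
#' @param composition_rules A [survey_composition()].
#' @param grid A [bathy_grid()], or `NULL` to synthesise a default
#'   shelf-slope margin large enough for the placements.
#' @param coastline Coastline polyline (data frame) or `NULL` (derived with
#'   the default grid).
#' @param seed Integer seed; the scene is a pure function of
#'   (rules, grid, seed).
#' @param out_dir Directory for WAVs and CSVs.
#' @param render_audio Set `FALSE` to skip WAV rendering (truth only).
#' @return A `scene_truth` list: `individuals`, `aggregations`, `clicks`
#'   (every rendered click mapped to its individual), `sightings`,
#'   `audio_manifest`, `grid`, `coastline`, `paths`.
#' @export
synth_survey <- function(n_aggregations = 19,
                         composition_rules = survey_composition(),
                         grid = NULL, coastline = NULL, seed = 1,
                         out_dir = tempdir(), render_audio = TRUE) {
  rules <- composition_rules
  stopifnot(inherits(rules, "survey_composition"))
  if (is.null(grid)) {
    bb <- synth_bathymetry(n_rows = 280, n_cols = 64, cell_m = 250)
    grid <- bb$grid
    coastline <- coastline %||% bb$coastline
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  empty <- function() {
    list(individuals = data.frame(), aggregations = data.frame(),
         clicks = data.frame(), sightings = data.frame(),
         audio_manifest = data.frame(), grid = grid, coastline = coastline,
         paths = list())
  }
  if (n_aggregations == 0) {
    out <- empty()
    class(out) <- "scene_truth"
    return(out)
  }

  withr::with_seed(seed, {
    # --- sizes and class assignment -----------------------------------------
    sizes <- rules$sizes
    if (is.null(sizes)) {
      sizes <- if (n_aggregations == length(default_sizes_19)) default_sizes_19
               else sample(default_sizes_19, n_aggregations, replace = TRUE)
    }
    if (length(sizes) != n_aggregations) {
      stop("`sizes` must have one entry per aggregation", call. = FALSE)
    }
    counts <- rules$class_counts
    if (sum(sizes) != sum(counts)) {
      # rescale class counts to the realised total (largest remainder)
      tot <- sum(sizes)
      raw <- counts / sum(counts) * tot
      counts <- floor(raw)
      rem <- tot - sum(counts)
      if (rem > 0) {
        add <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
        counts[add] <- counts[add] + 1
      }
    }
    labels <- interleave_classes(counts)
    groups <- split(labels, rep(seq_len(n_aggregations), sizes))

    # --- per-aggregation true IPIs ------------------------------------------
    sep <- rules$min_ipi_sep_ms
    win <- class_ipi_windows(sep)
    calf_group <- NA_integer_
    if (rules$include_calf) {
      with_imm <- which(vapply(groups, function(g) any(g == "immature"), logical(1)))
      if (length(with_imm)) calf_group <- with_imm[sample.int(length(with_imm), 1)]
    }
    agg_ipis <- vector("list", n_aggregations)
    for (a in seq_len(n_aggregations)) {
      g <- groups[[a]]
      ipis <- numeric(length(g))
      calf_flags <- logical(length(g))
      for (cl in unique(g)) {
        idx <- which(g == cl)
        k <- length(idx)
        w <- win[[cl]]
        if (cl == "immature" && a == calf_group[1] && !is.na(calf_group)) {
          # one calf fixed at 1.90 ms (visually confirmed); the rest clear of it
          ipis[idx[1]] <- 1.90
          calf_flags[idx[1]] <- TRUE
          if (k > 1) ipis[idx[-1]] <- spaced_uniform(k - 1, 1.90 + sep, w[2], sep)
        } else {
          ipis[idx] <- spaced_uniform(k, w[1], w[2], sep)
        }
      }
      agg_ipis[[a]] <- list(ipi = ipis, calf = calf_flags)
    }

    # --- behaviours and dates -----------------------------------------------
    hunting <- stats::runif(n_aggregations) < rules$p_hunting
    social <- rep(FALSE, n_aggregations)
    if (rules$n_socialising > 0) {
      social[sample.int(n_aggregations, min(rules$n_socialising, n_aggregations))] <- TRUE
    }
    visual <- sample(c("moving", "resting", ""), n_aggregations,
                     replace = TRUE, prob = c(0.45, 0.2, 0.35))

    survey_days <- seq(as.Date("2024-01-12"), as.Date("2024-05-15"), length.out = 24)
    n_active <- max(1L, min(10L, n_aggregations))
    active <- survey_days[unique(round(seq(1, 24, length.out = n_active)))]
    male_share <- vapply(groups, function(g) mean(g == "adult_male"), numeric(1))
    # males leave late in the season: male-heavy aggregations surveyed first
    date_order <- order(male_share, decreasing = TRUE)
    day_of <- rep(as.Date(NA), n_aggregations)
    day_of[date_order] <- active[ceiling(seq_len(n_aggregations) *
                                           length(active) / n_aggregations)]

    # --- placement -----------------------------------------------------------
    lat_rng <- range(grid$lat)
    lat_margin <- 1000 / M_PER_DEG_LAT
    slots <- seq(lat_rng[1] + lat_margin, lat_rng[2] - lat_margin,
                 length.out = max(n_aggregations, 2))
    if (n_aggregations > 1 &&
        (slots[2] - slots[1]) * M_PER_DEG_LAT < 2500) {
      stop("grid too small for the requested number of aggregation placements",
           call. = FALSE)
    }
    slots <- sample(slots, n_aggregations)
    lon_rng <- range(grid$lon)
    lon_margin <- 600 / m_per_deg_lon(mean(lat_rng))
    find_lon <- function(lat, target_depth) {
      f <- function(lon) depth_at(grid, lat, lon) - target_depth
      lo <- lon_rng[1] + lon_margin; hi <- lon_rng[2] - lon_margin
      if (f(lo) * f(hi) > 0) {
        stop("grid too small: target depth band not reachable", call. = FALSE)
      }
      stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
    }
    centers <- data.frame(lat = slots, lon = NA_real_)
    for (a in seq_len(n_aggregations)) {
      band <- if (hunting[a]) rules$hunting_depth_m else rules$other_depth_m
      band <- pmin(pmax(band, rules$isobath_range_m[1]), rules$isobath_range_m[2])
      centers$lon[a] <- find_lon(slots[a], stats::runif(1, band[1], band[2]))
    }

    # --- assemble tables and audio ------------------------------------------
    ind_rows <- list(); click_rows <- list(); sight_rows <- list()
    manifest_rows <- list(); agg_rows <- list()
    fs <- rules$sample_rate
    for (a in seq_len(n_aggregations)) {
      g <- groups[[a]]
      ipis <- agg_ipis[[a]]$ipi
      calf <- agg_ipis[[a]]$calf
      agg_id <- sprintf("%s/A%02d", format(day_of[a]), a)
      ind_rows[[a]] <- data.frame(
        aggregation_id = agg_id, individual = seq_along(g),
        true_ipi_ms = ipis, true_length_m = size_from_ipi(ipis),
        class_label = classify_individual(ipis), calf_confirmed = calf,
        stringsAsFactors = FALSE
      )
      # member GPS points: centre plus jitter, all within ~350 m
      n_pts <- min(length(g), 3L)
      jit_lat <- c(0, stats::runif(n_pts - 1, -350, 350)) / M_PER_DEG_LAT
      jit_lon <- c(0, stats::runif(n_pts - 1, -350, 350)) / m_per_deg_lon(centers$lat[a])
      notes <- if (any(calf)) "calf confirmed visually" else ""
      sight_rows[[a]] <- data.frame(
        datetime = paste0(format(day_of[a]), "T", sprintf("%02d:%02d:00", 8 + a %% 8, (a * 7) %% 60)),
        date = format(day_of[a]),
        lat = centers$lat[a] + jit_lat, lon = centers$lon[a] + jit_lon,
        visual_behaviours = visual[a], notes = notes,
        true_aggregation = agg_id, stringsAsFactors = FALSE
      )

      wav_path <- file.path(out_dir, sprintf("agg_%02d.wav", a))
      agg_clicks <- list()
      if (render_audio) {
        # plan: one regular train per individual, plus buzz/coda trains for
        # hunting/socialising, time-multiplexed with guard gaps (the
        # analyst's practice of reading one animal's click series at a time)
        plan <- lapply(seq_along(g), function(j) list(
          individual = j, kind = "regular",
          spec = train_spec("regular", n_clicks = rules$n_clicks, ici_s = rules$ici_s)
        ))
        if (hunting[a]) {
          plan[[length(plan) + 1L]] <- list(individual = 1L, kind = "buzz",
            spec = train_spec("buzz", n_clicks = 30, ici_s = 0.05))
        }
        if (social[a]) {
          plan[[length(plan) + 1L]] <- list(individual = 1L, kind = "coda",
            spec = train_spec("coda", n_clicks = 8, duration_s = 1.0))
        }
        segments <- vector("list", length(plan))
        seg_truth <- vector("list", length(plan))
        for (k in seq_along(plan)) {
          j <- plan[[k]]$individual
          cs <- click_spec(ipi_ms = ipis[j], snr_db = Inf, sample_rate = fs)
          # lead-in so the p0 pulse (one IPI before p1) is not clipped
          st <- synth_train(plan[[k]]$spec, cs,
                            seed = sample.int(2^30, 1),
                            t_start = ipis[j] / 1000 + 0.005,
                            render_audio = TRUE)
          segments[[k]] <- st$audio$samples
          seg_truth[[k]] <- data.frame(
            aggregation_id = agg_id, individual = j,
            time_s = st$truth$clicks$time_s, kind = plan[[k]]$kind,
            stringsAsFactors = FALSE
          )
        }
        # guard must exceed the 2 s train-segmentation gap so multiplexed
        # trains stay distinct downstream
        guard_n <- round(2.5 * fs)
        seg_off <- cumsum(c(round(0.5 * fs),
                            utils::head(lengths(segments), -1) + guard_n))
        total_n <- seg_off[length(seg_off)] +
          length(segments[[length(segments)]]) + round(0.25 * fs)
        x <- numeric(total_n)
        for (k in seq_along(segments)) {
          idx <- (seg_off[k] + 1L):(seg_off[k] + length(segments[[k]]))
          x[idx] <- x[idx] + segments[[k]]
          seg_truth[[k]]$time_s <- seg_truth[[k]]$time_s + seg_off[k] / fs
        }
        agg_clicks <- seg_truth
        if (is.finite(rules$snr_db)) {
          x <- x + stats::rnorm(length(x), 0, 1 / 10^(rules$snr_db / 20))
        }
        peak <- max(abs(x))
        if (peak > 1) x <- x / peak * 0.99
        write_wav(audio_segment(x, fs), wav_path, bit_depth = 24)
      }
      manifest_rows[[a]] <- data.frame(
        aggregation_id = agg_id, date = format(day_of[a]),
        lat = centers$lat[a], lon = centers$lon[a],
        wav = if (render_audio) wav_path else NA_character_,
        stringsAsFactors = FALSE
      )
      beh <- c(if (hunting[a]) "hunting", if (social[a]) "socialising",
               if (nzchar(visual[a])) visual[a])
      agg_rows[[a]] <- data.frame(
        aggregation_id = agg_id, date = format(day_of[a]),
        lat = centers$lat[a], lon = centers$lon[a], size = length(g),
        mean_length_m = mean(size_from_ipi(ipis)),
        has_immature = any(g == "immature"),
        behaviours = paste(beh, collapse = ";"),
        stringsAsFactors = FALSE
      )
      if (length(agg_clicks)) {
        click_rows[[a]] <- do.call(rbind, agg_clicks)
      }
    }

    individuals <- do.call(rbind, ind_rows)
    sightings <- do.call(rbind, sight_rows)
    aggregations <- do.call(rbind, agg_rows)
    audio_manifest <- do.call(rbind, manifest_rows)
    clicks <- if (length(click_rows)) do.call(rbind, click_rows) else data.frame()
    rownames(individuals) <- rownames(sightings) <- rownames(aggregations) <-
      rownames(audio_manifest) <- NULL

    paths <- list(
      sightings = file.path(out_dir, "sightings.csv"),
      manifest = file.path(out_dir, "audio_manifest.csv"),
      truth_individuals = file.path(out_dir, "truth_individuals.csv")
    )
    utils::write.csv(sightings, paths$sightings, row.names = FALSE)
    utils::write.csv(audio_manifest, paths$manifest, row.names = FALSE)
    utils::write.csv(individuals, paths$truth_individuals, row.names = FALSE)

    out <- list(individuals = individuals, aggregations = aggregations,
                clicks = clicks, sightings = sightings,
                audio_manifest = audio_manifest, grid = grid,
                coastline = coastline, paths = paths)
    class(out) <- "scene_truth"
    out
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d aggregations, %d individuals, %d truth clicks\n",
              nrow(x$aggregations), nrow(x$individuals),
              if (is.data.frame(x$clicks)) nrow(x$clicks) else 0L))
  invisible(x)
}
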