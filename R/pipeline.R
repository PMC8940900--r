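# End-to-end runner: simulate -> behavior -> photometry -> ephys -> stats.
# The statistics stage sees only the assembled per-mouse metrics table; the
# generator's ground truth is carried alongside for recovery testing but is
# never an input to any analysis.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param stages subset of `c("behavior", "photometry", "ephys")`; the stats
#'   stage always runs on whatever metrics exist.
#' @param video_hz tracking frame rate (default 30).
#' @param si_phase_s duration of each social-interaction phase (150 s).
#' @param epm_s,oft_s trial durations (300 s each).
#' @param si_base_frac interaction-zone occupancy in the no-target phase.
#' @param n_photometry number of mice (taken from the cohort head) given a
#'   photometry session; photometry is recorded during the EPM trial.
#' @param neurons_range min/max recorded neurons per mouse (default 3-7).
#' @param neuron_duration_s cell-attached record length per neuron.
#' @param neuron_rate_hz cell-attached sampling rate.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            stages = c("behavior", "photometry", "ephys"),
                            video_hz = 30, si_phase_s = 150,
                            epm_s = 300, oft_s = 300, si_base_frac = 0.25,
                            n_photometry = 6,
                            neurons_range = c(3, 7),
                            neuron_duration_s = 30, neuron_rate_hz = 5000) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(stages %in% c("behavior", "photometry", "ephys")))
  structure(list(cohort = cohort, stages = stages, video_hz = video_hz,
                 si_phase_s = si_phase_s, epm_s = epm_s, oft_s = oft_s,
                 si_base_frac = si_base_frac, n_photometry = n_photometry,
                 neurons_range = neurons_range,
                 neuron_duration_s = neuron_duration_s,
                 neuron_rate_hz = neuron_rate_hz),
            class = "pipeline_config")
}

# behavioral trials for one mouse; returns a one-row metrics data frame
simulate_mouse_behavior <- function(cfg, gt_row, seed) {
  si_arena <- arena_si()
  base <- cfg$si_base_frac
  tgt <- pmin(0.85, pmax(0.02, base * gt_row$si_true / 100))

  tr_no <- gen_trajectory(si_arena, c(interaction = base), cfg$si_phase_s,
                          cfg$video_hz, seed = split_seed(seed, "si_no"))
  tr_tg <- gen_trajectory(si_arena, c(interaction = tgt), cfg$si_phase_s,
                          cfg$video_hz, seed = split_seed(seed, "si_tg"))
  occ_no <- zone_occupancy(tr_no)
  occ_tg <- zone_occupancy(tr_tg)
  t_no <- occ_no$zones$time_s[occ_no$zones$zone == "interaction"]
  t_tg <- occ_tg$zones$time_s[occ_tg$zones$zone == "interaction"]
  si <- si_ratio(t_tg, t_no)

  open <- gt_row$open_frac_true
  epm_tr <- gen_trajectory(arena_epm(),
                           c(open = open, center = 0.12,
                             closed = max(0, 1 - open - 0.12)),
                           cfg$epm_s, cfg$video_hz,
                           seed = split_seed(seed, "epm"))
  occ_epm <- zone_occupancy(epm_tr)
  epm_open <- occ_epm$zones[occ_epm$zones$zone == "open", ]

  oft_target <- with_local_seed(split_seed(seed, "oft_t"), {
    pmin(0.5, pmax(0.01, 0.02 + 0.45 * open + stats::rnorm(1, 0, 0.02)))
  })
  oft_tr <- gen_trajectory(arena_oft(), c(center = oft_target), cfg$oft_s,
                           cfg$video_hz, seed = split_seed(seed, "oft"))
  occ_oft <- zone_occupancy(oft_tr)
  oft_c <- occ_oft$zones[occ_oft$zones$zone == "center", ]

  cons <- with_local_seed(split_seed(seed, "consume"), {
    sp_true <- pmin(98, pmax(5, 45 + 0.3 * gt_row$si_true + stats::rnorm(1, 0, 5)))
    fust_true <- pmin(3, pmax(0.1, 0.4 + 0.006 * gt_row$si_true + stats::rnorm(1, 0, 0.1)))
    list(sp = sp_true, fust = fust_true)
  })
  total_g <- 10
  sp <- sucrose_preference(total_g * cons$sp / 100, total_g * (1 - cons$sp / 100))
  fust <- fust_preference(40 * cons$fust, 40)

  data.frame(
    mouse = gt_row$mouse, stressed = gt_row$stressed,
    si_time_target_s = t_tg, si_time_notarget_s = t_no, si_ratio = si,
    group = classify_mouse(si, gt_row$stressed),
    si_distance_cm = occ_no$distance_cm,
    si_velocity_cm_s = occ_no$mean_velocity_cm_s,
    epm_open_time_s = epm_open$time_s,
    epm_open_pct = 100 * epm_open$time_s / cfg$epm_s,
    epm_open_entries = epm_open$entries,
    oft_center_pct = 100 * oft_c$time_s / cfg$oft_s,
    oft_center_entries = oft_c$entries,
    sucrose_preference = sp, fust_preference = fust,
    stringsAsFactors = FALSE
  ) -> row
  list(metrics = row, epm_traj = epm_tr)
}

# cell-attached recordings for one mouse; returns neuron-level features
simulate_mouse_ephys <- function(cfg, gt_row, seed) {
  with_local_seed(split_seed(seed, "ephys_n"), {
    k <- sample(cfg$neurons_range[1]:cfg$neurons_range[2], 1)
    rates <- pmax(0.5, gt_row$firing_true_hz + stats::rnorm(k, 0, 0.4))
    list(k = k, rates = rates)
  }) -> plan
  out <- lapply(seq_len(plan$k), function(j) {
    ca <- gen_cell_attached(plan$rates[j], cfg$neuron_duration_s,
                            noise_sd = 0.12,
                            seed = split_seed(seed, "neuron", j),
                            sample_rate_hz = cfg$neuron_rate_hz,
                            trough_latency_ms = 1.6)
    sp <- detect_spikes(ca)
    fr <- firing_rate(sp, ca$duration_s)
    lat <- spike_trough_latency(ca, sp)
    data.frame(mouse = gt_row$mouse, neuron = j, firing_hz = fr,
               trough_latency_ms = lat,
               is_putative_da = is.finite(lat) && classify_putative_da(fr, lat))
  })
  do.call(rbind, out)
}

# photometry session for one mouse (EPM trial); returns a one-row summary
simulate_mouse_photometry <- function(cfg, gt_row, epm_traj, seed) {
  rec <- gen_photometry(epm_traj, sensor = cfg$cohort$sensor,
                        base_per_min = cfg$cohort$transient_base_per_min,
                        zone_gain_per_min = gt_row$transient_mod_per_min,
                        rate_zone = "open",
                        seed = split_seed(seed, "photo"))
  series <- dff(rec)
  masks <- zone_masks(epm_traj, series$time_s)
  auc <- compartment_auc(series, masks)
  ev <- detect_events(series)
  sb <- NA_real_
  if (!is.null(rec$sync_events)) {
    margin <- 5.2
    ok <- rec$sync_events$time_s > margin &
      rec$sync_events$time_s < max(series$time_s) - margin
    if (any(ok)) {
      pe <- peri_event(series, data.frame(time_s = rec$sync_events$time_s[ok],
                                          label = "open_entry",
                                          mouse = gt_row$mouse))
      sb <- summary_bin(pe)
    }
  }
  open_auc <- auc[auc$zone == "open", ]
  data.frame(mouse = gt_row$mouse, events_per_min = ev$events_per_min,
             auc_open_per_s = open_auc$auc_per_s,
             summary_z_open_entry = sb)
}

#' Assemble the correlation panel and group comparisons from mouse metrics
#'
#' The statistics stage of the pipeline: takes only the per-mouse metrics
#' table (never the generator's ground truth) and computes the study's
#' comparison panel — firing against SI ratio (expected null) and against
#' EPM open-arm time (expected positive) in stressed mice, SI-linked indices
#' against sucrose/urine preference, EPM against OFT anxiety indices, and
#' CTL/A/AD group comparisons.
#'
#' @param metrics per-mouse metrics data frame (see [run_pipeline()]).
#' @return list with `correlations` (data frame) and `group_comparisons`
#'   (named list of `group_comparison` objects).
#' @export
analyze_cohort <- function(metrics) {
  stopifnot(is.data.frame(metrics), "group" %in% names(metrics))
  stressed <- metrics[metrics$stressed, , drop = FALSE]
  panel <- list(
    c("firing_hz", "si_ratio", "stressed"),
    c("firing_hz", "epm_open_pct", "stressed"),
    c("si_ratio", "sucrose_preference", "stressed"),
    c("si_ratio", "fust_preference", "stressed"),
    c("epm_open_pct", "oft_center_pct", "stressed")
  )
  rows <- lapply(panel, function(pr) {
    d <- if (pr[3] == "stressed") stressed else metrics
    if (!all(pr[1:2] %in% names(d)) || sum(stats::complete.cases(d[pr[1:2]])) < 3) {
      return(NULL)
    }
    r <- tryCatch(correlate(d[[pr[1]]], d[[pr[2]]], pr[1], pr[2]),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(x = pr[1], y = pr[2], subset = pr[3], method = r$method,
               estimate = r$estimate, p = r$p, n = r$n,
               ci_lo = if (is.null(r$conf_int)) NA_real_ else r$conf_int[1],
               ci_hi = if (is.null(r$conf_int)) NA_real_ else r$conf_int[2])
  })
  correlations <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  gcomp <- list()
  for (var in c("firing_hz", "epm_open_time_s", "si_ratio", "oft_center_pct")) {
    if (!var %in% names(metrics)) next
    s <- split(metrics[[var]], metrics$group)
    s <- s[vapply(s, function(v) sum(is.finite(v)) >= 2, logical(1))]
    s <- lapply(s, function(v) v[is.finite(v)])
    if (length(s) >= 2) {
      gcomp[[var]] <- compare_groups(s)
    }
  }
  list(correlations = correlations, group_comparisons = gcomp)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort, simulates the behavioral trials, photometry sessions
#' and cell-attached recordings each mouse contributes, extracts every
#' metric with the package's analysis operations, and runs the
#' normality-gated statistics stage on the assembled per-mouse table.
#' Deterministic given the configuration (which carries the master seed).
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report`: `metrics` (per-mouse table),
#'   `correlations`, `group_comparisons`, `seed`, `version`, and
#'   `ground_truth` (generator output, not used by any analysis stage).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$cohort$seed
  cohort <- gen_cohort(config$cohort)
  gt <- cohort$ground_truth
  if (!nrow(gt)) stop("missing stage inputs: empty cohort (simulate stage)")

  metrics <- NULL
  if ("behavior" %in% config$stages) {
    beh <- lapply(seq_len(nrow(gt)), function(i) {
      simulate_mouse_behavior(config, gt[i, ], split_seed(seed, "mouse", i))
    })
    metrics <- do.call(rbind, lapply(beh, `[[`, "metrics"))

    if ("photometry" %in% config$stages && config$n_photometry > 0) {
      sel <- seq_len(min(config$n_photometry, nrow(gt)))
      ph <- do.call(rbind, lapply(sel, function(i) {
        simulate_mouse_photometry(config, gt[i, ], beh[[i]]$epm_traj,
                                  split_seed(seed, "mouse", i))
      }))
      metrics <- merge(metrics, ph, by = "mouse", all.x = TRUE, sort = FALSE)
    }
  } else if ("photometry" %in% config$stages) {
    stop("missing stage inputs: photometry requires the behavior stage")
  }

  if ("ephys" %in% config$stages) {
    neurons <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
      simulate_mouse_ephys(config, gt[i, ], split_seed(seed, "mouse", i))
    }))
    mouse_feats <- per_mouse_mean(neurons)
    keep <- c("mouse", "n_neurons", "firing_hz", "trough_latency_ms")
    mouse_feats <- mouse_feats[, intersect(keep, names(mouse_feats))]
    metrics <- if (is.null(metrics)) {
      merge(gt[, c("mouse", "stressed")], mouse_feats, by = "mouse", sort = FALSE)
    } else {
      merge(metrics, mouse_feats, by = "mouse", all.x = TRUE, sort = FALSE)
    }
  }
  if (is.null(metrics)) stop("missing stage inputs: no analysis stage selected")
  metrics <- metrics[order(metrics$mouse), , drop = FALSE]
  rownames(metrics) <- NULL
  if (!"group" %in% names(metrics)) {
    metrics$group <- ifelse(metrics$stressed, NA_character_, "CTL")
  }

  stats_out <- analyze_cohort(metrics)
  structure(list(metrics = metrics,
                 correlations = stats_out$correlations,
                 group_comparisons = stats_out$group_comparisons,
                 seed = seed,
                 version = as.character(utils::packageVersion("circuitphys")),
                 ground_truth = gt),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d mice (seed %s), groups: %s\n",
              nrow(x$metrics), format(x$seed),
              paste(names(table(x$metrics$group)), table(x$metrics$group),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$correlations)) {
    cat("correlation panel:\n")
    print(x$correlations[, c("x", "y", "method", "estimate", "p", "n")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
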