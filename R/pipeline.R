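#' Study A: location validation
#'
#' Runs the second-by-second location comparison end to end on a simulation
#' bundle (or equivalent ingested data): cleans the ground-truth annotation
#' series (out-of-grid, dead-antenna and single-frame-jump rules), completes
#' the RFID stream by forward fill over the annotation time grid, aligns the
#' two streams and computes exact and near (eight-neighbour) match
#' percentages. When an observer ratings matrix is supplied, inter-observer
#' reliability (Fleiss' kappa) and pairwise intra-observer reliability
#' (Cohen's kappa on repeated ratings) are computed on the raw ratings.
#'
#' @param bundle A [make_bundle()] result (or a list with `config`,
#'   `rfid_log`, `video$series`, `periods`).
#' @param ratings Optional subjects x raters matrix for Fleiss' kappa.
#' @param repeat_ratings Optional named list of two-column matrices (first
#'   vs second scoring of the repeated frames, per observer) for Cohen's
#'   kappa.
#' @param out_dir Optional directory; when given, the match report and any
#'   reliability results are written as tab-delimited tables.
#' @return A list with `report` (a [match_stats()] report), `paired`,
#'   `truth`, `rfid` series, and `reliability` (list of [cor_result()] or
#'   `NULL`).
#' @export
run_study_a <- function(bundle, ratings = NULL, repeat_ratings = NULL,
                        out_dir = NULL) {
  grid <- bundle$config$grid
  raw <- as.data.frame(bundle$video$series)
  names(raw)[names(raw) == "individual"] <- "individual"
  truth <- clean_annotations(
    data.frame(time = raw$time, individual = raw$individual,
               antenna = raw$antenna), grid)

  times <- sort(unique(truth$time))
  birds <- unique(truth$individual)
  rfid <- do.call(rbind, lapply(birds, function(b)
    fill_forward(bundle$rfid_log, b, times)))
  rfid <- location_series(rfid$individual, rfid$time, rfid$antenna)

  group <- NULL
  if (!is.null(bundle$periods) && nrow(bundle$periods) > 1) {
    pid <- rep(NA_character_, length(times))
    for (i in seq_len(nrow(bundle$periods))) {
      sel <- times >= bundle$periods$start[i] & times < bundle$periods$end[i]
      pid[sel] <- bundle$periods$period[i]
    }
    group <- data.frame(time = times, group = pid)
  }
  paired <- align_streams(truth, rfid, group = group)
  report <- match_stats(paired, grid)

  reliability <- NULL
  if (!is.null(ratings) || !is.null(repeat_ratings)) {
    reliability <- list()
    if (!is.null(ratings))
      reliability$inter_observer <- fleiss_kappa(ratings)
    if (!is.null(repeat_ratings))
      for (nm in names(repeat_ratings)) {
        rr <- repeat_ratings[[nm]]
        reliability[[paste0("intra_", nm)]] <-
          cohen_kappa(rr[, 1], rr[, 2])
      }
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_match_report(report, file.path(out_dir, "location_matches.tsv"))
    if (!is.null(reliability))
      write_stats_table(reliability, file.path(out_dir, "reliability.tsv"))
  }
  list(report = report, paired = paired, truth = truth, rfid = rfid,
       reliability = reliability)
}

#' Study B: moving-distance validation
#'
#' Aggregates RFID distances per bird and period, pairs them with the video,
#' UWB and ground-truth distances from the bundle, and computes bootstrap
#' Spearman rank correlations for every available source pair. When the
#' period table carries a `day` column (longer recordings), repeated-measures
#' correlations of RFID vs UWB within days and within individuals are added.
#'
#' @param bundle A [make_bundle()] result.
#' @param n_boot Bootstrap resamples for the Spearman CIs.
#' @param seed Seed for the bootstrap.
#' @param window Debounce lookback, seconds.
#' @param out_dir Optional output directory for the paired-distance and
#'   correlation tables.
#' @return A list with `distances` (one row per bird-period with `rfid`,
#'   `video`, `uwb`, `truth` metres) and `correlations` (named list of
#'   [cor_result()]).
#' @export
run_study_b <- function(bundle, n_boot = 1000, seed = 1, window = 5,
                        out_dir = NULL) {
  grid <- bundle$config$grid
  tags <- unique(bundle$trajectories$bird)
  act <- period_aggregate(bundle$rfid_log, tags, grid, bundle$periods,
                          window = window, schedule = bundle$schedule)
  d <- data.frame(bird = act$tag_id, period = act$period,
                  rfid = act$total_metres)
  merge_src <- function(d, src, nm) {
    names(src)[names(src) == "metres"] <- nm
    merge(d, src, by = c("bird", "period"), all.x = TRUE)
  }
  d <- merge_src(d, bundle$video$distances, "video")
  d <- merge_src(d, bundle$uwb_distances, "uwb")
  d <- merge_src(d, bundle$true_distances, "truth")
  if ("day" %in% names(bundle$periods))
    d$day <- bundle$periods$day[match(d$period, bundle$periods$period)]

  pairs <- list(rfid_video = c("rfid", "video"),
                rfid_uwb = c("rfid", "uwb"),
                video_uwb = c("video", "uwb"),
                rfid_truth = c("rfid", "truth"))
  correlations <- list()
  for (nm in names(pairs)) {
    a <- d[[pairs[[nm]][1]]]; b <- d[[pairs[[nm]][2]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 4) {
      warning("fewer than 4 paired records for ", nm, "; skipped")
      next
    }
    correlations[[nm]] <- spearman_ci(a[ok], b[ok], n_boot = n_boot,
                                      seed = seed)
  }
  if ("day" %in% names(d)) {
    ok <- is.finite(d$rfid) & is.finite(d$uwb)
    dd <- d[ok, , drop = FALSE]
    correlations$rfid_uwb_within_day <- rmcorr(dd$day, dd$rfid, dd$uwb)
    correlations$rfid_uwb_within_individual <- rmcorr(dd$bird, dd$rfid,
                                                      dd$uwb)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(d, file.path(out_dir, "paired_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_stats_table(correlations,
                      file.path(out_dir, "distance_correlations.tsv"))
  }
  list(distances = d, correlations = correlations)
}
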