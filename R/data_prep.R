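#' Collapse photo records to daily detection records
#'
#' Aggregates a photo-level table to one record per site and calendar day.
#' A day is only considered reliably sampled when the camera produced at
#' least 36 pictures (25% of the 144 expected from a 10-minute interval);
#' days below that threshold are flagged `excluded` and treated as
#' unobserved downstream. Species flags are "any photo" detections and the
#' daily carrion flag is 1 if the carcass is visible on any usable photo
#' that day (fragments usually remain, so any-photo is the natural rule).
#'
#' @param photos data frame with columns `site_id`, `timestamp` (ISO-8601 or
#'   POSIXct), `arctic`, `red`, `carrion` (0/1) and optionally
#'   `usable_photo` (0/1; defaults to all usable).
#' @param min_photos minimum usable photos for a day to count as observed.
#' @return tibble with one row per site x day: `site_id`, `date`,
#'   `n_photos`, `arctic_seen`, `red_seen`, `carrion_present`, `excluded`.
#' @export
photos_to_days <- function(photos, min_photos = 36) {
  req <- c("site_id", "timestamp", "arctic", "red", "carrion")
  miss <- setdiff(req, names(photos))
  if (length(miss) > 0)
    stop("photo table is missing column(s): ", paste(miss, collapse = ", "))
  photos <- dplyr::as_tibble(photos)
  if (!("usable_photo" %in% names(photos))) photos$usable_photo <- 1L

  ts <- photos$timestamp
  if (!inherits(ts, "POSIXt")) {
    parsed <- suppressWarnings(lubridate::ymd_hms(as.character(ts), tz = "UTC",
                                                  quiet = TRUE))
    bad <- is.na(parsed) & !is.na(ts)
    if (any(bad)) {
      warning(sum(bad), " photo record(s) with malformed timestamps dropped")
      photos <- photos[!bad, , drop = FALSE]
      parsed <- parsed[!bad]
    }
    photos$timestamp <- parsed
  }
  if (anyDuplicated(photos[c("site_id", "timestamp")]) > 0)
    stop("duplicate site_id x timestamp in photo table")

  photos |>
    dplyr::filter(.data$usable_photo == 1) |>
    dplyr::mutate(date = lubridate::as_date(.data$timestamp)) |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(
      n_photos = dplyr::n(),
      arctic_seen = as.integer(any(.data$arctic == 1)),
      red_seen = as.integer(any(.data$red == 1)),
      carrion_present = as.integer(any(.data$carrion == 1)),
      .groups = "drop") |>
    dplyr::mutate(excluded = .data$n_photos < min_photos)
}

#' Encode a day's two species flags as a joint observed state
#'
#' @param arctic_seen,red_seen binary vectors.
#' @return factor with levels `none`, `A`, `R`, `AR`.
#' @export
day_state <- function(arctic_seen, red_seen) {
  stopifnot(all(arctic_seen %in% c(0, 1), na.rm = TRUE),
            all(red_seen %in% c(0, 1), na.rm = TRUE))
  lev <- c("none", "A", "R", "AR")
  factor(lev[1L + arctic_seen + 2L * red_seen], levels = lev)
}

obs_levels <- c("none", "A", "R", "AR")

#' Segment one camera-winter into weekly primary periods
#'
#' Builds consecutive 7-day weeks starting the day the carrion was first
#' introduced. A week is retained only if it has more than 3 observed days
#' (>= 4); observations beyond week 7 are removed; the whole camera-winter
#' is rejected (returns `NULL`) unless more than 3 weeks (>= 4) are
#' retained. Dropped weeks keep their calendar slot (all days unobserved)
#' so the weekly latent chain advances one transition per calendar week.
#'
#' @param days day records for one site x winter (from [photos_to_days()]),
#'   with columns `site_id`, `date`, `arctic_seen`, `red_seen`,
#'   `carrion_present` and optionally `excluded`.
#' @param carrion_intro_date date the carrion was first introduced.
#' @param n_weeks maximum number of weekly primary periods (default 7).
#' @param min_days_per_week,min_weeks retention thresholds (strict "more
#'   than 3" reading: defaults 4 and 4).
#' @return tibble with one row per week x day (`week` 1..7, `day` 1..7,
#'   `date`, `obs` factor or NA, `carrion` 0/1 or NA), or `NULL` when the
#'   camera-winter is rejected.
#' @export
segment_weeks <- function(days, carrion_intro_date, n_weeks = 7,
                          min_days_per_week = 4, min_weeks = 4) {
  if (missing(carrion_intro_date) || length(carrion_intro_date) != 1 ||
      is.na(carrion_intro_date))
    stop("carrion_intro_date missing for site ",
         paste(unique(days$site_id), collapse = ","))
  carrion_intro_date <- lubridate::as_date(carrion_intro_date)
  days <- dplyr::as_tibble(days)
  if (!("excluded" %in% names(days))) days$excluded <- FALSE

  grid <- tidyr::expand_grid(week = seq_len(n_weeks), day = 1:7) |>
    dplyr::mutate(date = carrion_intro_date + (.data$week - 1L) * 7L +
                    (.data$day - 1L))
  obs_days <- days |>
    dplyr::filter(!.data$excluded) |>
    dplyr::transmute(date = lubridate::as_date(.data$date),
                     obs = day_state(.data$arctic_seen, .data$red_seen),
                     carrion = as.integer(.data$carrion_present))
  out <- dplyr::left_join(grid, obs_days, by = "date")

  week_ok <- out |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$obs)), .groups = "drop") |>
    dplyr::mutate(keep = .data$n_obs >= min_days_per_week)
  if (sum(week_ok$keep) < min_weeks) return(NULL)

  dropped <- week_ok$week[!week_ok$keep]
  out$obs[out$week %in% dropped] <- NA
  out$carrion[out$week %in% dropped] <- NA_integer_
  out
}

#' Build filtered detection histories for all camera-winters
#'
#' Applies [segment_weeks()] per site x winter and combines the retained
#' histories into one table. Attach the winter labels through `intro_dates`.
#'
#' @param days day records (from [photos_to_days()] or the simulator).
#' @param intro_dates data frame `site_id`, `year`, `carrion_intro_date`.
#' @inheritParams segment_weeks
#' @return tibble (`site_id`, `year`, `week`, `day`, `date`, `obs`,
#'   `carrion`) with a `filter_report` attribute summarizing the filtering.
#' @export
build_histories <- function(days, intro_dates, n_weeks = 7,
                            min_days_per_week = 4, min_weeks = 4) {
  stopifnot(all(c("site_id", "year", "carrion_intro_date") %in%
                  names(intro_dates)))
  days <- dplyr::as_tibble(days)
  pieces <- vector("list", nrow(intro_dates))
  for (i in seq_len(nrow(intro_dates))) {
    sid <- intro_dates$site_id[i]
    yr <- intro_dates$year[i]
    intro <- lubridate::as_date(intro_dates$carrion_intro_date[i])
    sub <- days[days$site_id == sid &
                  lubridate::as_date(days$date) >= intro &
                  lubridate::as_date(days$date) < intro + 7L * n_weeks, ,
                drop = FALSE]
    seg <- segment_weeks(sub, intro, n_weeks, min_days_per_week, min_weeks)
    if (!is.null(seg))
      pieces[[i]] <- dplyr::mutate(seg, site_id = sid, year = yr,
                                   .before = 1)
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) stop("no camera-winter passed the filtering rules")
  report <- list(
    n_winters_in = nrow(intro_dates),
    n_winters_retained = nrow(dplyr::distinct(out, .data$site_id, .data$year)),
    n_days_observed = sum(!is.na(out$obs)),
    n_days_arctic = sum(out$obs %in% c("A", "AR")),
    n_days_red = sum(out$obs %in% c("R", "AR")),
    n_days_both = sum(out$obs %in% "AR"),
    n_days_carrion = sum(out$carrion %in% 1))
  attr(out, "filter_report") <- report
  out
}

#' Summarize the filtering of a detection-history table
#' @param histories output of [build_histories()].
#' @return named list of counts (JSON-serializable).
#' @export
filtering_summary <- function(histories) {
  rep <- attr(histories, "filter_report")
  if (!is.null(rep)) return(rep)
  list(
    n_winters_retained = nrow(dplyr::distinct(histories, .data$site_id,
                                              .data$year)),
    n_days_observed = sum(!is.na(histories$obs)),
    n_days_arctic = sum(histories$obs %in% c("A", "AR")),
    n_days_red = sum(histories$obs %in% c("R", "AR")),
    n_days_both = sum(histories$obs %in% "AR"),
    n_days_carrion = sum(histories$carrion %in% 1))
}
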