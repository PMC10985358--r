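make_photo_day <- function(site, date, n, arctic = 0, red = 0, carrion = 1) {
  dplyr::tibble(
    site_id = site,
    timestamp = sprintf("%s %02d:%02d:00", date, (seq_len(n) - 1) %/% 6,
                        ((seq_len(n) - 1) %% 6) * 10),
    arctic = c(rep(1, arctic), rep(0, n - arctic)),
    red = c(rep(1, red), rep(0, n - red)),
    carrion = carrion)
}

test_that("daily aggregation applies the 36-photo reliability filter", {
  photos <- dplyr::bind_rows(
    make_photo_day("S01", "2020-02-01", 35, arctic = 1),
    make_photo_day("S01", "2020-02-02", 36, arctic = 1),
    make_photo_day("S01", "2020-02-03", 144))
  days <- photos_to_days(photos)
  expect_equal(nrow(days), 3)
  expect_true(days$excluded[days$date == as.Date("2020-02-01")])
  d2 <- days[days$date == as.Date("2020-02-02"), ]
  expect_false(d2$excluded)
  expect_equal(d2$arctic_seen, 1L)
  d3 <- days[days$date == as.Date("2020-02-03"), ]
  expect_false(d3$excluded)
  expect_equal(d3$arctic_seen, 0L)
  expect_equal(d3$red_seen, 0L)
})

test_that("carrion flag is any-photo and only usable photos count", {
  photos <- make_photo_day("S01", "2020-02-01", 40, carrion = 0)
  photos$carrion[7] <- 1           # one photo with the carcass visible
  photos$usable_photo <- 1L
  photos$usable_photo[1:5] <- 0L   # bad visibility
  days <- photos_to_days(photos)
  expect_equal(days$carrion_present, 1L)
  expect_equal(days$n_photos, 35L)  # usable only -> drops below threshold
  expect_true(days$excluded)
})

test_that("malformed timestamps warn and duplicates error", {
  photos <- make_photo_day("S01", "2020-02-01", 40)
  photos$timestamp[3] <- "not-a-date"
  expect_warning(days <- photos_to_days(photos), "malformed")
  expect_equal(days$n_photos, 39L)
  dup <- make_photo_day("S01", "2020-02-01", 40)
  dup$timestamp[2] <- dup$timestamp[1]
  expect_error(photos_to_days(dup), "duplicate")
})

test_that("joint observed state encodes the two species flags", {
  expect_equal(as.character(day_state(c(0, 1, 0, 1), c(0, 0, 1, 1))),
               c("none", "A", "R", "AR"))
})

make_days <- function(intro, obs_dates, arctic = NULL, red = NULL) {
  dplyr::tibble(site_id = "S01", date = obs_dates,
                arctic_seen = as.integer(obs_dates %in% arctic),
                red_seen = as.integer(obs_dates %in% red),
                carrion_present = 1L, excluded = FALSE)
}

test_that("weeks need more than 3 observed days; winters more than 3 weeks", {
  intro <- as.Date("2020-02-01")
  # weeks 1, 2, 4, 5 have 4 observed days; week 3 exactly 3 -> dropped
  dates <- c(intro + 0:3, intro + 7:10, intro + 14:16, intro + 21:24,
             intro + 28:31)
  h <- segment_weeks(make_days(intro, dates), intro)
  n_obs <- tapply(!is.na(h$obs), h$week, sum)
  expect_equal(as.vector(n_obs[1:5]), c(4, 4, 0, 4, 4))
  # with week 5 removed only 3 weeks remain -> whole winter rejected
  expect_null(segment_weeks(make_days(intro, dates[1:15]), intro))
})

test_that("observations beyond week 7 are removed", {
  intro <- as.Date("2020-02-01")
  dates <- intro + 0:62   # 9 weeks of daily data
  h <- segment_weeks(make_days(intro, dates), intro)
  expect_equal(max(h$week), 7)
  expect_equal(sum(!is.na(h$obs)), 49)
})

test_that("missing carrion introduction date names the site", {
  expect_error(segment_weeks(make_days(as.Date("2020-02-01"),
                                       as.Date("2020-02-01")), NA),
               "S01")
})

test_that("filtering is idempotent and counts are reproducible", {
  fx <- make_fixture("boundary_filters")
  h <- build_histories(fx$days, fx$intro_dates)
  # boundary fixture: week 2 keeps its 36-photo day but loses its 35-photo
  # day; week 3 (3 observed days) is dropped entirely
  retained <- tapply(!is.na(h$obs), h$week, sum)
  expect_equal(as.vector(retained), c(7, 6, 0, 7, 7, 0, 0))
  rep1 <- filtering_summary(h)
  expect_equal(rep1$n_winters_retained, 1)
  expect_equal(rep1$n_days_observed, 27)
  expect_equal(rep1$n_days_arctic, 1)
  expect_equal(rep1$n_days_red, 1)  # the red day on an excluded day is lost

  # feed the retained days back through: nothing changes
  days2 <- h |>
    dplyr::filter(!is.na(.data$obs)) |>
    dplyr::transmute(site_id = .data$site_id, date = .data$date,
                     arctic_seen = as.integer(.data$obs %in% c("A", "AR")),
                     red_seen = as.integer(.data$obs %in% c("R", "AR")),
                     carrion_present = .data$carrion, excluded = FALSE)
  h2 <- build_histories(days2, fx$intro_dates)
  expect_equal(h2$obs, h$obs)
  expect_equal(filtering_summary(h2)$n_days_observed, 27)
})
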