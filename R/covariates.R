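#' Principal-component geographic gradients (CLG, TFG)
#'
#' Runs a PCA on the five standardized site-geography variables and returns
#' the first two component scores as the coast-to-land gradient (CLG) and
#' the tundra-to-forest gradient (TFG). Axis signs are fixed by convention:
#' CLG increases inland (positive loading on distance to coast) and TFG
#' increases toward forest (negative loading on distance to forest).
#'
#' @param geo data frame with columns `site_id`, `elevation`, `dist_coast`,
#'   `dist_road`, `dist_forest`, `prop_productive`.
#' @return tibble `site_id`, `CLG`, `TFG`, with attributes
#'   `variance_explained` (fractions for all axes) and `loadings`.
#' @export
geographic_pca <- function(geo) {
  vars <- c("elevation", "dist_coast", "dist_road", "dist_forest",
            "prop_productive")
  miss <- setdiff(vars, names(geo))
  if (length(miss) > 0)
    stop("geo table is missing column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(geo[vars])
  if (nrow(X) < length(vars))
    stop("need at least as many sites as geographic variables (",
         length(vars), ")")
  if (any(apply(X, 2, sd) == 0))
    stop("constant geographic column(s): ",
         paste(vars[apply(X, 2, sd) == 0], collapse = ", "))
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  # sign conventions for the two gradients
  if (pca$rotation["dist_coast", 1] < 0) {
    pca$rotation[, 1] <- -pca$rotation[, 1]
    pca$x[, 1] <- -pca$x[, 1]
  }
  if (pca$rotation["dist_forest", 2] > 0) {
    pca$rotation[, 2] <- -pca$rotation[, 2]
    pca$x[, 2] <- -pca$x[, 2]
  }
  out <- dplyr::tibble(site_id = geo$site_id,
                       CLG = pca$x[, 1], TFG = pca$x[, 2])
  attr(out, "variance_explained") <- pca$sdev^2 / sum(pca$sdev^2)
  attr(out, "loadings") <- pca$rotation
  out
}

#' Feeding-station density index
#'
#' Time-dependent Gaussian kernel density of supplemental feeding stations,
#' evaluated on a regular grid and read at each site's grid cell. Only
#' stations whose start date precedes the focal winter contribute. The
#' kernel standard deviation equals the bandwidth (15 km by default,
#' matching Arctic fox home-range scale); grid resolution 2 km.
#'
#' @param stations data frame `x`, `y` (metric projection, metres) and
#'   `start_date` (Date) or `start_year` (first winter the station was
#'   active).
#' @param sites data frame `site_id`, `x`, `y` (same projection).
#' @param winter_year focal winter (calendar year of the Jan-Apr season).
#' @param resolution,bandwidth grid cell size and kernel SD in metres.
#' @return tibble `site_id`, `feeding` (stations per square metre; 0 when no
#'   station is active).
#' @export
feeding_index <- function(stations, sites, winter_year, resolution = 2000,
                          bandwidth = 15000) {
  stopifnot(all(c("x", "y") %in% names(stations)),
            all(c("site_id", "x", "y") %in% names(sites)))
  coords <- rbind(stations[c("x", "y")], sites[c("x", "y")])
  if (all(abs(coords$x) <= 180) && all(abs(coords$y) <= 90))
    stop("coordinates look like longitude/latitude; project to a metric ",
         "coordinate system (metres) first")
  if ("start_year" %in% names(stations)) {
    active <- stations$start_year < winter_year
  } else if ("start_date" %in% names(stations)) {
    active <- lubridate::as_date(stations$start_date) <
      lubridate::make_date(winter_year, 1, 1)
  } else stop("stations need a start_date or start_year column")
  act <- stations[active, , drop = FALSE]
  if (nrow(act) == 0)
    return(dplyr::tibble(site_id = sites$site_id, feeding = 0))

  snap <- function(v) round(v / resolution) * resolution + resolution / 2
  cx <- snap(sites$x)
  cy <- snap(sites$y)
  dens <- vapply(seq_along(cx), function(i) {
    d2 <- (act$x - cx[i])^2 + (act$y - cy[i])^2
    sum(exp(-d2 / (2 * bandwidth^2))) / (2 * pi * bandwidth^2)
  }, numeric(1))
  dplyr::tibble(site_id = sites$site_id, feeding = dens)
}

#' Annual rodent abundance index
#'
#' Fall captures per 100 trap-nights, summed over the three focal rodent
#' species within each trapping site and averaged across sites. The index
#' for a camera winter in year t uses the fall of year t - 1.
#'
#' @param traps data frame `site`, `year`, `season`, `species`, `captures`,
#'   `trap_nights`.
#' @param winter_year calendar year of the winter season.
#' @param season label of the fall season rows (default `"fall"`).
#' @param lag years between the trapping fall and the winter (default 1).
#' @return single numeric index.
#' @export
rodent_index <- function(traps, winter_year, season = "fall", lag = 1) {
  stopifnot(all(c("site", "year", "season", "species", "captures",
                  "trap_nights") %in% names(traps)))
  sub <- traps[traps$season == season & traps$year == winter_year - lag, ,
               drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  per_site <- sub |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      rate = if (any(.data$trap_nights == 0)) NA_real_ else
        sum(100 * .data$captures / .data$trap_nights),
      .groups = "drop")
  if (anyNA(per_site$rate)) {
    warning("site(s) with zero trap-nights skipped: ",
            paste(per_site$site[is.na(per_site$rate)], collapse = ", "))
    per_site <- per_site[!is.na(per_site$rate), , drop = FALSE]
  }
  mean(per_site$rate)
}

#' Center and scale a covariate
#'
#' Standardizes to mean 0, sample SD 1 (the n - 1 convention of [sd()]),
#' keeping the transform parameters as attributes for back-transformation.
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized vector with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2)
    stop("cannot standardize a constant covariate")
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  structure((x - m) / s, center = m, scale = s)
}

#' Assemble the model covariate table
#'
#' Joins the geographic gradients, feeding index and rodent index into one
#' site x year table and standardizes each covariate over the analyzed
#' camera-winters. Raw values are kept in `*_raw` columns; the standardized
#' versions carry the plain names used by the model.
#'
#' @param winters data frame `site_id`, `year` (the camera-winters to cover).
#' @param geo geographic table for [geographic_pca()].
#' @param stations,sites_xy inputs for [feeding_index()]; `sites_xy` defaults
#'   to coordinates in `geo` if present.
#' @param traps rodent trapping table for [rodent_index()].
#' @return tibble keyed by site x year with columns `CLG`, `TFG`, `rodent`,
#'   `feeding` (standardized), their `*_raw` versions, and a `transforms`
#'   attribute with the centering/scaling parameters.
#' @export
build_covariates <- function(winters, geo, stations, traps,
                             sites_xy = NULL) {
  pca <- geographic_pca(geo)
  if (is.null(sites_xy)) {
    stopifnot(all(c("x", "y") %in% names(geo)))
    sites_xy <- geo[c("site_id", "x", "y")]
  }
  out <- dplyr::as_tibble(winters) |>
    dplyr::left_join(pca, by = "site_id") |>
    dplyr::rename(CLG_raw = "CLG", TFG_raw = "TFG")
  years <- sort(unique(out$year))
  feed <- dplyr::bind_rows(lapply(years, function(y)
    dplyr::mutate(feeding_index(stations, sites_xy, y), year = y)))
  rod <- dplyr::tibble(year = years,
                       rodent_raw = vapply(years, function(y)
                         rodent_index(traps, y), numeric(1)))
  out <- out |>
    dplyr::left_join(dplyr::rename(feed, feeding_raw = "feeding"),
                     by = c("site_id", "year")) |>
    dplyr::left_join(rod, by = "year")
  transforms <- list()
  for (v in c("CLG", "TFG", "rodent", "feeding")) {
    raw <- out[[paste0(v, "_raw")]]
    if (length(unique(raw[!is.na(raw)])) < 2) {
      warning("covariate '", v, "' is constant over the analyzed ",
              "camera-winters; centered only")
      z <- structure(raw - mean(raw, na.rm = TRUE),
                     center = mean(raw, na.rm = TRUE), scale = 1)
    } else {
      z <- standardize(raw)
    }
    out[[v]] <- as.numeric(z)
    transforms[[v]] <- list(center = attr(z, "center"),
                            scale = attr(z, "scale"))
  }
  attr(out, "transforms") <- transforms
  out
}
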