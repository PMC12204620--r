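# Corpus curation rules and geographic statistics: deduplication, the
# breeding-season filter, per-longitude species proportions, the zone of
# species overlap, hybrid-rate arithmetic, and WGS84 geodesic distances.

#' Deduplicate recordings by (recordist, date, location)
#'
#' Keeps the first occurrence of each (recordist, date, latitude,
#' longitude) key; recordings from the same observer at the same place and
#' date are likely repeated songs of one bird.  A missing recordist is
#' treated as its own distinct key value.
#'
#' @param records data frame with `recordist`, `date`, `latitude`,
#'   `longitude` columns.
#' @return the deduplicated data frame.
#' @export
dedupe_recordings <- function(records) {
  key <- paste(ifelse(is.na(records$recordist), paste0("\rNA",
               seq_len(nrow(records))), records$recordist),
               records$date, records$latitude, records$longitude,
               sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Deduplicate sightings by (date, latitude, longitude)
#'
#' Collapses repeated reports of the same bird: sightings sharing date and
#' exact coordinates count once.
#'
#' @param records data frame with `date`, `latitude`, `longitude`.
#' @return the deduplicated data frame.
#' @export
dedupe_sightings <- function(records) {
  key <- paste(records$date, records$latitude, records$longitude,
               sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Keep breeding-season records (April through August, inclusive)
#'
#' @param records data frame with an ISO-8601 `date` column.
#' @return records whose month is 4--8; unparseable or missing dates are
#'   dropped with a warning.
#' @export
breeding_season_filter <- function(records) {
  d <- as.Date(records$date, format = "%Y-%m-%d")
  bad <- is.na(d)
  if (any(bad))
    warning(sprintf("breeding_season_filter: dropping %d record(s) with %s",
                    sum(bad), "missing/unparseable dates"), call. = FALSE)
  month <- as.integer(format(d, "%m"))
  records[!bad & month >= 4L & month <= 8L, , drop = FALSE]
}

#' Per-longitude species proportions
#'
#' Bins records into half-open integer-degree longitude bins `[d, d + 1)`
#' labeled by their western edge, and computes each species' share of the
#' combined two-species count per bin.  Bins with no records are omitted.
#'
#' @param records data frame with `species` (only `"A"` and `"B"` allowed)
#'   and `longitude`.
#' @param bin_deg bin width in degrees (default 1).
#' @return data frame: `bin` (western edge), `n_A`, `n_B`, `prop_A`,
#'   `prop_B`.
#' @export
species_proportions_by_longitude <- function(records, bin_deg = 1) {
  if (any(!records$species %in% c("A", "B")))
    stop_fmt("species_proportions_by_longitude: records must be species %s",
             "A or B only (exclude hybrid/unsure first)")
  bin <- floor(records$longitude / bin_deg) * bin_deg
  tab <- table(bin = bin, species = factor(records$species,
                                           levels = c("A", "B")))
  bins <- as.numeric(rownames(tab))
  n_a <- as.integer(tab[, "A"]); n_b <- as.integer(tab[, "B"])
  tot <- n_a + n_b
  keep <- tot > 0
  data.frame(bin = bins[keep], n_A = n_a[keep], n_B = n_b[keep],
             prop_A = n_a[keep] / tot[keep], prop_B = n_b[keep] / tot[keep])
}

#' Locate the zone of species overlap along longitude
#'
#' Finds the widest contiguous run of longitude bins in which both species
#' are present with at least `min_count` records and at least `min_prop`
#' of the bin's combined count; ties go to the westernmost run.  The
#' returned eastern bound is the eastern edge of the last qualifying bin
#' (half-open bin arithmetic).
#'
#' @param proportions output of [species_proportions_by_longitude()].
#' @param min_prop minimum per-species proportion for co-occurrence.
#' @param min_count minimum per-species count for co-occurrence.
#' @param bin_deg bin width used to build `proportions`.
#' @return list of class `overlap_zone` with `west_deg`, `east_deg`,
#'   `n_bins`; or `NULL` (with class `no_overlap`) when no bin qualifies.
#' @export
find_overlap_zone <- function(proportions, min_prop = 0.05, min_count = 1,
                              bin_deg = 1) {
  if (nrow(proportions) == 0) stop_fmt("find_overlap_zone: empty table")
  ok_bins <- proportions$bin[proportions$n_A >= min_count &
                               proportions$n_B >= min_count &
                               proportions$prop_A >= min_prop &
                               proportions$prop_B >= min_prop]
  if (length(ok_bins) == 0)
    return(structure(list(west_deg = NA_real_, east_deg = NA_real_,
                          n_bins = 0L), class = "no_overlap"))
  ok_bins <- sort(ok_bins)
  # contiguous runs over the occupied-bin grid
  run_id <- cumsum(c(1, diff(ok_bins) > bin_deg))
  runs <- split(ok_bins, run_id)
  widths <- vapply(runs, length, integer(1))
  best <- runs[[which.max(widths)]]      # which.max: first (westernmost) tie
  structure(list(west_deg = min(best), east_deg = max(best) + bin_deg,
                 n_bins = length(best)),
            class = "overlap_zone")
}

#' Hybridization rate as a percentage
#'
#' @param n_hybrid unique hybrid sightings.
#' @param n_species unique single-species sightings in the same region and
#'   period.
#' @return `100 * n_hybrid / n_species`, rounded to one decimal.
#' @export
hybrid_rate <- function(n_hybrid, n_species) {
  if (n_species <= 0) stop_fmt("hybrid_rate: n_species must be positive")
  round(100 * n_hybrid / n_species, 1)
}

#' Pairwise geodesic distance matrix on the WGS84 ellipsoid
#'
#' Vincenty's inverse formula with WGS84 parameters (a = 6378137 m,
#' f = 1/298.257223563).  Near-antipodal pairs for which the iteration
#' fails to converge fall back to the spherical great-circle distance on
#' the mean-radius sphere (documented approximation, error below 0.6%).
#'
#' @param coords data frame or matrix with `longitude` and `latitude`
#'   columns (decimal degrees, west negative).
#' @return symmetric matrix of distances in meters with a zero diagonal.
#' @export
geodesic_distance_matrix <- function(coords) {
  coords <- as.data.frame(coords)
  lat <- coords$latitude; lon <- coords$longitude
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop_fmt("geodesic_distance_matrix: invalid coordinates")
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <- vincenty_inverse(lat[i], lon[i], lat[j], lon[j])
  }
  d
}

# Vincenty inverse geodesic distance (meters) between two points.
vincenty_inverse <- function(lat1, lon1, lat2, lon2,
                             max_iter = 200L, tol = 1e-12) {
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  rad <- pi / 180
  if (lat1 == lat2 && lon1 == lon2) return(0)
  U1 <- atan((1 - f) * tan(lat1 * rad))
  U2 <- atan((1 - f) * tan(lat2 * rad))
  L <- (lon2 - lon1) * rad
  sU1 <- sin(U1); cU1 <- cos(U1); sU2 <- sin(U2); cU2 <- cos(U2)
  lambda <- L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sl <- sin(lambda); cl <- cos(lambda)
    sin_sigma <- sqrt((cU2 * sl)^2 + (cU1 * sU2 - sU1 * cU2 * cl)^2)
    if (sin_sigma == 0) return(0)
    cos_sigma <- sU1 * sU2 + cU1 * cU2 * cl
    sigma <- atan2(sin_sigma, cos_sigma)
    sin_alpha <- cU1 * cU2 * sl / sin_sigma
    cos2_alpha <- 1 - sin_alpha^2
    cos_2sm <- if (cos2_alpha == 0) 0 else
      cos_sigma - 2 * sU1 * sU2 / cos2_alpha
    C <- f / 16 * cos2_alpha * (4 + f * (4 - 3 * cos2_alpha))
    lambda_new <- L + (1 - C) * f * sin_alpha *
      (sigma + C * sin_sigma *
         (cos_2sm + C * cos_sigma * (-1 + 2 * cos_2sm^2)))
    if (abs(lambda_new - lambda) < tol) {
      lambda <- lambda_new
      converged <- TRUE
      break
    }
    lambda <- lambda_new
  }
  if (!converged) {
    # near-antipodal fallback: great circle on the mean-radius sphere
    R <- (2 * a + b) / 3
    s1 <- lat1 * rad; s2 <- lat2 * rad
    dl <- (lon2 - lon1) * rad
    central <- acos(pmin(1, pmax(-1, sin(s1) * sin(s2) +
                                   cos(s1) * cos(s2) * cos(dl))))
    return(R * central)
  }
  sl <- sin(lambda); cl <- cos(lambda)
  sin_sigma <- sqrt((cU2 * sl)^2 + (cU1 * sU2 - sU1 * cU2 * cl)^2)
  cos_sigma <- sU1 * sU2 + cU1 * cU2 * cl
  sigma <- atan2(sin_sigma, cos_sigma)
  sin_alpha <- cU1 * cU2 * sl / sin_sigma
  cos2_alpha <- 1 - sin_alpha^2
  cos_2sm <- if (cos2_alpha == 0) 0 else
    cos_sigma - 2 * sU1 * sU2 / cos2_alpha
  u2 <- cos2_alpha * (a^2 - b^2) / b^2
  A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
  B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
  delta_sigma <- B * sin_sigma *
    (cos_2sm + B / 4 * (cos_sigma * (-1 + 2 * cos_2sm^2) -
                          B / 6 * cos_2sm * (-3 + 4 * sin_sigma^2) *
                          (-3 + 4 * cos_2sm^2)))
  b * A * (sigma - delta_sigma)
}
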