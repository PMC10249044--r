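#' Species parameters for fertile windows and radii
#'
#' Blue tit females are fertile from 2 days before laying onset, great
#' tits from 5 days before, until the penultimate laying day (one egg per
#' day). The base neighborhood radius is the median nest-to-nest distance
#' of identified extra-pair fathers: 96 m in blue tits, 72 m in great
#' tits; densities are also evaluated at two and three times that radius.
#'
#' @param species "bluetit" or "greattit".
#' @return List with `species`, `fertile_offset` (days), `base_radius`
#'   (m), `multipliers`.
#' @export
species_params <- function(species = c("bluetit", "greattit")) {
  species <- match.arg(species)
  list(
    species = species,
    fertile_offset = c(bluetit = 2, greattit = 5)[[species]],
    base_radius = c(bluetit = 96, greattit = 72)[[species]],
    multipliers = c(1, 2, 3)
  )
}

# spherical transverse Mercator centered on (lon0, lat0); meters
.project_tmerc <- function(lon, lat, lon0, lat0, radius = 6378137) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  b <- cos(phi) * sin(lam)
  x <- radius * atanh(b)
  y <- radius * (atan2(tan(phi), cos(lam)) - phi0)
  cbind(x = x, y = y)
}

#' Pairwise nest distances in meters
#'
#' Metric coordinates (`x`, `y`) are used directly (Euclidean).
#' Geographic coordinates (`lon`, `lat`) are first projected to a local
#' transverse-Mercator frame centered on the site centroid. Mixing the
#' two systems is an error.
#'
#' @param records nest tibble with `nest_id` and either `x`/`y` (meters)
#'   or `lon`/`lat` (degrees).
#' @return Symmetric distance matrix (m) with nest ids as dimnames.
#' @export
pairwise_distances <- function(records) {
  records <- as_tibble(records)
  has_xy <- all(c("x", "y") %in% names(records)) &&
    !all(is.na(records$x))
  has_ll <- all(c("lon", "lat") %in% names(records)) &&
    !all(is.na(records[["lon"]]))
  if (has_xy && has_ll) abort("mixed coordinate systems: give x/y or lon/lat, not both")
  if (!has_xy && !has_ll) abort("no coordinates found (need x/y or lon/lat)")
  if (has_xy) {
    xy <- cbind(records$x, records$y)
  } else {
    xy <- .project_tmerc(records$lon, records$lat,
                         mean(records$lon), mean(records$lat))
  }
  if (any(!is.finite(xy))) abort("non-finite coordinates")
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(records$nest_id, records$nest_id)
  d
}

# same-species, same-year nests other than the focal one
.conspecifics <- function(focal, records) {
  frow <- records[records$nest_id == focal, ]
  if (nrow(frow) != 1) abort(sprintf("unknown focal nest %s", focal))
  records[records$species == frow$species & records$year == frow$year &
            records$nest_id != focal, ]
}

#' Nearest conspecific neighbor distance
#'
#' Distance (m) to the nearest active same-species nest in the same year.
#' Both plots are eligible; the smaller distance wins.
#'
#' @param focal nest id.
#' @param records nest tibble (see [pairwise_distances()]).
#' @param dmat optional precomputed distance matrix.
#' @return Distance in meters; `NA` (with a warning) when the focal nest
#'   has no conspecific neighbor that year.
#' @export
nearest_neighbor_distance <- function(focal, records, dmat = NULL) {
  if (is.null(dmat)) dmat <- pairwise_distances(records)
  others <- .conspecifics(focal, records)
  if (!nrow(others)) {
    warn(sprintf("nest %s has no conspecific neighbor", focal))
    return(NA_real_)
  }
  min(dmat[focal, others$nest_id])
}

#' Fertile window of a breeding attempt
#'
#' Closed integer interval (day-of-year): from `laying_date - offset`
#' (species-specific) to the penultimate laying day,
#' `laying_date + clutch_size - 2`, assuming one egg per day.
#'
#' @param params a [species_params()] list.
#' @param laying_date integer day-of-year of the first egg.
#' @param clutch_size number of eggs (>= 1). A clutch of 1 yields a
#'   window ending the day before laying; the formula is kept as-is and
#'   the case is flagged with a warning.
#' @return Integer vector `c(start, end)` (vectorized: a 2-column matrix
#'   for vector input).
#' @export
fertile_window <- function(params, laying_date, clutch_size) {
  if (any(clutch_size < 1)) abort("clutch size must be >= 1")
  if (any(clutch_size == 1))
    warn("clutch of 1: fertile window ends before laying begins")
  start <- laying_date - params$fertile_offset
  end <- laying_date + clutch_size - 2
  if (length(laying_date) == 1) c(start = start, end = end)
  else cbind(start = start, end = end)
}

#' Conspecific neighbor density
#'
#' Number of other same-species, same-year nests within `radius` meters
#' of the focal nest (focal excluded; both plots eligible).
#'
#' @inheritParams nearest_neighbor_distance
#' @param radius radius in meters (> 0).
#' @return Integer count.
#' @export
neighbor_density <- function(focal, records, radius, dmat = NULL) {
  if (radius <= 0) abort("radius must be > 0")
  if (is.null(dmat)) dmat <- pairwise_distances(records)
  others <- .conspecifics(focal, records)
  if (!nrow(others)) return(0L)
  sum(dmat[focal, others$nest_id] <= radius)
}

#' Synchronous neighbor density
#'
#' Among the neighbors counted by [neighbor_density()], those whose
#' fertile window shares at least one day with the focal female's window.
#' Overlap is inclusive of endpoints: windows touching on a single day
#' count as synchronous (set `inclusive = FALSE` for the exclusive
#' convention).
#'
#' @inheritParams neighbor_density
#' @param params a [species_params()] list for the focal species.
#' @param inclusive closed-interval overlap (default `TRUE`).
#' @return Integer count (never exceeds [neighbor_density()]).
#' @export
synchronous_neighbor_density <- function(focal, records, radius, params,
                                         inclusive = TRUE, dmat = NULL) {
  if (radius <= 0) abort("radius must be > 0")
  if (is.null(dmat)) dmat <- pairwise_distances(records)
  frow <- records[records$nest_id == focal, ]
  others <- .conspecifics(focal, records)
  if (!nrow(others)) return(0L)
  others <- others[dmat[focal, others$nest_id] <= radius, , drop = FALSE]
  if (!nrow(others)) return(0L)
  fw <- fertile_window(params, frow$laying_date, frow$clutch_size)
  nw <- fertile_window(params, others$laying_date, others$clutch_size)
  if (is.null(dim(nw))) nw <- matrix(nw, ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (inclusive)
    sum(nw[, "start"] <= fw["end"] & nw[, "end"] >= fw["start"])
  else
    sum(nw[, "start"] < fw["end"] & nw[, "end"] > fw["start"])
}

#' Per-nest spatiotemporal metrics table
#'
#' Nearest-neighbor distance plus neighbor density and synchronous
#' neighbor density at each radius, computed per species and year
#' separately.
#'
#' @param records nest tibble with `nest_id`, `species`, `year`,
#'   coordinates, `laying_date`, `clutch_size`.
#' @param radii named or unnamed numeric vector of radii (m); defaults to
#'   each species' [species_params()] base radius times 1, 2, 3.
#' @param inclusive overlap convention passed to
#'   [synchronous_neighbor_density()].
#' @return Tibble: `nest_id`, `nnd`, and `nd_<radius>` / `snd_<radius>`
#'   columns.
#' @export
spatiotemporal_metrics <- function(records, radii = NULL, inclusive = TRUE) {
  records <- as_tibble(records)
  dmat <- pairwise_distances(records)
  purrr::map(split(records, ~ paste(species, year)), function(grp) {
    sp <- grp$species[1]
    params <- species_params(sp)
    rr <- radii %||% (params$base_radius * params$multipliers)
    rows <- purrr::map(grp$nest_id, function(nid) {
      out <- tibble(nest_id = nid,
                    nnd = suppressWarnings(
                      nearest_neighbor_distance(nid, records, dmat)))
      for (r in rr) {
        out[[paste0("nd_", r)]] <- neighbor_density(nid, records, r, dmat)
        out[[paste0("snd_", r)]] <-
          synchronous_neighbor_density(nid, records, r, params, inclusive, dmat)
      }
      out
    })
    bind_rows(rows)
  }) %>% bind_rows()
}

#' Derive neighborhood radii from extra-pair-father link distances
#'
#' The base radius is the median distance between an extra-pair father's
#' own nest and the nest where he sired offspring (even-count sets take
#' the mean of the middle two); the returned radii are the base times
#' each multiplier.
#'
#' @param link_distances numeric vector of EPF nest-to-nest distances (m).
#' @param multipliers numeric vector (default `c(1, 2, 3)`).
#' @param fallback radii to return (with a warning) when no link
#'   distances are available.
#' @return Numeric vector of radii with a `base` attribute.
#' @export
derive_radii <- function(link_distances, multipliers = c(1, 2, 3),
                         fallback = NULL) {
  link_distances <- link_distances[!is.na(link_distances)]
  if (!length(link_distances)) {
    if (is.null(fallback)) abort("no EPF link distances and no fallback radii")
    warn("no EPF link distances: using fallback radii")
    return(fallback)
  }
  base <- median(link_distances)
  structure(base * multipliers, base = base)
}

#' Distances of extra-pair-father links
#'
#' For each link, the distance between the male's own (social) nest and
#' the nest where he sired the offspring.
#'
#' @param epf_links tibble `male`, `offspring` from
#'   [find_extra_pair_fathers()].
#' @param ped a `social_pedigree` (locates the offspring's natal nest).
#' @param records nest tibble (locates the male's social nest via
#'   `father_id` and supplies coordinates).
#' @return `epf_links` with columns `male_nest`, `offspring_nest`,
#'   `distance`.
#' @export
epf_link_distances <- function(epf_links, ped, records) {
  records <- as_tibble(records)
  dmat <- pairwise_distances(records)
  male_nest <- records %>% select(male = "father_id", male_nest = "nest_id") %>%
    filter(!is.na(.data$male)) %>% distinct(.data$male, .keep_all = TRUE)
  off_nest <- ped %>% select(offspring = "id", offspring_nest = "natal_nest")
  out <- epf_links %>%
    left_join(male_nest, by = "male") %>%
    left_join(off_nest, by = "offspring")
  out$distance <- ifelse(
    is.na(out$male_nest) | is.na(out$offspring_nest), NA_real_,
    dmat[cbind(out$male_nest, out$offspring_nest)]
  )
  out
}
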