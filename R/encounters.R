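#' Read raw sighting records into encounter records
#'
#' Reads a sighting table (CSV or XLSX) and standardizes it into one
#' encounter record per row: date, time, position, the set of
#' photo-identified individuals present, reported group size, and whether
#' every member of the group was identified. Rows with unparseable dates or
#' out-of-range coordinates are rejected and reported via the
#' \code{"rejections"} attribute of the result, never silently dropped.
#'
#' @param path path to a CSV (RFC 4180) or XLSX file.
#' @param schema named list mapping the required logical fields
#'   \code{date}, \code{lat}, \code{lon}, \code{ids}, \code{group_size}
#'   (and optionally \code{time}, \code{source}, \code{all_identified},
#'   \code{encounter_id}) to column names in the file.
#' @param delim delimiter separating individual ids within the ids cell.
#' @param date_format strptime format for dates; default ISO-8601.
#' @return data.frame of encounter records with columns
#'   \code{encounter_id}, \code{date} (Date), \code{time} (character),
#'   \code{lon}, \code{lat}, \code{source}, \code{individuals}
#'   (list column of character vectors), \code{group_size},
#'   \code{all_identified}; rejected rows (with a \code{reason} column)
#'   are attached as \code{attr(x, "rejections")}.
#' @export
read_encounters <- function(path, schema = list(date = "date", lat = "lat",
                                                lon = "lon", ids = "ids",
                                                group_size = "group_size"),
                            delim = ";", date_format = "%Y-%m-%d") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty input: ", path)

  required <- c("date", "lat", "lon", "ids", "group_size")
  missing_keys <- setdiff(required, names(schema))
  if (length(missing_keys))
    stop("schema missing required field(s): ", paste(missing_keys, collapse = ", "))
  for (key in names(schema)) {
    if (!schema[[key]] %in% names(raw))
      stop("missing required column: '", schema[[key]], "' (schema field '", key, "')")
  }

  date <- as.Date(as.character(raw[[schema$date]]), format = date_format)
  lat <- suppressWarnings(as.numeric(raw[[schema$lat]]))
  lon <- suppressWarnings(as.numeric(raw[[schema$lon]]))
  ids <- .split_ids(raw[[schema$ids]], delim = delim)
  gs <- suppressWarnings(as.integer(raw[[schema$group_size]]))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(reason) & (is.na(lat) | is.na(lon))] <- "unparseable coordinates"
  reason[is.na(reason) & (lat < -90 | lat > 90 | lon < -180 | lon > 180)] <-
    "coordinates out of bounds"
  reason[is.na(reason) & lengths(ids) == 0L] <- "no individual ids"

  eid <- if (!is.null(schema$encounter_id)) as.character(raw[[schema$encounter_id]])
         else sprintf("row%04d", seq_len(nrow(raw)))
  tm <- if (!is.null(schema$time)) as.character(raw[[schema$time]]) else NA_character_
  src <- if (!is.null(schema$source)) as.character(raw[[schema$source]])
         else "opportunistic"
  all_id <- if (!is.null(schema$all_identified)) {
    v <- raw[[schema$all_identified]]
    if (is.logical(v)) v else tolower(as.character(v)) %in% c("true", "t", "1", "yes")
  } else lengths(ids) == gs

  keep <- is.na(reason)
  records <- data.frame(
    encounter_id = eid[keep], date = date[keep], time = tm[keep],
    lon = lon[keep], lat = lat[keep], source = src[keep],
    group_size = gs[keep], all_identified = all_id[keep],
    stringsAsFactors = FALSE
  )
  records$individuals <- ids[keep]
  bad <- which(!keep)
  rejections <- data.frame(row = bad, reason = reason[bad], stringsAsFactors = FALSE)
  attr(records, "rejections") <- rejections
  records
}

#' Consolidate sighting records into daily encounters
#'
#' Reduces same-day resights of the same group to a single sampling unit.
#' Within each calendar date, records are processed in ascending time order
#' (missing times last, input order preserved among ties); a record is
#' dropped when its individual set is equal to, or a subset of, a set
#' already retained that day, so the retained record keeps the first
#' sighting location. Same-day groups that are not subsets of one another
#' are kept as distinct encounters.
#'
#' @param records encounter data.frame as returned by [read_encounters()]
#'   or [simulate_encounters()].
#' @return the retained records, with a \code{"provenance"} attribute:
#'   a named list mapping each retained encounter_id to the encounter_ids
#'   it absorbed (empty character vector when none).
#' @export
consolidate_daily <- function(records) {
  stopifnot(is.data.frame(records), "individuals" %in% names(records))
  if (nrow(records) == 0L) {
    attr(records, "provenance") <- setNames(list(), character(0))
    return(records)
  }
  tmin <- .time_minutes(records$time)
  tmin[is.na(tmin)] <- Inf
  ord <- order(records$date, tmin)  # stable: ties keep input order
  keep <- logical(nrow(records))
  provenance <- list()
  for (day_idx in split(ord, as.character(records$date[ord]))) {
    retained <- integer(0)
    for (i in day_idx) {
      set_i <- records$individuals[[i]]
      absorbed_by <- 0L
      for (j in retained) {
        if (all(set_i %in% records$individuals[[j]])) { absorbed_by <- j; break }
      }
      if (absorbed_by > 0L) {
        key <- records$encounter_id[absorbed_by]
        provenance[[key]] <- c(provenance[[key]], records$encounter_id[i])
      } else {
        retained <- c(retained, i)
        keep[i] <- TRUE
        provenance[[records$encounter_id[i]]] <- character(0)
      }
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance[out$encounter_id]
  out
}

#' Filter daily encounters for network analysis
#'
#' Applies the two study inclusion rules: encounters where not every group
#' member was photo-identified are excluded entirely, and individuals
#' identified fewer than \code{min_sightings} times (counted once, in a
#' single pass over the remaining encounters) are masked from association
#' counting. Encounters containing masked individuals are kept, so that
#' associations among the retained individuals present are not lost.
#'
#' @param records daily-consolidated encounter data.frame.
#' @param min_sightings minimum number of daily encounters an individual
#'   must appear in to enter the network (default 3).
#' @return list with \code{records} (fully identified encounters),
#'   \code{retained_ids}, \code{excluded_ids}, and \code{counts}
#'   (named sighting counts over the fully identified encounters).
#' @export
filter_for_network <- function(records, min_sightings = 3) {
  stopifnot(is.data.frame(records), "individuals" %in% names(records))
  recs <- records[records$all_identified %in% TRUE, , drop = FALSE]
  counts <- table(unlist(recs$individuals))
  counts <- setNames(as.integer(counts), names(counts))
  retained <- names(counts)[counts >= min_sightings]
  excluded <- setdiff(names(counts), retained)
  if (length(retained) == 0L)
    stop("empty network: no individual reaches ", min_sightings, " sightings")
  rownames(recs) <- NULL
  list(records = recs, retained_ids = sort(retained),
       excluded_ids = sort(excluded), counts = counts)
}
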