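## Reading, validation and standardization of study and calibration data.
##
## On-disk formats:
##   study CSV:     site_id,set,work,dist,tree_1995,tree_2008,y_1995,y_2008,y_2009
##   detection CSV: site_id,count_1,count_2,count_3,count_4
## Empty cells encode missing values: a 0 is a survey that saw no birds,
## the absence of a survey is not.

STUDY_COLUMNS <- c("site_id", "set", "work", "dist", "tree_1995",
                   "tree_2008", "y_1995", "y_2008", "y_2009")
DETECTION_COLUMNS <- c("site_id", "count_1", "count_2", "count_3", "count_4")

#' Center and scale a covariate by twice its standard deviation
#'
#' Covariates are centered at the sample mean and divided by two sample
#' standard deviations, so that effect sizes of continuous and binary
#' covariates are directly comparable: a coefficient then measures the
#' change over a 2-SD span of the covariate, roughly its "low to high"
#' range.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return An object of class `scaled_covariate`: a list with `values`
#'   (the scaled vector, mean 0, sd 0.5), `center` (sample mean) and
#'   `scale` (twice the sample standard deviation, n-1 denominator).
#' @examples
#' standardize(c(1, 2, 3))$values  # -0.5, 0, 0.5
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop("standardize() needs a numeric vector of length >= 2", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("standardize() does not accept missing values", call. = FALSE)
  }
  s <- sd(values)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate scale: covariate is constant (sd = 0)", call. = FALSE)
  }
  ctr <- mean(values)
  structure(
    list(values = (values - ctr) / (2 * s), center = ctr, scale = 2 * s),
    class = "scaled_covariate"
  )
}

## Apply previously computed scaling constants to new values.
scale_with <- function(x, scaling) {
  (x - scaling$center) / scaling$scale
}

#' Assemble and validate a study dataset
#'
#' Bundles the per-site survey table, the optional repeated-count
#' detection-calibration table, and the covariate-scaling constants that
#' make "a site with average covariates" well defined downstream.
#'
#' Site strata encode detection history: `SET1` sites had a group detected
#' in the initial 1995 survey (so occupancy in 1995 is known), `SET2`
#' sites were detected only in later years, and `SET3` sites were surveyed
#' in 2008 and 2009 only and carry no distance/tree covariates.
#'
#' Tree densities from both eras are pooled into a single scaling because
#' the model fits one large-tree coefficient across eras; both columns
#' must therefore be on one scale.
#'
#' @param sites data.frame with columns
#'   `site_id,set,work,dist,tree_1995,tree_2008,y_1995,y_2008,y_2009`.
#' @param detection optional data.frame with columns
#'   `site_id,count_1..count_4`.
#' @param validate enforce the stratum invariants (recommended).
#' @param max_count biological cap on a single count; groups larger than
#'   this are treated as data errors.
#' @param require_set1_detection enforce `y_1995 >= 1` for SET1 sites.
#'   Unconditioned simulations from the fitted model can produce a zero
#'   count at a SET1 site and may switch this off.
#' @return object of class `study_dataset` with elements `sites`,
#'   `detection` and `scaling`.
#' @export
study_dataset <- function(sites, detection = NULL, validate = TRUE,
                          max_count = 12, require_set1_detection = TRUE) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  missing_cols <- setdiff(STUDY_COLUMNS, names(sites))
  if (length(missing_cols)) {
    stop("study table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sites <- sites[STUDY_COLUMNS]
  if (!is.null(detection)) {
    detection <- as.data.frame(detection, stringsAsFactors = FALSE)
    missing_cols <- setdiff(DETECTION_COLUMNS, names(detection))
    if (length(missing_cols)) {
      stop("detection table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    detection <- detection[DETECTION_COLUMNS]
  }
  if (validate) {
    validate_sites(sites, max_count = max_count,
                   require_set1_detection = require_set1_detection)
    if (!is.null(detection)) validate_detection(detection)
  }
  structure(
    list(sites = sites, detection = detection,
         scaling = compute_scaling(sites)),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  tab <- table(factor(x$sites$set, levels = c("SET1", "SET2", "SET3")))
  cat("study_dataset:", nrow(x$sites), "sites (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  if (!is.null(x$detection)) {
    cat("  detection study:", nrow(x$detection), "sites x",
        ncol(x$detection) - 1L, "visits\n")
  }
  if (!is.null(x$scaling)) {
    cat(sprintf("  scaling: dist center %.1f scale %.1f; tree center %.2f scale %.2f\n",
                x$scaling$dist$center, x$scaling$dist$scale,
                x$scaling$tree$center, x$scaling$tree$scale))
  }
  invisible(x)
}

## Scaling constants from the dataset itself. Trees from the two eras are
## pooled (one coefficient, one scale); SET3 sites carry no covariates.
compute_scaling <- function(sites) {
  non3 <- sites$set != "SET3"
  if (sum(non3) < 2) return(NULL)
  tree_pool <- c(sites$tree_1995[non3], sites$tree_2008[non3])
  dist_sc <- tryCatch(standardize(sites$dist[non3]),
                      error = function(e) NULL)
  tree_sc <- tryCatch(standardize(tree_pool), error = function(e) NULL)
  if (is.null(dist_sc) || is.null(tree_sc)) return(NULL)
  list(dist = list(center = dist_sc$center, scale = dist_sc$scale),
       tree = list(center = tree_sc$center, scale = tree_sc$scale))
}

is_count <- function(x) is.finite(x) & x >= 0 & x == floor(x)

validate_sites <- function(sites, max_count = 12,
                           require_set1_detection = TRUE) {
  fail <- function(id, msg) {
    stop(sprintf("site '%s': %s", id, msg), call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (r in seq_len(nrow(sites))) {
    s <- sites[r, ]
    id <- s$site_id
    if (!s$set %in% c("SET1", "SET2", "SET3")) {
      fail(id, paste0("unknown set '", s$set, "'"))
    }
    if (!s$work %in% c(0, 1)) fail(id, "work must be 0 or 1")
    for (col in c("y_1995", "y_2008", "y_2009")) {
      y <- s[[col]]
      if (!is.na(y) && (!is_count(y) || y > max_count)) {
        fail(id, sprintf("%s = %s is not an integer in [0, %d]",
                         col, format(y), max_count))
      }
    }
    if (s$set == "SET3") {
      if (!is.na(s$y_1995)) fail(id, "SET3 sites have no 1995 survey")
      if (is.na(s$y_2008) || s$y_2008 < 1) {
        fail(id, "SET3 sites were known occupied in 2008 (y_2008 >= 1 required)")
      }
      if (is.na(s$y_2009)) fail(id, "SET3 sites require a 2009 count")
      if (!is.na(s$dist) || !is.na(s$tree_1995) || !is.na(s$tree_2008)) {
        fail(id, "SET3 sites carry no dist/tree covariates")
      }
    } else {
      if (is.na(s$dist) || s$dist < 0) fail(id, "dist must be present and >= 0")
      for (col in c("tree_1995", "tree_2008")) {
        if (is.na(s[[col]]) || !is_count(s[[col]])) {
          fail(id, paste(col, "must be a present non-negative integer"))
        }
      }
      if (!is.na(s$y_2009)) fail(id, "2009 surveys were confined to SET3 sites")
      if (s$set == "SET1") {
        if (is.na(s$y_1995)) fail(id, "SET1 requires a 1995 count")
        if (require_set1_detection && s$y_1995 < 1) {
          fail(id, "SET1 sites were detected in 1995 (y_1995 >= 1 required)")
        }
      } else {
        if (!is.na(s$y_1995)) fail(id, "SET2 sites had no 1995 detection")
      }
    }
  }
  invisible(TRUE)
}

validate_detection <- function(detection) {
  if (anyDuplicated(detection$site_id)) {
    stop("duplicated detection site_id", call. = FALSE)
  }
  for (r in seq_len(nrow(detection))) {
    counts <- as.numeric(detection[r, DETECTION_COLUMNS[-1]])
    if (anyNA(counts) || !all(is_count(counts))) {
      stop(sprintf("detection site '%s': all four visit counts must be non-negative integers",
                   detection$site_id[r]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

read_numeric_column <- function(raw, col, path) {
  x <- raw[[col]]
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: cannot parse %s = '%s' on data line %d",
                 path, col, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Read a study dataset from CSV
#'
#' @param path study CSV (see [study_dataset()] for the column contract).
#' @param detection_path optional repeated-count calibration CSV.
#' @inheritParams study_dataset
#' @return a `study_dataset`.
#' @export
read_study <- function(path, detection_path = NULL, validate = TRUE,
                       max_count = 12, require_set1_detection = TRUE) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(STUDY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sites <- data.frame(site_id = raw$site_id, set = raw$set,
                      stringsAsFactors = FALSE)
  for (col in STUDY_COLUMNS[-(1:2)]) {
    sites[[col]] <- read_numeric_column(raw, col, path)
  }
  detection <- if (!is.null(detection_path)) {
    read_detection(detection_path)
  }
  study_dataset(sites, detection, validate = validate, max_count = max_count,
                require_set1_detection = require_set1_detection)
}

#' @rdname read_study
#' @export
read_detection <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(DETECTION_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  det <- data.frame(site_id = raw$site_id, stringsAsFactors = FALSE)
  for (col in DETECTION_COLUMNS[-1]) {
    det[[col]] <- read_numeric_column(raw, col, path)
  }
  det
}

format_csv_cell <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- ""
  out
}

write_plain_csv <- function(df, path) {
  con <- file(path, open = "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(capture_table(df), con)
  invisible(path)
}

#' Write a study dataset to CSV
#'
#' Writes the study table in canonical column order plus a JSON metadata
#' sidecar (`<path>.json`) carrying the covariate-scaling constants and,
#' when present, the generator seed. Missing values become empty cells.
#'
#' @param dataset a `study_dataset`.
#' @param path output CSV path.
#' @param detection_path optional path for the detection table.
#' @param sidecar write the JSON metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_study <- function(dataset, path, detection_path = NULL, sidecar = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  write_plain_csv(dataset$sites, path)
  if (!is.null(detection_path) && !is.null(dataset$detection)) {
    write_plain_csv(dataset$detection, detection_path)
  }
  if (sidecar) {
    meta <- list(scaling = dataset$scaling,
                 n_sites = nrow(dataset$sites),
                 seed = attr(dataset, "seed"))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Pick the large-tree covariate for a survey year
#'
#' Large-tree density was assessed in both survey eras; the 1995 density
#' applies to the 1995 surveys and the 2008 density to the 2008 and 2009
#' surveys. SET3 sites carry no habitat covariates.
#'
#' @param site one-row data.frame or list with `set`, `tree_1995`,
#'   `tree_2008`.
#' @param year one of 1995, 2008, 2009.
#' @return the tree density for that year's survey.
#' @export
covariate_for_year <- function(site, year) {
  year <- as.integer(year)
  if (!year %in% c(1995L, 2008L, 2009L)) {
    stop("year must be 1995, 2008 or 2009", call. = FALSE)
  }
  if (identical(site$set, "SET3")) {
    stop("SET3 sites have no covariate information", call. = FALSE)
  }
  if (year == 1995L) site$tree_1995 else site$tree_2008
}

## Order-independent FNV-1a style fingerprint of the dataset content,
## so artifacts can state which data they were computed from.
dataset_fingerprint <- function(dataset) {
  txt <- paste(
    paste(capture_table(dataset$sites), collapse = "\n"),
    if (!is.null(dataset$detection)) {
      paste(capture_table(dataset$detection), collapse = "\n")
    } else "",
    sep = "\n"
  )
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

capture_table <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  m <- vapply(df, format_csv_cell, character(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L)
  apply(m, 1L, paste, collapse = ",")
}
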