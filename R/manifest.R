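#' @name cohort_manifest
#' @title The cohort manifest
#'
#' @description
#' A cohort is described by a single delimited text file with one row per
#' acquired frame; per-embryo metadata (clinic, oocyte age, KID tag, ...) is
#' repeated on every row of that embryo. Columns:
#'
#' * `embryo_id` — unique embryo identifier (string)
#' * `clinic` — collection centre (string, free text)
#' * `oocyte_age_years` — age of the egg donor in years
#' * `kid_tag` — one of `KIDp`, `KIDn`, `KIDu`, `notKID`
#' * `ploidy_tag` — one of `euploid`, `aneuploid`, `none`
#' * `hard_discarded` — logical; discarded embryo that reached blastocyst
#' * `split` — one of `train`, `val`, `test` (constant within an embryo)
#' * `t_hours` — hours post fertilization of the frame (>= 0)
#' * `focal_index` — z-stack plane, integer in 0..6 (3 = central, 0 um)
#' * `image_path` — path to a grayscale raster (PNG or TIFF)
#' * `mask_path` — optional path to a binary embryo mask (empty if absent)
#'
#' Invariants enforced by [validate_manifest()]: known enum values, unique
#' (embryo, focal, t) triples with strictly increasing `t_hours` per focal
#' plane, per-embryo-constant metadata, `hard_discarded` only on `notKID`
#' embryos, and no embryo in more than one split.
NULL

MANIFEST_COLUMNS <- c(
  "embryo_id", "clinic", "oocyte_age_years", "kid_tag", "ploidy_tag",
  "hard_discarded", "split", "t_hours", "focal_index", "image_path",
  "mask_path"
)

#' Read a cohort manifest
#'
#' @param path path to a manifest CSV (see [cohort_manifest]).
#' @return a validated `data.frame` of class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing)) {
    stop("manifest schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df <- df[MANIFEST_COLUMNS]
  df$oocyte_age_years <- as.numeric(df$oocyte_age_years)
  df$t_hours <- as.numeric(df$t_hours)
  df$focal_index <- as.integer(df$focal_index)
  df$hard_discarded <- as.logical(df$hard_discarded)
  df$mask_path[is.na(df$mask_path)] <- ""
  validate_manifest(df)
  as_manifest(df)
}

#' Write a cohort manifest
#'
#' Field-lossless inverse of [read_manifest()]: `read_manifest(write_manifest(m))`
#' recovers every field, including non-ASCII clinic names.
#'
#' @param manifest a valid manifest `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  df <- as.data.frame(manifest)[MANIFEST_COLUMNS]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

as_manifest <- function(df) {
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Validate a cohort manifest
#'
#' Checks the schema and the structural invariants of the frame table
#' (see [cohort_manifest]). Fails with an informative error on the first
#' violated invariant.
#'
#' @param manifest a manifest `data.frame`.
#' @return `TRUE`, invisibly, if valid.
#' @export
validate_manifest <- function(manifest) {
  df <- as.data.frame(manifest)
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing)) {
    stop("manifest schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(invisible(TRUE))
  bad <- setdiff(unique(df$kid_tag), KID_TAGS)
  if (length(bad)) stop("unknown kid_tag value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$ploidy_tag), PLOIDY_TAGS)
  if (length(bad)) stop("unknown ploidy_tag value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$split), c("train", "val", "test"))
  if (length(bad)) stop("unknown split value(s): ", paste(bad, collapse = ", "))
  if (any(!df$focal_index %in% 0:6)) stop("focal_index must lie in 0..6")
  if (any(df$t_hours < 0)) stop("t_hours must be >= 0")

  # per-embryo-constant metadata and split integrity
  meta_cols <- c("clinic", "oocyte_age_years", "kid_tag", "ploidy_tag",
                 "hard_discarded", "split")
  for (col in meta_cols) {
    n_per <- tapply(df[[col]], df$embryo_id, function(x) length(unique(x)))
    if (any(n_per > 1L)) {
      stop("embryo metadata column '", col, "' varies within an embryo",
           if (col == "split") " (split integrity violated)" else "")
    }
  }
  emb <- embryo_table(as_manifest(df))
  if (anyDuplicated(emb$embryo_id)) stop("duplicate embryo_id in embryo table")
  if (any(emb$hard_discarded & emb$kid_tag != "notKID")) {
    stop("hard_discarded embryos must carry kid_tag notKID")
  }
  key <- paste(df$embryo_id, df$focal_index, df$t_hours)
  if (anyDuplicated(key)) {
    stop("duplicate (embryo, focal, t_hours) frame rows")
  }
  # strictly increasing timestamps per embryo x focal (as ordered in file)
  by_ef <- split(df$t_hours, paste(df$embryo_id, df$focal_index))
  if (any(vapply(by_ef, function(t) any(diff(t) <= 0), logical(1)))) {
    stop("t_hours must be strictly increasing within an embryo per focal plane")
  }
  invisible(TRUE)
}

#' Per-embryo metadata table
#'
#' Collapses the frame-level manifest to one row per embryo.
#'
#' @param manifest a manifest `data.frame`.
#' @return `data.frame` with one row per embryo: `embryo_id`, `clinic`,
#'   `oocyte_age_years`, `kid_tag`, `ploidy_tag`, `hard_discarded`, `split`,
#'   `n_frames`.
#' @export
embryo_table <- function(manifest) {
  df <- as.data.frame(manifest)
  first <- !duplicated(df$embryo_id)
  out <- df[first, c("embryo_id", "clinic", "oocyte_age_years", "kid_tag",
                     "ploidy_tag", "hard_discarded", "split")]
  out$n_frames <- as.integer(table(df$embryo_id)[out$embryo_id])
  rownames(out) <- NULL
  out
}

#' Numeric KID label
#'
#' Encodes the supervision signal: +1 for KIDp, -1 for KIDn, `NA` for KIDu
#' and notKID (unlabeled). Only the "is KIDp" property is ever needed to
#' protect positives in pseudo-labeling, so unlabeled embryos need no
#' distinct negative code.
#'
#' @param kid_tag character vector of KID tags.
#' @return numeric vector in \{-1, +1, NA\}.
#' @export
kid_label <- function(kid_tag) {
  bad <- setdiff(unique(kid_tag), KID_TAGS)
  if (length(bad)) stop("unknown kid_tag value(s): ", paste(bad, collapse = ", "))
  ifelse(kid_tag == "KIDp", 1, ifelse(kid_tag == "KIDn", -1, NA_real_))
}

#' Load one frame (image + optional mask) from disk
#'
#' Reads a grayscale raster and, when present, its binary mask. Intensities
#' are normalized to \[0, 1\]; masks are binarized to \{0, 1\}. Multi-channel
#' images are rejected rather than silently averaged.
#'
#' @param image_path path to an 8- or 16-bit single-channel PNG or TIFF.
#' @param mask_path optional mask path (`NULL`, `NA` or `""` for absent).
#' @return list with `image` (numeric matrix in \[0,1\]) and `mask`
#'   (0/1 matrix of the same dimensions, or `NULL`).
#' @export
load_frame <- function(image_path, mask_path = NULL) {
  img <- read_gray(image_path)
  mask <- NULL
  if (!is.null(mask_path) && !is.na(mask_path) && nzchar(mask_path)) {
    mask <- read_gray(mask_path)
    if (!identical(dim(mask), dim(img))) {
      stop("image and mask dimensions differ: ", paste(dim(img), collapse = "x"),
           " vs ", paste(dim(mask), collapse = "x"))
    }
    mask <- (mask > 0.5) + 0
  }
  list(image = img, mask = mask)
}

read_gray <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF images")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  )
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1]
    } else {
      stop("multi-channel image rejected (single-channel grayscale expected): ",
           path)
    }
  }
  x <- pmin(pmax(x, 0), 1)
  x
}

write_gray_png <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}
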