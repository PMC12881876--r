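#' Assemble a suture study table
#'
#' The central container of the package is an ordinary tibble with one row per
#' specimen. Geometry travels in list-columns so the whole pipeline chains with
#' the pipe:
#'
#' * `landmarks`: a k x 3 matrix of fixed landmarks per specimen (missing
#'   landmarks as `NA` rows; the file sentinel 9999 is converted on read),
#' * `curves`: a named list of ordered point matrices, one per suture
#'   (`interfrontal`, `sagittal`, `coronal`).
#'
#' Metadata columns (`specimen_id`, `species`, `clade`, `age_category`,
#' `developmental_mode`, `diet`) are plain vectors. The indices of the three
#' midline landmarks that define the midsagittal plane are stored in the
#' `midline` attribute.
#'
#' @param meta data frame of specimen metadata; must contain `specimen_id`.
#' @param landmarks list of k x 3 numeric matrices, one per specimen.
#' @param curves list (one element per specimen) of named lists of point
#'   matrices keyed by suture name.
#' @param midline integer vector of 3 landmark indices (1-based) spanning the
#'   midsagittal plane.
#' @return a `suture_study` tibble.
#' @export
suture_study <- function(meta, landmarks, curves, midline = c(1L, 2L, 3L)) {
  meta <- tibble::as_tibble(meta)
  if (!"specimen_id" %in% names(meta)) {
    stop("metadata must contain a 'specimen_id' column", call. = FALSE)
  }
  if (length(landmarks) != nrow(meta) || length(curves) != nrow(meta)) {
    stop("landmarks and curves must have one entry per metadata row", call. = FALSE)
  }
  midline <- as.integer(midline)
  if (length(midline) != 3L || anyDuplicated(midline) > 0) {
    stop("midline must be 3 distinct landmark indices", call. = FALSE)
  }
  out <- meta
  out$landmarks <- unname(lapply(landmarks, function(m) {
    m <- as.matrix(m)
    m[is_missing_row(m), ] <- NA_real_
    unname(m)
  }))
  out$curves <- unname(lapply(curves, function(cl) cl[intersect(SUTURE_NAMES, names(cl))]))
  attr(out, "midline") <- midline
  class(out) <- c("suture_study", class(out))
  out
}

study_midline <- function(study) {
  ml <- attr(study, "midline", exact = TRUE)
  if (is.null(ml)) c(1L, 2L, 3L) else ml
}

# Keep the class/attributes through dplyr verbs used internally.
restore_study <- function(new, old) {
  attr(new, "midline") <- study_midline(old)
  for (a in c("consensus", "gpa", "sliding_energy")) {
    if (!is.null(attr(old, a, exact = TRUE))) attr(new, a) <- attr(old, a, exact = TRUE)
  }
  if (!inherits(new, "suture_study")) class(new) <- c("suture_study", class(new))
  new
}

#' Relative developmental age from centroid size
#'
#' The continuous age proxy: a specimen's skull centroid size expressed as a
#' percentage of the centroid size of its species' reference adult. Values
#' above 100 are permitted (a non-adult may exceed the sampled adult).
#'
#' @param specimen_size,adult_size positive centroid sizes.
#' @param species,adult_species optional species labels; when both are given a
#'   mismatch is an error.
#' @return percentage (100 for the reference adult itself).
#' @export
relative_age <- function(specimen_size, adult_size, species = NULL, adult_species = NULL) {
  if (!is.null(species) && !is.null(adult_species) && !identical(species, adult_species)) {
    stop("relative age compares a specimen with an adult of the same species", call. = FALSE)
  }
  if (any(adult_size <= 0)) stop("adult centroid size must be positive", call. = FALSE)
  100 * specimen_size / adult_size
}

#' Fill the relative-age column of a study table
#'
#' Computes `centroid_size` per specimen from its raw landmarks (when not
#' already present) and `relative_age` as percentage of the same species'
#' adult centroid size.
#'
#' @param study a `suture_study` tibble with an `adult` specimen per species.
#' @return the study with `centroid_size` and `relative_age` columns.
#' @export
add_relative_age <- function(study) {
  if (!"centroid_size" %in% names(study) || anyNA(study$centroid_size)) {
    study$centroid_size <- vapply(study$landmarks, function(m) {
      centroid_size(m[!is_missing_row(m), , drop = FALSE])
    }, numeric(1))
  }
  adult <- study |>
    tibble::as_tibble() |>
    dplyr::filter(.data$age_category == "adult") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(adult_size = max(.data$centroid_size), .groups = "drop")
  missing_sp <- setdiff(unique(study$species), adult$species)
  if (length(missing_sp) > 0) {
    stop("species without an adult specimen: ", paste(missing_sp, collapse = ", "),
      call. = FALSE
    )
  }
  sizes <- adult$adult_size[match(study$species, adult$species)]
  study$relative_age <- relative_age(study$centroid_size, sizes)
  restore_study(study, study)
}
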