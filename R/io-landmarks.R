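#' Read landmark and suture-curve files
#'
#' Reads per-specimen blocks of fixed 3D landmarks plus the three digitized
#' suture curves from either of two interchange formats:
#'
#' * **TPS** — `LM3=` blocks of fixed landmarks, followed by `CURVES=3` and one
#'   `POINTS=` block per suture, then `ID=`. The three curve blocks are taken
#'   in the canonical order interfrontal, sagittal, coronal (TPS has no curve
#'   labels; this ordering is the package's documented dialect).
#' * **CSV** — long form with columns `specimen_id, object, index, x, y, z`
#'   where `object` is `"landmarks"` or a suture name.
#'
#' Missing landmarks carry the sentinel value 9999 on all three axes and are
#' converted to `NA` rows (their positions can be restored with
#' [estimate_missing()]). Curve point order is preserved exactly as digitized.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tps"` or `"csv"`.
#' @param n_fixed required number of fixed landmarks per specimen (default 69);
#'   a specimen with any other count is a structural error. `NULL` skips the
#'   check (used for derived files such as mirrored/aligned configurations).
#' @param midline indices of the three midsagittal landmarks.
#' @return a `suture_study` tibble with `specimen_id`, `landmarks` and
#'   `curves` columns.
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"), n_fixed = 69,
                           midline = c(1L, 2L, 3L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  recs <- if (format == "tps") parse_tps(path) else parse_landmark_csv(path)
  for (r in recs) {
    if (!is.null(n_fixed) && nrow(r$landmarks) != n_fixed) {
      stop(
        "specimen '", r$id, "' has ", nrow(r$landmarks),
        " fixed landmarks, expected ", n_fixed,
        call. = FALSE
      )
    }
    bad <- setdiff(names(r$curves), SUTURE_NAMES)
    if (length(bad) > 0) {
      stop("specimen '", r$id, "' has unrecognised curve label(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  suture_study(
    meta = tibble::tibble(specimen_id = vapply(recs, `[[`, "", "id")),
    landmarks = lapply(recs, `[[`, "landmarks"),
    curves = lapply(recs, `[[`, "curves"),
    midline = midline
  )
}

parse_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM3?=", lines[i], ignore.case = TRUE)) {
      stop("malformed TPS file: expected LM3= at line ", i, call. = FALSE)
    }
    n_lm <- as.integer(sub("^LM3?=", "", lines[i], ignore.case = TRUE))
    i <- i + 1L
    lm <- read_coord_lines(lines[seq.int(i, length.out = n_lm)], path)
    i <- i + n_lm
    curves <- list()
    if (i <= length(lines) && grepl("^CURVES=", lines[i], ignore.case = TRUE)) {
      n_curves <- as.integer(sub("^CURVES=", "", lines[i], ignore.case = TRUE))
      if (n_curves != 3L) {
        stop("expected 3 suture curves per specimen, found ", n_curves, call. = FALSE)
      }
      i <- i + 1L
      for (k in seq_len(n_curves)) {
        if (i > length(lines) || !grepl("^POINTS=", lines[i], ignore.case = TRUE)) {
          stop("malformed TPS file: expected POINTS= block", call. = FALSE)
        }
        n_pts <- as.integer(sub("^POINTS=", "", lines[i], ignore.case = TRUE))
        i <- i + 1L
        curves[[SUTURE_NAMES[k]]] <- read_coord_lines(
          lines[seq.int(i, length.out = n_pts)], path
        )
        i <- i + n_pts
      }
    }
    if (i > length(lines) || !grepl("^ID=", lines[i], ignore.case = TRUE)) {
      stop("malformed TPS file: expected ID= after specimen block", call. = FALSE)
    }
    id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
    i <- i + 1L
    recs[[length(recs) + 1L]] <- list(id = id, landmarks = lm, curves = curves)
  }
  recs
}

read_coord_lines <- function(lns, path) {
  if (anyNA(lns)) stop("truncated coordinate block in ", path, call. = FALSE)
  vals <- lapply(strsplit(lns, "[[:space:]]+"), as.numeric)
  if (any(lengths(vals) != 3L) || anyNA(unlist(vals))) {
    stop("non-numeric or non-3D coordinate line in ", path, call. = FALSE)
  }
  do.call(rbind, vals)
}

parse_landmark_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("specimen_id", "object", "index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, factor(df$specimen_id, levels = unique(df$specimen_id))), function(d) {
    objs <- split(d[order(d$index), ], d[order(d$index), ]$object)
    if (!"landmarks" %in% names(objs)) {
      stop("specimen '", d$specimen_id[1], "' has no 'landmarks' object", call. = FALSE)
    }
    mat <- function(o) unname(as.matrix(o[, c("x", "y", "z")]))
    list(
      id = as.character(d$specimen_id[1]),
      landmarks = mat(objs$landmarks),
      curves = lapply(objs[setdiff(names(objs), "landmarks")], mat)
    )
  }) |> unname()
}

#' Write a study's landmarks and curves
#'
#' Inverse of [read_landmarks()]; `read_landmarks(write_landmarks(x))`
#' round-trips geometry exactly. Missing (`NA`) landmarks are written with the
#' 9999 sentinel.
#'
#' @param study a `suture_study` tibble.
#' @param path output file; extension picks the format unless given.
#' @param format `"auto"`, `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(study, path, format = c("auto", "tps", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  }
  fmt <- function(m) {
    m[is.na(m)] <- SENTINEL_MISSING
    apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  }
  if (format == "tps") {
    out <- character(0)
    for (i in seq_len(nrow(study))) {
      lm <- study$landmarks[[i]]
      cv <- study$curves[[i]]
      out <- c(out, paste0("LM3=", nrow(lm)), fmt(lm), paste0("CURVES=", length(cv)))
      for (nm in SUTURE_NAMES) {
        if (!is.null(cv[[nm]])) out <- c(out, paste0("POINTS=", nrow(cv[[nm]])), fmt(cv[[nm]]))
      }
      out <- c(out, paste0("ID=", study$specimen_id[i]))
    }
    writeLines(out, path)
  } else {
    rows <- purrr::map_dfr(seq_len(nrow(study)), function(i) {
      lm <- study$landmarks[[i]]
      lm[is.na(lm)] <- SENTINEL_MISSING
      parts <- c(list(landmarks = lm), study$curves[[i]])
      purrr::map_dfr(names(parts), function(nm) {
        tibble::tibble(
          specimen_id = study$specimen_id[i], object = nm,
          index = seq_len(nrow(parts[[nm]])),
          x = parts[[nm]][, 1], y = parts[[nm]][, 2], z = parts[[nm]][, 3]
        )
      })
    })
    readr::write_csv(rows, path, progress = FALSE)
  }
  invisible(path)
}
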