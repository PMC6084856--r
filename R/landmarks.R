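#' Named anatomical landmarks
#'
#' A set of uniquely named 3D points (mm) in the patient frame. Typical names
#' are ANS, PNS (anterior/posterior nasal spine, defining the palatal plane),
#' lateral reference points, soft_palate_tip and epiglottis_tip (delimiting
#' the velo- and laryngopharyngeal regions).
#'
#' @param points named list of numeric 3-vectors, or a data.frame with
#'   columns name, x, y, z.
#' @return An object of class `landmarks` (data.frame name/x/y/z).
#' @export
landmarks <- function(points) {
  if (is.data.frame(points)) {
    df <- points[, c("name", "x", "y", "z")]
  } else {
    stopifnot(is.list(points), !is.null(names(points)))
    df <- data.frame(
      name = names(points),
      x = vapply(points, `[`, numeric(1), 1),
      y = vapply(points, `[`, numeric(1), 2),
      z = vapply(points, `[`, numeric(1), 3)
    )
  }
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name)) stop("landmark names must be unique")
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("landmark coordinates must be finite")
  }
  rownames(df) <- NULL
  class(df) <- c("landmarks", "data.frame")
  df
}

#' Extract one landmark as a 3-vector
#'
#' @param lms a [landmarks] object.
#' @param name landmark name.
#' @return numeric 3-vector (mm).
#' @export
landmark_point <- function(lms, name) {
  i <- match(name, lms$name)
  if (is.na(i)) stop("landmark not found: ", name)
  as.numeric(lms[i, c("x", "y", "z")])
}

#' Landmark coordinates as a matrix
#'
#' @param lms a [landmarks] object.
#' @return numeric n x 3 matrix with landmark names as row names.
#' @export
landmark_matrix <- function(lms) {
  m <- as.matrix(lms[, c("x", "y", "z")])
  rownames(m) <- lms$name
  m
}

#' Read / write landmarks (CSV with name,x,y,z columns, or JSON)
#'
#' @param path file path; format guessed from extension (.csv or .json).
#' @return a [landmarks] object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    landmarks(lapply(lst, as.numeric))
  } else {
    landmarks(read.csv(path, stringsAsFactors = FALSE))
  }
}

#' @rdname read_landmarks
#' @param lms a [landmarks] object.
#' @export
write_landmarks <- function(lms, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- lapply(seq_len(nrow(lms)), function(i)
      as.numeric(lms[i, c("x", "y", "z")]))
    names(lst) <- lms$name
    jsonlite::write_json(lst, path, digits = NA)
  } else {
    write.csv(as.data.frame(lms), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
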