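#' Longitudinal binary trial data
#'
#' Container for a two-arm trial with a binary outcome measured at visits
#' `1..J+1`, where visit 1 is baseline. Outcomes after treatment deviation
#' are missing, and missingness is monotone: once a visit is missing all
#' later visits are missing. All interfaces are 1-indexed in visits.
#'
#' @param y Matrix (patients by visits) with entries 0, 1 or `NA`.
#' @param arm Character or factor with entries `"active"` or `"reference"`.
#' @param id Optional patient identifiers; defaults to `p1, p2, ...`.
#' @param latent Optional matrix of latent continuous values underlying `y`
#'   (used by the simulation laboratory; same shape as `y`).
#' @return An object of class `trial_data` with elements `y`, `arm`, `id`,
#'   `J_plus_1`, `n_active`, `n_reference`.
#' @examples
#' td <- trial_data(rbind(c(1, 0), c(0, NA)), c("active", "reference"))
#' deviation_times(td)
#' @export
trial_data <- function(y, arm, id = NULL, latent = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y)
  arm <- as.character(arm)
  if (length(arm) != n) stop("`arm` must have one entry per patient", call. = FALSE)
  bad <- setdiff(unique(arm), c("active", "reference"))
  if (length(bad)) {
    stop("unknown arm label(s): ", paste(bad, collapse = ", "),
         " (use read_trial_csv() to map study-specific labels)", call. = FALSE)
  }
  id <- as.character(id %||% paste0("p", seq_len(n)))
  if (anyDuplicated(id)) stop("patient ids must be unique", call. = FALSE)
  dimnames(y) <- list(id, paste0("y", seq_len(ncol(y))))
  out <- structure(
    list(y = y, arm = factor(arm, levels = c("active", "reference")), id = id,
         J_plus_1 = ncol(y), n_active = sum(arm == "active"),
         n_reference = sum(arm == "reference")),
    class = "trial_data")
  if (!is.null(latent)) {
    latent <- as.matrix(latent)
    stopifnot(dim(latent) == dim(y))
    attr(out, "latent") <- latent
  }
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Trial data:", nrow(x$y), "patients (", x$n_active, "active /",
      x$n_reference, "reference ),", x$J_plus_1, "visits\n")
  miss <- colMeans(is.na(x$y))
  cat("Missing by visit:", paste(sprintf("%s=%.0f%%", colnames(x$y), 100 * miss),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Validate trial data against the monotone-deviation data model
#'
#' Checks that every outcome is 0, 1 or missing, that baseline (visit 1) is
#' observed for every patient, and that missingness is monotone. Non-monotone
#' (interim) gaps are not supported by the imputation algorithms.
#'
#' @param data A [trial_data] object.
#' @return A `validation_report`: list with `pass` (logical) and `violations`
#'   (data frame with columns `id`, `problem`).
#' @export
validate_trial <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  y <- data$y
  viol <- list()
  bad_val <- apply(y, 1L, function(r) any(!is.na(r) & r != 0 & r != 1))
  if (any(bad_val)) {
    viol[[length(viol) + 1L]] <- data.frame(id = data$id[bad_val],
                                            problem = "non-binary value")
  }
  no_base <- is.na(y[, 1L])
  if (any(no_base)) {
    viol[[length(viol) + 1L]] <- data.frame(id = data$id[no_base],
                                            problem = "baseline must be observed")
  }
  non_mono <- apply(y, 1L, function(r) {
    obs <- !is.na(r)
    any(diff(obs) > 0)   # missing followed by observed
  })
  if (any(non_mono)) {
    viol[[length(viol) + 1L]] <- data.frame(
      id = data$id[non_mono], problem = "non-monotone: interim missingness unsupported")
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(), problem = character())
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$pass) cat("Validation passed\n") else {
    cat("Validation failed:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

assert_valid_trial <- function(data) {
  rep <- validate_trial(data)
  if (!rep$pass) {
    stop("invalid trial data: ",
         paste(unique(rep$violations$problem), collapse = "; "), call. = FALSE)
  }
  invisible(data)
}

#' Per-patient deviation times
#'
#' The deviation time `d` is each patient's last observed visit. Completers
#' have `d = J+1`; a patient observed only at baseline has `d = 1`.
#'
#' @param data A validated [trial_data] object.
#' @return Integer vector of length `n` named by patient id.
#' @export
deviation_times <- function(data) {
  assert_valid_trial(data)
  d <- rowSums(!is.na(data$y))
  storage.mode(d) <- "integer"
  names(d) <- data$id
  d
}

#' Mask outcomes after deviation
#'
#' Sets all visits after each patient's deviation time to missing. Applying
#' [deviation_times()] to complete data and then masking reproduces the
#' monotone missingness pattern exactly.
#'
#' @param data A [trial_data] object with complete (or partially complete) `y`.
#' @param d Integer vector of deviation times, one per patient.
#' @return A [trial_data] object with post-deviation entries set to `NA`.
#' @export
mask_post_deviation <- function(data, d) {
  stopifnot(inherits(data, "trial_data"), length(d) == nrow(data$y))
  y <- data$y
  p <- ncol(y)
  for (j in seq_len(p)) y[d < j, j] <- NA_real_
  trial_data(y, data$arm, data$id, latent = attr(data, "latent"))
}

MISSING_CODES <- c("", "na", ".", "n/a")

#' Read wide-format trial data from CSV
#'
#' Expects a header `id,arm,y1,...,y<J+1>`. Missing outcomes may be coded as
#' an empty cell, `NA`, `.` or `N/A` (case-insensitive). Arm labels are mapped
#' onto the canonical `active`/`reference` pair.
#'
#' @param path Path to a CSV file.
#' @param active,reference Strings coding the two arms in the file.
#' @return A [trial_data] object.
#' @export
read_trial_csv <- function(path, active = "active", reference = "reference") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  nm <- names(df)
  ycols <- grep("^y[0-9]+$", nm, value = TRUE)
  if (!all(c("id", "arm") %in% nm) || length(ycols) < 2L) {
    stop("expected columns id, arm, y1..y<J+1> in ", path, call. = FALSE)
  }
  ycols <- paste0("y", seq_along(ycols))
  if (!all(ycols %in% nm)) stop("visit columns must be consecutive y1..y<J+1>", call. = FALSE)
  arm_raw <- df$arm
  if (!any(arm_raw == reference)) {
    stop("reference arm required: no rows with arm label '", reference, "'", call. = FALSE)
  }
  if (!any(arm_raw == active)) {
    stop("active arm required: no rows with arm label '", active, "'", call. = FALSE)
  }
  bad <- setdiff(unique(arm_raw), c(active, reference))
  if (length(bad)) stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  arm <- ifelse(arm_raw == active, "active", "reference")
  y <- sapply(df[ycols], function(col) {
    col <- trimws(col)
    col[tolower(col) %in% MISSING_CODES] <- NA_character_
    ok <- is.na(col) | col %in% c("0", "1")
    if (!all(ok)) stop("non-binary outcome value(s): ",
                       paste(utils::head(unique(col[!ok])), collapse = ", "),
                       call. = FALSE)
    as.numeric(col)
  })
  if (is.null(dim(y))) y <- matrix(y, nrow = nrow(df))
  trial_data(y, arm, id = df$id)
}

#' Write trial data as wide CSV
#'
#' Missing outcomes are written as empty cells.
#'
#' @param data A [trial_data] object.
#' @param path Output path.
#' @param active,reference Arm labels to write.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, active = "active", reference = "reference") {
  stopifnot(inherits(data, "trial_data"))
  df <- data.frame(id = data$id,
                   arm = ifelse(data$arm == "active", active, reference),
                   data$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
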