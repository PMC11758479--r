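# Container for a set of K completed binary datasets.

new_imputed_stack <- function(data, completions, method, assumption, K, seed) {
  structure(list(data = data, completions = completions, method = method,
                 assumption = assumption, K = as.integer(K), seed = seed),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack:", x$K, "completions |", x$method, "|", x$assumption, "\n")
  cat(nrow(x$data$y), "patients,", x$data$J_plus_1, "visits,",
      sum(is.na(x$data$y)), "imputed cells per completion\n")
  invisible(x)
}

#' Write an imputed stack as stacked CSV
#'
#' One block per dataset with an `imp` column: `imp = 0` is the original data
#' with blanks for missing values, `imp = 1..K` are the completed datasets.
#'
#' @param stack An `imputed_stack`.
#' @param path Output path.
#' @param active,reference Arm labels to write.
#' @return `path`, invisibly.
#' @export
write_imputed_csv <- function(stack, path, active = "active", reference = "reference") {
  stopifnot(inherits(stack, "imputed_stack"))
  data <- stack$data
  arm <- ifelse(data$arm == "active", active, reference)
  blocks <- c(list(data.frame(imp = 0L, id = data$id, arm = arm, data$y,
                              check.names = FALSE)),
              lapply(seq_len(stack$K), function(k) {
                data.frame(imp = k, id = data$id, arm = arm,
                           stack$completions[[k]], check.names = FALSE)
              }))
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a stacked imputation CSV
#'
#' Inverse of [write_imputed_csv()].
#'
#' @param path Path to a stacked CSV with an `imp` column.
#' @param active,reference Arm labels used in the file.
#' @return An `imputed_stack` (with unknown `method`/`assumption` fields).
#' @export
read_imputed_csv <- function(path, active = "active", reference = "reference") {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("imp" %in% names(df))
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  base <- df[df$imp == 0L, , drop = FALSE]
  arm <- ifelse(base$arm == active, "active", "reference")
  data <- trial_data(as.matrix(base[ycols]), arm, id = as.character(base$id))
  ks <- sort(unique(df$imp[df$imp > 0L]))
  completions <- lapply(ks, function(k) {
    blk <- df[df$imp == k, , drop = FALSE]
    blk <- blk[match(base$id, blk$id), , drop = FALSE]
    m <- as.matrix(blk[ycols])
    dimnames(m) <- dimnames(data$y)
    m
  })
  new_imputed_stack(data, completions, method = "unknown", assumption = "unknown",
                    K = length(ks), seed = NULL)
}
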