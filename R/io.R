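#' Write / read a dataset as a delimited table
#'
#' The table has columns \code{score} (blank where missing), \code{outcome}
#' and \code{aux}; the score range and provenance go into a YAML sidecar
#' named \code{<path>.yaml} (requires the \pkg{yaml} package) or, without
#' it, a plain \code{key: value} sidecar written by hand.
#'
#' @param data a \code{complete_dataset} (possibly with missing scores).
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "complete_dataset"))
  df <- data.frame(score = data$score, outcome = data$outcome,
                   aux = as.character(data$aux))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(lo = data$lo, hi = data$hi, n = data$n,
               profile = data$profile, method = data$method)
  side <- paste0(path, ".yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(meta), side)
  } else {
    writeLines(paste0(names(meta), ": ", unlist(meta)), side)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @param lo,hi range limits, used if no sidecar file is found.
#' @export
read_dataset <- function(path, lo = NULL, hi = NULL) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  stopifnot(all(c("score", "outcome", "aux") %in% names(df)))
  side <- paste0(path, ".yaml")
  profile <- NA_character_; method <- NA_character_
  if (file.exists(side)) {
    meta <- if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::read_yaml(side)
    } else {
      kv <- read.dcf(textConnection(gsub(": ", ": ", readLines(side))))
      as.list(kv[1, ])
    }
    lo <- as.numeric(meta$lo); hi <- as.numeric(meta$hi)
    if (!is.null(meta$profile)) profile <- as.character(meta$profile)
    if (!is.null(meta$method)) method <- as.character(meta$method)
  }
  if (is.null(lo) || is.null(hi))
    stop("score range unknown: supply lo and hi or provide the sidecar")
  complete_dataset(df$score, lo, hi, df$outcome,
                   factor(df$aux, levels = c("low", "moderate", "high",
                                             "very_high"), ordered = TRUE),
                   profile = profile, method = method)
}
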