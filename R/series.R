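#' Weekly body-weight series
#'
#' A `weight_series` is a data frame with one row per week holding the
#' observed body weight and the energy-balance numbers that produce the
#' recursion's forcing term.  Week labels follow the starvation-study
#' convention: `"0"` is the pre-starvation baseline and `"S<k>"` is
#' starvation week `k`; internally weeks are the integers `k`.
#'
#' @param week integer week indices or labels (`"0"`, `"S1"`, ...).
#' @param body_weight body weights (kg), > 0.
#' @param tee total energy expenditure (kcal/day); may be `NA`.
#' @param intake mean food intake (kcal/day); may be `NA`.
#' @param net_intake daily net energy intake (kcal/day); if omitted it is
#'   computed as `intake - tee` with a message.
#' @return a data frame of class `"weight_series"` with columns `week`,
#'   `label`, `body_weight`, `tee`, `intake`, `net_intake`, ordered by week.
#' @export
weight_series <- function(week, body_weight, tee = NA_real_,
                          intake = NA_real_, net_intake = NULL) {
  idx <- parse_week(week)
  n <- length(idx)
  stopifnot(length(body_weight) == n)
  if (anyDuplicated(idx)) stop("duplicate week indices in series")
  if (is.unsorted(idx, strictly = TRUE))
    stop("week indices must be strictly increasing")
  if (any(!is.finite(body_weight)) || any(body_weight <= 0))
    stop("body weights must be positive")
  tee <- rep_len(as.numeric(tee), n)
  intake <- rep_len(as.numeric(intake), n)
  if (is.null(net_intake)) {
    if (all(is.finite(tee)) && all(is.finite(intake))) {
      message("net intake not supplied; computed as intake - TEE")
      net_intake <- intake - tee
    } else {
      stop("supply 'net_intake', or both 'tee' and 'intake' to derive it")
    }
  }
  stopifnot(length(net_intake) == n)
  bad <- which(is.finite(tee) & is.finite(intake) &
                 abs(net_intake - (intake - tee)) > 0.02)
  if (length(bad))
    warning(sprintf("net intake inconsistent with intake - TEE at week(s) %s",
                    paste(idx[bad], collapse = ", ")))
  out <- data.frame(week = as.integer(idx),
                    label = ifelse(idx == 0, "0", paste0("S", idx)),
                    body_weight = as.numeric(body_weight),
                    tee = tee, intake = intake,
                    net_intake = as.numeric(net_intake),
                    stringsAsFactors = FALSE)
  class(out) <- c("weight_series", "data.frame")
  out
}

# "0" -> 0, "S13" -> 13; numeric input passes through
parse_week <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 0) || any(x != floor(x))) stop("week indices must be non-negative integers")
    return(as.integer(x))
  }
  x <- trimws(as.character(x))
  out <- suppressWarnings(ifelse(grepl("^S[0-9]+$", x), as.integer(sub("^S", "", x)),
                                 ifelse(grepl("^[0-9]+$", x), as.integer(x), NA_integer_)))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unparseable week token '%s' at position %d (expected '0' or 'S<k>')",
                 x[bad], bad))
  }
  out
}

# parse "S1:S24" / "1:24" window specs into c(from, to)
parse_window <- function(spec) {
  if (is.numeric(spec) && length(spec) == 2L) return(as.integer(spec))
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("window must be 'S<a>:S<b>' or a length-2 integer vector")
  w <- parse_week(parts)
  if (w[1] > w[2]) stop("window start exceeds window end")
  w
}

#' Subset a weight series by a closed week window
#'
#' @param series a [weight_series()].
#' @param from,to first and last week index (inclusive), as integers or
#'   labels such as `"S13"`.
#' @return the `weight_series` rows with `from <= week <= to`.
#' @export
series_window <- function(series, from, to) {
  stopifnot(inherits(series, "weight_series"))
  from <- parse_week(from); to <- parse_week(to)
  out <- series[series$week >= from & series$week <= to, , drop = FALSE]
  class(out) <- c("weight_series", "data.frame")
  out
}

#' Read a weekly series CSV
#'
#' Reads the standard comma-separated dialect with header
#' `week,body_weight_kg,tee_kcal_day,intake_kcal_day,net_intake_kcal_day`
#' and week tokens `0` or `S<k>`.  A missing net-intake column is derived
#' from intake and TEE with a message.  Parse failures name the offending
#' line (header = line 1).
#'
#' @param path file path.
#' @return a [weight_series()].
#' @export
read_series_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("week", "body_weight_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  idx <- tryCatch(parse_week(raw$week), error = function(e) {
    # recover the failing position to report a file line number
    msg <- conditionMessage(e)
    pos <- suppressWarnings(as.integer(sub(".*position ([0-9]+).*", "\\1", msg)))
    stop(sprintf("%s (line %d of %s)", sub(" at position.*", "", msg),
                 if (is.na(pos)) NA_integer_ else pos + 1L, path), call. = FALSE)
  })
  if (is.unsorted(idx, strictly = TRUE)) {
    bad <- which(diff(idx) <= 0)[1] + 1L
    stop(sprintf("week tokens out of order at line %d of %s", bad + 1L, path))
  }
  tee <- if ("tee_kcal_day" %in% names(raw)) raw$tee_kcal_day else NA_real_
  intake <- if ("intake_kcal_day" %in% names(raw)) raw$intake_kcal_day else NA_real_
  net <- if ("net_intake_kcal_day" %in% names(raw)) raw$net_intake_kcal_day else NULL
  weight_series(idx, raw$body_weight_kg, tee = tee, intake = intake,
                net_intake = net)
}

#' Write a weekly series CSV
#'
#' Inverse of [read_series_csv()]; writing then reading reproduces the
#' series exactly at stored precision.
#'
#' @param series a [weight_series()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "weight_series"))
  out <- data.frame(week = series$label,
                    body_weight_kg = series$body_weight,
                    tee_kcal_day = series$tee,
                    intake_kcal_day = series$intake,
                    net_intake_kcal_day = series$net_intake)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.weight_series <- function(x, ...) {
  cat(sprintf("weight_series: %d weeks (%s..%s)\n", nrow(x),
              x$label[1], x$label[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}
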