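#' Group weekly series from the Minnesota starvation experiment
#'
#' The published group-level table: body weight, total energy expenditure,
#' mean food intake and daily net energy intake for the baseline week 0 and
#' the 24 starvation weeks S1-S24.  Values are stored as a plain-text CSV
#' fixture inside the package and verified against a recorded checksum on
#' every load.
#'
#' @return a [weight_series()] with 25 rows (week 0 plus S1-S24).
#' @examples
#' g <- minnesota_group()
#' g$body_weight[g$week == 24]  # 52.57
#' @export
minnesota_group <- function() {
  path <- system.file("extdata", "minnesota_group.csv",
                      package = "diffweight", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  checksum <- sum(as.matrix(raw[, -1]))
  if (nrow(raw) != 25L || abs(checksum - 83900.86) > 0.005)
    stop("minnesota_group.csv fixture is corrupted (checksum mismatch)")
  weight_series(raw$week, raw$body_weight_kg, tee = raw$tee_kcal_day,
                intake = raw$intake_kcal_day,
                net_intake = raw$net_intake_kcal_day)
}

#' Per-subject weekly weights from the Minnesota starvation experiment
#'
#' The published per-subject table: for each of the 32 subjects, the
#' observed weekly weights S1-S24, the model trajectory printed alongside
#' them, and the printed per-subject coefficient of determination.
#'
#' @return a named list with one record per subject; each record is a list
#'   with elements `subject`, `observed` (24 weights), `model` (24 printed
#'   model weights) and `printed_r2`.
#' @examples
#' subs <- minnesota_subjects()
#' subs[["109"]]$printed_r2  # 0.996
#' @export
minnesota_subjects <- function() {
  path <- system.file("extdata", "minnesota_subjects.csv",
                      package = "diffweight", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject = "character"))
  wk <- paste0("S", 1:24)
  checksum <- sum(as.matrix(raw[, wk])) + sum(raw$r2, na.rm = TRUE)
  if (nrow(raw) != 64L || abs(checksum - 89287.14) > 0.005)
    stop("minnesota_subjects.csv fixture is corrupted (checksum mismatch)")
  ids <- unique(raw$subject)
  out <- lapply(ids, function(id) {
    obs <- raw[raw$subject == id & raw$series == "observed", wk]
    mod <- raw[raw$subject == id & raw$series == "model", ]
    list(subject = id,
         observed = setNames(as.numeric(obs[1, ]), wk),
         model = setNames(as.numeric(mod[1, wk]), wk),
         printed_r2 = mod$r2[1])
  })
  setNames(out, ids)
}
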