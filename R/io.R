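# CSV persistence of runs. Numbers are written with %.17g so the text
# round-trips to the identical double.

fmt_num <- function(x, digits = 17L) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

write_numeric_csv <- function(df, path, digits = 17L) {
  chr <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col, digits) else as.character(col)
  }), stringsAsFactors = FALSE)
  utils::write.table(chr, path, sep = ",", row.names = FALSE,
                     col.names = names(df), quote = FALSE)
}

#' Write a run to a directory of CSV files
#'
#' Emits `gyro.csv` (`t_s`, `omega_left_dps`, `omega_right_dps`,
#' `accel_trigger`), `mat.csv` (`t_slave_s`, `v01`..`v16`), `gps.csv`
#' (`t_s`, `lat_udeg`, `lon_udeg`) and `truth.csv` (`t_s`, `v_mps`,
#' `dist_m`, `copx_mm`, `copy_mm`, `section`). Values round-trip losslessly
#' through [read_run()].
#'
#' @param run A `raw_run`.
#' @param directory Output directory (created if missing).
#' @param overwrite Refuse to overwrite existing files unless TRUE.
#' @param digits Significant digits written (default 17: lossless doubles;
#'   smaller values trade precision for file size).
#' @return Invisibly, the written file paths.
#' @export
write_run <- function(run, directory, overwrite = FALSE, digits = 17L) {
  stopifnot(inherits(run, "raw_run"))
  if (is.null(run$truth) || nrow(run$truth) == 0L) stop("no samples")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  parts <- list(gyro = run$gyro, mat = run$mat, gps = run$gps,
                truth = run$truth)
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  paths <- file.path(directory, paste0(names(parts), ".csv"))
  if (!overwrite && any(file.exists(paths))) {
    stop("output files exist (use overwrite = TRUE): ",
         paste(basename(paths[file.exists(paths)]), collapse = ", "))
  }
  for (k in seq_along(parts)) write_numeric_csv(parts[[k]], paths[k], digits)
  invisible(paths)
}

#' Read a run written by [write_run()]
#'
#' @param directory Directory holding the CSV files.
#' @return A `raw_run` (without simulator metadata).
#' @export
read_run <- function(directory) {
  rd <- function(name) {
    p <- file.path(directory, paste0(name, ".csv"))
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p)
  }
  out <- list(gyro = rd("gyro"), mat = rd("mat"), gps = rd("gps"),
              truth = rd("truth"), meta = NULL)
  if (is.null(out$gyro) && is.null(out$truth)) {
    stop("no run files found in ", directory)
  }
  structure(out, class = "raw_run")
}
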