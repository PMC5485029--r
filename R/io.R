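# Long-format delimited I/O. All measurement and trajectory tables share
# one schema: time_h, species, value, sd (sd optional on read).

#' Read a long-format measurement table
#'
#' Expects a comma-separated file with header \code{time_h, species,
#' value, sd} (the \code{sd} column may be absent). Species names must be
#' model states or reported glycoforms (\code{glyco_*}); malformed rows and
#' negative concentrations are rejected with their line numbers.
#'
#' @param path file path.
#' @return data.frame with columns time_h, species, value, sd.
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "species", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: header must contain %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  df <- df[, .MEASUREMENT_COLS]
  df$time_h <- as.numeric(df$time_h)
  df$value <- as.numeric(df$value)
  df$sd <- as.numeric(df$sd)
  if (!nrow(df)) return(df)
  lineOf <- function(i) i + 1L  # header is line 1
  badNum <- which(!is.finite(df$time_h) | !is.finite(df$value))
  if (length(badNum))
    stop(sprintf("%s: non-numeric time or value at line(s) %s", path,
                 paste(lineOf(badNum), collapse = ", ")), call. = FALSE)
  unknown <- which(!df$species %in% .VALID_SPECIES)
  if (length(unknown))
    stop(sprintf(
      "%s: unknown species %s at line(s) %s; valid names are: %s", path,
      paste(unique(df$species[unknown]), collapse = ", "),
      paste(lineOf(unknown), collapse = ", "),
      paste(.VALID_SPECIES, collapse = ", ")), call. = FALSE)
  neg <- which(df$value < 0)
  if (length(neg))
    stop(sprintf("%s: negative concentration at line(s) %s", path,
                 paste(lineOf(neg), collapse = ", ")), call. = FALSE)
  df
}

#' @rdname readMeasurements
#' @param table data.frame with columns time_h, species, value and
#'   optionally sd.
#' @export
writeMeasurements <- function(table, path) {
  if (!"sd" %in% names(table)) table$sd <- NA_real_
  out <- data.frame(time_h = sprintf("%.17g", table$time_h),
                    species = table$species,
                    value = sprintf("%.17g", table$value),
                    sd = ifelse(is.na(table$sd), "NA",
                                sprintf("%.17g", table$sd)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten a trajectory to long format
#'
#' @param trajectory a [Trajectory-class].
#' @param species columns to keep (default: all states).
#' @return data.frame time_h, species, value (sd = NA).
#' @export
trajectoryToLong <- function(trajectory, species = NULL) {
  st <- trajectory@states
  if (is.null(species)) species <- colnames(st)
  st <- st[, species, drop = FALSE]
  data.frame(time_h = rep(trajectory@times, ncol(st)),
             species = rep(colnames(st), each = nrow(st)),
             value = as.vector(st),
             sd = NA_real_)
}

#' Write a trajectory as a long-format CSV
#'
#' Values are written at full precision so that
#' \code{readMeasurements(writeTrajectory(x))} round-trips exactly.
#'
#' @inheritParams trajectoryToLong
#' @param path file path.
#' @export
writeTrajectory <- function(trajectory, path, species = NULL) {
  writeMeasurements(trajectoryToLong(trajectory, species), path)
}
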