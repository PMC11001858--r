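# Reading/writing the recording CSV dialect: one column per (vessel, quantity)
# with headers "<VESSEL>_q" (flow, mL/min) and "<VESSEL>_p" (pressure, mmHg),
# plus an optional leading "t" column in seconds.

#' Read a waveform-set CSV
#'
#' Columns are named `<VESSEL>_q` (volumetric flow, mL/min) and `<VESSEL>_p`
#' (static gauge pressure, mmHg). An optional `t` column gives sample times in
#' seconds; when present the sample rate is inferred from it and checked for
#' jitter, otherwise `sample_rate` applies.
#'
#' A vessel whose flow column is present without its pressure column (or vice
#' versa) is reported as a missing-column error; `require_complete = TRUE`
#' additionally demands all 10 canonical vessels.
#'
#' @param path CSV file path.
#' @param sample_rate assumed sampling rate in Hz when no `t` column exists
#'   (default 1000).
#' @param time_column name of the time column (default `"t"`).
#' @param require_complete logical; require all 4 inlets and 6 outlets.
#' @return A [waveform_set].
#' @export
read_dataset_csv <- function(path, sample_rate = 1000, time_column = "t",
                             require_complete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  nm <- names(df)
  has_t <- time_column %in% nm
  data_cols <- setdiff(nm, time_column)
  parsed <- regmatches(data_cols, regexec("^(.+)_(q|p)$", data_cols))
  bad <- data_cols[vapply(parsed, length, integer(1)) == 0]
  if (length(bad))
    stop("unrecognised column(s): ", paste(bad, collapse = ", "),
         " (expected <VESSEL>_q / <VESSEL>_p)", call. = FALSE)
  vessels <- vapply(parsed, `[`, character(1), 2)
  suffix <- vapply(parsed, `[`, character(1), 3)

  # every vessel must come as a complete q/p pair; name the absent column
  missing <- character(0)
  for (v in unique(vessels)) {
    for (s in c("q", "p")) {
      if (!any(vessels == v & suffix == s))
        missing <- c(missing, paste0(v, "_", s))
    }
  }
  if (require_complete) {
    cv <- cow_vessels()
    want <- as.vector(outer(c(cv$inlets, cv$outlets), c("q", "p"), paste, sep = "_"))
    missing <- union(missing, setdiff(want, data_cols))
  }
  if (length(missing))
    stop("missing column(s): ", paste(sort(missing), collapse = ", "),
         call. = FALSE)

  for (cn in data_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric value in column '", cn, "' at data row ", bad_row,
           call. = FALSE)
    }
  }

  t0 <- 0
  if (has_t) {
    tv <- df[[time_column]]
    dts <- diff(tv)
    dt <- median(dts)
    if (dt <= 0 || any(abs(dts - dt) > 1e-3 * dt))
      stop("inconsistent time step in '", time_column,
           "' column (> 0.1% jitter)", call. = FALSE)
    sample_rate <- 1 / dt
    t0 <- tv[1]
  }

  wfs <- lapply(seq_along(data_cols), function(i) {
    waveform(df[[data_cols[i]]], sample_rate, vessel = vessels[i],
             quantity = if (suffix[i] == "q") "flow" else "pressure", t0 = t0)
  })
  waveform_set(wfs)
}

#' Write a waveform set to CSV
#'
#' Emits the dialect read by [read_dataset_csv()]: a `t` column in seconds
#' followed by `<VESSEL>_q` / `<VESSEL>_p` columns. Values are written with
#' enough digits for a round trip within 1e-9 relative error.
#'
#' @param ws a [waveform_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ws, path) {
  stopifnot(inherits(ws, "waveform_set"))
  if (length(ws$waveforms) == 0) stop("nothing to write: empty waveform set",
                                      call. = FALSE)
  ns <- vapply(ws$waveforms, function(w) length(w$values), integer(1))
  if (length(unique(ns)) != 1)
    stop("refusing to write: waveforms have mixed lengths", call. = FALSE)
  w1 <- ws$waveforms[[1]]
  cols <- c(list(t = waveform_times(w1)),
            lapply(ws$waveforms, function(w) w$values))
  df <- as.data.frame(cols, check.names = FALSE)
  # order vessels canonically where possible
  cv <- cow_vessels()
  want <- as.vector(t(outer(c(cv$inlets, cv$outlets), c("_q", "_p"), paste0)))
  ord <- c("t", intersect(want, names(df)), setdiff(names(df), c("t", want)))
  df <- df[, ord, drop = FALSE]
  df[] <- lapply(df, function(x) format(x, digits = 15, scientific = FALSE,
                                        trim = TRUE))
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}
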