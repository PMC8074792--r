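#' Channel metadata table
#'
#' Builds the channel descriptor used by [event_table()]. Each channel has a
#' unique name, a role (`"scatter-forward"`, `"scatter-side"` or
#' `"fluorescence"`), and optional excitation wavelength and emission band
#' (centre and full width, both in nm).
#'
#' @param names character vector of unique channel names.
#' @param roles character vector recycled to `length(names)`; when `NULL`,
#'   roles are guessed from the names (`FSC*` forward scatter, `SSC*` side
#'   scatter, everything else fluorescence).
#' @param excitation_nm,emission_center_nm,emission_width_nm optional numeric
#'   vectors (NA = unknown); emission widths must be positive when given.
#' @return a `data.frame` with one row per channel.
#' @export
channels <- function(names, roles = NULL, excitation_nm = NA_real_,
                     emission_center_nm = NA_real_, emission_width_nm = NA_real_) {
  names <- as.character(names)
  if (anyDuplicated(names)) stopf("channel names must be unique")
  if (any(!nzchar(names))) stopf("channel names must be non-empty")
  if (is.null(roles)) roles <- guess_channel_role(names)
  roles <- rep_len(roles, length(names))
  ok <- roles %in% c("scatter-forward", "scatter-side", "fluorescence")
  if (!all(ok)) stopf("unknown channel role: %s", roles[!ok][1L])
  w <- rep_len(as.numeric(emission_width_nm), length(names))
  if (any(!is.na(w) & w <= 0)) stopf("emission band width must be > 0")
  data.frame(
    name = names, role = roles,
    excitation_nm = rep_len(as.numeric(excitation_nm), length(names)),
    emission_center_nm = rep_len(as.numeric(emission_center_nm), length(names)),
    emission_width_nm = w,
    stringsAsFactors = FALSE
  )
}

guess_channel_role <- function(names) {
  ifelse(grepl("^fsc", names, ignore.case = TRUE), "scatter-forward",
         ifelse(grepl("^ssc", names, ignore.case = TRUE), "scatter-side",
                "fluorescence"))
}

#' Event-level cytometry table
#'
#' The central container for list-mode cytometry data: a numeric matrix of
#' per-event intensities (rows = events, columns = channels), channel
#' metadata, optional per-event acquisition times in seconds, and free-form
#' sample annotations (cell line, treatment, concentration, replicate, ...).
#'
#' @param events numeric matrix (or coercible) of finite intensities.
#' @param channels channel metadata from [channels()], or a character vector
#'   of channel names.
#' @param time_s optional numeric vector of per-event acquisition times
#'   (seconds), one per event.
#' @param sample_meta named list of sample annotations.
#' @return an object of class `EventTable`.
#' @export
event_table <- function(events, channels, time_s = NULL, sample_meta = list()) {
  events <- as.matrix(events)
  if (length(events)) storage.mode(events) <- "double"
  if (is.character(channels)) channels <- channels(channels)
  if (!is.data.frame(channels) || is.null(channels$name))
    stopf("`channels` must be a channel metadata data.frame or character vector")
  if (ncol(events) != nrow(channels))
    stopf("event matrix has %d columns but %d channels described",
          ncol(events), nrow(channels))
  if (length(events) && any(!is.finite(events)))
    stopf("event intensities must all be finite; drop or repair events first")
  colnames(events) <- channels$name
  if (!is.null(time_s)) {
    time_s <- as.numeric(time_s)
    if (length(time_s) != nrow(events))
      stopf("`time_s` must have one entry per event")
    if (length(time_s) && any(!is.finite(time_s))) stopf("`time_s` must be finite")
  }
  structure(
    list(events = events, channels = channels, time_s = time_s,
         sample_meta = as.list(sample_meta)),
    class = "EventTable"
  )
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("<EventTable: %d events x %d channels%s>\n",
              nrow(x$events), ncol(x$events),
              if (!is.null(x$time_s)) ", timed" else ""))
  cat("  channels:", paste(x$channels$name, collapse = ", "), "\n")
  if (length(x$sample_meta))
    cat("  meta:", paste(names(x$sample_meta),
                         vapply(x$sample_meta, format, ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.EventTable <- function(x) dim(x$events)

n_events <- function(table) nrow(table$events)

channel_names <- function(table) table$channels$name

channel_column <- function(table, name) {
  if (!name %in% channel_names(table))
    stopf("channel '%s' not present (have: %s)", name,
          paste(channel_names(table), collapse = ", "))
  table$events[, name]
}

fluorescence_channels <- function(table) {
  table$channels$name[table$channels$role == "fluorescence"]
}

subset_events <- function(table, keep) {
  out <- table
  out$events <- table$events[keep, , drop = FALSE]
  if (!is.null(table$time_s)) out$time_s <- table$time_s[keep]
  out
}

# ---------------------------------------------------------------------------
# reading / writing

#' Read event-level cytometry data
#'
#' Reads a per-event CSV (comma separated, mandatory header row, `.` decimal
#' separator, UTF-8) or an FCS 3.0/3.1 list-mode file. A CSV column named
#' `time_s`, or an FCS parameter named `Time` combined with the `$TIMESTEP`
#' keyword, is interpreted as per-event acquisition time in seconds. Events
#' containing non-finite intensities are dropped with a message; the dropped
#' count is attached as attribute `n_dropped`.
#'
#' @param path file to read.
#' @param format `"csv"` or `"fcs"`; default guesses from the file extension.
#' @param sample_meta optional annotations attached to the result.
#' @return an [event_table()].
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        sample_meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  parsed <- if (format == "csv") read_events_csv(path) else read_fcs(path)
  mat <- parsed$events
  finite <- if (nrow(mat) == 0L) logical(0) else rowSums(!is.finite(mat)) == 0L
  if (!is.null(parsed$time_s)) finite <- finite & is.finite(parsed$time_s)
  n_drop <- sum(!finite)
  if (n_drop > 0L) {
    message(sprintf("read_events: dropped %d event(s) with non-finite values", n_drop))
    mat <- mat[finite, , drop = FALSE]
    if (!is.null(parsed$time_s)) parsed$time_s <- parsed$time_s[finite]
  }
  out <- event_table(mat, parsed$channels, time_s = parsed$time_s,
                     sample_meta = sample_meta)
  attr(out, "n_dropped") <- n_drop
  out
}

read_events_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stopf("unparseable CSV '%s': %s", path, conditionMessage(e))
  )
  if (ncol(df) == 0L) stopf("CSV '%s' has no columns", path)
  nm <- colnames(df)
  looks_numeric <- !is.na(suppressWarnings(as.numeric(nm)))
  if (all(looks_numeric))
    stopf("CSV '%s' appears to lack a channel header row", path)
  if (nrow(df) == 0L) {
    df[] <- lapply(df, as.numeric)  # header-only file: column types unknowable
  } else {
    bad <- !vapply(df, is.numeric, TRUE)
    if (any(bad))
      stopf("CSV '%s': non-numeric column '%s'", path, nm[bad][1L])
  }
  time_s <- NULL
  if ("time_s" %in% nm) {
    time_s <- df[["time_s"]]
    df <- df[, setdiff(nm, "time_s"), drop = FALSE]
  }
  list(events = as.matrix(df), channels = channels(colnames(df)), time_s = time_s)
}

#' Write event-level cytometry data
#'
#' CSV output is a lossless round trip (full double precision, `time_s`
#' written as an extra column). FCS output is FCS 3.1, list mode, 32-bit float
#' data, little endian; per-event times are stored in a `Time` parameter with
#' `$TIMESTEP` set to 1 second.
#'
#' @param table an [event_table()].
#' @param path destination file.
#' @param format `"csv"` or `"fcs"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, format = c("auto", "csv", "fcs")) {
  stopifnot(inherits(table, "EventTable"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (format == "csv") write_events_csv(table, path) else write_fcs(table, path)
  invisible(path)
}

write_events_csv <- function(table, path) {
  df <- as.data.frame(table$events)
  if (!is.null(table$time_s)) df$time_s <- table$time_s
  ok <- tryCatch({
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  invisible(ok)
}

# --- minimal FCS 3.0/3.1 list-mode support (float data) --------------------
# Layout written: 58-byte header, primary TEXT with '/' delimiter and
# fixed-width offsets, float32 little-endian DATA, no ANALYSIS segment.

fcs_text_keywords <- function(table, data_begin, data_end) {
  ev <- table$events
  with_time <- !is.null(table$time_s)
  p <- ncol(ev) + as.integer(with_time)
  nm <- c(colnames(ev), if (with_time) "Time")
  rng <- vapply(seq_len(p), function(i) {
    v <- if (i <= ncol(ev)) ev[, i] else table$time_s
    max(1, ceiling(max(v, 0, na.rm = TRUE)) + 1)
  }, 0)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%012d", data_begin),
    "$ENDDATA" = sprintf("%012d", data_end),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(p), "$TOT" = as.character(nrow(ev))
  )
  if (with_time) kw <- c(kw, "$TIMESTEP" = "1.0")
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- nm[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- sprintf("%d", as.integer(rng[i]))
  }
  paste0("/", paste(names(kw), kw, sep = "/", collapse = "/"), "/")
}

write_fcs <- function(table, path) {
  ev <- table$events
  with_time <- !is.null(table$time_s)
  p <- ncol(ev) + as.integer(with_time)
  n <- nrow(ev)
  # fixed-width offsets in TEXT make the text length independent of the values
  text <- fcs_text_keywords(table, 0, 0)
  text_begin <- 58L
  text_end <- text_begin + nchar(text, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * p * n - 1L
  if (p * n == 0L) { data_begin <- 0L; data_end <- 0L }
  text <- fcs_text_keywords(table, data_begin, data_end)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    data_begin, if (data_end <= 99999999) data_end else 0L,
                    0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stopf("cannot write '%s'", path))
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (p * n > 0L) {
    dat <- if (with_time) cbind(ev, Time = table$time_s) else ev
    writeBin(as.vector(t(dat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopf("'%s' is not an FCS 3.0/3.1 file (header '%s')", path, version)
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)
  if (is.na(text_begin) || is.na(text_end) || text_end <= text_begin)
    stopf("FCS '%s': malformed header offsets", path)
  seek(con, text_begin)
  raw_text <- readChar(con, text_end - text_begin + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  parts <- strsplit(substring(raw_text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(as.list(vals), keys)
  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) stopf("FCS '%s': missing required keyword %s", path, k)
    v
  }
  p <- as.integer(need("$PAR")); n <- as.integer(need("$TOT"))
  if (need("$MODE") != "L") stopf("FCS '%s': only list mode ($MODE L) supported", path)
  dtype <- need("$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- if (substr(byteord, 1, 1) == "1") "little" else "big"
  if (is.na(data_begin) || data_begin == 0) data_begin <- as.numeric(need("$BEGINDATA"))
  nm <- vapply(seq_len(p), function(i) need(sprintf("$P%dN", i)), "")
  vals_n <- p * n
  mat <- if (vals_n == 0L) {
    matrix(numeric(0), nrow = 0, ncol = p)
  } else {
    seek(con, data_begin)
    x <- switch(dtype,
      "F" = readBin(con, "double", n = vals_n, size = 4L, endian = endian),
      "D" = readBin(con, "double", n = vals_n, size = 8L, endian = endian),
      "I" = {
        bits <- as.integer(need("$P1B"))
        if (!bits %in% c(16L, 32L))
          stopf("FCS '%s': unsupported integer width $P1B=%d", path, bits)
        as.numeric(readBin(con, "integer", n = vals_n, size = bits / 8L,
                           signed = bits > 16L, endian = endian))
      },
      stopf("FCS '%s': unsupported $DATATYPE '%s'", path, dtype)
    )
    if (length(x) != vals_n) stopf("FCS '%s': truncated data segment", path)
    matrix(x, ncol = p, byrow = TRUE)
  }
  colnames(mat) <- nm
  time_s <- NULL
  time_idx <- which(tolower(nm) == "time")
  if (length(time_idx) == 1L && !is.null(kw[["$TIMESTEP"]])) {
    time_s <- mat[, time_idx] * as.numeric(kw[["$TIMESTEP"]])
    mat <- mat[, -time_idx, drop = FALSE]
    nm <- nm[-time_idx]
  }
  list(events = mat, channels = channels(nm), time_s = time_s)
}

# ---------------------------------------------------------------------------
# compensation

#' Spillover matrix
#'
#' Square matrix indexed by fluorescence channel names; entry \eqn{(i, j)} is
#' the fraction of dye \eqn{i}'s signal detected in channel \eqn{j}. The
#' convention throughout is `observed = true %*% S` with unit diagonal, so
#' compensation solves `true = observed %*% solve(S)`.
#'
#' @param mat square numeric matrix.
#' @param channels channel names; defaults to `rownames(mat)`.
#' @return validated spillover matrix with dimnames set.
#' @export
spillover_matrix <- function(mat, channels = rownames(mat)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stopf("spillover matrix must be square")
  if (is.null(channels)) stopf("spillover channels must be named")
  channels <- as.character(channels)
  if (length(channels) != nrow(mat)) stopf("spillover dimnames mismatch")
  if (any(abs(diag(mat) - 1) > 1e-9))
    stopf("spillover diagonal must equal 1")
  d <- det(mat)
  if (!is.finite(d) || abs(d) < 1e-12) stopf("spillover matrix is singular")
  dimnames(mat) <- list(channels, channels)
  mat
}

#' Apply spectral compensation
#'
#' Linearly unmixes the fluorescence columns of an event table using a
#' spillover matrix under the convention `observed = true %*% S`; scatter and
#' time columns are untouched. All fluorescence channels of the table must be
#' covered by the spillover matrix.
#'
#' @param table an [event_table()].
#' @param spillover a [spillover_matrix()].
#' @return the compensated [event_table()].
#' @export
apply_compensation <- function(table, spillover) {
  stopifnot(inherits(table, "EventTable"))
  spillover <- spillover_matrix(spillover)
  fluo <- fluorescence_channels(table)
  missing <- setdiff(fluo, rownames(spillover))
  if (length(missing))
    stopf("spillover does not cover fluorescence channel(s): %s",
          paste(missing, collapse = ", "))
  extra <- setdiff(rownames(spillover), fluo)
  if (length(extra))
    stopf("spillover names not present as fluorescence channels: %s",
          paste(extra, collapse = ", "))
  s_inv <- tryCatch(solve(spillover),
                    error = function(e) stopf("spillover matrix is singular"))
  ord <- rownames(spillover)
  out <- table
  out$events[, ord] <- table$events[, ord, drop = FALSE] %*% s_inv
  out
}

# ---------------------------------------------------------------------------
# gating

#' Gates on one or two channels
#'
#' Constructors for the gate geometries used for event selection. All gates
#' are closed regions: events exactly on the boundary are kept.
#'
#' `gate_rectangle()` keeps events with `xlim[1] <= x <= xlim[2]` and
#' `ylim[1] <= y <= ylim[2]`; `gate_polygon()` keeps events inside or on a
#' simple polygon (>= 3 vertices); `gate_threshold()` keeps events above
#' (`>=`) or below (`<=`) a bound on a single channel.
#'
#' @param channels one or two channel names.
#' @param xlim,ylim ordered numeric bounds of the rectangle.
#' @param vertices numeric matrix with 2 columns (x, y), >= 3 rows.
#' @param channel single channel name.
#' @param bound threshold value in channel units.
#' @param side `"above"` or `"below"`.
#' @return an object of class `Gate`.
#' @name gates
NULL

#' @rdname gates
#' @export
gate_rectangle <- function(channels, xlim, ylim) {
  stopifnot(length(channels) == 2L, length(xlim) == 2L, length(ylim) == 2L)
  if (xlim[1] > xlim[2] || ylim[1] > ylim[2])
    stopf("rectangle bounds must be ordered (lo <= hi)")
  structure(list(kind = "rectangle", channels = as.character(channels),
                 xlim = as.numeric(xlim), ylim = as.numeric(ylim)),
            class = "Gate")
}

#' @rdname gates
#' @export
gate_polygon <- function(channels, vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(length(channels) == 2L)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stopf("polygon needs >= 3 vertices as a 2-column matrix")
  structure(list(kind = "polygon", channels = as.character(channels),
                 vertices = vertices),
            class = "Gate")
}

#' @rdname gates
#' @export
gate_threshold <- function(channel, bound, side = c("above", "below")) {
  side <- match.arg(side)
  stopifnot(length(channel) == 1L, is_scalar_number(bound))
  structure(list(kind = paste0("threshold-", side), channels = as.character(channel),
                 bound = as.numeric(bound)),
            class = "Gate")
}

# closed point-in-polygon: even-odd rule plus explicit on-edge test
points_in_polygon <- function(x, y, vx, vy) {
  n <- length(x)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- x >= pmin(xi, xj) & x <= pmax(xi, xj) &
      y >= pmin(yi, yj) & y <= pmax(yi, yj)
    on_edge <- on_edge | (abs(cross) <= 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1) & within)
    crosses <- ((yi > y) != (yj > y))
    if (any(crosses)) {
      xint <- xi + (xj - xi) * (y - yi) / (yj - yi)
      inside <- xor(inside, crosses & x < xint)
    }
    j <- i
  }
  inside | on_edge
}

#' Apply a gate to an event table
#'
#' Subsets events to those satisfying the gate predicate (closed regions:
#' boundary events kept). Sample annotations are preserved and a gating
#' report (`n_in`, `n_kept`, `fraction`) is attached as attribute
#' `gating_report`.
#'
#' @param table an [event_table()].
#' @param gate a gate from [gate_rectangle()], [gate_polygon()] or
#'   [gate_threshold()].
#' @return the gated [event_table()].
#' @export
apply_gate <- function(table, gate) {
  stopifnot(inherits(table, "EventTable"), inherits(gate, "Gate"))
  for (ch in gate$channels) channel_column(table, ch)  # errors if missing
  keep <- switch(gate$kind,
    "rectangle" = {
      x <- channel_column(table, gate$channels[1])
      y <- channel_column(table, gate$channels[2])
      x >= gate$xlim[1] & x <= gate$xlim[2] &
        y >= gate$ylim[1] & y <= gate$ylim[2]
    },
    "polygon" = {
      x <- channel_column(table, gate$channels[1])
      y <- channel_column(table, gate$channels[2])
      points_in_polygon(x, y, gate$vertices[, 1], gate$vertices[, 2])
    },
    "threshold-above" = channel_column(table, gate$channels[1]) >= gate$bound,
    "threshold-below" = channel_column(table, gate$channels[1]) <= gate$bound,
    stopf("unknown gate kind '%s'", gate$kind)
  )
  out <- subset_events(table, keep)
  attr(out, "gating_report") <- list(
    n_in = n_events(table), n_kept = sum(keep),
    fraction = if (n_events(table) > 0) sum(keep) / n_events(table) else NA_real_
  )
  out
}

# ---------------------------------------------------------------------------
# viability

#' Viability quadrant fractions
#'
#' Splits events into quadrants on a necrosis marker (e.g. a dead-cell DNA
#' stain) and an apoptosis marker (e.g. labelled annexin V) using per-channel
#' thresholds: an event is positive when its intensity exceeds the threshold.
#' The double-negative fraction is the living-cell readout.
#'
#' @param table an [event_table()] with at least one event.
#' @param necrosis_channel,apoptosis_channel channel names.
#' @param thresholds numeric length-2 vector `c(necrosis, apoptosis)` (finite).
#' @return named numeric vector `living`, `necrotic_only`, `apoptotic_only`,
#'   `double_positive` (sums to 1), with attribute `n_events`.
#' @export
viability_fractions <- function(table, necrosis_channel, apoptosis_channel,
                                thresholds) {
  stopifnot(inherits(table, "EventTable"))
  if (n_events(table) == 0L) stopf("viability fractions undefined for an empty table")
  if (length(thresholds) != 2L || any(!is.finite(thresholds)))
    stopf("`thresholds` must be two finite numbers c(necrosis, apoptosis)")
  nec <- channel_column(table, necrosis_channel) > thresholds[1]
  apo <- channel_column(table, apoptosis_channel) > thresholds[2]
  n <- n_events(table)
  out <- c(
    living = sum(!nec & !apo) / n,
    necrotic_only = sum(nec & !apo) / n,
    apoptotic_only = sum(!nec & apo) / n,
    double_positive = sum(nec & apo) / n
  )
  attr(out, "n_events") <- n
  out
}
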