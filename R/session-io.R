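#' Write a session to disk
#'
#' Two interchange formats are supported. `"csv"` writes a directory of plain
#' CSV files (comma-separated, header row, UTF-8, '.' decimal) plus a JSON
#' manifest holding the sampling rate and channel metadata. `"hdf5"` writes a
#' single HDF5 container with one group per modality: `/photometry`,
#' `/events`, `/units/<id>`, `/position`, with rate and units stored as
#' attributes. Both round-trip through [read_session()] with loss only from
#' float representation in CSV.
#'
#' @param x a [session()].
#' @param path destination directory (csv) or file (hdf5).
#' @param format `"csv"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(x, path, format = c("csv", "hdf5")) {
  stopifnot(inherits(x, "session"))
  format <- match.arg(format)
  if (format == "csv") write_session_csv(x, path) else write_session_h5(x, path)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path a session directory (csv format) or HDF5 file.
#' @param format `"csv"` or `"hdf5"`.
#' @return A validated [session()]; all type invariants are re-checked on
#'   read and violations raise errors rather than being repaired.
#' @export
read_session <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such session path: %s", path))
  if (format == "csv") read_session_csv(path) else read_session_h5(path)
}

# -- CSV bundle ---------------------------------------------------------------

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", file,
                 paste(missing, collapse = ", ")))
}

write_session_csv <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- list(format_version = 1L)
  if (!is.null(x$recording)) {
    man$photometry <- list(rate = x$recording$rate, t0 = x$recording$t0,
                           channel_label = x$recording$channel_label)
    utils::write.csv(data.frame(fluor = x$recording$trace),
                     file.path(path, "trace.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(data.frame(onset = x$events$onset,
                              label = x$events$label,
                              duration = x$events$duration),
                   file.path(path, "events.csv"), row.names = FALSE)
  if (length(x$units)) {
    man$units <- lapply(x$units, function(u) {
      m <- list(unit_id = u$unit_id, duration = u$duration,
                n_waveform_channels =
                  if (length(u$waveform_mean)) nrow(as.matrix_wf(u$waveform_mean)) else 0L)
      if (!is.null(u$light_pulses)) m$pulse_width <- u$light_pulses$width
      m
    })
    spk <- do.call(rbind, lapply(x$units, function(u)
      if (length(u$spike_times))
        data.frame(unit_id = u$unit_id, spike_time = u$spike_times)))
    utils::write.csv(
      if (is.null(spk)) data.frame(unit_id = character(), spike_time = numeric())
      else spk,
      file.path(path, "spikes.csv"), row.names = FALSE)
    utils::write.csv(wf_long(x$units), file.path(path, "waveforms.csv"),
                     row.names = FALSE)
    pul <- do.call(rbind, lapply(x$units, function(u)
      if (!is.null(u$light_pulses) && length(u$light_pulses$onsets))
        data.frame(unit_id = u$unit_id,
                   onset = u$light_pulses$onsets)))
    if (!is.null(pul))
      utils::write.csv(pul, file.path(path, "light_pulses.csv"),
                       row.names = FALSE)
  }
  if (!is.null(x$position))
    utils::write.csv(data.frame(time = x$position$times,
                                x = x$position$xy[, 1],
                                y = x$position$xy[, 2]),
                     file.path(path, "position.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "manifest.json"))
  path
}

as.matrix_wf <- function(w) if (is.matrix(w)) w else matrix(w, nrow = 1L)

wf_long <- function(units) {
  rows <- lapply(units, function(u) {
    out <- NULL
    for (kind in c("waveform_mean", "waveform_evoked")) {
      w <- u[[kind]]
      if (is.null(w) || !length(w)) next
      w <- as.matrix_wf(w)
      out <- rbind(out, data.frame(
        unit_id = u$unit_id, kind = sub("waveform_", "", kind),
        channel = rep(seq_len(nrow(w)), each = ncol(w)),
        sample = rep(seq_len(ncol(w)), nrow(w)),
        value = as.vector(t(w))))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = character(), kind = character(),
                      channel = integer(), sample = integer(),
                      value = numeric())
  out
}

wf_from_long <- function(df) {
  if (!nrow(df)) return(NULL)
  nch <- max(df$channel)
  ns <- max(df$sample)
  w <- matrix(NA_real_, nch, ns)
  w[cbind(df$channel, df$sample)] <- as.numeric(df$value)
  if (nch == 1L) as.vector(w) else w
}

read_session_csv <- function(path) {
  manp <- file.path(path, "manifest.json")
  if (!file.exists(manp)) stop(sprintf("%s: manifest.json not found", path))
  man <- jsonlite::fromJSON(manp, simplifyVector = TRUE)
  rec <- NULL
  if (!is.null(man$photometry)) {
    tr <- utils::read.csv(file.path(path, "trace.csv"))
    check_columns(tr, "fluor", "trace.csv")
    rec <- recording(as.numeric(tr$fluor), rate = man$photometry$rate,
                     t0 = man$photometry$t0,
                     channel_label = man$photometry$channel_label)
  }
  ev <- utils::read.csv(file.path(path, "events.csv"))
  check_columns(ev, c("onset", "label", "duration"), "events.csv")
  events <- event_stream(as.numeric(ev$onset), as.character(ev$label),
                         as.numeric(ev$duration))
  units <- list()
  if (!is.null(man$units) && length(man$units)) {
    spk <- utils::read.csv(file.path(path, "spikes.csv"))
    check_columns(spk, c("unit_id", "spike_time"), "spikes.csv")
    wfs <- utils::read.csv(file.path(path, "waveforms.csv"))
    pulp <- file.path(path, "light_pulses.csv")
    pul <- if (file.exists(pulp)) utils::read.csv(pulp) else NULL
    units <- lapply(man$units, function(m) {
      lp <- NULL
      if (!is.null(pul)) {
        on <- as.numeric(pul$onset[pul$unit_id == m$unit_id])
        if (length(on)) lp <- list(onsets = on, width = m$pulse_width)
      }
      spike_unit(as.numeric(spk$spike_time[spk$unit_id == m$unit_id]),
                 waveform_mean = wf_from_long(
                   wfs[wfs$unit_id == m$unit_id & wfs$kind == "mean", ]),
                 unit_id = m$unit_id, light_pulses = lp,
                 waveform_evoked = wf_from_long(
                   wfs[wfs$unit_id == m$unit_id & wfs$kind == "evoked", ]),
                 duration = m$duration)
    })
    names(units) <- vapply(units, `[[`, "", "unit_id")
  }
  pos <- NULL
  posp <- file.path(path, "position.csv")
  if (file.exists(posp)) {
    pp <- utils::read.csv(posp)
    check_columns(pp, c("time", "x", "y"), "position.csv")
    pos <- position_trace(as.numeric(pp$time), cbind(pp$x, pp$y))
  }
  session(rec, events, units, pos)
}

# -- HDF5 container -----------------------------------------------------------

h5_attr <- function(file, name, obj) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid))
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  vals <- rhdf5::h5readAttributes(file, obj)
  vals[[name]]
}

write_session_h5 <- function(x, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  if (!is.null(x$recording)) {
    rhdf5::h5createGroup(path, "photometry")
    rhdf5::h5write(x$recording$trace, path, "photometry/trace")
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "photometry")
    rhdf5::h5writeAttribute(x$recording$rate, gid, "rate")
    rhdf5::h5writeAttribute(x$recording$t0, gid, "t0")
    rhdf5::h5writeAttribute(x$recording$channel_label, gid, "channel_label")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  }
  rhdf5::h5createGroup(path, "events")
  rhdf5::h5write(x$events$onset, path, "events/onset")
  rhdf5::h5write(x$events$label, path, "events/label")
  rhdf5::h5write(x$events$duration, path, "events/duration")
  if (length(x$units)) {
    rhdf5::h5createGroup(path, "units")
    for (u in x$units) {
      g <- paste0("units/", u$unit_id)
      rhdf5::h5createGroup(path, g)
      rhdf5::h5write(u$spike_times, path, paste0(g, "/spike_times"))
      if (length(u$waveform_mean))
        rhdf5::h5write(as.matrix_wf(u$waveform_mean), path,
                       paste0(g, "/waveform_mean"))
      if (!is.null(u$waveform_evoked) && length(u$waveform_evoked))
        rhdf5::h5write(as.matrix_wf(u$waveform_evoked), path,
                       paste0(g, "/waveform_evoked"))
      if (!is.null(u$light_pulses))
        rhdf5::h5write(u$light_pulses$onsets, path, paste0(g, "/pulse_onsets"))
      fid <- rhdf5::H5Fopen(path)
      gid <- rhdf5::H5Gopen(fid, g)
      rhdf5::h5writeAttribute(u$duration, gid, "duration")
      if (!is.null(u$light_pulses))
        rhdf5::h5writeAttribute(u$light_pulses$width, gid, "pulse_width")
      rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    }
  }
  if (!is.null(x$position)) {
    rhdf5::h5createGroup(path, "position")
    rhdf5::h5write(x$position$times, path, "position/times")
    rhdf5::h5write(x$position$xy, path, "position/xy")
  }
  path
}

read_session_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  ls <- rhdf5::h5ls(path)
  top <- ls$name[ls$group == "/"]
  rec <- NULL
  if ("photometry" %in% top) {
    at <- rhdf5::h5readAttributes(path, "photometry")
    rec <- recording(as.numeric(rhdf5::h5read(path, "photometry/trace")),
                     rate = as.numeric(at$rate), t0 = as.numeric(at$t0),
                     channel_label = as.character(at$channel_label))
  }
  if (!"events" %in% top) stop(sprintf("%s: /events group not found", path))
  events <- event_stream(as.numeric(rhdf5::h5read(path, "events/onset")),
                         as.character(rhdf5::h5read(path, "events/label")),
                         as.numeric(rhdf5::h5read(path, "events/duration")))
  units <- list()
  if ("units" %in% top) {
    uids <- ls$name[ls$group == "/units"]
    units <- lapply(uids, function(uid) {
      g <- paste0("units/", uid)
      at <- rhdf5::h5readAttributes(path, g)
      members <- ls$name[ls$group == paste0("/", g)]
      wf <- if ("waveform_mean" %in% members)
        drop1(rhdf5::h5read(path, paste0(g, "/waveform_mean"))) else numeric()
      we <- if ("waveform_evoked" %in% members)
        drop1(rhdf5::h5read(path, paste0(g, "/waveform_evoked"))) else NULL
      lp <- if ("pulse_onsets" %in% members)
        list(onsets = as.numeric(rhdf5::h5read(path, paste0(g, "/pulse_onsets"))),
             width = as.numeric(at$pulse_width)) else NULL
      spike_unit(as.numeric(rhdf5::h5read(path, paste0(g, "/spike_times"))),
                 waveform_mean = wf, unit_id = uid, light_pulses = lp,
                 waveform_evoked = we, duration = as.numeric(at$duration))
    })
    names(units) <- uids
  }
  pos <- NULL
  if ("position" %in% top)
    pos <- position_trace(as.numeric(rhdf5::h5read(path, "position/times")),
                          rhdf5::h5read(path, "position/xy"))
  session(rec, events, units, pos)
}

drop1 <- function(w) { w <- as.matrix(w); if (nrow(w) == 1L) as.vector(w) else w }
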