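#' Construct a voltage-clamp protocol from segments
#'
#' @param ... segment descriptions from [holdSegment()], [rampSegment()] or
#'   [sineSegment()], or a single list of them.
#' @return A [VoltageProtocol-class].
#' @examples
#' p <- voltageProtocol(holdSegment(-80, 1000), rampSegment(-80, 40, 500))
#' voltageAt(p, c(0, 1000, 1250))
#' @export
voltageProtocol <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) && is.null(segs[[1]]$kind))
    segs <- segs[[1]]
  new("VoltageProtocol", segments = segs)
}

#' Protocol segment constructors
#'
#' Build the three supported segment kinds: a constant hold, a linear ramp,
#' and a sinusoid \code{vOffset + amplitude * sin(2*pi*t/period + phase)}
#' (with t measured from the segment start).
#'
#' @param v hold voltage (mV).
#' @param duration segment duration (ms), > 0.
#' @return A segment description list for [voltageProtocol()].
#' @export
holdSegment <- function(v, duration)
  list(kind = "hold", duration = duration, v = v)

#' @rdname holdSegment
#' @param vStart,vEnd ramp endpoint voltages (mV); the ramp reaches
#'   \code{vEnd} at the segment's right (open) end.
#' @export
rampSegment <- function(vStart, vEnd, duration)
  list(kind = "ramp", duration = duration, vStart = vStart, vEnd = vEnd)

#' @rdname holdSegment
#' @param vOffset,amplitude sinusoid offset and amplitude (mV).
#' @param period sinusoid period (ms), > 0.
#' @param phase phase at segment start (rad).
#' @export
sineSegment <- function(vOffset, amplitude, period, duration, phase = 0)
  list(kind = "sine", duration = duration, vOffset = vOffset,
       amplitude = amplitude, period = period, phase = phase)

#' Total protocol duration
#'
#' @param protocol a [VoltageProtocol-class].
#' @return Duration in ms.
#' @export
protocolDuration <- function(protocol)
  sum(vapply(protocol@segments, `[[`, numeric(1), "duration"))

#' Segment start times (including the final end time)
#' @noRd
.segmentBounds <- function(protocol)
  cumsum(c(0, vapply(protocol@segments, `[[`, numeric(1), "duration")))

.segmentVoltage <- function(seg, tRel) {
  switch(seg$kind,
    hold = rep(seg$v, length(tRel)),
    ramp = seg$vStart + tRel / seg$duration * (seg$vEnd - seg$vStart),
    sine = seg$vOffset + seg$amplitude *
      sin(2 * pi * tRel / seg$period + seg$phase))
}

#' Evaluate the protocol voltage at given times
#'
#' Segments are left-closed/right-open: at an internal boundary the later
#' segment's voltage applies. The final instant (t equal to the total
#' duration) takes the last segment's value.
#'
#' @param protocol a [VoltageProtocol-class].
#' @param t times (ms), each within \[0, total duration\].
#' @return Voltages (mV), one per time.
#' @export
voltageAt <- function(protocol, t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  bounds <- .segmentBounds(protocol)
  total <- bounds[length(bounds)]
  if (any(t < 0 | t > total))
    stop("time out of protocol range [0, ", total, "] ms", call. = FALSE)
  # left-closed/right-open; the final instant belongs to the last segment
  idx <- findInterval(t, bounds, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx > length(protocol@segments)] <- length(protocol@segments)
  v <- numeric(length(t))
  for (i in unique(idx)) {
    sel <- idx == i
    v[sel] <- .segmentVoltage(protocol@segments[[i]], t[sel] - bounds[i])
  }
  v
}

#' Built-in information-rich fixture protocol
#'
#' A deterministic 12 s voltage-clamp protocol designed to exercise
#' activation, inactivation and recovery of the hERG channel, so that all
#' nine model parameters are identifiable from a single recording: a 2 s
#' hold at -80 mV, a staircase of six 500 ms steps spanning -60 to +40 mV
#' each followed by a 500 ms step to -40 mV (where the large tail currents
#' expose deactivation and recovery), a 2 s sinusoidal sweep
#' (-30 +/- 30 mV, 200 ms period), and a final 2 s hold at -80 mV.
#'
#' @return A [VoltageProtocol-class] of total duration 12,000 ms.
#' @export
defaultFixtureProtocol <- function() {
  segs <- list(holdSegment(-80, 2000))
  for (v in seq(-60, 40, by = 20)) {
    segs <- c(segs, list(holdSegment(v, 500), holdSegment(-40, 500)))
  }
  segs <- c(segs,
            list(sineSegment(vOffset = -30, amplitude = 30, period = 200,
                             duration = 2000, phase = 0),
                 holdSegment(-80, 2000)))
  voltageProtocol(segs)
}

#' Write a protocol to its JSON file form
#'
#' @param protocol a [VoltageProtocol-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  jsonlite::write_json(list(segments = protocol@segments), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a protocol from its JSON file form
#'
#' @param path path to a protocol JSON file (an object with a "segments"
#'   list as written by [writeProtocol()]).
#' @return A [VoltageProtocol-class].
#' @export
readProtocol <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$segments))
    stop("protocol file must contain a 'segments' list", call. = FALSE)
  voltageProtocol(doc$segments)
}
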