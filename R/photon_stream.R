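#' Instrument configuration for polarization-resolved TCSPC
#'
#' Describes the excitation/detection hardware parameters needed to interpret a
#' photon stream: the laser pulse period (80 MHz repetition gives 12.5 ns), the
#' micro-time digitizer resolution, the macro-time clock tick, the g-factor
#' correcting unequal detection efficiency of the perpendicular channel, and
#' the dark count rate of each detector.
#'
#' @param pulse_period_ns Time between excitation pulses in ns (> 0).
#' @param micro_resolution_ns Micro-time bin width of the digitizer in ns;
#'   must be positive and no larger than the pulse period. Default: 1024 bins
#'   per pulse period.
#' @param macro_clock_s Duration of one macro-time tick in seconds. Default:
#'   one pulse period.
#' @param g_factor Dimensionless perpendicular-channel correction g (> 0).
#' @param dark_rate_par_cps,dark_rate_perp_cps Detector dark count rates in
#'   counts per second (>= 0).
#' @return An object of class `instrument_config`.
#' @examples
#' cfg <- instrument_config()           # 80 MHz defaults
#' cfg$pulse_period_ns                  # 12.5
#' @export
instrument_config <- function(pulse_period_ns = 12.5,
                              micro_resolution_ns = pulse_period_ns / 1024,
                              macro_clock_s = pulse_period_ns * 1e-9,
                              g_factor = 1,
                              dark_rate_par_cps = 500,
                              dark_rate_perp_cps = 500) {
  stopifnot(
    is.numeric(pulse_period_ns), length(pulse_period_ns) == 1L, pulse_period_ns > 0,
    is.numeric(micro_resolution_ns), micro_resolution_ns > 0,
    micro_resolution_ns <= pulse_period_ns,
    is.numeric(macro_clock_s), macro_clock_s > 0,
    is.numeric(g_factor), g_factor > 0,
    dark_rate_par_cps >= 0, dark_rate_perp_cps >= 0
  )
  structure(
    list(
      pulse_period_ns = as.numeric(pulse_period_ns),
      micro_resolution_ns = as.numeric(micro_resolution_ns),
      macro_clock_s = as.numeric(macro_clock_s),
      g_factor = as.numeric(g_factor),
      dark_rate_par_cps = as.numeric(dark_rate_par_cps),
      dark_rate_perp_cps = as.numeric(dark_rate_perp_cps)
    ),
    class = "instrument_config"
  )
}

# channel encoding is fixed: 0 = parallel, 1 = perpendicular
.CH_PAR <- 0L
.CH_PERP <- 1L

#' Map a channel name to its integer code
#' @param channel `"parallel"` or `"perpendicular"` (or the codes 0/1).
#' @return Integer code: 0 for parallel, 1 for perpendicular.
#' @keywords internal
channel_code <- function(channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (!ch %in% c(.CH_PAR, .CH_PERP)) stop("channel code must be 0 or 1")
    return(ch)
  }
  switch(match.arg(channel, c("parallel", "perpendicular")),
    parallel = .CH_PAR, perpendicular = .CH_PERP
  )
}

#' Polarization-resolved photon stream
#'
#' Container for per-photon TCSPC records. Each photon carries a detection
#' channel (0 = parallel, 1 = perpendicular), an integer macro-time in
#' macro-clock ticks since acquisition start, and a micro-time in ns since the
#' preceding excitation pulse. Macro-times are stored as integer-valued doubles
#' (exact up to 2^53) so long acquisitions do not overflow R's 32-bit integers.
#'
#' @param records Data frame with columns `channel` (integer 0/1),
#'   `macro_ticks` (integer-valued, non-decreasing) and `micro_ns`
#'   (0 <= micro < pulse period).
#' @param instrument An [instrument_config()].
#' @param duration_s Acquisition length in seconds; all records must fit.
#' @param provenance Free-text description or ground-truth reference.
#' @return An object of class `photon_stream`.
#' @export
photon_stream <- function(records, instrument, duration_s, provenance = "") {
  stopifnot(inherits(instrument, "instrument_config"),
            is.data.frame(records),
            all(c("channel", "macro_ticks", "micro_ns") %in% names(records)),
            is.numeric(duration_s), length(duration_s) == 1L, duration_s > 0)
  records <- records[, c("channel", "macro_ticks", "micro_ns")]
  n <- nrow(records)
  if (n > 0) {
    if (!all(records$channel %in% c(.CH_PAR, .CH_PERP)))
      stop("channel must be 0 (parallel) or 1 (perpendicular)")
    if (any(records$macro_ticks != floor(records$macro_ticks)))
      stop("macro_ticks must be integer-valued")
    if (is.unsorted(records$macro_ticks))
      stop("macro_ticks must be non-decreasing")
    bad <- which(records$micro_ns < 0 | records$micro_ns >= instrument$pulse_period_ns)
    if (length(bad))
      stop(sprintf("micro_time out of [0, pulse_period) at record %d (%.6g ns)",
                   bad[1], records$micro_ns[bad[1]]))
    if (max(records$macro_ticks) * instrument$macro_clock_s > duration_s)
      stop("records extend beyond the stated acquisition duration")
  }
  records$channel <- as.integer(records$channel)
  structure(
    list(records = records, instrument = instrument,
         duration_s = as.numeric(duration_s),
         provenance = as.character(provenance)),
    class = "photon_stream"
  )
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<photon_stream> %d photons over %.4g s (%.0f cps)\n",
              n, x$duration_s, n / x$duration_s))
  cat(sprintf("  parallel: %d  perpendicular: %d\n",
              sum(x$records$channel == .CH_PAR), sum(x$records$channel == .CH_PERP)))
  cat(sprintf("  pulse period %.4g ns, macro clock %.4g s, g = %.4g\n",
              x$instrument$pulse_period_ns, x$instrument$macro_clock_s,
              x$instrument$g_factor))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Mean detected count rate of a stream
#' @param stream A [photon_stream()].
#' @param channel Optional channel restriction (`"parallel"`/`"perpendicular"`).
#' @return Count rate in counts/s.
#' @export
count_rate <- function(stream, channel = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  n <- if (is.null(channel)) nrow(stream$records)
       else sum(stream$records$channel == channel_code(channel))
  n / stream$duration_s
}

#' Photon arrival times in seconds
#' @param stream A [photon_stream()].
#' @param channel Optional channel restriction.
#' @return Numeric vector of macro arrival times (s).
#' @export
arrival_times <- function(stream, channel = NULL) {
  r <- stream$records
  if (!is.null(channel)) r <- r[r$channel == channel_code(channel), ]
  r$macro_ticks * stream$instrument$macro_clock_s
}

# header fields written/required by the photon-record text format
.HEADER_FIELDS <- c("pulse_period_ns", "micro_resolution_ns", "macro_clock_s",
                    "g_factor", "dark_rate_par_cps", "dark_rate_perp_cps",
                    "duration_s")

#' Write a photon stream to the flat text photon-record format
#'
#' The format is a tab-delimited text file with a `# key = value` header
#' carrying the instrument metadata and acquisition duration, followed by one
#' row per photon: `channel<TAB>macro_time_ticks<TAB>micro_time_ns`
#' (channel 0 = parallel, 1 = perpendicular). Numbers are written with 17
#' significant digits so a read/write round trip is bit-exact.
#'
#' @param stream A [photon_stream()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_photon_stream()]
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  ins <- stream$instrument
  vals <- c(ins$pulse_period_ns, ins$micro_resolution_ns, ins$macro_clock_s,
            ins$g_factor, ins$dark_rate_par_cps, ins$dark_rate_perp_cps,
            stream$duration_s)
  hdr <- c("# fpfa photon stream v1",
           sprintf("# %s = %.17g", .HEADER_FIELDS, vals),
           "# channels = 0:parallel,1:perpendicular",
           paste0("# provenance = ", gsub("[\r\n]", " ", stream$provenance)),
           "channel\tmacro_time_ticks\tmicro_time_ns")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  r <- stream$records
  if (nrow(r) > 0) {
    writeLines(sprintf("%d\t%.0f\t%.17g", r$channel, r$macro_ticks, r$micro_ns), con)
  }
  invisible(path)
}

#' Read a photon stream from the flat text photon-record format
#'
#' @param path Path to a file written by [write_photon_stream()] (or produced
#'   by a converter emitting the same layout).
#' @return A [photon_stream()]; the instrument metadata is populated from the
#'   header and record order is preserved.
#' @export
read_photon_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 64L)
  hdr_n <- which(!startsWith(lines, "#"))[1]
  if (is.na(hdr_n)) stop("malformed photon file: no column-header line found")
  hdr <- lines[seq_len(hdr_n - 1L)]
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  named <- stats::setNames(vals[!is.na(keys)], keys[!is.na(keys)])
  missing <- setdiff(.HEADER_FIELDS, names(named))
  if (length(missing))
    stop("malformed photon file header: missing field '", missing[1], "'")
  num <- function(k) {
    v <- suppressWarnings(as.numeric(named[[k]]))
    if (is.na(v)) stop("malformed photon file header: field '", k,
                       "' is not numeric ('", named[[k]], "')")
    v
  }
  ins <- instrument_config(
    pulse_period_ns = num("pulse_period_ns"),
    micro_resolution_ns = num("micro_resolution_ns"),
    macro_clock_s = num("macro_clock_s"),
    g_factor = num("g_factor"),
    dark_rate_par_cps = num("dark_rate_par_cps"),
    dark_rate_perp_cps = num("dark_rate_perp_cps")
  )
  dat <- utils::read.table(path, sep = "\t", skip = hdr_n, header = FALSE,
                           col.names = c("channel", "macro_ticks", "micro_ns"),
                           colClasses = c("integer", "numeric", "numeric"),
                           comment.char = "")
  if (nrow(dat) > 0) {
    bad <- which(dat$micro_ns >= ins$pulse_period_ns | dat$micro_ns < 0)
    if (length(bad))
      stop(sprintf("invalid record %d: micro_time %.6g ns outside [0, %.6g)",
                   bad[1], dat$micro_ns[bad[1]], ins$pulse_period_ns))
  }
  prov <- if ("provenance" %in% names(named)) named[["provenance"]] else ""
  photon_stream(dat, ins, duration_s = num("duration_s"), provenance = prov)
}

#' Micro-time decay histogram of a photon stream
#'
#' Bins photon micro-times over one excitation period into half-open bins
#' `[left, right)`; the last bin absorbs any remainder when the bin width does
#' not divide the pulse period. Both polarization channels are histogrammed so
#' the result feeds directly into anisotropy and lifetime analysis, and the
#' expected constant dark-count level per bin is computed from the instrument
#' dark rates (rate x duration x bin fraction of the period).
#'
#' @param stream A [photon_stream()].
#' @param bin_width_ns Micro-time bin width in ns. Snapped to the nearest
#'   integer multiple of the stream's digitizer resolution (when coarser than
#'   it), so histogram bins always contain a whole number of ADC channels;
#'   otherwise the incommensurate grids beat against each other and imprint a
#'   sawtooth on the decay.
#' @return An object of class `decay_histogram` with fields `bin_centers_ns`,
#'   `counts_par`, `counts_perp`, `dark_level_par`, `dark_level_perp`,
#'   `bin_width_ns`, `duration_s`.
#' @export
micro_time_histogram <- function(stream, bin_width_ns = 0.1,
                                 channel = c("both", "parallel", "perpendicular")) {
  stopifnot(inherits(stream, "photon_stream"), bin_width_ns > 0)
  channel <- match.arg(channel)
  period <- stream$instrument$pulse_period_ns
  if (bin_width_ns > period) stop("bin_width_ns exceeds the pulse period")
  res <- stream$instrument$micro_resolution_ns
  if (is.finite(res) && res > 0 && bin_width_ns > res)
    bin_width_ns <- max(1, round(bin_width_ns / res)) * res
  n_bins <- max(1L, as.integer(floor(period / bin_width_ns + 1e-9)))
  bin_of <- function(micro) pmin(floor(micro / bin_width_ns), n_bins - 1L) + 1L
  hist_ch <- function(code) {
    m <- stream$records$micro_ns[stream$records$channel == code]
    if (length(m) == 0) {
      warning("no photons in ", if (code == .CH_PAR) "parallel" else "perpendicular",
              " channel; histogram of zeros")
      return(rep(0, n_bins))
    }
    as.numeric(tabulate(bin_of(m), nbins = n_bins))
  }
  counts_par <- if (channel %in% c("both", "parallel")) hist_ch(.CH_PAR) else rep(0, n_bins)
  counts_perp <- if (channel %in% c("both", "perpendicular")) hist_ch(.CH_PERP) else rep(0, n_bins)
  dark_bin <- function(rate) rate * stream$duration_s * (bin_width_ns / period)
  structure(
    list(
      bin_centers_ns = (seq_len(n_bins) - 0.5) * bin_width_ns,
      counts_par = counts_par,
      counts_perp = counts_perp,
      dark_level_par = if (channel %in% c("both", "parallel"))
        dark_bin(stream$instrument$dark_rate_par_cps) else 0,
      dark_level_perp = if (channel %in% c("both", "perpendicular"))
        dark_bin(stream$instrument$dark_rate_perp_cps) else 0,
      bin_width_ns = bin_width_ns,
      duration_s = stream$duration_s
    ),
    class = "decay_histogram"
  )
}

#' Binned intensity trace of a photon stream
#'
#' Counts photons in consecutive macro-time bins across the acquisition; the
#' last bin absorbs the remainder of the duration. The mean count per bin
#' divided by the bin width estimates the average count rate `<k>`, and a
#' regression on the trace is the standard quality check for bleaching.
#'
#' @param stream A [photon_stream()].
#' @param bin_width_s Trace bin width in seconds (<= duration).
#' @return Data frame with `time_s` (bin centers), `counts_par`, `counts_perp`
#'   and `counts` (total); attribute `bin_width_s`.
#' @export
intensity_trace <- function(stream, bin_width_s) {
  stopifnot(inherits(stream, "photon_stream"),
            bin_width_s > 0, bin_width_s <= stream$duration_s)
  n_bins <- max(1L, as.integer(floor(stream$duration_s / bin_width_s + 1e-9)))
  t_s <- arrival_times(stream)
  idx <- pmin(floor(t_s / bin_width_s), n_bins - 1L) + 1L
  par <- tabulate(idx[stream$records$channel == .CH_PAR], nbins = n_bins)
  perp <- tabulate(idx[stream$records$channel == .CH_PERP], nbins = n_bins)
  out <- data.frame(
    time_s = (seq_len(n_bins) - 0.5) * bin_width_s,
    counts_par = par, counts_perp = perp, counts = par + perp
  )
  attr(out, "bin_width_s") <- bin_width_s
  out
}

#' Export a decay histogram as TSV
#' @param hist A `decay_histogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_decay_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  utils::write.table(
    data.frame(bin_center_ns = hist$bin_centers_ns,
               counts_par = hist$counts_par, counts_perp = hist$counts_perp),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
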