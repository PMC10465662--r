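#' Unit conversion for pressure and flow values
#'
#' Exact conversion between the supported pressure units
#' (`Pa`, `kPa`, `mmHg`) and flow units (`m3/s`, `cm3/s`, `l/min`),
#' using 1 mmHg = 133.322387415 Pa.
#'
#' @param x numeric vector or [time_series()].
#' @param from,to unit labels.
#' @return Converted values (same shape as `x`; a `time_series` keeps its
#'   grid and gets the new unit label).
#' @export
convert_units <- function(x, from, to) {
  to_si <- c("Pa" = 1, "kPa" = 1e3, "mmHg" = 133.322387415,
             "m3/s" = 1, "cm3/s" = 1e-6, "l/min" = 1 / 6e4)
  if (!from %in% names(to_si)) stop("unknown unit label: ", from)
  if (!to %in% names(to_si)) stop("unknown unit label: ", to)
  kind <- function(u) if (u %in% c("Pa", "kPa", "mmHg")) "pressure" else "flow"
  if (kind(from) != kind(to))
    stop("cannot convert between pressure and flow units")
  f <- to_si[[from]] / to_si[[to]]
  if (inherits(x, "time_series")) {
    x$values <- x$values * f
    x$unit <- to
    x
  } else x * f
}

#' Relative waveform reconstruction error
#'
#' Discrete relative 2-norm error
#' \deqn{\frac{\|p - p_M\|_2}{\|p\|_2}}
#' between a reference signal and a model reconstruction over a window
#' (default: the whole record).  The conventional summary for judging a
#' fitted boundary condition is this error over one period at periodic
#' state; pass `period` to use the last full cycle.
#'
#' @param reference reference [time_series()].
#' @param model_out reconstructed `time_series` on the same grid.
#' @param window optional integer index vector selecting the comparison
#'   window.
#' @param period optional cycle length (s); when given (and `window` is
#'   not), the window is the last full cycle of the record.
#' @return Relative error (dimensionless fraction).
#' @export
relative_error <- function(reference, model_out, window = NULL,
                           period = NULL) {
  stopifnot(inherits(reference, "time_series"),
            inherits(model_out, "time_series"))
  if (length(reference$values) != length(model_out$values))
    stop("signals must share the sampling grid")
  if (is.null(window)) {
    K <- length(reference$values)
    window <- if (is.null(period)) seq_len(K)
              else seq(max(1L, K - round(period / reference$dt)), K)
  }
  ref <- Re(reference$values[window])
  mod <- Re(model_out$values[window])
  nrm <- sqrt(sum(ref^2))
  if (nrm == 0) stop("reference has zero norm over the window")
  sqrt(sum((ref - mod)^2)) / nrm
}

#' Write paired waveforms to CSV
#'
#' Plain-text format: a unit declaration comment line
#' `# units: s,<pressure unit>,<flow unit>` followed by a `t,p,q` header
#' and one row per sample.
#'
#' @param w a [hemo_waveforms()] (SI units internally).
#' @param path output file.
#' @param units length-2 character: pressure and flow units to write in.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(w, path, units = c("Pa", "m3/s")) {
  stopifnot(inherits(w, "hemo_waveforms"), length(units) == 2)
  p <- convert_units(Re(w$pressure$values), "Pa", units[1])
  q <- convert_units(Re(w$flow$values), "m3/s", units[2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: s,%s,%s", units[1], units[2]), con)
  utils::write.csv(data.frame(t = time_points(w$pressure), p = p, q = q),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read paired waveforms from CSV
#'
#' Parses the `# units:` declaration (default `s,Pa,m3/s` when absent),
#' checks that the time column is strictly increasing and uniformly
#' spaced (relative tolerance 1e-9 on the median step), converts to SI,
#' and returns a [hemo_waveforms()].
#'
#' @param path CSV file written by [write_waveforms()] or compatible.
#' @return A `hemo_waveforms` object (SI units).
#' @export
read_waveforms <- function(path) {
  first <- readLines(path, n = 1L)
  units <- c("Pa", "m3/s")
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("units:\\s*s\\s*,\\s*([^,]+)\\s*,\\s*(.+)$",
                                   first))[[1]]
    if (length(m) == 3) units <- trimws(m[2:3])
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "p", "q")
  if (!all(need %in% names(df)))
    stop("waveform CSV must have columns t,p,q (line 1-2 of ", path, ")")
  if (anyNA(df))
    stop("waveform CSV contains missing values: ", path)
  dtv <- diff(df$t)
  if (any(dtv <= 0))
    stop("time column must be strictly increasing (near line ",
         which(dtv <= 0)[1] + 2L, ")")
  dt <- stats::median(dtv)
  if (any(abs(dtv - dt) > 1e-9 * dt * pmax(1, abs(df$t[-1]) / dt)))
    stop("time column is not uniformly sampled (near line ",
         which(abs(dtv - dt) > 1e-9 * dt * pmax(1, abs(df$t[-1]) / dt))[1] + 2L,
         ")")
  p <- convert_units(df$p, units[1], "Pa")
  q <- convert_units(df$q, units[2], "m3/s")
  hemo_waveforms(time_series(p, dt = dt, t0 = df$t[1], unit = "Pa"),
                 time_series(q, dt = dt, t0 = df$t[1], unit = "m3/s"))
}

#' Serialize a boundary-condition model to JSON
#'
#' Pole-residue models use the schema
#' `{c0, poles: [{re, im}], residues: [{re, im}], Pd, units: "SI"}`;
#' Windkessel models use `{R1, R2, C, Pd, units: "SI"}`.  Numbers are
#' written at full (17 significant digit) precision so that round trips
#' are bit-stable.
#'
#' @param m a [pole_residue()] or [windkessel()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  # serialized by hand at 17 significant digits so that round trips are
  # bit-stable for IEEE doubles
  num <- function(x) sprintf("%.17g", x)
  cpx <- function(z) sprintf('{"re": %s, "im": %s}', num(Re(z)), num(Im(z)))
  txt <- if (inherits(m, "windkessel")) {
    sprintf('{"R1": %s, "R2": %s, "C": %s, "Pd": %s, "units": "SI"}',
            num(m$R1), num(m$R2), num(m$C), num(m$Pd))
  } else if (inherits(m, "pole_residue")) {
    sprintf(paste0('{"c0": %s, "poles": [%s], "residues": [%s], ',
                   '"Pd": %s, "units": "SI"}'),
            num(m$c0),
            paste(vapply(m$poles, cpx, character(1)), collapse = ", "),
            paste(vapply(m$residues, cpx, character(1)), collapse = ", "),
            num(m$Pd))
  } else stop("`m` must be a pole_residue or windkessel model")
  writeLines(txt, path)
  invisible(path)
}

#' Read a boundary-condition model from JSON
#'
#' Dispatches on the fields present: `R1/R2/C` gives a [windkessel()],
#' `c0/poles/residues` a [pole_residue()].
#'
#' @param path JSON file written by [write_model()].
#' @return A `windkessel` or `pole_residue` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- as.numeric   # integer-valued JSON numbers must stay doubles
  if (!is.null(obj$R1))
    return(windkessel(n(obj$R1), n(obj$R2), n(obj$C),
                      if (is.null(obj$Pd)) 0 else n(obj$Pd)))
  if (is.null(obj$c0)) stop("unrecognized model JSON: ", path)
  poles <- vapply(obj$poles,
                  function(z) complex(real = n(z$re), imaginary = n(z$im)),
                  complex(1))
  residues <- vapply(obj$residues,
                     function(z) complex(real = n(z$re), imaginary = n(z$im)),
                     complex(1))
  pole_residue(n(obj$c0), poles, residues,
               Pd = if (is.null(obj$Pd)) 0 else n(obj$Pd))
}

#' Representative large-artery outlet parameter sets
#'
#' Three-element Windkessel parameter sets representative of lumped
#' terminations at large systemic-artery outlets (brachiocephalic, left
#' common carotid, left subclavian, celiac and common iliac territories),
#' in SI units.  They serve as ground-truth models for the synthetic
#' experiments and examples.
#'
#' @return A `data.frame` with columns `outlet`, `R1`, `R2`, `C`, `Pd`.
#' @examples
#' sets <- arterial_outlet_params()
#' wk <- with(sets[sets$outlet == "brachiocephalic", ],
#'            windkessel(R1, R2, C, Pd))
#' @export
arterial_outlet_params <- function() {
  data.frame(
    outlet = c("brachiocephalic", "left_carotid", "left_subclavian",
               "celiac", "common_iliac"),
    R1 = c(0.26e8, 6.55e8, 0.67e8, 1.99e8, 0.97e8),
    R2 = c(8.43e8, 14.2e8, 15.4e8, 6.91e8, 13.5e8),
    C = c(10.5e-10, 1.23e-10, 6.13e-10, 4.36e-10, 6.06e-10),
    Pd = c(1580, 1640, 1680, 1410, 1710))
}
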