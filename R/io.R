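#' Decay histogram container
#'
#' A binned photon-counting decay (or prompt) histogram: channel-center times
#' in picoseconds with nonnegative integer counts and acquisition metadata.
#'
#' @param times Channel-center times, ps; uniform, strictly increasing.
#' @param counts Nonnegative integer photon counts per channel.
#' @param channel_width Time per channel, ps; derived from `times` if `NULL`.
#' @param role `"decay"` or `"prompt"`.
#' @param label Free-text sample identity (e.g. analyte concentration).
#'
#' @return An object of class `decay_histogram`.
#' @examples
#' h <- decay_histogram(times = (1:16 - 0.5) * 100,
#'                      counts = rpois(16, 50), role = "decay")
#' h
#' @export
decay_histogram <- function(times, counts, channel_width = NULL,
                            role = c("decay", "prompt"), label = "") {
  role <- match.arg(role)
  if (length(times) != length(counts)) {
    stop("times and counts must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a decay histogram needs at least 2 channels", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(counts))) {
    stop("times and counts must be finite", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  w <- dt[1]
  if (any(abs(dt - w) > 1e-9 * max(w, 1))) {
    stop("channel spacing must be uniform", call. = FALSE)
  }
  if (!is.null(channel_width)) {
    stop_if_not_scalar_number(channel_width, "channel_width", positive = TRUE)
    if (abs(channel_width - w) > 1e-6 * w) {
      stop("channel_width disagrees with the time-column spacing",
           call. = FALSE)
    }
    w <- channel_width
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  # observed photon counts are integers; real-valued counts are permitted so
  # noise-off model expectations can be carried in the same container
  structure(
    list(times = as.numeric(times), counts = as.numeric(counts),
         channel_width = w, role = role, label = as.character(label)[1]),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC %s histogram%s\n", x$role,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  %d channels x %.2f ps (window %.2f ns)\n",
              length(x$counts), x$channel_width,
              length(x$counts) * x$channel_width / 1000))
  pk <- which.max(x$counts)
  cat(sprintf("  total %g counts, peak %g at %.2f ns\n",
              sum(x$counts), x$counts[pk], x$times[pk] / 1000))
  invisible(x)
}

#' @export
plot.decay_histogram <- function(x, log = "y", ...) {
  y <- x$counts
  if (grepl("y", log)) y <- pmax(y, 0.5)
  plot(x$times / 1000, y, type = "s", log = log,
       xlab = "time (ns)", ylab = "counts",
       main = if (nzchar(x$label)) x$label else x$role, ...)
  invisible(x)
}

# Unit-normalized weight vector of a histogram (used as convolution kernel).
irf_weights <- function(irf) {
  tot <- sum(irf$counts)
  if (tot <= 0) stop("histogram has no counts (all-zero IRF)", call. = FALSE)
  irf$counts / tot
}

#' Write a decay histogram to a delimited text file
#'
#' Two tab-separated columns (`time_ps`, `counts`) preceded by `#`-prefixed
#' header lines carrying `channel_width`, `n_channels`, `role` and `label`.
#' Output bytes are deterministic for a given histogram (fixed formatting
#' and header order), so repeated writes are identical.
#'
#' @param hist A [decay_histogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_decay()]
#' @export
write_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    sprintf("# channel_width=%.10g", hist$channel_width),
    sprintf("# n_channels=%d", length(hist$counts)),
    sprintf("# role=%s", hist$role),
    sprintf("# label=%s", hist$label),
    "time_ps\tcounts"
  )
  body <- sprintf("%.10g\t%.10g", hist$times, hist$counts)
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a decay histogram from a delimited text file
#'
#' Parses the two-column dialect written by [write_decay()]. Channel width is
#' taken from the header when present, otherwise derived from the time
#' column. Non-uniform spacing, negative counts, or fewer than two channels
#' are errors.
#'
#' @param path Input file path.
#' @return A [decay_histogram()].
#' @export
read_decay <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty decay file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("^time_ps", body[1])) body <- body[-1]
  if (length(body) == 0L) stop("no data rows in decay file", call. = FALSE)
  parts <- strsplit(body, "[\t ,]+")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    stop(sprintf("malformed rows in %s (e.g. line %d)", path,
                 which(bad)[1]), call. = FALSE)
  }
  times <- as.numeric(vapply(parts, `[[`, "", 1L))
  counts <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (any(is.na(times)) || any(is.na(counts))) {
    stop("non-numeric values in decay file", call. = FALSE)
  }
  cw <- if (!is.null(meta$channel_width)) as.numeric(meta$channel_width)
        else NULL
  role <- if (!is.null(meta$role)) meta$role else "decay"
  if (!role %in% c("decay", "prompt")) {
    stop("unknown role in header: ", role, call. = FALSE)
  }
  label <- if (!is.null(meta$label)) meta$label else ""
  decay_histogram(times, counts, channel_width = cw, role = role,
                  label = label)
}

## ---------------------------------------------------------------------------
## Titration series

#' Titration series container
#'
#' Replicate sensor responses (binding-site lifetime tau2 in ns, or emission
#' intensity in rfu) measured across an ascending series of analyte
#' concentrations. Concentrations are stored in molar units; per-concentration
#' dispersions are sample standard deviations, `NA` (unavailable, not zero)
#' for single-replicate groups.
#'
#' @param concentrations Molar analyte concentrations, one per observation
#'   (strictly positive).
#' @param responses Responses, same length.
#' @param response_kind `"lifetime_tau2"` or `"intensity"`.
#' @param replicate Optional replicate index per observation; defaults to
#'   1, 2, ... within each concentration group.
#'
#' @return An object of class `titration_series`: a list with the long-format
#'   `data` (concentration, replicate, response), the `response_kind`, and a
#'   per-concentration `summary` data frame (mean, sd, n).
#' @examples
#' x <- rep(10^seq(-13, -8, length.out = 6), each = 3)
#' y <- predict_hill(hill_params(4.183, 3.983, 18e-12, 1.89), x)
#' titration_series(x, y, "lifetime_tau2")
#' @export
titration_series <- function(concentrations, responses,
                             response_kind = c("lifetime_tau2", "intensity"),
                             replicate = NULL) {
  response_kind <- match.arg(response_kind)
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length", call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be finite and strictly positive (molar)",
         call. = FALSE)
  }
  if (any(!is.finite(responses))) {
    stop("responses must be finite", call. = FALSE)
  }
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  responses <- responses[ord]
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(concentrations),
                            match(concentrations, unique(concentrations)),
                            FUN = seq_along)
  } else {
    replicate <- replicate[ord]
    key <- paste(concentrations, replicate)
    if (anyDuplicated(key)) {
      stop("duplicate (concentration, replicate) pairs", call. = FALSE)
    }
  }
  data <- data.frame(concentration = concentrations, replicate = replicate,
                     response = responses)
  grp <- factor(concentrations, levels = unique(concentrations))
  smry <- data.frame(
    concentration = unique(concentrations),
    mean = as.numeric(tapply(responses, grp, mean)),
    sd = as.numeric(tapply(responses, grp, function(v) {
      if (length(v) >= 2) sd(v) else NA_real_
    })),
    n = as.integer(tapply(responses, grp, length))
  )
  structure(
    list(data = data, response_kind = response_kind, summary = smry),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  units <- if (x$response_kind == "lifetime_tau2") "ns" else "rfu"
  cat(sprintf("Titration series (%s, %s): %d concentrations, %d observations\n",
              x$response_kind, units, nrow(x$summary), nrow(x$data)))
  cat(sprintf("  concentration range %.3g - %.3g M\n",
              min(x$summary$concentration), max(x$summary$concentration)))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parse a concentration with unit suffix to molar
#'
#' Accepts numbers with `fM`, `pM`, `nM`, `uM`/`µM`, `mM` or `M` suffixes
#' (e.g. `"18 pM"`, `"150nM"`), or plain numerics (already molar).
#'
#' @param x Character or numeric vector.
#' @return Numeric vector of molar concentrations.
#' @examples
#' parse_concentration(c("18 pM", "150 nM", "1e-12"))
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  scale <- c(fM = 1e-15, pM = 1e-12, nM = 1e-9, uM = 1e-6,
             "µM" = 1e-6, mM = 1e-3, M = 1)
  out <- vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec(
      "^([-+0-9.eE]+)\\s*(fM|pM|nM|uM|µM|mM|M)?$", s))[[1]]
    if (length(m) == 0L) return(NA_real_)
    val <- as.numeric(m[2])
    if (is.na(val)) return(NA_real_)
    if (nchar(m[3]) == 0L) val else val * scale[[m[3]]]
  }, numeric(1), USE.NAMES = FALSE)
  if (any(is.na(out))) {
    stop("unparseable concentration value(s): ",
         paste(head(x[is.na(out)], 3), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a titration series to a delimited text file
#'
#' Tab-separated columns `concentration_M`, `replicate`, `response`,
#' `response_units` (`ns` or `rfu`).
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  units <- if (series$response_kind == "lifetime_tau2") "ns" else "rfu"
  df <- data.frame(
    concentration_M = sprintf("%.10g", series$data$concentration),
    replicate = series$data$replicate,
    response = sprintf("%.10g", series$data$response),
    response_units = units
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read a titration table from a delimited text file
#'
#' Requires columns `concentration_M`, `replicate`, `response`; an optional
#' `response_units` column (`ns` or `rfu`) sets the response kind.
#' Concentrations may carry unit suffixes (fM/pM/nM/uM) and are converted to
#' molar. Rows are grouped by concentration, replicates checked for
#' duplicates, and the output sorted ascending in concentration. Fewer than
#' four distinct concentrations triggers a warning (isotherm fitting will
#' refuse such a series).
#'
#' @param path Input file path.
#' @param response_kind Override for the response kind; default taken from
#'   the `response_units` column (`ns` -> lifetime, `rfu` -> intensity).
#' @return A [titration_series()].
#' @export
read_titration <- function(path, response_kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("concentration_M", "replicate", "response")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  conc <- parse_concentration(df$concentration_M)
  if (is.null(response_kind)) {
    response_kind <- if ("response_units" %in% colnames(df) &&
                         any(df$response_units == "rfu")) {
      "intensity"
    } else {
      "lifetime_tau2"
    }
  }
  out <- titration_series(conc, as.numeric(df$response),
                          response_kind = response_kind,
                          replicate = df$replicate)
  if (nrow(out$summary) < 4L) {
    warning("fewer than 4 distinct concentrations: isotherm fitting will refuse this series",
            call. = FALSE)
  }
  out
}
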