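# Phase-space containers: the particle lists exchanged between the three
# pipeline stages. The on-disk container is a self-describing single file
# with a plain-text header block followed by fixed-width little-endian
# binary records (kind:1 byte, energy:8, position:3x8, direction:3x8,
# weight:8, history:8). A '#'-commented CSV export is provided for
# inspection and for text-only fixtures.

.phsp_cols <- c("kind", "energy_eV", "x_nm", "y_nm", "z_nm",
                "ux", "uy", "uz", "weight", "history")

#' Construct a phase-space object
#'
#' @param records Data frame with columns `kind` ("photon"/"electron"),
#'   `energy_eV`, `x_nm`, `y_nm`, `z_nm`, `ux`, `uy`, `uz` (unit direction),
#'   `weight` (> 0) and `history` (integer id of the primary history).
#' @param n_primaries Number of primary histories behind the records (> 0),
#'   needed for per-history normalisation.
#' @param stage Stage of origin (free text, e.g. "stage1").
#' @param source Source description.
#' @param seed RNG seed recorded for provenance.
#' @param geometry Short geometry descriptor (hashed into the header).
#' @return An object of class `ndf_phsp`.
#' @export
phase_space <- function(records, n_primaries, stage = "unknown",
                        source = "", seed = NA_integer_, geometry = "") {
  if (n_primaries <= 0) stop("n_primaries must be positive")
  if (nrow(records)) {
    stopifnot(all(.phsp_cols %in% names(records)))
    records <- records[.phsp_cols]
    if (!all(records$kind %in% c("photon", "electron")))
      stop("kind must be 'photon' or 'electron'")
    nrm <- sqrt(records$ux^2 + records$uy^2 + records$uz^2)
    if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors")
    if (any(records$energy_eV <= 0)) stop("record energies must be positive")
    if (any(records$weight <= 0)) stop("record weights must be positive")
    records$history <- as.numeric(records$history)
    records <- records[order(records$history), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- data.frame(kind = character(0), energy_eV = numeric(0),
                          x_nm = numeric(0), y_nm = numeric(0),
                          z_nm = numeric(0), ux = numeric(0),
                          uy = numeric(0), uz = numeric(0),
                          weight = numeric(0), history = numeric(0))
  }
  structure(list(header = list(format = "ndfphsp-1", stage = stage,
                               source = source, n_primaries = n_primaries,
                               seed = seed,
                               geometry_hash = .ndf_hash(geometry)),
                 records = records),
            class = "ndf_phsp")
}

.ndf_hash <- function(x) {
  # small stable text hash (polynomial rolling hash mod 2^31 - 1)
  b <- utf8ToInt(enc2utf8(paste(x, collapse = "|")))
  h <- 17
  for (v in b) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.ndf_phsp <- function(x, ...) {
  cat(sprintf("<phase space: %d records, %g primaries, stage %s>\n",
              nrow(x$records), x$header$n_primaries, x$header$stage))
  invisible(x)
}

#' Write a phase-space file (binary container)
#'
#' @param ps An `ndf_phsp` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phase_space <- function(ps, path) {
  stopifnot(inherits(ps, "ndf_phsp"))
  h <- ps$header
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf(paste0("ndfphsp-1\nstage: %s\nsource: %s\nn_primaries: %.17g\n",
                        "seed: %s\ngeometry_hash: %s\nn_records: %d\nrecords:\n"),
                 h$stage, h$source, h$n_primaries, as.character(h$seed),
                 h$geometry_hash, nrow(ps$records))
  writeChar(hdr, con, eos = NULL)
  r <- ps$records
  if (nrow(r)) {
    n <- nrow(r)
    kind <- as.raw(ifelse(r$kind == "photon", 0L, 1L))
    m <- t(as.matrix(r[c("energy_eV", "x_nm", "y_nm", "z_nm",
                         "ux", "uy", "uz", "weight", "history")]))
    nums_raw <- writeBin(as.vector(m), raw(), size = 8, endian = "little")
    buf <- raw(n * 73)
    kind_pos <- seq(1, by = 73, length.out = n)
    buf[kind_pos] <- kind
    buf[-kind_pos] <- nums_raw
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read a phase-space file written by [write_phase_space()]
#'
#' @param path Input path.
#' @return An `ndf_phsp` object; malformed headers or truncated records raise
#'   a parse error naming the byte offset.
#' @export
read_phase_space <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read the text header byte-wise up to the 'records:' sentinel
  hdr_bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b)) stop("parse error: header truncated at byte ",
                         length(hdr_bytes))
    hdr_bytes <- c(hdr_bytes, b)
    if (length(hdr_bytes) >= 9 &&
        rawToChar(hdr_bytes[(length(hdr_bytes) - 8):length(hdr_bytes)]) == "records:\n")
      break
    if (length(hdr_bytes) > 65536) stop("parse error: header sentinel not found")
  }
  lines <- strsplit(rawToChar(hdr_bytes), "\n")[[1]]
  if (lines[1] != "ndfphsp-1") stop("parse error: bad magic at byte 0")
  kv <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop("parse error: missing header field ", key)
    sub(paste0("^", key, ": "), "", ln[1])
  }
  n_rec <- as.integer(kv("n_records"))
  offset0 <- length(hdr_bytes)
  rec_size <- 1 + 9 * 8
  if (n_rec > 0) {
    buf <- readBin(con, "raw", n_rec * rec_size)
    if (length(buf) < n_rec * rec_size)
      stop("parse error: truncated record section at byte ",
           offset0 + length(buf))
    kind_raw <- buf[seq(1, by = rec_size, length.out = n_rec)]
    num_mask <- rep(c(FALSE, rep(TRUE, 72)), n_rec)
    nums <- readBin(buf[num_mask], "double", n = n_rec * 9, size = 8,
                    endian = "little")
    m <- matrix(nums, ncol = 9, byrow = TRUE)
    records <- data.frame(kind = ifelse(as.integer(kind_raw) == 0,
                                        "photon", "electron"),
                          energy_eV = m[, 1], x_nm = m[, 2], y_nm = m[, 3],
                          z_nm = m[, 4], ux = m[, 5], uy = m[, 6],
                          uz = m[, 7], weight = m[, 8], history = m[, 9])
  } else {
    records <- data.frame()
  }
  ps <- phase_space(records, n_primaries = as.numeric(kv("n_primaries")),
                    stage = kv("stage"), source = kv("source"),
                    seed = suppressWarnings(as.integer(kv("seed"))))
  ps$header$geometry_hash <- kv("geometry_hash")
  ps
}

#' Export / import a phase space as commented CSV
#'
#' Text twin of the binary container, with header fields on '#' comment
#' lines. Used for the committed plain-text fixtures.
#' @param ps An `ndf_phsp` object.
#' @param path File path.
#' @return `write_phase_space_csv()` returns `path`; `read_phase_space_csv()`
#'   an `ndf_phsp`.
#' @export
write_phase_space_csv <- function(ps, path) {
  h <- ps$header
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# ndfphsp-csv-1\n# stage: %s\n# source: %s\n# n_primaries: %.17g\n# seed: %s\n# geometry_hash: %s\n",
              h$stage, h$source, h$n_primaries, as.character(h$seed),
              h$geometry_hash), file = con)
  r <- ps$records
  num <- c("energy_eV", "x_nm", "y_nm", "z_nm", "ux", "uy", "uz", "weight")
  r[num] <- lapply(r[num], function(v) sprintf("%.17g", v))
  utils::write.csv(r, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_space_csv
#' @export
read_phase_space_csv <- function(path) {
  lines <- readLines(path, n = 10)
  kv <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop("parse error: missing CSV header field ", key)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  rec <- utils::read.csv(path, comment.char = "#")
  ps <- phase_space(rec, n_primaries = as.numeric(kv("n_primaries")),
                    stage = kv("stage"), source = kv("source"),
                    seed = suppressWarnings(as.integer(kv("seed"))))
  ps$header$geometry_hash <- kv("geometry_hash")
  ps
}

#' Summarise a phase space into an energy spectrum
#'
#' Weighted energy histogram of one particle kind, normalised per primary
#' history (the "spectrum entering the cell culture" view of a phase space).
#'
#' @param ps An `ndf_phsp` object.
#' @param kind "photon" or "electron".
#' @param breaks_eV Strictly increasing bin edges (eV).
#' @return An `ndf_spectrum`: data frame with `lower_eV`, `upper_eV`,
#'   `count_per_primary`, plus attributes `kind` and `n_primaries`. Records
#'   outside the edges are ignored; if no record of the kind exists an empty
#'   (all-zero) histogram is returned with a warning.
#' @export
summarize_spectrum <- function(ps, kind = c("photon", "electron"), breaks_eV) {
  kind <- match.arg(kind)
  if (any(diff(breaks_eV) <= 0)) stop("bin edges must be strictly increasing")
  r <- ps$records[ps$records$kind == kind, , drop = FALSE]
  nb <- length(breaks_eV) - 1
  counts <- numeric(nb)
  if (!nrow(r)) {
    warning("no records of kind '", kind, "': empty histogram")
  } else {
    bi <- findInterval(r$energy_eV, breaks_eV, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb
    if (any(ok))
      counts <- as.numeric(tapply(r$weight[ok], factor(bi[ok], levels = 1:nb),
                                  sum, default = 0))
  }
  out <- data.frame(lower_eV = breaks_eV[-length(breaks_eV)],
                    upper_eV = breaks_eV[-1],
                    count_per_primary = counts / ps$header$n_primaries)
  structure(out, kind = kind, n_primaries = ps$header$n_primaries,
            class = c("ndf_spectrum", "data.frame"))
}
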