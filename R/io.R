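# Plain-text file formats: photon/degradation trace CSV with '#' metadata
# headers, correlation-curve CSV, and schema-versioned results JSON.

.SCHEMA <- "fccstools/1"

.readHashedHeader <- function(lines) {
  hdr <- grep("^#", lines)
  if (length(hdr) && !identical(hdr, seq_along(hdr)))
    stop("metadata ('#') lines must precede the data")
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  list(meta = meta, nHeader = length(hdr))
}

.requireMeta <- function(meta, keys, path) {
  missing <- setdiff(keys, names(meta))
  if (length(missing))
    stop(sprintf("%s: missing metadata key(s): %s", path,
                 paste(missing, collapse = ", ")))
}

#' Read a photon or degradation trace CSV
#'
#' The file starts with '#'-prefixed metadata lines ("# key: value"); the
#' \code{kind} key selects the trace type. Photon traces have a single
#' \code{count} column and require \code{bin_width_s} and \code{channel};
#' degradation traces have columns
#' \code{frame,intensity,background,compartment,cell_id} and require
#' \code{frame_interval_s}. Parse errors name the offending line. CRLF and
#' LF files parse identically.
#'
#' @param path file path.
#' @return A \linkS4class{PhotonCountTrace} or
#'   \linkS4class{DegradationTrace}.
#' @export
readTraceCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hd <- .readHashedHeader(lines)
  meta <- hd$meta
  .requireMeta(meta, "kind", path)
  body <- lines[-seq_len(hd$nHeader)]
  if (length(body) < 2L) stop(path, ": no data rows")
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  rows <- body[-1L]
  lineNo <- hd$nHeader + 1L + seq_along(rows)

  if (meta$kind == "photon") {
    .requireMeta(meta, c("bin_width_s", "channel"), path)
    if (!identical(header, "count"))
      stop(path, ": photon trace must have a single 'count' column")
    cts <- suppressWarnings(as.numeric(rows))
    bad <- which(is.na(cts) | cts < 0 | cts != round(cts))
    if (length(bad))
      stop(sprintf("%s: invalid count at line %d ('%s')", path,
                   lineNo[bad[1L]], rows[bad[1L]]))
    photonCountTrace(cts, as.numeric(meta$bin_width_s), meta$channel)
  } else if (meta$kind == "degradation") {
    .requireMeta(meta, "frame_interval_s", path)
    want <- c("frame", "intensity", "background", "compartment", "cell_id")
    if (!identical(header, want))
      stop(path, ": degradation trace needs columns ",
           paste(want, collapse = ","))
    parts <- strsplit(rows, ",", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 5L))
      stop(sprintf("%s: malformed row at line %d", path,
                   lineNo[which(nf != 5L)[1L]]))
    fr <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    intens <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bgs <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(fr))
      stop(sprintf("%s: non-integer frame at line %d", path,
                   lineNo[which(is.na(fr))[1L]]))
    gaps <- which(diff(fr) != 1L)
    if (length(gaps))
      stop(sprintf("%s: frame gap or disorder at line %d (frames %d -> %d)",
                   path, lineNo[gaps[1L] + 1L], fr[gaps[1L]], fr[gaps[1L] + 1L]))
    if (anyNA(intens))
      stop(sprintf("%s: invalid intensity at line %d", path,
                   lineNo[which(is.na(intens))[1L]]))
    bg <- if (length(unique(bgs)) == 1L) bgs[1L] else bgs
    degradationTrace(fr, intens, background = bg,
                     compartment = parts[[1L]][4L],
                     frameInterval = as.numeric(meta$frame_interval_s),
                     cellId = parts[[1L]][5L])
  } else {
    stop(path, ": unknown trace kind '", meta$kind, "'")
  }
}

#' Write a trace CSV
#'
#' Inverse of [readTraceCsv()]; write -> read round-trips exactly.
#'
#' @param trace a \linkS4class{PhotonCountTrace} or
#'   \linkS4class{DegradationTrace}.
#' @param path output path.
#' @param extraMeta optional named character metadata to embed (e.g. seed).
#' @return \code{path}, invisibly.
#' @export
writeTraceCsv <- function(trace, path, extraMeta = character()) {
  metaLines <- function(kv) sprintf("# %s: %s", names(kv), unlist(kv))
  if (is(trace, "PhotonCountTrace")) {
    kv <- c(kind = "photon", channel = trace@channel,
            bin_width_s = format(trace@binWidth, digits = 17),
            duration_s = format(trace@binWidth * length(trace@counts),
                                digits = 17), extraMeta)
    writeLines(c(metaLines(kv), "count",
                 format(trace@counts, scientific = FALSE, trim = TRUE,
                        digits = 17)), path)
  } else if (is(trace, "DegradationTrace")) {
    kv <- c(kind = "degradation",
            frame_interval_s = format(trace@frameInterval, digits = 17),
            extraMeta)
    bg <- .bgVector(trace)
    rows <- sprintf("%d,%s,%s,%s,%s", trace@frames,
                    format(trace@intensities, digits = 17, trim = TRUE),
                    format(bg, digits = 17, trim = TRUE),
                    trace@compartment, trace@cellId)
    writeLines(c(metaLines(kv), "frame,intensity,background,compartment,cell_id",
                 rows), path)
  } else stop("unsupported trace type")
  invisible(path)
}

#' Read a correlation-curve CSV
#'
#' @param path file path (columns \code{lag_s,g,sd}; '#' metadata with
#'   \code{kind}).
#' @return A \linkS4class{CorrelationCurve}.
#' @export
readCurveCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hd <- .readHashedHeader(lines)
  .requireMeta(hd$meta, "kind", path)
  body <- lines[-seq_len(hd$nHeader)]
  if (!identical(body[1L], "lag_s,g,sd"))
    stop(path, ": curve CSV needs columns lag_s,g,sd")
  parts <- strsplit(body[-1L], ",", fixed = TRUE)
  lag <- as.numeric(vapply(parts, `[[`, "", 1L))
  g <- as.numeric(vapply(parts, `[[`, "", 2L))
  sdv <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (all(is.na(sdv))) sdv <- numeric() else if (anyNA(sdv))
    stop(path, ": mixed missing/present sd values")
  correlationCurve(lag, g, kind = hd$meta$kind, sd = sdv)
}

#' Write a correlation-curve CSV
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param path output path.
#' @param extraMeta optional named character metadata.
#' @return \code{path}, invisibly.
#' @export
writeCurveCsv <- function(curve, path, extraMeta = character()) {
  kv <- c(kind = curve@kind, extraMeta)
  sdv <- if (length(curve@sd))
    format(curve@sd, digits = 17, trim = TRUE) else rep("NA", length(curve@lags))
  rows <- sprintf("%s,%s,%s", format(curve@lags, digits = 17, trim = TRUE),
                  format(curve@g, digits = 17, trim = TRUE), sdv)
  writeLines(c(sprintf("# %s: %s", names(kv), unlist(kv)), "lag_s,g,sd", rows),
             path)
  invisible(path)
}

# ---- results JSON ----------------------------------------------------------

# plain-list records of result objects; numeric NA -> NULL, Inf -> "Inf"
.sanitizeLeaf <- function(x) {
  if (is.list(x)) return(lapply(x, .sanitizeLeaf))
  if (is.numeric(x) && length(x) == 1L) {
    if (is.na(x)) return(NULL)
    if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  }
  x
}

.restoreLeaf <- function(x) {
  if (is.list(x)) return(lapply(x, .restoreLeaf))
  if (is.character(x) && length(x) == 1L && x %in% c("Inf", "-Inf"))
    return(if (x == "Inf") Inf else -Inf)
  x
}

#' @rdname writeResultsJson
#' @export
setGeneric("asRecord", function(object) standardGeneric("asRecord"))

#' @rdname writeResultsJson
#' @export
setMethod("asRecord", "DiffusionFit", function(object) list(
  n_molecules = object@nMolecules, tau_d_s = object@tauD,
  fraction = object@fraction, d_um2_s = object@dCoef,
  kappa_used = object@kappaUsed, chi_sq_reduced = object@chiSqReduced,
  converged = object@converged, model_id = object@modelId,
  note = object@note))

#' @rdname writeResultsJson
#' @export
setMethod("asRecord", "InteractionResult", function(object) list(
  g_g0 = object@gG0, g_r0 = object@gR0, g_x0 = object@gX0,
  c_green_free_m = object@cGreenFree, c_red_free_m = object@cRedFree,
  c_complex_m = object@cComplex, kd_m = object@kd,
  bound_fraction_g = object@boundFractionG,
  bound_fraction_r = object@boundFractionR, q = object@q,
  valid = object@valid, note = object@note))

#' @rdname writeResultsJson
#' @export
setMethod("asRecord", "KineticsResult", function(object) list(
  onset_frame = if (is.na(object@onsetFrame)) NULL else object@onsetFrame,
  initial_speed = object@initialSpeed, max_speed = object@maxSpeed,
  max_speed_frame = if (is.na(object@maxSpeedFrame)) NULL
                    else object@maxSpeedFrame,
  params = object@params))

#' @rdname writeResultsJson
#' @export
setMethod("asRecord", "SyntheticTruth", function(object)
  list(kind = object@kind, params = object@params))

#' @rdname writeResultsJson
#' @export
setMethod("asRecord", "EquilibriumState", function(object) list(
  a_total_m = object@aTotal, b_total_m = object@bTotal, kd_m = object@kd,
  a_free_m = object@aFree, b_free_m = object@bFree,
  complex_m = object@complex))

#' Write / read a schema-versioned results JSON
#'
#' \code{writeResultsJson} serialises a result object (via its
#' \code{asRecord} method) together with an optional provenance record.
#' Infinite dissociation constants are written as the sentinel string
#' \code{"Inf"}; absent values (e.g. an undetected onset) are explicit
#' JSON nulls, never 0. \code{readResultsJson} restores the record with
#' those sentinels mapped back.
#'
#' @param result an object with an \code{asRecord} method, or a plain list.
#' @param path output path.
#' @param provenance optional list from [provenanceRecord()].
#' @return \code{path}, invisibly (writer); the restored record list with
#'   elements \code{schema}, \code{result_type}, \code{result},
#'   \code{provenance} (reader).
#' @export
writeResultsJson <- function(result, path, provenance = NULL) {
  rec <- if (isS4(result)) asRecord(result) else result
  payload <- list(schema = .SCHEMA,
                  result_type = class(result)[1L],
                  result = .sanitizeLeaf(rec),
                  provenance = provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeResultsJson
#' @export
readResultsJson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$schema, .SCHEMA))
    stop(path, ": unknown schema '", payload$schema, "'")
  payload$result <- .restoreLeaf(payload$result)
  payload
}

#' Provenance record for an output file
#'
#' Tool version, config and input-file MD5 hashes, seed and timestamp;
#' attached to every JSON the command-line tools write. Any input byte
#' change changes the corresponding hash.
#'
#' @param inputPaths character vector of input files (hashed).
#' @param configPath optional config file (hashed separately).
#' @param seed the seed used, if any.
#' @return a named list.
#' @export
provenanceRecord <- function(inputPaths = character(), configPath = NULL,
                             seed = NULL) {
  hashes <- if (length(inputPaths))
    as.list(tools::md5sum(inputPaths)) else list()
  list(tool = "fccstools",
       version = as.character(utils::packageVersion("fccstools")),
       config_hash = if (is.null(configPath)) NULL
                     else unname(tools::md5sum(configPath)),
       input_hashes = hashes,
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
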