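#' @include AllClasses.R
NULL

#' Construct a single-individual event table
#'
#' Lightweight record holding one individual's raw (untransformed) event
#' matrix together with its id and group label (0 = control, >= 1 =
#' responder). Event tables are the unit [assembleMultiSet()] combines into a
#' [CytoMultiSet].
#'
#' @param events numeric matrix, rows = cells, columns = markers.
#' @param markerNames character; defaults to `colnames(events)`.
#' @param individualId character scalar.
#' @param group integer >= 0.
#' @return an object of S3 class `"EventTable"`.
#' @export
eventTable <- function(events, markerNames = colnames(events),
                       individualId = "ind1", group = 0L) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.null(markerNames))
    stop("marker names are required (set colnames or markerNames)")
  if (length(markerNames) != ncol(events))
    stop("markerNames length must match the number of columns")
  if (anyDuplicated(markerNames)) stop("marker names must be unique")
  if (ncol(events) < 2L) stop("at least two markers are required")
  if (nrow(events) < 1L) stop("at least one event is required")
  if (anyNA(events)) stop("event table contains missing values")
  colnames(events) <- markerNames
  structure(
    list(individualId = as.character(individualId),
         group = as.integer(group),
         events = events,
         markerNames = as.character(markerNames)),
    class = "EventTable")
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("EventTable '%s' (group %d): %d events x %d markers\n",
              x$individualId, x$group, nrow(x$events), ncol(x$events)))
  invisible(x)
}

.scatterPattern <- "^(FSC|SSC)([- .].*)?$|^TIME$"

#' Read a single-individual event table from FCS or delimited text
#'
#' Supports FCS 3.0/3.1 (list mode, float/double/integer data) and delimited
#' text with one header row. FCS channels are named by $PnS (stain name) when
#' present, else $PnN. Unless an explicit `markers` subset is given, FCS
#' scatter and time channels (FSC*, SSC*, TIME) are dropped, keeping the
#' fluorescence panel. Intensities are returned raw; compensation is assumed
#' to have been applied upstream.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"fcs"` or `"delimited"`.
#' @param markers optional character vector restricting (and ordering) the
#'   marker panel; an unknown marker is an error naming the available panel.
#' @param individualId id for the resulting table; defaults to the file name.
#' @param group group label (0 control, >= 1 responder).
#' @param sep field separator for delimited input; `NULL` auto-detects
#'   comma/tab/semicolon from the header line.
#' @return an `EventTable`.
#' @export
readEvents <- function(path, format = c("auto", "fcs", "delimited"),
                       markers = NULL, individualId = NULL, group = 0L,
                       sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  }
  if (is.null(individualId))
    individualId <- sub("\\.[^.]*$", "", basename(path))
  mat <- if (format == "fcs") .readFcsMatrix(path) else
    .readDelimitedMatrix(path, sep = sep)
  available <- colnames(mat)
  if (is.null(markers)) {
    if (format == "fcs") {
      keep <- !grepl(.scatterPattern, available, ignore.case = TRUE)
      if (!any(keep))
        stop("no fluorescence channels left after dropping scatter/time; ",
             "pass `markers` explicitly")
      mat <- mat[, keep, drop = FALSE]
    }
  } else {
    missing <- setdiff(markers, available)
    if (length(missing))
      stop("marker(s) not present in file: ", paste(missing, collapse = ", "),
           "; available: ", paste(available, collapse = ", "))
    mat <- mat[, markers, drop = FALSE]
  }
  eventTable(mat, individualId = individualId, group = group)
}

.readDelimitedMatrix <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- c(",", "\t", ";")[which.max(c(
      lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
      lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
      lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))))]
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("delimited file contains missing or non-numeric values")
  mat
}

# Minimal FCS 3.0/3.1 reader: HEADER segment offsets, TEXT key-value segment,
# list-mode DATA segment in float32 (F), double (D) or unsigned integer (I).
.readFcsMatrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", n = 58L))
  version <- substr(header, 1, 6)
  if (!grepl("^FCS3\\.", version))
    stop("unsupported FCS version or not an FCS file: ", version)
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  textBegin <- off(11, 18); textEnd <- off(19, 26)
  dataBegin <- off(27, 34); dataEnd <- off(35, 42)
  if (is.na(textBegin) || is.na(textEnd) || textEnd <= textBegin)
    stop("malformed FCS header (TEXT offsets)")
  seek(con, textBegin)
  textRaw <- readBin(con, "raw", n = textEnd - textBegin + 1L)
  text <- rawToChar(textRaw)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  getkw <- function(key, default = NA_character_) {
    if (key %in% names(kw)) kw[[key]] else default
  }
  nPar <- as.integer(getkw("$PAR"))
  nTot <- as.integer(getkw("$TOT"))
  if (is.na(nPar) || is.na(nTot)) stop("FCS file lacks $PAR/$TOT keywords")
  dtype <- toupper(getkw("$DATATYPE", "F"))
  byteord <- getkw("$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (is.na(dataBegin) || dataBegin == 0) dataBegin <- as.numeric(getkw("$BEGINDATA"))
  if (is.na(dataEnd) || dataEnd == 0) dataEnd <- as.numeric(getkw("$ENDDATA"))
  if (is.na(dataBegin) || is.na(dataEnd) || dataEnd <= dataBegin)
    stop("malformed FCS DATA offsets")
  chName <- vapply(seq_len(nPar), function(j) {
    s <- getkw(sprintf("$P%dS", j))
    n <- getkw(sprintf("$P%dN", j))
    v <- if (!is.na(s) && nzchar(trimws(s))) s else n
    if (is.na(v) || !nzchar(trimws(v))) sprintf("P%d", j) else trimws(v)
  }, character(1))
  seek(con, dataBegin)
  nVal <- nPar * nTot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = nVal, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = nVal, size = 8L, endian = endian),
    I = {
      bits <- as.integer(getkw("$P1B", "16"))
      readBin(con, "integer", n = nVal, size = bits %/% 8L,
              signed = FALSE, endian = endian)
    },
    stop("unsupported FCS $DATATYPE: ", dtype))
  if (length(vals) < nVal)
    stop("FCS DATA segment truncated (expected ", nVal, " values)")
  mat <- matrix(as.double(vals), nrow = nTot, ncol = nPar, byrow = TRUE)
  colnames(mat) <- make.unique(chName)
  mat
}

#' Assemble event tables into a multiset
#'
#' Blocks keep the input order. All tables must carry the same marker panel;
#' permuted columns are reordered to the first table's (canonical) order, so
#' the column correspondence the simultaneous decomposition needs is
#' guaranteed.
#'
#' @param tables list of `EventTable` objects (see [eventTable()],
#'   [readEvents()]).
#' @param groups optional named vector (individual id -> group label)
#'   overriding the per-table labels, e.g. read from a two-column group map.
#' @return a [CytoMultiSet].
#' @export
assembleMultiSet <- function(tables, groups = NULL) {
  if (!length(tables)) stop("no event tables supplied")
  if (!all(vapply(tables, inherits, logical(1), "EventTable")))
    stop("all elements must be EventTable objects")
  ids <- vapply(tables, function(t) t$individualId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  panel <- tables[[1]]$markerNames
  blocks <- lapply(tables, function(t) {
    if (!setequal(t$markerNames, panel))
      stop("individual '", t$individualId,
           "' has a mismatched marker panel (expected: ",
           paste(panel, collapse = ", "), ")")
    t$events[, panel, drop = FALSE]
  })
  grp <- vapply(tables, function(t) t$group, integer(1))
  if (!is.null(groups)) {
    if (is.null(names(groups))) stop("`groups` must be named by individual id")
    hit <- match(ids, names(groups))
    if (anyNA(hit))
      stop("group map lacks individual(s): ",
           paste(ids[is.na(hit)], collapse = ", "))
    grp <- as.integer(groups[hit])
  }
  if (!any(grp == 0L)) stop("at least one control (group 0) block is required")
  new("CytoMultiSet", blocks = blocks, individualIds = ids,
      groups = grp, markerNames = panel)
}

#' Read a two-column group map (individual_id, group) from CSV
#'
#' @param path CSV file with a header row.
#' @return named integer vector.
#' @export
readGroupMap <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("group map needs two columns: individual_id, group")
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}
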