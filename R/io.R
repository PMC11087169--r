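#' @include AllClasses.R
NULL

# printed tables use en-dash "missing", unicode minus and occasionally a
# unicode hyphen for negatives; normalize all of them to ASCII on read
.normalizeGlyphs <- function(x) {
  x <- gsub("\u2212", "-", x)   # minus sign
  x <- gsub("\u2010", "-", x)   # hyphen
  x <- trimws(x)
  x
}

.missingMarkers <- c("\u2013", "-", "", "NA")

.parseNumericColumn <- function(x, col, file) {
  x <- .normalizeGlyphs(x)
  out <- rep(NA_real_, length(x))
  keep <- !x %in% .missingMarkers
  val <- suppressWarnings(as.numeric(x[keep]))
  if (any(is.na(val))) {
    bad <- which(keep)[which(is.na(val))[1]]
    stop(sprintf("malformed numeric value '%s' in column '%s', row %d of %s",
                 x[keep][is.na(val)][1], col, bad, basename(file)))
  }
  out[keep] <- val
  out
}

.endpointMetricCols <- c("V100", "D98", "Dmax", "Dmean", "D0.03cc")
.courseLabels <- c("nominal", "offline", "online", "online-f")

#' Read a long endpoint table (the printed-table CSV dialect)
#'
#' Columns: patient, course (nominal/offline/online/online-f), structure,
#' V100, D98, Dmax (percent of prescription), Dmean, D0.03cc (Gy-RBE).
#' En-dash and unicode minus glyphs are normalized to ASCII on read; the
#' missing marker becomes NA. An empty file yields an empty table.
#'
#' @param path CSV path.
#' @return data.frame with typed columns; missing markers preserved as NA.
#' @export
readEndpointTable <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) {
    return(data.frame(patient = integer(), course = character(),
                      structure = character(), V100 = numeric(),
                      D98 = numeric(), Dmax = numeric(), Dmean = numeric(),
                      "D0.03cc" = numeric(), check.names = FALSE))
  }
  need <- c("patient", "course", "structure", .endpointMetricCols)
  if (!all(need %in% names(raw)))
    stop("endpoint table lacks required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  out <- data.frame(patient = as.integer(raw$patient),
                    course = .normalizeGlyphs(raw$course),
                    structure = .normalizeGlyphs(raw$structure),
                    stringsAsFactors = FALSE, check.names = FALSE)
  badCourse <- !out$course %in% .courseLabels
  if (any(badCourse))
    stop(sprintf("unknown course label '%s' at row %d of %s",
                 out$course[badCourse][1], which(badCourse)[1], basename(path)))
  for (col in .endpointMetricCols)
    out[[col]] <- .parseNumericColumn(raw[[col]], col, path)
  out
}

#' Write a long endpoint table
#'
#' Inverse of [readEndpointTable()]; NA values are written as the ASCII
#' missing marker "-". Round-trips losslessly through [readEndpointTable()].
#'
#' @param tab endpoint table.
#' @param path output CSV path.
#' @export
writeEndpointTable <- function(tab, path) {
  out <- tab
  for (col in .endpointMetricCols)
    out[[col]] <- ifelse(is.na(out[[col]]), "-",
                         format(out[[col]], trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = which(names(out) == "structure"),
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a Table-4-shaped scorecard table
#'
#' @param path CSV with patient, course, one column per criterion, total.
#' @return data.frame with numeric criterion columns (NA for missing).
#' @export
readScoreTable <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  out <- data.frame(patient = as.integer(raw$patient),
                    course = .normalizeGlyphs(raw$course),
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(raw), c("patient", "course")))
    out[[col]] <- .parseNumericColumn(raw[[col]], col, path)
  out
}

#' Write a scorecard table as CSV (Table-4 column order)
#' @param scores scorecard data.frame as from [scoreEndpointTable()].
#' @param path output CSV path.
#' @export
writeScoreTable <- function(scores, path) {
  out <- scores
  numcols <- vapply(out, is.numeric, logical(1)) & names(out) != "patient"
  for (col in names(out)[numcols])
    out[[col]] <- ifelse(is.na(out[[col]]), "-",
                         format(out[[col]], trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- packaged fixtures -----------------------------------------------------

.extdata <- function(f) system.file("extdata", f, package = "aptscore",
                                    mustWork = TRUE)

#' Packaged transcriptions of the published endpoint and score tables
#'
#' `endpointTable3()`/`scoreTable4()` hold the ten-patient nominal/offline/
#' online endpoint metrics and the corresponding criterion scores;
#' `endpointTable6()`/`scoreTable7()` hold patient 5 including the manually
#' fine-tuned online course; `courseInfoTable1()` holds target volumes,
#' prescriptions and fraction counts.
#'
#' @return data.frame (see [readEndpointTable()]/[readScoreTable()]).
#' @export
endpointTable3 <- function() readEndpointTable(.extdata("table3_endpoints.csv"))

#' @rdname endpointTable3
#' @export
scoreTable4 <- function() readScoreTable(.extdata("table4_scores.csv"))

#' @rdname endpointTable3
#' @export
endpointTable6 <- function() readEndpointTable(.extdata("table6_endpoints.csv"))

#' @rdname endpointTable3
#' @export
scoreTable7 <- function() readScoreTable(.extdata("table7_scores.csv"))

#' @rdname endpointTable3
#' @export
courseInfoTable1 <- function() {
  p <- .extdata("table1_course_info.csv")
  raw <- utils::read.csv(p, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  out <- data.frame(patient = as.integer(raw$patient))
  for (col in setdiff(names(raw), "patient"))
    out[[col]] <- .parseNumericColumn(raw[[col]], col, p)
  out
}

# ---- NRRD grids ------------------------------------------------------------

#' Read / write dose grids as NRRD
#'
#' Minimal NRRD support for axis-aligned scalar grids (no installed R package
#' reads NRRD): NRRD0004, type double, 3-D, ascii or little-endian raw
#' encoding, diagonal space directions (= spacing) and space origin.
#'
#' @param grid a [DoseGrid-class].
#' @param path file path.
#' @param encoding "ascii" (text, diff-friendly) or "raw".
#' @return `readNRRD` returns a [DoseGrid-class]; `writeNRRD` the path,
#'   invisibly.
#' @export
writeNRRD <- function(grid, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  d <- dim(grid@values)
  sp <- grid@spacing
  hdr <- c("NRRD0004",
           "# aptscore dose grid",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   sp[1], sp[2], sp[3]),
           sprintf("space origin: (%g,%g,%g)",
                   grid@origin[1], grid@origin[2], grid@origin[3]),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(grid@values), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  } else {
    writeBin(as.vector(grid@values), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname writeNRRD
#' @export
readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header")
    if (line == "") break
    hdr <- c(hdr, line)
  }
  field <- function(key) {
    m <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^", key, ": "), "", m[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("not a NRRD file")
  if (field("dimension") != "3") stop("only 3-D NRRD grids are supported")
  sizes <- as.integer(strsplit(field("sizes"), " +")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+-]+", s))[[1]])
  dirs <- field("space directions")
  spacing <- if (is.null(dirs)) c(1, 1, 1) else {
    v <- nums(dirs); c(v[1], v[5], v[9])
  }
  org <- field("space origin")
  origin <- if (is.null(org)) c(0, 0, 0) else nums(org)
  enc <- field("encoding")
  n <- prod(sizes)
  vals <- if (identical(enc, "ascii")) {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else if (identical(enc, "raw")) {
    readBin(con, what = double(), n = n, size = 8, endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data length does not match sizes")
  DoseGrid(array(vals, dim = sizes), spacing = spacing, origin = origin)
}

# ---- scoring functions and configuration as JSON ---------------------------

#' Serialize scoring functions to and from JSON
#'
#' @param fns named list of scoring-function objects.
#' @param path JSON file path.
#' @export
writeScoringFunctions <- function(fns, path) {
  enc <- lapply(fns, function(fn) {
    if (is(fn, "SerialOrganScoringFunction")) {
      list(type = "serial", metric = fn@metric, tolerance = fn@tolerance,
           fullScore = fn@fullScore, penalty = fn@penalty)
    } else {
      list(type = "piecewise", metric = fn@metric, direction = fn@direction,
           goal = fn@goal, cap = fn@cap,
           knots_x = fn@knots[, 1], knots_score = fn@knots[, 2])
    }
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeScoringFunctions
#' @export
readScoringFunctions <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(enc, function(e) {
    if (identical(e$type, "serial")) {
      f <- serialScoringFunction(e$tolerance, e$fullScore, e$penalty)
      f@metric <- e$metric
      f
    } else {
      scoringFunction(e$metric, e$direction,
                      cbind(unlist(e$knots_x), unlist(e$knots_score)),
                      goal = e$goal, cap = e$cap)
    }
  })
}

#' Run configuration
#'
#' A fully serializable bundle of the tunable analysis parameters; every
#' artifact-producing command logs its resolved configuration, a content hash
#' and the seed.
#'
#' @param dropThreshold score drop (vs nominal) that triggers adaptation.
#' @param qactInterval fractions between QACT evaluations (offline policy).
#' @param replanLag fractions from offline evaluation to plan swap.
#' @param onlineMargin,offlineMargin CTV margins (mm) used when replanning.
#' @param seed integer seed for all stochastic steps.
#' @param outputDir output directory.
#' @param digits score rounding for reports.
#' @return a named list of class "aptscore_config".
#' @export
runConfig <- function(dropThreshold = 3, qactInterval = 10, replanLag = 5,
                      onlineMargin = 1.5, offlineMargin = 3, seed = 1,
                      outputDir = ".", digits = 1) {
  cfg <- list(dropThreshold = dropThreshold, qactInterval = qactInterval,
              replanLag = replanLag, onlineMargin = onlineMargin,
              offlineMargin = offlineMargin, seed = seed,
              outputDir = outputDir, digits = digits)
  class(cfg) <- "aptscore_config"
  cfg
}

#' @rdname runConfig
#' @param cfg a configuration list.
#' @param path JSON path.
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, cfg[names(cfg) %in% names(formals(runConfig))])
}

# hash + provenance line for logs
.configHash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash over the serialized config (modular
  # arithmetic keeps every intermediate inside the double-precision integers)
  h <- 216613626
  for (b in utf8ToInt(as.character(s))) h <- ((h * 131) %% 268435456 + b) %% 268435456
  sprintf("%07x", h)
}

.logRun <- function(cfg, what, file = NULL) {
  line <- sprintf("[aptscore %s] %s config=%s seed=%s",
                  as.character(utils::packageVersion("aptscore")), what,
                  .configHash(cfg), cfg$seed)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE) else message(line)
  invisible(line)
}
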