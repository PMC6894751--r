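# Tracked-cell data model: schema validation, constructor, and round-trip
# I/O. One directory per dataset: cells.csv, interfaces.csv, header.json.

.cellCols <- c("frame", "cell_id", "x", "y", "outline", "cell_type",
               "prev_id", "next_id")
.ifaceCols <- c("frame", "interface_id", "cell_a", "cell_b",
                "x1", "y1", "x2", "y2", "prev_id", "next_id")

# Outline serialisation: comma-separated "x y" pairs in loop order.
.formatOutline <- function(p) {
  paste(sprintf("%.15g %.15g", p[, 1], p[, 2]), collapse = ",")
}

#' Parse an outline string into a coordinate matrix
#' @param s outline string ("x1 y1,x2 y2,...").
#' @return numeric matrix (n x 2).
#' @export
parseOutline <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], " ", fixed = TRUE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("parseOutline: malformed outline string")
  m
}

# Validation used by the EmbryoTracks validity method. Returns a character
# vector of problems (empty when valid). Errors name the offending field
# and row.
validateTracksTables <- function(cells, interfaces, axisFrame, frameIntervalS,
                                 geomTol = 1e-6) {
  msg <- character()
  miss <- setdiff(.cellCols, names(cells))
  if (length(miss))
    return(sprintf("cells table missing columns: %s", paste(miss, collapse = ", ")))
  miss <- setdiff(.ifaceCols, names(interfaces))
  if (length(miss))
    return(sprintf("interfaces table missing columns: %s", paste(miss, collapse = ", ")))
  if (length(frameIntervalS) != 1 || frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a positive scalar")
  if (!all(c("ap", "dv", "midlineY") %in% names(axisFrame)))
    msg <- c(msg, "axisFrame must contain ap, dv, midlineY")
  else {
    ap <- axisFrame$ap; dv <- axisFrame$dv
    if (abs(sum(ap^2) - 1) > 1e-8 || abs(sum(dv^2) - 1) > 1e-8 ||
        abs(sum(ap * dv)) > 1e-8)
      msg <- c(msg, "axisFrame ap/dv must be orthonormal unit vectors")
  }
  if (nrow(cells) == 0) return(c(msg, "cells table is empty"))

  # unique cell ids per frame
  key <- paste(cells$frame, cells$cell_id)
  if (anyDuplicated(key))
    msg <- c(msg, sprintf("duplicate cell_id within frame at cells row %d",
                          anyDuplicated(key)))

  # interfaces must cite cells present in the same frame
  if (nrow(interfaces) > 0) {
    ka <- paste(interfaces$frame, interfaces$cell_a)
    kb <- paste(interfaces$frame, interfaces$cell_b)
    bad <- which(!(ka %in% key))[1]
    if (!is.na(bad))
      msg <- c(msg, sprintf("interfaces row %d: cell_a %s absent from frame %d",
                            bad, interfaces$cell_a[bad], interfaces$frame[bad]))
    bad <- which(!(kb %in% key))[1]
    if (!is.na(bad))
      msg <- c(msg, sprintf("interfaces row %d: cell_b %s absent from frame %d",
                            bad, interfaces$cell_b[bad], interfaces$frame[bad]))
    if (any(interfaces$cell_a == interfaces$cell_b))
      msg <- c(msg, "interfaces row with cell_a == cell_b")
  }

  # outline geometry: simple polygon, centroid matches the stored x, y
  for (i in seq_len(nrow(cells))) {
    p <- tryCatch(parseOutline(cells$outline[i]), error = function(e) NULL)
    if (is.null(p) || nrow(p) < 3) {
      msg <- c(msg, sprintf("cells row %d: unparsable or degenerate outline", i))
      break
    }
    if (!polygonIsSimple(p)) {
      msg <- c(msg, sprintf("cells row %d: outline polygon is not simple", i))
      break
    }
    cc <- polygonCentroid(p)
    if (max(abs(cc - c(cells$x[i], cells$y[i]))) > geomTol) {
      msg <- c(msg, sprintf("cells row %d: centroid does not match outline (off by %.2g um)",
                            i, max(abs(cc - c(cells$x[i], cells$y[i])))))
      break
    }
  }

  # temporal links: next_id must exist in the next frame
  frames <- sort(unique(cells$frame))
  for (fi in seq_along(frames)[-length(frames)]) {
    f <- frames[fi]; fn <- frames[fi + 1]
    sub <- cells[cells$frame == f & cells$next_id != -1, , drop = FALSE]
    there <- cells$cell_id[cells$frame == fn]
    bad <- which(!(sub$next_id %in% there))[1]
    if (!is.na(bad)) {
      msg <- c(msg, sprintf("broken temporal link: cell %s frame %d -> next_id %s missing in frame %d",
                            sub$cell_id[bad], f, sub$next_id[bad], fn))
      break
    }
  }
  msg
}

#' Construct an EmbryoTracks object
#'
#' Assembles and (by default) validates the tracked-cell data model. See
#' [EmbryoTracks-class] for the schema.
#'
#' @param cells per-frame cell table (frame, cell_id, x, y, outline,
#'   cell_type, prev_id, next_id).
#' @param interfaces per-frame interface table (frame, interface_id,
#'   cell_a, cell_b, x1, y1, x2, y2, prev_id, next_id).
#' @param frameIntervalS seconds between frames (default 30).
#' @param axisFrame list(ap, dv, midlineY); defaults to AP = x, DV = y,
#'   midline at y = 0.
#' @param meta free-form metadata list.
#' @param validate run schema validation (default TRUE).
#' @return an [EmbryoTracks-class] object.
#' @export
embryoTracks <- function(cells, interfaces, frameIntervalS = 30,
                         axisFrame = list(ap = c(1, 0), dv = c(0, 1),
                                          midlineY = 0),
                         meta = list(unit = "um"), validate = TRUE) {
  cells$frame <- as.integer(cells$frame)
  interfaces$frame <- as.integer(interfaces$frame)
  cells$outline <- as.character(cells$outline)
  interfaces$interface_id <- as.character(interfaces$interface_id)
  rownames(cells) <- NULL
  rownames(interfaces) <- NULL
  obj <- new("EmbryoTracks", frameIntervalS = frameIntervalS,
             axisFrame = axisFrame, cells = cells, interfaces = interfaces,
             meta = meta)
  if (validate) {
    problems <- validateTracksTables(cells, interfaces, axisFrame, frameIntervalS)
    if (length(problems))
      stop("tracks validation failed: ", paste(problems, collapse = "; "))
  }
  obj
}

#' Read tracked-cell tables from a directory
#'
#' Expects \code{cells.csv}, \code{interfaces.csv} and \code{header.json}
#' (frame_interval_s, ap_vector, dv_vector, midline_y, unit) as written by
#' [writeTracks()].
#'
#' @param path directory containing the three files.
#' @param validate run schema validation after reading (default TRUE).
#' @return an [EmbryoTracks-class] object.
#' @export
readTracks <- function(path, validate = TRUE) {
  fc <- file.path(path, "cells.csv")
  fi <- file.path(path, "interfaces.csv")
  fh <- file.path(path, "header.json")
  for (f in c(fc, fi, fh)) if (!file.exists(f)) stop("readTracks: missing file ", f)
  hdr <- jsonlite::read_json(fh, simplifyVector = TRUE)
  cells <- utils::read.csv(fc, stringsAsFactors = FALSE,
                           colClasses = c(outline = "character"))
  interfaces <- utils::read.csv(fi, stringsAsFactors = FALSE,
                                colClasses = c(interface_id = "character"))
  embryoTracks(cells, interfaces,
               frameIntervalS = hdr$frame_interval_s,
               axisFrame = list(ap = as.numeric(hdr$ap_vector),
                                dv = as.numeric(hdr$dv_vector),
                                midlineY = as.numeric(hdr$midline_y)),
               meta = as.list(hdr[setdiff(names(hdr),
                 c("frame_interval_s", "ap_vector", "dv_vector", "midline_y"))]),
               validate = validate)
}

#' Write tracked-cell tables to a directory
#'
#' Inverse of [readTracks()]: the write-then-read round trip preserves ids
#' and topology exactly and coordinates to better than 1e-9 micrometres.
#'
#' @param tracks an [EmbryoTracks-class] object.
#' @param path output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tracks@cells, file.path(path, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(tracks@interfaces, file.path(path, "interfaces.csv"),
                   row.names = FALSE)
  hdr <- c(list(frame_interval_s = tracks@frameIntervalS,
                ap_vector = tracks@axisFrame$ap,
                dv_vector = tracks@axisFrame$dv,
                midline_y = tracks@axisFrame$midlineY),
           tracks@meta)
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Interface lengths
#'
#' Straight-line distance between the interface endpoints (the
#' vertex-vertex line along which three cells meet).
#'
#' @param tracks an [EmbryoTracks-class] object.
#' @return numeric vector, one length (micrometres) per interface row.
#' @export
interfaceLengths <- function(tracks) {
  it <- tracks@interfaces
  sqrt((it$x2 - it$x1)^2 + (it$y2 - it$y1)^2)
}
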