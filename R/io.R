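#' Read and write vessel centerline networks
#'
#' Two plain-text formats are supported:
#' \describe{
#'   \item{`"vtp"`}{VTK PolyData XML with one PolyLine cell per branch, a
#'     point-data array `Radius` (mm), a cell-data integer array
#'     `BranchLabel` (1 = left_va, 2 = right_va, 3 = ba, 0 = unlabeled) and
#'     field-data arrays `confluence` / `basilar_tip` holding the landmark
#'     coordinates. ASCII encoding at full double precision (`%.17g`), so a
#'     write/read round trip reproduces coordinates to better than 1e-9 mm.}
#'   \item{`"csv"`}{columns `branch_label,point_index,x_mm,y_mm,z_mm,radius_mm`
#'     with a mandatory header; landmarks of a labeled network are
#'     reconstructed on read from the branch endpoints.}
#' }
#'
#' @param path file path.
#' @param format `"vtp"` or `"csv"`; default guessed from the extension.
#' @return `read_network()` returns a [vessel_network()] when the three
#'   anatomical labels are present, otherwise an unlabeled `polyline_set`
#'   (list of [centerline()]s).
#' @export
read_network <- function(path, format = c("auto", "vtp", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_named("io_error", "file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "csv"
  if (format == "vtp") read_network_vtp(path) else read_network_csv(path)
}

#' @rdname read_network
#' @param network a [vessel_network()] or a `polyline_set`.
#' @export
write_network <- function(network, path, format = c("auto", "vtp", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vtp$", path, ignore.case = TRUE)) "vtp" else "csv"
  if (format == "vtp") write_network_vtp(network, path) else write_network_csv(network, path)
  invisible(path)
}

## --- internal: flatten networks to branch lists -----------------------------

BRANCH_CODES <- c(left_va = 1L, right_va = 2L, ba = 3L)

as_branch_list <- function(network) {
  if (inherits(network, "vessel_network")) {
    list(branches = list(network$left_va, network$right_va, network$ba),
         labels = c("left_va", "right_va", "ba"),
         confluence = network$confluence, basilar_tip = network$basilar_tip)
  } else if (inherits(network, "polyline_set") || (is.list(network) &&
             all(vapply(network, inherits, TRUE, "centerline")))) {
    labs <- names(network)
    if (is.null(labs) || any(labs == ""))
      labs <- paste0("branch_", seq_along(network))
    list(branches = unclass(network), labels = labs,
         confluence = NULL, basilar_tip = NULL)
  } else {
    stop_named("validation_error",
               "network must be a vessel_network or a list of centerlines")
  }
}

branch_list_to_network <- function(bl) {
  std <- c("left_va", "right_va", "ba")
  if (all(std %in% bl$labels)) {
    b <- stats::setNames(bl$branches, bl$labels)
    if (is.null(bl$confluence)) {
      ## reconstruct landmarks: the BA endpoint shared with the VAs is the
      ## confluence, the far endpoint is the basilar tip
      ba_p <- b$ba$points
      ends <- rbind(ba_p[1, ], ba_p[nrow(ba_p), ])
      va_ends <- rbind(b$left_va$points[1, ],
                       b$left_va$points[nrow(b$left_va$points), ])
      d <- apply(ends, 1, function(e) min(rownorms(sweep(va_ends, 2, e))))
      conf_i <- which.min(d)
      bl$confluence <- ends[conf_i, ]
      bl$basilar_tip <- ends[3 - conf_i, ]
    }
    vessel_network(left_va = b$left_va, right_va = b$right_va, ba = b$ba,
                   confluence = bl$confluence, basilar_tip = bl$basilar_tip)
  } else {
    structure(stats::setNames(bl$branches, bl$labels), class = "polyline_set")
  }
}

## --- VTP --------------------------------------------------------------------

fmt_dbl <- function(x) sprintf("%.17g", x)

write_network_vtp <- function(network, path) {
  bl <- as_branch_list(network)
  npts <- vapply(bl$branches, function(b) nrow(b$points), 1L)
  all_pts <- do.call(rbind, lapply(bl$branches, `[[`, "points"))
  all_rad <- unlist(lapply(bl$branches, `[[`, "radii"))
  offs <- cumsum(npts)
  conn <- seq_len(sum(npts)) - 1L
  codes <- ifelse(bl$labels %in% names(BRANCH_CODES),
                  BRANCH_CODES[bl$labels], 0L)
  doc <- xml2::xml_new_root("VTKFile", type = "PolyData", version = "1.0",
                            byte_order = "LittleEndian")
  pd <- xml2::xml_add_child(doc, "PolyData")
  if (!is.null(bl$confluence)) {
    fd <- xml2::xml_add_child(pd, "FieldData")
    for (nm in c("confluence", "basilar_tip")) {
      da <- xml2::xml_add_child(fd, "DataArray", type = "Float64", Name = nm,
                                NumberOfTuples = "3", format = "ascii")
      xml2::xml_text(da) <- paste(fmt_dbl(bl[[nm]]), collapse = " ")
    }
  }
  piece <- xml2::xml_add_child(pd, "Piece",
                               NumberOfPoints = as.character(sum(npts)),
                               NumberOfVerts = "0",
                               NumberOfLines = as.character(length(bl$branches)),
                               NumberOfStrips = "0", NumberOfPolys = "0")
  pdat <- xml2::xml_add_child(piece, "PointData", Scalars = "Radius")
  da <- xml2::xml_add_child(pdat, "DataArray", type = "Float64", Name = "Radius",
                            format = "ascii")
  xml2::xml_text(da) <- paste(fmt_dbl(all_rad), collapse = " ")
  cdat <- xml2::xml_add_child(piece, "CellData", Scalars = "BranchLabel")
  da <- xml2::xml_add_child(cdat, "DataArray", type = "Int32", Name = "BranchLabel",
                            format = "ascii")
  xml2::xml_text(da) <- paste(codes, collapse = " ")
  pts <- xml2::xml_add_child(piece, "Points")
  da <- xml2::xml_add_child(pts, "DataArray", type = "Float64",
                            NumberOfComponents = "3", format = "ascii")
  xml2::xml_text(da) <- paste(fmt_dbl(as.numeric(t(all_pts))), collapse = " ")
  lines <- xml2::xml_add_child(piece, "Lines")
  da <- xml2::xml_add_child(lines, "DataArray", type = "Int64",
                            Name = "connectivity", format = "ascii")
  xml2::xml_text(da) <- paste(conn, collapse = " ")
  da <- xml2::xml_add_child(lines, "DataArray", type = "Int64",
                            Name = "offsets", format = "ascii")
  xml2::xml_text(da) <- paste(offs, collapse = " ")
  xml2::write_xml(doc, path)
}

parse_numeric_text <- function(txt, what, path) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
  if (anyNA(vals))
    stop_named("parse_error", "non-numeric value in %s array of %s", what, path)
  vals
}

read_network_vtp <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_named("parse_error", "not valid XML: %s (%s)", path, conditionMessage(e)))
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing"))
    stop_named("parse_error", "no <Piece> element in %s", path)
  get_arr <- function(xpath, what, required = TRUE) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing")) {
      if (required) stop_named("parse_error", "missing %s array in %s", what, path)
      return(NULL)
    }
    parse_numeric_text(xml2::xml_text(node), what, path)
  }
  coords <- get_arr(".//Points/DataArray", "Points")
  pts <- matrix(coords, ncol = 3, byrow = TRUE)
  rad <- get_arr(".//PointData/DataArray[@Name='Radius']", "Radius")
  if (length(rad) != nrow(pts))
    stop_named("parse_error", "Radius array length %d != point count %d in %s",
               length(rad), nrow(pts), path)
  offs <- get_arr(".//Lines/DataArray[@Name='offsets']", "offsets")
  conn <- get_arr(".//Lines/DataArray[@Name='connectivity']", "connectivity")
  codes <- get_arr(".//CellData/DataArray[@Name='BranchLabel']", "BranchLabel",
                   required = FALSE)
  starts <- c(1, utils::head(offs, -1) + 1)
  branches <- list(); labels <- character(0)
  code_names <- stats::setNames(names(BRANCH_CODES), BRANCH_CODES)
  for (i in seq_along(offs)) {
    idx <- conn[starts[i]:offs[i]] + 1L
    branches[[i]] <- centerline(pts[idx, , drop = FALSE], rad[idx])
    labels[i] <- if (!is.null(codes) && as.character(codes[i]) %in% names(code_names))
      code_names[[as.character(codes[i])]] else paste0("branch_", i)
  }
  conf <- get_arr(".//FieldData/DataArray[@Name='confluence']", "confluence",
                  required = FALSE)
  tip <- get_arr(".//FieldData/DataArray[@Name='basilar_tip']", "basilar_tip",
                 required = FALSE)
  branch_list_to_network(list(branches = branches, labels = labels,
                              confluence = conf, basilar_tip = tip))
}

## --- CSV --------------------------------------------------------------------

write_network_csv <- function(network, path) {
  bl <- as_branch_list(network)
  rows <- do.call(rbind, lapply(seq_along(bl$branches), function(i) {
    b <- bl$branches[[i]]
    data.frame(branch_label = bl$labels[i],
               point_index = seq_len(nrow(b$points)) - 1L,
               x_mm = fmt_dbl(b$points[, 1]),
               y_mm = fmt_dbl(b$points[, 2]),
               z_mm = fmt_dbl(b$points[, 3]),
               radius_mm = fmt_dbl(b$radii))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

read_network_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                                 colClasses = "character"),
                 error = function(e)
                   stop_named("parse_error", "cannot read CSV %s: %s",
                              path, conditionMessage(e)))
  need <- c("branch_label", "point_index", "x_mm", "y_mm", "z_mm", "radius_mm")
  if (!all(need %in% names(df)))
    stop_named("parse_error", "CSV %s missing columns: %s", path,
               paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("x_mm", "y_mm", "z_mm", "radius_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) || anyNA(v))
      stop_named("parse_error",
                 "non-numeric value in column '%s' at data row %d of %s",
                 col, if (length(bad)) bad[1] else which(is.na(v))[1], path)
    df[[col]] <- v
  }
  labs <- unique(df$branch_label)
  branches <- lapply(labs, function(l) {
    sub <- df[df$branch_label == l, , drop = FALSE]
    sub <- sub[order(as.integer(sub$point_index)), , drop = FALSE]
    centerline(cbind(sub$x_mm, sub$y_mm, sub$z_mm), sub$radius_mm)
  })
  branch_list_to_network(list(branches = branches, labels = labs,
                              confluence = NULL, basilar_tip = NULL))
}
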