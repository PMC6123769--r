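#' Read an unmerged reflection file
#'
#' Two text dialects are supported. `xds_ascii_like`: a header of
#' `!KEY=value` lines (FORMAT, SPACE_GROUP_NUMBER, UNIT_CELL_CONSTANTS,
#' optional WEDGE_DEGREES) terminated by `!END_OF_HEADER`, then whitespace
#' separated `h k l I sigI` rows up to `!END_OF_DATA`. `csv`: header row
#' `h,k,l,i,sigi` plus a sidecar-free cell/symmetry passed via `cell`/`ops`.
#' Friedel mates are never merged on read.
#'
#' @param path File path.
#' @param dialect "xds_ascii_like" or "csv".
#' @param cell,ops Required for the csv dialect (the format carries no header).
#' @param id Dataset id; defaults to the file name without extension.
#' @return An [xtal_dataset()].
#' @export
read_unmerged <- function(path, dialect = c("xds_ascii_like", "csv"),
                          cell = NULL, ops = NULL, id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    obs <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!identical(names(obs), c("h", "k", "l", "i", "sigi")))
      stop(path, ": csv header must be exactly 'h,k,l,i,sigi'")
    if (is.null(cell) || is.null(ops))
      stop("csv dialect needs explicit cell and ops")
    check_rows(obs, path, offset = 1L)
    return(xtal_dataset(id, cell, ops, obs))
  }
  lines <- readLines(path)
  hdr_end <- match("!END_OF_HEADER", lines)
  if (is.na(hdr_end)) stop(path, ": missing !END_OF_HEADER")
  hdr <- lines[seq_len(hdr_end - 1)]
  get_key <- function(key) {
    hit <- grep(paste0("^!", key, "="), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^!", key, "="), "", hit[1])
  }
  sg <- get_key("SPACE_GROUP_NUMBER")
  cc <- get_key("UNIT_CELL_CONSTANTS")
  if (is.null(sg)) stop(path, ": header lacks !SPACE_GROUP_NUMBER")
  if (is.null(cc)) stop(path, ": header lacks !UNIT_CELL_CONSTANTS")
  cst <- scan(text = cc, quiet = TRUE)
  if (length(cst) != 6) stop(path, ": UNIT_CELL_CONSTANTS needs 6 numbers")
  cell <- unit_cell(cst[1], cst[2], cst[3], cst[4], cst[5], cst[6])
  ops <- space_group_point_group(as.integer(sg))
  wedge <- get_key("WEDGE_DEGREES")
  wedge <- if (is.null(wedge)) NA_real_ else as.numeric(wedge)
  data_end <- match("!END_OF_DATA", lines)
  if (is.na(data_end)) data_end <- length(lines) + 1L
  body <- lines[seq.int(hdr_end + 1L, data_end - 1L)]
  keep <- nzchar(trimws(body))
  body_ln <- which(keep) + hdr_end          # original line numbers
  body <- body[keep]
  if (length(body) == 0) stop(path, ": no reflection rows")
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 5))
    stop(path, ": line ", body_ln[which(nf != 5)[1]], ": expected 5 fields")
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- which(rowSums(matrix(is.na(vals), ncol = 5, byrow = TRUE)) > 0)[1]
    stop(path, ": line ", body_ln[bad], ": non-numeric field")
  }
  m <- matrix(vals, ncol = 5, byrow = TRUE)
  obs <- data.frame(h = m[, 1], k = m[, 2], l = m[, 3], i = m[, 4], sigi = m[, 5])
  check_rows(obs, path, line_numbers = body_ln)
  xtal_dataset(id, cell, ops, obs, wedge_deg = wedge)
}

check_rows <- function(obs, path, offset = 0L, line_numbers = NULL) {
  if (is.null(line_numbers)) line_numbers <- seq_len(nrow(obs)) + offset
  bad <- which(!is.finite(obs$sigi) | obs$sigi <= 0)
  if (length(bad))
    stop(path, ": line ", line_numbers[bad[1]], ": sigma must be > 0")
  bad <- which(obs$h == 0 & obs$k == 0 & obs$l == 0)
  if (length(bad))
    stop(path, ": line ", line_numbers[bad[1]], ": hkl (0,0,0)")
  invisible(TRUE)
}

#' Write an unmerged dataset
#'
#' @param ds An [xtal_dataset()].
#' @param path Output path.
#' @param dialect "xds_ascii_like" or "csv".
#' @export
write_unmerged <- function(ds, path, dialect = c("xds_ascii_like", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is_xtal_dataset(ds))
  if (dialect == "csv") {
    utils::write.csv(ds$obs, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "!FORMAT=XDS_ASCII MERGE=FALSE FRIEDEL'S_LAW=FALSE",
    sprintf("!SPACE_GROUP_NUMBER=%d", point_group_space_group_number(ds$ops)),
    sprintf("!UNIT_CELL_CONSTANTS= %.4f %.4f %.4f %.3f %.3f %.3f",
            ds$cell$a, ds$cell$b, ds$cell$c,
            ds$cell$alpha, ds$cell$beta, ds$cell$gamma),
    if (!is.na(ds$wedge_deg)) sprintf("!WEDGE_DEGREES=%.2f", ds$wedge_deg),
    "!END_OF_HEADER"
  )
  rows <- sprintf("%d %d %d %.4f %.4f",
                  ds$obs$h, ds$obs$k, ds$obs$l, ds$obs$i, ds$obs$sigi)
  writeLines(c(hdr, rows, "!END_OF_DATA"), path)
  invisible(path)
}

#' Write a merged reflection set
#'
#' `xds_ascii_like` writes `h k l I sigI` rows with a MERGE=TRUE header (the
#' canonical ASU triple per unique key; Friedel-separated sets write the "-"
#' mate as -h -k -l). `shelx_hklf4` writes fixed-width 3I4,2F8.2 rows.
#'
#' @param merged A [merged_set()].
#' @param path Output path.
#' @param dialect "xds_ascii_like" or "shelx_hklf4".
#' @export
write_merged <- function(merged, path, dialect = c("xds_ascii_like", "shelx_hklf4")) {
  dialect <- match.arg(dialect)
  stopifnot(is_merged_set(merged))
  e <- merged$entries
  if (nrow(e) == 0) stop("empty merged set")
  sgn <- ifelse(e$friedel == "-", -1L, 1L)
  h <- e$h * sgn; k <- e$k * sgn; l <- e$l * sgn
  if (dialect == "shelx_hklf4") {
    if (any(abs(h) > 999 | abs(k) > 999 | abs(l) > 999))
      stop("index overflows I4 field")
    if (any(e$i <= -1e6 | e$i >= 1e7) || any(e$sigma >= 1e7))
      stop("intensity magnitude overflows F8.2 field")
    rows <- sprintf("%4d%4d%4d%8.2f%8.2f", h, k, l, e$i, e$sigma)
    writeLines(rows, path)
    return(invisible(path))
  }
  hdr <- c(
    sprintf("!FORMAT=XDS_ASCII MERGE=TRUE FRIEDEL'S_LAW=%s",
            if (merged$anomalous) "FALSE" else "TRUE"),
    sprintf("!SPACE_GROUP_NUMBER=%d", point_group_space_group_number(merged$ops)),
    sprintf("!UNIT_CELL_CONSTANTS= %.4f %.4f %.4f %.3f %.3f %.3f",
            merged$cell$a, merged$cell$b, merged$cell$c,
            merged$cell$alpha, merged$cell$beta, merged$cell$gamma),
    "!END_OF_HEADER"
  )
  rows <- sprintf("%d %d %d %.4f %.4f", h, k, l, e$i, e$sigma)
  writeLines(c(hdr, rows, "!END_OF_DATA"), path)
  invisible(path)
}

#' Read a merged reflection set written by [write_merged()]
#'
#' @param path File path (xds_ascii_like dialect).
#' @return A [merged_set()] (n_obs is not stored in the format and is set
#'   to 1).
#' @export
read_merged <- function(path) {
  ds <- read_unmerged(path, "xds_ascii_like")
  lines <- readLines(path, n = 1)
  anom <- grepl("FRIEDEL'S_LAW=FALSE", lines[1], fixed = TRUE)
  asu <- map_to_asu(as.matrix(ds$obs[c("h", "k", "l")]), ds$ops, anomalous = anom)
  entries <- data.frame(asu, i = ds$obs$i, sigma = ds$obs$sigi, n_obs = 1L,
                        stringsAsFactors = FALSE)
  new_merged_set(entries, ds$cell, ds$ops, anomalous = anom)
}
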