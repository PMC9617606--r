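#' Read a STAR table
#'
#' Parses a RELION-dialect STAR file: a `data_` block containing a `loop_`
#' with `_column #N` headers followed by whitespace-separated rows.  Only the
#' first data block is read.  Numeric-looking columns are converted.
#'
#' @param path path to a STAR file.
#' @return A data.frame, one row per record; column names are the STAR tags
#'   without the leading underscore.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  i_data <- which(startsWith(lines, "data_"))
  if (!length(i_data)) stop("no data_ block in STAR file: ", path)
  i_loop <- which(lines == "loop_")
  i_loop <- i_loop[i_loop > i_data[1]][1]
  if (is.na(i_loop)) stop("no loop_ in STAR data block: ", path)
  rest <- lines[(i_loop + 1):length(lines)]
  is_tag <- startsWith(rest, "_")
  n_tags <- match(FALSE, is_tag, nomatch = length(rest) + 1) - 1
  if (n_tags == 0) stop("loop_ has no column tags: ", path)
  tags <- sub("^_", "", sub("\\s+#\\d+\\s*$", "", rest[seq_len(n_tags)]))
  body <- rest[seq.int(n_tags + 1, length.out = length(rest) - n_tags)]
  stop_at <- which(startsWith(body, "data_"))
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1)]
  if (!length(body)) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(tags)))
    names(df) <- tags
    return(df)
  }
  cells <- strsplit(body, "\\s+")
  bad <- vapply(cells, length, 1L) != length(tags)
  if (any(bad)) stop("STAR row with wrong number of cells at data line ",
                     which(bad)[1])
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- tags
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}

#' Write a STAR table
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param block data block name (default `"data_"`).
#' @return Invisibly, `path`.
#' @export
write_star <- function(df, path, block = "data_") {
  stopifnot(is.data.frame(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", block, "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, trim = TRUE, digits = 10, scientific = FALSE)
      else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Build a tomogram table from a folder of MRC files
#'
#' Scans a directory for MRC volumes and fills one STAR row per tomogram with
#' defaults: pixel size from each header, a default defocus and subtomogram
#' count, and empty mask/deconvolved paths.
#'
#' @param folder directory containing `.mrc`/`.rec` volumes.
#' @param pixel_size override the header pixel size for all rows (required if
#'   a header carries none).
#' @param defocus default defocus in micrometres (underfocus positive).
#' @param number_subtomos default number of subtomograms to extract per
#'   tomogram.
#' @return A data.frame with columns `rlnIndex`, `rlnMicrographName`,
#'   `rlnPixelSize`, `rlnDefocus`, `rlnNumberSubtomo`, `rlnMaskName`,
#'   `rlnDeconvTomoName`.
#' @export
prepare_star <- function(folder, pixel_size = NULL, defocus = 0,
                         number_subtomos = 100) {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  files <- list.files(folder, pattern = "\\.(mrc|mrcs|rec|map)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) {
    warning("no MRC-like files found in ", folder)
    return(data.frame(rlnIndex = integer(), rlnMicrographName = character(),
                      rlnPixelSize = numeric(), rlnDefocus = numeric(),
                      rlnNumberSubtomo = integer(), rlnMaskName = character(),
                      rlnDeconvTomoName = character(),
                      stringsAsFactors = FALSE))
  }
  px <- vapply(files, function(f) {
    if (!is.null(pixel_size)) return(pixel_size)
    p <- withCallingHandlers(read_mrc_pixel_size(f),
                             warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(p)) stop("no pixel size in header of ", f,
                       "; pass pixel_size explicitly")
    p
  }, numeric(1))
  data.frame(rlnIndex = seq_along(files),
             rlnMicrographName = files,
             rlnPixelSize = px,
             rlnDefocus = defocus,
             rlnNumberSubtomo = number_subtomos,
             rlnMaskName = "None",
             rlnDeconvTomoName = "None",
             stringsAsFactors = FALSE)
}

# Header-only pixel size read (NA if the header has no usable cell).
read_mrc_pixel_size <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (ints[8] > 0 && cella[1] > 0) cella[1] / ints[8] else NA_real_
}
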