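#' Read and write landscape text files
#'
#' Landscapes are exchanged as plain-text files so a set of
#' pre-generated landscapes can be reused across scenarios and runs.
#' The dialect is: a header of comment lines
#' `# width=<int> height=<int> hurst=<float> G=<float>`, then a line
#' `# attribute=T` followed by `height` whitespace-delimited rows of
#' `width` values (the standardized temperature field), then
#' `# attribute=H` and its grid. Values are written with full decimal
#' precision (`%.17g`), so a write/read round-trip is bitwise exact.
#'
#' @param landscape A [make_landscape()] object.
#' @param path File path.
#' @return `read_landscape_file()` returns a `"landscape"` object;
#'   `write_landscape_file()` returns `path` invisibly.
#' @examples
#' set.seed(7)
#' land <- make_landscape(4, 3, hurst = 0.5, G = 0.3)
#' tf <- tempfile(fileext = ".txt")
#' write_landscape_file(land, tf)
#' land2 <- read_landscape_file(tf)
#' identical(unclass(land$t_base), unclass(land2$t_base))
#' @export
write_landscape_file <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  fmt_grid <- function(m)
    apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  lines <- c(
    sprintf("# width=%d height=%d hurst=%.17g G=%.17g",
            landscape$width, landscape$height, landscape$hurst, landscape$G),
    "# attribute=T", fmt_grid(landscape$t_base),
    "# attribute=H", fmt_grid(landscape$h_base)
  )
  writeLines(lines, con = path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_landscape_file
#' @export
read_landscape_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], "#"))
    stop("landscape file: missing header line", call. = FALSE)

  hdr <- parse_header_kv(lines[[1]])
  for (key in c("width", "height", "hurst"))
    if (is.na(hdr[key]))
      stop(sprintf("landscape file: header is missing '%s'", key),
           call. = FALSE)
  width <- as.integer(hdr[["width"]]); height <- as.integer(hdr[["height"]])
  G <- if (is.na(hdr["G"])) 1 else hdr[["G"]]

  read_block <- function(start, attr_name) {
    tag <- sprintf("# attribute=%s", attr_name)
    if (start > length(lines) || trimws(lines[[start]]) != tag)
      stop(sprintf("landscape file: expected '%s' block at line %d",
                   attr_name, start), call. = FALSE)
    rows <- lines[start + seq_len(height)]
    if (length(rows) < height || anyNA(rows))
      stop(sprintf("landscape file: attribute %s grid is truncated",
                   attr_name), call. = FALSE)
    vals <- lapply(seq_along(rows), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[[i]]),
                                                "[[:space:]]+")[[1]]))
      if (length(v) != width || anyNA(v))
        stop(sprintf(
          "landscape file: attribute %s row %d has %d valid values, expected %d",
          attr_name, i, sum(!is.na(v)), width), call. = FALSE)
      v
    })
    matrix(unlist(vals), nrow = height, ncol = width, byrow = TRUE)
  }

  t_base <- read_block(2, "T")
  h_base <- read_block(3 + height, "H")
  structure(
    list(t_base = structure(t_base, class = c("field", "matrix", "array")),
         h_base = structure(h_base, class = c("field", "matrix", "array")),
         G = G, hurst = hdr[["hurst"]], width = width, height = height),
    class = "landscape"
  )
}

#' Export or import a fluctuation series
#'
#' Writes the global temperature fluctuation series as a single-column
#' CSV with header `epsilon` (full precision), so a run's temporal
#' forcing can be archived or replayed.
#'
#' @param epsilon Numeric vector from [generate_fluctuations()].
#' @param path File path.
#' @return `read_fluctuations_file()` returns the numeric vector;
#'   `write_fluctuations_file()` returns `path` invisibly.
#' @export
write_fluctuations_file <- function(epsilon, path) {
  stopifnot(is.numeric(epsilon), length(epsilon) >= 1)
  writeLines(c("epsilon", sprintf("%.17g", epsilon)), con = path)
  invisible(path)
}

#' @rdname write_fluctuations_file
#' @export
read_fluctuations_file <- function(path) {
  d <- utils::read.csv(path)
  if (!identical(names(d), "epsilon"))
    stop("fluctuation file must have the single column 'epsilon'",
         call. = FALSE)
  as.numeric(d$epsilon)
}

parse_header_kv <- function(line) {
  toks <- regmatches(line, gregexpr("[A-Za-z]+=[^[:space:]]+", line))[[1]]
  keys <- sub("=.*", "", toks)
  vals <- suppressWarnings(as.numeric(sub(".*=", "", toks)))
  out <- c(width = NA_real_, height = NA_real_, hurst = NA_real_, G = NA_real_)
  out[keys[keys %in% names(out)]] <- vals[keys %in% names(out)]
  out
}
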