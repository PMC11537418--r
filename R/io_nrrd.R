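#' Read a NRRD scalar grid
#'
#' Minimal NRRD reader covering the subset this package writes: 3-D (or
#' 4-D vector) grids, \code{text} or \code{ascii} encoding, with
#' \code{space directions} / \code{space origin} metadata carrying the voxel
#' size and world offset in micrometres.
#'
#' @param path file path.
#' @return list with \code{data} (array), \code{voxel_size}, \code{origin}.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^NRRD", lines[1])) stop("not a NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("NRRD header not terminated by blank line")
  hdr <- lines[2:(blank - 1)]
  hdr <- hdr[!grepl("^#", hdr)]
  kv <- strsplit(hdr, ":\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  field <- function(k) vals[match(k, keys)]
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  enc <- field("encoding")
  if (!enc %in% c("text", "txt", "ascii")) stop("unsupported NRRD encoding: ", enc)
  vs <- 1
  if (!is.na(field("space directions"))) {
    dirs <- regmatches(field("space directions"), gregexpr("\\(([^)]*)\\)", field("space directions")))[[1]]
    if (length(dirs) > 0) {
      v1 <- as.numeric(strsplit(gsub("[()]", "", dirs[1]), ",")[[1]])
      vs <- sqrt(sum(v1^2))
    }
  }
  org <- c(0, 0, 0)
  if (!is.na(field("space origin"))) {
    org <- as.numeric(strsplit(gsub("[()]", "", field("space origin")), ",")[[1]])
  }
  vals_num <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
                   quiet = TRUE)
  data <- array(vals_num, dim = sizes)
  list(data = data, voxel_size = vs, origin = org)
}

#' Write a NRRD scalar (or vector) grid
#'
#' Text-encoded NRRD so outputs stay plain-text.
#'
#' @param data numeric/logical array (3-D scalar or 4-D with vector axis first).
#' @param path output file.
#' @param voxel_size micrometres per voxel edge.
#' @param origin world offset (micrometres).
#' @export
write_nrrd <- function(data, path, voxel_size = 1, origin = c(0, 0, 0)) {
  nd <- length(dim(data))
  dirs <- switch(
    as.character(nd),
    "3" = sprintf("(%g,0,0) (0,%g,0) (0,0,%g)", voxel_size, voxel_size, voxel_size),
    "4" = sprintf("none (%g,0,0) (0,%g,0) (0,0,%g)", voxel_size, voxel_size, voxel_size),
    stop("only 3-D or 4-D arrays supported"))
  hdr <- c(
    "NRRD0004",
    "# ca1forge volumetric grid",
    "type: double",
    sprintf("dimension: %d", nd),
    sprintf("sizes: %s", paste(dim(data), collapse = " ")),
    "encoding: text",
    sprintf("space directions: %s", dirs),
    sprintf("space origin: (%s)", paste(origin, collapse = ",")),
    "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(sprintf("%.17g", as.vector(as.numeric(data))),
                   collapse = " "), con)
  invisible(path)
}
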