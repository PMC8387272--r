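#' Read a feature table from its on-disk files
#'
#' Expects the dialect written by [write_feature_table()]: a comma-separated
#' intensity matrix (feature ids as row names, sample ids as columns, "." as
#' decimal mark, empty cells for missing values), an MSP-like spectra file
#' (blocks of `NAME:`, `RI:`, optional `ANNOTATION:`, `Num Peaks:` followed by
#' one `mz intensity` pair per line), and a sample metadata table mapping
#' sample id to role and product id. Features absent from the spectra file are
#' retained without a spectrum and are skipped by the spectral matcher.
#'
#' @param path intensity matrix CSV.
#' @param spectra_path MSP spectra file.
#' @param metadata_path sample metadata CSV (`sample_id`, `role`, `product_id`).
#' @param platform_name platform label; defaults to the intensity file's
#'   directory name.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, spectra_path, metadata_path,
                               platform_name = basename(dirname(path))) {
  m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  specs <- read_msp(spectra_path)
  ids <- rownames(m)
  extra <- setdiff(names(specs), ids)
  if (length(extra)) {
    stop(sprintf("spectra file contains unknown feature ids: %s",
                 paste(utils::head(extra, 5), collapse = ", ")), call. = FALSE)
  }
  feats <- lapply(ids, function(id) {
    s <- specs[[id]]
    if (is.null(s)) {
      # RI unknown without a spectrum block; store 0 and no spectrum —
      # such features never enter the matcher
      feature(id, 0, NULL)
    } else {
      feature(id, s$ri, mass_spectrum(s$mz, s$intensity), s$annotation)
    }
  })
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity in intensity file", call. = FALSE)
  feature_table(platform_name, feats, meta, m)
}

#' Write a feature table to a directory
#'
#' Emits `intensities.csv`, `spectra.msp` and `samples.csv` in the dialect
#' read back by [read_feature_table()]. Numeric values are printed at full
#' precision (17 significant digits) so that a write/read round trip
#' reproduces the matrix bit-exactly.
#'
#' @param table a [feature_table()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_feature_table <- function(table, dir) {
  stopifnot(inherits(table, "feature_table"))
  if (length(table$features) == 0L) stop("nothing to write: empty feature list", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(intensities = file.path(dir, "intensities.csv"),
             spectra = file.path(dir, "spectra.msp"),
             samples = file.path(dir, "samples.csv"))

  m <- table$intensities
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow = nrow(m),
                dimnames = dimnames(m))
  chr[is.na(m)] <- NA  # formatC renders NA as " NA"; restore true NA cells
  df <- data.frame(feature_id = rownames(m), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, paths[["intensities"]], row.names = FALSE, na = "")

  con <- file(paths[["spectra"]], "w")
  on.exit(close(con), add = TRUE)
  for (f in table$features) {
    if (is.null(f$spectrum)) next
    writeLines(sprintf("NAME: %s", f$feature_id), con)
    writeLines(sprintf("RI: %s", formatC(f$retention_index, digits = 17, format = "g")), con)
    if (!is.na(f$annotation)) writeLines(sprintf("ANNOTATION: %s", f$annotation), con)
    writeLines(sprintf("Num Peaks: %d", length(f$spectrum$mz)), con)
    writeLines(paste(formatC(f$spectrum$mz, digits = 17, format = "g"),
                     formatC(f$spectrum$intensity, digits = 17, format = "g")), con)
    writeLines("", con)
  }

  utils::write.csv(table$samples, paths[["samples"]], row.names = FALSE, na = "")
  invisible(paths)
}

# Parse MSP-like spectra text into a named list of
# list(ri, mz, intensity, annotation) blocks keyed by feature id.
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^NAME:", ln, ignore.case = TRUE)) {
      stop(sprintf("malformed MSP file at line %d: expected NAME:", i), call. = FALSE)
    }
    id <- trimws(sub("^NAME:", "", ln, ignore.case = TRUE))
    ri <- NA_real_; ann <- NA_character_; npeaks <- NA_integer_
    i <- i + 1L
    while (i <= n) {
      ln <- trimws(lines[i])
      if (grepl("^RI:", ln, ignore.case = TRUE)) {
        ri <- as.numeric(trimws(sub("^RI:", "", ln, ignore.case = TRUE)))
      } else if (grepl("^ANNOTATION:", ln, ignore.case = TRUE)) {
        ann <- trimws(sub("^ANNOTATION:", "", ln, ignore.case = TRUE))
      } else if (grepl("^Num Peaks:", ln, ignore.case = TRUE)) {
        npeaks <- as.integer(trimws(sub("^Num Peaks:", "", ln, ignore.case = TRUE)))
        i <- i + 1L
        break
      } else {
        stop(sprintf("malformed MSP block '%s' at line %d", id, i), call. = FALSE)
      }
      i <- i + 1L
    }
    if (is.na(npeaks)) stop(sprintf("MSP block '%s' lacks Num Peaks", id), call. = FALSE)
    mz <- numeric(npeaks); inten <- numeric(npeaks)
    for (k in seq_len(npeaks)) {
      parts <- strsplit(trimws(lines[i]), "[[:space:];]+")[[1]]
      if (length(parts) < 2L) stop(sprintf("malformed peak line %d in block '%s'", i, id), call. = FALSE)
      mz[k] <- as.numeric(parts[1]); inten[k] <- as.numeric(parts[2])
      i <- i + 1L
    }
    if (is.na(ri)) stop(sprintf("MSP block '%s' lacks RI", id), call. = FALSE)
    out[[id]] <- list(ri = ri, mz = mz, intensity = inten, annotation = ann)
  }
  out
}

#' Read a design table from CSV
#' @param path CSV with `product_id` plus one column per design factor.
#' @return A [design_table()].
#' @export
read_design_table <- function(path) {
  design_table(utils::read.csv(path, check.names = FALSE, colClasses = "character"))
}

#' Read a long-format sensory table from CSV
#' @param path CSV with `panellist_id`, `product_id`, `attribute`,
#'   `intensity` and optionally `session`.
#' @return A [sensory_table()].
#' @export
read_sensory_table <- function(path) {
  sensory_table(utils::read.csv(path, check.names = FALSE))
}

#' Write the full synthetic bundle to a directory tree
#'
#' Writes `a/` and `b/` platform directories (via [write_feature_table()]),
#' `design.csv`, `sensory.csv` and, when ground truth is present,
#' `truth.json`.
#'
#' @param bundle a list as returned by [generate_two_platform_data()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(bundle$table_a, file.path(dir, "a"))
  write_feature_table(bundle$table_b, file.path(dir, "b"))
  utils::write.csv(as.data.frame(bundle$design), file.path(dir, "design.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(bundle$sensory), file.path(dir, "sensory.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
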