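# Mass-spectrum comparison measures and library identification. Measures are
# registered by id (see register_measure()) so further match factors can be
# plugged in; both built-ins return scores in [0, 1] over the union of the
# two spectra's nominal masses, with 0 filled in for missing ions.

# align two spectra on the union of their m/z values
align_spectra <- function(a, b) {
  stopifnot(inherits(a, "mass_spectrum"), inherits(b, "mass_spectrum"))
  if (!length(a$mz) || !length(b$mz)) stop("cannot compare an empty spectrum")
  u <- sort(union(a$mz, b$mz))
  va <- numeric(length(u)); vb <- numeric(length(u))
  va[match(a$mz, u)] <- a$abundance
  vb[match(b$mz, u)] <- b$abundance
  list(mz = u, a = va, b = vb)
}

#' Cosine match factor between two mass spectra
#'
#' Normalized dot product over the union of nominal masses:
#' `sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))`.  Symmetric, invariant
#' under scaling either spectrum by a positive constant; 1 for identical
#' relative patterns, 0 for disjoint m/z support.
#'
#' @param a,b non-empty `mass_spectrum` objects.
#' @return score in \[0, 1\].
#' @export
cosine_match <- function(a, b) {
  v <- align_spectra(a, b)
  na <- sqrt(sum(v$a^2)); nb <- sqrt(sum(v$b^2))
  if (na == 0 || nb == 0) return(0)
  min(max(sum(v$a * v$b) / (na * nb), 0), 1)
}

#' Euclidean match factor between two mass spectra
#'
#' Both spectra are normalized to unit maximum abundance; the score is
#' `1 - d / sqrt(2 * |union|)` where `d` is the Euclidean distance over the
#' m/z union.  Symmetric and bounded in \[0, 1\]: two vectors in `[0, 1]^n`
#' are at most `sqrt(n) <= sqrt(2 n)` apart.
#'
#' @param a,b non-empty `mass_spectrum` objects.
#' @return score in \[0, 1\].
#' @export
euclidean_match <- function(a, b) {
  v <- align_spectra(a, b)
  ma <- max(v$a); mb <- max(v$b)
  if (ma == 0 || mb == 0) return(0)
  d <- sqrt(sum((v$a / ma - v$b / mb)^2))
  min(max(1 - d / sqrt(2 * length(v$mz)), 0), 1)
}

#' Identify a spectrum against a library
#'
#' Scores every library entry with the requested measure and returns the
#' entries reaching `min_score`, sorted by descending score; ties keep
#' library order.
#'
#' @param peak_spectrum the query `mass_spectrum`.
#' @param library non-empty list of library entries (see [read_msp_library()]).
#' @param measure_id id of a registered measure (default `"cosine"`).
#' @param min_score minimum score to report (default 0).
#' @return data.frame with columns `name`, `score`, `measure_id`, sorted by
#'   descending score; zero rows if nothing reaches `min_score`.
#' @export
identify_peak <- function(peak_spectrum, library, measure_id = "cosine",
                          min_score = 0) {
  if (!length(library)) stop("library must be non-empty")
  entry <- registry_lookup("measures", measure_id)
  scores <- vapply(library, function(e) entry$fun(peak_spectrum, e$spectrum),
                   double(1))
  keep <- which(scores >= min_score)
  o <- keep[order(-scores[keep])]  # order() is stable: ties keep library order
  data.frame(name = vapply(library[o], `[[`, character(1), "name"),
             score = scores[o], measure_id = rep(measure_id, length(o)),
             row.names = NULL)
}

#' Construct a spectral-library entry
#'
#' @param name compound name, non-empty.
#' @param spectrum non-empty `mass_spectrum`.
#' @param metadata optional named character vector (formula, CAS, ...).
#' @return a list of class `library_entry`.
#' @export
library_entry <- function(name, spectrum, metadata = character()) {
  stopifnot(is.character(name), nzchar(name),
            inherits(spectrum, "mass_spectrum"))
  if (!length(spectrum$mz)) stop("library entry needs a non-empty spectrum")
  structure(list(name = name, spectrum = spectrum, metadata = metadata),
            class = "library_entry")
}

#' Read a NIST MSP-format spectral library
#'
#' Parses the MSP text dialect: records start at `Name:`, must carry
#' `Num Peaks:`, and list m/z-intensity pairs separated by semicolons and/or
#' whitespace, possibly several per line.  `Formula:` and `CAS#:` lines are
#' kept as entry metadata.  Fractional m/z are rounded to nominal mass and
#' merged.
#'
#' @param path path to an MSP file.
#' @return list of `library_entry` objects (empty for an empty file).
#' @export
read_msp_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!grepl("^Name:", line, ignore.case = TRUE)) {
      i <- i + 1L
      next
    }
    name <- trimws(sub("^Name:", "", line, ignore.case = TRUE))
    md <- character()
    npeaks <- NA_integer_
    i <- i + 1L
    while (i <= n) {
      l <- trimws(lines[i])
      if (grepl("^Num Peaks:", l, ignore.case = TRUE)) {
        npeaks <- as.integer(trimws(sub("^Num Peaks:", "", l,
                                        ignore.case = TRUE)))
        i <- i + 1L
        break
      }
      if (grepl("^Name:", l, ignore.case = TRUE))
        stop("MSP parse error: entry '", name, "' has no 'Num Peaks:' line")
      kv <- regmatches(l, regexec("^([A-Za-z#/ ]+):\\s*(.*)$", l))[[1]]
      if (length(kv) == 3L) md[trimws(kv[2])] <- kv[3]
      i <- i + 1L
    }
    if (is.na(npeaks))
      stop("MSP parse error: entry '", name, "' has no 'Num Peaks:' line")
    nums <- numeric()
    while (i <= n && length(nums) < 2L * npeaks) {
      l <- trimws(lines[i])
      if (!nzchar(l)) { i <- i + 1L; next }
      tok <- strsplit(l, "[;,[:space:]]+")[[1]]
      tok <- tok[nzchar(tok)]
      vals <- suppressWarnings(as.numeric(tok))
      if (anyNA(vals)) break
      nums <- c(nums, vals)
      i <- i + 1L
    }
    if (length(nums) != 2L * npeaks)
      stop("MSP parse error: entry '", name, "' declares ", npeaks,
           " peaks but lists ", length(nums) %/% 2L)
    k <- seq_len(npeaks)
    nom <- nominalize(nums[2L * k - 1L], nums[2L * k])
    entries[[length(entries) + 1L]] <-
      library_entry(name, mass_spectrum(nom$mz, nom$abundance), md)
  }
  entries
}

#' Write an MSP-format spectral library
#'
#' @param library list of `library_entry` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp_library <- function(library, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (e in library) {
    cat(sprintf("Name: %s\n", e$name), file = con)
    for (k in names(e$metadata))
      cat(sprintf("%s: %s\n", k, e$metadata[[k]]), file = con)
    cat(sprintf("Num Peaks: %d\n", length(e$spectrum$mz)), file = con)
    cat(paste(sprintf("%d %s;", e$spectrum$mz, fmt_dbl(e$spectrum$abundance)),
              collapse = " "), "\n\n", sep = "", file = con)
  }
  invisible(path)
}
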