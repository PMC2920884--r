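# Converter registry with content-based format probing, plus readers and
# writers for mzXML (3.x subset), ANDI-MS NetCDF and the package's native XML
# format. All importers enforce the nominal-mass policy: fractional m/z are
# rounded half-up to the nearest integer and collisions merged by summing.

register_formats <- function() {
  registry_put("formats", "mzxml", list(
    format_id = "mzxml", extensions = c("mzxml"),
    sniff = function(head) grepl("<mzXML", head, fixed = TRUE),
    read = read_mzxml, write = write_mzxml), overwrite = TRUE)
  registry_put("formats", "andi-netcdf", list(
    format_id = "andi-netcdf", extensions = c("cdf", "nc"),
    sniff = function(head) startsWith(head, "CDF"),
    read = read_andi_netcdf, write = write_andi_netcdf), overwrite = TRUE)
  registry_put("formats", "native-xml", list(
    format_id = "native-xml", extensions = c("chrom.xml"),
    sniff = function(head) grepl("<chromatogram", head, fixed = TRUE),
    read = read_native_xml, write = write_native_xml), overwrite = TRUE)
}

#' Probe a file for an importable chromatogram format
#'
#' Sniffs the file content (XML root element for mzXML and the native format,
#' the `CDF` magic bytes for NetCDF) and falls back to the file extension.
#' Never raises on unreadable content: unknown files yield
#' `format_id = "unknown"` and `importable = FALSE`.
#'
#' @param path path to an existing file.
#' @return a list of class `probe_result` with `path`, `format_id` and
#'   `importable`.
#' @export
probe <- function(path) {
  if (!file.exists(path) || dir.exists(path)) stop("no such file: ", path)
  head <- tryCatch({
    con <- file(path, "rb")
    on.exit(close(con))
    b <- readBin(con, raw(), n = 4096L)
    # magic strings are ASCII; blank out NULs and non-ASCII bytes so binary
    # content stays sniffable as text in any locale
    b[b == as.raw(0L) | b > as.raw(127L)] <- as.raw(32L)
    rawToChar(b)
  }, error = function(e) "")
  reg <- registry_get("formats")
  fid <- "unknown"
  for (f in reg[sort(names(reg))])
    if (isTRUE(tryCatch(f$sniff(head), error = function(e) FALSE))) {
      fid <- f$format_id
      break
    }
  if (fid == "unknown") {
    ext <- tolower(tools::file_ext(path))
    for (f in reg[sort(names(reg))])
      if (ext %in% f$extensions) {
        fid <- f$format_id
        break
      }
  }
  structure(list(path = path, format_id = fid, importable = fid != "unknown"),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$path, x$format_id,
              if (x$importable) " (importable)" else ""))
  invisible(x)
}

#' Read a chromatogram from a file
#'
#' @param path path to an mzXML, ANDI-MS NetCDF or native XML file.
#' @param format_id optional format override; by default the format is probed
#'   from the content.
#' @return a `chromatogram`; its metadata records `source_format` and
#'   `source_file`.
#' @export
read_chromatogram <- function(path, format_id = NULL) {
  if (is.null(format_id)) {
    pr <- probe(path)
    if (!pr$importable)
      stop("unsupported format: cannot probe ", path)
    format_id <- pr$format_id
  }
  entry <- registry_lookup("formats", format_id)
  if (is.null(entry$read)) stop("format '", format_id, "' is not readable")
  x <- entry$read(path)
  x$metadata["source_format"] <- format_id
  x$metadata["source_file"] <- path
  assert_chromatogram_valid(x)
  x
}

#' Write a chromatogram to a file
#'
#' The written file is re-readable by [read_chromatogram()].  The native XML
#' format additionally persists metadata, the attached baseline and the peak
#' list; mzXML and ANDI NetCDF persist scan data only.
#'
#' @param x a `chromatogram`.
#' @param path output path.
#' @param format_id one of `"mzxml"`, `"andi-netcdf"`, `"native-xml"`.
#' @param ... format options (e.g. `precision = 32` for mzXML).
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(x, path, format_id, ...) {
  stopifnot(inherits(x, "chromatogram"))
  entry <- registry_lookup("formats", format_id)
  if (is.null(entry$write)) stop("format '", format_id, "' is not writable")
  entry$write(x, path, ...)
  invisible(path)
}

#' Recursively list importable files under a directory
#'
#' @param directory an existing directory.
#' @return list of `probe_result`s for every regular file, in lexicographic
#'   path order.
#' @export
list_importable <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- sort(list.files(directory, recursive = TRUE, full.names = TRUE))
  files <- files[!dir.exists(files)]
  lapply(files, probe)
}

# ---- nominal-mass import policy ------------------------------------------

# round half-up to integer nominal mass and merge collisions by summing
nominalize <- function(mz, abundance) {
  imz <- as.integer(floor(mz + 0.5))
  imz[imz < 1L] <- 1L
  if (anyDuplicated(imz)) {
    ab <- vapply(split(abundance, imz), sum, double(1))
    imz <- as.integer(names(ab))
    o <- order(imz)
    list(mz = imz[o], abundance = unname(ab)[o])
  } else {
    o <- order(imz)
    list(mz = imz[o], abundance = abundance[o])
  }
}

scan_from_raw <- function(rt_ms, mz, abundance) {
  keep <- abundance >= 0 & !is.na(mz)
  n <- nominalize(mz[keep], abundance[keep])
  ms_scan(rt_ms, mass_spectrum(n$mz, n$abundance))
}

# ---- mzXML ----------------------------------------------------------------

# minimal mzXML 3.x subset: msRun/scan, peaks base64-encoded network-byte-order
# interleaved (m/z, intensity); precision 32 or 64; zlib accepted on read.
read_mzxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed mzXML in ", path, ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  scans <- xml2::xml_find_all(doc, ".//msRun/scan | .//scan")
  if (!length(scans)) stop("malformed mzXML: no scan elements in ", path)
  out <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    rt <- parse_iso_duration_ms(xml2::xml_attr(sc, "retentionTime"))
    pk <- xml2::xml_find_first(sc, "./peaks")
    if (is.na(xml2::xml_attr(sc, "num")) || inherits(pk, "xml_missing"))
      stop("malformed mzXML: scan ", i, " lacks num/peaks in ", path)
    prec <- xml2::xml_attr(pk, "precision")
    prec <- if (is.na(prec)) 32L else as.integer(prec)
    if (!prec %in% c(32L, 64L))
      stop("malformed mzXML: unsupported precision '", prec, "' at scan ", i)
    comp <- xml2::xml_attr(pk, "compressionType")
    b <- jsonlite::base64_dec(gsub("\\s", "", xml2::xml_text(pk)))
    if (!is.na(comp) && comp == "zlib")
      b <- memDecompress(b, type = "gzip")
    vals <- readBin(b, "double", n = length(b) %/% (prec %/% 8L),
                    size = prec %/% 8L, endian = "big")
    npk <- as.integer(xml2::xml_attr(sc, "peaksCount"))
    if (!is.na(npk) && npk * 2L != length(vals))
      stop("malformed mzXML: peaksCount mismatch at scan element ", i)
    k <- seq_len(length(vals) %/% 2L)
    out[[i]] <- scan_from_raw(rt, vals[2L * k - 1L], vals[2L * k])
  }
  chromatogram(out, metadata = c(source_format = "mzxml"))
}

parse_iso_duration_ms <- function(s) {
  if (is.na(s)) stop("malformed mzXML: scan lacks retentionTime")
  m <- regmatches(s, regexec("^PT([0-9.]+)S$", s))[[1]]
  if (length(m) != 2L) stop("malformed mzXML: bad retentionTime '", s, "'")
  as.integer(round(as.numeric(m[2]) * 1000))
}

write_mzxml <- function(x, path, precision = 64L) {
  precision <- as.integer(precision)
  stopifnot(precision %in% c(32L, 64L))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">')
  w(sprintf(' <msRun scanCount="%d">', n_scans(x)))
  for (i in seq_len(n_scans(x))) {
    s <- x$scans[[i]]
    sp <- s$spectrum
    inter <- as.vector(rbind(as.double(sp$mz), sp$abundance))
    b64 <- gsub("[\r\n]", "", jsonlite::base64_enc(
      writeBin(inter, raw(), size = precision %/% 8L, endian = "big")))
    w(sprintf('  <scan num="%d" msLevel="1" peaksCount="%d" retentionTime="PT%.3fS">',
              i, length(sp$mz), s$rt / 1000))
    w(sprintf('   <peaks precision="%d" byteOrder="network" contentType="m/z-int" compressionType="none" compressedLen="0">%s</peaks>',
              precision, b64))
    w('  </scan>')
  }
  w(' </msRun>')
  w('</mzXML>')
  invisible(path)
}

# ---- ANDI-MS NetCDF -------------------------------------------------------

andi_metadata_atts <- c("operator_name", "sample_name", "instrument_name",
                        "experiment_title")

read_andi_netcdf <- function(path) {
  nc <- tryCatch(nc3_read(path), error = function(e)
    stop("malformed NetCDF in ", path, ": ", conditionMessage(e)))
  need <- c("scan_acquisition_time", "scan_index", "point_count",
            "mass_values", "intensity_values")
  miss <- setdiff(need, names(nc$vars))
  if (length(miss))
    stop("malformed ANDI NetCDF: missing variable(s) ",
         paste(miss, collapse = ", "), " in ", path)
  rt_ms <- as.integer(round(nc$vars$scan_acquisition_time$data * 1000))
  sidx <- nc$vars$scan_index$data
  pcnt <- nc$vars$point_count$data
  mz <- nc$vars$mass_values$data
  ab <- nc$vars$intensity_values$data
  scans <- vector("list", length(rt_ms))
  for (i in seq_along(rt_ms)) {
    if (pcnt[i] > 0L) {
      j <- (sidx[i] + 1L):(sidx[i] + pcnt[i])
      scans[[i]] <- scan_from_raw(rt_ms[i], mz[j], ab[j])
    } else {
      scans[[i]] <- ms_scan(rt_ms[i], mass_spectrum())
    }
  }
  md <- c(source_format = "andi-netcdf")
  for (a in intersect(andi_metadata_atts, names(nc$atts)))
    md[a] <- nc$atts[[a]]
  chromatogram(scans, metadata = md)
}

write_andi_netcdf <- function(x, path) {
  n <- n_scans(x)
  pcnt <- vapply(x$scans, function(s) length(s$spectrum$mz), integer(1))
  total <- sum(pcnt)
  if (total < 1L)
    stop("cannot write ANDI NetCDF: chromatogram holds no ions")
  atts <- c(dataset_completeness = "C1+C2", ms_template_revision = "1.0.1",
            netcdf_revision = "chromkit nc3")
  for (a in intersect(andi_metadata_atts, names(x$metadata)))
    atts[a] <- x$metadata[[a]]
  vars <- list(
    list(name = "scan_acquisition_time", type = "double",
         dims = "scan_number", data = scan_times(x) / 1000),
    list(name = "scan_index", type = "int", dims = "scan_number",
         data = cumsum(c(0L, pcnt))[seq_len(n)]),
    list(name = "point_count", type = "int", dims = "scan_number",
         data = pcnt),
    list(name = "mass_values", type = "double", dims = "point_number",
         data = as.double(unlist(lapply(x$scans, function(s) s$spectrum$mz)))),
    list(name = "intensity_values", type = "double", dims = "point_number",
         data = unlist(lapply(x$scans, function(s) s$spectrum$abundance))))
  nc3_write(path, dims = c(scan_number = n, point_number = total),
            atts = atts, vars = vars)
  invisible(path)
}

# ---- native XML -----------------------------------------------------------

# Documented native schema, version 1.0 (see the format vignette): root
# <chromatogram version="1.0"> with <metadata>, <scans> (scan rt_ms + ion
# elements), optional <baseline> (space-separated per-scan values) and
# optional <peaks>. Full double precision via %.17g.
fmt_dbl <- function(x) sprintf("%.17g", x)

write_native_xml <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<chromatogram version="1.0">')
  w(' <metadata>')
  for (k in names(x$metadata))
    w(sprintf('  <entry key="%s">%s</entry>', esc(k), esc(x$metadata[[k]])))
  w(' </metadata>')
  w(sprintf(' <scans count="%d">', n_scans(x)))
  for (s in x$scans) {
    w(sprintf('  <scan rt_ms="%d">', s$rt))
    sp <- s$spectrum
    for (j in seq_along(sp$mz))
      w(sprintf('   <ion mz="%d" abundance="%s"/>', sp$mz[j],
                fmt_dbl(sp$abundance[j])))
    w('  </scan>')
  }
  w(' </scans>')
  if (!is.null(x$baseline))
    w(sprintf(' <baseline>%s</baseline>',
              paste(fmt_dbl(x$baseline), collapse = " ")))
  if (length(x$peaks)) {
    w(' <peaks>')
    for (p in x$peaks) {
      w(sprintf(paste0('  <peak start_scan="%d" apex_scan="%d" stop_scan="%d"',
                       ' bg_start="%s" bg_stop="%s"%s%s>'),
                p$start_scan, p$apex_scan, p$stop_scan,
                fmt_dbl(p$background_line[1]), fmt_dbl(p$background_line[2]),
                if (is.null(p$area)) "" else
                  sprintf(' area="%s"', fmt_dbl(p$area)),
                if (is.null(p$integrator_id)) "" else
                  sprintf(' integrator_id="%s"', esc(p$integrator_id))))
      w(sprintf('   <profile>%s</profile>',
                paste(fmt_dbl(p$profile), collapse = " ")))
      w('  </peak>')
    }
    w(' </peaks>')
  }
  w('</chromatogram>')
  invisible(path)
}

read_native_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed native XML in ", path, ": ", conditionMessage(e)))
  if (xml2::xml_name(doc) != "chromatogram")
    stop("malformed native XML: root element is <", xml2::xml_name(doc),
         ">, expected <chromatogram> in ", path)
  entries <- xml2::xml_find_all(doc, "./metadata/entry")
  md <- stats::setNames(xml2::xml_text(entries),
                        xml2::xml_attr(entries, "key"))
  scan_nodes <- xml2::xml_find_all(doc, "./scans/scan")
  if (!length(scan_nodes)) stop("malformed native XML: no scans in ", path)
  scans <- lapply(scan_nodes, function(sn) {
    ions <- xml2::xml_find_all(sn, "./ion")
    ms_scan(as.integer(xml2::xml_attr(sn, "rt_ms")),
         mass_spectrum(as.integer(xml2::xml_attr(ions, "mz")),
                       as.numeric(xml2::xml_attr(ions, "abundance"))))
  })
  x <- chromatogram(scans, metadata = md)
  bl <- xml2::xml_find_first(doc, "./baseline")
  if (!inherits(bl, "xml_missing"))
    x <- set_baseline(x, as.numeric(strsplit(trimws(xml2::xml_text(bl)),
                                             "\\s+")[[1]]))
  pk_nodes <- xml2::xml_find_all(doc, "./peaks/peak")
  x$peaks <- lapply(pk_nodes, function(pn) {
    p <- new_peak(as.integer(xml2::xml_attr(pn, "start_scan")),
                  as.integer(xml2::xml_attr(pn, "apex_scan")),
                  as.integer(xml2::xml_attr(pn, "stop_scan")),
                  as.numeric(strsplit(trimws(xml2::xml_text(
                    xml2::xml_find_first(pn, "./profile"))), "\\s+")[[1]]),
                  background_line = c(as.numeric(xml2::xml_attr(pn, "bg_start")),
                                      as.numeric(xml2::xml_attr(pn, "bg_stop"))))
    area <- xml2::xml_attr(pn, "area")
    if (!is.na(area)) p$area <- as.numeric(area)
    iid <- xml2::xml_attr(pn, "integrator_id")
    if (!is.na(iid)) p$integrator_id <- iid
    p
  })
  x
}
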