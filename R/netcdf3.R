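# Minimal NetCDF-3 "classic" codec (big-endian, 32-bit offsets), sufficient
# for ANDI-MS chromatogram files: fixed-size dimensions, global text
# attributes and non-record variables of type int, float or double. Record
# variables, and the 64-bit-offset variant on write, are out of scope.

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L; NC_INT <- 4L
NC_FLOAT <- 5L; NC_DOUBLE <- 6L

nc_type_size <- function(type)
  c(1L, 1L, 2L, 4L, 4L, 8L)[type]

nc_type_id <- function(type)
  switch(type, int = NC_INT, float = NC_FLOAT, double = NC_DOUBLE,
         char = NC_CHAR, stop("unsupported NetCDF type: ", type))

pad4 <- function(b) {
  r <- length(b) %% 4L
  if (r) c(b, raw(4L - r)) else b
}

nc_raw_int <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "big")

nc_raw_name <- function(s) {
  b <- charToRaw(s)
  c(nc_raw_int(length(b)), pad4(b))
}

nc_raw_values <- function(type, data) {
  switch(type,
         int = nc_raw_int(data),
         float = writeBin(as.double(data), raw(), size = 4L, endian = "big"),
         double = writeBin(as.double(data), raw(), size = 8L, endian = "big"),
         char = charToRaw(as.character(data)),
         stop("unsupported NetCDF type: ", type))
}

# Write a classic NetCDF-3 file.
#   dims: named integer vector (fixed sizes >= 1)
#   atts: named character vector of global text attributes
#   vars: list of list(name, type ("int"|"float"|"double"), dims (names), data)
nc3_write <- function(path, dims, atts, vars) {
  dim_names <- names(dims)
  stopifnot(length(dims) >= 1L, all(dims >= 1L))

  dim_block <- c(nc_raw_int(10L), nc_raw_int(length(dims)),
                 unlist(lapply(seq_along(dims), function(i)
                   c(nc_raw_name(dim_names[i]), nc_raw_int(dims[i])))))

  att_raw <- function(nm, val) {
    b <- charToRaw(val)
    c(nc_raw_name(nm), nc_raw_int(NC_CHAR), nc_raw_int(length(b)), pad4(b))
  }
  gatt_block <- if (length(atts))
    c(nc_raw_int(12L), nc_raw_int(length(atts)),
      unlist(lapply(seq_along(atts), function(i)
        att_raw(names(atts)[i], atts[[i]]))))
  else c(nc_raw_int(0L), nc_raw_int(0L))

  var_meta <- lapply(vars, function(v) {
    dimids <- match(v$dims, dim_names) - 1L
    if (anyNA(dimids)) stop("variable references unknown dimension")
    nelem <- prod(dims[v$dims])
    if (length(v$data) != nelem)
      stop(sprintf("variable %s: data length %d != %d", v$name,
                   length(v$data), nelem))
    payload <- pad4(nc_raw_values(v$type, v$data))
    head_len <- length(nc_raw_name(v$name)) + 4L + 4L * length(dimids) +
      8L + 4L + 4L + 4L   # ndims+dimids, absent vatts, type, vsize, begin
    list(v = v, dimids = dimids, payload = payload, head_len = head_len)
  })

  header_len <- 4L + 4L + length(dim_block) + length(gatt_block) +
    8L + sum(vapply(var_meta, `[[`, integer(1), "head_len"))
  begins <- header_len + c(0L, cumsum(vapply(
    var_meta, function(m) length(m$payload), integer(1))))[seq_along(var_meta)]

  var_block <- c(nc_raw_int(11L), nc_raw_int(length(vars)),
                 unlist(lapply(seq_along(var_meta), function(i) {
    m <- var_meta[[i]]
    c(nc_raw_name(m$v$name), nc_raw_int(length(m$dimids)),
      nc_raw_int(m$dimids), nc_raw_int(0L), nc_raw_int(0L),
      nc_raw_int(nc_type_id(m$v$type)), nc_raw_int(length(m$payload)),
      nc_raw_int(begins[i]))
  })))

  out <- c(charToRaw("CDF"), as.raw(1L), nc_raw_int(0L), dim_block,
           gatt_block, var_block,
           unlist(lapply(var_meta, `[[`, "payload")))
  writeBin(out, path)
  invisible(path)
}

# cursor-based reader over a raw vector
nc3_reader <- function(b) {
  pos <- 0L
  list(
    int = function(n = 1L) {
      v <- readBin(b[(pos + 1L):(pos + 4L * n)], "integer", n = n, size = 4L,
                   endian = "big")
      pos <<- pos + 4L * n
      v
    },
    bytes = function(n) {
      v <- b[(pos + 1L):(pos + n)]
      pos <<- pos + n
      v
    },
    skip = function(n) pos <<- pos + as.integer(n),
    tell = function() pos
  )
}

nc3_read_name <- function(rd) {
  n <- rd$int()
  nm <- rawToChar(rd$bytes(n))
  pad <- (4L - n %% 4L) %% 4L
  if (pad) rd$skip(pad)
  nm
}

nc3_read_values <- function(b, type, nelem) {
  switch(as.character(type),
         "1" = as.integer(readBin(b, "integer", n = nelem, size = 1L)),
         "2" = rawToChar(b[seq_len(nelem)]),
         "3" = readBin(b, "integer", n = nelem, size = 2L, endian = "big"),
         "4" = readBin(b, "integer", n = nelem, size = 4L, endian = "big"),
         "5" = readBin(b, "double", n = nelem, size = 4L, endian = "big"),
         "6" = readBin(b, "double", n = nelem, size = 8L, endian = "big"),
         stop("unsupported NetCDF type id: ", type))
}

nc3_read_atts <- function(rd, b) {
  tag <- rd$int(); n <- rd$int()
  if (tag == 0L || n == 0L) return(list())
  atts <- list()
  for (i in seq_len(n)) {
    nm <- nc3_read_name(rd)
    type <- rd$int(); nelem <- rd$int()
    nbytes <- nelem * nc_type_size(type)
    raw_vals <- rd$bytes(nbytes)
    pad <- (4L - nbytes %% 4L) %% 4L
    if (pad) rd$skip(pad)
    atts[[nm]] <- nc3_read_values(raw_vals, type, nelem)
  }
  atts
}

# Read a classic NetCDF-3 file (fixed-size variables only).
# Returns list(dims, atts, vars); each var: list(type_id, dims, atts, data).
nc3_read <- function(path) {
  b <- readBin(path, raw(), n = file.size(path))
  if (length(b) < 8L || rawToChar(b[1:3]) != "CDF")
    stop("not a NetCDF classic file: ", path)
  version <- as.integer(b[4])
  if (!version %in% c(1L, 2L))
    stop("unsupported NetCDF version byte: ", version)
  off_size <- if (version == 2L) 8L else 4L
  rd <- nc3_reader(b)
  rd$skip(4L)
  numrecs <- rd$int()
  if (numrecs != 0L && numrecs != -1L)
    stop("record variables are not supported")

  tag <- rd$int(); n <- rd$int()
  dims <- integer(); dim_names <- character()
  if (tag == 10L && n > 0L)
    for (i in seq_len(n)) {
      dim_names <- c(dim_names, nc3_read_name(rd))
      dims <- c(dims, rd$int())
    }
  names(dims) <- dim_names

  atts <- nc3_read_atts(rd, b)

  tag <- rd$int(); nvars <- rd$int()
  vars <- list()
  if (tag == 11L && nvars > 0L)
    for (i in seq_len(nvars)) {
      nm <- nc3_read_name(rd)
      ndims <- rd$int()
      dimids <- if (ndims > 0L) rd$int(ndims) else integer()
      vatts <- nc3_read_atts(rd, b)
      type <- rd$int()
      vsize <- rd$int()
      begin <- if (off_size == 8L) {
        hi <- rd$int(); lo <- rd$int()
        hi * 2^32 + (lo %% 2^32 + 2^32) %% 2^32
      } else rd$int()
      nelem <- if (ndims > 0L) prod(dims[dimids + 1L]) else 1L
      nbytes <- nelem * nc_type_size(type)
      data <- nc3_read_values(b[(begin + 1L):(begin + nbytes)], type, nelem)
      vars[[nm]] <- list(type_id = type, dims = dim_names[dimids + 1L],
                         atts = vatts, data = data)
    }
  list(dims = dims, atts = atts, vars = vars)
}
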