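# Minimal ZIP archive writer (store method, no compression).
#
# The E4 dialect bundles plain CSV text in a zip per recording. Reading uses
# R's internal unzip; writing is done here so archives are reproducible
# byte-for-byte (fixed DOS timestamp, fixed member order).

.crc32_table <- local({
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  tab <- integer(256L)
  for (i in 0:255) {
    cr <- i
    for (k in 1:8) {
      cr <- if (bitwAnd(cr, 1L) == 1L) {
        bitwXor(bitwShiftR(cr, 1L), poly)
      } else {
        bitwShiftR(cr, 1L)
      }
    }
    tab[i + 1L] <- cr
  }
  tab
})

# CRC-32 of a raw vector, returned as a non-negative double.
crc32 <- function(bytes) {
  tab <- .crc32_table
  cr <- -1L
  for (b in as.integer(bytes)) {
    cr <- bitwXor(bitwShiftR(cr, 8L), tab[bitwAnd(bitwXor(cr, b), 255L) + 1L])
  }
  cr <- bitwXor(cr, -1L)
  if (cr < 0) cr + 2^32 else as.double(cr)
}

.w16 <- function(con, x) writeBin(as.integer(x %% 65536), con, size = 2L, endian = "little")
.w32 <- function(con, x) {
  x <- as.double(x) %% 2^32
  .w16(con, x %% 65536)
  .w16(con, x %/% 65536)
}

#' Write a zip archive of text members
#'
#' Writes a standards-conformant zip archive using the "store" method with a
#' fixed modification timestamp, so identical content always yields an
#' identical archive. Members are written in the order given.
#'
#' @param path Output file path.
#' @param members Named list; names are member file names, values are
#'   character vectors (joined with `"\n"`) or raw vectors.
#' @return `path`, invisibly.
#' @keywords internal
zip_write <- function(path, members) {
  stopifnot(length(members) > 0, !is.null(names(members)))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot write archive: ", path, call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  offsets <- numeric(length(members))
  crcs <- numeric(length(members))
  sizes <- numeric(length(members))
  datas <- vector("list", length(members))
  pos <- 0
  for (i in seq_along(members)) {
    nm <- names(members)[i]
    dat <- members[[i]]
    if (!is.raw(dat)) dat <- charToRaw(paste0(paste(dat, collapse = "\n"), "\n"))
    datas[[i]] <- dat
    offsets[i] <- pos
    crcs[i] <- crc32(dat)
    sizes[i] <- length(dat)
    name_raw <- charToRaw(nm)
    .w32(con, 0x04034b50)
    .w16(con, 20); .w16(con, 0); .w16(con, 0) # version, flags, method=store
    .w16(con, 0); .w16(con, 0x21)             # DOS time/date: 1980-01-01
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(name_raw)); .w16(con, 0)
    writeBin(name_raw, con)
    writeBin(dat, con)
    pos <- pos + 30 + length(name_raw) + sizes[i]
  }
  cd_start <- pos
  for (i in seq_along(members)) {
    name_raw <- charToRaw(names(members)[i])
    .w32(con, 0x02014b50)
    .w16(con, 20); .w16(con, 20); .w16(con, 0); .w16(con, 0)
    .w16(con, 0); .w16(con, 0x21)
    .w32(con, crcs[i]); .w32(con, sizes[i]); .w32(con, sizes[i])
    .w16(con, length(name_raw)); .w16(con, 0); .w16(con, 0)
    .w16(con, 0); .w16(con, 0)
    .w32(con, 0)
    .w32(con, offsets[i])
    writeBin(name_raw, con)
    pos <- pos + 46 + length(name_raw)
  }
  .w32(con, 0x06054b50)
  .w16(con, 0); .w16(con, 0)
  .w16(con, length(members)); .w16(con, length(members))
  .w32(con, pos - cd_start); .w32(con, cd_start)
  .w16(con, 0)
  invisible(path)
}
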