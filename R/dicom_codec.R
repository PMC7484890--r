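# Minimal DICOM codec: explicit VR little endian, the tag subset needed for
# CT image series, RTSTRUCT and RTPLAN objects. Readers tolerate unknown
# tags (skipped by their encoded length); writers emit only the minimal
# required modules. Not a general-purpose DICOM implementation.

TRANSFER_SYNTAX_EVRLE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.10.1457"  # synthetic-fixture UID root

SOP_CLASS <- c(
  ct       = "1.2.840.10008.5.1.4.1.1.2",
  rtstruct = "1.2.840.10008.5.1.4.1.1.481.3",
  rtplan   = "1.2.840.10008.5.1.4.1.1.481.5"
)

# ---- byte helpers ----------------------------------------------------------

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256,
               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_to_u16 <- function(r) {
  m <- matrix(as.integer(r), nrow = 2)
  m[1, ] + 256L * m[2, ]
}

raw_to_u32 <- function(r) {
  m <- matrix(as.numeric(as.integer(r)), nrow = 4)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

str_payload <- function(x, null_pad = FALSE) {
  r <- charToRaw(paste(x, collapse = "\\"))
  pad_even(r, if (null_pad) as.raw(0) else as.raw(0x20))
}

ds_payload <- function(x) {
  str_payload(vapply(x, function(v) sprintf("%.10g", v), character(1)))
}

is_payload <- function(x) str_payload(sprintf("%d", as.integer(x)))

# long-form VRs (2 reserved bytes + 4-byte length)
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")

# ---- element / dataset writers --------------------------------------------

# value: raw payload for scalar VRs, or a list of item datasets (each a list
# of elements from dcm_el) for SQ.
dcm_el <- function(group, elem, vr, value) {
  list(group = group, elem = elem, vr = vr, value = value)
}

encode_element <- function(el) {
  payload <- if (el$vr == "SQ") {
    items <- lapply(el$value, function(item) {
      body <- encode_dataset(item)
      c(u16le(0xFFFE), u16le(0xE000), u32le(length(body)), body)
    })
    do.call(c, c(items, list(raw(0))))
  } else el$value
  head <- c(u16le(el$group), u16le(el$elem), charToRaw(el$vr))
  if (el$vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), u32le(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("payload too long for short VR")
    c(head, u16le(length(payload)), payload)
  }
}

encode_dataset <- function(elements) {
  do.call(c, c(lapply(elements, encode_element), list(raw(0))))
}

# Write a complete Part-10 file: preamble, DICM, file meta group, dataset.
write_dicom_file <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta <- list(
    dcm_el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_el(0x0002, 0x0002, "UI", str_payload(sop_class_uid, TRUE)),
    dcm_el(0x0002, 0x0003, "UI", str_payload(sop_instance_uid, TRUE)),
    dcm_el(0x0002, 0x0010, "UI", str_payload(TRANSFER_SYNTAX_EVRLE, TRUE)),
    dcm_el(0x0002, 0x0012, "UI", str_payload(paste0(UID_ROOT, ".0.1"), TRUE))
  )
  meta_body <- encode_dataset(meta)
  meta_len <- dcm_el(0x0002, 0x0000, "UL", u32le(length(meta_body)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(encode_element(meta_len), con)
  writeBin(meta_body, con)
  writeBin(encode_dataset(dataset), con)
  invisible(path)
}

# ---- reader ----------------------------------------------------------------

# Parse a dataset from raw bytes starting at pos (1-based); stops after
# nbytes (NA = to end) or at an item-delimitation tag. Returns
# list(elements = named list, pos = next position). Element names are
# "GGGGEEEE" uppercase hex; values decoded by VR; SQ values are lists of
# nested element lists.
parse_dataset <- function(bytes, pos, nbytes = NA) {
  end <- if (is.na(nbytes)) length(bytes) else pos + nbytes - 1
  out <- list()
  while (pos <= end) {
    group <- raw_to_u16(bytes[pos:(pos + 1)]); elem <- raw_to_u16(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4
    if (group == 0xFFFE) {  # item / delimiters (undefined-length framing)
      len <- raw_to_u32(bytes[pos:(pos + 3)]); pos <- pos + 4
      if (elem == 0xE00D || elem == 0xE0DD) break
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(bytes[pos:(pos + 1)]); pos <- pos + 2
    if (vr %in% LONG_VRS) {
      pos <- pos + 2
      len <- raw_to_u32(bytes[pos:(pos + 3)]); pos <- pos + 4
    } else {
      len <- raw_to_u16(bytes[pos:(pos + 1)]); pos <- pos + 2
    }
    name <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {           # undefined length
        repeat {
          ig <- raw_to_u16(bytes[pos:(pos + 1)]); ie <- raw_to_u16(bytes[(pos + 2):(pos + 3)])
          ilen <- raw_to_u32(bytes[(pos + 4):(pos + 7)]); pos <- pos + 8
          if (ig == 0xFFFE && ie == 0xE0DD) break
          if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
          res <- parse_dataset(bytes, pos,
                               if (ilen == 4294967295) NA else ilen)
          items[[length(items) + 1]] <- res$elements
          pos <- res$pos
        }
      } else {
        sq_end <- pos + len
        while (pos < sq_end) {
          ig <- raw_to_u16(bytes[pos:(pos + 1)]); ie <- raw_to_u16(bytes[(pos + 2):(pos + 3)])
          ilen <- raw_to_u32(bytes[(pos + 4):(pos + 7)]); pos <- pos + 8
          if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
          res <- parse_dataset(bytes, pos, if (ilen == 4294967295) NA else ilen)
          items[[length(items) + 1]] <- res$elements
          pos <- res$pos
        }
      }
      out[[name]] <- items
    } else {
      val_raw <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      out[[name]] <- decode_value(vr, val_raw)
    }
  }
  list(elements = out, pos = pos)
}

decode_value <- function(vr, r) {
  if (length(r) == 0) return(switch(vr, DS = , IS = numeric(0),
                                    US = , UL = integer(0), ""))
  switch(vr,
    US = raw_to_u16(r),
    UL = raw_to_u32(r),
    DS = as.numeric(strsplit(trimws(rawToChar(r)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(r)), "\\\\")[[1]]),
    UI = , CS = , SH = , LO = , PN = , DA = , TM = , ST = , LT = , AE = {
      s <- rawToChar(r[r != as.raw(0)])
      v <- strsplit(s, "\\\\")[[1]]
      trimws(if (length(v)) v else "")
    },
    r)  # OB/OW/unknown: keep raw
}

# Read a Part-10 DICOM file into a nested element list.
read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  meta <- parse_meta(bytes)
  tsx <- meta$elements[["00020010"]]
  if (!identical(tsx, TRANSFER_SYNTAX_EVRLE))
    stop("unsupported transfer syntax: ", tsx)
  parse_dataset(bytes, meta$pos)$elements
}

parse_meta <- function(bytes) {
  pos <- 133
  out <- list()
  repeat {
    if (pos + 3 > length(bytes)) break
    group <- raw_to_u16(bytes[pos:(pos + 1)])
    if (group != 0x0002) break
    elem <- raw_to_u16(bytes[(pos + 2):(pos + 3)])
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- raw_to_u32(bytes[(pos + 8):(pos + 11)]); body <- pos + 12
    } else {
      len <- raw_to_u16(bytes[(pos + 6):(pos + 7)]); body <- pos + 8
    }
    val <- if (len > 0) bytes[body:(body + len - 1)] else raw(0)
    out[[sprintf("%04X%04X", group, elem)]] <- decode_value(vr, val)
    pos <- body + len
  }
  list(elements = out, pos = pos)
}

dcm_get <- function(ds, name, required = FALSE, what = name) {
  v <- ds[[name]]
  if (is.null(v) && required) stop("missing DICOM element ", what)
  v
}
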