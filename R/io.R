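#' Write a surface or scalar map as GIFTI
#'
#' Minimal GIFTI (.surf.gii / .shape.gii / .func.gii) writer using ASCII
#' data encoding: surfaces carry a POINTSET (mm) and a TRIANGLE array
#' (0-based on disk), scalar maps one SHAPE array per map.
#'
#' @param x a [TriSurface-class] or [ScalarMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGifti <- function(x, path) {
  da <- function(intent, dtype, dims, values, fmt) {
    dimAttrs <- paste(
      sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims), collapse = " ")
    paste0(
      '<DataArray Intent="', intent, '" DataType="', dtype,
      '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="',
      length(dims), '" ', dimAttrs,
      ' Encoding="ASCII" Endian="LittleEndian" ExternalFileName=""',
      ' ExternalFileOffset="">\n<Data>',
      paste(sprintf(fmt, values), collapse = " "),
      '</Data>\n</DataArray>\n')
  }
  if (is(x, "TriSurface")) {
    v <- t(vertices(x))                      # row-major vertex rows
    f <- t(triangles(x)) - 1L                # 0-based on disk
    body <- paste0(
      da("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
         c(nVertices(x), 3L), as.numeric(v), "%.7g"),
      da("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
         c(nrow(triangles(x)), 3L), as.integer(f), "%d"))
    n <- 2L
  } else if (is(x, "ScalarMap")) {
    body <- da("NIFTI_INTENT_SHAPE", "NIFTI_TYPE_FLOAT32",
               length(mapValues(x)), mapValues(x), "%.7g")
    n <- 1L
  } else stop("writeGifti handles TriSurface and ScalarMap objects")
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="', n, '">\n',
                body, '</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Read a GIFTI surface or scalar file
#'
#' Supports ASCII and (uncompressed) Base64Binary encodings of POINTSET /
#' TRIANGLE / shape-like data arrays.
#'
#' @param path a .gii file.
#' @return a [TriSurface-class] if the file holds pointset + triangles,
#'   otherwise a [ScalarMap-class] (first data array).
#' @export
readGifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  parsed <- lapply(arrays, function(a) {
    enc <- xml2::xml_attr(a, "Encoding")
    dtype <- xml2::xml_attr(a, "DataType")
    dims <- as.integer(vapply(0:(as.integer(
      xml2::xml_attr(a, "Dimensionality")) - 1L), function(d)
        xml2::xml_attr(a, paste0("Dim", d)), character(1)))
    txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    vals <- if (enc == "ASCII") {
      scan(text = txt, quiet = TRUE)
    } else if (enc == "Base64Binary") {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (grepl("INT32", dtype)) readBin(raw, "integer", n = prod(dims),
                                         size = 4, endian = "little")
      else readBin(raw, "numeric", n = prod(dims), size = 4,
                   endian = "little")
    } else stop("unsupported GIFTI encoding: ", enc)
    m <- if (length(dims) == 2L)
      matrix(vals, nrow = dims[1], byrow = TRUE) else vals
    list(intent = xml2::xml_attr(a, "Intent"), data = m)
  })
  intents <- vapply(parsed, `[[`, character(1), "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (!is.na(ip) && !is.na(it)) {
    triSurface(parsed[[ip]]$data, parsed[[it]]$data + 1L)
  } else {
    scalarMap(as.numeric(parsed[[1]]$data))
  }
}

#' Write / read tensor volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti: tensor volumes are stored as 4-D images with
#' six volumes in lower-triangular order (dxx, dxy, dyy, dxz, dyz, dzz),
#' masks as uint8, both carrying the voxel-to-world affine in the sform.
#'
#' @param vol a [TensorVolume-class].
#' @param path output .nii / .nii.gz path.
#' @return `path` invisibly (writers); the reconstructed object (readers).
#' @export
writeTensorNifti <- function(vol, path) {
  img <- RNifti::asNifti(vol@data)
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeTensorNifti
#' @export
readTensorNifti <- function(path) {
  img <- RNifti::readNifti(path)
  tensorVolume(array(as.numeric(img), dim = dim(img)),
               matrix(as.vector(RNifti::xform(img)), 4, 4))
}

#' @rdname writeTensorNifti
#' @param mask a [VoxelMask-class].
#' @export
writeMaskNifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask@mask), dim = dim(mask@mask)),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(mask@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeTensorNifti
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  new("VoxelMask", mask = array(as.numeric(img) != 0, dim = dim(img)),
      affine = matrix(as.vector(RNifti::xform(img)), 4, 4))
}

#' Write streamlines in TrackVis TRK format
#'
#' Binary .trk (version 2, 1000-byte header).  Point coordinates are
#' stored in TrackVis "voxmm" convention (voxel indices scaled by voxel
#' size); the voxel-to-world affine is written to the vox_to_ras header
#' field and used to undo the mapping on read, so a write/read round trip
#' reproduces world-mm polylines to float precision.
#'
#' @param streams a [StreamlineSet-class].
#' @param path output .trk path.
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @param dim integer length-3 voxel counts of the reference grid.
#' @return `path`, invisibly.
#' @export
writeTrk <- function(streams, path, affine, dim) {
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)          # id_string[6]
  writeBin(as.integer(dim), con, size = 2)              # dim[3] int16
  writeBin(as.numeric(vs), con, size = 4)               # voxel_size[3]
  writeBin(rep(0, 3), con, size = 4)                    # origin[3]
  writeBin(0L, con, size = 2)                           # n_scalars
  writeBin(raw(200), con)                               # scalar_name[10][20]
  writeBin(0L, con, size = 2)                           # n_properties
  writeBin(raw(200), con)                               # property_name[10][20]
  writeBin(as.numeric(t(affine)), con, size = 4)        # vox_to_ras, row-major
  writeBin(raw(444), con)                               # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)            # voxel_order[4]
  writeBin(raw(4), con)                                 # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)          # image_orientation
  writeBin(raw(2), con)                                 # pad1
  writeBin(raw(6), con)                                 # invert/swap flags
  writeBin(nStreamlines(streams), con, size = 4)        # n_count
  writeBin(2L, con, size = 4)                           # version
  writeBin(1000L, con, size = 4)                        # hdr_size
  ainv <- solve(affine)
  for (m in streams@points) {
    writeBin(nrow(m), con, size = 4)
    vox <- t(ainv %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox + 0.5, 2, vs, "*")   # trk voxmm: corner-based voxels
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

#' @rdname writeTrk
#' @export
readTrk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (!identical(id, "TRACK")) stop("not a TrackVis TRK file")
  dim <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  invisible(readBin(con, "numeric", 3, size = 4))
  ns <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  np <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  affine <- matrix(readBin(con, "numeric", 16, size = 4), 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444))
  invisible(readBin(con, "raw", 4))       # voxel_order
  invisible(readBin(con, "raw", 4))       # pad2
  invisible(readBin(con, "numeric", 6, size = 4))
  invisible(readBin(con, "raw", 2 + 6))
  nCount <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr <- readBin(con, "integer", 1, size = 4)
  if (hdr != 1000L) stop("unexpected TRK header size: ", hdr)
  pts <- vector("list", nCount)
  for (i in seq_len(nCount)) {
    npts <- readBin(con, "integer", 1, size = 4)
    dat <- matrix(readBin(con, "numeric", npts * (3 + ns), size = 4),
                  ncol = 3 + ns, byrow = TRUE)
    if (np > 0) invisible(readBin(con, "numeric", np, size = 4))
    vox <- sweep(dat[, 1:3, drop = FALSE], 2, vs, "/") - 0.5
    pts[[i]] <- t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
  }
  streamlineSet(pts)
}

#' Write / read a cohort or subject-summary table as TSV
#' @param df data.frame.
#' @param path .tsv path.
#' @return `path` invisibly; `readTsv` returns the data.frame.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) read.delim(path, sep = "\t")
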