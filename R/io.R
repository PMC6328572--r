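#' Read a volumetric image
#'
#' Reads a NIfTI file (\code{.nii}/\code{.nii.gz}) or a directory containing
#' one uncompressed little-endian DICOM series. DICOM stored values are
#' converted to Hounsfield units with the rescale slope/intercept; axes are
#' normalized to the package convention (x fastest, spacing in mm, voxel
#' (0,0,0) center at \code{origin}).
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param format_hint optional, one of "nifti" or "dicom".
#' @return A [coro_volume].
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file or directory", path))
  fmt <- format_hint
  if (is.null(fmt)) fmt <- if (dir.exists(path)) "dicom" else "nifti"
  if (fmt == "dicom") return(read_dicom_series(path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "unreadable NIfTI file '%s': %s", path,
                    conditionMessage(e))))
  dat <- array(as.numeric(img), dim = dim(img))
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) >= 3)) {
    sp <- sqrt(colSums(xf[1:3, 1:3]^2))
    orig <- xf[1:3, 4]
  } else {
    sp <- abs(RNifti::pixdim(img))[1:3]
    orig <- c(0, 0, 0)
  }
  if (any(sp <= 0)) sp <- abs(RNifti::pixdim(img))[1:3]
  coro_volume(dat, spacing = as.numeric(sp), origin = as.numeric(orig))
}

#' Write a volume to NIfTI
#' @param volume a [coro_volume].
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI datatype (default "double" preserves HU exactly).
#' @return invisibly, \code{path}.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  dirp <- dirname(path)
  if (!dir.exists(dirp)) stop(sprintf("unwritable path: '%s'", path))
  img <- RNifti::asNifti(volume$data, datatype = datatype,
                         pixdim = volume$spacing)
  aff <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask to NIfTI (uint8)
#' @param mask a [coro_mask].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_mask <- function(mask, path) {
  vol <- coro_volume(array(as.numeric(mask$data), dim = dim(mask$data)),
                     spacing = mask$spacing, origin = mask$origin)
  write_volume(vol, path, datatype = "uint8")
}

#' Read a binary mask written by [write_mask]
#' @param path NIfTI path.
#' @return A [coro_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  coro_mask(v$data > 0.5, spacing = v$spacing, origin = v$origin)
}

# ---------------------------------------------------------------------------
# Minimal DICOM series reader: uncompressed explicit/implicit VR little
# endian, single series, no nested sequences in the tags we need.

dicom_parse_file <- function(fname) {
  raw <- readBin(fname, "raw", n = file.info(fname)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a part-10 DICOM file", fname))
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               endian = "little", signed = FALSE)
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4,
                               endian = "little")
  pos <- 132L                       # 0-based offset just past "DICM"
  tags <- list()
  explicit <- TRUE
  ts <- "1.2.840.10008.1.2.1"
  in_meta <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 8 <= n) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    if (in_meta && grp != 2L) {        # meta group over: switch syntax
      in_meta <- FALSE
      explicit <- !identical(ts, "1.2.840.10008.1.2")
      if (!(ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
        stop(sprintf("unsupported DICOM transfer syntax %s in '%s'", ts,
                     fname))
    }
    exp_here <- if (in_meta) TRUE else explicit
    if (exp_here) {
      vr <- rawToChar(raw[pos + 5:6])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(pos + 4L); hdr <- 8L
    }
    body <- pos + hdr
    if (len == -1L) {                  # undefined length: scan for delimiter
      p <- body
      while (p + 8 <= n) {
        if (u16(p) == 0xFFFE && u16(p + 2L) == 0xE0DD) break
        p <- p + 2L
      }
      pos <- p + 8L
      next
    }
    key <- sprintf("%04x,%04x", grp, ele)
    val <- raw[(body + 1):(body + len)]
    tags[[key]] <- list(vr = vr, bytes = val)
    pos <- body + len
  }
  tags
}

dicom_str <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t)) return(default)
  trimws(gsub("\\0", "", rawToChar(t$bytes)))
}

dicom_num <- function(tags, key, default = NULL) {
  s <- dicom_str(tags, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t)) return(default)
  readBin(t$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop(sprintf("no files in DICOM directory '%s'", dir))
  slices <- lapply(files, function(f) {
    tags <- dicom_parse_file(f)
    rows <- dicom_us(tags, "0028,0010")
    cols <- dicom_us(tags, "0028,0011")
    if (is.null(rows) || is.null(cols))
      stop(sprintf("'%s' has no image dimensions", f))
    bits <- dicom_us(tags, "0028,0100", 16L)
    if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
    signed <- identical(dicom_us(tags, "0028,0103", 0L), 1L)
    px <- tags[["7fe0,0010"]]
    if (is.null(px)) stop(sprintf("'%s' has no pixel data", f))
    v <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = signed)
    slope <- dicom_num(tags, "0028,1053", 1)[1]
    inter <- dicom_num(tags, "0028,1052", 0)[1]
    list(series = dicom_str(tags, "0020,000e", "unknown"),
         ipp = dicom_num(tags, "0020,0032", c(0, 0, 0)),
         iop = dicom_num(tags, "0020,0037", c(1, 0, 0, 0, 1, 0)),
         pixsp = dicom_num(tags, "0028,0030", c(1, 1)),
         # column index varies fastest in the byte stream -> x
         data = matrix(v * slope + inter, nrow = cols, ncol = rows))
  })
  series <- unique(vapply(slices, `[[`, "", "series"))
  if (length(series) > 1)
    stop(sprintf("directory contains %d DICOM series (%s); supply one series",
                 length(series), paste(series, collapse = ", ")))
  iop <- slices[[1]]$iop
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  pos <- vapply(slices, function(s) sum(s$ipp * normal), 0.0)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  dz <- if (length(pos) > 1) mean(diff(pos)) else 1
  pixsp <- slices[[1]]$pixsp        # [row spacing (y), col spacing (x)]
  dat <- array(0, dim = c(dim(slices[[1]]$data), length(slices)))
  for (k in seq_along(slices)) dat[, , k] <- slices[[k]]$data
  v <- coro_volume(dat, spacing = c(pixsp[2], pixsp[1], abs(dz)),
                   origin = slices[[1]]$ipp)
  attr(v, "orientation") <- iop
  v
}
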