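# File I/O: NIfTI volumes (via RNifti), FSL-style bvec/bval gradient
# sidecars, MRtrix TCK streamlines, and tabular results.

#' Write a volume (3D or 4D) as NIfTI
#' @param data Numeric array.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(2, 2, 2)) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  im <- RNifti::asNifti(data)
  pd <- RNifti::pixdim(im)
  pd[1:3] <- voxel_size
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI volume as a plain array (+ voxel size attribute)
#' @param path NIfTI file.
#' @return Array with attribute `voxel_size`.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  out <- array(as.numeric(im), dim(im))
  attr(out, "voxel_size") <- RNifti::pixdim(im)[1:3]
  out
}

#' Write a gradient scheme as FSL bvec/bval text files
#' @param scheme A [gradient_scheme()].
#' @param prefix Path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return The two paths, invisibly.
#' @export
write_scheme <- function(scheme, prefix) {
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")), bvec)
  invisible(c(bval, bvec))
}

#' Read an FSL bvec/bval pair into a gradient scheme
#' @param prefix Path prefix as in [write_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_scheme <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  rows <- lapply(readLines(paste0(prefix, ".bvec")), function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  gradient_scheme(bvals, t(do.call(rbind, rows)))
}

#' Write streamlines in MRtrix TCK format
#' @param streamlines List of point matrices (world mm) or a bundle.
#' @param path Output `.tck` file.
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  if (inherits(streamlines, "bundle")) streamlines <- streamlines$streamlines
  if (inherits(streamlines, "mean_curve")) streamlines <- list(streamlines$points)
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(streamlines)))
  # offset must count its own digits; try widths until self-consistent
  off <- NA_integer_
  for (guess in 1:9) {
    cand <- sum(nchar(header) + 1L) + nchar("file: . ") + guess +
      nchar("\nEND\n")
    if (nchar(as.character(cand)) == guess) { off <- cand; break }
  }
  header <- c(header, sprintf("file: . %d", off), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con,
            eos = NULL, useBytes = TRUE)
  for (pts in streamlines) {
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK streamline file
#' @param path A `.tck` file.
#' @return List of point matrices.
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  end_pat <- charToRaw("\nEND\n")
  hdr_end <- NA_integer_
  for (i in seq_len(min(2048L, length(raw)) - 4L)) {
    if (all(raw[i:(i + 4L)] == end_pat)) { hdr_end <- i + 4L; break }
  }
  if (is.na(hdr_end)) stop("not a TCK file: header terminator not found")
  lines <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\n")[[1]]
  if (!identical(lines[1], "mrtrix tracks")) stop("not a TCK file")
  fl <- grep("^file: \\. ", lines, value = TRUE)
  off <- as.integer(sub("^file: \\. ", "", fl[1]))
  vals <- readBin(raw[(off + 1L):length(raw)], "numeric", size = 4L,
                  n = (length(raw) - off) / 4L, endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  out <- list()
  cur <- integer(0)
  for (r in seq_len(nrow(m))) {
    if (all(is.infinite(m[r, ]))) break
    if (all(is.nan(m[r, ]))) {
      if (length(cur)) out[[length(out) + 1L]] <- m[cur, , drop = FALSE]
      cur <- integer(0)
    } else cur <- c(cur, r)
  }
  if (length(cur)) out[[length(out) + 1L]] <- m[cur, , drop = FALSE]
  out
}

#' Write per-subject metric profiles as long-format TSV
#' @param profiles Long data frame (`subject`, `bundle`, `metric`, `point`,
#'   `raw`, `smoothed`).
#' @param path Output `.tsv`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
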