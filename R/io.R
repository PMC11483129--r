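## File-format plumbing. Volumes go through RNifti; meshes, streamlines and
## fixel tables use plain-text formats whose numeric payloads are written
## with "%.17g" so a read -> write -> read cycle is exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a volume as NIfTI
#'
#' The affine maps 0-based voxel indices to world mm under the voxel-center
#' convention (`world = origin + index * voxel_size`).
#'
#' @param vol 3D (or 4D) numeric/logical array
#' @param path output `.nii` / `.nii.gz` path
#' @param origin world coordinate of the first voxel center
#' @param voxel_size isotropic voxel edge, mm
#' @param datatype NIfTI datatype (e.g. "int8" for masks, "float32")
#' @return the path, invisibly
#' @export
write_volume_nifti <- function(vol, path, origin = c(0, 0, 0), voxel_size = 1,
                               datatype = "float32") {
  storage.mode(vol) <- if (startsWith(datatype, "int")) "integer" else "double"
  attr(vol, "pixdim") <- rep(voxel_size, 3)
  img <- RNifti::asNifti(vol, datatype = datatype)
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @return list with `data` array, `origin`, `voxel_size`, `affine`
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.vector(img), dim(img)),
       origin = aff[1:3, 4], voxel_size = aff[1, 1], affine = aff)
}

#' Write / read a triangle mesh as whitespace-separated text
#'
#' Header `V F`, then V vertex rows (x y z, mm) and F 1-based face rows.
#' @param surface list with `vertices`, `faces`
#' @param path file path
#' @return the path, invisibly
#' @export
write_surface_txt <- function(surface, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(nrow(surface$vertices), nrow(surface$faces)), con)
  writeLines(paste(fmt_num(surface$vertices[, 1]), fmt_num(surface$vertices[, 2]),
                   fmt_num(surface$vertices[, 3])), con)
  writeLines(paste(surface$faces[, 1], surface$faces[, 2], surface$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_surface_txt
#' @export
read_surface_txt <- function(path) {
  hd <- scan(path, integer(), n = 2, quiet = TRUE)
  nv <- hd[1]; nf <- hd[2]
  dat <- scan(path, numeric(), skip = 1, quiet = TRUE)
  if (length(dat) != 3 * (nv + nf))
    stop(sprintf("malformed surface file %s: expected %d numbers after header, found %d",
                 path, 3 * (nv + nf), length(dat)))
  v <- matrix(dat[seq_len(3 * nv)], nv, 3, byrow = TRUE)
  f <- matrix(as.integer(dat[3 * nv + seq_len(3 * nf)]), nf, 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

#' Write / read streamlines in a text TCK-style format
#'
#' A small header (`ufiber streamlines`, count, step), then one `x y z` row
#' per point with `nan nan nan` rows separating consecutive streamlines.
#' @param set a `streamline_set`
#' @param path file path
#' @return the path, invisibly
#' @export
write_streamlines_tck <- function(set, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ufiber streamlines",
               paste("count:", length(set$n_points)),
               paste("step:", fmt_num(set$step)),
               "END"), con)
  for (i in seq_along(set$n_points)) {
    m <- set$n_points[i]
    P <- set$points[seq_len(m), , i, drop = FALSE][, , 1, drop = TRUE]
    if (m == 1) P <- matrix(P, 1, 3)
    writeLines(paste(fmt_num(P[, 1]), fmt_num(P[, 2]), fmt_num(P[, 3])), con)
    writeLines("nan nan nan", con)
  }
  invisible(path)
}

#' @rdname write_streamlines_tck
#' @return list of point matrices (one per streamline) plus `step`
#' @export
read_streamlines_tck <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "ufiber streamlines") stop("not a ufiber streamline file: ", path)
  endh <- match("END", ln)
  step <- as.numeric(sub("step: *", "", ln[startsWith(ln, "step:")]))
  vals <- ln[(endh + 1):length(ln)]
  M <- matrix(as.numeric(unlist(strsplit(vals, " "))), ncol = 3, byrow = TRUE)
  brk <- which(is.na(M[, 1]))
  starts <- c(1, head(brk, -1) + 1)
  out <- lapply(seq_along(brk), function(i)
    M[seq(starts[i], brk[i] - 1), , drop = FALSE])
  list(streamlines = out, step = step)
}

#' Flat CSV form of a streamline set
#'
#' Columns vertex_id, point_index, x, y, z.
#' @inheritParams write_streamlines_tck
#' @export
write_streamlines_csv <- function(set, path) {
  rows <- lapply(seq_along(set$n_points), function(i) {
    m <- set$n_points[i]
    P <- set$points[seq_len(m), , i, drop = FALSE][, , 1, drop = TRUE]
    if (m == 1) P <- matrix(P, 1, 3)
    data.frame(vertex_id = i, point_index = seq_len(m),
               x = fmt_num(P[, 1]), y = fmt_num(P[, 2]), z = fmt_num(P[, 3]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fixel field as a fixel directory
#'
#' Mirrors the on-disk fixel-directory convention: `index.nii.gz` holds two
#' volumes (per-voxel fixel count and 0-based offset), `directions.txt` the
#' unit axial directions and `afd.txt` the densities, both in fixel order.
#'
#' @param field a [fixel_field()]
#' @param dir directory (created if needed)
#' @return the directory, invisibly
#' @export
write_fixel_dir <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- array(0L, c(field$dim, 2))
  idx[, , , 1] <- field$count
  idx[, , , 2] <- field$offset
  write_volume_nifti(idx, file.path(dir, "index.nii.gz"),
                     origin = field$origin, voxel_size = field$voxel_size,
                     datatype = "int32")
  writeLines(paste(fmt_num(field$dir[, 1]), fmt_num(field$dir[, 2]),
                   fmt_num(field$dir[, 3])), file.path(dir, "directions.txt"))
  writeLines(fmt_num(field$afd), file.path(dir, "afd.txt"))
  invisible(dir)
}

#' @rdname write_fixel_dir
#' @export
read_fixel_dir <- function(dir) {
  idx <- read_volume_nifti(file.path(dir, "index.nii.gz"))
  dm <- dim(idx$data)[1:3]
  count <- array(as.integer(idx$data[, , , 1]), dm)
  dtxt <- readLines(file.path(dir, "directions.txt"))
  dirs <- if (length(dtxt)) {
    matrix(as.numeric(unlist(strsplit(dtxt, " "))), ncol = 3, byrow = TRUE)
  } else matrix(numeric(0), 0, 3)
  afd <- as.numeric(readLines(file.path(dir, "afd.txt")))
  vox <- rep(which(count > 0), count[count > 0])
  ## fixels are stored in voxel order: offsets are implied by the counts
  fixel_field(vox, dirs, afd, dim = dm, origin = idx$origin,
              voxel_size = idx$voxel_size)
}

#' Write / read tapping sessions as an event CSV
#'
#' Columns trial_id, modality, target_ms, epoch, event_type, onset_ms;
#' multiple sessions concatenate with a subject_id column.
#'
#' @param sessions one `tapping_session` or a list of them
#' @param path CSV path
#' @return the path, invisibly
#' @export
write_events_csv <- function(sessions, path) {
  if (inherits(sessions, "tapping_session")) sessions <- list(sessions)
  dat <- do.call(rbind, lapply(sessions, function(s) {
    cbind(subject_id = s$subject_id, s$events)
  }))
  dat$onset_ms <- fmt_num(dat$onset_ms)
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(dat, dat$subject_id), function(d) {
    structure(list(events = d[, setdiff(names(d), "subject_id")],
                   subject_id = d$subject_id[1],
                   modality = d$modality[1],
                   target_intervals = sort(unique(d$target_ms))),
              class = "tapping_session")
  })
}
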