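# File formats: raw k-space datasets in HDF5 (documented custom layout),
# parameter maps in NIfTI-1, configuration in YAML, statistics in JSON.
#
# HDF5 layout (version 1.0):
#   /lines_re, /lines_im   [n_readouts x matrix] real matrices
#   /meta/<field>          per-readout metadata vectors
#   /ground_truth/...      reference phantom maps and motion traces
#   /seq/<field>, /config_json, attributes: layout_version, seed,
#   noise_sigma

KSPACE_LAYOUT_VERSION <- "1.0"

#' Write a k-space dataset to HDF5
#'
#' @param ds a [acquire] result
#' @param path output file (overwritten)
#' @return `path`, invisibly
#' @export
write_kspace_h5 <- function(ds, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(ds$lines), path, "lines_re")
  rhdf5::h5write(Im(ds$lines), path, "lines_im")
  rhdf5::h5createGroup(path, "meta")
  meta <- ds$meta
  meta$scan <- as.character(meta$scan)
  for (nm in names(meta)) {
    val <- meta[[nm]]
    if (is.logical(val)) val <- as.integer(val)
    rhdf5::h5write(val, path, paste0("meta/", nm))
  }
  rhdf5::h5createGroup(path, "seq")
  for (nm in names(ds$seq)) {
    rhdf5::h5write(ds$seq[[nm]], path, paste0("seq/", nm))
  }
  rhdf5::h5createGroup(path, "ground_truth")
  gt <- ds$ground_truth
  rhdf5::h5write(gt$phantom$labels, path, "ground_truth/labels")
  rhdf5::h5write(gt$phantom$t1_pre, path, "ground_truth/t1_pre")
  rhdf5::h5write(gt$phantom$t1_post, path, "ground_truth/t1_post")
  rhdf5::h5write(gt$phantom$m0, path, "ground_truth/m0")
  rhdf5::h5write(gt$cardiac_phase, path, "ground_truth/cardiac_phase")
  rhdf5::h5write(gt$resp_s, path, "ground_truth/resp_s")
  rhdf5::h5write(storage_masks(gt$phantom$masks), path,
                 "ground_truth/septal_mask")
  cfg_json <- jsonlite::toJSON(strip_config(ds$config), auto_unbox = TRUE,
                               digits = NA)
  rhdf5::h5write(as.character(cfg_json), path, "config_json")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(KSPACE_LAYOUT_VERSION, fid, "layout_version")
  rhdf5::h5writeAttribute(ds$seed, fid, "seed")
  rhdf5::h5writeAttribute(ds$noise_sigma, fid, "noise_sigma")
  rhdf5::h5writeAttribute(ds$gaussian_sigma_ky, fid, "gaussian_sigma_ky")
  rhdf5::h5writeAttribute(config_hash(ds$config), fid, "config_hash")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @keywords internal
#' @noRd
storage_masks <- function(masks) masks$septal + 0L

#' @keywords internal
#' @noRd
strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$tissues <- lapply(cfg$tissues, unclass)
  cfg
}

#' Hash of a configuration object (provenance tracking)
#' @param config any serializable object
#' @export
config_hash <- function(config) digest::digest(strip_config(config))

#' Read a k-space dataset from HDF5
#'
#' @param path file written by [write_kspace_h5]
#' @return a `kspace_dataset`
#' @export
read_kspace_h5 <- function(path) {
  if (!file.exists(path)) stop("read_kspace_h5: no such file: ", path)
  contents <- rhdf5::h5ls(path)
  need <- c("lines_re", "lines_im", "meta", "seq")
  have <- contents$name[contents$group == "/"]
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("read_kspace_h5: missing dataset(s): ",
         paste0("/", missing, collapse = ", "))
  }
  attrs <- rhdf5::h5readAttributes(path, "/")
  ver <- attrs$layout_version
  if (is.null(ver)) {
    stop("read_kspace_h5: missing layout_version attribute")
  }
  if (!identical(as.character(ver), KSPACE_LAYOUT_VERSION)) {
    stop(sprintf("read_kspace_h5: layout version %s unsupported (expect %s)",
                 ver, KSPACE_LAYOUT_VERSION))
  }
  lines <- rhdf5::h5read(path, "lines_re") +
    1i * rhdf5::h5read(path, "lines_im")
  meta_names <- contents$name[contents$group == "/meta"]
  meta <- as.data.frame(lapply(stats::setNames(meta_names, meta_names),
                               function(nm) {
                                 as.vector(rhdf5::h5read(path,
                                                         paste0("meta/", nm)))
                               }))
  meta$is_training <- meta$is_training == 1
  sq_names <- contents$name[contents$group == "/seq"]
  sq <- lapply(stats::setNames(sq_names, sq_names), function(nm) {
    as.vector(rhdf5::h5read(path, paste0("seq/", nm)))
  })
  sq <- do.call(seq_params, sq[c("tr", "te", "flip_nominal",
                                 "recovery_period", "n_ir_pulses",
                                 "readouts_per_period", "matrix", "fov",
                                 "slice_thickness")])
  config <- jsonlite::fromJSON(as.character(rhdf5::h5read(path,
                                                          "config_json")))
  gt <- list(labels = rhdf5::h5read(path, "ground_truth/labels"),
             t1_pre = rhdf5::h5read(path, "ground_truth/t1_pre"),
             t1_post = rhdf5::h5read(path, "ground_truth/t1_post"),
             m0 = rhdf5::h5read(path, "ground_truth/m0"),
             cardiac_phase = as.vector(rhdf5::h5read(path,
                                                     "ground_truth/cardiac_phase")),
             resp_s = as.vector(rhdf5::h5read(path, "ground_truth/resp_s")),
             septal_mask = rhdf5::h5read(path,
                                         "ground_truth/septal_mask") == 1)
  rhdf5::h5closeAll()
  meta <- meta[order(meta$readout_id), ]
  rownames(meta) <- NULL
  structure(list(lines = lines, meta = meta, ground_truth = gt, seq = sq,
                 config = config,
                 noise_sigma = as.vector(attrs$noise_sigma),
                 gaussian_sigma_ky = as.vector(attrs$gaussian_sigma_ky),
                 seed = as.vector(attrs$seed)),
            class = "kspace_dataset")
}

# ---- minimal NIfTI-1 -------------------------------------------------------
# Single-file uncompressed .nii, float32, with correct pixdim.  No NIfTI
# package ships with the target environment, so the 348-byte header is
# written directly.

#' Write a 2D/3D map as NIfTI-1
#'
#' @param img numeric matrix or 3D array; NA stored as NaN
#' @param path output `.nii` path
#' @param voxel voxel dimensions (mm), length 3
#' @return `path`, invisibly
#' @export
write_map_nifti <- function(img, path, voxel = c(0.3125, 0.3125, 1.5)) {
  if (any(!is.finite(img))) {
    warning("write_map_nifti: non-finite values stored as NaN")
  }
  d <- dim(img)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused
  wi(c(3, d, 1, 1, 1, 1), 2)                   # dim[8]
  writeBin(raw(12), con)                       # intent_p1..p3
  wi(0, 2)                                     # intent_code
  wi(16, 2)                                    # datatype = float32
  wi(32, 2)                                    # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, voxel, 1, 1, 1, 1))                  # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0, 2)                                     # slice_end
  writeBin(raw(1), con)                        # slice_code
  writeBin(as.raw(2), con)                     # xyzt_units: mm
  wf(c(0, 0, 0))                               # cal_max/min, slice_duration
  wf(0)                                        # toffset
  wi(c(0, 0), 4)                               # glmax/glmin
  writeBin(raw(80 + 24), con)                  # descrip + aux_file
  wi(0, 2)                                     # qform_code
  wi(1, 2)                                     # sform_code
  wf(c(0, 0, 0, 0, 0, 0))                      # quaternions
  wf(c(voxel[1], 0, 0, 0))                     # srow_x
  wf(c(0, voxel[2], 0, 0))                     # srow_y
  wf(c(0, 0, voxel[3], 0))                     # srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  vals <- as.numeric(img)
  vals[!is.finite(vals)] <- NaN
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_map_nifti]
#'
#' @param path `.nii` path
#' @return list with `img` (array) and `pixdim` (length 3)
#' @export
read_map_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, 4, endian = "little")
  if (hdr_size != 348) stop("read_map_nifti: not a NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dims <- readBin(con, "integer", 8, 2, endian = "little")
  invisible(readBin(con, "raw", 12))
  invisible(readBin(con, "integer", 1, 2, endian = "little"))  # intent_code
  datatype <- readBin(con, "integer", 1, 2, endian = "little")
  if (datatype != 16) stop("read_map_nifti: only float32 supported")
  invisible(readBin(con, "integer", 1, 2, endian = "little"))
  invisible(readBin(con, "integer", 1, 2, endian = "little"))
  pixdim <- readBin(con, "numeric", 8, 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, 4, endian = "little")
  seek(con, vox_offset)
  n <- prod(dims[2:(dims[1] + 1)])
  vals <- readBin(con, "numeric", n, 4, endian = "little")
  img <- array(vals, dims[2:(dims[1] + 1)])
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  list(img = img, pixdim = pixdim[2:4])
}

#' Write parameter and ECV maps as NIfTI-1 files
#'
#' @param maps a [fit_t1_maps] result
#' @param ecv optional [compute_ecv] result
#' @param dir output directory (created)
#' @param seq a [seq_params] providing the voxel size
#' @return character vector of written paths
#' @export
write_maps_nifti <- function(maps, ecv = NULL, dir, seq) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  voxel <- c(in_plane_voxel_size(seq), in_plane_voxel_size(seq),
             seq$slice_thickness)
  paths <- c()
  for (nm in c("t1_pre", "t1_post", "m0", "alpha", "b")) {
    p <- file.path(dir, paste0(nm, ".nii"))
    suppressWarnings(write_map_nifti(maps[[nm]], p, voxel))
    paths <- c(paths, p)
  }
  if (!is.null(ecv)) {
    p <- file.path(dir, "ecv.nii")
    suppressWarnings(write_map_nifti(ecv$ecv_map, p, voxel))
    paths <- c(paths, p)
    p <- file.path(dir, "ecv_qc.nii")
    suppressWarnings(write_map_nifti(ecv$qc_out_of_range + 0, p, voxel))
    paths <- c(paths, p)
  }
  paths
}
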