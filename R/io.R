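#' Write / read a dual-echo study as NIfTI volumes with a JSON sidecar
#'
#' A study is stored as two 4D NIfTI volumes (first and second echo), 3D
#' NIfTI volumes for the mask and the pre/post longitudinal factors, and a
#' JSON sidecar holding the acquisition parameters. `read_dge_study()`
#' validates grid agreement between the echoes and the presence of the
#' required sidecar fields, and reconstructs a `dge_study` object (without
#' simulation truth).
#'
#' @param study A `dge_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_dge_study()` returns the sidecar path invisibly;
#'   `read_dge_study()` a `dge_study`.
#' @export
write_dge_study <- function(study, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- function(x) file.path(dir, paste0(prefix, "_", x))
  RNifti::writeNifti(RNifti::asNifti(study$f), pt("echo1.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$s), pt("echo2.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$mask * 1), pt("mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$e_pre), pt("epre.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$e_post), pt("epost.nii.gz"))
  acq <- study$acq
  sidecar <- list(tr = acq$tr, te1 = acq$te1, te2 = acq$te2,
                  theta_nominal = acq$theta_nominal,
                  frame_interval = acq$frame_interval,
                  n_frames = acq$n_frames,
                  injection_frame = acq$injection_frame,
                  package_version = as.character(utils::packageVersion("dcenms")))
  jsonlite::write_json(sidecar, pt("sidecar.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(pt("sidecar.json"))
}

#' @rdname write_dge_study
#' @param path_echo1,path_echo2 Paths to the 4D echo volumes.
#' @param sidecar Path to the JSON sidecar.
#' @param path_mask,path_epre,path_epost Optional paths for the mask and the
#'   longitudinal factor maps; defaults substitute `echo1` in
#'   `path_echo1`'s name.
#' @export
read_dge_study <- function(path_echo1, path_echo2, sidecar,
                           path_mask = NULL, path_epre = NULL,
                           path_epost = NULL) {
  guess <- function(tag) sub("echo1", tag, path_echo1, fixed = TRUE)
  if (is.null(path_mask)) path_mask <- guess("mask")
  if (is.null(path_epre)) path_epre <- guess("epre")
  if (is.null(path_epost)) path_epost <- guess("epost")
  f <- array(as.numeric(RNifti::readNifti(path_echo1)),
             dim = dim(RNifti::readNifti(path_echo1)))
  s <- array(as.numeric(RNifti::readNifti(path_echo2)),
             dim = dim(RNifti::readNifti(path_echo2)))
  if (!identical(dim(f), dim(s)))
    stop(sprintf("echo grids differ: %s vs %s",
                 paste(dim(f), collapse = "x"),
                 paste(dim(s), collapse = "x")))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  req <- c("tr", "te1", "te2", "frame_interval", "n_frames",
           "injection_frame")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("sidecar missing required key(s): ", paste(miss, collapse = ", "))
  if (meta$n_frames != dim(f)[4])
    stop(sprintf("sidecar n_frames (%d) does not match volume (%d)",
                 meta$n_frames, dim(f)[4]))
  acq <- acq_params(tr = meta$tr, te1 = meta$te1, te2 = meta$te2,
                    theta_nominal = meta$theta_nominal %||% (18 * pi / 180),
                    frame_interval = meta$frame_interval,
                    n_frames = meta$n_frames,
                    injection_frame = meta$injection_frame)
  rd3 <- function(p) array(as.numeric(RNifti::readNifti(p)), dim = dim(f)[1:3])
  structure(list(f = f, s = s, mask = rd3(path_mask) > 0, acq = acq,
                 e_pre = rd3(path_epre), e_post = rd3(path_epost),
                 truth = NULL, spec = NULL),
            class = "dge_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write parameter maps as NIfTI
#'
#' @param fit An `nms_fit`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_nms_maps <- function(fit, dir, prefix = "nms") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (map in c("label", "vp", "ktrans", "ve")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, map))
    RNifti::writeNifti(RNifti::asNifti(fit[[map]] * 1), p)
    paths <- c(paths, p)
  }
  tab <- file.path(dir, sprintf("%s_results.csv", prefix))
  utils::write.csv(fit$results, tab, row.names = FALSE)
  invisible(c(paths, tab))
}

#' Serialize / restore an adaptive bundle as versioned JSON
#'
#' Plain-text persistence of a trained bundle: network weights, thresholds,
#' target scalings, hidden sizes and the training seed, under a format
#' version tag.
#'
#' @param bundle An `am_bundle`.
#' @param path Output JSON path.
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()` an
#'   `am_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  ser_net <- function(net) {
    if (is.null(net)) return(NULL)
    list(w1 = as.numeric(net$w1), b1 = net$b1, w2 = net$w2, b2 = net$b2,
         hidden = net$hidden, d = net$d, y_center = net$y_center,
         y_scale = net$y_scale, classes = net$classes, seed = net$seed)
  }
  obj <- list(format = "dcenms-bundle-v1",
              nms_net = ser_net(bundle$nms_net),
              thresholds = bundle$thresholds,
              pk_nets = lapply(bundle$pk_nets, ser_net),
              mask_source = bundle$mask_source, seed = bundle$seed,
              hidden = as.list(bundle$hidden))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dcenms-bundle-v1"))
    stop("unrecognized bundle format: ", obj$format)
  des_net <- function(sn) {
    if (is.null(sn) || !length(sn)) return(NULL)
    structure(list(w1 = matrix(sn$w1, sn$hidden, sn$d), b1 = sn$b1,
                   w2 = sn$w2, b2 = sn$b2, y_center = sn$y_center,
                   y_scale = sn$y_scale, hidden = sn$hidden, d = sn$d,
                   classes = isTRUE(sn$classes), seed = sn$seed,
                   trace = tibble::tibble()),
              class = "dce_mlp")
  }
  structure(list(nms_net = des_net(obj$nms_net),
                 thresholds = tibble::as_tibble(obj$thresholds),
                 pk_nets = lapply(obj$pk_nets, des_net),
                 missing_nets = names(obj$pk_nets)[vapply(
                   obj$pk_nets, function(n) is.null(n) || !length(n),
                   logical(1))],
                 mask_source = obj$mask_source, seed = obj$seed,
                 hidden = unlist(obj$hidden)),
            class = "am_bundle")
}
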