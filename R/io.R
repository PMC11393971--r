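#' Read a 4D dynamic contrast-enhanced volume from NIfTI
#'
#' Loads an `(x, y, z, t)` dynamic series. The frame interval is taken from
#' the NIfTI header timing (4th pixdim) unless overridden by `dt`, which
#' always wins.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param dt Optional frame-interval override, seconds.
#' @return An object of class `dynamic_volume`: `data` (4D array), `grid`
#'   ([time_grid()]) and the source image (for the affine / header).
#' @export
read_dynamic_volume <- function(path, dt = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop(sprintf("expected 4D (x, y, z, t) data, got %dD", length(d)), call. = FALSE)
  }
  if (is.null(dt)) {
    pd <- RNifti::pixdim(img)
    dt <- if (length(pd) >= 4L) pd[4] else 0
    if (!is.finite(dt) || dt <= 0) {
      stop("no usable frame timing in the header; pass `dt` explicitly", call. = FALSE)
    }
  }
  structure(list(data = array(as.numeric(img), dim = d),
                 grid = time_grid(d[4], dt),
                 reference = img),
            class = "dynamic_volume")
}

#' @export
print.dynamic_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_volume> %d x %d x %d spatial, %d frames, dt = %g s\n",
              d[1], d[2], d[3], d[4], x$grid$dt))
  invisible(x)
}

#' Default analysis mask for a dynamic volume
#'
#' Voxels whose peak concentration over time exceeds `threshold` (default
#' 0.01 mmol/L); everything else is background.
#'
#' @param vol A `dynamic_volume`.
#' @param threshold Peak-concentration threshold.
#' @return A logical 3D array.
#' @export
default_mask <- function(vol, threshold = 0.01) {
  if (!inherits(vol, "dynamic_volume")) stop("`vol` must be a `dynamic_volume`", call. = FALSE)
  apply(vol$data, 1:3, max) > threshold
}

#' Fit a pharmacokinetic model to every masked voxel
#'
#' For each voxel inside the mask: the precontrast frames are zeroed
#' ([zero_precontrast()]), the network produces a coarse estimate (batched
#' over all masked voxels), and a short refinement polishes it
#' ([two_stage_fit()]). Unmasked voxels are written as zero.
#'
#' @param vol A `dynamic_volume`.
#' @param model A trained `fmrdi_nn`.
#' @param cfg A [fit_config()].
#' @param mask Logical 3D array; `NULL` uses [default_mask()].
#' @param zero_frames Apply the precontrast zeroing rule before fitting
#'   (default `TRUE`, the clinical protocol). Zeroing trades a small bias on
#'   the early enhancement frames for robustness to baseline noise; disable
#'   it for noise-free synthetic volumes.
#' @param search_frames Precontrast search window (default 15 frames).
#' @param supersample Forward-model quadrature refinement.
#' @return An object of class `parameter_maps`: 3D maps `ktrans`, `kep`,
#'   `t0`, `lambda_weight`, `residual`, `converged`, plus the reference image
#'   and the provenance list.
#' @export
fit_volume <- function(vol, model, cfg = fit_config(), mask = NULL,
                       zero_frames = TRUE, search_frames = 15L,
                       supersample = 10L) {
  if (!inherits(vol, "dynamic_volume")) stop("`vol` must be a `dynamic_volume`", call. = FALSE)
  if (is.null(mask)) mask <- default_mask(vol)
  sdim <- dim(vol$data)[1:3]
  if (!identical(dim(mask), sdim)) stop("mask shape must match the spatial dims", call. = FALSE)
  idx <- which(mask)
  maps <- list(ktrans = array(0, sdim), kep = array(0, sdim), t0 = array(0, sdim),
               lambda_weight = array(0, sdim), residual = array(0, sdim),
               converged = array(0, sdim))
  n_failed <- 0L
  if (length(idx) > 0L) {
    flat <- matrix(vol$data, prod(sdim), dim(vol$data)[4])
    curves <- flat[idx, , drop = FALSE]
    if (zero_frames) {
      for (i in seq_len(nrow(curves))) {
        curves[i, ] <- zero_precontrast(curves[i, ], search_frames)$curve
      }
    }
    for (i in seq_len(nrow(curves))) {
      v <- idx[i]
      res <- tryCatch(
        two_stage_fit(model, curves[i, ], vol$grid, cfg, supersample = supersample),
        error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      maps$ktrans[v] <- res$params[["ktrans"]]
      maps$kep[v] <- res$params[["kep"]]
      maps$t0[v] <- res$params[["t0"]]
      maps$lambda_weight[v] <- res$params[["lambda_weight"]]
      maps$residual[v] <- res$residual
      maps$converged[v] <- as.numeric(res$converged)
    }
  }
  structure(list(maps = maps, reference = vol$reference,
                 provenance = list(n_voxels = length(idx), n_failed = n_failed,
                                   seed = cfg$seed, method = cfg$method,
                                   search_frames = as.integer(search_frames))),
            class = "parameter_maps")
}

# Small stable hash (FNV-1a over the serialized object) for config provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write parameter maps as NIfTI files with a provenance sidecar
#'
#' One NIfTI per map (`ktrans`, `kep`, `t0`, `lambda_weight`, `residual`,
#' `converged`), the spatial reference copied from the input volume, plus a
#' `provenance.json` sidecar carrying the seed, fitting method and a config
#' hash.
#'
#' @param pmaps A `parameter_maps` object from [fit_volume()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_parameter_maps <- function(pmaps, out_dir) {
  if (!inherits(pmaps, "parameter_maps")) stop("`pmaps` must be `parameter_maps`", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  template <- pmaps$reference[, , , 1]
  files <- character(0)
  for (nm in names(pmaps$maps)) {
    path <- file.path(out_dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(pmaps$maps[[nm]], reference = template)
    RNifti::writeNifti(img, path)
    files <- c(files, path)
  }
  sidecar <- file.path(out_dir, "provenance.json")
  prov <- pmaps$provenance
  prov$config_hash <- config_hash(pmaps$provenance)
  jsonlite::write_json(prov, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' Read parameter maps written by [write_parameter_maps()]
#'
#' @param out_dir Directory containing the map files.
#' @return A named list of 3D arrays.
#' @export
read_parameter_maps <- function(out_dir) {
  nms <- c("ktrans", "kep", "t0", "lambda_weight", "residual", "converged")
  out <- list()
  for (nm in nms) {
    path <- file.path(out_dir, paste0(nm, ".nii.gz"))
    if (file.exists(path)) {
      img <- RNifti::readNifti(path)
      d <- dim(img)
      if (length(d) == 2L) d <- c(d, 1L)  # NIfTI drops trailing singletons
      out[[nm]] <- array(as.numeric(img), dim = d)
    }
  }
  out
}

#' Curve and batch CSV round-trips
#'
#' `write_curve_csv()` stores one curve as `time_s, value` rows;
#' `write_batch_csv()` stores a synthetic batch with parameter columns
#' followed by one column per time point (`c1 ... cL`). The matching readers
#' rebuild the objects.
#'
#' @param values Numeric curve.
#' @param grid A [time_grid()].
#' @param path CSV path.
#' @return Readers return the parsed object; writers return the path,
#'   invisibly.
#' @export
write_curve_csv <- function(values, grid, path) {
  assert_grid(grid)
  if (length(values) != grid$n_points) stop("curve length must match the grid", call. = FALSE)
  utils::write.csv(data.frame(time_s = grid$times, value = values), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("expected columns `time_s` and `value`", call. = FALSE)
  }
  df
}

#' @rdname write_curve_csv
#' @param batch A list with `curves` and `params` as from
#'   [synthesize_batch()].
#' @export
write_batch_csv <- function(batch, path) {
  cn <- paste0("c", seq_len(ncol(batch$curves)))
  df <- cbind(batch$params, as.data.frame(batch$curves) |> stats::setNames(cn))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path)
  ccols <- grep("^c[0-9]+$", names(df))
  list(curves = as.matrix(df[, ccols, drop = FALSE]) |> unname(),
       params = df[, setdiff(seq_along(df), ccols), drop = FALSE])
}
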