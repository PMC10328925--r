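#' Construct a mask stack
#'
#' A mask stack holds one binary mask per frame together with the temporal
#' and spatial calibration. Pixel coordinates follow the screen convention:
#' x is the column index increasing rightward, y the row index increasing
#' downward, with pixel centres at integer coordinates (1-based). Physical
#' coordinates are pixel coordinates times the pixel size.
#'
#' @param masks List of matrices; any nonzero pixel is foreground.
#' @param config A [track_config()] with pixel size and frame interval.
#' @return An object of class `mask_stack`: a list with `masks` (list of 0/1
#'   integer matrices), `frame_index`, `time_s` (equal to
#'   `(frame_index - 1) * frame_interval_s`) and `config`.
#' @export
mask_stack <- function(masks, config = track_config()) {
  stopifnot(is.list(masks), length(masks) >= 1,
            inherits(config, "track_config"))
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stop("frame ", bad, " has dimensions ", dims[1, bad], "x", dims[2, bad],
         " but frame 1 has ", dims[1, 1], "x", dims[2, 1], call. = FALSE)
  }
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "integer"
    m[m != 0L] <- 1L
    m
  })
  empty <- which(vapply(masks, sum, integer(1)) == 0L)
  if (length(empty)) {
    stop("frame ", empty[1], " contains no foreground pixels", call. = FALSE)
  }
  n <- length(masks)
  structure(
    list(masks = masks,
         frame_index = seq_len(n),
         time_s = (seq_len(n) - 1) * config$frame_interval_s,
         config = config),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat("<mask_stack> ", length(x$masks), " frames of ", d[1], "x", d[2],
      " px, dt = ", x$config$frame_interval_s, " s, pixel size = ",
      x$config$pixel_size_um, " um\n", sep = "")
  invisible(x)
}

#' @export
length.mask_stack <- function(x) length(x$masks)

#' Read a time-lapse mask sequence
#'
#' Reads either a multi-page TIFF or a directory of single-page PNG/TIFF
#' images taken in lexicographic file-name order. Any nonzero pixel is
#' treated as foreground regardless of bit depth. Frame `n` is assigned
#' `time_s = (n - 1) * frame_interval_s`.
#'
#' @param path Path to a multi-page TIFF file or a directory of images.
#' @param config A [track_config()].
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(path, config = track_config()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      stop("no PNG/TIFF images found in directory '", path, "'", call. = FALSE)
    }
    masks <- lapply(files, read_single_image)
  } else {
    if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (!length(pages)) stop("TIFF '", path, "' contains no pages", call. = FALSE)
    masks <- lapply(pages, drop_channels)
  }
  mask_stack(masks, config)
}

read_single_image <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file, as.is = TRUE)
  }
  drop_channels(img)
}

# collapse a possible channel dimension: foreground where any channel nonzero
drop_channels <- function(img) {
  if (length(dim(img)) == 3) img <- apply(img != 0, c(1, 2), any)
  (img != 0) * 1L
}

#' Write a mask stack as a multi-page TIFF
#'
#' Foreground pixels are written as 255 in an 8-bit file; reading the file
#' back with [read_mask_stack()] reproduces the binary masks exactly.
#'
#' @param stack A [mask_stack()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mask_stack"))
  pages <- lapply(stack$masks, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Label 8-connected foreground components
#'
#' @param mask Matrix; nonzero pixels are foreground.
#' @return Integer matrix of the same shape: 0 for background, 1..k for the
#'   k components, numbered in column-major discovery order.
#' @keywords internal
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  npr <- nr + 2L
  pad <- matrix(0L, npr, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- (mask != 0)
  lab <- matrix(0L, npr, nc + 2L)
  offs <- c(-1L, 1L, -npr, npr, -npr - 1L, -npr + 1L, npr - 1L, npr + 1L)
  cur <- 0L
  for (s in which(pad != 0L)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      nb <- unique(rep(frontier, each = 8L) + offs)
      nb <- nb[pad[nb] != 0L & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab[2:(nr + 1L), 2:(nc + 1L)]
}

#' Reduce a mask to a single connected component
#'
#' The analysis assumes a single cell per frame; this enforces that contract
#' by keeping exactly one 8-connected foreground component. Under policy
#' `"largest"` the component with the most pixels is kept; ties are broken in
#' favour of the component whose first pixel in row-major (row, column) order
#' comes first. Under policy `"nearest"` the component whose centroid is
#' closest to `prev_centroid` (pixel coordinates `c(x, y)`, e.g. from the
#' previous frame) is kept.
#'
#' @param mask Matrix; nonzero pixels are foreground.
#' @param policy `"largest"` or `"nearest"`.
#' @param prev_centroid Numeric `c(x, y)` in pixel coordinates; required for
#'   policy `"nearest"`.
#' @return A 0/1 integer matrix with exactly one foreground component.
#' @export
select_component <- function(mask, policy = c("largest", "nearest"),
                             prev_centroid = NULL) {
  policy <- match.arg(policy)
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) stop("mask contains no foreground component", call. = FALSE)
  if (k == 1L) return((lab == 1L) * 1L)
  if (policy == "largest") {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # row-major rank of each component's first pixel
      rank_rm <- vapply(best, function(i) {
        idx <- which(lab == i, arr.ind = TRUE)
        min((idx[, 1] - 1) * ncol(mask) + idx[, 2])
      }, numeric(1))
      best <- best[which.min(rank_rm)]
    }
  } else {
    if (is.null(prev_centroid) || length(prev_centroid) != 2) {
      stop("policy 'nearest' requires prev_centroid = c(x, y)", call. = FALSE)
    }
    d2 <- vapply(seq_len(k), function(i) {
      idx <- which(lab == i, arr.ind = TRUE)
      cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
      (cx - prev_centroid[1])^2 + (cy - prev_centroid[2])^2
    }, numeric(1))
    best <- which.min(d2)
  }
  (lab == best) * 1L
}

#' Apply single-component selection to every frame of a stack
#'
#' With policy `"nearest"`, the first frame uses `"largest"` and each later
#' frame the centroid of the component kept in the previous frame.
#'
#' @inheritParams select_component
#' @param stack A [mask_stack()].
#' @return A [mask_stack()] in which every frame has one component.
#' @export
select_components <- function(stack, policy = c("largest", "nearest")) {
  policy <- match.arg(policy)
  stopifnot(inherits(stack, "mask_stack"))
  prev <- NULL
  masks <- vector("list", length(stack$masks))
  for (i in seq_along(stack$masks)) {
    m <- tryCatch(
      if (policy == "nearest" && !is.null(prev)) {
        select_component(stack$masks[[i]], "nearest", prev_centroid = prev)
      } else {
        select_component(stack$masks[[i]], "largest")
      },
      error = function(e) {
        stop("frame ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    idx <- which(m != 0L, arr.ind = TRUE)
    prev <- c(mean(idx[, 2]), mean(idx[, 1]))
    masks[[i]] <- m
  }
  mask_stack(masks, stack$config)
}

# stable CSV schema of the per-frame step table
step_table_columns <- c(
  "frame", "time_s", "centroid_x_um", "centroid_y_um", "area_um2",
  "elongation", "orientation_deg", "smm_deg", "umm_deg", "turning_deg",
  "ma_dynamics_deg", "speed_um_s",
  "flag_zero_displacement", "flag_low_elongation", "flag_no_reference_side",
  "flag_degenerate",
  "smm_label", "smm_sign", "alpha_label", "alpha_sign",
  "dphi_label", "dphi_sign", "eps_label", "behaviour"
)

#' Write the per-frame step table as CSV
#'
#' One row per frame with a fixed, documented column schema (see
#' `morphomig:::step_table_columns`). Descriptors that are undefined at a
#' frame (sMM and M.A. dynamics at the last frame, turning angle at the
#' first and last, anything on a flagged step) are written as empty fields.
#' Columns not present in `track` (e.g. labels on an unlabelled track) are
#' written empty.
#'
#' @param track Data frame of per-frame records, as produced by
#'   [compute_track()], [label_track()] or [annotate_behaviours()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_step_table <- function(track, path) {
  stopifnot(is.data.frame(track))
  out <- as.data.frame(track)
  for (col in setdiff(step_table_columns, names(out))) out[[col]] <- NA
  out <- out[, step_table_columns]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a step table written by [write_step_table()]
#'
#' @param path CSV path.
#' @return A tibble with the step-table schema; empty fields become `NA`.
#' @export
read_step_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(step_table_columns, names(df))
  if (length(missing)) {
    stop("'", path, "' is not a step table; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in grep("^flag_", step_table_columns, value = TRUE)) {
    df[[col]] <- as.logical(df[[col]])
  }
  tibble::as_tibble(df)
}
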