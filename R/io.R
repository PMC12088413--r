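# Stack I/O: multi-page 16-bit TIFF per channel + JSON sidecar carrying
# voxel sizes, identifiers and (optionally) ground truth.

#' Write a stack to disk
#'
#' Writes one multi-page 16-bit TIFF per channel (`hei10.tif`, `asy1.tif`,
#' `zyp1.tif`, z-slices as pages) plus a `cell.json` sidecar with voxel
#' sizes (um, z/y/x), identifiers and any attached ground truth. Intensities
#' are stored as integer counts, so a write/read round trip is exact.
#'
#' @param stack a `stack3c`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "stack3c"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("hei10", "asy1", "zyp1")) {
    arr <- stack[[ch]]
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
  }
  truth <- attr(stack, "truth")
  side <- list(voxel_size_um = stack$voxel_size,
               axis_order = c("z", "y", "x"),
               cell_id = stack$cell_id, plant_id = stack$plant_id,
               genotype = stack$genotype,
               channels = c("hei10", "asy1", "zyp1"))
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, file.path(dir, "cell.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read stacks from disk
#'
#' Reads cell directories written by [write_cell_stack()] (or laid out the
#' same way): three single-channel multi-page TIFFs named by the configured
#' channel map plus a JSON sidecar. Voxel sizes must be present in the
#' sidecar; a missing voxel size is an error, never a silent default.
#'
#' @param path a cell directory, or a directory of cell directories.
#' @param channels named character vector mapping channel roles to file
#'   names (without extension).
#' @return a `stack3c`, or a list of them when `path` holds several cells.
#' @export
read_stacks <- function(path,
                        channels = c(hei10 = "hei10", asy1 = "asy1",
                                     zyp1 = "zyp1")) {
  if (!file.exists(file.path(path, "cell.json"))) {
    subs <- list.dirs(path, recursive = FALSE)
    subs <- subs[file.exists(file.path(subs, "cell.json"))]
    if (!length(subs))
      stop("read_stacks: no cell.json under ", path)
    return(lapply(subs, read_stacks, channels = channels))
  }
  side <- jsonlite::read_json(file.path(path, "cell.json"),
                              simplifyVector = TRUE)
  if (is.null(side$voxel_size_um) || length(side$voxel_size_um) != 3 ||
      any(!is.finite(as.numeric(side$voxel_size_um))))
    stop("read_stacks: missing voxel size metadata in ",
         file.path(path, "cell.json"))
  if (length(channels) != 3)
    stop("read_stacks: exactly 3 channels required, got ", length(channels))
  arrs <- lapply(channels, function(ch) {
    f <- file.path(path, paste0(ch, ".tif"))
    if (!file.exists(f)) stop("read_stacks: missing channel file ", f)
    pages <- tiff::readTIFF(f, all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- round(pages[[z]] * 65535)
    arr
  })
  out <- new_stack3c(arrs[["hei10"]], arrs[["asy1"]], arrs[["zyp1"]],
                     as.numeric(side$voxel_size_um),
                     cell_id = side$cell_id %||% basename(path),
                     plant_id = side$plant_id %||% "plant",
                     genotype = side$genotype %||% "NA")
  if (!is.null(side$truth)) attr(out, "truth") <- side$truth
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
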