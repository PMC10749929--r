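# Dataset manifests, fixture bundle IO, and serialized inter-stage
# alignment state. State files are versioned, self-describing JSON with
# full-precision numbers (no database, by design).

STATE_VERSION <- "emstitch-state-1"

#' Load a tile dataset from a manifest directory
#'
#' Expects `manifest.csv` with columns `section`, `mfov`, `beam`, `x_nm`,
#' `y_nm`, `file` (grayscale PNG paths relative to the directory), an
#' optional `roi.csv` (`section`, `center_x_nm`, `center_y_nm`,
#' `angle_deg`), and an optional `layout.json` written by
#' [write_fixture_bundle()].
#'
#' @param dir dataset directory.
#' @return list of class `emstitch_dataset`: `sections` (list; each a tile
#'   list as used by [montage_section()]), `rois`, `layout`,
#'   `pixel_size_nm`.
#' @export
load_manifest <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("section", "mfov", "beam", "x_nm", "y_nm", "file")
  if (!all(need %in% names(man)))
    stop("manifest schema error: missing column(s) ",
         paste(setdiff(need, names(man)), collapse = ", "))
  if (any(!is.finite(man$x_nm)) || any(!is.finite(man$y_nm)))
    stop("manifest schema error: non-finite coordinates")
  layout <- NULL
  lpath <- file.path(dir, "layout.json")
  if (file.exists(lpath)) {
    lj <- jsonlite::read_json(lpath, simplifyVector = TRUE)
    layout <- hex_layout(n_rings = lj$n_rings,
                         tile_shape_px = lj$tile_shape_px,
                         pixel_size_nm = lj$pixel_size_nm,
                         intra_overlap_nm = lj$intra_overlap_nm,
                         inter_overlap_nm = lj$inter_overlap_nm)
  }
  ps <- if (!is.null(layout)) layout$pixel_size_nm else 16
  sections <- list()
  for (s in sort(unique(man$section))) {
    rows <- man[man$section == s, ]
    tiles <- lapply(seq_len(nrow(rows)), function(k) {
      f <- file.path(dir, rows$file[k])
      if (!file.exists(f)) stop("missing tile image: ", rows$file[k])
      list(image = read_gray_png(f), mfov_id = rows$mfov[k],
           beam_id = rows$beam[k],
           nominal_xy = c(rows$x_nm[k], rows$y_nm[k]),
           pixel_size_nm = ps)
    })
    sections[[as.character(s)]] <- tiles
  }
  rois <- NULL
  rpath <- file.path(dir, "roi.csv")
  if (file.exists(rpath)) {
    rr <- utils::read.csv(rpath, stringsAsFactors = FALSE)
    rois <- lapply(seq_len(nrow(rr)), function(k)
      list(center_nm = c(rr$center_x_nm[k], rr$center_y_nm[k]),
           angle_deg = rr$angle_deg[k]))
  }
  structure(list(sections = sections, rois = rois, layout = layout,
                 pixel_size_nm = ps),
            class = "emstitch_dataset")
}

#' Write a montage fixture as a loadable dataset bundle
#'
#' @param fixture [montage_fixture()] output.
#' @param dir target directory (created).
#' @param section section id to record (default 1).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fixture, dir, section = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(fixture$tiles), function(k) {
    t <- fixture$tiles[[k]]
    fn <- sprintf("s%03d_m%03d_b%03d.png", section, t$mfov_id, t$beam_id)
    write_gray_png(t$image, file.path(dir, fn))
    data.frame(section = section, mfov = t$mfov_id, beam = t$beam_id,
               x_nm = t$nominal_xy[1], y_nm = t$nominal_xy[2], file = fn)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  lay <- fixture$layout
  jsonlite::write_json(list(
    n_rings = (sum(sapply(fixture$tiles, function(t) t$mfov_id == 1)) - 1) %/% 6,
    tile_shape_px = lay$tile_shape_px, pixel_size_nm = lay$pixel_size_nm,
    intra_overlap_nm = lay$intra_overlap_nm,
    inter_overlap_nm = lay$inter_overlap_nm),
    file.path(dir, "layout.json"), auto_unbox = TRUE, digits = I(17))
  jsonlite::write_json(list(seed = fixture$seed,
                            true_xy = fixture$truth$true_xy,
                            offsets = fixture$truth$offsets,
                            blank = fixture$truth$blank),
                       file.path(dir, "truth.json"), digits = I(17))
  invisible(dir)
}

affine_to_list <- function(A) list(linear = as.vector(A$linear),
                                   translation = A$translation)
affine_from_list <- function(l) affine2d(matrix(unlist(l$linear), 2, 2),
                                         unlist(l$translation))

field_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  list(grid = f$grid, active = f$active, u = as.vector(f$u), dim_u = dim(f$u),
       pixel_size_nm = f$pixel_size_nm)
}
field_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  structure(list(grid = matrix(unlist(l$grid), ncol = 2, byrow = TRUE),
                 active = as.logical(unlist(l$active)),
                 u = array(unlist(l$u), unlist(l$dim_u)),
                 pixel_size_nm = l$pixel_size_nm),
            class = "fine_alignment")
}

#' Save / load serialized alignment state
#'
#' A `transform_chain` round-trips losslessly (coordinates bit-exact) through
#' a versioned JSON container; loading a file with a different version tag
#' is an explicit error, never a silent reinterpretation.
#'
#' @param chain `transform_chain`.
#' @param path file path.
#' @return `save_state`: `path` invisibly; `load_state`: the chain.
#' @export
save_state <- function(chain, path) {
  stopifnot(inherits(chain, "transform_chain"))
  obj <- list(
    version = STATE_VERSION,
    n_sections = chain$n_sections,
    bbox_px = chain$bbox_px,
    pixel_size_nm = chain$pixel_size_nm,
    coarse = if (!is.null(chain$coarse)) lapply(chain$coarse, affine_to_list),
    rough = if (!is.null(chain$rough)) lapply(chain$rough, affine_to_list),
    fine = field_to_list(chain$fine),
    ultra = field_to_list(chain$ultra))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("unreadable state file: ",
                                           conditionMessage(e)))
  if (is.null(obj$version) || !identical(obj$version, STATE_VERSION))
    stop("state version mismatch: found '", obj$version %||% "<none>",
         "', expected '", STATE_VERSION, "'")
  transform_chain(
    coarse = if (!is.null(obj$coarse)) lapply(obj$coarse, affine_from_list),
    rough = if (!is.null(obj$rough)) lapply(obj$rough, affine_from_list),
    fine = field_from_list(obj$fine),
    ultra = field_from_list(obj$ultra),
    bbox_px = unlist(obj$bbox_px),
    pixel_size_nm = obj$pixel_size_nm)
}
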