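#' Pipeline configuration with production defaults
#'
#' Returns the full set of numeric pipeline parameters. All lengths are nm.
#' Defaults are the production values for a 16 nm working pixel size; pass
#' overrides as named arguments (or a named list via `overrides`) to adapt to
#' other acquisition geometries or to desk-scale fixtures.
#'
#' Parameter groups:
#' * 2D montaging: two-pass outlier box tolerances (pass 1 intra 768 nm,
#'   inter 15,440 x 13,440 nm; pass 2 intra 64 nm, inter 4,480 nm), grayscale
#'   variance floor 1, replaced-delta weight, feather ramps (0.5 um intra,
#'   3 um inter), 2D blockwise export overlap 8 um.
#' * nxcorr preprocessing: CLAHE clip limit 30 with 32 x 32 tiles and
#'   Laplacian-of-Gaussian sigma 4, both stated at 16 nm pixels and scaled
#'   inversely with pixel size.
#' * brightness/gradient correction: 1 um box filter, 20% large-component
#'   rejection fraction, 3 x 3 sub-tiles, top-32 histogram neighbors, group
#'   size 5,000, rejection quantiles.
#' * rough alignment: Lowe ratio 1.42, RANSAC tolerance 5.12 um, minimum 32
#'   matches, maximum translation 196 um, 25 um grid, 60 um keypoint cutoff,
#'   z-blocks of 721 context / 241 solved sections.
#' * fine / ultrafine: grids 16 um / 2 um, crops 32/4.8 um and 12.8/3.2 um,
#'   neighbors +/-4 / +/-2, rotation sweep +/-15 deg step 3, RANSAC 12 um,
#'   57 um reconsideration diameter, replaced weight 0.5, 61 um affine-filter
#'   box, neighbor weights (1, 1, 0.4, 0.1), L2 0 / 0.05, ROI scale 110%.
#' * export: 8 px block overlap.
#'
#' @param ... named parameter overrides.
#' @param overrides optional named list of overrides (applied before `...`).
#' @return named list of class `emstitch_config`.
#' @export
pipeline_config <- function(..., overrides = NULL) {
  cfg <- list(
    working_pixel_nm   = 16,
    # --- 2D montage outlier passes (box side lengths, nm) ---
    tol_pass1_intra_nm = c(768, 768),
    tol_pass1_inter_nm = c(15440, 13440),
    tol_pass2_intra_nm = c(64, 64),
    tol_pass2_inter_nm = c(4480, 4480),
    variance_floor     = 1,
    replaced_weight_2d = 0.5,
    feather_intra_nm   = 500,
    feather_inter_nm   = 3000,
    export2d_overlap_nm = 8000,
    # --- nxcorr preprocessing (at 16 nm; scaled inversely with pixel size) ---
    clahe_clip         = 30,
    clahe_tile_px      = 32,
    log_sigma_px       = 4,
    # --- 2D gradient / brightness correction ---
    gradient_box_nm    = 1000,
    large_component_frac = 0.20,
    reject_quantiles   = c(0.005, 0.995),
    subtile_grid       = c(3, 3),
    hist_top_n         = 32,
    hist_max_dist      = 0.2,
    subtile_group_size = 5000,
    hist_bins          = 256,
    surface_order      = 2,
    # --- rough alignment ---
    lowe_ratio         = 1.42,
    rough_ransac_tol_nm = 5120,
    min_matches        = 32,
    max_translation_nm = 196000,
    rough_grid_nm      = 25000,
    keypoint_cutoff_nm = 60000,
    block_context      = 721,
    block_solve        = 241,
    rough_n_neighbors  = 4,
    min_keypoint_radius_nm = 0,

    # --- fine / ultrafine ---
    fine_grid_nm       = 16000,
    fine_src_crop_nm   = 32000,
    fine_dst_crop_nm   = 4800,
    fine_n_neighbors   = 4,
    rot_sweep_deg      = seq(-15, 15, by = 3),
    fine_ransac_tol_nm = 12000,
    reconsider_diam_nm = 57000,
    replaced_weight    = 0.5,
    affine_filter_box_nm = 61000,
    neighbor_weights   = c(1.0, 1.0, 0.4, 0.1),
    fine_l2            = 0,
    ultra_grid_nm      = 2000,
    ultra_src_crop_nm  = 12800,
    ultra_dst_crop_nm  = 3200,
    ultra_n_neighbors  = 2,
    ultra_l2           = 0.05,
    roi_scale          = 1.10,
    # --- fine outlier re-admission (neighborhood similarity) ---
    readmit_k          = 3,
    readmit_angle_deg  = 30,
    readmit_rel        = 0.3,
    # --- ransac / mls internals ---
    ransac_iters       = 1000,
    mls_alpha          = 2,
    # --- tissue mask provider ---
    mask_pixel_nm      = 1024,
    # --- export ---
    export_overlap_px  = 8
  )
  ov <- c(overrides, list(...))
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "emstitch_config")
}

#' Load configuration overrides from a flat YAML-like key: value file
#'
#' Accepts a plain text file with `key: value` lines (values parsed with
#' [utils::type.convert]; comma-separated values become numeric vectors).
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return `emstitch_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  ov <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    ov[[key]] <- utils::type.convert(parts, as.is = TRUE)
  }
  pipeline_config(overrides = ov)
}
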