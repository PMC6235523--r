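#' Aligned raster layers for spatial pathway models
#'
#' A `landscape_grid` holds the co-registered per-cell layers the spatial
#' pathways need: a land-cover class, tree cover, soil organic carbon to 1 m,
#' climate normals, conifer fraction, and boolean exclusion masks. All layers
#' share one shape and one cell area; there is no projection handling --
#' the grid is an abstract equal-area lattice.
#'
#' @param land_cover integer or character matrix over
#'   [land_cover_classes()].
#' @param tree_cover numeric matrix, percent canopy cover in \[0, 100\].
#' @param soil_c_1m numeric matrix, Mg C ha^-1 to 1 m depth, >= 0.
#' @param mat numeric matrix, mean annual temperature, deg C.
#' @param map_mm numeric matrix, mean annual precipitation, mm yr^-1, >= 0.
#' @param conifer_frac numeric matrix in \[0, 1\].
#' @param masks named list of logical matrices; recognised names are
#'   `urban`, `impervious`, `major_road`, `histosol`, `protected`. Missing
#'   masks default to all-`FALSE`.
#' @param cell_area_ha area of one cell in hectares.
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(land_cover, tree_cover, soil_c_1m, mat, map_mm,
                           conifer_frac, masks = list(), cell_area_ha = 100) {
  if (is.character(land_cover)) {
    lc <- matrix(match(land_cover, land_cover_classes()),
                 nrow = nrow(land_cover))
    if (anyNA(lc)) stop("unknown land-cover class label")
    land_cover <- lc
  }
  shape <- dim(land_cover)
  layers <- list(land_cover = land_cover, tree_cover = tree_cover,
                 soil_c_1m = soil_c_1m, mat = mat, map_mm = map_mm,
                 conifer_frac = conifer_frac)
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !identical(dim(layers[[nm]]), shape))
      stop(sprintf("layer '%s' does not share the grid shape %dx%d",
                   nm, shape[1], shape[2]))
  }
  if (any(land_cover != round(land_cover)) ||
      any(land_cover < 1 | land_cover > length(land_cover_classes())))
    stop("land_cover codes must be whole numbers in range")
  storage.mode(land_cover) <- "integer"
  layers$land_cover <- land_cover
  if (any(tree_cover < 0 | tree_cover > 100)) stop("tree_cover outside [0, 100]")
  if (any(soil_c_1m < 0)) stop("soil_c_1m must be >= 0")
  if (any(map_mm < 0)) stop("map_mm must be >= 0")
  if (any(conifer_frac < 0 | conifer_frac > 1))
    stop("conifer_frac outside [0, 1]")
  stopifnot(is.numeric(cell_area_ha), cell_area_ha > 0)
  full_masks <- list()
  for (nm in mask_names()) {
    m <- masks[[nm]]
    if (is.null(m)) m <- matrix(FALSE, shape[1], shape[2])
    if (is.numeric(m)) m <- matrix(m != 0, shape[1], shape[2])
    if (!identical(dim(m), shape))
      stop(sprintf("mask '%s' does not share the grid shape", nm))
    full_masks[[nm]] <- m
  }
  unknown <- setdiff(names(masks), mask_names())
  if (length(unknown))
    stop("unknown mask(s): ", paste(unknown, collapse = ", "))
  structure(
    c(layers, list(masks = full_masks, cell_area_ha = cell_area_ha,
                   shape = shape)),
    class = "landscape_grid"
  )
}

#' @rdname landscape_grid
#' @export
land_cover_classes <- function() {
  c("forest", "grassland", "shrubland", "cropland", "pasture", "urban",
    "water", "wetland")
}

mask_names <- function() {
  c("urban", "impervious", "major_road", "histosol", "protected")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells of %g ha (%.4g Mha)\n",
              x$shape[1], x$shape[2], x$cell_area_ha,
              prod(x$shape) * x$cell_area_ha / 1e6))
  tab <- table(factor(land_cover_classes()[x$land_cover],
                      levels = land_cover_classes()))
  cat("  cover:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read and write single layers as ESRI ASCII grids
#'
#' The plain-text `.asc` interchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of whitespace-separated values, northernmost row first.
#'
#' @param path file path ending in `.asc`.
#' @param nodata value written for `NA` cells.
#' @return `read_esri_ascii()` returns a numeric matrix (row 1 = north).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[req]]))
      stop(sprintf("'%s' missing from ESRI ASCII header in %s", req, path))
  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("%s: expected %d values, found %d", path,
                 hdr$ncols * hdr$nrows, length(vals)))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  attr(m, "cellsize") <- hdr$cellsize
  m
}

#' @rdname read_esri_ascii
#' @param m numeric (or logical) matrix to write.
#' @param cellsize cell edge length written to the header (map units).
#' @export
write_esri_ascii <- function(m, path, cellsize = 1000, nodata = -9999) {
  if (is.logical(m)) m <- m * 1L
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %d", as.integer(nodata)))
  body <- apply(m, 1, function(r) {
    r[is.na(r)] <- nodata
    paste(sprintf("%.10g", r), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a landscape as .asc layers plus a YAML manifest
#'
#' Each layer and mask is stored as one ESRI ASCII grid; a `manifest.yml`
#' in the same directory binds layer names to files and records the cell
#' area. Masks are stored as 0/1 grids.
#'
#' @param grid a [landscape_grid()].
#' @param dir output directory (created if needed).
#' @return `read_landscape()` returns the reconstructed [landscape_grid()].
#' @export
write_landscape <- function(grid, dir) {
  stopifnot(inherits(grid, "landscape_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layer_nms <- c("land_cover", "tree_cover", "soil_c_1m", "mat", "map_mm",
                 "conifer_frac")
  manifest <- list(cell_area_ha = grid$cell_area_ha, layers = list(),
                   masks = list())
  cellsize <- sqrt(grid$cell_area_ha * 1e4)  # metres, for the .asc header
  for (nm in layer_nms) {
    f <- paste0(nm, ".asc")
    write_esri_ascii(grid[[nm]], file.path(dir, f), cellsize = cellsize)
    manifest$layers[[nm]] <- f
  }
  for (nm in mask_names()) {
    f <- paste0("mask_", nm, ".asc")
    write_esri_ascii(grid$masks[[nm]], file.path(dir, f), cellsize = cellsize)
    manifest$masks[[nm]] <- f
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  get_layer <- function(f) unclass(read_esri_ascii(file.path(dir, f)))
  layers <- lapply(manifest$layers, function(f) {
    m <- get_layer(f); attr(m, "cellsize") <- NULL; m
  })
  masks <- lapply(manifest$masks, function(f) {
    m <- get_layer(f); attr(m, "cellsize") <- NULL; m != 0
  })
  landscape_grid(land_cover = layers$land_cover,
                 tree_cover = layers$tree_cover,
                 soil_c_1m = layers$soil_c_1m,
                 mat = layers$mat, map_mm = layers$map_mm,
                 conifer_frac = layers$conifer_frac,
                 masks = masks, cell_area_ha = manifest$cell_area_ha)
}
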