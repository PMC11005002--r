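#' @include model.R
NULL

#' Write a field snapshot
#'
#' Stores all fields losslessly in a compressed single-file container
#' (RDS) together with a manifest (time, step, energy breakdown, config
#' hash). The write is atomic with respect to readers: data go to a
#' `<path>.incomplete` file first and are renamed on success, and
#' [readSnapshot()] refuses files whose marker is still present.
#'
#' @param state a [FieldState-class].
#' @param path destination file (conventionally `.rds`).
#' @param grid the [SimGrid-class] (stored for spacing/origin metadata).
#' @param step integer step number for the manifest.
#' @param energy optional [EnergyBreakdown-class] for the manifest.
#' @param configHash optional provenance hash string.
#' @param vti also export a VTK image-data volume next to `path`.
#' @return `path`, invisibly.
#' @export
writeSnapshot <- function(state, path, grid = NULL, step = NA_integer_,
                          energy = NULL, configHash = NA_character_,
                          vti = FALSE) {
  payload <- list(
    state = state,
    grid = if (is.null(grid)) NULL else list(shape = grid@shape,
                                             spacing = grid@spacing,
                                             boundary = grid@boundary),
    manifest = list(time = state@time, step = step,
                    energy = if (is.null(energy)) NULL
                             else as.list(energyComponents(energy)),
                    energyTotal = if (is.null(energy)) NULL
                                  else totalEnergy(energy),
                    configHash = configHash))
  tmp <- paste0(path, ".incomplete")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  saveRDS(payload, tmp)
  if (!file.rename(tmp, path))
    stop("failed to finalize snapshot ", path)
  ok <- TRUE
  if (vti && !is.null(grid)) {
    fields <- c(stats::setNames(state@phi,
                                paste0("phi", seq_along(state@phi))),
                list(psi1 = state@psi1, psi2 = state@psi2,
                     eta = state@eta))
    writeVTI(fields, grid, paste0(tools::file_path_sans_ext(path), ".vti"))
  }
  invisible(path)
}

#' Read a snapshot written by [writeSnapshot()]
#'
#' @param path snapshot file.
#' @return list with components `state` ([FieldState-class]), `grid`
#'   metadata, and `manifest`.
#' @export
readSnapshot <- function(path) {
  if (endsWith(path, ".incomplete") || file.exists(paste0(path, ".incomplete")))
    stop("snapshot ", path, " is marked incomplete; refusing to read")
  if (!file.exists(path)) stop("snapshot not found: ", path)
  readRDS(path)
}

#' Export scalar fields as a VTK image-data (.vti) volume
#'
#' Writes one XML VTK ImageData file with one point-data scalar array per
#' field, placed at voxel centers: origin = spacing/2, spacing = the
#' grid spacing. ASCII encoding — portable and diffable, at the cost of
#' size; intended for external 3D viewers.
#'
#' @param fields named list of 3D arrays sharing the grid shape.
#' @param grid a [SimGrid-class].
#' @param path destination `.vti` file.
#' @return `path`, invisibly.
#' @export
writeVTI <- function(fields, grid, path) {
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    stop("fields must be a named list")
  s <- grid@shape; h <- grid@spacing
  con <- file(path, open = "wt")
  on.exit(close(con))
  ext <- sprintf("0 %d 0 %d 0 %d", s[1] - 1L, s[2] - 1L, s[3] - 1L)
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="%s" Origin="%.9g %.9g %.9g" Spacing="%.9g %.9g %.9g">',
            ext, h[1] / 2, h[2] / 2, h[3] / 2, h[1], h[2], h[3]),
    sprintf('    <Piece Extent="%s">', ext),
    sprintf('      <PointData Scalars="%s">', names(fields)[1])), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!identical(dim(f), as.integer(s)) && !identical(dim(f), s))
      stop("field '", nm, "' does not match the grid shape")
    writeLines(sprintf(
      '        <DataArray type="Float32" Name="%s" format="ascii">', nm),
      con)
    # x varies fastest in both R arrays and VTK ImageData
    writeLines(paste(formatC(as.vector(f), format = "g", digits = 7),
                     collapse = " "), con)
    writeLines('        </DataArray>', con)
  }
  writeLines(c('      </PointData>', '    </Piece>', '  </ImageData>',
               '</VTKFile>'), con)
  invisible(path)
}

#' Write per-droplet metrics to CSV
#'
#' @param droplets a [DropletSet-class].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeDropletsCsv <- function(droplets, path) {
  utils::write.csv(dropletTable(droplets), path, row.names = FALSE)
  invisible(path)
}

#' Write a radial profile to CSV
#'
#' @param profile a [RadialProfile-class].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a morphology call to JSON
#'
#' @param call a [MorphologyCall-class].
#' @param path destination JSON.
#' @return `path`, invisibly.
#' @export
writeMorphologyJson <- function(call, path) {
  jsonlite::write_json(list(regime = regime(call),
                            evidence = morphologyEvidence(call)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
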