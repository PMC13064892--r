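#' Write an image field as a multi-page TIFF with a sidecar
#'
#' Pages are ordered channel-major (for each channel, all z planes), with
#' channel order as in `field$channel_roles`. Pixel data are stored as
#' 32-bit float after division by a scale factor recorded in the sidecar
#' YAML (`<path>.yaml`), so values round-trip at single precision. The
#' sidecar also records channel roles, z-plane count and the field's
#' condition/replicate labels.
#'
#' @param field An `image_field` (see [generate_field()]).
#' @param path Output TIFF path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  pix <- field$pixels
  lo <- min(pix); hi <- max(pix)
  offset <- if (lo < 0) lo else 0
  scale <- max(hi - offset, 1e-12)
  pages <- list()
  for (ch in seq_along(field$channel_roles))
    for (z in seq_len(field$n_z))
      pages[[length(pages) + 1L]] <- (pix[ch, z, , ] - offset) / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(channel_roles = as.list(field$channel_roles),
               n_z = field$n_z, scale = scale, offset = offset,
               condition = field$condition,
               replicate = field$replicate,
               field_id = field$field_id)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image field from a multi-page TIFF
#'
#' Reads pixel data without any rescaling or normalization beyond undoing
#' the storage scale recorded in the sidecar (the quantification contract
#' is to operate on unprocessed images). Channel roles and z layout come
#' from the sidecar when present, otherwise from `channel_role_map` and
#' `n_z`.
#'
#' @param path TIFF path (sidecar at `<path>.yaml` if written by
#'   [write_field()]).
#' @param channel_role_map Character vector of channel roles in page
#'   order; overrides the sidecar if given.
#' @param n_z Number of z planes per channel (sidecar default 1).
#' @param required_roles Roles that must be present; defaults to the three
#'   channels fixed-cell quantification needs.
#' @return An `image_field`.
#' @export
read_field <- function(path, channel_role_map = NULL, n_z = NULL,
                       required_roles = c("dna", "reference", "target")) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  roles <- if (!is.null(channel_role_map)) channel_role_map
           else unlist(meta$channel_roles)
  if (is.null(roles))
    stop("no channel role map: give 'channel_role_map' or a sidecar")
  nz <- if (!is.null(n_z)) as.integer(n_z)
        else if (!is.null(meta$n_z)) as.integer(meta$n_z) else 1L
  missing_roles <- setdiff(required_roles, roles)
  if (length(missing_roles) > 0)
    stop("channel role map is missing required role(s): ",
         paste(missing_roles, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(roles) * nz)
    stop("TIFF has ", length(pages), " pages but the layout declares ",
         length(roles), " channels x ", nz, " z planes")
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  offset <- if (!is.null(meta$offset)) meta$offset else 0
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  pix <- array(0, dim = c(length(roles), nz, nr, nc))
  p <- 0L
  for (ch in seq_along(roles))
    for (z in seq_len(nz)) {
      p <- p + 1L
      pix[ch, z, , ] <- pages[[p]] * scale + offset
    }
  structure(
    list(pixels = pix, channel_roles = roles, n_z = nz,
         condition = if (!is.null(meta$condition)) meta$condition else NA,
         replicate = if (!is.null(meta$replicate)) meta$replicate else NA,
         field_id = if (!is.null(meta$field_id)) meta$field_id
                    else basename(path)),
    class = "image_field")
}

#' Maximum-intensity projection of an image field
#'
#' Per channel, each output pixel is the maximum over z of that pixel.
#' All fixed-cell quantification in this package runs on such
#' projections. Metadata are preserved; a single-plane field is returned
#' unchanged apart from copying.
#'
#' @param field An `image_field` with >= 1 z plane.
#' @return An `image_field` with z size 1.
#' @export
max_project <- function(field) {
  stopifnot(inherits(field, "image_field"), field$n_z >= 1)
  d <- dim(field$pixels)
  out <- array(0, dim = c(d[1], 1L, d[3], d[4]))
  for (ch in seq_len(d[1])) {
    m <- field$pixels[ch, 1, , ]
    if (d[2] > 1)
      for (z in 2:d[2]) m <- pmax(m, field$pixels[ch, z, , ])
    out[ch, 1, , ] <- m
  }
  field$pixels <- out
  field$n_z <- 1L
  field
}

#' Extract one channel of a projected field as a matrix
#'
#' @param field An `image_field` with a single z plane.
#' @param role Channel role name.
#' @return A numeric matrix (row, col).
#' @export
get_channel <- function(field, role) {
  stopifnot(inherits(field, "image_field"))
  if (field$n_z != 1L)
    stop("field has ", field$n_z, " z planes; call max_project() first")
  i <- match(role, field$channel_roles)
  if (is.na(i)) stop("field has no channel with role '", role, "'")
  field$pixels[i, 1, , ]
}
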