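## Marker keep-list and segment-mass configuration.
##
## The analysis mirrors every left-foot-in-front trial about the sagittal
## plane, so only markers that are symmetric under a left/right swap can be
## retained: bilateral L*/R* pairs plus midline markers (which map to
## themselves). The default 28-marker subset and its relative segment-mass
## weights ship as a YAML config and can be overridden per run.

.config_cache <- new.env(parent = emptyenv())

.load_default_config <- function() {
  if (is.null(.config_cache$cfg)) {
    path <- system.file("extdata", "plugin_gait_config.yaml",
                        package = "posturePMA", mustWork = TRUE)
    .config_cache$cfg <- yaml::read_yaml(path)
  }
  .config_cache$cfg
}

#' Default symmetric marker set
#'
#' The 28-marker symmetric subset of the Plug-in-Gait full-body set (hands
#' and asymmetric offset markers omitted) used when no keep-list is supplied.
#'
#' @return character vector of 28 marker labels.
#' @export
defaultMarkerSet <- function() {
  as.character(.load_default_config()$markers)
}

#' Default segment-mass table
#'
#' Relative segment-mass weights per marker (Winter anthropometric
#' proportions, each segment's mass split equally among that segment's
#' retained markers). Weights sum to 1 over [defaultMarkerSet()].
#'
#' @return named numeric vector of weights.
#' @export
defaultMassTable <- function() {
  m <- unlist(.load_default_config()$masses)
  m[defaultMarkerSet()]
}

#' Read a marker/mass configuration from YAML
#'
#' @param path YAML file with top-level keys \code{markers} (keep-list) and
#'   \code{masses} (label -> relative mass).
#' @return list with \code{markers} (character) and \code{masses} (named
#'   numeric).
#' @export
readMarkerConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$markers) || is.null(cfg$masses))
    stop("marker config must contain 'markers' and 'masses'")
  masses <- unlist(cfg$masses)
  list(markers = as.character(cfg$markers), masses = masses)
}

#' Normalize a segment-mass table over a retained marker set
#'
#' Subsets the weights to \code{markers} and rescales them to sum to 1.
#'
#' @param masses named numeric vector of relative masses.
#' @param markers character vector of retained marker labels.
#' @return named numeric vector over \code{markers}, summing to 1.
#' @export
normalizeMasses <- function(masses, markers) {
  miss <- setdiff(markers, names(masses))
  if (length(miss))
    stop("no segment-mass weight for marker(s): ", paste(miss, collapse = ", "))
  w <- masses[markers]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("segment-mass weights must be positive and finite")
  w / sum(w)
}

## Column labels "<MARKER>_X" etc. for a marker vector, in stable order.
.coordColumns <- function(markers) {
  as.vector(t(outer(markers, c("X", "Y", "Z"), paste, sep = "_")))
}

## Mirror partner of each label: swap leading L <-> R for bilateral markers,
## midline markers map to themselves.
.mirrorLabel <- function(labels) {
  out <- labels
  isL <- grepl("^L", labels)
  isR <- grepl("^R", labels)
  out[isL] <- sub("^L", "R", labels[isL])
  out[isR] <- sub("^R", "L", labels[isR])
  out
}
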