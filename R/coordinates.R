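#' Fixed-site coordinate system of the bHLH domain
#'
#' The bHLH domain is enumerated on a fixed site numbering: the DNA-binding
#' basic region occupies sites 1-13, Helix 1 sites 14-28, Helix 2 sites 50-64,
#' and the variable-length loop the nominal sites 29-49. Only the 43 fixed
#' sites (basic and the two helices) enter numeric datasets and classifiers;
#' loop residues may be stored but are never modelled.
#'
#' @param basic,helix1,loop,helix2 Integer site ranges for the four
#'   subdomains. Defaults give the standard bHLH numbering.
#'
#' @return A \code{BhlhCoordinateMap} object.
#' @aliases BhlhCoordinateMap-class
#' @name BhlhCoordinateMap
#' @export
#' @examples
#' map <- BhlhCoordinates()
#' fixedSites(map)
BhlhCoordinates <- function(basic = 1:13, helix1 = 14:28, loop = 29:49,
                            helix2 = 50:64) {
  new("BhlhCoordinateMap",
      basic = as.integer(basic), helix1 = as.integer(helix1),
      loop = as.integer(loop), helix2 = as.integer(helix2))
}

#' Fixed (modelled) sites of a coordinate map
#'
#' @param x A \code{BhlhCoordinateMap} or \code{EnumeratedAlignment}.
#' @return Integer vector of fixed site indices (43 for the default map).
#' @name fixedSites
#' @export
setMethod("fixedSites", "BhlhCoordinateMap", function(x) {
  c(x@basic, x@helix1, x@helix2)
})

#' @rdname fixedSites
#' @export
setMethod("fixedSites", "EnumeratedAlignment", function(x) fixedSites(x@map))

#' Sites of one subdomain
#'
#' @param map A \code{BhlhCoordinateMap}.
#' @param subdomain One of \code{"basic"}, \code{"helix1"}, \code{"loop"},
#'   \code{"helix2"}.
#' @return Integer site indices.
#' @export
subdomainSites <- function(map, subdomain = c("basic", "helix1", "loop",
                                              "helix2")) {
  subdomain <- match.arg(subdomain)
  slot(map, subdomain)
}

setMethod("show", "BhlhCoordinateMap", function(object) {
  cat("BhlhCoordinateMap\n")
  fmt <- function(x) sprintf("%d-%d (%d sites)", min(x), max(x), length(x))
  cat("  basic : ", fmt(object@basic), "\n", sep = "")
  cat("  helix1: ", fmt(object@helix1), "\n", sep = "")
  cat("  loop  : ", fmt(object@loop), " [not modelled]\n", sep = "")
  cat("  helix2: ", fmt(object@helix2), "\n", sep = "")
})
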